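---
title: "Recovering free-energy profiles from steered-dynamics work ensembles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering free-energy profiles from steered-dynamics work ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smdpmf)
```

## The problem

Reactive events such as proton transfer or covalent-bond rearrangement are
far too rare to observe in unbiased molecular dynamics. Steered molecular
dynamics (SMD) forces progress along a chosen collective variable (CV) with
a moving restraint, but the resulting trajectories are driven out of
equilibrium and the accumulated restraint work overestimates the free-energy
change. The Jarzynski equality,

$$ e^{-\beta \Delta F(\lambda)} = \left\langle e^{-\beta W(\lambda)}
\right\rangle, $$

repairs this: the *exponential* average of the work over replicate
realizations of the same steering protocol recovers the equilibrium
potential of mean force (PMF) along the control parameter $\lambda$. In
practice only a handful of replicates are affordable (thirty is typical for
QM/MM work), and the finite-sample exponential average is biased high. This
package implements the full chain -- CV definition, replicate steering,
work accumulation, exponential averaging, finite-sample bias correction
with an error band, and barrier readout -- on small Langevin model systems
whose free energies are known exactly, so that every stage can be validated
against an analytic or quadrature oracle rather than against another
simulation.

## Collective variables and restraints

The CV class is the linear combination of interatomic distances (LCOD),
$\xi(r) = \sum_i c_i\,\lVert r_{a_i} - r_{b_i}\rVert$, specified as atom
pairs plus signed coefficients (`lcod_spec()`). With pairs
$(\mathrm{D},\mathrm{H})$, $(\mathrm{A},\mathrm{H})$ and coefficients
$(+1,-1)$ it is the classic proton-transfer coordinate: negative while the
hydrogen is donor-bound, zero at the donor--acceptor midpoint, positive
after transfer. Repeated atoms are allowed and their gradient contributions
accumulate; a pair at exactly zero separation contributes zero to the value
but has no defined gradient, which the package treats as an error for any
force evaluation.

Steering applies a harmonic path restraint $U(r;\lambda) =
\tfrac{k}{2}(\xi(r)-\lambda)^2$ with $\lambda(t)$ moving linearly between
its endpoints. The default $k = 1000$ kcal mol$^{-1}$ Å$^{-2}$ is chosen so
that the restraint energy at a lag of 0.1 Å (50 kcal/mol) exceeds any
barrier in the model landscapes by an order of magnitude; with soft springs
the CV lags the target and then catches up in discontinuous jumps, which
corrupts the work integral (see the diagnostics below). A flat-well
spherical restraint (zero inside a radius, harmonic walls outside;
`flat_well_restraint()`) keeps a satellite atom near a center without
biasing its interior motion; the defaults (radius 3 Å, walls 10 kcal
mol$^{-1}$ Å$^{-2}$) implement a weak containment appropriate for holding a
reagent near a reaction center.

## Model systems and their oracles

`make_system()` builds four one-dimensional Langevin systems. Keeping the
mobile coordinate one-dimensional is deliberate: the marginal Boltzmann
density along the CV then has a constant Jacobian, so the exact PMF equals
the site potential and every estimator test has a closed-form or
quadrature answer (`exact_free_energy()`, `exact_pmf()`,
`boltzmann_density()`).

* **dragged_harmonic_trap** -- a free particle whose distance to an anchor
  is steered. Translation on a uniform landscape costs nothing, so
  $\Delta F = 0$ identically: a null test for the whole chain.
* **stiffness_switch** -- the control parameter is the stiffness of a
  harmonic well, switched from $k_1$ to $k_2 = e^2 k_1$. The Gaussian
  partition function gives $\Delta F = \tfrac{1}{2} k_BT \ln(k_2/k_1) =
  1\,k_BT$ exactly.
* **quartic_double_well** -- $V_0\big(((x-c)/a)^2 - 1\big)^2$ with
  $V_0 = 3$ kcal/mol ($\approx 5\,k_BT$ at 300 K), minima 2 Å apart; the
  steered PMF is compared point-by-point against the potential.
* **three_atom_transfer** -- collinear donor--H--acceptor (2.8 Å apart,
  bonded minima at 1.0 Å) with a 3.5 kcal/mol interior barrier. At 300 K
  the hydrogen hops spontaneously a few times per 100 ps, which exercises
  the unforced-event machinery at a realistic rarity relative to the frame
  interval.

Temperature defaults to 300 K everywhere; energies are kcal/mol, lengths Å,
times ps, and $k_B = 0.0019872041$ kcal mol$^{-1}$ K$^{-1}$.

What the generator emulates: thermal motion at fixed temperature,
snapshot-based replicate initialization from a restrained run,
per-replicate seeds, work accumulation against a moving restraint, rare
unforced barrier crossings, and the lag/jump phenomenology of soft springs.
What it does not emulate: electronic structure (bond making/breaking
energetics), solvent, multidimensional coupling, periodic boundaries, or
inertia-dominated dynamics. Passing tests therefore demonstrate that the
*estimators and protocol logic* are correct, not that any particular
chemical barrier height is right -- on real systems the engine behind the
work ensemble would be a QM/MM code, with this package consuming its work
functions unchanged via `work_ensemble()`/`read_work_ensemble()`.

## Integration and work accumulation

The default integrator is overdamped Euler--Maruyama,
$x_{n+1} = x_n + \Delta t\,F_n/\gamma + \sqrt{2k_BT\Delta t/\gamma}\,\xi_n$,
which is the simplest scheme whose stationary statistics can be verified
directly (its variance error is $O(\Delta t\,k/\gamma)$ and the defaults
keep $\Delta t\,k/\gamma \le 0.1$ for the stiffest force constant present;
the equipartition test pins this at the percent level). An underdamped
BAOAB variant is available for users who want inertial dynamics. Time steps
are chosen per system from this stability criterion -- e.g. $10^{-4}$ ps
under a $k = 1000$ restraint -- rather than inherited from any particular
molecular force field; the packaged reference-protocol configuration keeps
the conventional 0.5 fs × 2,000,000 steps bookkeeping of production QM/MM
runs for its arithmetic.

Work is accumulated per integrator step by a midpoint rule in $\lambda$:
$\mathrm{d}W_n = \left.\partial U/\partial\lambda\right|_{x_n,
\bar\lambda_n} (\lambda_{n+1}-\lambda_n)$ with $\bar\lambda_n$ the midpoint
of the step's $\lambda$ increment, evaluated at the pre-step state; the
system then propagates under $\lambda_{n+1}$. For the CV restraint
$\partial U/\partial\lambda = -k(\xi - \lambda)$; when the control
parameter is itself a potential parameter (the stiffness switch),
$\partial U/\partial\lambda = (x - x_c)^2/2$. The rule is exact for a
constant integrand, which makes $W \equiv 0$ *exactly* under a static
target -- a property the tests assert, and the reason the first row of
every work ensemble is identically zero. Supporting both control modes is
a deliberate generalization: the steering machinery is agnostic about
whether $\lambda$ moves a restraint or reshapes the Hamiltonian, and the
stiffness switch provides the one nontrivial closed-form $\Delta F$ in the
suite.

Replicates start from snapshots written every `snapshot_interval` steps of
an equilibrium run restrained at $\lambda_0$, and each replicate carries
its own explicit integer seed (recorded in all outputs). Explicit seeds are
a deliberate departure from wall-clock seeding: they make ensembles exactly
reproducible, which the byte-identity tests rely on, while still
decorrelating replicates.

## Bias correction and the error band

With $N$ replicates the Jarzynski estimator $\Delta F_{JE} = -k_BT\ln
\frac1N\sum_i e^{-W_i/k_BT}$ (computed by log-sum-exp; stable for $|W|$ up
to $10^4\,k_BT$) is biased above the truth, the more so the larger the
dissipated work $W_{dis} = \bar W - \Delta F$. The correction backend
models the work distribution as Gaussian with the fluctuation--dissipation
variance $\sigma_W^2 = 2k_BT\,W_{dis}$ -- the standard near-equilibrium
model under which the published correction procedures were derived -- and
subtracts the *exact* expected bias of the finite-$N$ estimator under that
model. For moderate $N$ this expectation (and the estimator's mean-square
error, reported as the RMSE band around the corrected curve) is computed
numerically on a frozen normal design, making the correction a
deterministic function of its inputs; for large $N$ the delta-method
asymptote $B \approx (e^{2w}-1)/2N$ (in $k_BT$ units, $w = W_{dis}/k_BT$)
takes over. Because the raw estimate itself underestimates $W_{dis}$, the
dissipated work is iterated to self-consistency, $\hat W_{dis} = \bar W -
\Delta F_{BC}$. The correction vanishes exactly when all works are equal
and decays as $1/N$; on the Gaussian benchmark with $W_{dis} = 2\,k_BT$
and $N = 30$ it removes over 90% of the raw bias (the Monte-Carlo oracle
in the test suite measures this directly, which is also how the backend is
validated -- against simulation, not against printed constants). The band
is drawn symmetrically as $\Delta F_{BC} \pm \sqrt{\mathrm{MSE}}$.

Two caveats are honest and documented: the Gaussian model is an
approximation for strongly dissipative, non-Gaussian work distributions
(where no small-sample correction is reliable anyway), and the RMSE band is
a one-standard-error statement, so roughly one run in three will miss a
known answer by more than the band -- it is an error bar, not a bound.

## Steering diagnostics

`steering_diagnostics()` quantifies restraint quality per replicate: the
maximum lag $|\xi - \lambda|$, the fraction of frames within four
equilibrium restraint widths $\sigma = \sqrt{k_BT/k}$ (flagged `lagging`
below 95%), the largest inter-frame CV jump (flagged `discontinuous` above
ten widths), and the slope of achieved-versus-target. The ten-width
threshold operationalizes the qualitative "catch-up jump" failure mode: a
spring that lets the CV stick in a well and then snap across. A
force-balance argument sets the regime where the flag must fire: sticking
requires the maximum landscape force to exceed the spring force at a lag of
order the inter-well distance $d$, while flagging requires $d >
10\sqrt{k_BT/k}$; for a $V_0 = 20$ kcal/mol well pair 2 Å apart this puts
$k \sim 50$ kcal mol$^{-1}$ Å$^{-2}$ squarely in the jump regime, and the
test suite constructs exactly that failure case (and verifies that the
default stiff spring does not fire).

## Transfer events and pathway classification

`detect_events()` finds sign changes of a transfer coordinate that escape a
hysteresis band $\pm h$ and persist: the series must have been beyond the
band on the opposite side, and the new side must hold for at least
`min_dwell_frames` consecutive frames or to the end of the series. The
defaults $h = 0.1$ Å and four frames suppress thermal recrossing noise at
the model systems' amplitudes; both are configurable because real analyses
may need different dead bands. Two events from different coordinates are
"concomitant" when their crossings fall within one sampling interval
(2.5 ps in the reference protocol) -- at that resolution the partial
reactions are simultaneous.

`classify_pathway()` combines three difference coordinates (acid→water,
water→acceptor, acid→acceptor) into a label: `water_mediated` when both
water-involving transfers occur, `direct` when only the acid→acceptor
transfer occurs, `none` otherwise, with an ambiguity flag rather than an
error when both patterns appear. The final-frame nearest-heavy-atom
assignment of each hydrogen is reported as provenance, mirroring how
product structures are identified by atom naming in practice. One known
limitation of pure difference coordinates: $d(\mathrm{D},\mathrm{H}) -
d(\mathrm{X},\mathrm{H})$ can turn positive merely because the hydrogen
moved far from the donor, not because it reached X; classification is
therefore most reliable when the candidate sites are not collinear with
the transfer path, and the water→acceptor coordinate (which requires the
water's own hydrogen to move) is the discriminating signal.

## Problem sizes and determinism

The shipped tests and the acceptance script run the estimator studies at
desk scale: $N = 30$ replicates of $10^4$ steps for the stiffness switch,
$2\times10^5$ steps for the trap and double well (dissipated work a few
tenths of $k_BT$, i.e. near-quasi-static), $10^5$ retained samples for the
equipartition check, $10^4$ Monte-Carlo ensembles for the bias benchmark,
and 250 ps of unforced three-atom dynamics for event detection. These sizes
were chosen so each oracle comparison has Monte-Carlo error comfortably
below its stated tolerance. All randomness flows through explicit seeds:
identical configuration plus identical seeds gives byte-identical tabular
outputs, and the bias backend's internal design is frozen, so estimates are
reproducible functions of the data.

## Known limitations

One-directional Jarzynski averaging only (no two-sided or
bridge estimators); no weighted-histogram analysis; LCOD is the only CV
class; the toy engine is classical, non-periodic and one-dimensional per
mobile atom; nuclear quantum effects are out of scope. The headline outputs
on real systems -- barrier heights in kcal/mol -- inherit whatever level of
theory produced the work functions; this package only guarantees that the
averaging, correction and readout applied to them are right.
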