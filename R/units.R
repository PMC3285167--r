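#' Physical constants and unit conventions
#'
#' The package works in AMBER-style units throughout: lengths in angstroms
#' (\eqn{\mathrm{\AA}}), energies in kcal/mol, time in picoseconds,
#' temperature in kelvin. `boltzmann_kcal` is Boltzmann's constant in
#' kcal/(mol K).
#'
#' @format A length-one numeric.
#' @export
boltzmann_kcal <- 0.0019872041

#' Thermal energy kT
#'
#' @param temperature Temperature in kelvin.
#' @return kT in kcal/mol.
#' @export
kT <- function(temperature) boltzmann_kcal * temperature

# log(mean(exp(x))) without overflow
logmeanexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(mean(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)

# run expr with a private, fixed RNG stream; user RNG state untouched
with_private_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
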