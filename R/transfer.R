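#' Proton-transfer coordinate series from a trajectory
#'
#' The transfer coordinate is \eqn{d(\mathrm{donor},H) -
#' d(\mathrm{acceptor},H)}: negative while the hydrogen is donor-bound,
#' zero at the midpoint of the donor--acceptor axis, positive after
#' transfer. It is exactly the LCOD with pairs (donor, H), (acceptor, H)
#' and coefficients (+1, -1). The same machinery describes heavy-atom
#' departure coordinates by placing the departing atom in the hydrogen
#' slot.
#'
#' @param trajectory A `trajectory` object (see [simulate_system()]) or any
#'   list with `times` and `coords` (frames x atoms x 3).
#' @param donor,hydrogen,acceptor Atom indices.
#' @return An object of class `transfer_series`: `times` (ps), `values`
#'   (angstrom), atom identities, `sampling_interval`.
#' @export
transfer_coordinate <- function(trajectory, donor, hydrogen, acceptor) {
  co <- trajectory$coords
  na <- dim(co)[2]
  if (any(c(donor, hydrogen, acceptor) > na) ||
      any(c(donor, hydrogen, acceptor) < 1))
    stopf("atom index out of range (trajectory has %d atoms)", na)
  dDH <- sqrt(rowSums((co[, donor, , drop = FALSE] -
                         co[, hydrogen, , drop = FALSE])^2, dims = 1))
  dAH <- sqrt(rowSums((co[, acceptor, , drop = FALSE] -
                         co[, hydrogen, , drop = FALSE])^2, dims = 1))
  times <- trajectory$times
  si <- trajectory$sampling_interval %||%
    (if (length(times) > 1) times[2] - times[1] else NA_real_)
  structure(list(times = times, values = as.numeric(dDH - dAH),
                 donor = donor, hydrogen = hydrogen, acceptor = acceptor,
                 sampling_interval = si),
            class = "transfer_series")
}

#' @export
print.transfer_series <- function(x, ...) {
  cat(sprintf(
    "transfer coordinate d(%d,%d) - d(%d,%d): %d frames, range [%.3g, %.3g]\n",
    x$donor, x$hydrogen, x$acceptor, x$hydrogen, length(x$values),
    min(x$values), max(x$values)))
  invisible(x)
}

#' Detect sustained transfer events in a coordinate series
#'
#' An event is a sign change of the transfer coordinate that escapes a
#' hysteresis band \eqn{\pm h} and persists: the series must previously have
#' been beyond the band on the opposite side, and after the crossing it must
#' stay beyond the band for at least `min_dwell_frames` consecutive frames
#' (or to the end of the series). Shorter excursions are thermal
#' recrossings and are discarded. Events are returned time-ordered.
#'
#' @param series A [transfer_coordinate()] result (or list with `times`,
#'   `values`).
#' @param min_dwell_frames Minimum post-crossing dwell, frames (default 4).
#' @param hysteresis Half-width \eqn{h} of the dead band, angstrom
#'   (default 0.1).
#' @return A data.frame of class `transfer_events` with columns
#'   `crossing_time`, `frame`, `direction` (`"forward"` = donor to
#'   acceptor), `pre_dwell`, `post_dwell`.
#' @export
detect_events <- function(series, min_dwell_frames = 4L, hysteresis = 0.1) {
  v <- series$values
  if (length(v) == 0L) stopf("empty coordinate series")
  tm <- series$times
  s <- integer(length(v))
  s[v >= hysteresis] <- 1L
  s[v <= -hysteresis] <- -1L
  ev <- list()
  side <- 0L       # last armed side
  side_len <- 0L   # length of the run that armed it
  i <- 1L
  n <- length(v)
  while (i <= n) {
    if (s[i] == 0L) { i <- i + 1L; next }
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    run_len <- j - i + 1L
    sustained <- run_len >= min_dwell_frames || j == n
    if (side != 0L && s[i] != side && sustained) {
      ev[[length(ev) + 1L]] <- data.frame(
        crossing_time = tm[i], frame = i,
        direction = if (s[i] == 1L) "forward" else "reverse",
        pre_dwell = side_len, post_dwell = run_len)
    }
    if (sustained || side == 0L) { side <- s[i]; side_len <- run_len }
    i <- j + 1L
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(crossing_time = numeric(), frame = integer(),
               direction = character(), pre_dwell = integer(),
               post_dwell = integer())
  class(out) <- c("transfer_events", "data.frame")
  out
}

#' Pair events from two coordinate series within a time window
#'
#' Flags pairs of events whose crossing times differ by at most `window`
#' as concomitant within the sampling resolution (the default window is one
#' trajectory sampling interval).
#'
#' @param events_a,events_b [detect_events()] results.
#' @param window Pairing window (ps); must be > 0.
#' @return data.frame with `time_a`, `time_b`, `dt` and `concomitant`
#'   (logical), one row per cross-pair (empty if either list is empty).
#' @export
concomitance <- function(events_a, events_b, window) {
  if (window <= 0) stopf("concomitance window must be > 0")
  if (nrow(events_a) == 0L || nrow(events_b) == 0L)
    return(data.frame(time_a = numeric(), time_b = numeric(),
                      dt = numeric(), concomitant = logical()))
  g <- expand.grid(a = seq_len(nrow(events_a)), b = seq_len(nrow(events_b)))
  dt <- abs(events_a$crossing_time[g$a] - events_b$crossing_time[g$b])
  data.frame(time_a = events_a$crossing_time[g$a],
             time_b = events_b$crossing_time[g$b],
             dt = dt, concomitant = dt <= window)
}

#' Classify a dehydration/transfer pathway
#'
#' Given role assignments -- a protonated donor acid (donor heavy atom and
#' its acidic hydrogen), an intermediate water (oxygen and a transferable
#' hydrogen) and the final acceptor -- the trajectory is classified as:
#' `"water_mediated"` if sustained acid-to-water and water-to-acceptor
#' events both occur (any order; their concomitance is reported),
#' `"direct"` if a single acid-to-acceptor event occurs with no water
#' events, and `"none"` otherwise. If both patterns are present the label
#' is `"water_mediated"` with `ambiguous = TRUE` rather than an error. As
#' provenance, each hydrogen's nearest heavy atom in the final frame is
#' reported (the end-state bonding-partner check).
#'
#' @param trajectory A trajectory object.
#' @param roles List with atom indices `donor`, `donor_hydrogen`,
#'   `water_oxygen`, `water_hydrogen`, `acceptor`.
#' @param min_dwell_frames,hysteresis Event-detection settings
#'   (see [detect_events()]).
#' @param window Concomitance window (ps); default one sampling interval.
#' @return An object of class `pathway_classification`: `label`,
#'   `ambiguous`, the three event tables, `concomitance` (for the
#'   water-mediated pair), `provenance`.
#' @export
classify_pathway <- function(trajectory, roles, min_dwell_frames = 4L,
                             hysteresis = 0.1, window = NULL) {
  need <- c("donor", "donor_hydrogen", "water_oxygen", "water_hydrogen",
            "acceptor")
  if (!all(need %in% names(roles)))
    stopf("roles must name: %s", paste(need, collapse = ", "))
  s_aw <- transfer_coordinate(trajectory, roles$donor, roles$donor_hydrogen,
                              roles$water_oxygen)
  s_wa <- transfer_coordinate(trajectory, roles$water_oxygen,
                              roles$water_hydrogen, roles$acceptor)
  s_da <- transfer_coordinate(trajectory, roles$donor, roles$donor_hydrogen,
                              roles$acceptor)
  e_aw <- detect_events(s_aw, min_dwell_frames, hysteresis)
  e_wa <- detect_events(s_wa, min_dwell_frames, hysteresis)
  e_da <- detect_events(s_da, min_dwell_frames, hysteresis)
  f_aw <- any(e_aw$direction == "forward")
  f_wa <- any(e_wa$direction == "forward")
  f_da <- any(e_da$direction == "forward")
  water_mediated <- f_aw && f_wa
  direct <- f_da && !f_aw && !f_wa
  label <- if (water_mediated) "water_mediated" else
    if (direct) "direct" else "none"
  ambiguous <- water_mediated && f_da
  window <- window %||% trajectory$sampling_interval %||% 2.5
  conc <- if (water_mediated) concomitance(e_aw, e_wa, window) else NULL

  # end-state provenance: nearest heavy atom to each hydrogen, last frame
  last <- dim(trajectory$coords)[1]
  heavies <- c(donor = roles$donor, water_oxygen = roles$water_oxygen,
               acceptor = roles$acceptor)
  nearest <- function(h) {
    d <- vapply(heavies, function(a)
      sqrt(sum((trajectory$coords[last, h, ] -
                  trajectory$coords[last, a, ])^2)), numeric(1))
    names(which.min(d))
  }
  provenance <- c(donor_hydrogen = nearest(roles$donor_hydrogen),
                  water_hydrogen = nearest(roles$water_hydrogen))
  structure(list(label = label, ambiguous = ambiguous,
                 events_acid_water = e_aw, events_water_acceptor = e_wa,
                 events_acid_acceptor = e_da, concomitance = conc,
                 provenance = provenance),
            class = "pathway_classification")
}

#' @export
print.pathway_classification <- function(x, ...) {
  cat(sprintf("pathway: %s%s\n", x$label,
              if (x$ambiguous) " (ambiguous: direct pattern also present)"
              else ""))
  cat(sprintf("  events acid->water: %d, water->acceptor: %d, acid->acceptor: %d\n",
              nrow(x$events_acid_water), nrow(x$events_water_acceptor),
              nrow(x$events_acid_acceptor)))
  cat(sprintf("  final bonding partners: donor H -> %s, water H -> %s\n",
              x$provenance[["donor_hydrogen"]],
              x$provenance[["water_hydrogen"]]))
  invisible(x)
}
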