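# Tab-separated, self-describing file formats. Every writer emits
# '# key: value' header lines sufficient to identify the producing stage,
# then a header row and tab-separated numeric columns formatted with a
# fixed %.10g so that reruns are byte-identical.

fmt_num <- function(x) sprintf("%.10g", x)

write_tsv_block <- function(path, meta, df) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = " ")), con)
  writeLines(paste(names(df), collapse = "\t"), con)
  rows <- do.call(paste, c(lapply(df, fmt_num), sep = "\t"))
  writeLines(rows, con)
  invisible(path)
}

read_tsv_block <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines)
  meta <- list()
  for (l in lines[hdr]) {
    kv <- sub("^# ", "", l)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- trimws(sub("^[^:]*:", "", kv))
  }
  body <- lines[setdiff(seq_along(lines), hdr)]
  df <- utils::read.delim(text = body, check.names = FALSE)
  list(meta = meta, data = df)
}

#' Write / read a work-ensemble file
#'
#' Tab-separated: first column `lambda`, one work column per replicate.
#' Header comments carry temperature, spring constant, seeds and the
#' protocol hash, making the file self-describing.
#'
#' @param ensemble A [work_ensemble()].
#' @param path Output path.
#' @return `path`, invisibly (`read_work_ensemble` returns a
#'   [work_ensemble()]).
#' @export
write_work_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "work_ensemble"))
  prot <- ensemble$protocol
  meta <- list(format = "smdpmf work ensemble v1",
               temperature_K = fmt_num(ensemble$temperature),
               n_replicates = ncol(ensemble$works))
  if (!is.null(prot)) {
    meta$k_spring <- fmt_num(prot$k)
    meta$control <- prot$control
    meta$n_steps <- prot$n_steps
    meta$dt_ps <- fmt_num(prot$dt)
    meta$protocol_hash <- protocol_hash(prot)
  }
  if (!is.null(ensemble$seeds))
    meta$seeds <- paste(ensemble$seeds, collapse = ",")
  df <- data.frame(lambda = ensemble$lambda_grid, ensemble$works)
  names(df) <- c("lambda", paste0("W_rep", seq_len(ncol(ensemble$works))))
  write_tsv_block(path, meta, df)
}

#' @rdname write_work_ensemble
#' @export
read_work_ensemble <- function(path) {
  blk <- read_tsv_block(path)
  lam <- blk$data$lambda
  works <- as.matrix(blk$data[, -1, drop = FALSE])
  seeds <- if (!is.null(blk$meta$seeds))
    as.integer(strsplit(blk$meta$seeds, ",")[[1]]) else NULL
  work_ensemble(lam, works,
                temperature = as.numeric(blk$meta$temperature_K),
                seeds = seeds)
}

#' Write a PMF table with its barrier report
#'
#' Columns: lambda, raw Jarzynski average, bias-corrected average, RMSE
#' band, mean work, dissipated work. The forward/reverse barrier heights
#' are written as header comments.
#'
#' @param pmf A [pmf_from_ensemble()] result.
#' @param path Output path.
#' @param extra_meta Named list of extra header fields.
#' @export
write_pmf_table <- function(pmf, path, extra_meta = list()) {
  stopifnot(inherits(pmf, "pmf_estimate"))
  br <- barrier_heights(pmf)
  meta <- c(list(format = "smdpmf pmf table v1",
                 temperature_K = fmt_num(pmf$temperature),
                 n_replicates = pmf$n_replicates,
                 forward_barrier_kcal = fmt_num(br$forward_barrier),
                 reverse_barrier_kcal = fmt_num(br$reverse_barrier),
                 barrier_position = fmt_num(br$barrier_position),
                 steering_direction = br$steering_direction),
            extra_meta)
  df <- data.frame(lambda = pmf$lambda_grid, raw = pmf$raw_jarzynski,
                   corrected = pmf$bias_corrected, rmse = pmf$rmse_band,
                   mean_work = pmf$mean_work,
                   dissipated = pmf$dissipated_work)
  write_tsv_block(path, meta, df)
}

#' Write a trajectory as a tab-separated table
#'
#' Columns: time, x/y/z per atom, CV value, restraint energy; header
#' comments carry system name, seed and sampling interval.
#'
#' @param trajectory A `trajectory` object.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  na <- dim(trajectory$coords)[2]
  cols <- list(time = trajectory$times)
  for (a in seq_len(na)) {
    cols[[paste0("x", a)]] <- trajectory$coords[, a, 1]
    cols[[paste0("y", a)]] <- trajectory$coords[, a, 2]
    cols[[paste0("z", a)]] <- trajectory$coords[, a, 3]
  }
  cols$cv <- trajectory$cv
  cols$restraint_energy <- trajectory$restraint_energy
  meta <- list(format = "smdpmf trajectory v1",
               system = trajectory$system %||% "unknown",
               seed = trajectory$seed %||% "NA",
               sampling_interval_ps = fmt_num(trajectory$sampling_interval))
  write_tsv_block(path, meta, as.data.frame(cols))
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  blk <- read_tsv_block(path)
  df <- blk$data
  xcols <- grep("^x[0-9]+$", names(df))
  na <- length(xcols)
  nf <- nrow(df)
  coords <- array(0, dim = c(nf, na, 3))
  for (a in seq_len(na)) {
    coords[, a, 1] <- df[[paste0("x", a)]]
    coords[, a, 2] <- df[[paste0("y", a)]]
    coords[, a, 3] <- df[[paste0("z", a)]]
  }
  structure(list(times = df$time, coords = coords, cv = df$cv,
                 restraint_energy = df$restraint_energy,
                 sampling_interval =
                   as.numeric(blk$meta$sampling_interval_ps),
                 system = blk$meta$system),
            class = "trajectory")
}
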