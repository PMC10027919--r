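#' Detect the stance phase from the vertical force
#'
#' Finds the longest run of samples with vertical force at or above
#' `threshold` (30 N by convention, marking heel contact and toe-off) and
#' returns its first and last sample indices (1-based, inclusive). Runs
#' shorter than `min_duration` are ignored, which discards plate-edge
#' grazes and aiming steps.
#'
#' @param fz vertical force series, newtons.
#' @param fs sampling rate, Hz.
#' @param threshold contact threshold, newtons; comparison is `>=`.
#' @param min_duration minimum contact duration, seconds.
#' @return integer vector `c(start, end)`.
#' @export
detect_stance <- function(fz, fs, threshold = 30, min_duration = 0.1) {
  if (length(fz) == 0) gs_error("gaitsym_no_contact", "empty series")
  runs <- logical_runs(fz >= threshold)
  if (nrow(runs) > 0) {
    len <- runs[, "end"] - runs[, "start"] + 1L
    keep <- len >= min_duration * fs
    runs <- runs[keep, , drop = FALSE]
    len <- len[keep]
  }
  if (nrow(runs) == 0)
    gs_error("gaitsym_no_contact",
             sprintf("no vertical-force run >= %g N lasting >= %g s", threshold, min_duration))
  best <- which.max(runs[, "end"] - runs[, "start"])
  c(start = unname(runs[best, "start"]), end = unname(runs[best, "end"]))
}

#' Time-normalize a stance segment to a fixed node grid
#'
#' Resamples a cropped stance segment onto `n_nodes` evenly spaced points
#' (0-100% of stance) with an interpolating cubic spline. The first and
#' last output values equal the first and last input samples.
#'
#' @param y numeric segment (length >= 4 for cubic support).
#' @param n_nodes output grid size (101 by convention).
#' @return numeric vector of length `n_nodes`.
#' @export
time_normalize <- function(y, n_nodes = 101L) {
  m <- length(y)
  if (m < 4) gs_error("gaitsym_segment_too_short",
                      "need at least 4 samples for cubic spline resampling")
  x <- seq(0, 1, length.out = m)
  stats::spline(x, y, xout = seq(0, 1, length.out = n_nodes), method = "fmm")$y
}

#' Convert force to body-weight units
#'
#' BW units are defined as newtons divided by ten times the body mass in
#' kilograms (so a 70 kg runner's 700 N is 1.0 BW).
#'
#' @param force newtons.
#' @param mass kilograms (> 0).
#' @return force in BW units.
#' @export
normalize_bw <- function(force, mass) {
  if (!is.numeric(mass) || mass <= 0)
    gs_error("gaitsym_invalid_arg", "mass must be positive")
  force / (10 * mass)
}

#' Preprocess one trial into three 101-node BW stance curves
#'
#' Detects the stance window on the vertical axis, crops all three axes
#' with that same window, spline-resamples each to `n_nodes` points and
#' converts to BW units.
#'
#' @param trial a `"grf_trial"`.
#' @param threshold,min_duration passed to [detect_stance()].
#' @param n_nodes output nodes per curve.
#' @return object of class `"stance_curves"`: list with numeric vectors
#'   `X`, `Y`, `Z` (each `n_nodes` long, BW), the sample `window`, and the
#'   trial metadata.
#' @export
preprocess_trial <- function(trial, threshold = 30, min_duration = 0.1,
                             n_nodes = 101L) {
  stopifnot(inherits(trial, "grf_trial"))
  w <- detect_stance(trial$fz_N, trial$fs, threshold, min_duration)
  idx <- w["start"]:w["end"]
  crv <- lapply(list(X = trial$fx_N, Y = trial$fy_N, Z = trial$fz_N),
                function(f) normalize_bw(time_normalize(f[idx], n_nodes), trial$mass))
  structure(c(crv, list(window = w, subject = trial$subject, side = trial$side,
                        condition = trial$condition, trial = trial$trial)),
            class = "stance_curves")
}

# One trial's stance curves -> tidy long rows.
curves_to_table <- function(sc, trial) {
  n <- length(sc$X)
  do.call(rbind, lapply(c("X", "Y", "Z"), function(ax)
    data.frame(subject = trial$subject, side = trial$side,
               condition = trial$condition, trial = trial$trial, axis = ax,
               node = seq_len(n) - 1L, value_bw = sc[[ax]])))
}

#' Preprocess every trial of a dataset into a tidy curve table
#'
#' @param trials list of `"grf_trial"` objects (e.g. from [read_dataset()]).
#' @inheritParams preprocess_trial
#' @return tidy data.frame: `subject`, `side`, `condition`, `trial`,
#'   `axis`, `node`, `value_bw`.
#' @export
preprocess_dataset <- function(trials, threshold = 30, min_duration = 0.1,
                               n_nodes = 101L) {
  do.call(rbind, lapply(trials, function(tr)
    curves_to_table(preprocess_trial(tr, threshold, min_duration, n_nodes), tr)))
}
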