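#' Symmetry Function amplitude
#'
#' The normalising amplitude `A = 2 / (range(right) + range(left))`, where
#' range is max minus min over the stance curve. It rescales the bilateral
#' difference by the typical signal magnitude, so the Symmetry Function is
#' invariant to common scaling of both limbs.
#'
#' @param right,left numeric stance curves of equal length (101 nodes by
#'   convention).
#' @return scalar amplitude.
#' @export
sf_amplitude <- function(right, left) {
  stopifnot(length(right) == length(left))
  denom <- diff(range(right)) + diff(range(left))
  if (denom == 0)
    gs_error("gaitsym_degenerate_amplitude",
             "both curves are constant; symmetry amplitude undefined")
  2 / denom
}

#' Symmetry Function curve
#'
#' Pointwise Symmetry Function `SF(t) = A * |right(t) - left(t)|` over the
#' stance-node grid. SF is 0 for perfectly symmetric limbs; values above
#' 0.05 are conventionally deemed asymmetric.
#'
#' @inheritParams sf_amplitude
#' @return numeric vector of SF values (same length as the inputs).
#' @examples
#' tau <- seq(0, 1, length.out = 101)
#' sf_curve(tau, 1 - tau)     # |2*tau - 1|
#' @export
sf_curve <- function(right, left) {
  sf_amplitude(right, left) * abs(right - left)
}

#' Integral of a Symmetry Function curve
#'
#' Trapezoidal integral of SF over normalized stance time in \[0, 1\]; a
#' scalar summary of overall asymmetry (0 = perfect symmetry).
#'
#' @param sf numeric SF values on an even node grid.
#' @return scalar integral.
#' @export
sf_integral <- function(sf) {
  n <- length(sf)
  stopifnot(n >= 2)
  h <- 1 / (n - 1)
  sum((sf[-1] + sf[-n]) / 2) * h
}

#' Asymmetric stance intervals
#'
#' Maximal runs of consecutive nodes with SF strictly above `threshold`,
#' reported as inclusive stance percentages (node indices 0-100).
#'
#' @param sf numeric SF values.
#' @param threshold asymmetry threshold (default 0.05).
#' @return data.frame with columns `start_pct`, `end_pct` (zero rows when
#'   the whole stance is symmetric).
#' @export
asymmetric_intervals <- function(sf, threshold = 0.05) {
  runs <- logical_runs(sf > threshold)
  data.frame(start_pct = runs[, "start"] - 1L, end_pct = runs[, "end"] - 1L)
}

#' Symmetry Functions for a whole curve dataset
#'
#' Pairs left and right stance curves within each (subject, condition,
#' axis) cell - the i-th left trial with the i-th right trial, in trial
#' order - and computes one SF curve per pair.
#'
#' @param curves tidy curve table from [preprocess_dataset()] /
#'   [simulate_curves()].
#' @return tidy data.frame: `subject`, `condition`, `trial` (pair rank),
#'   `axis`, `node`, `sf`.
#' @export
sf_dataset <- function(curves) {
  stopifnot(all(c("subject", "side", "condition", "trial", "axis",
                  "node", "value_bw") %in% names(curves)))
  cells <- unique(curves[, c("subject", "condition", "axis")])
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    cell <- curves[curves$subject == cells$subject[i] &
                   curves$condition == cells$condition[i] &
                   curves$axis == cells$axis[i], ]
    lt <- sort(unique(cell$trial[cell$side == "L"]))
    rt <- sort(unique(cell$trial[cell$side == "R"]))
    if (length(lt) != length(rt))
      gs_error("gaitsym_unpaired_trial",
               sprintf("unpaired trials for subject %s, condition %s, axis %s (%d left vs %d right)",
                       cells$subject[i], cells$condition[i], cells$axis[i],
                       length(lt), length(rt)))
    out[[i]] <- do.call(rbind, lapply(seq_along(lt), function(k) {
      l <- cell[cell$side == "L" & cell$trial == lt[k], ]
      r <- cell[cell$side == "R" & cell$trial == rt[k], ]
      l <- l[order(l$node), ]; r <- r[order(r$node), ]
      data.frame(subject = cells$subject[i], condition = cells$condition[i],
                 trial = k, axis = cells$axis[i], node = l$node,
                 sf = sf_curve(r$value_bw, l$value_bw))
    }))
  }
  do.call(rbind, out)
}

#' Summaries of a Symmetry Function table
#'
#' Per (subject, condition, trial, axis): the SF integral and the
#' asymmetric intervals of each SF curve. Also returns per-axis,
#' per-condition mean SF curves (averaged over trials within subject,
#' then over subjects) with their asymmetric intervals.
#'
#' @param sf_table output of [sf_dataset()].
#' @param threshold asymmetry threshold for interval extraction.
#' @return list with `per_curve` (data.frame: subject, condition, trial,
#'   axis, sf_integral, n_asym_intervals), `mean_curves` (data.frame:
#'   condition, axis, node, sf) and `mean_intervals` (data.frame:
#'   condition, axis, start_pct, end_pct).
#' @export
sf_summary <- function(sf_table, threshold = 0.05) {
  key <- interaction(sf_table$subject, sf_table$condition, sf_table$trial,
                     sf_table$axis, drop = TRUE)
  per <- do.call(rbind, lapply(split(sf_table, key), function(d) {
    d <- d[order(d$node), ]
    data.frame(subject = d$subject[1], condition = d$condition[1],
               trial = d$trial[1], axis = d$axis[1],
               sf_integral = sf_integral(d$sf),
               n_asym_intervals = nrow(asymmetric_intervals(d$sf, threshold)))
  }))
  rownames(per) <- NULL
  # subject-mean then grand-mean SF curves
  subj_mean <- stats::aggregate(sf ~ subject + condition + axis + node,
                                data = sf_table, FUN = mean)
  grand <- stats::aggregate(sf ~ condition + axis + node, data = subj_mean,
                            FUN = mean)
  grand <- grand[order(grand$condition, grand$axis, grand$node), ]
  ivl <- do.call(rbind, lapply(split(grand, interaction(grand$condition, grand$axis,
                                                        drop = TRUE)), function(d) {
    iv <- asymmetric_intervals(d$sf[order(d$node)], threshold)
    if (nrow(iv) == 0) return(NULL)
    cbind(condition = d$condition[1], axis = d$axis[1], iv)
  }))
  if (is.null(ivl))
    ivl <- data.frame(condition = character(), axis = character(),
                      start_pct = integer(), end_pct = integer())
  rownames(ivl) <- NULL
  list(per_curve = per, mean_curves = grand, mean_intervals = ivl)
}
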