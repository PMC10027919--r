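# Shared fixtures, generated in code and cached per test run.

.fixtures <- new.env(parent = emptyenv())

# Study-sized dominance+fatigue curve table (14 subjects x 3 trials).
study_curves <- function() {
  if (is.null(.fixtures$study)) {
    .fixtures$study <- simulate_curves(14, 3, "dominance+fatigue",
                                       noise_spec(0.02, 10), seed = 20240915L)
  }
  .fixtures$study
}

study_sf <- function() {
  if (is.null(.fixtures$study_sf)) .fixtures$study_sf <- sf_dataset(study_curves())
  .fixtures$study_sf
}

# subject-mean curve matrix (rows = subjects, cols = nodes)
subj_mean_mat <- function(d, col) {
  agg <- stats::aggregate(d[[col]], by = list(subject = d$subject, node = d$node),
                          FUN = mean)
  subs <- sort(unique(agg$subject)); nodes <- sort(unique(agg$node))
  M <- matrix(NA_real_, length(subs), length(nodes))
  M[cbind(match(agg$subject, subs), match(agg$node, nodes))] <- agg$x
  M
}

# smooth 1D noise fields as a matrix of n independent rows
noise_field <- function(n, q = 101, fwhm = 10) {
  t(replicate(n, smooth_noise(q, 1, fwhm)))
}
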