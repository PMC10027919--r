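#' Simulate one raw force-plate trial
#'
#' Generates a three-axis raw GRF recording in newtons for one stance of
#' one limb. The stance waveform is the axis template (left limbs with the
#' asymmetry spec applied, right limbs always from the bare template) plus
#' temporally smooth noise, multiplied by ten times the body mass so that
#' 1 BW corresponds to `10 * mass` newtons. The stance is padded on both
#' sides with flight segments whose vertical force ripples between 5 and
#' 20 N, so the 30 N stance-detection threshold is genuinely exercised.
#'
#' @param templates template parameter list ([default_template_params()]).
#' @param asymmetry an [asym_spec()]; applied to left-limb trials only.
#' @param noise a [noise_spec()].
#' @param side `"L"` or `"R"`.
#' @param condition `"pre"` or `"post"`; fatigue bumps in `asymmetry`
#'   apply only when `"post"` (and only to the left limb).
#' @param mass body mass, kg (> 0).
#' @param fs sampling rate, Hz (> 0).
#' @param stance_duration foot-contact duration, s (> 0).
#' @param pad_duration flight-pad duration on each side, s.
#' @param seed integer seed; identical seeds give identical trials.
#' @param subject,trial identifiers carried into the result.
#' @return object of class `"grf_trial"`: list with `time_s`, `fx_N`,
#'   `fy_N`, `fz_N`, `fs`, `mass`, `side`, `condition`, `subject`, `trial`.
#' @export
make_trial <- function(templates = NULL, asymmetry = asym_spec(),
                       noise = noise_spec(), side = c("R", "L"),
                       condition = c("pre", "post"), mass = 70,
                       fs = 1000, stance_duration = 0.25,
                       pad_duration = 0.1, seed = 1L,
                       subject = "S01", trial = 1L) {
  side <- match.arg(side)
  condition <- match.arg(condition)
  if (mass <= 0) gs_error("gaitsym_invalid_arg", "mass must be positive")
  if (fs <= 0) gs_error("gaitsym_invalid_arg", "sampling rate must be positive")
  if (stance_duration <= 0) gs_error("gaitsym_invalid_arg", "stance_duration must be positive")
  stopifnot(inherits(asymmetry, "asym_spec"), inherits(noise, "noise_spec"))

  n_st <- max(4L, round(stance_duration * fs))
  n_pad <- max(0L, round(pad_duration * fs))
  s <- seq(0, 1, length.out = n_st)
  # noise FWHM is specified in 101-node stance units; convert to samples
  fwhm_samples <- noise$smooth_fwhm * (n_st - 1) / 100

  with_seed(seed, {
    bw <- lapply(c(X = "X", Y = "Y", Z = "Z"), function(ax) {
      f <- template_fun(ax, templates)
      if (side == "L") {
        v <- asymmetry$amplitude_ratio * f(pmin(1, pmax(0, s - asymmetry$time_shift)))
        add_bumps <- function(v, b) {
          if (is.null(b)) return(v)
          for (k in which(b$axis == ax))
            v <- v + b$height[k] * exp(-((s - b$center[k])^2) / (2 * b$width[k]^2))
          v
        }
        v <- add_bumps(v, asymmetry$bumps)
        if (condition == "post") v <- add_bumps(v, asymmetry$fatigue)
      } else {
        v <- f(s)
      }
      v + smooth_noise(n_st, noise$sd, fwhm_samples)
    })
    stance <- lapply(bw, function(v) v * 10 * mass)
    pad <- function() {                       # sub-threshold flight ripple
      if (n_pad == 0L) return(numeric(0))
      base <- runif(1, 8, 15)
      pmin(20, pmax(5, base + smooth_noise(n_pad, 2, max(1, fs / 100))))
    }
    lat <- function() {
      if (n_pad == 0L) return(numeric(0))
      smooth_noise(n_pad, 1, max(1, fs / 100))
    }
    fz <- c(pad(), stance$Z, pad())
    fx <- c(lat(), stance$X, lat())
    fy <- c(lat(), stance$Y, lat())
    n <- length(fz)
    structure(list(time_s = (seq_len(n) - 1) / fs, fx_N = fx, fy_N = fy,
                   fz_N = fz, fs = fs, mass = mass, side = side,
                   condition = condition, subject = subject, trial = trial),
              class = "grf_trial")
  })
}

#' @export
print.grf_trial <- function(x, ...) {
  cat(sprintf("<grf_trial> subject %s, side %s, condition %s, trial %d\n",
              x$subject, x$side, x$condition, x$trial))
  cat(sprintf("  %d samples @ %g Hz, mass %.1f kg, peak Fz %.0f N\n",
              length(x$fz_N), x$fs, x$mass, max(x$fz_N)))
  invisible(x)
}

draw_subjects <- function(n_subjects, seed) {
  with_seed(derive_seed(seed, "subjects"), {
    mass <- rnorm(n_subjects, 70.17, 6.57)
    while (any(bad <- mass < 50 | mass > 95))      # truncated normal, cohort-like
      mass[bad] <- rnorm(sum(bad), 70.17, 6.57)
    data.frame(subject = sprintf("S%02d", seq_len(n_subjects)),
               mass = round(mass, 2),
               age = round(pmax(18, rnorm(n_subjects, 22.93, 1.07))))
  })
}

#' Generate a complete labelled bilateral GRF dataset on disk
#'
#' Writes `n_subjects * n_trials * 2 sides * 2 conditions` trial CSV files
#' plus a JSON manifest to `out_dir`. Subject masses are drawn from a
#' normal distribution (mean 70.17, sd 6.57 kg) truncated to \[50, 95\],
#' emulating an amateur-runner cohort; all randomness derives from `seed`.
#'
#' @param n_subjects number of subjects (>= 2).
#' @param n_trials trials per subject, side and condition (>= 1).
#' @param asymmetry an [asym_spec()] or profile name for [asym_profile()].
#' @param noise a [noise_spec()].
#' @param seed integer root seed.
#' @param out_dir output directory (created if missing).
#' @param ... further arguments passed to [make_trial()].
#' @return object of class `"grf_manifest"`: list with `records`
#'   (data.frame: subject, mass, age, side, condition, trial, file) and
#'   `seed`.
#' @export
make_dataset <- function(n_subjects = 14, n_trials = 3,
                         asymmetry = asym_profile("dominance+fatigue"),
                         noise = noise_spec(), seed = 1L, out_dir, ...) {
  if (n_subjects < 2) gs_error("gaitsym_invalid_arg", "need at least 2 subjects")
  if (n_trials < 1) gs_error("gaitsym_invalid_arg", "need at least 1 trial")
  if (is.character(asymmetry)) asymmetry <- asym_profile(asymmetry)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    gs_error("gaitsym_io_error", sprintf("cannot create directory '%s'", out_dir))

  subj <- draw_subjects(n_subjects, seed)
  grid <- expand.grid(trial = seq_len(n_trials), condition = c("pre", "post"),
                      side = c("L", "R"), subject = subj$subject,
                      stringsAsFactors = FALSE)
  grid <- grid[order(grid$subject, grid$side, grid$condition, grid$trial), ]
  recs <- merge(grid, subj, by = "subject", sort = FALSE)
  recs$file <- sprintf("%s_%s_%s_%d.csv", recs$subject, recs$side,
                       recs$condition, recs$trial)
  for (i in seq_len(nrow(recs))) {
    tr <- make_trial(asymmetry = asymmetry, noise = noise,
                     side = recs$side[i], condition = recs$condition[i],
                     mass = recs$mass[i],
                     seed = derive_seed(seed, recs$subject[i], recs$side[i],
                                        recs$condition[i], recs$trial[i]),
                     subject = recs$subject[i], trial = recs$trial[i], ...)
    write_trial_csv(tr, file.path(out_dir, recs$file[i]))
  }
  man <- structure(list(records = recs[, c("subject", "mass", "age", "side",
                                           "condition", "trial", "file")],
                        seed = as.integer(seed)),
                   class = "grf_manifest")
  write_manifest(man, file.path(out_dir, "manifest.json"))
  man
}

#' Simulate a preprocessed curve table in memory
#'
#' Convenience composition of [make_trial()] and [preprocess_trial()] that
#' skips file I/O: generates the same trials [make_dataset()] would write
#' and returns the tidy 101-node BW curve table directly.
#'
#' @inheritParams make_dataset
#' @param ... passed to [make_trial()].
#' @return tidy data.frame: `subject`, `side`, `condition`, `trial`,
#'   `axis`, `node` (0-100), `value_bw`.
#' @export
simulate_curves <- function(n_subjects = 14, n_trials = 3,
                            asymmetry = asym_profile("dominance+fatigue"),
                            noise = noise_spec(), seed = 1L, ...) {
  if (is.character(asymmetry)) asymmetry <- asym_profile(asymmetry)
  subj <- draw_subjects(n_subjects, seed)
  out <- vector("list", n_subjects * n_trials * 4L)
  k <- 0L
  for (i in seq_len(n_subjects)) for (sd. in c("L", "R"))
    for (cond in c("pre", "post")) for (tr in seq_len(n_trials)) {
      trial <- make_trial(asymmetry = asymmetry, noise = noise, side = sd.,
                          condition = cond, mass = subj$mass[i],
                          seed = derive_seed(seed, subj$subject[i], sd., cond, tr),
                          subject = subj$subject[i], trial = tr, ...)
      k <- k + 1L
      out[[k]] <- curves_to_table(preprocess_trial(trial), trial)
    }
  do.call(rbind, out)
}
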