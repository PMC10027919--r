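#' Default GRF waveform template parameters
#'
#' Each axis template is a sum of Gaussian bumps over the stance fraction
#' `s` in \[0, 1\], in body-weight (BW) units, tapered to exactly zero at
#' touch-down (`s = 0`) and toe-off (`s = 1`). The default shapes emulate
#' heel-strike running stance:
#' \describe{
#'   \item{Z (vertical)}{impact peak ~0.9 BW at 13\% of stance plus active
#'     peak ~2.5 BW at 45\%; non-negative everywhere.}
#'   \item{Y (anterior-posterior)}{braking lobe -0.3 BW at 25\% and
#'     propulsion lobe +0.3 BW at 75\%.}
#'   \item{X (medial-lateral)}{two low bumps of at most 0.15 BW.}
#' }
#' The bump parameterisation is a modelling choice of this package; no
#' canonical parametric GRF waveform exists, and Gaussian mixtures are
#' smooth, differentiable and parameter-sparse.
#'
#' @return named list with one element per axis (`X`, `Y`, `Z`), each a
#'   list of numeric vectors `amp` (BW), `center` and `width` (stance
#'   fractions).
#' @export
default_template_params <- function() {
  list(
    X = list(amp = c(0.10, 0.15), center = c(0.20, 0.55), width = c(0.08, 0.15)),
    Y = list(amp = c(-0.30, 0.30), center = c(0.25, 0.75), width = c(0.10, 0.10)),
    Z = list(amp = c(0.90, 2.50), center = c(0.13, 0.45), width = c(0.045, 0.16))
  )
}

check_template_params <- function(axis, p) {
  if (!axis %in% c("X", "Y", "Z"))
    gs_error("gaitsym_invalid_axis", sprintf("invalid axis '%s' (use X, Y or Z)", axis))
  stopifnot(is.numeric(p$amp), is.numeric(p$center), is.numeric(p$width),
            length(p$amp) == length(p$center), length(p$amp) == length(p$width))
  if (any(p$width <= 0))
    gs_error("gaitsym_invalid_template", "peak widths must be positive")
  if (any(p$center < 0 | p$center > 1))
    gs_error("gaitsym_invalid_template", "peak centers must lie in [0, 1]")
  if (axis == "Z" && any(p$amp < 0))
    gs_error("gaitsym_invalid_template", "vertical (Z) amplitudes must be non-negative")
  invisible(p)
}

# Continuous template evaluator: Gaussian bump sum times an edge taper that
# forces exact zeros at s = 0 and s = 1 (taper ramps over the outer 2%).
template_fun <- function(axis, params = NULL) {
  p <- (params %||% default_template_params())[[axis]]
  check_template_params(axis, p)
  edge <- 0.02
  function(s) {
    g <- rep(0, length(s))
    for (k in seq_along(p$amp))
      g <- g + p$amp[k] * exp(-((s - p$center[k])^2) / (2 * p$width[k]^2))
    taper <- pmin(1, pmax(0, s / edge), pmax(0, (1 - s) / edge))
    g * taper
  }
}

#' Build a GRF axis template on a fine grid
#'
#' Evaluates the Gaussian-bump stance template of one axis on `n` evenly
#' spaced points spanning stance fractions 0 to 1.
#'
#' @param axis one of `"X"`, `"Y"`, `"Z"`.
#' @param params template parameter list as in [default_template_params()];
#'   `NULL` uses the defaults.
#' @param n grid size.
#' @return numeric vector of length `n`, BW units; first and last values
#'   are exactly 0.
#' @examples
#' z <- build_template("Z", n = 501)
#' max(z)                       # active peak, ~2.5 BW
#' @export
build_template <- function(axis, params = NULL, n = 1001L) {
  stopifnot(n >= 2)
  template_fun(axis, params)(seq(0, 1, length.out = n))
}

#' Bilateral asymmetry specification
#'
#' Describes how the left limb differs from the right. The right limb is
#' always generated from the bare templates; the left limb is scaled by
#' `amplitude_ratio`, shifted in time by `time_shift` (fraction of stance),
#' and perturbed by axis-specific Gaussian `bumps`. `fatigue` holds extra
#' bumps applied to the left limb only when the trial condition is
#' `"post"`, modelling a fatigue-induced worsening of asymmetry.
#'
#' @param amplitude_ratio positive multiplier on the left limb.
#' @param time_shift stance-fraction shift of the left limb, in \[0, 1\].
#' @param bumps `NULL` or data.frame with columns `axis`, `center`,
#'   `width`, `height` (BW); added to the left limb.
#' @param fatigue like `bumps`, applied additionally when condition is
#'   `"post"`.
#' @return object of class `"asym_spec"`.
#' @export
asym_spec <- function(amplitude_ratio = 1, time_shift = 0,
                      bumps = NULL, fatigue = NULL) {
  if (!is.numeric(amplitude_ratio) || amplitude_ratio <= 0)
    gs_error("gaitsym_invalid_asymmetry", "amplitude_ratio must be positive")
  if (time_shift < 0 || time_shift > 1)
    gs_error("gaitsym_invalid_asymmetry", "time_shift must lie in [0, 1]")
  chk <- function(b, what) {
    if (is.null(b)) return(NULL)
    b <- as.data.frame(b)
    stopifnot(all(c("axis", "center", "width", "height") %in% names(b)))
    if (any(b$width <= 0)) gs_error("gaitsym_invalid_asymmetry",
                                    sprintf("%s bump widths must be positive", what))
    if (any(b$center < 0 | b$center > 1))
      gs_error("gaitsym_invalid_asymmetry",
               sprintf("%s bump centers must lie in [0, 1]", what))
    if (!all(b$axis %in% c("X", "Y", "Z")))
      gs_error("gaitsym_invalid_asymmetry", "bump axis must be X, Y or Z")
    b
  }
  structure(list(amplitude_ratio = amplitude_ratio, time_shift = time_shift,
                 bumps = chk(bumps, "asymmetry"), fatigue = chk(fatigue, "fatigue")),
            class = "asym_spec")
}

#' Named asymmetry profiles
#'
#' Three study conditions used throughout the package:
#' \describe{
#'   \item{null}{identity: left equals right up to noise.}
#'   \item{dominance}{a stable limb-dominance pattern: 5\% amplitude
#'     scaling, 1\% time shift, and two medial-lateral (X) bumps on the
#'     left limb, concentrating asymmetry in the X axis.}
#'   \item{dominance+fatigue}{dominance plus a narrow late-stance
#'     medial-lateral bump (0.08 BW, centred near 89\% of the detected
#'     stance phase) present only post-fatigue; comfortably above the
#'     ~0.05 BW detection floor at the default noise level and cohort
#'     size.}
#' }
#'
#' @param name profile name.
#' @return an [asym_spec()] object.
#' @export
asym_profile <- function(name = c("null", "dominance", "dominance+fatigue")) {
  name <- match.arg(name)
  dom_bumps <- data.frame(axis = c("X", "X"), center = c(0.22, 0.60),
                          width = c(0.10, 0.15), height = c(0.10, 0.08))
  # centered at ~89% of the *detected* stance: the 30 N contact threshold
  # crops the template tails, so template fraction 0.80 maps to roughly
  # node 89 of the 101-node detected-stance grid
  fat_bump <- data.frame(axis = "X", center = 0.80, width = 0.02, height = 0.08)
  switch(name,
    "null" = asym_spec(),
    "dominance" = asym_spec(amplitude_ratio = 1.05, time_shift = 0.01,
                            bumps = dom_bumps),
    "dominance+fatigue" = asym_spec(amplitude_ratio = 1.05, time_shift = 0.01,
                                    bumps = dom_bumps, fatigue = fat_bump))
}

#' Temporally smooth noise specification
#'
#' Noise is white Gaussian convolved with a Gaussian kernel of full width
#' at half maximum `smooth_fwhm` (expressed in 101-node stance units) and
#' scaled so the marginal standard deviation equals `sd` BW. Smoothing by a
#' Gaussian kernel makes the random-field smoothness assumptions of the
#' downstream SPM inference hold by construction.
#'
#' @param sd marginal standard deviation, BW units.
#' @param smooth_fwhm temporal correlation length, nodes (>= 1).
#' @return object of class `"noise_spec"`.
#' @export
noise_spec <- function(sd = 0.02, smooth_fwhm = 10) {
  if (sd < 0) gs_error("gaitsym_invalid_noise", "noise sd must be >= 0")
  if (smooth_fwhm < 1) gs_error("gaitsym_invalid_noise", "smooth_fwhm must be >= 1")
  structure(list(sd = sd, smooth_fwhm = smooth_fwhm), class = "noise_spec")
}

#' Generate smooth Gaussian noise
#'
#' White Gaussian noise convolved with a Gaussian kernel of the stated
#' FWHM (in samples) and scaled analytically (by `1/sqrt(sum(k^2))` for a
#' unit-white input) so the marginal standard deviation equals `sd`.
#'
#' @param n number of samples.
#' @param sd target marginal standard deviation.
#' @param fwhm kernel full width at half maximum, samples.
#' @return numeric vector of length `n`.
#' @export
smooth_noise <- function(n, sd = 1, fwhm = 10) {
  if (sd == 0) return(rep(0, n))
  sigma <- fwhm / sqrt(8 * log(2))
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  w <- rnorm(n + 2L * half)
  y <- stats::filter(w, k, method = "convolution", sides = 2)
  y <- as.numeric(y[(half + 1L):(half + n)])
  y * sd / sqrt(sum(k^2))
}
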