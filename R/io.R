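#' Write / read one trial CSV
#'
#' Trial files carry the header `time_s,fx_N,fy_N,fz_N`. Subject metadata
#' lives in the manifest, not the trial file.
#'
#' @param trial a `"grf_trial"`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  stopifnot(inherits(trial, "grf_trial"))
  df <- data.frame(time_s = trial$time_s, fx_N = trial$fx_N,
                   fy_N = trial$fy_N, fz_N = trial$fz_N)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @param mass,side,condition,subject,trial metadata attached to the
#'   returned trial (normally taken from the manifest record).
#' @export
read_trial_csv <- function(path, mass, side, condition,
                           subject = NA_character_, trial = NA_integer_) {
  df <- read.csv(path)
  stopifnot(all(c("time_s", "fx_N", "fy_N", "fz_N") %in% names(df)))
  if (nrow(df) < 2 || any(diff(df$time_s) <= 0))
    gs_error("gaitsym_io_error", sprintf("'%s': time must be strictly increasing", path))
  fs <- 1 / stats::median(diff(df$time_s))
  structure(list(time_s = df$time_s, fx_N = df$fx_N, fy_N = df$fy_N,
                 fz_N = df$fz_N, fs = fs, mass = mass, side = side,
                 condition = condition, subject = subject, trial = trial),
            class = "grf_trial")
}

#' Write / read a dataset manifest (JSON)
#'
#' @param manifest a `"grf_manifest"` object.
#' @param path JSON file path.
#' @return `path` (writer) or a `"grf_manifest"` (reader).
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "grf_manifest"))
  jsonlite::write_json(list(seed = manifest$seed, records = manifest$records),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  recs <- as.data.frame(x$records)
  key <- do.call(paste, recs[c("subject", "side", "condition", "trial")])
  if (anyDuplicated(key))
    gs_error("gaitsym_invalid_manifest", "duplicate (subject, side, condition, trial)")
  if (any(recs$mass <= 0))
    gs_error("gaitsym_invalid_manifest", "masses must be positive")
  structure(list(records = recs, seed = as.integer(x$seed)),
            class = "grf_manifest")
}

#' Read all trials listed in a manifest
#'
#' @param manifest a `"grf_manifest"`.
#' @param dir directory containing the trial CSV files.
#' @return list of `"grf_trial"` objects.
#' @export
read_dataset <- function(manifest, dir) {
  r <- manifest$records
  lapply(seq_len(nrow(r)), function(i)
    read_trial_csv(file.path(dir, r$file[i]), mass = r$mass[i],
                   side = r$side[i], condition = r$condition[i],
                   subject = r$subject[i], trial = r$trial[i]))
}

#' Write / read a tidy curve table CSV
#'
#' Long-format table of preprocessed stance curves:
#' `subject,side,condition,trial,axis,node,value_bw`.
#'
#' @param curves tidy curves data.frame.
#' @param path CSV path.
#' @export
write_curves_csv <- function(curves, path) {
  write.csv(curves, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curves_csv
#' @export
read_curves_csv <- function(path) read.csv(path, stringsAsFactors = FALSE)
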