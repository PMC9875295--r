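#' Construct a spectra set
#'
#' The central data container of the pipeline: a frequency grid (THz), a
#' power-spectrum matrix with one row per leaf sample, and the reference
#' nitrogen content (% mass) of each sample.
#'
#' @param frequencies_thz strictly increasing numeric vector of frequency
#'   points, all within \[0, 1.4\] THz (the working range of the method).
#' @param power numeric matrix of spectral values, samples in rows, one column
#'   per frequency point (arbitrary power units).
#' @param nitrogen_pct numeric vector of reference nitrogen contents (% mass),
#'   finite and non-negative, one per sample.
#' @param sample_ids character vector of unique sample identifiers.
#' @param gradient_labels optional character vector of nitrogen-stress group
#'   labels, one per sample.
#' @return an object of class `spectra_set`.
#' @export
spectra_set <- function(frequencies_thz, power, nitrogen_pct, sample_ids,
                        gradient_labels = NULL) {
  power <- as.matrix(power)
  obj <- structure(
    list(frequencies_thz = as.numeric(frequencies_thz),
         power = power,
         nitrogen_pct = as.numeric(nitrogen_pct),
         sample_ids = as.character(sample_ids),
         gradient_labels = if (!is.null(gradient_labels))
           as.character(gradient_labels)),
    class = "spectra_set")
  validate_spectra_set(obj)
}

#' Validate a spectra set
#'
#' Checks every structural invariant: strictly increasing frequencies within
#' \[0, 1.4\] THz, matching matrix dimensions, unique sample ids, finite
#' non-negative nitrogen values.
#'
#' @param x a `spectra_set`.
#' @return `x`, invisibly unchanged, or an error.
#' @export
validate_spectra_set <- function(x) {
  f <- x$frequencies_thz
  if (length(f) < 1 || any(!is.finite(f)))
    stop("frequencies must be finite")
  if (any(diff(f) <= 0))
    stop("frequencies must be strictly increasing")
  if (min(f) < 0 || max(f) > 1.4 + 1e-9)
    stop("frequencies must lie within [0, 1.4] THz")
  n <- nrow(x$power)
  if (n < 1) stop("a spectra set needs at least one sample")
  if (ncol(x$power) != length(f))
    stop("power has ", ncol(x$power), " columns but there are ",
         length(f), " frequency points")
  if (length(x$nitrogen_pct) != n || length(x$sample_ids) != n)
    stop("nitrogen_pct and sample_ids must have one entry per power row")
  if (anyDuplicated(x$sample_ids))
    stop("duplicate sample id: ", x$sample_ids[duplicated(x$sample_ids)][1])
  if (any(!is.finite(x$nitrogen_pct)) || any(x$nitrogen_pct < 0))
    stop("nitrogen_pct values must be finite and non-negative")
  if (!is.null(x$gradient_labels) && length(x$gradient_labels) != n)
    stop("gradient_labels must have one entry per sample")
  if (any(!is.finite(x$power)))
    stop("power values must be finite")
  x
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d samples x %d frequency points (%.4g - %.4g THz)\n",
              nrow(x$power), length(x$frequencies_thz),
              min(x$frequencies_thz), max(x$frequencies_thz)))
  cat(sprintf("  nitrogen: %.3g - %.3g %% mass\n",
              min(x$nitrogen_pct), max(x$nitrogen_pct)))
  if (!is.null(x$gradient_labels))
    cat("  gradients:", paste(unique(x$gradient_labels), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples in a spectra set
#' @param x a `spectra_set`.
#' @return integer.
#' @export
n_samples <- function(x) nrow(x$power)

#' Subset a spectra set by sample
#' @param x a `spectra_set`.
#' @param i integer sample indices.
#' @param ... unused.
#' @return a `spectra_set` with the selected samples.
#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$frequencies_thz, x$power[i, , drop = FALSE],
              x$nitrogen_pct[i], x$sample_ids[i],
              if (!is.null(x$gradient_labels)) x$gradient_labels[i])
}

# ---- spectra CSV dialect ---------------------------------------------------
# column 1 sample_id, column 2 nitrogen_pct, optional column 3 gradient,
# remaining columns numeric THz frequencies as headers; UTF-8, comma, dot.

#' Read a spectra CSV file
#'
#' The dialect: first column `sample_id`, second `nitrogen_pct`, optional
#' third `gradient`, remaining column headers are numeric THz frequencies.
#'
#' @param path file path.
#' @return a validated [spectra_set()].
#' @export
read_spectra <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "sample_id" || names(df)[2] != "nitrogen_pct")
    stop("not a spectra CSV: first columns must be sample_id, nitrogen_pct")
  has_gradient <- ncol(df) >= 3 && names(df)[3] == "gradient"
  first_freq <- if (has_gradient) 4L else 3L
  freq_names <- names(df)[first_freq:ncol(df)]
  freqs <- suppressWarnings(as.numeric(freq_names))
  if (any(is.na(freqs)))
    stop("non-numeric frequency header: ", freq_names[is.na(freqs)][1])
  power <- as.matrix(df[, first_freq:ncol(df), drop = FALSE])
  dimnames(power) <- NULL
  spectra_set(freqs, power, df$nitrogen_pct, df$sample_id,
              if (has_gradient) df$gradient)
}

#' Write a spectra set to CSV
#'
#' Frequencies are serialized with 8 significant digits, enough to round-trip
#' the generator's grid exactly at reading precision.
#'
#' @param data a `spectra_set`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path) {
  validate_spectra_set(data)
  if (nrow(data$power) == 0) stop("refusing to write an empty spectra set")
  df <- data.frame(sample_id = data$sample_ids,
                   nitrogen_pct = data$nitrogen_pct,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(data$gradient_labels)) df$gradient <- data$gradient_labels
  pw <- as.data.frame(data$power)
  names(pw) <- formatC(data$frequencies_thz, digits = 8, format = "g")
  df <- cbind(df, pw)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---- fit reports -----------------------------------------------------------

#' Construct a fit report
#'
#' The row schema of the final comparison tables: calibration and prediction
#' RMSE (% nitrogen) and determination coefficients for one
#' (selection, model) pair.
#'
#' @param rmsec_pct,rmsep_pct calibration / prediction RMSE (% nitrogen).
#' @param r2_cal,r2_pred calibration / prediction determination coefficients.
#' @param model_name,selection_name labels for the regressor and the band
#'   selector that produced the fit.
#' @param n_cal,n_pred calibration / prediction set sizes.
#' @return an object of class `fit_report`.
#' @export
fit_report <- function(rmsec_pct, rmsep_pct, r2_cal, r2_pred,
                       model_name, selection_name, n_cal, n_pred) {
  if (rmsec_pct < 0 || rmsep_pct < 0) stop("RMSE values must be >= 0")
  if (r2_cal > 1 + 1e-12 || r2_pred > 1 + 1e-12) stop("R^2 cannot exceed 1")
  structure(
    list(rmsec_pct = rmsec_pct, rmsep_pct = rmsep_pct,
         r2_cal = r2_cal, r2_pred = r2_pred,
         model_name = model_name, selection_name = selection_name,
         n_cal = as.integer(n_cal), n_pred = as.integer(n_pred)),
    class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s + %s: RMSEC %.4f%%  Rc2 %.4f  RMSEP %.4f%%  Rp2 %.4f  (n = %d/%d)\n",
              x$selection_name, x$model_name, x$rmsec_pct, x$r2_cal,
              x$rmsep_pct, x$r2_pred, x$n_cal, x$n_pred))
  invisible(x)
}

#' Write one or more fit reports to a JSON file
#'
#' Reports are stored as a JSON array of flat objects with fixed key names
#' (the `fit_report` fields); appending adds to the array.
#'
#' @param report a `fit_report` or a list of them.
#' @param path output file path.
#' @param append if `TRUE` and `path` exists, existing reports are kept.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, append = FALSE) {
  if (inherits(report, "fit_report")) report <- list(report)
  existing <- if (append && file.exists(path)) read_report(path) else list()
  all_reports <- c(existing, report)
  payload <- lapply(all_reports, function(r) unclass(r))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read fit reports back from JSON
#'
#' @param path file written by [write_report()].
#' @return list of `fit_report` objects.
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path)
  lapply(raw, function(r) {
    fit_report(r$rmsec_pct, r$rmsep_pct, r$r2_cal, r$r2_pred,
               r$model_name, r$selection_name, r$n_cal, r$n_pred)
  })
}
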