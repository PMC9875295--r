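#' Savitzky-Golay smoothing of a spectra set
#'
#' Each sample's spectrum is replaced by its Savitzky-Golay filtered version:
#' a polynomial of order `poly_order` is least-squares fitted over a sliding
#' window of `window_points` points and the centre point is replaced by the
#' fitted value. At the spectrum ends the window polynomial fitted on the
#' first/last full window is evaluated at the edge positions, so the output
#' grid stays aligned with the input (no truncation). Delegates to
#' [signal::sgolayfilt()].
#'
#' @param data a [spectra_set()].
#' @param window_points odd window width, >= 3 (default 7, the width used
#'   throughout this pipeline).
#' @param poly_order polynomial order, < `window_points` (default 2).
#' @return a `spectra_set` with smoothed power; frequencies, nitrogen values
#'   and ids unchanged.
#' @export
#' @examples
#' s <- generate_spectra(sim_config(n_gradients = 2, samples_per_gradient = 3,
#'                                  gradient_means_pct = c(2, 4),
#'                                  n_frequencies = 64))
#' sm <- sg_smooth(s)
sg_smooth <- function(data, window_points = 7, poly_order = 2) {
  validate_spectra_set(data)
  if (window_points < 3 || window_points %% 2 == 0)
    stop("window_points must be an odd integer >= 3")
  if (poly_order < 0 || poly_order >= window_points)
    stop("poly_order must be non-negative and smaller than window_points")
  if (ncol(data$power) < window_points)
    stop("spectrum has ", ncol(data$power),
         " points, shorter than the window (", window_points, ")")
  smoothed <- t(apply(data$power, 1L, signal::sgolayfilt,
                      p = poly_order, n = window_points))
  spectra_set(data$frequencies_thz, smoothed, data$nitrogen_pct,
              data$sample_ids, data$gradient_labels)
}
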