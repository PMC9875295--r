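#' Evaluate a trained regressor on a calibration/prediction split
#'
#' Computes RMSEC and Rc-squared on the calibration samples and RMSEP and
#' Rp-squared on the prediction samples, restricted to the selected
#' frequency variables — one row of the final comparison tables.
#'
#' @param model a fitted model with a `predict` method (`rbf_model`,
#'   `bpnn_model` or `pls_model`), trained on
#'   `data$power[split$cal_indices, selection]`.
#' @param data a [spectra_set()].
#' @param split a `split_result`.
#' @param selection integer indices of the selected frequency variables
#'   (defaults to the full spectrum).
#' @param model_name,selection_name labels for the report.
#' @return a [fit_report()].
#' @export
evaluate_model <- function(model, data, split,
                           selection = seq_along(data$frequencies_thz),
                           model_name = class(model)[1],
                           selection_name = "full") {
  validate_spectra_set(data)
  if (length(split$pred_indices) == 0) stop("empty prediction set")
  Xc <- data$power[split$cal_indices, selection, drop = FALSE]
  Xp <- data$power[split$pred_indices, selection, drop = FALSE]
  yc <- data$nitrogen_pct[split$cal_indices]
  yp <- data$nitrogen_pct[split$pred_indices]
  yc_hat <- predict(model, Xc)
  yp_hat <- predict(model, Xp)
  fit_report(rmsec_pct = rmse(yc, yc_hat),
             rmsep_pct = rmse(yp, yp_hat),
             r2_cal = r_squared(yc, yc_hat),
             r2_pred = r_squared(yp, yp_hat),
             model_name = model_name,
             selection_name = selection_name,
             n_cal = length(split$cal_indices),
             n_pred = length(split$pred_indices))
}
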