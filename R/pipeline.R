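#' Assemble a pipeline configuration
#'
#' One object drives the whole workflow: simulate or load spectra, smooth,
#' split into calibration/prediction sets, select characteristic frequency
#' bands, train a calibration model, evaluate. Every stochastic stage draws
#' its own sub-seed from `global_seed` via [derive_seed()], so a configuration
#' fully determines the result.
#'
#' @param smoothing list with `window_points`, `poly_order`.
#' @param split list with `method` (`"ks"` or `"rs"`) and `n_cal`.
#' @param selection list with `method` (`"uve"`, `"scars"`, `"ipls"` or
#'   `"none"`) plus per-method parameters (`n_components`, and e.g. `n_runs`,
#'   `mc_fraction`, `n_mc`, `n_folds` for SCARS; `n_intervals` for iPLS;
#'   `noise_scale`, `threshold_factor` for UVE).
#' @param model list with `name` (`"rbf"` or `"bpnn"`) plus parameters
#'   (`spread` or `spreads` for the RBF — when `spread` is `NULL` the sweep
#'   picks it; `hidden_size`, `learning_rate`, `max_epochs` for the BPNN).
#' @param simulation a [sim_config()] used when no `input` file is given; its
#'   seed is re-derived from `global_seed` unless `simulation_seed_fixed`.
#' @param input optional path to a spectra CSV to analyse instead of
#'   simulating.
#' @param global_seed integer master seed.
#' @param simulation_seed_fixed if `TRUE`, keep the seed stored in
#'   `simulation` instead of deriving one from `global_seed`.
#' @param output_dir optional directory; when set, every intermediate
#'   artifact (smoothed spectra CSV, split JSON, selection JSON, model
#'   parameters, report JSON, log) is written there.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(smoothing = list(window_points = 7, poly_order = 2),
                            split = list(method = "ks", n_cal = 60),
                            selection = list(method = "scars"),
                            model = list(name = "rbf"),
                            simulation = sim_config(),
                            input = NULL,
                            global_seed = 1,
                            simulation_seed_fixed = FALSE,
                            output_dir = NULL) {
  structure(list(smoothing = smoothing, split = split, selection = selection,
                 model = model, simulation = simulation, input = input,
                 global_seed = global_seed,
                 simulation_seed_fixed = simulation_seed_fixed,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' The file mirrors the [pipeline_config()] structure (top-level keys
#' `smoothing`, `split`, `selection`, `model`, `simulation`, `input`,
#' `global_seed`, `output_dir`); omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  defaults <- pipeline_config()
  for (key in c("smoothing", "split", "selection", "model")) {
    if (!is.null(raw[[key]])) defaults[[key]] <- utils::modifyList(defaults[[key]], raw[[key]])
  }
  if (!is.null(raw$simulation))
    defaults$simulation <- do.call(sim_config,
                                   utils::modifyList(unclass(sim_config()), raw$simulation))
  for (key in c("input", "global_seed", "output_dir", "simulation_seed_fixed")) {
    if (!is.null(raw[[key]])) defaults[[key]] <- raw[[key]]
  }
  defaults
}

pipeline_get <- function(lst, name, default) {
  if (is.null(lst[[name]])) default else lst[[name]]
}

persist <- function(output_dir, name, writer) {
  if (is.null(output_dir)) return(invisible(NULL))
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  writer(file.path(output_dir, name))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

pipeline_prepare <- function(config, log) {
  gs <- config$global_seed
  data <- run_stage("ingest", {
    if (!is.null(config$input)) {
      read_spectra(config$input)
    } else {
      sim <- config$simulation
      if (!isTRUE(config$simulation_seed_fixed))
        sim$seed <- derive_seed(gs, "simulate")
      log("simulate", sprintf("seed %d, %d samples x %d points", sim$seed,
                              sim$n_gradients * sim$samples_per_gradient,
                              sim$n_frequencies))
      generate_spectra(sim)
    }
  })
  smoothed <- run_stage("smooth", sg_smooth(
    data,
    window_points = pipeline_get(config$smoothing, "window_points", 7),
    poly_order = pipeline_get(config$smoothing, "poly_order", 2)))
  persist(config$output_dir, "smoothed_spectra.csv",
          function(p) write_spectra(smoothed, p))

  split <- run_stage("split", {
    n_cal <- pipeline_get(config$split, "n_cal", 60)
    if (tolower(pipeline_get(config$split, "method", "ks")) == "ks") {
      ks_split(smoothed, n_cal)
    } else {
      rs_split(smoothed, n_cal, seed = derive_seed(gs, "split"))
    }
  })
  log("split", sprintf("%s: %d cal / %d pred", split$method,
                       length(split$cal_indices), length(split$pred_indices)))
  persist(config$output_dir, "split.json", function(p)
    jsonlite::write_json(unclass(split), p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE))
  list(smoothed = smoothed, split = split)
}

pipeline_select <- function(config, smoothed, split, log, method = NULL) {
  gs <- config$global_seed
  sel_cfg <- config$selection
  if (!is.null(method)) sel_cfg$method <- method
  method <- tolower(pipeline_get(sel_cfg, "method", "scars"))
  X <- smoothed$power[split$cal_indices, , drop = FALSE]
  y <- smoothed$nitrogen_pct[split$cal_indices]
  ncomp <- pipeline_get(sel_cfg, "n_components",
                        switch(method, uve = 2, scars = 8, 5))
  run_stage(paste0("select-", method), {
    res <- switch(
      method,
      none = list(selected = seq_along(smoothed$frequencies_thz)),
      uve = uve_select(X, y, n_components = ncomp,
                       noise_scale = pipeline_get(sel_cfg, "noise_scale", 1e-10),
                       threshold_factor = pipeline_get(sel_cfg, "threshold_factor", 1),
                       seed = derive_seed(gs, "uve")),
      scars = scars_select(X, y, n_components = ncomp,
                           n_runs = pipeline_get(sel_cfg, "n_runs", 50),
                           mc_fraction = pipeline_get(sel_cfg, "mc_fraction", 0.8),
                           n_mc = pipeline_get(sel_cfg, "n_mc", 50),
                           n_folds = pipeline_get(sel_cfg, "n_folds", 10),
                           seed = derive_seed(gs, "scars")),
      ipls = ipls_select(X, y, smoothed$frequencies_thz,
                         n_intervals = pipeline_get(sel_cfg, "n_intervals", 22),
                         n_components = ncomp),
      stop("unknown selection method: ", method))
    log(paste0("select-", method),
        sprintf("%d variables; frequencies (THz): %s%s",
                length(res$selected),
                paste(utils::head(round(smoothed$frequencies_thz[res$selected], 4), 8),
                      collapse = ", "),
                if (length(res$selected) > 8) ", ..." else ""))
    persist(config$output_dir, paste0("selection_", method, ".json"), function(p)
      jsonlite::write_json(list(method = method, selected = res$selected,
                                frequencies_thz = smoothed$frequencies_thz[res$selected]),
                           p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
    res
  })
}

pipeline_train_eval <- function(config, smoothed, split, selection, sel_name,
                                log, model_name = NULL) {
  gs <- config$global_seed
  mdl_cfg <- config$model
  if (!is.null(model_name)) mdl_cfg$name <- model_name
  name <- tolower(pipeline_get(mdl_cfg, "name", "rbf"))
  Xc <- smoothed$power[split$cal_indices, selection, drop = FALSE]
  yc <- smoothed$nitrogen_pct[split$cal_indices]
  model <- run_stage(paste0("train-", name), switch(
    name,
    rbf = {
      spread <- pipeline_get(mdl_cfg, "spread", NULL)
      if (is.null(spread)) {
        sweep_res <- rbf_spread_sweep(
          Xc, yc, pipeline_get(mdl_cfg, "spreads", seq(0.1, 1, by = 0.1)))
        spread <- sweep_res$best_spread
        log("train-rbf", sprintf("spread sweep chose %.2g", spread))
      }
      rbf_train(Xc, yc, spread)
    },
    bpnn = bpnn_train(Xc, yc,
                      hidden_size = pipeline_get(mdl_cfg, "hidden_size", 6),
                      learning_rate = pipeline_get(mdl_cfg, "learning_rate", 0.01),
                      max_epochs = pipeline_get(mdl_cfg, "max_epochs", 22),
                      seed = derive_seed(gs, "bpnn")),
    stop("unknown model: ", name)))
  report <- run_stage("evaluate",
                      evaluate_model(model, smoothed, split, selection,
                                     model_name = toupper(name),
                                     selection_name = toupper(sel_name)))
  log("evaluate", format_report_line(report))
  list(model = model, report = report)
}

format_report_line <- function(r) {
  sprintf("%s+%s RMSEC=%.4f Rc2=%.4f RMSEP=%.4f Rp2=%.4f",
          r$selection_name, r$model_name, r$rmsec_pct, r$r2_cal,
          r$rmsep_pct, r$r2_pred)
}

make_logger <- function(config, verbose) {
  lines <- character(0)
  log <- function(stage, msg) {
    line <- sprintf("[%s] %s", stage, msg)
    lines[[length(lines) + 1L]] <<- line
    if (verbose) message(line)
    invisible(NULL)
  }
  list(log = log, lines = function() lines)
}

#' Run the full pipeline under one configuration
#'
#' Executes the stages in order — ingest/simulate, smooth, split, select,
#' train, evaluate — and returns the final [fit_report()]. With an
#' `output_dir`, every intermediate artifact and a plain-text log (seeds,
#' parameters, selected frequencies) are written there; the report JSON is
#' free of timestamps, so identical configurations produce byte-identical
#' reports.
#'
#' @param config a [pipeline_config()].
#' @param verbose emit progress messages.
#' @return a `fit_report`; the log, split, selection and model are attached
#'   as attributes `log`, `split`, `selection`, `model`.
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = FALSE) {
  lg <- make_logger(config, verbose)
  lg$log("config", sprintf("global seed %d", config$global_seed))
  prep <- pipeline_prepare(config, lg$log)
  sel_method <- tolower(pipeline_get(config$selection, "method", "scars"))
  sel <- pipeline_select(config, prep$smoothed, prep$split, lg$log)
  fit <- pipeline_train_eval(config, prep$smoothed, prep$split, sel$selected,
                             sel_method, lg$log)
  persist(config$output_dir, "report.json",
          function(p) write_report(fit$report, p))
  persist(config$output_dir, "pipeline.log",
          function(p) writeLines(lg$lines(), p))
  structure(fit$report, log = lg$lines(), split = prep$split,
            selection = sel, model = fit$model)
}

#' Run the selection-by-model comparison matrix
#'
#' Shares one simulated/loaded, smoothed and split data set across all
#' (selection, model) pairs, computes each selection once, trains and
#' evaluates every pair, and returns the grid of reports — the structure of
#' the final comparison tables. A failing cell is recorded as an error
#' message without aborting the others.
#'
#' @param config a [pipeline_config()]; its own `selection$method` and
#'   `model$name` are ignored in favour of the grids.
#' @param selections character vector of selection methods.
#' @param models character vector of model names.
#' @param verbose emit progress messages.
#' @return list with `reports` (list of `fit_report` or `try-error`, named
#'   `"<selection>_<model>"`), `table` (data.frame of the successful cells),
#'   and `selections` (the per-method selection results).
#' @export
run_matrix <- function(config = pipeline_config(),
                       selections = c("uve", "scars", "ipls"),
                       models = c("rbf", "bpnn"),
                       verbose = FALSE) {
  if (length(selections) == 0 || length(models) == 0)
    stop("selections and models must be non-empty")
  lg <- make_logger(config, verbose)
  prep <- pipeline_prepare(config, lg$log)
  sels <- lapply(selections, function(s)
    pipeline_select(config, prep$smoothed, prep$split, lg$log, method = s))
  names(sels) <- selections
  reports <- list()
  for (s in selections) {
    for (m in models) {
      cell <- paste0(s, "_", m)
      reports[[cell]] <- tryCatch(
        pipeline_train_eval(config, prep$smoothed, prep$split,
                            sels[[s]]$selected, s, lg$log,
                            model_name = m)$report,
        error = function(e) {
          lg$log(cell, paste("FAILED:", conditionMessage(e)))
          structure(conditionMessage(e), class = "try-error")
        })
    }
  }
  ok <- !vapply(reports, inherits, logical(1), "try-error")
  tab <- do.call(rbind, lapply(reports[ok], function(r)
    data.frame(selection = r$selection_name, model = r$model_name,
               rmsec_pct = r$rmsec_pct, r2_cal = r$r2_cal,
               rmsep_pct = r$rmsep_pct, r2_pred = r$r2_pred)))
  rownames(tab) <- NULL
  persist(config$output_dir, "matrix_report.json",
          function(p) write_report(reports[ok], p))
  persist(config$output_dir, "pipeline.log",
          function(p) writeLines(lg$lines(), p))
  list(reports = reports, table = tab, selections = sels,
       split = prep$split, log = lg$lines())
}
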