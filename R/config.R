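#' Default pipeline configuration
#'
#' A nested list holding every tunable parameter of the pipeline: simulator
#' settings, preprocessing (target rate, wavelet, levels, threshold mode),
#' segmentation windows, EWT band boundaries and transition width, classifier
#' grids and the master seed. Values not overridden keep their defaults.
#'
#' @param ... named overrides, e.g. `default_config(seed = 7)` or nested
#'   `default_config(ewt = list(boundaries_hz = c(120, 450)))` (nested lists
#'   are merged element-wise).
#' @return a named list of class `pcg_config`.
#' @export
default_config <- function(...) {
  cfg <- list(
    seed = 20260909L,
    preprocess = list(
      target_fs = 2000,
      wavelet = "sym3",
      levels = 3L,
      threshold_mode = "soft"
    ),
    segmentation = list(
      highpass_hz = 200,
      envelope_smooth_ms = 20,
      peak_threshold_frac = 0.30,
      peak_threshold_quantile = 0.95,
      min_peak_separation_s = 0.200,
      diastole_offset_s = 0.100,
      diastole_duration_s = 0.128,
      n_keep = 10L,
      use_r_times = TRUE
    ),
    ewt = list(
      boundaries_hz = c(150, 500),
      tau_over_pi = 0.1,
      nfft = 1024L
    ),
    sim = sim_params(),
    classify = list(
      train_n = 60L,
      test_n = 15L,
      test_class_counts = c(mild = 5L, moderate = 4L, severe = 6L),
      cv_folds = 5L,
      svm_C_grid = c(0.1, 0.32, 1, 3.2, 10),
      svm_gamma_grid = c(0.001, 0.0032, 0.01, 0.032, 0.1),
      xgb_n_grid = c(100L, 300L, 500L),
      xgb_lr_grid = c(0.01, 0.05, 0.1),
      xgb_depth_grid = c(3L, 5L, 7L),
      xgb_subsample_grid = c(0.7, 0.8, 1.0)
    )
  )
  merge_config(cfg, list(...))
}

merge_config <- function(base, overrides) {
  for (nm in names(overrides)) {
    if (is.list(base[[nm]]) && is.list(overrides[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], overrides[[nm]])
    } else {
      base[[nm]] <- overrides[[nm]]
    }
  }
  class(base) <- "pcg_config"
  base
}

#' Read / write a pipeline configuration file (JSON)
#'
#' @param path file path.
#' @return for `read_config`, a `pcg_config` list merged over the defaults.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  merge_config(default_config(), raw)
}

#' @rdname read_config
#' @param config a `pcg_config` list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
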