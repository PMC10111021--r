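# One-call orchestration of the five stages (simulate -> [voxelize/clean/
# re-mesh] -> align -> encode -> predict) under a single validated
# configuration with one master seed.

.pipeline_defaults <- function() list(
  K = 66L,                  # subjects
  n_points = 5000L,         # points per corresponded cloud
  noise_sd = 0.05,          # outcome noise SD (fractional LVMI units)
  n_theta = 56L, n_phi = 72L,  # mesh resolution
  voxel_stage = FALSE,      # run voxelize -> clean -> extract_surface
  voxel_spacing_mm = 1.0,
  cube_diameter_vox = 5L,   # closing structuring element
  ball_diameter_vox = 5L,   # median footprint
  smooth_iterations = 20L,  # Laplacian iterations
  relaxation = 0.1,         # Laplacian relaxation factor
  icp_max_iters = 100L,
  icp_tol = 1e-8,
  refine_passes = 1L,
  encoder = "pls",
  n_components = 5L,
  svr_c = 1.0,
  svr_epsilon = 0.1,
  test_fraction = 0.15,
  vip_threshold = 2.6,
  seed = 1L,
  out_dir = NULL
)

#' Build and validate a pipeline configuration
#'
#' Starts from defaults, overrides with named arguments, and range-checks
#' every value. Unknown keys are rejected.
#'
#' @param ... named overrides of the default configuration.
#' @return a validated named list of class `lv_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- .pipeline_defaults()
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all configuration overrides must be named")
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(defaults, over)
  chk <- function(cond, key, msg) if (!cond) stop("config `", key, "`: ", msg)
  chk(cfg$K >= 3, "K", "must be >= 3")
  chk(cfg$n_points >= 10, "n_points", "must be >= 10")
  chk(cfg$noise_sd >= 0, "noise_sd", "must be >= 0")
  chk(cfg$relaxation >= 0 && cfg$relaxation <= 1, "relaxation",
      "must be in [0, 1]")
  chk(cfg$test_fraction > 0 && cfg$test_fraction < 1, "test_fraction",
      "must be in (0, 1)")
  chk(cfg$encoder %in% c("pls", "pca"), "encoder", "must be 'pls' or 'pca'")
  chk(cfg$n_components >= 1, "n_components", "must be >= 1")
  chk(cfg$cube_diameter_vox %% 2 == 1, "cube_diameter_vox", "must be odd")
  chk(cfg$svr_c > 0, "svr_c", "must be > 0")
  chk(cfg$svr_epsilon >= 0, "svr_epsilon", "must be >= 0")
  chk(cfg$voxel_spacing_mm > 0, "voxel_spacing_mm", "must be > 0")
  chk(cfg$seed == as.integer(cfg$seed), "seed", "must be an integer")
  structure(cfg, class = c("lv_config", "list"))
}

#' Load a pipeline configuration from a YAML file
#' @param path YAML file; an empty file yields all defaults.
#' @return validated `lv_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(pipeline_config, vals)
}

#' Save a pipeline configuration to YAML
#' @param config an `lv_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config)[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

config_hash <- function(config) {
  # order-independent digest of the configuration values
  keys <- sort(names(config))
  txt <- paste(keys, vapply(config[keys], function(v)
    paste(format(v, digits = 15), collapse = ","), character(1)),
    collapse = ";")
  sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1))
}

#' Run the full shape-to-outcome pipeline
#'
#' Simulates a cohort, optionally pushes every subject through the
#' label-volume stage (voxelize, clean, re-mesh), builds the corresponded
#' cohort, fits PLS and PCA encoders, evaluates the SVR predictor against
#' the clinical baseline, and computes VIP localization. All randomness
#' derives from `config$seed`. If `config$out_dir` is set, stage outputs
#' (cohort.csv, deviations.csv, mean_shape.ply, scores.csv,
#' variance_explained.csv, vip_per_point.csv, predictions.csv,
#' eval_report.json) are written there; the expensive alignment stage is
#' cached on disk keyed by a configuration hash and reused on reruns.
#'
#' @param config an `lv_config` from [pipeline_config()].
#' @return an `lv_run_report` list with the cohort, evaluations, VIP result
#'   and per-stage timings.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "lv_config"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- t1 - t0
    t0 <<- t1
  }

  truth <- ground_truth(noise_sd = config$noise_sd)
  synth <- generate_cohort(K = config$K, truth = truth, seed = config$seed,
                           n_theta = config$n_theta, n_phi = config$n_phi)
  tick("simulate")

  meshes <- synth$meshes
  if (config$voxel_stage) {
    meshes <- lapply(meshes, function(m) {
      lab <- voxelize(m, spacing_mm = config$voxel_spacing_mm)
      lab <- clean_label(lab, config$cube_diameter_vox, config$ball_diameter_vox)
      extract_surface(lab, config$smooth_iterations, config$relaxation)
    })
    tick("mask2mesh")
  }

  hash <- config_hash(config)
  cache_file <- if (!is.null(config$out_dir))
    file.path(config$out_dir, sprintf("aligned_cache_%d.rds", hash)) else NULL
  cohort <- NULL
  if (!is.null(cache_file) && file.exists(cache_file))
    cohort <- readRDS(cache_file)
  if (is.null(cohort)) {
    cohort <- build_cohort(meshes, synth$outcomes, synth$covariates,
                           n_points = config$n_points, seed = config$seed,
                           refine_passes = config$refine_passes,
                           max_iters = config$icp_max_iters, tol = config$icp_tol)
  }
  tick("align")

  pls_model <- fit_pls(cohort$deviations, cohort$outcomes, config$n_components,
                       mean_shape = cohort$mean_shape)
  pca_model <- fit_pca(cohort$deviations, config$n_components,
                       y = cohort$outcomes, mean_shape = cohort$mean_shape)
  vip_res <- vip(pls_model, threshold = config$vip_threshold)
  tick("encode")

  eval_pls <- evaluate_prediction(cohort, "pls", config$n_components,
                                  config$test_fraction, config$seed,
                                  C = config$svr_c, epsilon = config$svr_epsilon)
  eval_pca <- evaluate_prediction(cohort, "pca", config$n_components,
                                  config$test_fraction, config$seed,
                                  C = config$svr_c, epsilon = config$svr_epsilon)
  eval_base <- evaluate_baseline(cohort, config$test_fraction, config$seed)
  tick("predict")

  report <- structure(list(
    config = config, config_hash = hash, cohort = cohort, synth = synth,
    pls_model = pls_model, pca_model = pca_model, vip = vip_res,
    eval_pls = eval_pls, eval_pca = eval_pca, eval_baseline = eval_base,
    reference_index = cohort$reference_index, timings = timings),
    class = "lv_run_report")

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_run_outputs(report, config$out_dir)
  }
  report
}

#' @export
print.lv_run_report <- function(x, ...) {
  cat("lv_run_report\n")
  cat(sprintf("  reference shape: #%s\n", x$reference_index))
  for (e in list(x$eval_pls, x$eval_pca, x$eval_baseline))
    cat(sprintf("  %-8s test RMSE %.3f, test R2 %.3f\n", e$encoder,
                e$rmse_test, e$r2_test))
  invisible(x)
}

write_run_outputs <- function(report, out_dir) {
  cohort <- report$cohort
  cfg <- report$config
  write.csv(as.data.frame(report$synth),
            file.path(out_dir, "cohort.csv"), row.names = FALSE)
  dev <- as.data.frame(cohort$deviations)
  names(dev) <- paste0("v", seq_len(ncol(dev)))
  write.csv(dev, file.path(out_dir, "deviations.csv"), row.names = FALSE)
  saveRDS(cohort, file.path(out_dir,
                            sprintf("aligned_cache_%d.rds", report$config_hash)))
  write_ply(lv_cloud(cohort$mean_shape), file.path(out_dir, "mean_shape.ply"))
  sc <- as.data.frame(report$pls_model$scores)
  names(sc) <- paste0("score_", seq_len(ncol(sc)))
  write.csv(sc, file.path(out_dir, "scores.csv"), row.names = FALSE)
  ev <- explained_variance_curve(report$pls_model, cohort$outcomes)
  write.csv(data.frame(component = seq_along(ev$per_component),
                       per_component = ev$per_component,
                       cumulative = ev$cumulative),
            file.path(out_dir, "variance_explained.csv"), row.names = FALSE)
  write.csv(data.frame(point = seq_along(report$vip$per_point),
                       vip = report$vip$per_point,
                       above_threshold = report$vip$per_point > report$vip$threshold),
            file.path(out_dir, "vip_per_point.csv"), row.names = FALSE)
  ep <- report$eval_pls
  pred <- data.frame(
    subject_id = c(ep$split$train, ep$split$test),
    split = rep(c("train", "test"), c(length(ep$split$train), length(ep$split$test))),
    y = c(ep$y[ep$split$train], ep$y[ep$split$test]),
    y_hat = c(ep$y_hat_train, ep$y_hat_test))
  write.csv(pred[order(pred$subject_id), ],
            file.path(out_dir, "predictions.csv"), row.names = FALSE)
  summary <- list(
    reference_index = report$reference_index,
    n_components = cfg$n_components,
    seed = cfg$seed,
    config_hash = report$config_hash,
    icp_iterations = if (!is.null(cohort$icp_report)) cohort$icp_report$iterations,
    metrics = list(
      pls = list(rmse_test = ep$rmse_test, r2_test = ep$r2_test,
                 rmse_train = ep$rmse_train, r2_train = ep$r2_train),
      pca = list(rmse_test = report$eval_pca$rmse_test,
                 r2_test = report$eval_pca$r2_test),
      baseline = list(rmse_test = report$eval_baseline$rmse_test,
                      r2_test = report$eval_baseline$r2_test)),
    timings = as.list(report$timings))
  jsonlite::write_json(summary, file.path(out_dir, "eval_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Sweep the number of shape components
#'
#' Re-evaluates the predictor at several component counts, reporting train
#' and test metrics for each.
#'
#' @param cohort an `lv_cohort`.
#' @param nc_values component counts to try (default 3, 4, 5, 6).
#' @param ... passed to [evaluate_prediction()].
#' @return data.frame with one row per component count.
#' @export
sweep_components <- function(cohort, nc_values = c(3L, 4L, 5L, 6L), ...) {
  rows <- lapply(nc_values, function(nc) {
    ev <- evaluate_prediction(cohort, n_components = nc, ...)
    data.frame(n_components = nc, rmse_train = ev$rmse_train,
               rmse_test = ev$rmse_test, r2_train = ev$r2_train,
               r2_test = ev$r2_test)
  })
  do.call(rbind, rows)
}
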