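# Outcome definition, SVR prediction from shape scores, RMSE / R-squared
# evaluation, and the bivariate clinical baseline regression.

#' Fractional one-year LVMI regression
#'
#' `(post - pre) / pre`: the fractional change in left ventricular mass
#' index one year after the intervention (negative = mass regression).
#'
#' @param pre pre-intervention LVMI (> 0).
#' @param post one-year LVMI.
#' @return fractional change (vectorized).
#' @export
lvmi_regression <- function(pre, post) {
  if (any(pre <= 0)) stop("pre-intervention LVMI must be > 0")
  (post - pre) / pre
}

#' Random train/test split of a cohort
#'
#' @param K number of subjects (>= 2).
#' @param test_fraction fraction held out (default 0.15); the test set has
#'   `round(test_fraction * K)` subjects, at least 1.
#' @param seed integer seed; the split is reproducible from it.
#' @return list with sorted integer vectors `train` and `test` (disjoint,
#'   exhaustive).
#' @export
split_cohort <- function(K, test_fraction = 0.15, seed = 1L) {
  if (K < 2L) stop("K must be >= 2")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  n_test <- max(1L, as.integer(round(test_fraction * K)))
  if (n_test >= K) stop("test_fraction leaves an empty training set")
  set.seed(seed)
  test <- sort(sample.int(K, n_test))
  list(train = setdiff(seq_len(K), test), test = test)
}

#' Root-mean-square error
#' @param y,y_hat equal-length numeric vectors.
#' @return sqrt(mean squared error).
#' @export
rmse <- function(y, y_hat) {
  if (length(y) == 0L) stop("empty input")
  if (length(y) != length(y_hat)) stop("length mismatch")
  sqrt(mean((y - y_hat)^2))
}

#' Coefficient of determination (R-squared)
#'
#' `1 - sum((y - y_hat)^2) / sum((y - mean(y))^2)`. Equals 1 for perfect
#' prediction, 0 for the mean predictor, and may be negative for predictors
#' worse than the mean.
#'
#' @param y,y_hat equal-length numeric vectors; y must not be constant.
#' @return R-squared (<= 1).
#' @export
r2_score <- function(y, y_hat) {
  if (length(y) < 2L) stop("need at least two observations")
  if (length(y) != length(y_hat)) stop("length mismatch")
  tot <- sum((y - mean(y))^2)
  if (tot == 0) stop("constant outcome: R-squared undefined")
  1 - sum((y - y_hat)^2) / tot
}

#' Fit a linear-kernel SVR on shape scores
#'
#' Features are standardized with training statistics and the outcome is
#' z-scored before fitting an epsilon-insensitive linear support vector
#' regression; predictions are returned on the normalized outcome scale,
#' with the inverse transform stored on the object.
#'
#' @param scores_train n x m feature matrix (shape scores).
#' @param y_train outcome vector.
#' @param C SVR cost parameter.
#' @param epsilon insensitivity tube half-width (normalized outcome units).
#' @return an object of class `lv_predictor` (kind "svr_linear").
#' @export
fit_svr <- function(scores_train, y_train, C = 1, epsilon = 0.1) {
  X <- as.matrix(scores_train)
  if (nrow(X) != length(y_train)) stop("row/outcome mismatch")
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  if (any(scl == 0)) {
    warning("constant feature(s) in SVR input")
    scl[scl == 0] <- 1
  }
  y_center <- mean(y_train)
  y_scale <- sd(y_train)
  if (y_scale == 0) stop("constant training outcome")
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  ys <- (y_train - y_center) / y_scale
  fit <- e1071::svm(Xs, ys, type = "eps-regression", kernel = "linear",
                    cost = C, epsilon = epsilon, scale = FALSE)
  structure(list(kind = "svr_linear", fit = fit, center = ctr, scale = scl,
                 y_center = y_center, y_scale = y_scale,
                 hyperparameters = list(C = C, epsilon = epsilon)),
            class = "lv_predictor")
}

#' Fit the bivariate clinical baseline regression
#'
#' Ordinary least squares of the outcome on pre-intervention LVMI (t1) and
#' LVEF (t2): `y = p0 + p1 t1 + p2 t2`.
#'
#' @param pre_lvmi,lvef clinical covariates (length K >= 3).
#' @param y outcome.
#' @return an `lv_predictor` (kind "baseline_bivariate") with coefficients
#'   `p0`, `p1`, `p2`.
#' @export
fit_baseline_bivariate <- function(pre_lvmi, lvef, y) {
  K <- length(y)
  if (K < 3L) stop("need K >= 3")
  X <- cbind(1, pre_lvmi, lvef)
  if (qr(X)$rank < 3L) stop("collinear covariates: baseline fit undefined")
  fit <- lm(y ~ pre_lvmi + lvef)
  cf <- coef(fit)
  structure(list(kind = "baseline_bivariate", fit = fit,
                 p0 = unname(cf[1]), p1 = unname(cf[2]), p2 = unname(cf[3]),
                 y_center = mean(y), y_scale = sd(y)),
            class = "lv_predictor")
}

#' @export
print.lv_predictor <- function(x, ...) {
  if (x$kind == "baseline_bivariate")
    cat(sprintf("lv_predictor (baseline): y = %.4g + %.4g t1 + %.4g t2\n",
                x$p0, x$p1, x$p2))
  else
    cat(sprintf("lv_predictor (%s): C = %g, epsilon = %g\n", x$kind,
                x$hyperparameters$C, x$hyperparameters$epsilon))
  invisible(x)
}

#' Predict from a fitted predictor
#' @param object an `lv_predictor`.
#' @param newdata feature matrix (scores) or data.frame with pre_lvmi/lvef.
#' @param output "normalized" (z-scored outcome units, default) or
#'   "original".
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.lv_predictor <- function(object, newdata,
                                 output = c("normalized", "original"), ...) {
  output <- match.arg(output)
  if (object$kind == "svr_linear") {
    Xs <- sweep(sweep(as.matrix(newdata), 2, object$center), 2, object$scale, "/")
    pred_norm <- as.vector(predict(object$fit, Xs))
  } else {
    raw <- object$p0 + object$p1 * newdata$pre_lvmi + object$p2 * newdata$lvef
    pred_norm <- (raw - object$y_center) / object$y_scale
  }
  if (output == "normalized") pred_norm
  else pred_norm * object$y_scale + object$y_center
}

#' End-to-end evaluation of outcome prediction from a cohort
#'
#' Splits the cohort, fits the shape encoder on the training subjects only
#' (the supervised PLS encoder never sees test outcomes; this leakage guard
#' is structural), projects both sides onto the modes, fits the linear SVR
#' on training scores, and reports train/test RMSE (on the normalized
#' outcome scale) and R-squared. Optionally appends the clinical covariates
#' (pre_lvmi, lvef) to the score vectors.
#'
#' @param cohort an `lv_cohort` from [build_cohort()].
#' @param encoder "pls" or "pca".
#' @param n_components number of shape modes fed to the predictor.
#' @param test_fraction held-out fraction (default 0.15).
#' @param seed split seed.
#' @param C,epsilon SVR hyperparameters.
#' @param extra_covariates append (pre_lvmi, lvef) to the scores.
#' @param encoder_fit "per_split" (default, leakage-safe) fits the encoder
#'   on training rows only; "full_data" reproduces the ambiguous
#'   fit-once-on-everything alternative and flags the report as leaky.
#' @return an object of class `lv_eval` with rmse/r2 for train and test,
#'   the split, predictions, and metadata.
#' @export
evaluate_prediction <- function(cohort, encoder = c("pls", "pca"),
                                n_components = 5L, test_fraction = 0.15,
                                seed = 1L, C = 1, epsilon = 0.1,
                                extra_covariates = FALSE,
                                encoder_fit = c("per_split", "full_data")) {
  encoder <- match.arg(encoder)
  encoder_fit <- match.arg(encoder_fit)
  stopifnot(inherits(cohort, "lv_cohort"))
  K <- nrow(cohort$deviations)
  split <- split_cohort(K, test_fraction, seed)
  y <- cohort$outcomes
  X <- cohort$deviations
  fit_rows <- if (encoder_fit == "per_split") split$train else seq_len(K)
  model <- if (encoder == "pls")
    fit_pls(X[fit_rows, , drop = FALSE], y[fit_rows], n_components)
  else
    fit_pca(X[fit_rows, , drop = FALSE], n_components, y = y[fit_rows])
  sc_train <- project_scores(model, X[split$train, , drop = FALSE])
  sc_test <- project_scores(model, X[split$test, , drop = FALSE])
  if (extra_covariates) {
    if (is.null(cohort$covariates)) stop("cohort has no covariates")
    cv <- as.matrix(cohort$covariates[, c("pre_lvmi", "lvef")])
    sc_train <- cbind(sc_train, cv[split$train, , drop = FALSE])
    sc_test <- cbind(sc_test, cv[split$test, , drop = FALSE])
  }
  svr <- fit_svr(sc_train, y[split$train], C = C, epsilon = epsilon)
  yn_train <- (y[split$train] - svr$y_center) / svr$y_scale
  yn_test <- (y[split$test] - svr$y_center) / svr$y_scale
  pred_train <- predict(svr, sc_train)
  pred_test <- predict(svr, sc_test)
  structure(list(
    rmse_train = rmse(yn_train, pred_train),
    rmse_test = rmse(yn_test, pred_test),
    r2_train = r2_score(yn_train, pred_train),
    r2_test = if (length(split$test) >= 2L) r2_score(yn_test, pred_test) else NA_real_,
    split = split, test_fraction = test_fraction, seed = seed,
    encoder = encoder, n_components = model$n_components,
    leakage_free = encoder_fit == "per_split",
    y = y, y_hat_test = pred_test * svr$y_scale + svr$y_center,
    y_hat_train = pred_train * svr$y_scale + svr$y_center,
    predictor = svr, shape_model = model), class = "lv_eval")
}

#' Evaluate the clinical bivariate baseline on the same split protocol
#'
#' @inheritParams evaluate_prediction
#' @return an `lv_eval` for the baseline regression, metrics on the same
#'   normalized outcome scale as [evaluate_prediction()].
#' @export
evaluate_baseline <- function(cohort, test_fraction = 0.15, seed = 1L) {
  stopifnot(inherits(cohort, "lv_cohort"))
  if (is.null(cohort$covariates)) stop("cohort has no covariates")
  K <- nrow(cohort$deviations)
  split <- split_cohort(K, test_fraction, seed)
  y <- cohort$outcomes
  cv <- cohort$covariates
  base <- fit_baseline_bivariate(cv$pre_lvmi[split$train], cv$lvef[split$train],
                                 y[split$train])
  yn_train <- (y[split$train] - base$y_center) / base$y_scale
  yn_test <- (y[split$test] - base$y_center) / base$y_scale
  pred_train <- predict(base, cv[split$train, ])
  pred_test <- predict(base, cv[split$test, ])
  structure(list(
    rmse_train = rmse(yn_train, pred_train),
    rmse_test = rmse(yn_test, pred_test),
    r2_train = r2_score(yn_train, pred_train),
    r2_test = if (length(split$test) >= 2L) r2_score(yn_test, pred_test) else NA_real_,
    split = split, test_fraction = test_fraction, seed = seed,
    encoder = "baseline", n_components = 0L, leakage_free = TRUE,
    y = y, y_hat_test = pred_test * base$y_scale + base$y_center,
    y_hat_train = pred_train * base$y_scale + base$y_center,
    predictor = base), class = "lv_eval")
}

#' @export
print.lv_eval <- function(x, ...) {
  cat(sprintf(
    "lv_eval (%s, nc=%d): train RMSE %.3f / R2 %.3f; test RMSE %.3f / R2 %.3f\n",
    x$encoder, x$n_components, x$rmse_train, x$r2_train, x$rmse_test, x$r2_test))
  invisible(x)
}

#' Small grid search over SVR hyperparameters
#'
#' Evaluates the shape-score predictor over a grid of cost and epsilon
#' values, reporting median held-out metrics across split seeds.
#'
#' @param cohort an `lv_cohort`.
#' @param C_grid,epsilon_grid hyperparameter grids.
#' @param n_components shape modes fed to the predictor.
#' @param seeds split seeds to median over.
#' @param ... passed to [evaluate_prediction()].
#' @return data.frame with one row per (C, epsilon) pair, sorted by median
#'   test RMSE.
#' @export
svr_grid_search <- function(cohort, C_grid = c(0.1, 1, 10),
                            epsilon_grid = c(0.01, 0.1, 0.3),
                            n_components = 5L, seeds = 1:5, ...) {
  grid <- expand.grid(C = C_grid, epsilon = epsilon_grid)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    evs <- lapply(seeds, function(s)
      evaluate_prediction(cohort, n_components = n_components, seed = s,
                          C = grid$C[i], epsilon = grid$epsilon[i], ...))
    data.frame(C = grid$C[i], epsilon = grid$epsilon[i],
               rmse_test = median(vapply(evs, `[[`, numeric(1), "rmse_test")),
               r2_test = median(vapply(evs, `[[`, numeric(1), "r2_test")))
  })
  out <- do.call(rbind, rows)
  out[order(out$rmse_test), ]
}
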