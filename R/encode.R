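# Shape encoding of the deviation matrix: supervised PLS1 (NIPALS) and
# unsupervised PCA, plus mode reconstruction, variance-explained curves,
# mode-variation shapes and VIP variable importance.

.fix_signs <- function(modes) {
  # sign convention: each mode's largest-magnitude entry is positive
  apply(modes, 2, function(u) if (u[which.max(abs(u))] < 0) -1 else 1)
}

#' Fit a supervised PLS1 shape model
#'
#' Univariate-response NIPALS partial least squares with deflation: each
#' component's weight vector maximizes covariance with the (deflated)
#' outcome. Stores weights (for VIP), loadings (the shape modes U_m),
#' scores (a_km) and the per-component explained outcome variance
#' (incremental in-sample R-squared of y on the leading scores).
#'
#' @param deviations K x p deviation matrix (rows: flattened shapes minus
#'   the mean shape).
#' @param y length-K outcome.
#' @param n_components number of components (< K).
#' @param mean_shape optional N x 3 mean shape for reconstruction.
#' @return an object of class `lv_shape_model` (method "pls").
#' @export
fit_pls <- function(deviations, y, n_components = 5L, mean_shape = NULL) {
  X <- as.matrix(deviations)
  K <- nrow(X)
  p <- ncol(X)
  if (length(y) != K) stop("y length must match rows of deviations")
  if (sd(y) == 0) stop("constant outcome: PLS undefined")
  if (n_components >= K) stop("n_components must be < number of subjects")
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  y_center <- mean(y)
  yc <- y - y_center
  A <- n_components
  W <- matrix(0, p, A)
  P <- matrix(0, p, A)
  Tm <- matrix(0, K, A)
  q <- numeric(A)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    w <- crossprod(Xc, yc)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-300) {
      A <- a - 1L
      warning("outcome fully deflated after ", A, " components")
      break
    }
    w <- w / nw
    t_ <- as.vector(Xc %*% w)
    tt <- sum(t_^2)
    p_ <- as.vector(crossprod(Xc, t_)) / tt
    q_a <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, p_)
    yc <- yc - q_a * t_
    W[, a] <- w
    P[, a] <- p_
    Tm[, a] <- t_
    q[a] <- q_a
    ssy[a] <- q_a^2 * tt
  }
  if (A == 0L) stop("no usable PLS components")
  W <- W[, seq_len(A), drop = FALSE]
  P <- P[, seq_len(A), drop = FALSE]
  Tm <- Tm[, seq_len(A), drop = FALSE]
  q <- q[seq_len(A)]
  ssy <- ssy[seq_len(A)]
  sgn <- .fix_signs(P)
  W <- sweep(W, 2, sgn, "*")
  P <- sweep(P, 2, sgn, "*")
  Tm <- sweep(Tm, 2, sgn, "*")
  q <- q * sgn
  rotation <- W %*% solve(crossprod(P, W))
  model <- structure(list(method = "pls", modes = P, scores = Tm, weights = W,
                          q = q, ssy = ssy, rotation = rotation,
                          center = center, y_center = y_center,
                          n_components = A, mean_shape = mean_shape),
                     class = "lv_shape_model")
  model$explained_outcome_variance <-
    explained_variance_curve(model, y)$per_component
  model
}

#' Fit an unsupervised PCA shape model
#'
#' Modes are the leading right singular vectors (eigenvectors of the
#' deviation covariance), orthonormal; scores are the projections. The
#' outcome, if supplied, is used only to report explained outcome variance.
#'
#' @inheritParams fit_pls
#' @param y optional outcome for the variance-explained report.
#' @return an object of class `lv_shape_model` (method "pca").
#' @export
fit_pca <- function(deviations, n_components = 5L, y = NULL, mean_shape = NULL) {
  X <- as.matrix(deviations)
  K <- nrow(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  sv <- svd(Xc, nu = min(K, ncol(X)), nv = min(K, ncol(X)))
  rank <- sum(sv$d > sv$d[1] * 1e-12)
  A <- n_components
  if (A > rank) {
    warning("n_components exceeds rank ", rank, "; truncated")
    A <- rank
  }
  U <- sv$v[, seq_len(A), drop = FALSE]
  sgn <- .fix_signs(U)
  U <- sweep(U, 2, sgn, "*")
  scores <- Xc %*% U
  model <- structure(list(method = "pca", modes = U, scores = scores,
                          rotation = U, center = center,
                          singular_values = sv$d[seq_len(A)],
                          y_center = if (is.null(y)) NA_real_ else mean(y),
                          n_components = A, mean_shape = mean_shape),
                     class = "lv_shape_model")
  if (!is.null(y))
    model$explained_outcome_variance <-
      explained_variance_curve(model, y)$per_component
  model
}

#' @export
print.lv_shape_model <- function(x, ...) {
  cat(sprintf("lv_shape_model (%s): %d components over %d variables\n",
              toupper(x$method), x$n_components, nrow(x$modes)))
  invisible(x)
}

#' Project new deviation vectors onto a fitted model's scores
#' @param model an `lv_shape_model`.
#' @param deviations matrix (rows: flattened deviations on the same mean).
#' @return score matrix (rows x n_components).
#' @export
project_scores <- function(model, deviations) {
  Xc <- sweep(as.matrix(deviations), 2, model$center)
  Xc %*% model$rotation
}

#' Reconstruct a shape from mode scores
#'
#' The mean shape plus the score-weighted sum of shape modes.
#'
#' @param model a fitted `lv_shape_model` with a stored mean shape.
#' @param scores length-n_components score vector.
#' @return an [lv_cloud()] (N x 3).
#' @export
reconstruct <- function(model, scores) {
  if (length(scores) != model$n_components)
    stop("score length must equal n_components")
  flat <- model$center + as.vector(model$modes %*% scores)
  if (!is.null(model$mean_shape))
    flat <- flat + as.vector(t(model$mean_shape))
  lv_cloud(matrix(flat, ncol = 3, byrow = TRUE))
}

#' Variance explained in the outcome per shape component
#'
#' Incremental in-sample R-squared of the outcome regressed on the first m
#' scores, for m = 1..n_components.
#'
#' @param model a fitted `lv_shape_model`.
#' @param y outcome vector.
#' @return list with `per_component` and `cumulative` fractions.
#' @export
explained_variance_curve <- function(model, y) {
  Tm <- model$scores
  tss <- sum((y - mean(y))^2)
  cum <- vapply(seq_len(ncol(Tm)), function(m) {
    fit <- stats::lm.fit(cbind(1, Tm[, seq_len(m), drop = FALSE]), y)
    1 - sum(fit$residuals^2) / tss
  }, numeric(1))
  cum <- cummax(cum)  # guard tiny numerical dips
  list(per_component = diff(c(0, cum)), cumulative = cum)
}

#' Shapes along one mode of variation
#'
#' Reconstructs the shapes at `multipliers` times the score standard
#' deviation along one mode, all other scores zero; the 0 entry is the mean
#' shape.
#'
#' @param model a fitted `lv_shape_model`.
#' @param mode_index which mode to vary.
#' @param multipliers score multiples of sigma (default -2..2).
#' @return named list of [lv_cloud()]s.
#' @export
mode_variation_meshes <- function(model, mode_index,
                                  multipliers = c(-2, -1, 0, 1, 2)) {
  if (mode_index < 1L || mode_index > model$n_components)
    stop("invalid mode index")
  sig <- sd(model$scores[, mode_index])
  out <- lapply(multipliers, function(m) {
    sc <- rep(0, model$n_components)
    sc[mode_index] <- m * sig
    reconstruct(model, sc)
  })
  names(out) <- sprintf("%+gsigma", multipliers)
  out
}

#' Variable importance in projection (VIP) scores
#'
#' Standard VIP for a PLS model:
#' `VIP_j = sqrt(p * sum_a SSY_a w_ja^2 / sum_a SSY_a)` with unit-norm
#' weight vectors, where SSY_a is the outcome sum of squares captured by
#' component a; mean squared VIP over variables is exactly 1. Per-point
#' scores aggregate a point's x, y, z variable VIPs by root mean square.
#'
#' @param model a PLS `lv_shape_model` (PCA models are rejected: VIP is
#'   defined through PLS weights).
#' @param threshold per-point importance threshold used to flag critical
#'   points (default 2.6).
#' @return an object of class `lv_vip`: `per_variable` (3N), `per_point`
#'   (N), `threshold`, `critical_points` (indices above threshold).
#' @export
vip <- function(model, threshold = 2.6) {
  if (!identical(model$method, "pls"))
    stop("VIP is only defined for PLS models")
  W <- model$weights
  ssy <- model$ssy
  p <- nrow(W)
  num <- as.vector(W^2 %*% ssy)
  per_var <- sqrt(p * num / sum(ssy))
  per_point <- sqrt(colMeans(matrix(per_var^2, nrow = 3)))
  structure(list(per_variable = per_var, per_point = per_point,
                 threshold = threshold,
                 critical_points = which(per_point > threshold)),
            class = "lv_vip")
}

#' @export
print.lv_vip <- function(x, ...) {
  cat(sprintf("lv_vip: %d points, %d above threshold %.2f (max VIP %.2f)\n",
              length(x$per_point), length(x$critical_points), x$threshold,
              max(x$per_point)))
  invisible(x)
}
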