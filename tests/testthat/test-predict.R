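test_that("LVMI regression fraction follows its definition", {
  expect_equal(lvmi_regression(100, 100), 0)
  expect_equal(lvmi_regression(100, 80), -0.20)
  expect_equal(lvmi_regression(c(100, 50), c(80, 60)), c(-0.2, 0.2))
  expect_error(lvmi_regression(0, 50), "> 0")
  expect_error(lvmi_regression(-10, 50), "> 0")
})

test_that("cohort splitting is exact, exhaustive and reproducible", {
  sp <- split_cohort(66, 0.15, seed = 3)
  expect_length(sp$test, 10)   # round(0.15 * 66)
  expect_length(sp$train, 56)
  expect_setequal(c(sp$train, sp$test), 1:66)
  expect_length(intersect(sp$train, sp$test), 0)

  expect_identical(split_cohort(66, 0.15, seed = 3), sp)
  expect_false(identical(split_cohort(66, 0.15, seed = 4)$test, sp$test))

  expect_length(split_cohort(10, 0.01, seed = 1)$test, 1)  # at least one
  expect_error(split_cohort(1, 0.15, 1), "K")
  expect_error(split_cohort(10, 0, 1), "test_fraction")
  expect_error(split_cohort(10, 1, 1), "test_fraction")
})

test_that("RMSE and R2 match their closed forms", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(0, 0), c(1, 1)), 1)
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_error(rmse(numeric(), numeric()), "empty")
  expect_error(rmse(1:3, 1:2), "mismatch")

  expect_equal(r2_score(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(4, 7, 1, 3)
  expect_equal(r2_score(y, rep(mean(y), 4)), 0)
  expect_equal(r2_score(c(0, 1), c(1, 0)), -3)
  expect_error(r2_score(c(2, 2), c(1, 2)), "constant")
  expect_error(r2_score(c(1), c(1)), "two")
})

test_that("linear SVR fits realizable linear outcomes nearly perfectly", {
  set.seed(41)
  X <- matrix(rnorm(200), 50, 4)
  y <- as.vector(X %*% c(1, -2, 0.5, 3)) + 5
  fit <- fit_svr(X, y, C = 100, epsilon = 0)
  yn <- (y - fit$y_center) / fit$y_scale
  expect_gt(r2_score(yn, predict(fit, X)), 0.999)
  # inverse transform returns the original scale
  expect_equal(predict(fit, X, output = "original"), y, tolerance = 0.05)
})

test_that("SVR fits are stable under row duplication and symmetric at the centroid", {
  set.seed(42)
  X <- matrix(rnorm(120), 30, 4)
  y <- as.vector(X %*% c(2, 1, -1, 0.5)) + 1
  f1 <- fit_svr(X, y, C = 100, epsilon = 0)
  f2 <- fit_svr(rbind(X, X), c(y, y), C = 100, epsilon = 0)
  probe <- matrix(rnorm(40), 10, 4)
  # agreement is bounded by the solver working tolerance, not by the data
  expect_equal(predict(f1, probe), predict(f2, probe), tolerance = 0.05)
  # and row order does not matter beyond the same solver tolerance
  ord <- sample(30)
  f3 <- fit_svr(X[ord, ], y[ord], C = 100, epsilon = 0)
  expect_equal(predict(f1, probe), predict(f3, probe), tolerance = 0.05)

  # symmetric design: prediction at the training centroid ~ mean outcome
  Xs <- rbind(X, -X)
  ys <- c(y, -y) + 3
  fs <- fit_svr(Xs, ys, epsilon = 0.1)
  ctr <- matrix(colMeans(Xs), 1)
  expect_lt(abs(predict(fs, ctr)), 0.1 + 0.02)  # epsilon + tolerance

  expect_warning(fit_svr(cbind(X, 1), y), "constant")
})

test_that("bivariate clinical baseline is exact least squares", {
  set.seed(43)
  t1 <- rnorm(20, 120, 25)
  t2 <- rnorm(20, 55, 8)

  # constant outcome
  fit_c <- fit_baseline_bivariate(t1, t2, rep(0.3, 20))
  expect_equal(fit_c$p0, 0.3, tolerance = 1e-10)
  expect_equal(fit_c$p1, 0, tolerance = 1e-10)
  expect_equal(fit_c$p2, 0, tolerance = 1e-10)

  # noise-free recovery of planted coefficients
  y <- 113 + 0.32 * t1 - 0.82 * t2
  fit <- fit_baseline_bivariate(t1, t2, y)
  expect_equal(c(fit$p0, fit$p1, fit$p2), c(113, 0.32, -0.82), tolerance = 1e-8)

  # normal-equations oracle on noisy data
  y2 <- y + rnorm(20)
  fit2 <- fit_baseline_bivariate(t1, t2, y2)
  A <- cbind(1, t1, t2)
  beta <- solve(t(A) %*% A, t(A) %*% y2)
  expect_equal(c(fit2$p0, fit2$p1, fit2$p2), as.vector(beta), tolerance = 1e-8)

  expect_error(fit_baseline_bivariate(t1, 2 * t1 + 1, y), "collinear")
  expect_error(fit_baseline_bivariate(t1[1:2], t2[1:2], y[1:2]), "K")
})

test_that("evaluation is leakage-safe by default and flags the alternative", {
  fx <- small_cohort()
  ev <- evaluate_prediction(fx$cohort, "pls", 4, seed = 5)
  expect_true(ev$leakage_free)
  expect_s3_class(ev, "lv_eval")
  expect_length(intersect(ev$split$train, ev$split$test), 0)
  expect_lte(ev$r2_train, 1)
  expect_gte(ev$rmse_test, 0)

  ev2 <- evaluate_prediction(fx$cohort, "pls", 4, seed = 5,
                             encoder_fit = "full_data")
  expect_false(ev2$leakage_free)
})

test_that("train fit exceeds test fit on average over seeds", {
  fx <- small_cohort()
  gaps <- vapply(1:8, function(s) {
    ev <- evaluate_prediction(fx$cohort, "pls", 4, seed = s)
    ev$r2_train - ev$r2_test
  }, numeric(1))
  expect_gt(mean(gaps), 0)
})

test_that("appending clinical covariates barely moves test accuracy", {
  # covariates are functions of latents already expressed in the shapes
  fx <- small_cohort()
  d <- vapply(1:6, function(s) {
    a <- evaluate_prediction(fx$cohort, "pls", 4, seed = s)
    b <- evaluate_prediction(fx$cohort, "pls", 4, seed = s,
                             extra_covariates = TRUE)
    b$r2_test - a$r2_test
  }, numeric(1))
  expect_lt(abs(median(d)), 0.05)
})

test_that("baseline evaluation shares the split protocol and the normalized scale", {
  fx <- small_cohort()
  ev <- evaluate_baseline(fx$cohort, seed = 7)
  ev_shape <- evaluate_prediction(fx$cohort, "pls", 4, seed = 7)
  expect_identical(ev$split, ev_shape$split)
  expect_gte(ev$rmse_test, 0)
  expect_lte(ev$r2_test, 1)
})

test_that("the SVR hyperparameter grid search ranks configurations", {
  fx <- small_cohort()
  gs <- svr_grid_search(fx$cohort, C_grid = c(0.5, 2), epsilon_grid = c(0.05, 0.2),
                        n_components = 3L, seeds = 1:2)
  expect_equal(nrow(gs), 4L)
  expect_true(!is.unsorted(gs$rmse_test))
  expect_true(all(is.finite(gs$r2_test)))
})
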