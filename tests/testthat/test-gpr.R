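unit_params <- function(sv = 1, ls = 1, nv = 0) {
  list(signal_variance = sv, lengthscale = ls, noise_variance = nv)
}

test_that("RBF kernel matches its closed form and is symmetric PSD", {
  p <- unit_params()
  expect_equal(gpr_kernel(matrix(0.3), matrix(0.3), p)[1, 1], 1)
  expect_equal(gpr_kernel(matrix(0), matrix(1), p)[1, 1], exp(-0.5),
               tolerance = 1e-12)
  p2 <- unit_params(sv = 2.5, ls = 0.7)
  expect_equal(gpr_kernel(matrix(c(0, 0), 1), matrix(c(1, 1), 1), p2)[1, 1],
               2.5 * exp(-2 / (2 * 0.7^2)), tolerance = 1e-12)

  set.seed(1)
  A <- matrix(rnorm(12), ncol = 2)
  B <- matrix(rnorm(8), ncol = 2)
  expect_equal(gpr_kernel(A, B, p2), t(gpr_kernel(B, A, p2)))
  K <- gpr_kernel(A, A, p2)
  expect_true(all(eigen(K, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_error(gpr_kernel(A, matrix(rnorm(9), ncol = 3), p2), "column")
})

test_that("log marginal likelihood agrees with dense oracles", {
  # univariate closed form: standard normal log-density of y = 1
  val <- gpr_lml(matrix(0), 1, unit_params(), jitter_rel = 0)
  expect_equal(val, -0.5 * log(2 * pi) - 0.5, tolerance = 1e-12)

  set.seed(42)
  for (n in 3:8) {
    X <- matrix(rnorm(2 * n), ncol = 2)
    y <- rnorm(n)
    p <- unit_params(sv = exp(rnorm(1)), ls = runif(1, 0.5, 2),
                     nv = runif(1, 0.05, 0.5))
    expect_equal(gpr_lml(X, y, p, jitter_rel = 0), lml_oracle(X, y, p),
                 tolerance = 1e-8)
  }

  # duplicated inputs are absorbed by observation noise, not a crash
  Xd <- matrix(c(1, 1, 2), ncol = 1)
  v1 <- gpr_lml(Xd, c(0.5, 0.6, -1), unit_params(nv = 0.1))
  v2 <- gpr_lml(Xd + c(0, 1e-6, 0), c(0.5, 0.6, -1), unit_params(nv = 0.1))
  expect_true(is.finite(v1))
  expect_lt(abs(v1 - v2), 1e-3)
})

test_that("posterior mean and variance match explicit matrix algebra", {
  p <- unit_params(sv = 1.3, ls = 0.8, nv = 0.09)
  X <- matrix(c(-0.5, 0.7), ncol = 1)
  y <- c(0.2, -1.1)
  fit <- manual_gpr(X, y, p)
  Xs <- matrix(c(-1, 0, 0.4), ncol = 1)
  pr <- predict(fit, Xs, se.fit = TRUE)
  orc <- posterior_oracle(X, y, Xs, p)
  expect_equal(pr$fit, orc$mean, tolerance = 1e-10)
  expect_equal(pr$se.fit^2, orc$var, tolerance = 1e-10)

  # interpolation as noise vanishes
  p0 <- unit_params(nv = 1e-12)
  fit0 <- manual_gpr(X, y, p0)
  expect_equal(predict(fit0, X), y, tolerance = 1e-6)

  # reversion to the prior far from data
  far <- predict(fit, matrix(100), se.fit = TRUE)
  expect_equal(far$fit, 0, tolerance = 1e-8)
  expect_equal(far$se.fit, sqrt(p$signal_variance), tolerance = 1e-8)

  expect_error(predict(fit, matrix(1:4, ncol = 2)), "column")
})

test_that("posterior mean with fixed hyperparameters matches kernlab", {
  skip_if_not_installed("kernlab")
  set.seed(9)
  X <- matrix(runif(24), ncol = 2)
  y <- sin(3 * X[, 1]) + X[, 2] + rnorm(12, sd = 0.05)
  p <- unit_params(sv = 1, ls = 0.7, nv = 0.05)
  Xs <- matrix(runif(10), ncol = 2)
  mine <- predict(manual_gpr(X, y, p), Xs)
  gp <- kernlab::gausspr(X, y, kernel = kernlab::rbfdot(sigma = 1 / (2 * 0.7^2)),
                         var = 0.05, scaled = FALSE)
  expect_equal(mine, drop(kernlab::predict(gp, Xs)), tolerance = 1e-6)
})

test_that("hyperparameter fitting recovers a known lengthscale", {
  true_ls <- 0.5
  set.seed(7)
  X <- matrix(sort(runif(20, 0, 3)), ncol = 1)
  K <- gpr_kernel(X, X, unit_params(ls = true_ls)) + diag(1e-10, 20)
  y <- drop(crossprod(chol(K), rnorm(20)))
  fit <- gpr(X, y, control = fit_control(standardize = FALSE, seed = 1))
  expect_lt(abs(coef(fit)[["lengthscale"]] - true_ls) / true_ls, 0.25)
  expect_lt(coef(fit)[["noise_variance"]], 1e-2)
})

test_that("fits are deterministic given the seed and handle constant targets", {
  set.seed(5)
  X <- matrix(rnorm(24), ncol = 2)
  y <- X[, 1]^2 + rnorm(12, sd = 0.1)
  f1 <- gpr(X, y, control = fit_control(seed = 3))
  f2 <- gpr(X, y, control = fit_control(seed = 3))
  expect_identical(coef(f1), coef(f2))
  expect_identical(predict(f1, X), predict(f2, X))

  const <- gpr(X, rep(2.5, 12), control = fit_control(seed = 0))
  expect_equal(unname(predict(const, matrix(rnorm(6), ncol = 2))),
               rep(2.5, 3), tolerance = 1e-6)
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(11)
  X <- matrix(rnorm(30), ncol = 2)
  y <- sin(X[, 1]) + 0.3 * X[, 2] + rnorm(15, sd = 0.1)
  fit <- gpr(X, y, control = fit_control(seed = 2))
  queries <- matrix(rnorm(40, sd = 3), ncol = 2)
  pr <- predict(fit, queries, se.fit = TRUE)
  prior_sd <- fit$y_scale * sqrt(fit$params$signal_variance)
  expect_true(all(pr$se.fit <= prior_sd + 1e-10))
  expect_true(all(pr$se.fit >= 0))
})

test_that("standardized fits are invariant to affine descriptor rescaling", {
  set.seed(13)
  X <- matrix(rnorm(28), ncol = 2)
  y <- X[, 1] - 2 * X[, 2] + rnorm(14, sd = 0.1)
  scales <- c(100, 0.01)
  shifts <- c(-5, 30)
  Xr <- sweep(sweep(X, 2L, scales, "*"), 2L, shifts, "+")
  q <- matrix(rnorm(10), ncol = 2)
  qr <- sweep(sweep(q, 2L, scales, "*"), 2L, shifts, "+")
  f1 <- gpr(X, y, control = fit_control(seed = 4))
  f2 <- gpr(Xr, y, control = fit_control(seed = 4))
  p1 <- predict(f1, q, se.fit = TRUE)
  p2 <- predict(f2, qr, se.fit = TRUE)
  expect_equal(p1$fit, p2$fit, tolerance = 1e-6)
  # uncertainties wobble slightly more: the optimum shifts in the last
  # bits when standardization absorbs the rescaling
  expect_equal(p1$se.fit, p2$se.fit, tolerance = 1e-4)
})

test_that("formula interface and modelling verbs work end to end", {
  cfg <- synthetic_config(n_boranes = 14, seed = 21)
  lib <- sample_library(cfg)
  exps <- sample_experiments(lib, cfg)
  df <- merge(as.data.frame(lib), as.data.frame(exps), by = "borane_id")
  fit <- gpr(tof_h ~ dGw_kcal + dGh_kcal, data = df,
             control = fit_control(seed = 1))
  expect_s3_class(fit, "gpr")
  expect_length(fitted(fit), 14)
  expect_equal(residuals(fit), df$tof_h - fitted(fit))
  expect_named(coef(fit), c("signal_variance", "lengthscale",
                            "noise_variance"))
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 3, seed = 99)
  expect_equal(dim(sims), c(14, 3))
  expect_identical(sims, simulate(fit, nsim = 3, seed = 99))
  expect_output(print(summary(fit)), "Gaussian-process regression")
  # prediction from a data frame picks the right columns
  pr <- predict(fit, df[1:3, ], se.fit = TRUE)
  expect_length(pr$fit, 3)
})

test_that("ARD fits expose one lengthscale per descriptor", {
  set.seed(17)
  X <- matrix(rnorm(40), ncol = 2)
  y <- sin(2 * X[, 1]) + rnorm(20, sd = 0.05) # second column irrelevant
  fit <- gpr(X, y, control = fit_control(ard = TRUE, seed = 1))
  ls <- coef(fit)[c("lengthscale.1", "lengthscale.2")]
  expect_length(ls, 2)
  expect_gt(ls[[2]], ls[[1]]) # irrelevant direction gets the longer scale
})

test_that("JSON serialization reproduces the model", {
  cfg <- synthetic_config(n_boranes = 10, seed = 3)
  lib <- sample_library(cfg)
  exps <- sample_experiments(lib, cfg)
  ds <- assemble_dataset(lib, exps, c("dGw_kcal", "dGh_kcal"))
  fit <- gpr(ds, control = fit_control(seed = 2))
  path <- withr::local_tempfile(fileext = ".json")
  write_gpr_json(fit, path)
  back <- read_gpr_json(path)
  q <- as.matrix(lib[1:4, c("dGw_kcal", "dGh_kcal")])
  expect_equal(predict(back, q, se.fit = TRUE),
               predict(fit, q, se.fit = TRUE), tolerance = 1e-10)
  expect_identical(back$borane_ids, fit$borane_ids)
})
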