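# Shared fixtures: tiny hand-written tables and dense linear-algebra
# oracles, independent of the package's Cholesky code paths.

# A three-borane library with hand-chosen descriptor values.
tiny_library <- function() {
  as_borane_library(data.frame(
    borane_id = c("B1a", "B2b", "B3c"),
    core = c("B1", "B2", "B3"),
    aryl_variant = c("a", "b", "c"),
    lumo_ev = c(-1.10, -0.95, -1.30),
    dGw_kcal = c(-2.5, 0.8, -4.1),
    dGh_kcal = c(18.2, 21.7, 16.9),
    edef_h2o_kcal = c(7.5, 9.1, NA),
    edef_thf_kcal = c(11.2, 13.4, 12.8),
    qB_e = c(0.31, 0.37, 0.29),
    qC_e = c(-0.12, -0.18, -0.10),
    stringsAsFactors = FALSE
  ))
}

tiny_experiments <- function() {
  as_experiments(data.frame(
    borane_id = c("B1a", "B2b", "B3c"),
    yield_fraction = c(0.50, 0.20, 0.90),
    loading_fraction = c(0.05, 0.05, 0.05),
    time_h = c(6, 6, 6),
    stringsAsFactors = FALSE
  ))
}

# Dense-matrix log marginal likelihood oracle: explicit inverse and
# determinant, no Cholesky shortcuts.
lml_oracle <- function(X, y, params) {
  K <- params$signal_variance *
    exp(-0.5 * as.matrix(stats::dist(X / params$lengthscale))^2) +
    diag(params$noise_variance, length(y))
  -0.5 * drop(t(y) %*% solve(K) %*% y) -
    0.5 * determinant(K, logarithm = TRUE)$modulus[1] -
    0.5 * length(y) * log(2 * pi)
}

# Dense posterior mean/variance oracle with fixed hyperparameters.
posterior_oracle <- function(X, y, Xstar, params) {
  rbf <- function(A, B) {
    params$signal_variance *
      exp(-0.5 * outer(rowSums((A / params$lengthscale)^2),
                       rowSums((B / params$lengthscale)^2), "+") +
            tcrossprod(A / params$lengthscale, B / params$lengthscale))
  }
  K <- rbf(X, X) + diag(params$noise_variance, nrow(X))
  Ks <- rbf(X, Xstar)
  Kss <- rbf(Xstar, Xstar)
  Kinv <- solve(K)
  list(mean = drop(t(Ks) %*% Kinv %*% y),
       var = diag(Kss - t(Ks) %*% Kinv %*% Ks))
}

# Build a gpr object directly from fixed hyperparameters (no fitting), so
# prediction algebra can be tested in isolation.
manual_gpr <- function(X, y, params, jitter = 0) {
  X <- as.matrix(X)
  K <- gpr_kernel(X, X, params) +
    diag(params$noise_variance + jitter, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  structure(
    list(params = params, X_train = X, y_train = y,
         x_mean = rep(0, ncol(X)), x_scale = rep(1, ncol(X)),
         y_mean = 0, y_scale = 1,
         cholesky_factor = L, alpha = alpha, jitter = jitter,
         lml = NA_real_, control = fit_control(standardize = FALSE),
         feature_names = colnames(X), n = length(y), d = ncol(X),
         call = NULL),
    class = "gpr"
  )
}

# Synthetic campaign inputs: a 54-member library whose measured subset is
# the 15 boranes identified by name in the study text.
text_identified_measured <- function() {
  c("B1a", "B2a", "B3a", "B5a", "B6a", "B1v", "B1w", "BCF",
    "B1f", "B2b", "B2c", "B2e", "B3b", "B3c", "B3s")
}

library_with_text_ids <- function(seed = 0) {
  measured <- text_identified_measured()
  extra <- c("B4b", "B4c", "B4e")
  pool <- as.vector(t(outer(paste0("B", 1:6), letters[1:23], paste0)))
  fill <- setdiff(pool, c(measured, extra))[seq_len(54 - 18)]
  ids <- c(measured, extra, fill)
  cfg <- synthetic_config(n_boranes = 54L, seed = seed)
  sample_library(cfg, borane_ids = ids)
}
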