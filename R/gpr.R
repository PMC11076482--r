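# Gaussian-process regression with an RBF kernel, written out in full:
# squared-exponential covariance, Cholesky-based marginal likelihood with
# analytic gradients, multi-restart L-BFGS hyperparameter optimisation and
# exact posterior mean/variance. This is the surrogate model behind the
# descriptor-pair TOF models.

#' Fitting control for Gaussian-process regression
#'
#' @param standardize Standardize descriptor columns and targets to zero
#'   mean / unit variance before fitting (default `TRUE`; descriptors carry
#'   incommensurate units, eV vs kcal/mol, so unstandardized fitting is
#'   rarely defensible). Disable for parity experiments against external
#'   GPR implementations.
#' @param ard Use a separate lengthscale per descriptor (automatic
#'   relevance determination). Default `FALSE`: isotropic RBF.
#' @param restarts Number of optimizer starts (>= 1). The first start is
#'   the unit initialisation `(1, 1, 1)` in standardized space; the rest
#'   are drawn log-uniformly from `restart_range`.
#' @param seed Integer seed controlling the restart draws; fits are
#'   reproducible given the seed.
#' @param init Initial `(signal_variance, lengthscale, noise_variance)` for
#'   the first start.
#' @param bounds Length-2 positive numeric: box constraints applied to every
#'   hyperparameter (optimisation runs in log space).
#' @param restart_range Length-2 positive numeric: log-uniform sampling
#'   range for restart initialisations.
#' @param jitter_rel Initial diagonal jitter as a multiple of
#'   `trace(K)/n`; escalated tenfold on Cholesky failure.
#' @param jitter_max Maximum jitter multiple before the decomposition is
#'   declared non-positive-definite.
#' @return A list of class `"gpr_control"`.
#' @export
fit_control <- function(standardize = TRUE, ard = FALSE, restarts = 5L,
                        seed = 0L, init = c(1, 1, 1),
                        bounds = c(1e-8, 1e6),
                        restart_range = c(1e-2, 1e2),
                        jitter_rel = 1e-10, jitter_max = 1e-4) {
  stopifnot(is.logical(standardize), length(standardize) == 1L,
            is.logical(ard), length(ard) == 1L)
  if (!is_count(restarts) || restarts < 1L) {
    stopf("fit_control(): restarts must be a positive integer")
  }
  if (!is_count(seed)) stopf("fit_control(): seed must be an integer")
  if (length(init) != 3L || any(init <= 0)) {
    stopf("fit_control(): init must be three positive values")
  }
  if (length(bounds) != 2L || any(bounds <= 0) || bounds[1] >= bounds[2]) {
    stopf("fit_control(): bounds must be increasing and positive")
  }
  if (jitter_rel < 0 || jitter_max < jitter_rel) {
    stopf("fit_control(): need 0 <= jitter_rel <= jitter_max")
  }
  structure(
    list(standardize = standardize, ard = ard,
         restarts = as.integer(restarts), seed = as.integer(seed),
         init = as.numeric(init), bounds = as.numeric(bounds),
         restart_range = as.numeric(restart_range),
         jitter_rel = jitter_rel, jitter_max = jitter_max),
    class = "gpr_control"
  )
}

.as_params <- function(params) {
  need <- c("signal_variance", "lengthscale", "noise_variance")
  if (!is.list(params) || !all(need %in% names(params))) {
    stopf("params must be a list with fields %s", paste(need, collapse = ", "))
  }
  sv <- params$signal_variance; ls <- params$lengthscale
  nv <- params$noise_variance
  if (!is.numeric(sv) || length(sv) != 1L || !is.finite(sv) || sv <= 0 ||
      !is.numeric(nv) || length(nv) != 1L || !is.finite(nv) || nv < 0 ||
      !is.numeric(ls) || any(!is.finite(ls)) || any(ls <= 0)) {
    stopf("kernel hyperparameters must be positive and finite")
  }
  list(signal_variance = sv, lengthscale = as.numeric(ls),
       noise_variance = nv)
}

.as_matrix <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x)) x <- matrix(as.numeric(x), ncol = 1L)
  storage.mode(x) <- "double"
  x
}

# Squared distances between rows of A and B after dividing each column by
# its lengthscale (recycled when isotropic).
.scaled_sqdist <- function(A, B, lengthscale) {
  d <- ncol(A)
  ls <- if (length(lengthscale) == 1L) rep(lengthscale, d) else lengthscale
  if (length(ls) != d) {
    stopf("lengthscale has length %d but inputs have %d column(s)",
          length(lengthscale), d)
  }
  As <- sweep(A, 2L, ls, "/")
  Bs <- sweep(B, 2L, ls, "/")
  D2 <- outer(rowSums(As^2), rowSums(Bs^2), "+") - 2 * tcrossprod(As, Bs)
  D2[D2 < 0] <- 0
  D2
}

#' RBF covariance matrix
#'
#' `K[i, j] = signal_variance * exp(-||a_i - b_j||^2 / (2 * lengthscale^2))`
#' (with per-column lengthscales under ARD). Symmetric positive
#' semi-definite when `A` and `B` coincide. The observation-noise term is
#' *not* added here.
#'
#' @param A,B Numeric matrices with the same number of columns (rows are
#'   points).
#' @param params List with `signal_variance`, `lengthscale` (scalar or one
#'   per column) and `noise_variance`.
#' @return The `nrow(A)` x `nrow(B)` covariance matrix.
#' @examples
#' gpr_kernel(matrix(0), matrix(1),
#'            list(signal_variance = 1, lengthscale = 1,
#'                 noise_variance = 0)) # exp(-0.5)
#' @export
gpr_kernel <- function(A, B, params) {
  params <- .as_params(params)
  A <- .as_matrix(A); B <- .as_matrix(B)
  if (ncol(A) != ncol(B)) {
    stopf("gpr_kernel(): A has %d column(s) but B has %d", ncol(A), ncol(B))
  }
  params$signal_variance *
    exp(-0.5 * .scaled_sqdist(A, B, params$lengthscale))
}

# Cholesky of K + (noise + jitter) I with jitter escalation. Returns the
# factor and the jitter actually used.
.chol_with_jitter <- function(K, noise_variance, jitter_rel, jitter_max) {
  n <- nrow(K)
  scale <- sum(diag(K)) / n + noise_variance
  jit <- jitter_rel * scale
  jmax <- jitter_max * scale
  repeat {
    L <- tryCatch(chol(K + diag(noise_variance + jit, n)),
                  error = function(e) NULL)
    if (!is.null(L)) return(list(L = L, jitter = jit))
    if (jit == 0) jit <- 1e-12 * scale else jit <- jit * 10
    if (jit > jmax) {
      stopf("kernel matrix not positive definite even with jitter %.3g", jit)
    }
  }
}

#' Log marginal likelihood of a GP regression model
#'
#' The log density of `y` under a zero-mean multivariate normal with
#' covariance `K(X, X) + noise_variance * I`, evaluated via Cholesky
#' factorisation with escalating diagonal jitter. This is the objective
#' maximised during hyperparameter fitting. No standardization is applied
#' here; pass data on the scale you mean.
#'
#' @param X Numeric matrix of inputs (rows are points).
#' @param y Numeric response vector.
#' @param params Kernel hyperparameters (see [gpr_kernel()]).
#' @param jitter_rel,jitter_max Jitter escalation schedule as multiples of
#'   `trace(K)/n + noise_variance`.
#' @return The scalar log marginal likelihood.
#' @export
gpr_lml <- function(X, y, params, jitter_rel = 1e-10, jitter_max = 1e-4) {
  X <- .as_matrix(X)
  params <- .as_params(params)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stopf("X and y disagree on n")
  K <- gpr_kernel(X, X, params)
  ch <- .chol_with_jitter(K, params$noise_variance,
                          jitter_rel, jitter_max)
  L <- ch$L
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  n <- length(y)
  as.numeric(-0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi))
}

# Objective and analytic gradient in log-hyperparameter space.
# lp = c(log sv, log ls (1 or d values), log nv).
.neg_lml_grad <- function(lp, X, y, ard, jitter_rel, jitter_max) {
  d <- ncol(X)
  n_ls <- if (ard) d else 1L
  sv <- exp(lp[1]); ls <- exp(lp[2:(1 + n_ls)]); nv <- exp(lp[2 + n_ls])
  n <- length(y)
  D2 <- .scaled_sqdist(X, X, ls)
  R <- exp(-0.5 * D2)
  K <- sv * R
  ch <- .chol_with_jitter(K, nv, jitter_rel, jitter_max)
  L <- ch$L
  alpha <- backsolve(L, backsolve(L, y, transpose = TRUE))
  lml <- -0.5 * sum(y * alpha) - sum(log(diag(L))) - 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  W <- tcrossprod(alpha) - Kinv   # dL/dK = W/2
  grad <- numeric(length(lp))
  grad[1] <- 0.5 * sum(W * K)                 # d/dlog sv
  if (ard) {
    for (k in seq_len(d)) {
      Dk <- outer(X[, k], X[, k], "-")^2 / ls[k]^2
      grad[1 + k] <- 0.5 * sum(W * (K * Dk))  # d/dlog ls_k
    }
  } else {
    grad[2] <- 0.5 * sum(W * (K * D2))        # d/dlog ls
  }
  grad[2 + n_ls] <- 0.5 * nv * sum(diag(W))   # d/dlog nv
  list(value = -lml, grad = -grad, lml = lml)
}

.standardizer <- function(M) {
  mu <- colMeans(M)
  sd_ <- apply(M, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  list(mean = mu, scale = sd_)
}

#' Gaussian-process regression of turnover frequency on descriptors
#'
#' Fits a GP with an RBF kernel and Gaussian observation noise by maximum
#' marginal likelihood (multi-restart L-BFGS-B in log-hyperparameter
#' space). Inputs and targets are standardized by default; predictions are
#' returned on the original scale. The fitted object supports the usual
#' modelling verbs: [predict.gpr()], `print`, `summary`, `coef`, `fitted`,
#' `residuals`, `simulate`, `plot`, `logLik`.
#'
#' @param x A numeric matrix/data frame of inputs, a `tof_dataset` (see
#'   [assemble_dataset()]), or a model formula.
#' @param ... Passed between methods.
#' @return An object of class `"gpr"`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(30), ncol = 1)
#' y <- sin(4 * x[, 1]) + rnorm(30, sd = 0.1)
#' fit <- gpr(x, y, control = fit_control(restarts = 2))
#' predict(fit, matrix(c(0.2, 0.8), ncol = 1), se.fit = TRUE)
#' @export
gpr <- function(x, ...) UseMethod("gpr")

#' @rdname gpr
#' @param y Numeric response vector (TOF, h^-1).
#' @param control A [fit_control()] list.
#' @param feature_names Optional column labels for the inputs.
#' @export
gpr.default <- function(x, y, control = fit_control(),
                        feature_names = NULL, ...) {
  X <- .as_matrix(x)
  if (is.null(feature_names)) feature_names <- colnames(X)
  .gpr_fit(X, as.numeric(y), control, feature_names)
}

#' @rdname gpr
#' @export
gpr.tof_dataset <- function(x, control = fit_control(), ...) {
  fit <- .gpr_fit(x$X, x$y, control, x$feature_names)
  fit$borane_ids <- x$borane_ids
  fit
}

#' @rdname gpr
#' @param formula A formula such as `tof_h ~ dGw_kcal + dGh_kcal`.
#' @param data A data frame holding the formula variables.
#' @export
gpr.formula <- function(formula, data, control = fit_control(), ...) {
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- .as_matrix(mf[, -1L, drop = FALSE])
  fit <- .gpr_fit(X, as.numeric(y), control, colnames(mf)[-1L])
  fit$call <- match.call()
  fit
}

.gpr_fit <- function(X, y, control, feature_names = NULL) {
  if (!inherits(control, "gpr_control")) {
    stopf("control must come from fit_control()")
  }
  n <- length(y)
  if (nrow(X) != n) stopf("x and y disagree on n (%d vs %d)", nrow(X), n)
  if (n < 3L) stopf("gpr() needs at least 3 observations, got %d", n)
  if (anyNA(X) || anyNA(y)) stopf("gpr() does not accept missing values")
  d <- ncol(X)

  if (control$standardize) {
    sx <- .standardizer(X)
    sy <- .standardizer(matrix(y, ncol = 1L))
    Xs <- sweep(sweep(X, 2L, sx$mean, "-"), 2L, sx$scale, "/")
    ys <- (y - sy$mean) / sy$scale
  } else {
    sx <- list(mean = rep(0, d), scale = rep(1, d))
    sy <- list(mean = 0, scale = 1)
    Xs <- X; ys <- y
  }

  n_ls <- if (control$ard) d else 1L
  init0 <- log(c(control$init[1], rep(control$init[2], n_ls),
                 control$init[3]))
  starts <- list(init0)
  if (control$restarts > 1L) {
    extra <- with_seed(control$seed, {
      lapply(seq_len(control$restarts - 1L), function(i) {
        stats::runif(2L + n_ls, log(control$restart_range[1]),
                     log(control$restart_range[2]))
      })
    })
    starts <- c(starts, extra)
  }

  lower <- rep(log(control$bounds[1]), 2L + n_ls)
  upper <- rep(log(control$bounds[2]), 2L + n_ls)
  fn <- function(p) .neg_lml_grad(p, Xs, ys, control$ard,
                                  control$jitter_rel, control$jitter_max)$value
  gr <- function(p) .neg_lml_grad(p, Xs, ys, control$ard,
                                  control$jitter_rel, control$jitter_max)$grad

  best <- NULL
  failures <- character()
  for (s in starts) {
    res <- tryCatch(
      stats::optim(s, fn, gr, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 200L)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, conditionMessage(res))
      next
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    stopf("gpr(): all %d optimizer restart(s) failed: %s",
          length(starts), paste(unique(failures), collapse = " | "))
  }

  lp <- best$par
  params <- list(signal_variance = exp(lp[1]),
                 lengthscale = exp(lp[2:(1 + n_ls)]),
                 noise_variance = exp(lp[2 + n_ls]))
  K <- gpr_kernel(Xs, Xs, params)
  ch <- .chol_with_jitter(K, params$noise_variance,
                          control$jitter_rel, control$jitter_max)
  alpha <- backsolve(ch$L, backsolve(ch$L, ys, transpose = TRUE))
  lml <- as.numeric(-0.5 * sum(ys * alpha) - sum(log(diag(ch$L))) -
                      0.5 * n * log(2 * pi))

  structure(
    list(params = params, X_train = Xs, y_train = ys,
         x_mean = sx$mean, x_scale = sx$scale,
         y_mean = as.numeric(sy$mean), y_scale = as.numeric(sy$scale),
         cholesky_factor = ch$L, alpha = alpha, jitter = ch$jitter,
         lml = lml, control = control, feature_names = feature_names,
         n = n, d = d, call = sys.call(-1)),
    class = "gpr"
  )
}

#' Posterior prediction from a fitted GP
#'
#' Standard GP posterior mean and standard deviation, de-standardized to
#' TOF units. By default the reported uncertainty is the latent-function
#' standard deviation (excluding observation noise); set
#' `include_noise = TRUE` for full predictive noise.
#'
#' @param object A fitted [gpr()] model.
#' @param newdata Matrix or data frame of query points (columns as in
#'   training; data frames may carry extra columns when the model stores
#'   feature names).
#' @param se.fit Return standard deviations alongside the means.
#' @param include_noise Add the observation-noise variance to the reported
#'   uncertainty.
#' @param ... Unused.
#' @return A numeric vector of posterior means, or (with `se.fit = TRUE`) a
#'   list with components `fit` and `se.fit`.
#' @export
predict.gpr <- function(object, newdata, se.fit = FALSE,
                        include_noise = FALSE, ...) {
  if (missing(newdata)) {
    Xs <- object$X_train
  } else {
    if (is.data.frame(newdata) && !is.null(object$feature_names) &&
        all(object$feature_names %in% names(newdata))) {
      newdata <- newdata[, object$feature_names, drop = FALSE]
    }
    Xn <- .as_matrix(newdata)
    if (ncol(Xn) != object$d) {
      stopf("newdata has %d column(s); model was trained on %d",
            ncol(Xn), object$d)
    }
    Xs <- sweep(sweep(Xn, 2L, object$x_mean, "-"), 2L, object$x_scale, "/")
  }
  Kstar <- gpr_kernel(object$X_train, Xs, object$params)
  mean_s <- drop(crossprod(Kstar, object$alpha))
  mean_out <- object$y_mean + object$y_scale * mean_s
  if (!se.fit) return(mean_out)
  v <- backsolve(object$cholesky_factor, Kstar, transpose = TRUE)
  var_s <- object$params$signal_variance - colSums(v^2)
  if (include_noise) var_s <- var_s + object$params$noise_variance
  var_s[var_s < 0] <- 0
  list(fit = mean_out, se.fit = object$y_scale * sqrt(var_s))
}
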