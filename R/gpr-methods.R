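# Standard modelling verbs for fitted GP surrogates, plus JSON
# serialization for campaign reproducibility.

#' @export
print.gpr <- function(x, ...) {
  kern <- if (x$control$ard) "RBF (ARD)" else "RBF (isotropic)"
  cat(sprintf("Gaussian-process regression, %s kernel\n", kern))
  cat(sprintf("  n = %d observations, d = %d descriptor(s)%s\n", x$n, x$d,
              if (!is.null(x$feature_names))
                sprintf(" (%s)", paste(x$feature_names, collapse = ", "))
              else ""))
  cat(sprintf("  signal variance  %.4g\n", x$params$signal_variance))
  cat(sprintf("  lengthscale      %s\n",
              paste(sprintf("%.4g", x$params$lengthscale), collapse = ", ")))
  cat(sprintf("  noise variance   %.4g\n", x$params$noise_variance))
  cat(sprintf("  log marginal likelihood %.4f\n", x$lml))
  invisible(x)
}

#' @export
summary.gpr <- function(object, ...) {
  structure(list(fit = object,
                 fitted = stats::fitted(object),
                 residuals = stats::residuals(object)),
            class = "summary.gpr")
}

#' @export
print.summary.gpr <- function(x, ...) {
  print(x$fit)
  std <- x$fit$control$standardize
  cat(sprintf("  standardized inputs/targets: %s\n",
              if (std) "yes" else "no"))
  cat(sprintf("  optimizer restarts %d, seed %d, jitter used %.3g\n",
              x$fit$control$restarts, x$fit$control$seed, x$fit$jitter))
  cat("Residuals (TOF units):\n")
  print(summary(x$residuals))
  invisible(x)
}

#' @export
coef.gpr <- function(object, ...) {
  p <- object$params
  ls <- p$lengthscale
  names(ls) <- if (length(ls) == 1L) "lengthscale" else
    paste0("lengthscale.", seq_along(ls))
  c(signal_variance = p$signal_variance, ls,
    noise_variance = p$noise_variance)
}

#' @export
fitted.gpr <- function(object, ...) {
  predict(object)
}

#' @export
residuals.gpr <- function(object, ...) {
  y <- object$y_mean + object$y_scale * object$y_train
  y - stats::fitted(object)
}

#' @export
logLik.gpr <- function(object, ...) {
  structure(object$lml, df = 2L + length(object$params$lengthscale),
            nobs = object$n, class = "logLik")
}

#' Draw from the GP posterior
#'
#' Joint multivariate-normal draws of the latent function at `newdata`
#' (default: the training inputs), on the original TOF scale.
#'
#' @param object A fitted [gpr()] model.
#' @param nsim Number of draws.
#' @param seed Optional seed (caller's RNG state is preserved).
#' @param newdata Query points; defaults to the training inputs.
#' @param ... Unused.
#' @return A matrix with one column per draw.
#' @export
simulate.gpr <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  Xs <- if (missing(newdata)) {
    # already standardized
    object$X_train
  } else {
    Xn <- .as_matrix(newdata)
    sweep(sweep(Xn, 2L, object$x_mean, "-"), 2L, object$x_scale, "/")
  }
  Kstar <- gpr_kernel(object$X_train, Xs, object$params)
  mean_s <- drop(crossprod(Kstar, object$alpha))
  v <- backsolve(object$cholesky_factor, Kstar, transpose = TRUE)
  Kss <- gpr_kernel(Xs, Xs, object$params)
  cov_s <- Kss - crossprod(v)
  m <- nrow(Xs)
  cov_s <- cov_s + diag(1e-10 * (sum(diag(Kss)) / m + 1), m)
  Lp <- chol(cov_s)
  draw <- function() {
    z <- stats::rnorm(m)
    object$y_mean + object$y_scale * (mean_s + drop(crossprod(Lp, z)))
  }
  sims <- if (is.null(seed)) {
    replicate(nsim, draw())
  } else {
    with_seed(seed, replicate(nsim, draw()))
  }
  matrix(sims, nrow = m, ncol = nsim)
}

#' Observed-versus-fitted plot for a GP surrogate
#'
#' Plots experimental TOF against the posterior mean at the training
#' inputs, with 1-sigma latent-function bars and the identity line.
#'
#' @param x A fitted [gpr()] model.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.gpr <- function(x, ...) {
  pr <- predict(x, se.fit = TRUE)
  obs <- x$y_mean + x$y_scale * x$y_train
  rng <- range(obs, pr$fit + pr$se.fit, pr$fit - pr$se.fit)
  graphics::plot(obs, pr$fit, xlim = rng, ylim = rng,
                 xlab = "observed TOF [1/h]",
                 ylab = "predicted TOF [1/h]", pch = 19, ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::arrows(obs, pr$fit - pr$se.fit, obs, pr$fit + pr$se.fit,
                   angle = 90, code = 3, length = 0.03, col = "grey40")
  invisible(x)
}

#' Serialize a fitted GP to JSON and back
#'
#' Stores hyperparameters, standardization state, training data and a
#' checksum of the training matrix so a campaign run can be reproduced and
#' verified. The Cholesky cache is rebuilt on load.
#'
#' @param model A fitted [gpr()] model.
#' @param path Destination/ source JSON file.
#' @return `write_gpr_json()` returns `path` invisibly; `read_gpr_json()`
#'   the restored `gpr` object.
#' @export
write_gpr_json <- function(model, path) {
  if (!inherits(model, "gpr")) stopf("expected a 'gpr' model")
  doc <- list(
    type = "catscout_gpr",
    params = model$params,
    standardization = list(x_mean = model$x_mean, x_scale = model$x_scale,
                           y_mean = model$y_mean, y_scale = model$y_scale),
    control = unclass(model$control),
    feature_names = model$feature_names,
    borane_ids = model$borane_ids,
    X_train = model$X_train, y_train = model$y_train,
    lml = model$lml,
    checksum = data_checksum(c(model$X_train, model$y_train))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_gpr_json
#' @export
read_gpr_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$type, "catscout_gpr")) {
    stopf("'%s' is not a serialized catscout GPR model", path)
  }
  X <- .as_matrix(doc$X_train)
  y <- as.numeric(doc$y_train)
  if (!identical(doc$checksum, data_checksum(c(X, y)))) {
    stopf("training-data checksum mismatch in '%s'", path)
  }
  ctrl <- do.call(fit_control, doc$control[names(formals(fit_control))])
  params <- .as_params(as.list(doc$params))
  K <- gpr_kernel(X, X, params)
  ch <- .chol_with_jitter(K, params$noise_variance,
                          ctrl$jitter_rel, ctrl$jitter_max)
  alpha <- backsolve(ch$L, backsolve(ch$L, y, transpose = TRUE))
  structure(
    list(params = params, X_train = X, y_train = y,
         x_mean = as.numeric(doc$standardization$x_mean),
         x_scale = as.numeric(doc$standardization$x_scale),
         y_mean = as.numeric(doc$standardization$y_mean),
         y_scale = as.numeric(doc$standardization$y_scale),
         cholesky_factor = ch$L, alpha = alpha, jitter = ch$jitter,
         lml = as.numeric(doc$lml), control = ctrl,
         feature_names = doc$feature_names,
         borane_ids = doc$borane_ids,
         n = length(y), d = ncol(X), call = NULL),
    class = "gpr"
  )
}
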