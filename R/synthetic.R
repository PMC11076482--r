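# Seeded synthetic borane libraries and TOF experiments with known ground
# truth. The generator emulates the statistical structure the screening
# analysis assumes: mutually correlated, acidity-linked descriptors, and an
# observed TOF that is a noisy function of the H2-cleavage barrier and the
# water-adduct energy ONLY (so descriptor pairs can be benchmarked against
# a known set of generative drivers), bounded above by the
# quantitative-yield ceiling of the model reaction.

#' Configuration of the synthetic borane generator
#'
#' Two independent standard-normal latents drive each borane: an *acidity*
#' latent `a` (loading on LUMO, the H2-cleavage barrier and the Mulliken
#' charges) and a *back-strain* latent `b` (loading on the water-adduct
#' energy and the deformation energies). `lambda` in \[0, 1\] couples the
#' LUMO level and the barrier through `a`: their correlation is
#' `lambda^2`.
#'
#' The noise-free TOF surface depends on the barrier `dGh` and water
#' tolerance `dGw` only:
#' \deqn{T(dGh, dGw) = T_{max}\, e^{-k_H (dGh - g_0)}
#'   \left[1 + e^{-k_w (dGw - w_0)}\right]^{-1},}
#' clipped at the quantitative-yield ceiling `1 / (loading * time_h)`.
#' Observed TOFs are multiplicatively lognormal:
#' `T_obs = T * exp(sigma_obs * zeta)`, re-expressed as a yield at the
#' configured loading/time and clipped to \[0, 1\].
#'
#' All location/scale defaults are artifact choices: they place `dGh`
#' roughly in 14--26 kcal/mol and TOF in 0--4 1/h so synthetic data are
#' commensurate with real descriptor tables, without claiming fidelity to
#' any particular borane.
#'
#' @param n_boranes Library size (default 54).
#' @param seed Single global seed; each generator stage derives its own
#'   child seed so stages can be regenerated independently.
#' @param lambda Acidity coupling between LUMO and barrier, in \[0, 1\].
#' @param mu_L,sigma_L LUMO location/scale (eV).
#' @param mu_H,sigma_H Barrier location/scale (kcal/mol).
#' @param mu_w,sigma_w Water-adduct energy location/scale (kcal/mol).
#' @param mu_edef_h2o,mu_edef_thf,sigma_edef Deformation-energy medians
#'   (kcal/mol) and log-scale spread; strictly positive by construction
#'   (lognormal in the strain latent).
#' @param qB0,qB_slope,qB_noise_sd,qC0,qC_slope,qC_noise_sd Mulliken-charge
#'   affine loadings on the acidity latent plus independent noise (e).
#' @param T_max,k_H,g0,k_w,w0 TOF-surface parameters (see above).
#' @param sigma_obs Multiplicative observation-noise sd (log scale),
#'   `0 <= sigma_obs < 1`.
#' @param loading,time_h Model-reaction catalyst loading (mole fraction)
#'   and time (h); they set the yield ceiling.
#' @return A validated list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_boranes = 54L, seed = 0L, lambda = 0.8,
                             mu_L = -1.0, sigma_L = 0.25,
                             mu_H = 20, sigma_H = 2,
                             mu_w = -1, sigma_w = 2,
                             mu_edef_h2o = 8, mu_edef_thf = 12,
                             sigma_edef = 0.3,
                             qB0 = 0.35, qB_slope = 0.05,
                             qB_noise_sd = 0.02,
                             qC0 = -0.15, qC_slope = -0.03,
                             qC_noise_sd = 0.02,
                             T_max = 4, k_H = 0.4, g0 = 16,
                             k_w = 1.0, w0 = -1,
                             sigma_obs = 0.2,
                             loading = 0.05, time_h = 6) {
  if (!is_count(n_boranes) || n_boranes < 1L) {
    stopf("synthetic_config(): n_boranes must be a positive integer")
  }
  if (!is_count(seed)) stopf("synthetic_config(): seed must be an integer")
  if (!is_number(lambda) || lambda < 0 || lambda > 1) {
    stopf("synthetic_config(): lambda must lie in [0, 1]")
  }
  for (nm in c("sigma_L", "sigma_H", "sigma_w", "mu_edef_h2o",
               "mu_edef_thf", "sigma_edef", "qB_noise_sd", "qC_noise_sd",
               "T_max", "k_H", "k_w", "loading", "time_h")) {
    v <- get(nm)
    if (!is_number(v) || v <= 0) {
      stopf("synthetic_config(): %s must be positive", nm)
    }
  }
  if (!is_number(sigma_obs) || sigma_obs < 0 || sigma_obs >= 1) {
    stopf("synthetic_config(): sigma_obs must lie in [0, 1)")
  }
  structure(
    list(n_boranes = as.integer(n_boranes), seed = as.integer(seed),
         lambda = lambda, mu_L = mu_L, sigma_L = sigma_L,
         mu_H = mu_H, sigma_H = sigma_H, mu_w = mu_w, sigma_w = sigma_w,
         mu_edef_h2o = mu_edef_h2o, mu_edef_thf = mu_edef_thf,
         sigma_edef = sigma_edef,
         qB0 = qB0, qB_slope = qB_slope, qB_noise_sd = qB_noise_sd,
         qC0 = qC0, qC_slope = qC_slope, qC_noise_sd = qC_noise_sd,
         T_max = T_max, k_H = k_H, g0 = g0, k_w = k_w, w0 = w0,
         sigma_obs = sigma_obs, loading = loading, time_h = time_h),
    class = "synthetic_config"
  )
}

.default_synthetic_ids <- function(n) {
  ids <- as.vector(t(outer(paste0("B", 1:6), letters[1:23], paste0)))
  if (n > length(ids)) {
    stopf("cannot generate %d distinct borane ids (max %d)", n, length(ids))
  }
  ids[seq_len(n)]
}

#' Sample a synthetic borane descriptor library
#'
#' Draws `n_boranes` records with acidity-linked descriptors (see
#' [synthetic_config()] for the generative model). All records carry every
#' descriptor and are tagged synthetically accessible.
#'
#' @param config A [synthetic_config()].
#' @param borane_ids Optional explicit identifiers (length `n_boranes`,
#'   obeying the id grammar); defaults to `B1a, B1b, ...` in core-major
#'   order.
#' @return A validated `borane_library` data frame.
#' @export
sample_library <- function(config, borane_ids = NULL) {
  if (!inherits(config, "synthetic_config")) {
    stopf("expected a synthetic_config")
  }
  n <- config$n_boranes
  ids <- borane_ids %||% .default_synthetic_ids(n)
  if (length(ids) != n) {
    stopf("borane_ids must have length n_boranes = %d", n)
  }
  lam <- config$lambda
  draws <- with_seed(child_seed(config$seed, "library"), {
    list(a = stats::rnorm(n), b = stats::rnorm(n),
         e_lumo = stats::rnorm(n), e_acid = stats::rnorm(n),
         e_qB = stats::rnorm(n), e_qC = stats::rnorm(n))
  })
  a <- draws$a
  b <- draws$b
  a_prime <- lam * a + sqrt(1 - lam^2) * draws$e_acid
  lumo <- config$mu_L - lam * config$sigma_L * a +
    sqrt(1 - lam^2) * config$sigma_L * draws$e_lumo
  dGh <- pmax(config$mu_H - config$sigma_H * a_prime, 0.5)
  dGw <- config$mu_w + config$sigma_w * b
  edef_h2o <- config$mu_edef_h2o * exp(config$sigma_edef * b)
  edef_thf <- config$mu_edef_thf * exp(config$sigma_edef * b)
  qB <- config$qB0 + config$qB_slope * a + config$qB_noise_sd * draws$e_qB
  qC <- config$qC0 + config$qC_slope * a + config$qC_noise_sd * draws$e_qC
  df <- data.frame(
    borane_id = ids,
    core = ifelse(ids == "BCF", "BCF", substr(ids, 1, 2)),
    aryl_variant = ifelse(ids == "BCF", "", substr(ids, 3, 3)),
    lumo_ev = lumo, dGw_kcal = dGw, dGh_kcal = dGh,
    edef_h2o_kcal = edef_h2o, edef_thf_kcal = edef_thf,
    qB_e = qB, qC_e = qC, accessible = TRUE,
    stringsAsFactors = FALSE
  )
  as_borane_library(df)
}

#' Noise-free TOF of synthetic boranes
#'
#' Evaluates the generative TOF surface (a decreasing exponential in the
#' H2-cleavage barrier times a logistic gate on water tolerance, clipped at
#' the yield ceiling) for each record. Depends on `dGh_kcal` and
#' `dGw_kcal` only.
#'
#' @param records A `borane_library` (or any data frame with `dGh_kcal`
#'   and `dGw_kcal`).
#' @param config A [synthetic_config()].
#' @return Numeric vector of noise-free TOFs (1/h).
#' @export
true_tof <- function(records, config) {
  if (!inherits(config, "synthetic_config")) {
    stopf("expected a synthetic_config")
  }
  dGh <- records$dGh_kcal
  dGw <- records$dGw_kcal
  if (is.null(dGh) || is.null(dGw) || anyNA(dGh) || anyNA(dGw)) {
    stopf("true_tof(): records must carry dGh_kcal and dGw_kcal")
  }
  tof <- config$T_max * exp(-config$k_H * (dGh - config$g0)) /
    (1 + exp(-config$k_w * (dGw - config$w0)))
  ceiling_tof <- 1 / (config$loading * config$time_h)
  pmin(tof, ceiling_tof)
}

#' Sample noisy TOF experiments for synthetic boranes
#'
#' Observes each record's true TOF under multiplicative lognormal noise,
#' re-expresses it as a product yield at the configured loading/time
#' (clipped to \[0, 1\] — the quantitative-yield ceiling) and returns a
#' validated experiment table.
#'
#' @param records A `borane_library` subset to "measure".
#' @param config A [synthetic_config()].
#' @return A `borane_experiments` data frame (one row per record).
#' @export
sample_experiments <- function(records, config) {
  if (!inherits(config, "synthetic_config")) {
    stopf("expected a synthetic_config")
  }
  truth <- true_tof(records, config)
  n <- length(truth)
  zeta <- with_seed(child_seed(config$seed, "experiments"),
                    stats::rnorm(n))
  observed <- truth * exp(config$sigma_obs * zeta)
  yield <- pmin(pmax(observed * config$loading * config$time_h, 0), 1)
  as_experiments(data.frame(
    borane_id = records$borane_id,
    yield_fraction = yield,
    loading_fraction = config$loading,
    time_h = config$time_h,
    stringsAsFactors = FALSE
  ))
}

#' Choose which synthetic boranes are "measured"
#'
#' Deterministically samples `n` borane ids to play the role of the
#' experimentally measured training set (child seed `"split"` of the
#' config seed).
#'
#' @param library A `borane_library`.
#' @param n Number of measured boranes.
#' @param config A [synthetic_config()] (supplies the seed).
#' @return Character vector of borane ids.
#' @export
sample_measured_ids <- function(library, n, config) {
  if (!inherits(config, "synthetic_config")) {
    stopf("expected a synthetic_config")
  }
  if (n > nrow(library)) stopf("n exceeds library size")
  with_seed(child_seed(config$seed, "split"),
            sort(sample(library$borane_id, n)))
}
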