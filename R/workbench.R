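# Descriptor-pair model workbench: the labelled model registry,
# leave-one-out cross-validation, Q2 scoring, and model building, updating
# and comparison.

#' Construct a descriptor-pair model specification
#'
#' @param label Short model label, unique within a registry (e.g. `"I"`).
#' @param pair Character vector of two distinct descriptor names.
#' @param lb_tag Optional Lewis-base tag (`"H2O"`/`"THF"`) for
#'   deformation-energy models.
#' @return A `model_spec` list.
#' @export
model_spec <- function(label, pair, lb_tag = NULL) {
  if (!is.character(label) || length(label) != 1L || !nzchar(label)) {
    stopf("model_spec(): label must be a non-empty string")
  }
  if (!is.character(pair) || length(pair) != 2L || pair[1] == pair[2]) {
    stopf("model_spec(): pair must name two distinct descriptors")
  }
  unknown <- setdiff(pair, descriptor_names())
  if (length(unknown)) {
    stopf("model_spec(): unknown descriptor(s): %s",
          paste(unknown, collapse = ", "))
  }
  structure(list(label = label, pair = pair, lb_tag = lb_tag),
            class = "model_spec")
}

#' The default descriptor-pair model registry
#'
#' Seven labelled two-descriptor TOF models:
#' \describe{
#'   \item{I}{water tolerance vs H2-cleavage barrier (`dGw_kcal`, `dGh_kcal`)}
#'   \item{II}{LUMO level vs barrier (`lumo_ev`, `dGh_kcal`)}
#'   \item{III}{LUMO level vs water tolerance (`lumo_ev`, `dGw_kcal`)}
#'   \item{IV}{H2O-adduct deformation energy vs barrier (`edef_h2o_kcal`, `dGh_kcal`)}
#'   \item{V}{THF-adduct deformation energy vs barrier (`edef_thf_kcal`, `dGh_kcal`)}
#'   \item{VI}{boron Mulliken charge vs barrier (`qB_e`, `dGh_kcal`)}
#'   \item{VII}{ipso-carbon Mulliken charge vs barrier (`qC_e`, `dGh_kcal`)}
#' }
#'
#' @return A named list of [model_spec()] objects.
#' @export
default_model_registry <- function() {
  specs <- list(
    model_spec("I",   c("dGw_kcal", "dGh_kcal")),
    model_spec("II",  c("lumo_ev", "dGh_kcal")),
    model_spec("III", c("lumo_ev", "dGw_kcal")),
    model_spec("IV",  c("edef_h2o_kcal", "dGh_kcal"), lb_tag = "H2O"),
    model_spec("V",   c("edef_thf_kcal", "dGh_kcal"), lb_tag = "THF"),
    model_spec("VI",  c("qB_e", "dGh_kcal")),
    model_spec("VII", c("qC_e", "dGh_kcal"))
  )
  names(specs) <- vapply(specs, `[[`, "", "label")
  specs
}

#' Leave-one-out Q2
#'
#' The cross-validated coefficient of determination,
#' \deqn{Q^2 = 1 - \frac{\sum_i (y_i - \hat y_{-i})^2}
#'                      {\sum_i (y_i - \bar y)^2},}
#' with the denominator centred on the overall mean of the observed
#' response (chemometrics convention; fold-wise centring would change
#' negative-Q2 cases). Values approach 1 for a model that explains the
#' data; values at or below 0 indicate no improvement over the mean
#' predictor. May be negative.
#'
#' @param y Observed responses.
#' @param y_loo Held-out (leave-one-out) predictions, same length.
#' @return The scalar Q2.
#' @examples
#' q_squared(c(1, 2, 3), c(1, 2, 4)) # 0.5
#' @export
q_squared <- function(y, y_loo) {
  y <- as.numeric(y); y_loo <- as.numeric(y_loo)
  if (length(y) != length(y_loo)) {
    stopf("q_squared(): y and y_loo must have equal length")
  }
  if (anyNA(y) || anyNA(y_loo)) stopf("q_squared(): missing values")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot <= 0) {
    stopf("q_squared(): y has zero variance; Q2 is undefined")
  }
  1 - sum((y - y_loo)^2) / ss_tot
}

#' Leave-one-out predictions for a descriptor-pair dataset
#'
#' For each row i, predicts its TOF from a GP trained on all other rows.
#' Two modes:
#' \describe{
#'   \item{`refit = TRUE` (default)}{hyperparameters are refit in every
#'     fold — true leave-one-out; each fold uses the same [fit_control()]
#'     (and seed).}
#'   \item{`refit = FALSE`}{hyperparameters are fixed (from `params`, or
#'     from a single fit on the full data) and the held-out means are
#'     obtained from the closed-form LOO identity
#'     \eqn{\hat y_{-i} = y_i - [K^{-1}y]_i / [K^{-1}]_{ii}} in
#'     standardized space. Standardization state is taken from the full
#'     data.}
#' }
#'
#' @param dataset A `tof_dataset` (n >= 4).
#' @param control A [fit_control()] list.
#' @param refit Refit hyperparameters per fold.
#' @param params Optional fixed hyperparameters for `refit = FALSE`.
#' @return Numeric vector of held-out predicted TOFs, named by borane id.
#' @export
loo_predict <- function(dataset, control = fit_control(), refit = TRUE,
                        params = NULL) {
  if (!inherits(dataset, "tof_dataset")) stopf("expected a tof_dataset")
  n <- length(dataset$y)
  if (n < 4L) stopf("leave-one-out needs at least 4 rows, got %d", n)
  preds <- numeric(n)
  if (refit) {
    for (i in seq_len(n)) {
      fit <- tryCatch(
        gpr.default(dataset$X[-i, , drop = FALSE], dataset$y[-i],
                    control = control,
                    feature_names = dataset$feature_names),
        error = function(e) {
          stopf("LOO fold %d (holding out %s) failed: %s",
                i, dataset$borane_ids[i], conditionMessage(e))
        }
      )
      preds[i] <- predict(fit, dataset$X[i, , drop = FALSE])
    }
  } else {
    if (is.null(params)) {
      full <- gpr.default(dataset$X, dataset$y, control = control,
                          feature_names = dataset$feature_names)
      params <- full$params
    } else {
      params <- .as_params(params)
    }
    if (control$standardize) {
      sx <- .standardizer(dataset$X)
      sy <- .standardizer(matrix(dataset$y, ncol = 1L))
    } else {
      sx <- list(mean = rep(0, ncol(dataset$X)),
                 scale = rep(1, ncol(dataset$X)))
      sy <- list(mean = 0, scale = 1)
    }
    Xs <- sweep(sweep(dataset$X, 2L, sx$mean, "-"), 2L, sx$scale, "/")
    ys <- (dataset$y - sy$mean) / sy$scale
    K <- gpr_kernel(Xs, Xs, params)
    ch <- .chol_with_jitter(K, params$noise_variance,
                            control$jitter_rel, control$jitter_max)
    Kinv <- chol2inv(ch$L)
    alpha <- drop(Kinv %*% ys)
    mu_s <- ys - alpha / diag(Kinv)
    preds <- as.numeric(sy$mean) + as.numeric(sy$scale) * mu_s
  }
  names(preds) <- dataset$borane_ids
  preds
}

#' Build a labelled descriptor-pair TOF model
#'
#' Assembles the training dataset for `spec`'s descriptor pair, computes
#' leave-one-out predictions and Q2, and fits a final GP on all rows for
#' downstream virtual screening.
#'
#' @param library A `borane_library` (or coercible data frame).
#' @param experiments A `borane_experiments` (or coercible data frame).
#' @param spec A [model_spec()].
#' @param control A [fit_control()] list.
#' @param loo_mode `"refit"` (true LOO, default) or `"fixed"`
#'   (closed-form residuals at the full-fit hyperparameters).
#' @return A `tof_model_report`: spec, `q2`, per-borane LOO predictions,
#'   the final fitted [gpr()] model, and the tables needed to update it.
#' @examples
#' cfg <- synthetic_config(n_boranes = 12, seed = 7)
#' lib <- sample_library(cfg)
#' exps <- sample_experiments(lib, cfg)
#' rep1 <- build_model(lib, exps, default_model_registry()[["I"]],
#'                     control = fit_control(restarts = 2))
#' rep1$q2
#' @export
build_model <- function(library, experiments, spec,
                        control = fit_control(),
                        loo_mode = c("refit", "fixed")) {
  if (!inherits(spec, "model_spec")) stopf("spec must come from model_spec()")
  loo_mode <- match.arg(loo_mode)
  library <- as_borane_library(library)
  experiments <- as_experiments(experiments)
  dataset <- assemble_dataset(library, experiments, spec$pair)
  if (length(dataset$y) < 4L) {
    stopf("model %s: need at least 4 experiments for LOO, got %d",
          spec$label, length(dataset$y))
  }
  preds <- loo_predict(dataset, control = control,
                       refit = loo_mode == "refit")
  q2 <- q_squared(dataset$y, preds)
  final <- gpr.tof_dataset(dataset, control = control)
  structure(
    list(spec = spec, q2 = q2,
         loo = data.frame(borane_id = dataset$borane_ids,
                          observed = dataset$y, predicted = unname(preds),
                          stringsAsFactors = FALSE),
         model = final, dataset = dataset,
         library = library, experiments = experiments,
         control = control, loo_mode = loo_mode,
         n_train = length(dataset$y),
         training_ids = dataset$borane_ids),
    class = "tof_model_report"
  )
}

#' @export
print.tof_model_report <- function(x, ...) {
  cat(sprintf("Model %s: (%s), n_train = %d\n",
              x$spec$label, paste(x$spec$pair, collapse = ", "), x$n_train))
  cat(sprintf("  LOO Q2 = %.2f (%s-hyperparameter folds)\n",
              round_half_up(x$q2, 2L),
              if (x$loo_mode == "refit") "refit" else "fixed"))
  invisible(x)
}

#' Update a model with newly measured boranes
#'
#' Rebuilds the report on the union of the original and new experiment
#' rows (same spec, same fitting control); the label gains a prime
#' suffix. A borane present in both tables is an error — observations are
#' never silently averaged.
#'
#' @param report A `tof_model_report` from [build_model()].
#' @param new_experiments Experiment rows for the newly measured boranes
#'   (may be empty, in which case only the label changes).
#' @return The updated `tof_model_report`.
#' @export
update_model <- function(report, new_experiments) {
  if (!inherits(report, "tof_model_report")) {
    stopf("expected a tof_model_report")
  }
  old <- report$experiments
  if (is.null(new_experiments) || nrow(new_experiments) == 0L) {
    new_all <- old
  } else {
    new_experiments <- as_experiments(new_experiments)
    dup <- intersect(old$borane_id, new_experiments$borane_id)
    if (length(dup)) {
      stopf("update_model(): borane(s) already measured: %s",
            paste(dup, collapse = ", "))
    }
    cols <- intersect(names(old), names(new_experiments))
    new_all <- as_experiments(rbind(as.data.frame(old)[, cols],
                                    as.data.frame(new_experiments)[, cols]))
  }
  spec2 <- model_spec(paste0(report$spec$label, "'"), report$spec$pair,
                      report$spec$lb_tag)
  build_model(report$library, new_all, spec2, control = report$control,
              loo_mode = report$loo_mode)
}

#' Rank competing descriptor-pair models by Q2
#'
#' Sorts reports by Q2 (descending; ties broken by label order) and flags
#' models whose Q2 falls below a reliability floor. All reports must have
#' been scored on the same experiment set — ranking models validated on
#' different boranes is not meaningful.
#'
#' @param reports A list of `tof_model_report`s (>= 2).
#' @param floor Reliability floor for flagging (default 0.5; purely a
#'   reporting aid).
#' @return A data frame with columns `label`, `pair`, `n_train`, `q2`,
#'   `unreliable`, sorted by decreasing Q2.
#' @export
compare_models <- function(reports, floor = 0.5) {
  if (!is.list(reports) || length(reports) < 2L ||
      !all(vapply(reports, inherits, TRUE, "tof_model_report"))) {
    stopf("compare_models(): need a list of at least two model reports")
  }
  id_sets <- lapply(reports, function(r) sort(r$training_ids))
  if (!all(vapply(id_sets, identical, TRUE, id_sets[[1]]))) {
    stopf("compare_models(): reports were scored on different experiment sets")
  }
  tab <- data.frame(
    label = vapply(reports, function(r) r$spec$label, ""),
    pair = vapply(reports, function(r) paste(r$spec$pair, collapse = "+"), ""),
    n_train = vapply(reports, function(r) r$n_train, 0L),
    q2 = vapply(reports, function(r) r$q2, 0),
    stringsAsFactors = FALSE
  )
  tab$unreliable <- tab$q2 < floor
  tab <- tab[order(-tab$q2, tab$label), ]
  rownames(tab) <- NULL
  tab
}

#' Write a campaign model-summary table
#'
#' One row per model: label, descriptor pair, training size and Q2
#' (presented at 2 decimals, the reporting convention).
#'
#' @param reports List of `tof_model_report`s.
#' @param path Destination CSV.
#' @return `path`, invisibly.
#' @export
write_model_summary <- function(reports, path) {
  tab <- data.frame(
    label = vapply(reports, function(r) r$spec$label, ""),
    pair = vapply(reports, function(r) paste(r$spec$pair, collapse = "+"), ""),
    n_train = vapply(reports, function(r) r$n_train, 0L),
    q2 = round_half_up(vapply(reports, function(r) r$q2, 0), 2L),
    stringsAsFactors = FALSE
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a model report to JSON
#'
#' @param report A `tof_model_report`.
#' @param path Destination JSON file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  if (!inherits(report, "tof_model_report")) {
    stopf("expected a tof_model_report")
  }
  doc <- list(
    type = "catscout_model_report",
    label = report$spec$label,
    pair = report$spec$pair,
    lb_tag = report$spec$lb_tag,
    n_train = report$n_train,
    q2 = report$q2,
    loo = report$loo,
    loo_mode = report$loo_mode,
    params = report$model$params,
    training_ids = report$training_ids
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
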