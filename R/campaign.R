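# Virtual screening over the untested library, cross-model disagreement
# detection, validation-batch selection and the orchestrated campaign
# driver.

#' Predict TOF for every untested library member
#'
#' Candidates are library members that carry both of the model's
#' descriptors and have no experimental measurement in the report's
#' training set. Untested members lacking a required descriptor are
#' excluded and listed in the `skipped` attribute.
#'
#' @param report A `tof_model_report` from [build_model()].
#' @param library A `borane_library` (or coercible data frame).
#' @return A data frame (`tof_predictions`) with columns `borane_id`,
#'   `model`, `mean`, `sd` (TOF units, 1/h; `sd` is the latent-function
#'   uncertainty), one row per candidate, plus a `skipped` attribute naming
#'   excluded ids. Zero eligible candidates yields an empty frame with a
#'   warning.
#' @export
predict_candidates <- function(report, library) {
  if (!inherits(report, "tof_model_report")) {
    stopf("expected a tof_model_report")
  }
  library <- as_borane_library(library)
  untested <- library[!(library$borane_id %in% report$training_ids), ,
                      drop = FALSE]
  pair <- report$spec$pair
  has_desc <- !apply(is.na(untested[, pair, drop = FALSE]), 1L, any)
  skipped <- untested$borane_id[!has_desc]
  cand <- untested[has_desc, , drop = FALSE]
  if (nrow(cand) == 0L) {
    warningf("no eligible candidates for model %s", report$spec$label)
    out <- data.frame(borane_id = character(), model = character(),
                      mean = numeric(), sd = numeric(),
                      stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    class(out) <- c("tof_predictions", "data.frame")
    return(out)
  }
  Xn <- as.matrix(cand[, pair, drop = FALSE])
  pr <- predict(report$model, Xn, se.fit = TRUE)
  out <- data.frame(borane_id = cand$borane_id,
                    model = report$spec$label,
                    mean = pr$fit, sd = pr$se.fit,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("tof_predictions", "data.frame")
  out
}

#' Flag candidates on which two models disagree
#'
#' Returns the candidates whose predicted mean TOFs under two models differ
#' by strictly more than `tau`, sorted by decreasing gap. Both prediction
#' sets must cover the same candidates. Disagreement is symmetric: swapping
#' the models permutes the mean columns but not the flagged set.
#'
#' @param results_a,results_b `tof_predictions` for the same candidate set
#'   under two models.
#' @param tau Disagreement threshold in TOF units (default 1.0 1/h, sized
#'   so that cross-model gaps of a few 1/h flag while ordinary jitter does
#'   not).
#' @return Data frame with columns `borane_id`, `mean_a`, `mean_b`, `gap`,
#'   sorted by decreasing gap; attributes `model_a`/`model_b` carry the
#'   labels.
#' @export
detect_disagreement <- function(results_a, results_b, tau = 1.0) {
  if (!is_number(tau) || tau <= 0) stopf("tau must be positive")
  if (!setequal(results_a$borane_id, results_b$borane_id) ||
      nrow(results_a) != nrow(results_b)) {
    stopf("detect_disagreement(): candidate sets differ between models")
  }
  idx <- match(results_a$borane_id, results_b$borane_id)
  gap <- abs(results_a$mean - results_b$mean[idx])
  flag <- gap > tau
  out <- data.frame(borane_id = results_a$borane_id[flag],
                    mean_a = results_a$mean[flag],
                    mean_b = results_b$mean[idx][flag],
                    gap = gap[flag],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$gap, out$borane_id), ]
  rownames(out) <- NULL
  attr(out, "model_a") <- unique(results_a$model)
  attr(out, "model_b") <- unique(results_b$model)
  out
}

#' Select the next validation batch
#'
#' Picks `k` candidates for experimental validation: strategy `"mean"`
#' takes the top-k predicted means (exploitation — the campaign default);
#' `"ucb"` takes the top-k of mean + sd (mild exploration using the GP's
#' own uncertainty). Ties break deterministically by borane id.
#'
#' @param results A `tof_predictions` data frame.
#' @param k Batch size (`1 <= k <=` number of candidates).
#' @param strategy `"mean"` or `"ucb"`.
#' @return Character vector of `k` borane ids.
#' @export
select_validation_batch <- function(results, k, strategy = c("mean", "ucb")) {
  strategy <- match.arg(strategy)
  if (!is_count(k) || k < 1L) stopf("k must be a positive integer")
  if (k > nrow(results)) {
    stopf("k = %d exceeds the %d available candidate(s)", k, nrow(results))
  }
  score <- switch(strategy,
                  mean = results$mean,
                  ucb = results$mean + results$sd)
  results$borane_id[order(-score, results$borane_id)][seq_len(k)]
}

#' Configure a screening campaign
#'
#' @param library A `borane_library`, or a path to a library CSV.
#' @param experiments A `borane_experiments`, or a path to an experiments
#'   CSV (the initial training measurements).
#' @param new_experiments Optional experiments for the validation batch
#'   (triggers the update/re-rank/recommend stages).
#' @param models Character vector of registry labels to build (default:
#'   the full registry, skipping models whose descriptors are absent from
#'   the measured boranes is *not* done silently — requesting an
#'   unsupported model errors).
#' @param tau Disagreement threshold (1/h).
#' @param batch_size Validation-batch size.
#' @param strategy Batch-selection strategy (see
#'   [select_validation_batch()]).
#' @param control A [fit_control()]; its seed is re-derived from `seed`.
#' @param out_dir Output directory for the report bundle.
#' @param seed Campaign master seed.
#' @param floor Q2 reliability floor for flagging.
#' @param accessible_only Restrict the final catalyst recommendation to
#'   candidates tagged synthetically accessible.
#' @return A validated `campaign_config` list.
#' @export
campaign_config <- function(library, experiments, new_experiments = NULL,
                            models = NULL, tau = 1.0, batch_size = 3L,
                            strategy = "mean", control = fit_control(),
                            out_dir = tempfile("campaign"), seed = 0L,
                            floor = 0.5, accessible_only = TRUE) {
  if (!is_number(tau) || tau <= 0) stopf("campaign_config(): tau must be > 0")
  if (!is_count(batch_size) || batch_size < 1L) {
    stopf("campaign_config(): batch_size must be >= 1")
  }
  if (!is_count(seed)) stopf("campaign_config(): seed must be an integer")
  strategy <- match.arg(strategy, c("mean", "ucb"))
  if (!inherits(control, "gpr_control")) {
    stopf("campaign_config(): control must come from fit_control()")
  }
  structure(
    list(library = library, experiments = experiments,
         new_experiments = new_experiments, models = models,
         tau = tau, batch_size = as.integer(batch_size),
         strategy = strategy, control = control,
         out_dir = out_dir, seed = as.integer(seed), floor = floor,
         accessible_only = isTRUE(accessible_only)),
    class = "campaign_config"
  )
}

.load_table <- function(x, reader, coercer) {
  if (is.character(x) && length(x) == 1L) reader(x) else coercer(x)
}

#' Run the orchestrated screening campaign
#'
#' Executes, in order: (1) build the registry models on the measured
#' boranes and write the model table; (2) predict TOF for every untested
#' candidate under every model; (3) flag cross-model disagreements at
#' `tau`; (4) select a validation batch from the best-Q2 model's
#' predictions; and, when `new_experiments` are supplied, (5) update every
#' model with the new measurements, re-rank, and (6) recommend the
#' catalyst with the top predicted mean under the best updated model
#' (restricted to accessible candidates). All outputs are a pure function
#' of the inputs, the configuration and the seed; no timestamps are
#' written. A failure in any stage aborts with the stage name after
#' writing a MANIFEST marking the bundle incomplete.
#'
#' @param config A [campaign_config()].
#' @return Invisibly, a list with the model reports, prediction tables,
#'   disagreement report, validation batch, updated reports/ranking and
#'   recommendation (when applicable), and the output file manifest.
#' @export
run_campaign <- function(config) {
  if (!inherits(config, "campaign_config")) {
    stopf("expected a campaign_config")
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  log_lines <- character()
  stage <- "setup"
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }
  fail <- function(e) {
    manifest <- list(complete = FALSE, failed_stage = stage,
                     error = conditionMessage(e), files = files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "campaign.log"))
    stopf("campaign stage '%s' failed: %s", stage, conditionMessage(e))
  }
  emit <- function(name) files <<- c(files, name)

  out <- tryCatch({
    stage <- "load-inputs"
    library <- .load_table(config$library, read_borane_library,
                           as_borane_library)
    experiments <- .load_table(config$experiments, read_experiments,
                               as_experiments)
    note("library with %d boranes, %d measured", nrow(library),
         nrow(experiments))

    stage <- "build-models"
    registry <- default_model_registry()
    labels <- config$models %||% names(registry)
    unknown <- setdiff(labels, names(registry))
    if (length(unknown)) {
      stopf("unknown model label(s): %s", paste(unknown, collapse = ", "))
    }
    control <- config$control
    control$seed <- child_seed(config$seed, "fit")
    reports <- lapply(registry[labels], function(sp) {
      build_model(library, experiments, sp, control = control)
    })
    write_model_summary(reports, file.path(config$out_dir, "models.csv"))
    emit("models.csv")
    for (r in reports) {
      fn <- sprintf("model_%s.json", r$spec$label)
      write_report_json(r, file.path(config$out_dir, fn))
      emit(fn)
    }
    ranking <- compare_models(reports, floor = config$floor)
    note("built %d model(s); best Q2 = %.2f (Model %s)", length(reports),
         ranking$q2[1], ranking$label[1])

    stage <- "predict-candidates"
    predictions <- lapply(reports, predict_candidates, library = library)
    pred_tab <- do.call(rbind, lapply(predictions, as.data.frame))
    rownames(pred_tab) <- NULL
    utils::write.csv(pred_tab, file.path(config$out_dir, "predictions.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("predictions.csv")
    skipped <- lapply(predictions, attr, "skipped")
    jsonlite::write_json(skipped, file.path(config$out_dir, "skipped.json"),
                         auto_unbox = FALSE, digits = NA, pretty = TRUE)
    emit("skipped.json")
    note("predicted %d candidate(s) per model",
         if (length(predictions)) nrow(predictions[[1]]) else 0L)

    stage <- "detect-disagreement"
    disagreements <- list()
    if (length(predictions) >= 2L) {
      combs <- utils::combn(names(predictions), 2L, simplify = FALSE)
      for (cb in combs) {
        d <- detect_disagreement(predictions[[cb[1]]], predictions[[cb[2]]],
                                 tau = config$tau)
        if (nrow(d)) {
          d$model_a <- cb[1]; d$model_b <- cb[2]
          disagreements[[paste(cb, collapse = "-")]] <- d
        }
      }
    }
    dis_tab <- if (length(disagreements)) {
      do.call(rbind, c(disagreements, make.row.names = FALSE))
    } else {
      data.frame(borane_id = character(), mean_a = numeric(),
                 mean_b = numeric(), gap = numeric(),
                 model_a = character(), model_b = character(),
                 stringsAsFactors = FALSE)
    }
    utils::write.csv(dis_tab, file.path(config$out_dir, "disagreement.csv"),
                     row.names = FALSE, quote = FALSE)
    emit("disagreement.csv")
    note("%d disagreement(s) above tau = %.2f", nrow(dis_tab), config$tau)

    stage <- "select-batch"
    best_label <- ranking$label[1]
    best_preds <- predictions[[best_label]]
    batch <- if (nrow(best_preds)) {
      select_validation_batch(best_preds,
                              min(config$batch_size, nrow(best_preds)),
                              strategy = config$strategy)
    } else character()
    jsonlite::write_json(
      list(model = best_label, strategy = config$strategy, batch = batch),
      file.path(config$out_dir, "validation_batch.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("validation_batch.json")
    note("validation batch under Model %s: %s", best_label,
         paste(batch, collapse = ", "))

    updated <- NULL; updated_ranking <- NULL; recommendation <- NULL
    if (!is.null(config$new_experiments) &&
        nrow(as.data.frame(config$new_experiments)) > 0L) {
      stage <- "update-models"
      new_exps <- .load_table(config$new_experiments, read_experiments,
                              as_experiments)
      updated <- lapply(reports, update_model, new_experiments = new_exps)
      names(updated) <- vapply(updated, function(r) r$spec$label, "")
      write_model_summary(updated,
                          file.path(config$out_dir, "models_updated.csv"))
      emit("models_updated.csv")
      updated_ranking <- compare_models(updated, floor = config$floor)
      note("updated %d model(s); best Q2 = %.2f (Model %s)",
           length(updated), updated_ranking$q2[1], updated_ranking$label[1])

      stage <- "recommend"
      best_up <- updated[[updated_ranking$label[1]]]
      cand_preds <- predict_candidates(best_up, library)
      if (config$accessible_only) {
        acc <- library$borane_id[library$accessible]
        cand_preds <- cand_preds[cand_preds$borane_id %in% acc, ,
                                 drop = FALSE]
      }
      if (nrow(cand_preds) == 0L) {
        stopf("no accessible untested candidates left to recommend")
      }
      top <- select_validation_batch(cand_preds, 1L, strategy = "mean")
      recommendation <- list(
        model = best_up$spec$label,
        q2 = best_up$q2,
        borane_id = top,
        predicted_tof = round_half_up(
          cand_preds$mean[cand_preds$borane_id == top], 2L)
      )
      jsonlite::write_json(recommendation,
                           file.path(config$out_dir, "recommendation.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("recommendation.json")
      note("recommended %s (Model %s, predicted TOF %.2f 1/h)",
           recommendation$borane_id, recommendation$model,
           recommendation$predicted_tof)
    }

    stage <- "finalize"
    manifest <- list(complete = TRUE, seed = config$seed, files = files)
    jsonlite::write_json(manifest, file.path(config$out_dir, "MANIFEST.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "campaign.log"))

    list(reports = reports, ranking = ranking, predictions = predictions,
         disagreement = dis_tab, validation_batch = batch,
         updated = updated, updated_ranking = updated_ranking,
         recommendation = recommendation, files = files,
         out_dir = config$out_dir, log = log_lines)
  }, error = function(e) {
    if (grepl("^campaign stage", conditionMessage(e))) stop(e)
    fail(e)
  })
  invisible(out)
}
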