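make_predictions <- function(ids, means, sds = rep(0.1, length(ids)),
                             model = "I") {
  out <- data.frame(borane_id = ids, model = model, mean = means, sd = sds,
                    stringsAsFactors = FALSE)
  class(out) <- c("tof_predictions", "data.frame")
  out
}

test_that("candidate predictions cover exactly the untested, fully described boranes", {
  lib <- library_with_text_ids(seed = 2)
  cfg <- synthetic_config(n_boranes = 54, seed = 2)
  exps <- sample_experiments(lib, cfg)
  measured <- text_identified_measured()
  train <- exps[exps$borane_id %in% measured, ]
  rep1 <- build_model(lib, train, default_model_registry()[["I"]],
                      control = fit_control(seed = 1))
  preds <- predict_candidates(rep1, lib)
  expect_identical(nrow(preds), 39L)
  expect_false(any(preds$borane_id %in% measured))
  expect_true(all(preds$sd >= 0))
  expect_false(anyDuplicated(preds$borane_id) > 0)

  # composition: each row equals a direct predict() call
  q <- as.matrix(lib[match(preds$borane_id, lib$borane_id),
                     rep1$spec$pair])
  direct <- predict(rep1$model, q, se.fit = TRUE)
  expect_equal(preds$mean, unname(direct$fit))
  expect_equal(preds$sd, unname(direct$se.fit))

  # candidates missing a descriptor are skipped and reported
  lib2 <- lib
  lib2$dGw_kcal[lib2$borane_id == "B4b"] <- NA
  lib2 <- as_borane_library(lib2)
  preds2 <- predict_candidates(rep1, lib2)
  expect_identical(nrow(preds2), 38L)
  expect_identical(attr(preds2, "skipped"), "B4b")
})

test_that("disagreement detection flags strict exceedances, symmetrically", {
  a <- make_predictions(c("B4b", "B4c", "B4e"), c(3.50, 3.66, 3.59),
                        model = "I")
  b <- make_predictions(c("B4b", "B4c", "B4e"), c(0.55, 0.23, 0.55),
                        model = "II")
  d <- detect_disagreement(a, b, tau = 1.0)
  expect_identical(d$borane_id, c("B4c", "B4e", "B4b")) # gap descending
  expect_equal(d$gap, c(3.43, 3.04, 2.95))

  # symmetric: swapping models preserves the flagged set
  d2 <- detect_disagreement(b, a, tau = 1.0)
  expect_setequal(d2$borane_id, d$borane_id)
  expect_equal(d2$gap, d$gap)

  # identical predictions -> empty; boundary gap == tau is not flagged
  expect_identical(nrow(detect_disagreement(a, a, tau = 1.0)), 0L)
  c1 <- make_predictions("B4b", 1.0)
  c2 <- make_predictions("B4b", 2.0)
  expect_identical(nrow(detect_disagreement(c1, c2, tau = 1.0)), 0L)
  expect_identical(nrow(detect_disagreement(c1, c2, tau = 0.999)), 1L)

  expect_error(detect_disagreement(a, make_predictions("B4b", 1)), "differ")
})

test_that("validation batches follow the configured acquisition strategy", {
  set.seed(4)
  ids <- paste0("B2", letters[1:10])
  preds <- make_predictions(ids, runif(10, 0, 4), sds = runif(10, 0, 1))
  top3 <- select_validation_batch(preds, 3, "mean")
  expect_identical(top3, preds$borane_id[order(-preds$mean,
                                               preds$borane_id)][1:3])
  ucb3 <- select_validation_batch(preds, 3, "ucb")
  score <- preds$mean + preds$sd
  expect_identical(ucb3, preds$borane_id[order(-score,
                                               preds$borane_id)][1:3])
  expect_setequal(select_validation_batch(preds, 10, "mean"), ids)
  # deterministic tie-break by id
  tied <- make_predictions(c("B2b", "B2a"), c(1, 1))
  expect_identical(select_validation_batch(tied, 1, "mean"), "B2a")
  expect_error(select_validation_batch(preds, 11, "mean"), "exceeds")
  expect_error(select_validation_batch(preds, 3, "epsilon"), "arg")
})

test_that("a full campaign runs, updates, recommends and is byte-deterministic", {
  lib <- library_with_text_ids(seed = 5)
  cfg <- synthetic_config(n_boranes = 54, seed = 5)
  exps <- sample_experiments(lib, cfg)
  measured <- text_identified_measured()
  train <- exps[exps$borane_id %in% measured, ]

  run_once <- function(dir) {
    first <- run_campaign(campaign_config(
      library = lib, experiments = train, models = c("I", "III"),
      out_dir = file.path(dir, "pass1"), seed = 42,
      control = fit_control(restarts = 3)))
    batch <- first$validation_batch
    new_exps <- exps[exps$borane_id %in% batch, ]
    run_campaign(campaign_config(
      library = lib, experiments = train, new_experiments = new_exps,
      models = c("I", "III"), out_dir = file.path(dir, "pass2"), seed = 42,
      control = fit_control(restarts = 3)))
  }

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  res1 <- run_once(d1)
  res2 <- run_once(d2)

  expected <- c("models.csv", "model_I.json", "model_III.json",
                "predictions.csv", "skipped.json", "disagreement.csv",
                "validation_batch.json", "models_updated.csv",
                "recommendation.json", "MANIFEST.json", "campaign.log")
  for (f in expected) {
    expect_true(file.exists(file.path(d1, "pass2", f)), label = f)
  }
  manifest <- jsonlite::read_json(file.path(d1, "pass2", "MANIFEST.json"))
  expect_true(manifest$complete)

  # same inputs + same seed -> byte-identical report bundle
  for (f in expected) {
    expect_identical(readBin(file.path(d1, "pass2", f), "raw", 1e6),
                     readBin(file.path(d2, "pass2", f), "raw", 1e6),
                     label = f)
  }

  expect_identical(res1$updated[[1]]$spec$label, "I'")
  expect_identical(res1$updated[[1]]$n_train, 18L)
  expect_false(res1$recommendation$borane_id %in%
                 c(measured, res1$validation_batch))
})

test_that("a failing stage aborts with its name and an incomplete manifest", {
  lib <- library_with_text_ids(seed = 6)
  cfg <- synthetic_config(n_boranes = 54, seed = 6)
  exps <- sample_experiments(lib, cfg)
  train <- exps[exps$borane_id %in% text_identified_measured(), ]
  dir <- withr::local_tempdir()
  expect_error(
    run_campaign(campaign_config(lib, train, models = c("I", "IX"),
                                 out_dir = dir, seed = 1)),
    "stage 'build-models'.*unknown model")
  manifest <- jsonlite::read_json(file.path(dir, "MANIFEST.json"))
  expect_false(manifest$complete)
  expect_identical(manifest$failed_stage, "build-models")
})

test_that("campaign recommendations recover near-optimal boranes on known truth", {
  reg_labels <- c("I", "III")
  hits <- vapply(1:25, function(s) {
    cfg <- synthetic_config(n_boranes = 54, seed = 1000 + s)
    lib <- sample_library(cfg)
    exps <- sample_experiments(lib, cfg)
    meas <- sample_measured_ids(lib, 15, cfg)
    train <- exps[exps$borane_id %in% meas, ]
    dir <- tempfile("camp")
    first <- run_campaign(campaign_config(
      lib, train, models = reg_labels, out_dir = file.path(dir, "p1"),
      seed = s, control = fit_control(restarts = 3)))
    new_exps <- exps[exps$borane_id %in% first$validation_batch, ]
    second <- run_campaign(campaign_config(
      lib, train, new_experiments = new_exps, models = reg_labels,
      out_dir = file.path(dir, "p2"), seed = s,
      control = fit_control(restarts = 3)))
    unlink(dir, recursive = TRUE)
    # the recommendation is drawn from the boranes still untested after
    # the validation batch was measured; score it against that pool
    cand <- setdiff(lib$borane_id, c(meas, first$validation_batch))
    truth <- true_tof(lib[match(cand, lib$borane_id), ], cfg)
    decile <- cand[rank(-truth, ties.method = "first") <=
                     ceiling(length(cand) / 10)]
    second$recommendation$borane_id %in% decile
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
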