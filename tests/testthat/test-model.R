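test_that("normalization mean-centers and scales with external statistics", {
  rec <- make_records(2, core = c(0, 10))
  stats <- feature_stats(rec, "core_size")
  expect_equal(stats$mean, 5)
  expect_equal(stats$sd, sd(c(0, 10)))  # n-1 denominator, ~7.071
  out <- normalize_features(rec, stats)
  expect_equal(out$core_size, c(-1, 1) / sqrt(2), tolerance = 1e-10)

  # an already standardized column is unchanged up to floating error
  z <- as.numeric(scale(c(1, 4, 9)))
  rec3 <- make_records(3, core = z)
  out3 <- normalize_features(rec3, feature_stats(rec3, "core_size"))
  expect_equal(out3$core_size, z, tolerance = 1e-12)

  # constant column: centered only
  recc <- make_records(3, core = rep(7, 3))
  outc <- normalize_features(recc, feature_stats(recc, "core_size"))
  expect_equal(outc$core_size, rep(0, 3))

  bad <- feature_stats(make_records(1), "core_size")
  bad$mean <- NA_real_
  expect_error(normalize_features(rec, bad), "statistics")
})

test_that("the 60/40 split partitions deterministically", {
  rec <- make_records(10)
  parts <- split_train_test(rec, seed = 3)
  expect_equal(nrow(parts$train), 6)
  expect_equal(nrow(parts$test), 4)
  expect_setequal(c(parts$train$record_id, parts$test$record_id),
                  rec$record_id)
  expect_length(intersect(parts$train$record_id, parts$test$record_id), 0)
  again <- split_train_test(rec, seed = 3)
  expect_identical(parts$train$record_id, again$train$record_id)
  other <- split_train_test(rec, seed = 4)
  expect_false(identical(parts$train$record_id, other$train$record_id))
  expect_error(split_train_test(rec[1, ], seed = 1), "at least 2")
})

test_that("the forest learns a separable dose threshold", {
  rec <- make_dose_signal_records(300)
  parts <- split_train_test(rec, seed = 1)
  cfg <- model_config(n_trees = 200, base_seed = 1)
  fit <- train_classifier(parts$train, cfg, levels_from = rec)
  acc <- mean(predict(fit, parts$test) == parts$test$label)
  expect_gte(acc, 0.95)
  # seeded refits reproduce predictions exactly
  fit2 <- train_classifier(parts$train, cfg, levels_from = rec)
  expect_identical(predict(fit, parts$test), predict(fit2, parts$test))
})

test_that("permuted labels give chance-level accuracy", {
  rec <- make_dose_signal_records(300)
  rec$label <- withr::with_seed(99, sample(rec$label))
  rec$viability_pct <- ifelse(rec$label == "Toxic", 20, 95)
  parts <- split_train_test(rec, seed = 1)
  cfg <- model_config(n_trees = 200, base_seed = 1)
  fit <- train_classifier(parts$train, cfg, levels_from = rec)
  acc <- mean(predict(fit, parts$test) == parts$test$label)
  maj <- max(table(parts$test$label)) / nrow(parts$test)
  n <- nrow(parts$test)
  expect_lt(abs(acc - maj), 3 * sqrt(maj * (1 - maj) / n))
})

test_that("single-class training data are rejected", {
  rec <- make_records(20, viability = rep(95, 20))
  expect_error(train_classifier(rec, model_config()), "both classes")
})

test_that("metrics match a brute-force counting oracle", {
  count_oracle <- function(pred, truth) {
    tp <- 0; fp <- 0; fn <- 0; tn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == "Toxic" && truth[i] == "Toxic") tp <- tp + 1
      if (pred[i] == "Toxic" && truth[i] == "Nontoxic") fp <- fp + 1
      if (pred[i] == "Nontoxic" && truth[i] == "Toxic") fn <- fn + 1
      if (pred[i] == "Nontoxic" && truth[i] == "Nontoxic") tn <- tn + 1
    }
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    sens <- if (tp + fn > 0) tp / (tp + fn) else 0
    list(tp = tp, fp = fp, fn = fn, tn = tn, precision = prec,
         sensitivity = sens, accuracy = (tp + tn) / length(pred),
         f1 = if (prec + sens > 0) 2 * prec * sens / (prec + sens) else 0)
  }
  withr::with_seed(31, {
    for (rep in 1:20) {
      n <- sample(3:40, 1)
      pred <- sample(c("Toxic", "Nontoxic"), n, replace = TRUE)
      truth <- sample(c("Toxic", "Nontoxic"), n, replace = TRUE)
      got <- compute_metrics(pred, truth)
      want <- count_oracle(pred, truth)
      for (field in names(want)) expect_equal(got[[field]], want[[field]])
      # F1 lies between precision and sensitivity when both are positive
      if (want$precision > 0 && want$sensitivity > 0) {
        eps <- 1e-12  # harmonic-mean bounds, up to floating error
        expect_gte(got$f1, min(want$precision, want$sensitivity) - eps)
        expect_lte(got$f1, max(want$precision, want$sensitivity) + eps)
      }
    }
  })
  expect_error(compute_metrics(character(0), character(0)), "non-empty")
})

test_that("f1 is the harmonic mean of precision and sensitivity", {
  expect_equal(f1_score(0.8, 0.03), 2 * 0.8 * 0.03 / 0.83)
  expect_equal(round(100 * f1_score(0.8, 0.03)), 6)
  expect_equal(round(100 * f1_score(0.91, 0.88)), 89)
  expect_equal(f1_score(1, 1), 1)
  expect_equal(f1_score(0, 0), 0)
})

test_that("replicated experiments average metrics and reproduce exactly", {
  rec <- make_dose_signal_records(240)
  cfg1 <- model_config(n_trees = 100, base_seed = 5, n_replications = 1,
                       cv_folds = 0)
  one <- run_experiment(rec, cfg1)
  expect_equal(nrow(one$metrics), 1)
  expect_equal(one$summary$f1, one$metrics$f1)

  cfg3 <- model_config(n_trees = 100, base_seed = 5, n_replications = 3,
                       cv_folds = 0)
  three <- run_experiment(rec, cfg3)
  expect_equal(nrow(three$metrics), 3)
  expect_equal(three$summary$accuracy, mean(three$metrics$accuracy))
  expect_equal(three$summary$f1, mean(three$metrics$f1))

  rerun <- run_experiment(rec, cfg3)
  expect_identical(three$metrics, rerun$metrics)

  td <- tidy(three)
  expect_equal(nrow(td), 3)
  g <- glance(three)
  expect_equal(g$n, 240)
  expect_equal(g$f1, three$summary$f1)
})

test_that("cross-validation reports fold-averaged training metrics", {
  rec <- make_dose_signal_records(200)
  cfg <- model_config(n_trees = 80, base_seed = 2, n_replications = 2,
                      cv_folds = 3)
  ex <- run_experiment(rec, cfg)
  expect_equal(nrow(ex$cv), 2)
  expect_true(all(ex$cv$accuracy >= 0 & ex$cv$accuracy <= 1))
})

test_that("dropping the physicochemical attributes degrades the model", {
  s <- small_synth(seed = 42, n = 1500)
  tier_ii <- build_dataset_ii(s$records, s$catalogs)
  base <- model_config(n_trees = 150, base_seed = 10, n_replications = 2,
                       cv_folds = 0)
  dose_only <- base
  dose_only$features <- "dose"
  with_pchem <- base
  with_pchem$features <- c("dose", "pchem")
  f1_dose <- run_experiment(tier_ii, dose_only)$summary$f1
  f1_pchem <- run_experiment(tier_ii, with_pchem)$summary$f1
  expect_lt(f1_dose, f1_pchem)
})
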