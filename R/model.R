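# Random-forest classification of the Toxic/Nontoxic endpoint: feature
# encoding, mean-center/scale normalization, replicated 60/40 validation,
# cross-validation and the confusion-matrix metrics.

#' Configuration for model training and validation
#'
#' @param n_trees Number of trees in the forest.
#' @param mtry Features tried per split; `NULL` means `floor(sqrt(p))`.
#' @param base_seed Base random seed; replication `i` uses `base_seed + i`.
#' @param n_replications Number of random 60/40 splits to average over.
#' @param train_fraction Fraction of records in the training partition.
#' @param cv_folds Folds for the stratified cross-validation on the
#'   training partition; `0` disables cross-validation.
#' @param features Attribute categories to model, a subset of
#'   `names(attribute_categories())`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(n_trees = 500, mtry = NULL, base_seed = 100,
                         n_replications = 5, train_fraction = 0.6,
                         cv_folds = 5, features = c("dose", "pchem", "qm",
                                                    "tox")) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must be in (0, 1)", call. = FALSE)
  }
  if (n_replications < 1) stop("n_replications must be >= 1", call. = FALSE)
  unknown <- setdiff(features, names(attribute_categories()))
  if (length(unknown) > 0) {
    stop("unknown feature categories: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  structure(
    list(n_trees = n_trees, mtry = mtry, base_seed = as.integer(base_seed),
         n_replications = as.integer(n_replications),
         train_fraction = train_fraction, cv_folds = as.integer(cv_folds),
         features = features),
    class = "model_config"
  )
}

model_feature_columns <- function(features) {
  unlist(attribute_categories()[features], use.names = FALSE)
}

#' Per-attribute normalization statistics
#'
#' Mean and standard deviation (n - 1 denominator) of each numeric modeling
#' attribute, computed over present values; intended to be computed on the
#' training partition and applied to both partitions.
#'
#' @param records Record tibble.
#' @param columns Numeric columns to summarize; defaults to every numeric
#'   modeling attribute present in `records`.
#' @return Tibble with columns `attribute`, `mean`, `sd`.
#' @export
feature_stats <- function(records,
                          columns = intersect(numeric_record_columns(),
                                              names(records))) {
  purrr::map_dfr(columns, function(col) {
    x <- records[[col]][!is.na(records[[col]])]
    tibble::tibble(
      attribute = col,
      mean = if (length(x)) mean(x) else NA_real_,
      sd = if (length(x) > 1) stats::sd(x) else 0
    )
  })
}

#' Mean-center and scale numeric attributes
#'
#' Transforms each numeric attribute to `(x - mean)/sd` using externally
#' supplied statistics (see [feature_stats()]). A zero or undefined SD
#' (constant column) centers without scaling.
#'
#' @param records Record tibble.
#' @param stats Tibble from [feature_stats()], typically computed on the
#'   training partition.
#' @return The normalized tibble.
#' @export
normalize_features <- function(records, stats) {
  stopifnot(is.data.frame(stats),
            all(c("attribute", "mean", "sd") %in% names(stats)))
  out <- records
  for (i in seq_len(nrow(stats))) {
    col <- stats$attribute[i]
    if (!col %in% names(out)) {
      stop("no such attribute to normalize: ", col, call. = FALSE)
    }
    if (!is.finite(stats$mean[i])) {
      stop("missing normalization statistics for ", col, call. = FALSE)
    }
    s <- stats$sd[i]
    if (!is.finite(s) || s == 0) s <- 1
    out[[col]] <- (out[[col]] - stats$mean[i]) / s
  }
  out
}

#' Random 60/40 train/test split
#'
#' Simple (unstratified) random partition; `round(train_fraction * n)`
#' records train. The same seed always yields the same partition.
#'
#' @param records Record tibble with at least two rows.
#' @param seed Integer seed.
#' @param train_fraction Training fraction, default 0.6.
#' @return List with tibbles `train` and `test`.
#' @export
split_train_test <- function(records, seed, train_fraction = 0.6) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n < 2) stop("need at least 2 records to split", call. = FALSE)
  n_train <- round(train_fraction * n)
  n_train <- min(max(n_train, 1L), n - 1L)
  idx <- withr::with_seed(as.integer(seed), sample(n, n_train))
  list(train = records[sort(idx), ], test = records[-sort(idx), ])
}

# One-hot encode the modeling frame. Factor levels are taken from `levels_from`
# (usually the full table) so train and test matrices align.
encode_features <- function(records, features, levels_from = records) {
  cols <- model_feature_columns(features)
  nominal <- intersect(cols, tox_nominal_attributes())
  numeric_cols <- setdiff(cols, nominal)
  mats <- list()
  if (length(numeric_cols) > 0) {
    mats$num <- as.matrix(records[numeric_cols])
  }
  for (col in nominal) {
    lev <- sort(unique(levels_from[[col]]))
    f <- factor(records[[col]], levels = lev)
    if (anyNA(f)) {
      stop("unseen or missing level in nominal attribute ", col, call. = FALSE)
    }
    m <- outer(f, lev, "==") * 1
    colnames(m) <- paste0(col, "_", lev)
    mats[[col]] <- m
  }
  do.call(cbind, mats)
}

#' Train a random-forest Toxic/Nontoxic classifier
#'
#' Fits a seeded random forest on the encoded training records (numeric
#' attributes as-is, nominal Tox attributes one-hot, `cell_name` never
#' used). Exposes the out-of-bag error and out-of-bag class predictions.
#'
#' @param train Training record tibble containing both classes.
#' @param config A [model_config()].
#' @param seed Seed for this fit; defaults to `config$base_seed`.
#' @param levels_from Tibble supplying the nominal level sets (defaults to
#'   `train`); pass the full table so test-set encoding aligns.
#' @return An object of class `nanosar_rf` with elements `fit`
#'   (the underlying randomForest), `oob_error`, `features`, `levels_from`.
#' @export
train_classifier <- function(train, config = model_config(),
                             seed = config$base_seed, levels_from = train) {
  stopifnot(is.data.frame(train))
  y <- factor(train$label, levels = c("Nontoxic", "Toxic"))
  if (length(unique(y)) < 2) {
    stop("training set must contain both classes", call. = FALSE)
  }
  x <- encode_features(train, config$features, levels_from)
  if (anyNA(x)) {
    stop("training features contain missing values; impute first",
         call. = FALSE)
  }
  mtry <- config$mtry
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- withr::with_seed(
    as.integer(seed),
    randomForest::randomForest(x, y, ntree = config$n_trees, mtry = mtry)
  )
  oob_error <- unname(fit$err.rate[config$n_trees, "OOB"])
  structure(
    list(fit = fit, oob_error = oob_error, features = config$features,
         levels_from = levels_from, config = config),
    class = "nanosar_rf"
  )
}

#' @export
predict.nanosar_rf <- function(object, newdata, ...) {
  x <- encode_features(newdata, object$features, object$levels_from)
  if (anyNA(x)) {
    stop("prediction features contain missing values; impute first",
         call. = FALSE)
  }
  as.character(stats::predict(object$fit, x))
}

#' Confusion-matrix performance metrics with Toxic as the positive class
#'
#' @param predictions Character vector of `"Toxic"`/`"Nontoxic"` predictions.
#' @param truth Character vector of true labels, same length.
#' @return One-row tibble with `tp`, `fp`, `fn`, `tn`, `precision`,
#'   `sensitivity`, `accuracy`, `f1` (proportions in \[0, 1\]). Undefined
#'   ratios (empty denominators) are reported as 0.
#' @export
compute_metrics <- function(predictions, truth) {
  if (length(predictions) == 0 || length(predictions) != length(truth)) {
    stop("predictions and truth must be non-empty and of equal length",
         call. = FALSE)
  }
  tp <- sum(predictions == "Toxic" & truth == "Toxic")
  fp <- sum(predictions == "Toxic" & truth == "Nontoxic")
  fn <- sum(predictions == "Nontoxic" & truth == "Toxic")
  tn <- sum(predictions == "Nontoxic" & truth == "Nontoxic")
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  sensitivity <- if (tp + fn > 0) tp / (tp + fn) else 0
  tibble::tibble(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = precision, sensitivity = sensitivity,
    accuracy = (tp + tn) / length(truth),
    f1 = f1_score(precision, sensitivity)
  )
}

#' F1 score from precision and sensitivity
#'
#' Harmonic mean `2 P S / (P + S)`, defined as 0 when both are 0.
#'
#' @param precision,sensitivity Proportions in \[0, 1\].
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(precision, sensitivity) {
  ifelse(precision + sensitivity > 0,
         2 * precision * sensitivity / (precision + sensitivity), 0)
}

# train-partition means for the numeric modeling columns, used to impute
# both partitions without leakage
impute_from_train <- function(train, test, columns) {
  for (col in columns) {
    if (!anyNA(train[[col]]) && !anyNA(test[[col]])) next
    present <- train[[col]][!is.na(train[[col]])]
    if (length(present) == 0) {
      stop("cannot impute ", col, ": no values in training partition",
           call. = FALSE)
    }
    m <- mean(present)
    train[[col]][is.na(train[[col]])] <- m
    test[[col]][is.na(test[[col]])] <- m
  }
  list(train = train, test = test)
}

stratified_folds <- function(y, k, seed) {
  withr::with_seed(as.integer(seed), {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Replicated 60/40 validation of the random-forest model
#'
#' For each replication `i` (seed `base_seed + i`): split 60/40, impute any
#' missing numeric values with training-partition means, mean-center and
#' scale on training statistics, fit the forest, evaluate on the held-out
#' 40 percent (external validation), and optionally run stratified k-fold
#' cross-validation within the training partition. Metrics are averaged
#' arithmetically across replications. The whole procedure is a pure
#' function of `(records, config)`.
#'
#' @param records Labeled record tibble (a dataset tier).
#' @param config A [model_config()].
#' @return An object of class `nanosar_experiment`: list with `metrics`
#'   (per-replication external-validation tibble), `summary` (their mean),
#'   `cv` (per-replication cross-validation means, or `NULL`), `oob_error`
#'   (per replication), `config`, `n`.
#' @export
run_experiment <- function(records, config = model_config()) {
  stopifnot(is.data.frame(records))
  num_cols <- intersect(model_feature_columns(config$features),
                        numeric_record_columns())
  reps <- purrr::map(seq_len(config$n_replications), function(i) {
    seed <- config$base_seed + i
    parts <- split_train_test(records, seed, config$train_fraction)
    parts <- impute_from_train(parts$train, parts$test, num_cols)
    stats <- feature_stats(parts$train, num_cols)
    train <- normalize_features(parts$train, stats)
    test <- normalize_features(parts$test, stats)
    model <- train_classifier(train, config, seed = seed,
                              levels_from = records)
    ext <- compute_metrics(predict(model, test), test$label)
    cv <- NULL
    if (config$cv_folds >= 2) {
      fold <- stratified_folds(train$label, config$cv_folds, seed)
      cv_metrics <- purrr::map_dfr(seq_len(config$cv_folds), function(f) {
        tr <- train[fold != f, ]
        te <- train[fold == f, ]
        m <- train_classifier(tr, config, seed = seed, levels_from = records)
        compute_metrics(predict(m, te), te$label)
      })
      cv <- dplyr::summarise(cv_metrics,
                             dplyr::across(dplyr::everything(), mean))
    }
    list(ext = dplyr::mutate(ext, replication = i, .before = 1),
         cv = cv, oob = model$oob_error)
  })
  metrics <- dplyr::bind_rows(purrr::map(reps, "ext"))
  summary <- dplyr::summarise(
    dplyr::select(metrics, -"replication"),
    dplyr::across(dplyr::everything(), mean)
  )
  cv <- if (config$cv_folds >= 2) {
    dplyr::bind_rows(purrr::map(reps, "cv"))
  }
  structure(
    list(metrics = metrics, summary = summary, cv = cv,
         oob_error = purrr::map_dbl(reps, "oob"), config = config,
         n = nrow(records)),
    class = "nanosar_experiment"
  )
}

#' @export
print.nanosar_experiment <- function(x, ...) {
  cat("Random-forest Toxic/Nontoxic validation:", x$n, "records,",
      x$config$n_replications, "replication(s)\n")
  cat("Averaged external validation (Toxic positive):\n")
  s <- x$summary
  cat(sprintf("  precision %.0f%%  sensitivity %.0f%%  accuracy %.0f%%  F1 %.0f%%\n",
              100 * s$precision, 100 * s$sensitivity, 100 * s$accuracy,
              100 * s$f1))
  invisible(x)
}

#' Tidy per-replication validation metrics
#'
#' @param x A `nanosar_experiment`.
#' @param ... Unused.
#' @return Tibble of per-replication external-validation metrics.
#' @export
tidy.nanosar_experiment <- function(x, ...) {
  x$metrics
}

#' One-row summary of an experiment
#'
#' @param x A `nanosar_experiment`.
#' @param ... Unused.
#' @return One-row tibble of replication-averaged metrics plus `n` and
#'   `n_replications`.
#' @export
glance.nanosar_experiment <- function(x, ...) {
  dplyr::mutate(x$summary, n = x$n,
                n_replications = x$config$n_replications)
}
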