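# Attribute importance: leave-one-out out-of-bag errors, and validation of
# attribute-category combinations built around dose.

# OOB error of a forest trained on `records` restricted to `columns`,
# averaged over the replicated training partitions.
oob_error_for_columns <- function(records, columns, config) {
  nominal <- intersect(columns, tox_nominal_attributes())
  numeric_cols <- setdiff(columns, nominal)
  mean(vapply(seq_len(config$n_replications), function(i) {
    seed <- config$base_seed + i
    parts <- split_train_test(records, seed, config$train_fraction)
    parts <- impute_from_train(parts$train, parts$test, numeric_cols)
    stats <- feature_stats(parts$train, numeric_cols)
    train <- normalize_features(parts$train, stats)
    y <- factor(train$label, levels = c("Nontoxic", "Toxic"))
    x <- encode_features_cols(train, columns, levels_from = records)
    mtry <- config$mtry
    if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
    fit <- withr::with_seed(
      as.integer(seed),
      randomForest::randomForest(x, y, ntree = config$n_trees, mtry = mtry)
    )
    unname(fit$err.rate[config$n_trees, "OOB"])
  }, numeric(1)))
}

# like encode_features() but for an explicit column list
encode_features_cols <- function(records, columns, levels_from) {
  nominal <- intersect(columns, tox_nominal_attributes())
  numeric_cols <- setdiff(columns, nominal)
  mats <- list()
  if (length(numeric_cols) > 0) mats$num <- as.matrix(records[numeric_cols])
  for (col in nominal) {
    lev <- sort(unique(levels_from[[col]]))
    f <- factor(records[[col]], levels = lev)
    m <- outer(f, lev, "==") * 1
    colnames(m) <- paste0(col, "_", lev)
    mats[[col]] <- m
  }
  do.call(cbind, mats)
}

#' Leave-one-out out-of-bag attribute importance
#'
#' Removes each modeling attribute in turn, refits the seeded forest on the
#' remaining attributes over the replicated training partitions, and records
#' the out-of-bag error: dropping an important attribute raises the OOB
#' error. The ranking is by OOB error descending. The protocol does not
#' account for redundancy between attributes — removing one of two highly
#' correlated attributes barely moves the error.
#'
#' @param records Labeled record tibble.
#' @param config A [model_config()]; `config$features` defines the modeled
#'   categories whose attributes are ranked.
#' @return An object of class `importance_report`: tibble `importance`
#'   (attribute, oob_error, rank), scalar `baseline_oob` (all attributes),
#'   and `config`.
#' @export
loo_oob_importance <- function(records, config = model_config()) {
  columns <- model_feature_columns(config$features)
  if (length(columns) < 2) {
    stop("need at least two modeling attributes", call. = FALSE)
  }
  baseline <- oob_error_for_columns(records, columns, config)
  oob <- vapply(columns, function(col) {
    oob_error_for_columns(records, setdiff(columns, col), config)
  }, numeric(1))
  imp <- tibble::tibble(attribute = columns, oob_error = unname(oob))
  imp <- dplyr::arrange(imp, dplyr::desc(.data$oob_error), .data$attribute)
  imp$rank <- seq_len(nrow(imp))
  structure(
    list(importance = imp, baseline_oob = baseline, config = config),
    class = "importance_report"
  )
}

#' @export
print.importance_report <- function(x, ...) {
  cat(sprintf("Leave-one-out OOB importance (baseline OOB error %.4f)\n",
              x$baseline_oob))
  print(x$importance)
  invisible(x)
}

#' Tidy a leave-one-out importance report
#'
#' @param x An `importance_report`.
#' @param ... Unused.
#' @return Tibble with `attribute`, `oob_error`, `rank`.
#' @export
tidy.importance_report <- function(x, ...) {
  x$importance
}

#' Validate attribute-category combinations built around dose
#'
#' Dose is always included; each requested combination of the `pchem`,
#' `qm` and `tox` categories is added in turn and the replicated 60/40
#' validation is run on that feature set, reporting averaged accuracy and
#' F1.
#'
#' @param records Labeled record tibble.
#' @param combinations List of character vectors of category tokens (each a
#'   subset of `c("pchem", "qm", "tox")`); e.g.
#'   `list("pchem", "qm", "tox", c("pchem", "qm"), c("pchem", "tox"))`.
#' @param config A [model_config()]; its `features` field is overridden per
#'   combination.
#' @return Tibble with `combination`, `accuracy`, `f1` (and the full metric
#'   set), one row per combination.
#' @export
category_combination_study <- function(records, combinations,
                                       config = model_config()) {
  if (length(combinations) == 0) {
    stop("`combinations` must be non-empty", call. = FALSE)
  }
  purrr::map_dfr(combinations, function(combo) {
    combo <- setdiff(combo, "dose")
    unknown <- setdiff(combo, c("pchem", "qm", "tox"))
    if (length(unknown) > 0) {
      stop("unknown category token: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cfg <- config
    cfg$features <- c("dose", combo)
    res <- run_experiment(records, cfg)
    dplyr::mutate(
      res$summary,
      combination = paste(c("dose", combo), collapse = "+"),
      .before = 1
    )
  })
}
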