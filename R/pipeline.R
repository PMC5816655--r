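# End-to-end orchestration: build the four dataset tiers, run the model,
# applicability-domain and importance analyses per tier, and write a
# reproducible run directory with a manifest.

#' Build the four preprocessing tiers of a record table
#'
#' Tier I is the scored original data (missing values are mean-substituted
#' later, at modeling time, so scores are unaffected); tier II is the
#' gap-filled, rescored table with unfillable records dropped; tiers III-A
#' and III-B keep the top 50 and 20 percent of tier II by PChem score.
#'
#' @param records Record tibble.
#' @param catalogs A [nano_catalogs()] object.
#' @param keep_fractions Screening fractions for the III tiers.
#' @return Named list of scored tibbles `I`, `II`, `III-A`, `III-B`.
#' @export
build_dataset_tiers <- function(records, catalogs,
                                keep_fractions = c(`III-A` = 0.5,
                                                   `III-B` = 0.2)) {
  tier_i <- score_records(records)
  tier_ii <- build_dataset_ii(records, catalogs)
  tiers <- c(
    list(I = tier_i, II = tier_ii),
    purrr::map(as.list(keep_fractions),
               function(f) screen_by_score(tier_ii, f))
  )
  tiers
}

#' Run the full meta-analysis pipeline
#'
#' Generates (or loads) the record table and catalogs, assigns the
#' endpoint, scores, gap-fills and screens into the four tiers, then runs
#' the replicated random-forest validation, the applicability-domain
#' analysis (on the first replication's training partition) and, optionally,
#' the leave-one-out importance and category studies per tier. When
#' `out_dir` is given, all tables are written as CSV, all reports as JSON,
#' plus a manifest tying the outputs to the configuration; reruns with the
#' same configuration reproduce the outputs.
#'
#' @param config Either a [synth_config()] (synthetic input) or a list with
#'   elements `records_csv` and `catalogs_dir` (CSV input). May also be a
#'   path to a YAML file holding the synthetic generator fields under
#'   `generator:` or the CSV paths under `input:`.
#' @param out_dir Optional output directory.
#' @param model A [model_config()].
#' @param ad_k,ad_Z Applicability-domain parameters.
#' @param importance_tier Tier name on which to run the importance studies,
#'   or `NULL` to skip them.
#' @return A list of class `nanosar_run`: `tiers`, `experiments`,
#'   `ad_profiles`, `importance`, `categories`, `manifest`.
#' @export
run_pipeline <- function(config = synth_config(), out_dir = NULL,
                         model = model_config(), ad_k = 5, ad_Z = 1.645,
                         importance_tier = NULL) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  if (inherits(config, "synth_config")) {
    synth <- generate_dataset(config)
    records <- synth$records
    catalogs <- synth$catalogs
    input_desc <- list(type = "synthetic", seed = config$seed,
                       n_records = config$n_records)
  } else {
    stopifnot(is.list(config), !is.null(config$records_csv))
    records <- read_nano_records(config$records_csv)
    catalogs <- if (!is.null(config$catalogs_dir)) {
      read_catalogs(config$catalogs_dir)
    } else {
      nano_catalogs()
    }
    input_desc <- list(type = "csv", records_csv = config$records_csv)
  }

  tiers <- build_dataset_tiers(records, catalogs)
  experiments <- purrr::map(tiers, run_experiment, config = model)
  ad_profiles <- purrr::map(tiers, function(tier) {
    num_cols <- setdiff(model_feature_columns(c("dose", "pchem", "qm",
                                                "tox")),
                        tox_nominal_attributes())
    parts <- split_train_test(tier, model$base_seed + 1,
                              model$train_fraction)
    train <- impute_from_train(parts$train, parts$test, num_cols)$train
    build_ad_profile(train, k = ad_k, Z = ad_Z)
  })

  importance <- NULL
  categories <- NULL
  if (!is.null(importance_tier)) {
    stopifnot(importance_tier %in% names(tiers))
    importance <- loo_oob_importance(tiers[[importance_tier]], model)
    categories <- category_combination_study(
      tiers[[importance_tier]],
      list("pchem", "qm", "tox", c("pchem", "qm"), c("pchem", "tox")),
      model
    )
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nanosar")),
    input = input_desc,
    model = unclass(model),
    ad = list(k = ad_k, Z = ad_Z),
    tier_rows = purrr::map_int(tiers, nrow),
    toxic_rows = purrr::map_int(tiers, ~ sum(.x$label == "Toxic")),
    importance_tier = importance_tier
  )

  run <- structure(
    list(tiers = tiers, experiments = experiments,
         ad_profiles = ad_profiles, importance = importance,
         categories = categories, manifest = manifest),
    class = "nanosar_run"
  )
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the yaml package", call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$generator)) {
    do.call(synth_config, cfg$generator)
  } else if (!is.null(cfg$input)) {
    cfg$input
  } else {
    stop("config must contain a `generator:` or `input:` block",
         call. = FALSE)
  }
}

write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (nm in names(run$tiers)) {
    tier <- run$tiers[[nm]]
    readr::write_csv(tier, file.path(out_dir, paste0("dataset_", nm, ".csv")),
                     na = "", progress = FALSE)
    ex <- run$experiments[[nm]]
    jsonlite::write_json(
      list(per_replication = ex$metrics, mean = ex$summary,
           cv = ex$cv, oob_error = ex$oob_error),
      file.path(out_dir, paste0("metrics_", nm, ".json")),
      auto_unbox = TRUE, digits = NA
    )
    write_ad_profile(run$ad_profiles[[nm]],
                     file.path(out_dir, paste0("ad_", nm, ".json")))
  }
  if (!is.null(run$importance)) {
    jsonlite::write_json(
      list(baseline_oob = run$importance$baseline_oob,
           importance = run$importance$importance),
      file.path(out_dir, "importance.json"), auto_unbox = TRUE, digits = NA
    )
    readr::write_csv(run$categories, file.path(out_dir, "categories.csv"),
                     progress = FALSE)
  }
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.nanosar_run <- function(x, ...) {
  cat("nanosar pipeline run\n")
  cat("Tier sizes:",
      paste(names(x$manifest$tier_rows), x$manifest$tier_rows,
            sep = "=", collapse = ", "), "\n")
  for (nm in names(x$experiments)) {
    s <- x$experiments[[nm]]$summary
    cat(sprintf(
      "  %-6s precision %3.0f%%  sensitivity %3.0f%%  accuracy %3.0f%%  F1 %3.0f%%\n",
      nm, 100 * s$precision, 100 * s$sensitivity, 100 * s$accuracy,
      100 * s$f1))
  }
  invisible(x)
}
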