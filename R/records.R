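# Record-table I/O, validation, endpoint assignment and missingness summary.

#' Assign the Toxic/Nontoxic endpoint from viability
#'
#' A record is labeled `"Toxic"` when the measured cell viability is strictly
#' below 50 percent and `"Nontoxic"` otherwise; a viability of exactly 50
#' is Nontoxic. Viability readouts above 100 percent are legitimate assay
#' artifacts and are labeled by the same rule.
#'
#' @param viability Numeric vector of viability percentages.
#' @return Character vector of `"Toxic"` / `"Nontoxic"`.
#' @examples
#' assign_endpoint(c(49.9, 50, 100))
#' @export
assign_endpoint <- function(viability) {
  if (!is.numeric(viability) || any(!is.finite(viability))) {
    stop("`viability` must be a finite numeric vector", call. = FALSE)
  }
  ifelse(viability < 50, "Toxic", "Nontoxic")
}

# strict = TRUE enforces the curated-data invariant value-absent <=>
# source-absent; strict = FALSE tolerates imputed values (value present,
# provenance absent), which by construction score zero
validate_records <- function(records, context = "record table",
                             strict = TRUE) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(record_columns(), names(records))
  if (length(missing_cols) > 0) {
    stop(
      context, ": missing columns: ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(records$record_id)) {
    stop(context, ": record_id values must be unique", call. = FALSE)
  }
  vocab <- method_vocab()
  for (attr in pchem_attributes()) {
    value <- records[[attr]]
    src <- records[[paste0(attr, "_source")]]
    mth <- records[[paste0(attr, "_method")]]
    bad_src <- !is.na(src) & !src %in% source_levels()
    if (any(bad_src)) {
      stop(
        context, ": unknown source level '", src[bad_src][1], "' for ", attr,
        " at record ", records$record_id[bad_src][1],
        call. = FALSE
      )
    }
    bad_mth <- !is.na(mth) & !mth %in% vocab[[attr]]
    if (any(bad_mth)) {
      stop(
        context, ": unknown method '", mth[bad_mth][1], "' for ", attr,
        " at record ", records$record_id[bad_mth][1],
        call. = FALSE
      )
    }
    # value absent <=> source absent (=> only, if not strict); absent
    # source => no method
    incoherent <- (is.na(value) & !is.na(src)) | (is.na(src) & !is.na(mth))
    if (strict) incoherent <- incoherent | (!is.na(value) & is.na(src))
    if (any(incoherent)) {
      stop(
        context, ": provenance incoherent for ", attr, " at record ",
        records$record_id[incoherent][1],
        " (value, source and method must be absent together)",
        call. = FALSE
      )
    }
  }
  bad_label <- !is.na(records$label) &
    (records$label != assign_endpoint(records$viability_pct))
  if (any(bad_label)) {
    stop(
      context, ": label inconsistent with the 50% viability rule at record ",
      records$record_id[bad_label][1],
      call. = FALSE
    )
  }
  invisible(records)
}

#' Read a nanotoxicity record table from CSV
#'
#' Reads the canonical flat CSV (one exposure observation per row), maps
#' empty cells to absent measurements, validates provenance coherence and
#' enum vocabularies, and (re)assigns the Toxic/Nontoxic endpoint from the
#' viability column.
#'
#' @param path Path to a CSV file with the canonical header
#'   (see [record_columns()]); the `label` column is optional on input.
#' @return A tibble of validated records with a `label` column.
#' @seealso [write_nano_records()]
#' @export
read_nano_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  num_cols <- numeric_record_columns()
  spec <- readr::cols(.default = readr::col_character())
  raw <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                         progress = FALSE)
  expected <- setdiff(record_columns(), "label")
  unknown <- setdiff(names(raw), record_columns())
  if (length(unknown) > 0) {
    stop("unknown column(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(expected, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(num_cols, names(raw))) {
    parsed <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- !is.na(raw[[col]]) & is.na(parsed)
    if (any(bad)) {
      stop(
        "non-numeric value '", raw[[col]][bad][1], "' in column ", col,
        " at row ", which(bad)[1],
        call. = FALSE
      )
    }
    raw[[col]] <- parsed
  }
  if (any(!is.finite(raw$viability_pct))) {
    stop("viability_pct must be present and finite for every row",
         call. = FALSE)
  }
  raw$label <- assign_endpoint(raw$viability_pct)
  records <- dplyr::select(raw, dplyr::all_of(record_columns()))
  validate_records(records, context = path)
  tibble::as_tibble(records)
}

#' Write a record table to CSV
#'
#' Inverse of [read_nano_records()]: absent measurements become empty cells,
#' so a write/read round trip reproduces the table exactly.
#'
#' @param records Record tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_nano_records <- function(records, path) {
  validate_records(records)
  readr::write_csv(records[record_columns()], path, na = "", progress = FALSE)
  invisible(path)
}

#' Summarize per-attribute missingness of the PChem data
#'
#' Literature-curated nanotoxicity data are sparse in particle
#' characterization; this reports the fraction of records with an absent
#' value for each of the four PChem attributes.
#'
#' @param records Record tibble.
#' @return Tibble with columns `attribute`, `n_missing`, `n`,
#'   `missing_fraction`.
#' @export
summarize_missingness <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("record table is empty", call. = FALSE)
  purrr::map_dfr(pchem_attributes(), function(attr) {
    n_missing <- sum(is.na(records[[attr]]))
    tibble::tibble(
      attribute = attr,
      n_missing = n_missing,
      n = nrow(records),
      missing_fraction = n_missing / nrow(records)
    )
  })
}
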