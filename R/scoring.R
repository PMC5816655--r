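# PChem data-quality scoring: per-attribute source + method scores, the
# 0-5 final score, and score-based screening into quality tiers.

#' Score the data source of a measurement
#'
#' Data reported from the authors' own experiments score 3, values adapted
#' from manufacturers' specifications score 2, values reused from other
#' references on the same nanomaterial score 1, and absent data score 0.
#'
#' @param source_level Character vector of source levels
#'   (`"experimental"`, `"manufacturer"`, `"reference"`) or `NA` for absent.
#' @return Integer vector of source scores in 0..3.
#' @export
score_source <- function(source_level) {
  known <- is.na(source_level) | source_level %in% source_levels()
  if (!all(known)) {
    stop("unknown source level: ", source_level[!known][1], call. = FALSE)
  }
  out <- dplyr::case_when(
    is.na(source_level) ~ 0L,
    source_level == "experimental" ~ 3L,
    source_level == "manufacturer" ~ 2L,
    source_level == "reference" ~ 1L
  )
  out
}

#' Score the measurement method of a PChem attribute
#'
#' The field's gold-standard technique for each attribute (TEM for core
#' size, DLS/NTA for hydrodynamic size, zeta potential for surface charge,
#' BET for specific surface area) scores 2; less common methods and values
#' estimated from other attributes score 1; no information scores 0.
#'
#' @param attribute One of [pchem_attributes()].
#' @param method_label Character vector of method labels for that attribute,
#'   or `NA` for no information.
#' @return Integer vector of method scores in 0..2.
#' @export
score_method <- function(attribute, method_label) {
  vocab <- method_vocab()
  if (!attribute %in% names(vocab)) {
    stop("unknown PChem attribute: ", attribute, call. = FALSE)
  }
  known <- is.na(method_label) | method_label %in% vocab[[attribute]]
  if (!all(known)) {
    stop(
      "unknown method '", method_label[!known][1], "' for ", attribute,
      call. = FALSE
    )
  }
  dplyr::case_when(
    is.na(method_label) ~ 0L,
    method_label == gold_standard_method(attribute) ~ 2L,
    TRUE ~ 1L
  )
}

#' Compute PChem data-quality scores for every record
#'
#' Each of the four PChem attributes receives the sum of its data-source
#' score (0-3) and measurement-method score (0-2); the final PChem score of
#' a record is the arithmetic mean of the four attribute totals, so it lies
#' in \[0, 5\]. A fully experimental record characterized by the
#' gold-standard methods scores the maximum of 5; a record with no PChem
#' data scores 0.
#'
#' @param records Record tibble.
#' @return The input with `<attribute>_score` columns and a `pchem_score`
#'   column appended (existing score columns are recomputed).
#' @export
score_records <- function(records) {
  validate_records(records, strict = FALSE)
  out <- records
  for (attr in pchem_attributes()) {
    out[[paste0(attr, "_score")]] <-
      score_source(out[[paste0(attr, "_source")]]) +
      score_method(attr, out[[paste0(attr, "_method")]])
  }
  out$pchem_score <- rowMeans(
    as.matrix(out[paste0(pchem_attributes(), "_score")])
  )
  tibble::as_tibble(out)
}

#' Screen records by PChem score
#'
#' Sorts records by final PChem score in descending order (ties broken by
#' `record_id` so membership is deterministic) and keeps the top
#' `floor(keep_fraction * n)` records, at least one. Screening the gap-filled
#' dataset with fractions 0.5 and 0.2 yields the quality tiers III-A and
#' III-B.
#'
#' @param records Scored record tibble (see [score_records()]).
#' @param keep_fraction Fraction of records to keep, in (0, 1].
#' @return Tibble of the retained records, highest scores first.
#' @export
screen_by_score <- function(records, keep_fraction) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0) stop("record table is empty", call. = FALSE)
  if (!is.numeric(keep_fraction) || length(keep_fraction) != 1 ||
      keep_fraction <= 0 || keep_fraction > 1) {
    stop("`keep_fraction` must be a single number in (0, 1]", call. = FALSE)
  }
  if (!"pchem_score" %in% names(records)) {
    stop("records must be scored first (see score_records())", call. = FALSE)
  }
  n_keep <- max(1L, floor(keep_fraction * nrow(records)))
  ord <- order(-records$pchem_score, records$record_id)
  records[ord, ][seq_len(n_keep), ]
}
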