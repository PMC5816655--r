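# Rule-based gap filling of missing PChem/QM values: manufacturer catalog,
# reference lookup, diameter/surface-area estimation, and mean substitution.

#' Estimate specific surface area from core diameter
#'
#' For a spherical particle of diameter `d` (nm) and bulk density `rho`
#' (g/cm^3), the geometric specific surface area is `SSA = 6 / (d * rho)`;
#' with these units the SI reduction gives `6000 / (d * rho)` in m^2/g.
#'
#' @param d Core diameter in nm, positive.
#' @param rho Bulk density in g/cm^3, positive.
#' @return Specific surface area in m^2/g.
#' @examples
#' estimate_ssa_from_core(60, 1.0) # 100 m^2/g
#' @export
estimate_ssa_from_core <- function(d, rho) {
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("`rho` must be positive and finite", call. = FALSE)
  }
  6000 / (d * rho)
}

#' Estimate core diameter from specific surface area
#'
#' Algebraic inverse of [estimate_ssa_from_core()]:
#' `d = 6000 / (SSA * rho)` nm.
#'
#' @param ssa Specific surface area in m^2/g, positive.
#' @param rho Bulk density in g/cm^3, positive.
#' @return Core diameter in nm.
#' @export
estimate_core_from_ssa <- function(ssa, rho) {
  if (any(!is.finite(ssa)) || any(ssa <= 0)) {
    stop("`ssa` must be positive and finite", call. = FALSE)
  }
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("`rho` must be positive and finite", call. = FALSE)
  }
  6000 / (ssa * rho)
}

#' Bundle gap-filling lookup tables
#'
#' @param manufacturer Tibble with columns `material_id`, `attribute`,
#'   `value`, `method` (method may be `NA`): the manufacturers'
#'   characterization data for products identified by brand + product number.
#' @param reference Tibble with the same columns: values adapted from other
#'   publications on the same nanomaterial.
#' @param density Tibble with columns `composition`, `rho_g_cm3` (positive).
#' @param qm Tibble with columns `composition`, `dHsf_eV`, `Ec_eV`, `Ev_eV`,
#'   `chi_eV`; every entry must satisfy `Ev_eV < Ec_eV`.
#' @return A list of class `nano_catalogs`.
#' @export
nano_catalogs <- function(manufacturer = NULL, reference = NULL,
                          density = NULL, qm = NULL) {
  empty_lookup <- tibble::tibble(
    material_id = character(), attribute = character(),
    value = numeric(), method = character()
  )
  if (is.null(manufacturer)) manufacturer <- empty_lookup
  if (is.null(reference)) reference <- empty_lookup
  if (is.null(density)) {
    density <- tibble::tibble(composition = character(), rho_g_cm3 = numeric())
  }
  if (is.null(qm)) {
    qm <- tibble::tibble(
      composition = character(), dHsf_eV = numeric(), Ec_eV = numeric(),
      Ev_eV = numeric(), chi_eV = numeric()
    )
  }
  for (tbl in list(manufacturer, reference)) {
    stopifnot(all(c("material_id", "attribute", "value", "method") %in% names(tbl)))
    if (anyDuplicated(tbl[c("material_id", "attribute")])) {
      stop("catalog must have one entry per material_id x attribute",
           call. = FALSE)
    }
  }
  if (any(density$rho_g_cm3 <= 0)) {
    stop("densities must be positive", call. = FALSE)
  }
  if (any(qm$Ev_eV >= qm$Ec_eV)) {
    stop("QM table must satisfy Ev < Ec", call. = FALSE)
  }
  structure(
    list(manufacturer = tibble::as_tibble(manufacturer),
         reference = tibble::as_tibble(reference),
         density = tibble::as_tibble(density),
         qm = tibble::as_tibble(qm)),
    class = "nano_catalogs"
  )
}

#' Read gap-filling catalogs from a directory of CSV files
#'
#' Expects `manufacturer_catalog.csv`, `reference_catalog.csv`,
#' `density.csv` and `qm_table.csv`; any file may be absent, in which case
#' that lookup is empty.
#'
#' @param dir Directory containing the catalog CSVs.
#' @return A `nano_catalogs` object.
#' @export
read_catalogs <- function(dir) {
  read_one <- function(name, col_types) {
    path <- file.path(dir, name)
    if (!file.exists(path)) return(NULL)
    readr::read_csv(path, col_types = col_types, na = c("", "NA"),
                    progress = FALSE)
  }
  nano_catalogs(
    manufacturer = read_one("manufacturer_catalog.csv", "ccdc"),
    reference = read_one("reference_catalog.csv", "ccdc"),
    density = read_one("density.csv", "cd"),
    qm = read_one("qm_table.csv", "cdddd")
  )
}

# Vectorized catalog pass for one attribute: returns value/method vectors
# aligned with material_id, NA where the catalog has no entry.
lookup_attribute <- function(lookup, material_id, attribute) {
  sub <- lookup[lookup$attribute == attribute, ]
  idx <- match(material_id, sub$material_id)
  list(value = sub$value[idx], method = sub$method[idx])
}

#' Fill missing PChem and QM values by rule
#'
#' For each absent PChem attribute the first hit in the priority order
#' manufacturer catalog > reference catalog > estimation (core diameter and
#' specific surface area interconverted via `SSA = 6/(d * rho)`) supplies
#' the value, with provenance updated accordingly; absent QM values are
#' looked up by composition. Attributes with no applicable rule stay absent
#' and are flagged in the fill report. Composition-level QM fills on
#' particles below 5 nm trigger a warning, since bulk-like electronic
#' properties stop being size-independent in that regime.
#'
#' Catalog fills carry `source_level` `"manufacturer"` or `"reference"`
#' (method `"other"` when the catalog states none); estimates carry the
#' basis value's source level and an `estimated_from_*` method label.
#'
#' @param records Record tibble.
#' @param catalogs A [nano_catalogs()] object.
#' @return The filled tibble, with the fill report (one row per change or
#'   unfillable flag) attached as attribute `"fill_report"`; retrieve it
#'   with [fill_report()].
#' @export
fill_records <- function(records, catalogs) {
  validate_records(records)
  stopifnot(inherits(catalogs, "nano_catalogs"))
  out <- records
  report <- list()
  note <- function(ids, attribute, action, value, method) {
    if (length(ids) == 0) return(invisible())
    report[[length(report) + 1]] <<- tibble::tibble(
      record_id = ids, attribute = attribute, action = action,
      value = value, method = method
    )
  }

  # pass 1: catalog lookups (manufacturer preferred over reference, matching
  # the source-score ordering 2 > 1)
  for (attr in pchem_attributes()) {
    for (src in c("manufacturer", "reference")) {
      todo <- is.na(out[[attr]])
      if (!any(todo)) break
      hit <- lookup_attribute(catalogs[[src]], out$material_id, attr)
      use <- todo & !is.na(hit$value)
      if (!any(use)) next
      method <- hit$method[use]
      method[is.na(method)] <- "other"  # unstated method: conservative
      out[[attr]][use] <- hit$value[use]
      out[[paste0(attr, "_source")]][use] <- src
      out[[paste0(attr, "_method")]][use] <- method
      note(out$record_id[use], attr, paste0("fill_", src),
           hit$value[use], method)
    }
  }

  # pass 2: core size <-> surface area estimation through the density table;
  # the estimate inherits the basis value's source level, and the method
  # label records that it is an estimate (method score 1)
  rho <- catalogs$density$rho_g_cm3[
    match(out$composition, catalogs$density$composition)
  ]
  est_ssa <- is.na(out$surface_area) & !is.na(out$core_size) &
    out$core_size > 0 & !is.na(rho)
  if (any(est_ssa)) {
    out$surface_area[est_ssa] <-
      estimate_ssa_from_core(out$core_size[est_ssa], rho[est_ssa])
    out$surface_area_source[est_ssa] <- out$core_size_source[est_ssa]
    out$surface_area_method[est_ssa] <- "estimated_from_core"
    note(out$record_id[est_ssa], "surface_area", "estimate_eq1",
         out$surface_area[est_ssa], "estimated_from_core")
  }
  est_core <- is.na(out$core_size) & !is.na(out$surface_area) &
    out$surface_area > 0 & !is.na(rho)
  if (any(est_core)) {
    out$core_size[est_core] <-
      estimate_core_from_ssa(out$surface_area[est_core], rho[est_core])
    out$core_size_source[est_core] <- out$surface_area_source[est_core]
    out$core_size_method[est_core] <- "estimated_from_ssa"
    note(out$record_id[est_core], "core_size", "estimate_eq1",
         out$core_size[est_core], "estimated_from_ssa")
  }

  # QM properties are composition-level lookups
  qm_idx <- match(out$composition, catalogs$qm$composition)
  tiny <- !is.na(out$core_size) & out$core_size < 5 &
    rowSums(is.na(out[qm_attributes()])) > 0 & !is.na(qm_idx)
  if (any(tiny)) {
    warning(
      sum(tiny), " record(s) below 5 nm receive composition-level QM values;",
      " size-dependent deviations are expected at this scale",
      call. = FALSE
    )
  }
  for (attr in qm_attributes()) {
    qm_val <- catalogs$qm[[attr]][qm_idx]
    use <- is.na(out[[attr]]) & !is.na(qm_val)
    if (!any(use)) next
    out[[attr]][use] <- qm_val[use]
    note(out$record_id[use], attr, "fill_qm_table", qm_val[use], NA_character_)
  }

  # flag what no rule could fill
  for (attr in c(pchem_attributes(), qm_attributes())) {
    left <- is.na(out[[attr]])
    note(out$record_id[left], attr, "unfillable", NA_real_, NA_character_)
  }

  report <- dplyr::bind_rows(report)
  if (nrow(report) == 0) {
    report <- tibble::tibble(
      record_id = character(), attribute = character(), action = character(),
      value = numeric(), method = character()
    )
  }
  report <- dplyr::arrange(report, .data$record_id, .data$attribute)
  validate_records(out, context = "filled record table")
  attr(out, "fill_report") <- report
  out
}

#' Retrieve the fill report attached by [fill_records()]
#'
#' @param records A tibble returned by [fill_records()] or
#'   [build_dataset_ii()].
#' @return Tibble with columns `record_id`, `attribute`, `action`, `value`,
#'   `method`.
#' @export
fill_report <- function(records) {
  rep <- attr(records, "fill_report")
  if (is.null(rep)) stop("no fill report attached", call. = FALSE)
  rep
}

#' Build the gap-filled dataset (tier II)
#'
#' Applies [fill_records()], removes every record that still has an absent
#' PChem or QM value, and recomputes the PChem scores on the filled
#' provenance. Filling can only move a source score up from 0 (to 1 or 2)
#' and a method score up from 0, so no surviving record's final score drops.
#'
#' @param records Record tibble (scored or not; scores are recomputed).
#' @param catalogs A [nano_catalogs()] object.
#' @return Scored tibble of fully characterized records, with the fill
#'   report and the excluded record ids (attribute `"excluded"`) attached.
#' @export
build_dataset_ii <- function(records, catalogs) {
  filled <- fill_records(records, catalogs)
  complete <- stats::complete.cases(
    filled[c(pchem_attributes(), qm_attributes())]
  )
  if (!any(complete)) {
    stop("gap filling left no fully characterized records", call. = FALSE)
  }
  out <- score_records(filled[complete, ])
  attr(out, "fill_report") <- fill_report(filled)
  attr(out, "excluded") <- filled$record_id[!complete]
  out
}

#' Mean-substitute missing numeric PChem values
#'
#' Replaces each absent PChem value by the attribute mean over present
#' values in `stats_source` (typically the training partition, so the test
#' partition never leaks into the statistics). Provenance columns are left
#' untouched: an imputed value is still "no data" for scoring purposes, so
#' PChem scores are unchanged.
#'
#' @param records Record tibble to impute.
#' @param stats_source Record tibble from which attribute means are computed;
#'   defaults to `records`.
#' @return The imputed tibble.
#' @export
mean_substitute <- function(records, stats_source = records) {
  stopifnot(is.data.frame(records), is.data.frame(stats_source))
  out <- records
  for (attr in pchem_attributes()) {
    if (!any(is.na(out[[attr]]))) next
    present <- stats_source[[attr]][!is.na(stats_source[[attr]])]
    if (length(present) == 0) {
      stop("cannot mean-substitute ", attr,
           ": no present values in stats_source", call. = FALSE)
    }
    out[[attr]][is.na(out[[attr]])] <- mean(present)
  }
  out
}
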