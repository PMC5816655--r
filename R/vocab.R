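# Attribute vocabularies and the canonical column dictionary shared by every
# module. All tables in the package are plain tibbles with these columns.

#' Physicochemical attributes carrying provenance
#'
#' The four physicochemical (PChem) attributes that are scored for data
#' quality and eligible for gap filling: core size (nm), hydrodynamic size
#' (nm), surface charge (mV) and specific surface area (m^2/g).
#'
#' @return Character vector of the four PChem column names.
#' @export
pchem_attributes <- function() {
  c("core_size", "hydro_size", "surface_charge", "surface_area")
}

#' Quantum-mechanical attribute columns
#'
#' Formation enthalpy, conduction/valence band energies and electronegativity
#' of the oxide, all in eV. These are composition-level constants looked up
#' from a QM table rather than measured per record.
#'
#' @return Character vector of the four QM column names.
#' @export
qm_attributes <- function() {
  c("dHsf_eV", "Ec_eV", "Ev_eV", "chi_eV")
}

# Valid data-source levels for a present measurement (absent values carry NA).
source_levels <- function() c("experimental", "manufacturer", "reference")

# Measurement-method vocabulary per PChem attribute. The first entry is the
# gold-standard method (method score 2); the rest score 1; NA scores 0.
method_vocab <- function() {
  list(
    core_size      = c("TEM", "SEM_AFM", "estimated_from_ssa", "other"),
    hydro_size     = c("DLS_NTA", "other"),
    surface_charge = c("zeta_potential", "other"),
    surface_area   = c("BET", "estimated_from_core", "other")
  )
}

gold_standard_method <- function(attribute) {
  method_vocab()[[attribute]][1]
}

# Nominal toxicological attributes used in modeling (cell_name is carried in
# the schema but deliberately never modeled: it has too many levels).
tox_nominal_attributes <- function() {
  c("assay", "cell_species", "cell_origin", "cell_type")
}

#' Attribute-category map used for modeling and importance studies
#'
#' Maps the category tokens `dose`, `pchem`, `qm` and `tox` to record
#' columns. Exposure time belongs to the toxicological category; dose is its
#' own category; `cell_name` is excluded from modeling throughout.
#'
#' @return Named list of character vectors of column names.
#' @export
attribute_categories <- function() {
  list(
    dose  = "dose_ug_mL",
    pchem = pchem_attributes(),
    qm    = qm_attributes(),
    tox   = c(tox_nominal_attributes(), "time_h")
  )
}

#' Canonical record-table columns
#'
#' The column dictionary of the flat record table: one row per exposure
#' observation, PChem values accompanied by `*_source` (data-source level)
#' and `*_method` (measurement method) provenance columns. Empty CSV cells
#' map to `NA` (absent).
#'
#' @return Character vector of column names in canonical order.
#' @export
record_columns <- function() {
  pchem <- pchem_attributes()
  c(
    "record_id", "material_id", "composition",
    as.vector(rbind(pchem, paste0(pchem, "_source"), paste0(pchem, "_method"))),
    qm_attributes(),
    "assay", "cell_name", "cell_species", "cell_origin", "cell_type",
    "dose_ug_mL", "time_h", "viability_pct", "label"
  )
}

numeric_record_columns <- function() {
  c(pchem_attributes(), qm_attributes(), "dose_ug_mL", "time_h", "viability_pct")
}

# Default closed vocabulary of 26 metal oxide composition tokens.
default_compositions <- function() {
  c(
    "TiO2", "ZnO", "SiO2", "CuO", "Fe2O3", "Fe3O4", "Al2O3", "CeO2", "NiO",
    "ZrO2", "SnO2", "MgO", "Co3O4", "Cr2O3", "Mn2O3", "Sb2O3", "La2O3",
    "Y2O3", "Yb2O3", "Gd2O3", "HfO2", "In2O3", "V2O3", "WO3", "CoO", "Ni2O3"
  )
}
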