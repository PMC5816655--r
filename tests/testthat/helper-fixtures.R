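# Fixture builders used across the suite. All fixtures are constructed in
# code; make_records() produces a minimal valid record table.

make_records <- function(n = 3,
                         viability = rep(90, n),
                         core = rep(30, n),
                         dose = rep(10, n)) {
  tibble::tibble(
    record_id = sprintf("R%03d", seq_len(n)),
    material_id = rep("M001", n),
    composition = rep("TiO2", n),
    core_size = core,
    core_size_source = ifelse(is.na(core), NA_character_, "experimental"),
    core_size_method = ifelse(is.na(core), NA_character_, "TEM"),
    hydro_size = core * 2,
    hydro_size_source = ifelse(is.na(core), NA_character_, "experimental"),
    hydro_size_method = ifelse(is.na(core), NA_character_, "DLS_NTA"),
    surface_charge = rep(-20, n),
    surface_charge_source = rep("experimental", n),
    surface_charge_method = rep("zeta_potential", n),
    surface_area = 6000 / (ifelse(is.na(core), 30, core) * 4.23),
    surface_area_source = rep("experimental", n),
    surface_area_method = rep("BET", n),
    dHsf_eV = rep(-6.2, n),
    Ec_eV = rep(-4.2, n),
    Ev_eV = rep(-7.4, n),
    chi_eV = rep(5.8, n),
    assay = rep("MTT", n),
    cell_name = rep("CL01", n),
    cell_species = rep("human", n),
    cell_origin = rep("lung", n),
    cell_type = rep("normal", n),
    dose_ug_mL = dose,
    time_h = rep(24, n),
    viability_pct = viability,
    label = assign_endpoint(viability)
  )
}

# set one PChem attribute of row i to absent (value + provenance)
drop_attr <- function(records, i, attr) {
  records[[attr]][i] <- NA_real_
  records[[paste0(attr, "_source")]][i] <- NA_character_
  records[[paste0(attr, "_method")]][i] <- NA_character_
  records
}

# a small labeled table with a clean dose-driven signal for model tests:
# toxic exactly when dose > 50, balanced enough for a forest
make_dose_signal_records <- function(n = 200, seed = 1) {
  withr::with_seed(seed, {
    dose <- sample(c(1, 5, 10, 25, 50, 100, 200), n, replace = TRUE)
    viab <- ifelse(dose > 50, 20, 95)
    rec <- make_records(n, viability = viab, core = runif(n, 10, 90),
                        dose = dose)
    rec$record_id <- sprintf("R%04d", seq_len(n))
    rec$assay <- sample(c("MTT", "WST", "LDH"), n, replace = TRUE)
    rec$cell_species <- sample(c("human", "mouse"), n, replace = TRUE)
    rec$cell_origin <- sample(c("lung", "liver"), n, replace = TRUE)
    rec$cell_type <- sample(c("normal", "cancer"), n, replace = TRUE)
    rec$time_h <- sample(c(6, 24, 48), n, replace = TRUE)
    rec$surface_charge <- rnorm(n, -20, 8)
    rec
  })
}

# small synthetic dataset shared by slower tests
small_synth <- function(seed = 42, n = 600, ...) {
  generate_dataset(synth_config(n_records = n, seed = seed, ...))
}
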