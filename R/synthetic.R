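# Synthetic literature-style nanotoxicity data: materials with true
# physicochemical properties, an article-quality latent that drives both
# missingness and assay noise, provenance-dependent observation noise,
# recoverable catalogs, and a Hill dose-response generating the viability
# endpoint.

#' Configuration for the synthetic dataset generator
#'
#' Defaults emulate the structure of a large literature-curated metal oxide
#' dataset: 6,842 exposure records over 26 oxide compositions, marginal
#' per-attribute missingness of 18/39/41/74 percent (core size,
#' hydrodynamic size, surface charge, specific surface area), a strongly
#' Nontoxic-majority endpoint, and two linked quality gradients. First,
#' observation noise grows from authors' own measurements to manufacturer
#' specifications to values reused from other references. Second, each
#' record carries a continuous latent study-quality multiplier: sloppier
#' studies report fewer PChem attributes (missingness odds increase with
#' the multiplier, with intercepts calibrated so the marginal rates are
#' exactly the configured profile), use less recognized measurement
#' methods, and have proportionally noisier viability readouts. Both
#' gradients are what make data-quality scoring and screening informative.
#'
#' @param n_records Number of exposure records.
#' @param n_materials Number of distinct nanomaterial products.
#' @param compositions Closed vocabulary of oxide tokens.
#' @param missingness Named marginal probabilities of an absent value per
#'   PChem attribute.
#' @param provenance_mix Named probabilities over the recoverability strata
#'   of a material x attribute pair: `manufacturer` (missing values
#'   recoverable from the manufacturer catalog), `reference` (recoverable
#'   from other publications), and `experimental` / `unfillable` (the
#'   attribute is characterized only in the article itself, so a missing
#'   value has no external source; core size and surface area may still be
#'   recovered from each other through the density table).
#' @param noise_cv Named relative observation-noise scales by source level;
#'   non-decreasing from experimental to reference makes screening carry
#'   signal, though any non-negative values are accepted.
#' @param viability_noise_sd Assay-noise SD (viability points) of the
#'   median-quality study; a record's SD is this base times its study-noise
#'   multiplier, capped at `viability_noise_cap`.
#' @param study_noise_sdlog Log-scale SD of the lognormal study-quality
#'   noise multiplier (median 1); 0 gives homogeneous assay noise.
#' @param viability_noise_cap Upper bound on a record's assay-noise SD.
#' @param missing_quality_coef Log-odds slope of per-attribute missingness
#'   in the centered log study-noise multiplier; per-attribute intercepts
#'   are calibrated so the marginal rates equal `missingness` exactly in
#'   expectation. 0 recovers attribute-wise MCAR.
#' @param method_quality_coef Log-odds slope of gold-standard method choice
#'   in the same latent (negative association: sloppier studies use less
#'   recognized methods).
#' @param gold_method_prob Baseline probability that a reported measurement
#'   used the attribute's gold-standard method (for a median-quality study).
#' @param charge_session_sd Per-record SD (mV) of the surface charge around
#'   its material mean: zeta potential depends on the dispersion medium.
#' @param hydro_session_sd Log-scale per-record SD of the agglomeration
#'   multiplier: hydrodynamic size depends on the dispersion protocol.
#' @param dose_grid Administered doses, ug/mL.
#' @param time_grid Exposure times, hours.
#' @param log_ec50_sd SD of the composition-level log-EC50 offsets.
#' @param size_exponent,time_exponent Elasticities of EC50 in core size
#'   (positive: small particles are more toxic) and exposure time
#'   (negative: longer exposures lower EC50).
#' @param hill Hill slope of the dose-response, positive.
#' @param toxic_target_fraction Target fraction of Toxic records; the
#'   generator calibrates the EC50 scale, noise included, so the expected
#'   toxic fraction matches it.
#' @param seed Integer seed; the same configuration generates identical
#'   output.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_records = 6842,
                         n_materials = 26,
                         compositions = default_compositions(),
                         missingness = c(core_size = 0.18, hydro_size = 0.39,
                                         surface_charge = 0.41,
                                         surface_area = 0.74),
                         provenance_mix = c(experimental = 0.15,
                                            manufacturer = 0.45,
                                            reference = 0.25,
                                            unfillable = 0.15),
                         noise_cv = c(experimental = 0.03,
                                      manufacturer = 0.30,
                                      reference = 0.60),
                         viability_noise_sd = 12,
                         study_noise_sdlog = 2.0,
                         viability_noise_cap = 40,
                         missing_quality_coef = 2.5,
                         method_quality_coef = 1.2,
                         gold_method_prob = 0.6,
                         charge_session_sd = 6,
                         hydro_session_sd = 0.35,
                         dose_grid = c(2, 10, 50, 200),
                         time_grid = c(6, 12, 24, 48, 72),
                         log_ec50_sd = 0.2,
                         size_exponent = 1.2,
                         time_exponent = -0.1,
                         hill = 1.2,
                         toxic_target_fraction = 0.2,
                         seed = 42) {
  cfg <- list(
    n_records = n_records, n_materials = n_materials,
    compositions = compositions,
    missingness = missingness[pchem_attributes()],
    provenance_mix = provenance_mix, noise_cv = noise_cv,
    viability_noise_sd = viability_noise_sd,
    study_noise_sdlog = study_noise_sdlog,
    viability_noise_cap = viability_noise_cap,
    missing_quality_coef = missing_quality_coef,
    method_quality_coef = method_quality_coef,
    gold_method_prob = gold_method_prob,
    charge_session_sd = charge_session_sd,
    hydro_session_sd = hydro_session_sd,
    dose_grid = dose_grid, time_grid = time_grid,
    log_ec50_sd = log_ec50_sd, size_exponent = size_exponent,
    time_exponent = time_exponent, hill = hill,
    toxic_target_fraction = toxic_target_fraction, seed = as.integer(seed)
  )
  if (cfg$n_records < 1 || cfg$n_materials < 1) {
    stop("n_records and n_materials must be positive", call. = FALSE)
  }
  if (length(cfg$dose_grid) == 0 || any(cfg$dose_grid < 0)) {
    stop("dose_grid must be non-empty and non-negative", call. = FALSE)
  }
  if (length(cfg$time_grid) == 0 || any(cfg$time_grid <= 0)) {
    stop("time_grid must be non-empty and positive", call. = FALSE)
  }
  if (any(is.na(cfg$missingness)) || any(cfg$missingness < 0) ||
      any(cfg$missingness > 1)) {
    stop("missingness must name all four PChem attributes with rates in [0,1]",
         call. = FALSE)
  }
  strata <- c("experimental", "manufacturer", "reference", "unfillable")
  if (!setequal(names(cfg$provenance_mix), strata) ||
      any(cfg$provenance_mix < 0) ||
      abs(sum(cfg$provenance_mix) - 1) > 1e-8) {
    stop("provenance_mix must be a probability vector over ",
         paste(strata, collapse = "/"), call. = FALSE)
  }
  cfg$provenance_mix <- cfg$provenance_mix[strata]
  if (cfg$viability_noise_sd < 0 || cfg$study_noise_sdlog < 0 ||
      cfg$viability_noise_cap < 0) {
    stop("viability noise parameters must be non-negative", call. = FALSE)
  }
  if (any(cfg$noise_cv < 0)) stop("noise scales must be >= 0", call. = FALSE)
  if (cfg$charge_session_sd < 0 || cfg$hydro_session_sd < 0) {
    stop("session variation SDs must be >= 0", call. = FALSE)
  }
  if (cfg$gold_method_prob <= 0 || cfg$gold_method_prob >= 1) {
    stop("gold_method_prob must be in (0, 1)", call. = FALSE)
  }
  if (cfg$hill <= 0) stop("hill must be positive", call. = FALSE)
  if (cfg$toxic_target_fraction <= 0 || cfg$toxic_target_fraction >= 1) {
    stop("toxic_target_fraction must be in (0, 1)", call. = FALSE)
  }
  structure(cfg, class = "synth_config")
}

#' Hill dose-response for cell viability
#'
#' `V(dose) = 100 / (1 + (dose/EC50)^hill)`: 100 percent viability at zero
#' dose, 50 percent at the EC50, monotone non-increasing in dose.
#'
#' @param dose Dose, ug/mL, non-negative.
#' @param ec50 Half-maximal effective concentration, ug/mL, positive.
#' @param hill Hill slope, positive.
#' @return Viability percent before assay noise.
#' @export
viability_model <- function(dose, ec50, hill) {
  if (any(!is.finite(ec50)) || any(ec50 <= 0)) {
    stop("`ec50` must be positive", call. = FALSE)
  }
  if (any(!is.finite(hill)) || any(hill <= 0)) {
    stop("`hill` must be positive", call. = FALSE)
  }
  if (any(dose < 0)) stop("`dose` must be non-negative", call. = FALSE)
  100 / (1 + (dose / ec50)^hill)
}

# multiplicative noise for positive-valued attributes, additive for charge
noisy_value <- function(truth, cv, attribute) {
  if (cv == 0) return(truth)
  n <- length(truth)
  if (attribute == "surface_charge") {
    truth + stats::rnorm(n, 0, cv * (abs(truth) + 10))
  } else {
    truth * pmax(1 + stats::rnorm(n, 0, cv), 0.1)
  }
}

# per-record missingness probabilities increasing in the centered log
# study-noise multiplier, with the intercept calibrated so the mean equals
# the marginal rate exactly over the realized latent values
quality_missing_prob <- function(rate, clog, coef) {
  if (rate <= 0) return(rep(0, length(clog)))
  if (rate >= 1) return(rep(1, length(clog)))
  if (coef == 0 || stats::sd(clog) == 0) return(rep(rate, length(clog)))
  f <- function(delta) mean(stats::plogis(delta + coef * clog)) - rate
  delta <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
  stats::plogis(delta + coef * clog)
}

#' Generate a synthetic literature-style nanotoxicity dataset
#'
#' Draws materials with true core size, density-consistent specific surface
#' area (`SSA = 6000/(d * rho)` exactly), surface charge and a baseline
#' agglomeration state; samples exposure records over the dose/time grids,
#' cell lines and assays, with per-record session variation of surface
#' charge and hydrodynamic size (both depend on the dispersion protocol,
#' hydrodynamic size never below core size); produces viability from a Hill
#' dose-response whose EC50 depends on composition, core size and exposure
#' time, plus Gaussian assay noise whose SD scales with the record's latent
#' study-quality multiplier; then degrades the truth into literature-style
#' observations: per-attribute missingness (odds increasing in the latent,
#' marginal rates preserved) and provenance-linked observation noise.
#' Manufacturer and reference catalogs are emitted for exactly the
#' recoverable material x attribute strata, so gap filling can be exercised
#' end to end. Output is a pure function of the configuration (including
#' its seed).
#'
#' @param config A [synth_config()].
#' @return A list of class `nano_synth` with elements `records`,
#'   `catalogs` (a [nano_catalogs()] object), `truth` (noiseless values,
#'   EC50s, per-record assay-noise SD and true labels) and `config`.
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  withr::with_seed(config$seed, generate_dataset_impl(config))
}

generate_dataset_impl <- function(cfg) {
  n_comp <- length(cfg$compositions)
  pchem <- pchem_attributes()

  # composition-level physics: density, electronic-structure constants
  density <- tibble::tibble(
    composition = cfg$compositions,
    rho_g_cm3 = round(stats::runif(n_comp, 2.2, 7.2), 2)
  )
  ec_ev <- stats::runif(n_comp, -4.5, -0.5)
  qm <- tibble::tibble(
    composition = cfg$compositions,
    dHsf_eV = round(stats::runif(n_comp, -12, -1), 2),
    Ec_eV = round(ec_ev, 2),
    Ev_eV = round(ec_ev - stats::runif(n_comp, 1.5, 6), 2),
    chi_eV = round(stats::runif(n_comp, 4.5, 6.8), 2)
  )

  # materials: one row per commercial product
  mat <- tibble::tibble(
    material_id = sprintf("M%03d", seq_len(cfg$n_materials)),
    composition = sample(cfg$compositions, cfg$n_materials, replace = TRUE),
    core_true = pmin(pmax(stats::rlnorm(cfg$n_materials, log(30), 0.6), 6), 400),
    charge_true = stats::rnorm(cfg$n_materials, 0, 22),
    agglomeration = 1 + stats::rlnorm(cfg$n_materials, log(0.8), 0.5)
  )
  mat$rho <- density$rho_g_cm3[match(mat$composition, density$composition)]
  mat$ssa_true <- estimate_ssa_from_core(mat$core_true, mat$rho)
  mat$hydro_true <- mat$core_true * mat$agglomeration
  mat$log_ec50_comp <- stats::rnorm(n_comp, 0, cfg$log_ec50_sd)[
    match(mat$composition, cfg$compositions)
  ]

  # recoverability stratum per material x attribute
  strata <- names(cfg$provenance_mix)
  stratum <- matrix(
    sample(strata, cfg$n_materials * 4, replace = TRUE,
           prob = cfg$provenance_mix),
    nrow = cfg$n_materials, dimnames = list(NULL, pchem)
  )

  # cell-line dictionary (cell_name has too many levels to model, on purpose)
  cells <- tibble::tibble(
    cell_name = sprintf("CL%02d", 1:55),
    cell_species = sample(c("human", "mouse", "rat", "hamster"), 55,
                          replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
    cell_origin = sample(c("lung", "liver", "skin", "kidney", "blood",
                           "brain", "intestine"), 55, replace = TRUE),
    cell_type = sample(c("normal", "cancer"), 55, replace = TRUE)
  )

  # exposure records
  n <- cfg$n_records
  mi <- sample(cfg$n_materials, n, replace = TRUE)
  cell_i <- sample(nrow(cells), n, replace = TRUE)
  # latent study quality: a lognormal noise multiplier shared by the
  # record's assay noise, missingness odds and method choice
  study_mult <- stats::rlnorm(n, 0, cfg$study_noise_sdlog)
  noise_sd <- pmin(cfg$viability_noise_sd * study_mult,
                   cfg$viability_noise_cap)
  clog <- if (n > 1) log(study_mult) - mean(log(study_mult)) else rep(0, n)
  rec <- tibble::tibble(
    record_id = sprintf("R%05d", seq_len(n)),
    material_id = mat$material_id[mi],
    composition = mat$composition[mi],
    assay = sample(c("MTT", "WST", "XTT", "LDH", "CCK8", "NRU"), n,
                   replace = TRUE),
    cell_name = cells$cell_name[cell_i],
    cell_species = cells$cell_species[cell_i],
    cell_origin = cells$cell_origin[cell_i],
    cell_type = cells$cell_type[cell_i],
    dose_ug_mL = sample(cfg$dose_grid, n, replace = TRUE),
    time_h = sample(cfg$time_grid, n, replace = TRUE)
  )

  # per-record session state: zeta potential and agglomeration depend on the
  # dispersion medium, so they vary around the material baseline
  charge_rec <- mat$charge_true[mi] +
    stats::rnorm(n, 0, cfg$charge_session_sd)
  aggl_rec <- (mat$agglomeration[mi] - 1) *
    stats::rlnorm(n, 0, cfg$hydro_session_sd) + 1
  hydro_rec <- pmax(mat$core_true[mi] * aggl_rec, mat$core_true[mi])

  # EC50 model with composition, size and time effects; assay noise drawn
  # up front so the global EC50 scale can be calibrated, noise included, to
  # the target toxic fraction: toxic <=> V_true + eps < 50
  # <=> dose/ec50 > t_eps with t_eps = (100/(50 - eps) - 1)^(1/hill)
  log_ec50_raw <- mat$log_ec50_comp[mi] +
    cfg$size_exponent * log(mat$core_true[mi] / 30) +
    cfg$time_exponent * log(rec$time_h / 24)
  eps <- stats::rnorm(n, 0, noise_sd)
  ratio_raw <- rec$dose_ug_mL / exp(log_ec50_raw)
  t_eps <- rep(Inf, n)
  flippable <- eps < 50
  t_eps[flippable] <- pmax(100 / (50 - eps[flippable]) - 1, 0)^(1 / cfg$hill)
  margin <- ifelse(t_eps > 0, ratio_raw / t_eps, Inf)
  scale_c <- stats::quantile(margin, 1 - cfg$toxic_target_fraction,
                             names = FALSE)
  if (!is.finite(scale_c) || scale_c <= 0) {
    stop("EC50 calibration failed; check dose grid and noise settings",
         call. = FALSE)
  }
  ec50 <- exp(log_ec50_raw) * scale_c
  viab_true <- viability_model(rec$dose_ug_mL, ec50, cfg$hill)
  rec$viability_pct <- viab_true + eps
  rec$label <- assign_endpoint(rec$viability_pct)

  # observed PChem values: experimental-grade noise, quality-dependent
  # missingness (marginal rates preserved), provenance columns
  truth_by_attr <- list(
    core_size = mat$core_true[mi], hydro_size = hydro_rec,
    surface_charge = charge_rec, surface_area = mat$ssa_true[mi]
  )
  gold_prob <- stats::plogis(stats::qlogis(cfg$gold_method_prob) -
                               cfg$method_quality_coef * clog)
  nongold <- list(core_size = "SEM_AFM", hydro_size = "other",
                  surface_charge = "other", surface_area = "other")
  for (attr in pchem) {
    obs <- noisy_value(truth_by_attr[[attr]], cfg$noise_cv[["experimental"]],
                       attr)
    p_miss <- quality_missing_prob(cfg$missingness[[attr]], clog,
                                   cfg$missing_quality_coef)
    missing <- stats::runif(n) < p_miss
    method <- ifelse(stats::runif(n) < gold_prob,
                     gold_standard_method(attr), nongold[[attr]])
    obs[missing] <- NA_real_
    method[missing] <- NA_character_
    rec[[attr]] <- obs
    rec[[paste0(attr, "_source")]] <-
      ifelse(missing, NA_character_, "experimental")
    rec[[paste0(attr, "_method")]] <- method
  }
  # physical coherence of the observed sizes: suspension diameter cannot be
  # below the primary particle diameter
  both <- !is.na(rec$core_size) & !is.na(rec$hydro_size)
  rec$hydro_size[both] <- pmax(rec$hydro_size[both], rec$core_size[both])

  # QM attributes are composition-level lookups, complete by construction
  qm_idx <- match(rec$composition, qm$composition)
  for (attr in qm_attributes()) rec[[attr]] <- qm[[attr]][qm_idx]

  # catalogs covering exactly the recoverable strata
  make_catalog <- function(level) {
    entries <- list()
    for (attr in pchem) {
      in_stratum <- which(stratum[, attr] == level)
      if (length(in_stratum) == 0) next
      truth <- switch(attr,
        core_size = mat$core_true, hydro_size = mat$hydro_true,
        surface_charge = mat$charge_true, surface_area = mat$ssa_true
      )[in_stratum]
      stated_prob <- if (level == "manufacturer") 0.5 else 0.3
      entries[[attr]] <- tibble::tibble(
        material_id = mat$material_id[in_stratum],
        attribute = attr,
        value = noisy_value(truth, cfg$noise_cv[[level]], attr),
        method = ifelse(stats::runif(length(in_stratum)) < stated_prob,
                        gold_standard_method(attr), NA_character_)
      )
    }
    out <- dplyr::bind_rows(entries)
    if (nrow(out) == 0) {
      out <- tibble::tibble(material_id = character(),
                            attribute = character(), value = numeric(),
                            method = character())
    }
    dplyr::arrange(out, .data$material_id, .data$attribute)
  }
  catalogs <- nano_catalogs(
    manufacturer = make_catalog("manufacturer"),
    reference = make_catalog("reference"),
    density = density,
    qm = qm
  )

  truth <- tibble::tibble(
    record_id = rec$record_id,
    material_id = rec$material_id,
    study_noise_sd = noise_sd,
    core_size_true = truth_by_attr$core_size,
    hydro_size_true = hydro_rec,
    surface_charge_true = charge_rec,
    surface_area_true = truth_by_attr$surface_area,
    ec50_ug_mL = ec50,
    viability_true = viab_true,
    label_true = assign_endpoint(viab_true)
  )

  records <- rec[record_columns()]
  validate_records(records, context = "synthetic record table")
  structure(
    list(records = records, catalogs = catalogs, truth = truth, config = cfg),
    class = "nano_synth"
  )
}

#' Write a synthetic dataset to a directory of CSV files
#'
#' Emits `records.csv`, the four catalog CSVs understood by
#' [read_catalogs()], and `truth.csv`.
#'
#' @param synth A `nano_synth` object from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(synth, dir) {
  stopifnot(inherits(synth, "nano_synth"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_nano_records(synth$records, file.path(dir, "records.csv"))
  cat_files <- c(manufacturer = "manufacturer_catalog.csv",
                 reference = "reference_catalog.csv")
  for (nm in names(cat_files)) {
    readr::write_csv(synth$catalogs[[nm]], file.path(dir, cat_files[[nm]]),
                     na = "", progress = FALSE)
  }
  readr::write_csv(synth$catalogs$density, file.path(dir, "density.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(synth$catalogs$qm, file.path(dir, "qm_table.csv"),
                   na = "", progress = FALSE)
  readr::write_csv(synth$truth, file.path(dir, "truth.csv"), na = "",
                   progress = FALSE)
  invisible(dir)
}
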