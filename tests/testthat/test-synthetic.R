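test_that("viability follows the Hill dose-response", {
  expect_equal(viability_model(0, 50, 1.5), 100)
  expect_equal(viability_model(50, 50, 1.5), 50)
  expect_lt(viability_model(50 * 1e4, 50, 1.5), 0.1)
  d <- seq(0, 400, by = 10)
  expect_true(all(diff(viability_model(d, 30, 2)) <= 0))
  expect_error(viability_model(10, -1, 2), "positive")
  expect_error(viability_model(10, 50, 0), "positive")
  expect_error(viability_model(-1, 50, 2), "non-negative")
})

test_that("generation is a pure function of the configuration", {
  cfg <- synth_config(n_records = 250, seed = 42)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$catalogs$manufacturer, b$catalogs$manufacturer)
  c <- generate_dataset(synth_config(n_records = 250, seed = 43))
  expect_false(identical(a$records$viability_pct, c$records$viability_pct))
})

test_that("observed missingness matches the configured marginal profile", {
  s <- small_synth(seed = 3, n = 4000)
  miss <- summarize_missingness(s$records)
  rates <- s$config$missingness
  for (attr in names(rates)) {
    p <- rates[[attr]]
    got <- miss$missing_fraction[miss$attribute == attr]
    expect_lt(abs(got - p), 3 * sqrt(p * (1 - p) / 4000))
  }
})

test_that("zero noise and zero missingness reproduce the truth exactly", {
  s <- generate_dataset(synth_config(
    n_records = 300, seed = 5,
    missingness = c(core_size = 0, hydro_size = 0, surface_charge = 0,
                    surface_area = 0),
    noise_cv = c(experimental = 0, manufacturer = 0, reference = 0),
    viability_noise_sd = 0, study_noise_sdlog = 0,
    charge_session_sd = 0, hydro_session_sd = 0
  ))
  rec <- s$records
  tr <- s$truth
  expect_equal(rec$core_size, tr$core_size_true)
  expect_equal(rec$hydro_size, tr$hydro_size_true)
  expect_equal(rec$surface_charge, tr$surface_charge_true)
  expect_equal(rec$surface_area, tr$surface_area_true)
  rho <- s$catalogs$density$rho_g_cm3[
    match(rec$composition, s$catalogs$density$composition)
  ]
  expect_equal(rec$surface_area, 6000 / (rec$core_size * rho))
  expect_equal(rec$viability_pct, tr$viability_true)
  expect_equal(rec$label, tr$label_true)
})

test_that("gap filling recovers the true surface area under zero noise", {
  # surface area always missing, nothing else; no external catalogs, so the
  # only route is estimation from core size through the density table
  s <- generate_dataset(synth_config(
    n_records = 200, seed = 8,
    missingness = c(core_size = 0, hydro_size = 0, surface_charge = 0,
                    surface_area = 1),
    provenance_mix = c(experimental = 0, manufacturer = 0, reference = 0,
                       unfillable = 1),
    noise_cv = c(experimental = 0, manufacturer = 0, reference = 0),
    viability_noise_sd = 0, study_noise_sdlog = 0,
    charge_session_sd = 0, hydro_session_sd = 0
  ))
  expect_true(all(is.na(s$records$surface_area)))
  ii <- build_dataset_ii(s$records, s$catalogs)
  expect_equal(nrow(ii), 200)
  tr <- s$truth[match(ii$record_id, s$truth$record_id), ]
  expect_equal(ii$surface_area, tr$surface_area_true)
  expect_true(all(ii$surface_area_method == "estimated_from_core"))
})

test_that("the realized class imbalance tracks the configured target", {
  s <- small_synth(seed = 13, n = 4000)
  p <- s$config$toxic_target_fraction
  toxic <- mean(s$records$label == "Toxic")
  expect_lt(abs(toxic - p), 3 * sqrt(p * (1 - p) / 4000))
  # Nontoxic is the dominant class
  expect_gt(mean(s$records$label == "Nontoxic"), 0.5)
})

test_that("observation error grows from experimental to reference sources", {
  s <- small_synth(seed = 21, n = 4000)
  tr <- s$truth
  # experimental stratum: observed core sizes in the records
  present <- !is.na(s$records$core_size)
  err_exp <- mean(abs(s$records$core_size[present] -
                        tr$core_size_true[present]) /
                    tr$core_size_true[present])
  # catalog strata: entries against the material-level truth
  mat_truth <- tr$core_size_true[!duplicated(tr$material_id)]
  names(mat_truth) <- tr$material_id[!duplicated(tr$material_id)]
  cat_err <- function(cat) {
    sub <- cat[cat$attribute == "core_size", ]
    sub <- sub[sub$material_id %in% names(mat_truth), ]
    mean(abs(sub$value - mat_truth[sub$material_id]) /
           mat_truth[sub$material_id])
  }
  err_mfr <- cat_err(s$catalogs$manufacturer)
  err_ref <- cat_err(s$catalogs$reference)
  expect_lte(err_exp, err_mfr)
  expect_lte(err_mfr, err_ref)
})

test_that("hydrodynamic size is never below core size", {
  s <- small_synth(seed = 17, n = 2000)
  both <- !is.na(s$records$core_size) & !is.na(s$records$hydro_size)
  expect_true(all(s$records$hydro_size[both] >= s$records$core_size[both]))
  expect_true(all(s$truth$hydro_size_true >= s$truth$core_size_true))
})

test_that("datasets round trip through a directory of CSV files", {
  s <- small_synth(seed = 2, n = 120)
  dir <- withr::local_tempdir()
  write_dataset(s, dir)
  back <- read_nano_records(file.path(dir, "records.csv"))
  expect_equal(as.data.frame(back), as.data.frame(s$records))
  cats <- read_catalogs(dir)
  expect_equal(as.data.frame(cats$manufacturer),
               as.data.frame(s$catalogs$manufacturer))
  expect_equal(as.data.frame(cats$qm), as.data.frame(s$catalogs$qm))
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(dose_grid = numeric(0)), "dose_grid")
  expect_error(synth_config(hill = 0), "hill")
  expect_error(synth_config(missingness = c(core_size = 1.2, hydro_size = 0,
                                            surface_charge = 0,
                                            surface_area = 0)), "missingness")
  expect_error(synth_config(toxic_target_fraction = 0), "toxic_target")
  expect_error(
    synth_config(provenance_mix = c(experimental = 1, manufacturer = 1,
                                    reference = 0, unfillable = 0)),
    "provenance_mix"
  )
})
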