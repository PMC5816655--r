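test_that("surface-area/diameter estimation matches the SI-unit oracle", {
  # independent oracle: convert to SI (m, kg/m^3), apply SSA = 6/(d*rho)
  # in m^2/kg, convert to m^2/g
  ssa_si <- function(d_nm, rho_gcm3) {
    (6 / ((d_nm * 1e-9) * (rho_gcm3 * 1000))) / 1000
  }
  expect_equal(estimate_ssa_from_core(60, 1.0), 100)
  expect_equal(estimate_ssa_from_core(60, 1.0), ssa_si(60, 1.0))
  expect_equal(estimate_ssa_from_core(21, 4.23), ssa_si(21, 4.23))
  expect_equal(estimate_ssa_from_core(21, 4.23), 67.5, tolerance = 1e-3)

  expect_equal(estimate_core_from_ssa(100, 1.0), 60)
  expect_equal(estimate_core_from_ssa(6000, 1.0), 1)

  expect_error(estimate_ssa_from_core(0, 1), "positive")
  expect_error(estimate_ssa_from_core(10, -1), "positive")
  expect_error(estimate_core_from_ssa(-5, 1), "positive")
})

test_that("estimation round trip is the identity for positive inputs", {
  withr::with_seed(4, {
    d <- runif(200, 0.5, 500)
    rho <- runif(200, 0.5, 12)
  })
  expect_equal(estimate_core_from_ssa(estimate_ssa_from_core(d, rho), rho), d)
  ssa <- runif(200, 1, 800)
  expect_equal(estimate_ssa_from_core(estimate_core_from_ssa(ssa, 5.6), 5.6),
               ssa)
})

make_test_catalogs <- function() {
  nano_catalogs(
    manufacturer = tibble::tibble(
      material_id = c("M001", "M001"),
      attribute = c("core_size", "hydro_size"),
      value = c(25, 140),
      method = c("TEM", NA)
    ),
    reference = tibble::tibble(
      material_id = c("M001", "M001"),
      attribute = c("core_size", "surface_charge"),
      value = c(28, -31),
      method = c(NA, "zeta_potential")
    ),
    density = tibble::tibble(composition = "TiO2", rho_g_cm3 = 4.23),
    qm = tibble::tibble(composition = "TiO2", dHsf_eV = -6.2, Ec_eV = -4.2,
                        Ev_eV = -7.4, chi_eV = 5.8)
  )
}

test_that("filling follows manufacturer > reference > estimation priority", {
  cats <- make_test_catalogs()

  rec <- drop_attr(make_records(1), 1, "core_size")
  filled <- fill_records(rec, cats)
  expect_equal(filled$core_size, 25)  # manufacturer wins over reference
  expect_equal(filled$core_size_source, "manufacturer")
  expect_equal(filled$core_size_method, "TEM")

  rec <- drop_attr(make_records(1), 1, "surface_charge")
  filled <- fill_records(rec, cats)
  expect_equal(filled$surface_charge, -31)
  expect_equal(filled$surface_charge_source, "reference")

  # catalog entry without a stated method scores as "other"
  rec <- drop_attr(make_records(1), 1, "hydro_size")
  filled <- fill_records(rec, cats)
  expect_equal(filled$hydro_size_method, "other")
})

test_that("estimation fills carry the basis provenance and an estimate label", {
  cats <- make_test_catalogs()
  rec <- drop_attr(make_records(1, core = 60), 1, "surface_area")
  filled <- fill_records(rec, cats)
  expect_equal(filled$surface_area, 6000 / (60 * 4.23))
  expect_equal(filled$surface_area_method, "estimated_from_core")
  expect_equal(filled$surface_area_source, filled$core_size_source)

  rec2 <- drop_attr(make_records(1), 1, "core_size")
  rec2$material_id <- "M999"  # no catalog entry: estimation from SSA
  filled2 <- fill_records(rec2, cats)
  expect_equal(filled2$core_size,
               estimate_core_from_ssa(rec2$surface_area, 4.23))
  expect_equal(filled2$core_size_method, "estimated_from_ssa")
})

test_that("unfillable attributes stay absent and are reported", {
  cats <- make_test_catalogs()
  rec <- drop_attr(make_records(1), 1, "hydro_size")
  rec$material_id <- "M999"
  filled <- fill_records(rec, cats)
  expect_true(is.na(filled$hydro_size))
  rep <- fill_report(filled)
  expect_true(any(rep$attribute == "hydro_size" & rep$action == "unfillable"))
})

test_that("filling is idempotent", {
  cats <- make_test_catalogs()
  rec <- drop_attr(drop_attr(make_records(3), 1, "core_size"),
                   2, "surface_area")
  once <- fill_records(rec, cats)
  twice <- fill_records(once, cats)
  strip <- function(x) {
    x <- as.data.frame(x)
    attr(x, "fill_report") <- NULL
    x
  }
  expect_equal(strip(twice), strip(once))
  # and the second pass has nothing left to change
  rep2 <- fill_report(twice)
  expect_equal(nrow(rep2[rep2$action != "unfillable", ]), 0)
})

test_that("the gap-filled tier is complete and excludes unfillable rows", {
  cats <- make_test_catalogs()
  rec <- make_records(5)
  rec <- drop_attr(rec, 1, "core_size")     # manufacturer-recoverable
  rec <- drop_attr(rec, 2, "surface_area")  # estimable from core
  rec <- drop_attr(rec, 3, "hydro_size")    # recoverable for M001
  rec <- drop_attr(rec, 4, "hydro_size")
  rec$material_id[4] <- "M999"              # unfillable
  rec$composition[4] <- "ZnO"

  ii <- build_dataset_ii(rec, cats)
  expect_equal(nrow(ii), 4)
  expect_equal(attr(ii, "excluded"), "R004")
  expect_false(anyNA(ii[c(pchem_attributes(), qm_attributes())]))
  expect_true("pchem_score" %in% names(ii))

  complete <- make_records(3)
  same <- build_dataset_ii(complete, cats)
  expect_equal(same$record_id, complete$record_id)
  expect_equal(same$core_size, complete$core_size)
  expect_error(build_dataset_ii(rec[4, ], cats), "no fully characterized")
})

test_that("mean substitution uses stats-source means and keeps scores", {
  rec <- make_records(3, core = c(1, 2, NA))
  rec <- drop_attr(rec, 3, "core_size")
  rec$core_size[1:2] <- c(1, 2)
  out <- mean_substitute(rec)
  expect_equal(out$core_size, c(1, 2, 1.5))

  # provenance untouched: the imputed cell still scores zero, so the
  # final scores before and after substitution are identical
  expect_equal(score_records(out)$pchem_score, score_records(rec)$pchem_score)
  expect_true(is.na(out$core_size_source[3]))

  full <- make_records(2)
  expect_equal(mean_substitute(full), full)

  empty <- drop_attr(drop_attr(make_records(2), 1, "surface_area"),
                     2, "surface_area")
  expect_error(mean_substitute(empty), "no present values")

  # statistics can come from a separate (training) table
  stats_src <- make_records(2, core = c(10, 30))
  out2 <- mean_substitute(rec, stats_src)
  expect_equal(out2$core_size[3], 20)
})
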