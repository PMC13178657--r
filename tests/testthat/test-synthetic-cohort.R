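test_that("configured stratum counts are honored exactly, also off-default", {
  cfg <- miniConfig()
  co <- generateCohort(cfg, tissues = FALSE, expression = FALSE, seed = 30)
  cl <- clinicalTable(co); tr <- truthTable(co)
  expect_identical(nrow(cl), 14L)
  expect_identical(sum(cl$ici_treated), 10L)
  expect_identical(sum(cl$driver_status == "EGFR"), 2L)
  expect_identical(sum(cl$driver_status == "ALK"), 2L)
  expect_identical(as.integer(table(factor(tr$outcome_class,
    levels = c("DCB", "non-DCB", "early-censored")))), c(4L, 5L, 1L))
  expect_identical(sum(tr$favorable), 2L)

  cfg2 <- miniConfig()
  cfg2@counts[c("n_total", "n_ici", "n_wt", "n_dcb", "n_nondcb",
                "n_earlycensor")] <- c(9L, 6L, 5L, 2L, 4L, 0L)
  co2 <- generateCohort(cfg2, tissues = FALSE, expression = FALSE, seed = 31)
  tr2 <- truthTable(co2)
  expect_identical(sum(tr2$outcome_class %in% "DCB"), 2L)
  expect_identical(sum(tr2$outcome_class %in% "non-DCB"), 4L)
})

test_that("class bounds and censoring follow the outcome-model contract", {
  cfg <- miniConfig()
  co <- generateCohort(cfg, tissues = FALSE, expression = FALSE, seed = 33)
  cl <- clinicalTable(co)
  ici <- cl$ici_treated == 1
  dcb <- classifyDCB(cl$pfs_days[ici], cl$pfs_event[ici])
  ## the 1-year classifier reproduces the configured counts exactly
  expect_identical(as.integer(table(dcb)), c(4L, 5L, 1L))
  ## non-DCB progress before 1 year; early-censored are censored before 1 year
  expect_true(all(cl$pfs_event[ici][dcb == "non-DCB"] == 1))
  expect_true(all(cl$pfs_days[ici][dcb == "early-censored"] < 365))
  expect_true(all(cl$pfs_days <= cfg@survival[["censor_days"]]))
  expect_true(all(cl$os_days <= cfg@survival[["censor_days"]]))
  expect_true(all(cl$pfs_event[cl$pfs_days >= cfg@survival[["censor_days"]]] == 0))
})

test_that("identical seeds reproduce cohorts byte-identically", {
  cfg <- miniConfig()
  a <- generateCohort(cfg, tissues = "ici", expression = TRUE, seed = 34)
  b <- generateCohort(cfg, tissues = "ici", expression = TRUE, seed = 34)
  expect_identical(clinicalTable(a), clinicalTable(b))
  expect_identical(truthTable(a), truthTable(b))
  expect_identical(cohortTissues(a), cohortTissues(b))
  expect_identical(a@expression, b@expression)
  d <- generateCohort(cfg, tissues = FALSE, expression = FALSE, seed = 35)
  expect_false(identical(clinicalTable(a)$pfs_days, clinicalTable(d)$pfs_days))
})

test_that("empty and inconsistent configurations behave as contracted", {
  cfg <- miniConfig()
  cfg@counts[c("n_total", "n_ici", "n_egfr", "n_alk", "n_wt", "n_dcb",
               "n_nondcb", "n_earlycensor", "n_ici_egfr", "n_ici_alk",
               "n_favorable", "n_favorable_dcb")] <- 0L
  co <- generateCohort(cfg, seed = 36)
  expect_identical(nrow(clinicalTable(co)), 0L)
  expect_length(cohortTissues(co), 0)

  bad <- miniConfig()
  expect_error({bad@counts[["n_dcb"]] <- 7L; validObject(bad)}, "must equal n_ici")
  bad2 <- miniConfig()
  expect_error({bad2@counts[["n_egfr"]] <- 5L; validObject(bad2)}, "n_total")
})

test_that("tissue generation follows the configured spatial point processes", {
  cfg <- defaultCohortConfig()
  pan <- defaultPanel()
  ## one circular nest of exactly 1 mm^2 (r = 564.19 um)
  geom <- list(width = 2000, height = 2000,
               centers = cbind(1000, 1000), radii = 1000 / sqrt(pi),
               nestAreaMM2 = 1, stromaAreaMM2 = 4 - 1)
  ov <- zeroImmuneOverrides()
  ov$cd8_tn <- 300; ov$trm_frac <- 0
  g <- generatePatientTissue(sampleProfile(seed = 37, overrides = ov),
                             geom, pan, cfg, seed = 41, withTruth = TRUE)
  nCd8 <- sum(g$labels == "cd8_t")
  expect_lt(abs(nCd8 - 300), 3 * sqrt(300))   # Poisson(300) draw
  ## CD8 cells were placed inside the nest only
  xy <- cellCoords(g$cells)[g$labels == "cd8_t", , drop = FALSE]
  expect_true(all((xy[, 1] - 1000)^2 + (xy[, 2] - 1000)^2 <= geom$radii^2 + 1e-6))

  ## zero immune densities with an all-CAF stroma: only cancer cells and CAFs
  ov2 <- zeroImmuneOverrides(); ov2$caf_frac <- 1
  g2 <- generatePatientTissue(sampleProfile(seed = 38, overrides = ov2),
                              geom, pan, cfg, seed = 42, withTruth = TRUE)
  expect_identical(sort(unique(g2$labels)), c("caf", "cancer"))
  ## cancer inside nests, CAFs outside
  xyC <- cellCoords(g2$cells)
  inNest <- (xyC[, 1] - 1000)^2 + (xyC[, 2] - 1000)^2 <= geom$radii^2
  expect_true(all(inNest[g2$labels == "cancer"]))
  expect_identical(sum(inNest[g2$labels == "caf"]), 0L)
})

test_that("the packaged default reproduces the printed cohort structure", {
  cfg <- defaultCohortConfig()
  expect_identical(unname(cfg@counts[c("n_total", "n_ici", "n_egfr", "n_alk",
                                       "n_dcb", "n_nondcb", "n_earlycensor")]),
                   c(103L, 81L, 19L, 13L, 30L, 49L, 2L))
  expect_identical(cfg@survival[["hr_pfs_dcb"]], 0.15)
  expect_identical(cfg@survival[["hr_os_dcb"]], 0.11)
  expect_identical(cfg@survival[["hr_tncd8"]], 1.79)
  ## config round-trips through YAML
  path <- withr::local_tempfile(fileext = ".yaml")
  writeCohortConfig(cfg, path)
  cfg2 <- readCohortConfig(path)
  expect_identical(cfg2@counts, cfg@counts)
  expect_equal(cfg2@survival, cfg@survival)
  expect_equal(cfg2@cells$densities, cfg@cells$densities)
})
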