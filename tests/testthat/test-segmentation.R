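test_that("degenerate inputs yield degenerate grids", {
  p <- tinyPanel()
  empty <- cellTable(character(0), numeric(0), numeric(0),
                     matrix(numeric(0), 0, 4,
                            dimnames = list(NULL, markerNames(p))))
  g <- segmentTissue(empty, character(0),
                     segmentationParams(fieldWidth = 400, fieldHeight = 400))
  expect_equal(compartmentAreas(g)[["TN"]], 0)
  expect_equal(compartmentAreas(g)[["ISA"]], 0)
  expect_equal(compartmentAreas(g)[["background"]], 0.16)

  ## leukocytes without cancer cells: no TN, stroma called around the cells
  ints <- matrix(2, 5, 4, dimnames = list(NULL, markerNames(p)))
  ct <- cellTable(letters[1:5], c(200, 210, 220, 200, 210),
                  c(200, 200, 210, 210, 220), ints)
  g2 <- segmentTissue(ct, rep("beta", 5),
                      segmentationParams(fieldWidth = 400, fieldHeight = 400))
  expect_equal(compartmentAreas(g2)[["TN"]], 0)
  expect_gt(compartmentAreas(g2)[["ISA"]], 0)
  lab <- gridLabels(g2)
  expect_identical(lab[11, 11], 2L)   # grid cell holding the cells
  expect_identical(lab[1, 1], 3L)     # far corner stays background
})

test_that("nest area is recovered within 10% of the generating geometry", {
  cfg <- defaultCohortConfig()
  pan <- defaultPanel()
  set.seed(31)
  geom <- tissueGeometry(cfg@geometry)   # two-nest default geometry
  prof <- sampleProfile(seed = 31, overrides = zeroImmuneOverrides())
  ct <- generatePatientTissue(prof, geom, pan, cfg, seed = 99)
  lab <- assignSubsets(binarizeMarkers(ct, pan), pan)
  g <- segmentTissue(ct, lab, segmentationParams(fieldWidth = geom$width,
                                                 fieldHeight = geom$height))
  expect_lt(abs(compartmentAreas(g)[["TN"]] / geom$nestAreaMM2 - 1), 0.10)
})

test_that("cancer cells land in TN and CAFs in ISA (>=95% each)", {
  cfg <- defaultCohortConfig()
  pan <- defaultPanel()
  set.seed(32)
  geom <- tissueGeometry(cfg@geometry)
  ct <- generatePatientTissue(sampleProfile(seed = 32), geom, pan, cfg, seed = 55)
  lab <- assignSubsets(binarizeMarkers(ct, pan), pan)
  g <- segmentTissue(ct, lab, segmentationParams(fieldWidth = geom$width,
                                                 fieldHeight = geom$height))
  comp <- assignCompartment(ct, g)
  expect_gte(mean(comp[lab == "cancer"] == "TN"), 0.95)
  expect_gte(mean(comp[lab == "caf"] == "ISA"), 0.95)
  ## no CAF was generated inside a nest
  xy <- cellCoords(ct)[lab == "caf", , drop = FALSE]
  inside <- rep(FALSE, nrow(xy))
  for (i in seq_along(geom$radii))
    inside <- inside | ((xy[, 1] - geom$centers[i, 1])^2 +
                        (xy[, 2] - geom$centers[i, 2])^2 <= geom$radii[i]^2)
  expect_identical(sum(inside), 0L)
})

test_that("compartment areas partition the grid area", {
  cfg <- miniConfig()
  co <- generateCohort(cfg, tissues = "ici", expression = FALSE, seed = 6)
  ct <- cohortTissues(co)[[1]]
  lab <- assignSubsets(binarizeMarkers(ct, co@panel), co@panel)
  g <- segmentTissue(ct, lab, segmentationParams(fieldWidth = 1200,
                                                 fieldHeight = 1200))
  a <- compartmentAreas(g)
  expect_equal(sum(a), prod(dim(gridLabels(g))) * g@pitch^2 / 1e6,
               tolerance = 1e-10)
})

test_that("segmentation is equivariant to a one-pitch translation", {
  p <- tinyPanel()
  set.seed(40)
  n <- 120
  x <- runif(n, 100, 300); y <- runif(n, 100, 300)
  ints <- matrix(2, n, 4, dimnames = list(NULL, markerNames(p)))
  ct <- cellTable(sprintf("c%d", 1:n), x, y, ints)
  ct2 <- cellTable(sprintf("c%d", 1:n), x + 20, y + 20, ints)
  lab <- rep("cancer", n)
  prm <- segmentationParams(fieldWidth = 480, fieldHeight = 480)
  g1 <- gridLabels(segmentTissue(ct, lab, prm))
  prm2 <- segmentationParams(fieldWidth = 500, fieldHeight = 500)
  g2 <- gridLabels(segmentTissue(ct2, lab, prm2))
  ## interior of the shifted grid equals the original, shifted by one cell
  expect_identical(g1[3:22, 3:22], g2[4:23, 4:23])
})

test_that("cells map to grid cells by half-open intervals, background to ISA", {
  p <- tinyPanel()
  ints <- matrix(2, 2, 4, dimnames = list(NULL, markerNames(p)))
  ct <- cellTable(c("a", "b"), c(20, 19.999), c(0, 0), ints)
  g <- new("SegmentationGrid",
           labels = matrix(c(1L, 2L, 3L, 3L), 2, 2), pitch = 20,
           areas = c(TN = 0.0004, ISA = 0.0004, background = 0.0008))
  comp <- assignCompartment(ct, g)
  expect_identical(as.character(comp), c("ISA", "TN"))  # x=20 falls in bin 2
  ## a cell on a background grid cell is tissue, assigned ISA
  ct3 <- cellTable("z", 30, 30, ints[1, , drop = FALSE])
  expect_identical(as.character(assignCompartment(ct3, g)), "ISA")
})
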