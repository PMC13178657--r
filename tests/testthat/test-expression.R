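test_that("differential expression matches per-gene Welch t-tests", {
  set.seed(14)
  m <- matrix(rnorm(27 * 20), 27, 20,
              dimnames = list(sprintf("s%02d", 1:27), sprintf("G%02d", 1:20)))
  grp <- factor(rep(c("mut", "wt"), c(9, 18)), levels = c("mut", "wt"))
  de <- differentialExpression(m, grp)
  for (j in c(1, 7, 20)) {
    ht <- t.test(m[grp == "mut", j], m[grp == "wt", j])
    expect_equal(de$p[j], ht$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[j], unname(diff(rev(ht$estimate))), tolerance = 1e-12)
  }
  expect_equal(de$q, bhAdjust(de$p))

  ## identical group means give zero fold change
  m0 <- rbind(m[1:9, ], m[1:9, ], m[1:9, ])
  grp0 <- factor(rep(c("a", "b"), c(9, 18)))
  expect_equal(differentialExpression(m0, grp0)$log2fc, rep(0, 20))
  expect_error(differentialExpression(m[1:3, ], factor(c("a", "a", "b"))),
               "at least 2")
})

test_that("a planted 2-log2 shift is recovered in the mean over replicates", {
  genes <- defaultGenePanel()
  grp <- factor(rep(c("EGFR-mut", "EGFR-wt"), c(9, 18)),
                levels = c("EGFR-mut", "EGFR-wt"))
  set.seed(15)
  fc <- replicate(100, {
    m <- generateExpression(grp, genes, effects = c(NT5E = 2), noiseSd = 1)
    differentialExpression(m, grp)$log2fc[match("NT5E", genes)]
  })
  expect_lt(abs(mean(fc) - 2), 0.2)

  ## no planted effects: all true fold changes zero, p-values uniform
  set.seed(16)
  m0 <- generateExpression(grp, genes, noiseSd = 1)
  de0 <- differentialExpression(m0, grp)
  ks <- suppressWarnings(ks.test(de0$p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(de0$log2fc)), 0.05)
})

test_that("label permutation keeps BH discoveries near the nominal level", {
  genes <- defaultGenePanel(200)
  grp <- factor(rep(c("A", "B"), c(9, 18)))
  set.seed(17)
  m <- generateExpression(grp, genes, effects = c(NT5E = 3), noiseSd = 1)
  hits <- replicate(20, {
    dePerm <- differentialExpression(m, sample(grp))
    sum(dePerm$q <= 0.05)
  })
  expect_lte(mean(hits > 0), 0.3)
})

test_that("signature scores are mean z-scores with affine invariance", {
  set.seed(18)
  m <- matrix(rnorm(8 * 6), 8, 6,
              dimnames = list(paste0("s", 1:8), c("X1", "X2", "X3", "Y1", "Y2", "Y3")))
  s1 <- signatureScore(m, "X1")
  expect_equal(unname(s1), unname(scale(m[, "X1"])[, 1]))
  sc <- signatureScore(m, c("X1", "X2", "X3"))
  expect_equal(mean(sc), 0, tolerance = 1e-12)       # cohort mean zero
  ## gene-wise affine rescaling leaves the score unchanged
  m2 <- sweep(sweep(m, 2, c(2, 3, 0.5, 1, 1, 9), "*"), 2, runif(6), "+")
  expect_equal(signatureScore(m2, c("X1", "X2", "X3")), sc, tolerance = 1e-10)
  expect_warning(signatureScore(m, c("X1", "NOPE")), "NOPE")
  expect_error(signatureScore(m, "NOPE"), "no gene-set member")
})

test_that("the composite CD8B-hi / MRC1-lo / FAP-lo profile follows median rules", {
  m <- cbind(CD8B = c(5, 1, 5, 1), MRC1 = c(1, 1, 5, 5),
             FAP = c(1, 5, 1, 5), OTHER = rnorm(4))
  rownames(m) <- paste0("s", 1:4)
  lab <- compositeProfile(m)
  expect_identical(as.character(lab), c("fTME-like", "other", "other", "other"))

  ## all-identical samples: median ties go low, CD8B-high is strict
  mEq <- matrix(3, 4, 3, dimnames = list(paste0("s", 1:4), c("CD8B", "MRC1", "FAP")))
  expect_true(all(compositeProfile(mEq) == "other"))

  ## invariance under monotone transforms
  set.seed(19)
  m3 <- matrix(rlnorm(30), 10, 3,
               dimnames = list(paste0("s", 1:10), c("CD8B", "MRC1", "FAP")))
  expect_identical(compositeProfile(m3), compositeProfile(log(m3)))
  expect_error(compositeProfile(m3[, 1:2, drop = FALSE]), "FAP")
})

test_that("the default expression panel and cohort matrix have 726 genes", {
  expect_identical(length(defaultGenePanel()), 726L)
  expect_false(anyDuplicated(defaultGenePanel()) > 0)
  cfg <- miniConfig()
  cfg@counts[c("n_egfr", "n_alk", "n_wt", "n_ici_egfr", "n_ici_alk")] <-
    c(4L, 2L, 8L, 2L, 1L)
  cfg@expression$n_egfr <- 3; cfg@expression$n_wt <- 5
  co <- generateCohort(cfg, tissues = FALSE, expression = TRUE, seed = 20)
  expect_identical(dim(co@expression), c(8L, 726L))
  expect_identical(as.integer(table(co@expressionGroup)), c(3L, 5L))
})
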