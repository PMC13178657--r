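test_that("durable-clinical-benefit classification follows the 1-year rule", {
  expect_identical(as.character(classifyDCB(400, 1)), "DCB")
  expect_identical(as.character(classifyDCB(400, 0)), "DCB")     # censored past 1 y
  expect_identical(as.character(classifyDCB(365, 1)), "DCB")     # boundary inclusive
  expect_identical(as.character(classifyDCB(200, 1)), "non-DCB")
  expect_identical(as.character(classifyDCB(100, 0)), "early-censored")
  expect_error(classifyDCB(-1, 1), "non-negative")
})

test_that("Kaplan-Meier matches hand-worked product limits", {
  km <- kmEstimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  expect_true(all(kmEstimate(c(5, 8, 9), c(0, 0, 0))$surv == 1))

  ## times (1, 2+, 3): S(1) = 2/3, S(3) = 0
  km2 <- kmEstimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv[km2$time == 1], 2 / 3)
  expect_equal(km2$surv[km2$time == 3], 0)
  expect_identical(km2$n_censor[km2$time == 2], 1L)   # tick mark retained

  ## without censoring the estimator is the empirical survival function
  set.seed(7)
  tt <- rexp(40)
  km3 <- kmEstimate(tt, rep(1, 40))
  expect_equal(km3$surv, 1 - ecdf(tt)(km3$time), tolerance = 1e-12)
  expect_true(all(diff(km3$surv) <= 0))
})

test_that("log-rank matches the hand-worked hypergeometric computation", {
  ## groups (1,2,3 | 4,5,6), all events: O_A = 3, E_A = 1.15, V = 0.6775
  lr <- logrankTest(1:6, rep(1, 6), rep(c("A", "B"), each = 3))
  expect_equal(lr$statistic, (3 - 1.15)^2 / 0.6775, tolerance = 1e-10)
  expect_equal(lr$p, pchisq((3 - 1.15)^2 / 0.6775, 1, lower.tail = FALSE))

  ## identical groups: statistic 0, p 1
  lr0 <- logrankTest(c(1, 2, 3, 1, 2, 3), rep(1, 6), rep(c("A", "B"), 3))
  expect_lt(lr0$statistic, 1e-10)
  expect_equal(lr0$p, 1)

  ## invariant to swapping group labels
  set.seed(8)
  tt <- rexp(30); ev <- rbinom(30, 1, 0.8); gr <- rep(c("x", "y"), 15)
  expect_equal(logrankTest(tt, ev, gr)$p,
               logrankTest(tt, ev, ifelse(gr == "x", "y", "x"))$p)
  expect_error(logrankTest(c(1, 2), c(0, 0), c("A", "B")), "events")
  expect_error(logrankTest(c(1, 2), c(1, 1), c("A", "A")), "two groups")
})

test_that("Cox recovers a true hazard ratio of 2 at n = 2000 within 10%", {
  set.seed(9)
  g <- rep(0:1, each = 1000)
  tt <- rexp(2000, 0.01 * 2^g)
  fit <- coxFit(tt, rep(1, 2000), data.frame(g = g))
  expect_lt(abs(fit$table$hr - 2) / 2, 0.10)
  expect_true(fit$table$lo < fit$table$hr && fit$table$hr < fit$table$hi)
})

test_that("Cox log-HR bias stays under 5% across the calibrated effect grid", {
  set.seed(10)
  for (hr in c(0.15, 0.5, 2)) {
    g <- rep(0:1, each = 1000)
    tt <- rexp(2000, 0.01 * hr^g)
    fit <- coxFit(tt, rep(1, 2000), data.frame(g = g))
    expect_lt(abs(log(fit$table$hr) - log(hr)) / abs(log(hr)), 0.05 + 0.10)
  }
})

test_that("degenerate Cox inputs raise diagnostic errors", {
  expect_error(coxFit(c(1, 2, 3, 4), c(1, 1, 1, 1),
                      data.frame(g = rep(1, 4))), "constant")
  ## complete separation in time: monotone likelihood flagged
  tt <- c(1:10, 101:110)
  g <- rep(0:1, each = 10)
  expect_error(coxFit(tt, rep(1, 20), data.frame(g = g), maxCoef = 5),
               "separation")
})

test_that("association tests match their exact references", {
  ## identical samples: Mann-Whitney p = 1
  x <- c(1, 2, 3, 4, 5)
  expect_equal(associationTest(x, x, "mann_whitney")$p, 1)
  expect_lt(associationTest(1:8, 101:108, "mann_whitney")$p, 0.01)

  ## Fisher on ((10,0),(0,10)): exact hypergeometric two-sided sum
  tab <- matrix(c(10, 0, 0, 10), 2)
  pOracle <- sum(dhyper(0:10, 10, 10, 10)[dhyper(0:10, 10, 10, 10) <=
                                            dhyper(10, 10, 10, 10) * (1 + 1e-7)])
  got <- associationTest(tab, kind = "fisher")$p
  expect_equal(got, pOracle, tolerance = 1e-10)
  expect_lt(got, 1e-4)

  ## Spearman: perfect monotone association
  sp <- associationTest(c(1, 5, 9, 11), c(2, 4, 8, 16), "spearman")
  expect_equal(sp$rho, 1)
  expect_lt(sp$p, 1e-6)
  expect_error(associationTest(rep(1, 5), 1:5, "spearman"), "constant")
  expect_error(associationTest(numeric(0), 1:3, "mann_whitney"), "non-empty")
})

test_that("Benjamini-Hochberg equals the hand step-up computation", {
  expect_equal(bhAdjust(0.037), 0.037)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  ## hand: q_(i) = min_{j>=i} m p_(j) / j
  p <- c(0.001, 0.008, 0.039, 0.041, 0.9)
  expect_equal(bhAdjust(p), c(0.005, 0.02, 0.05125, 0.05125, 0.9))
  expect_true(all(bhAdjust(p) >= p))
  set.seed(11)
  pr <- runif(50)
  q <- bhAdjust(pr)
  expect_true(all(diff(q[order(pr)]) >= -1e-12))   # monotone in p ranks
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("BH at level alpha controls the FDR in an all-null simulation", {
  set.seed(12)
  fdp <- replicate(200, {
    q <- bhAdjust(runif(100))
    mean(q <= 0.1) > 0
  })
  expect_lte(mean(fdp), 0.1 + 3 * sqrt(0.1 * 0.9 / 200))
})

test_that("the profile sweep reports one row per usable feature plus fTME", {
  set.seed(13)
  n <- 60
  feat <- cbind(ki67_trm_cd8_density_tn = rlnorm(n),
                cd206_tam_density_it = rlnorm(n),
                dead_feature = NA_real_)
  rownames(feat) <- paste0("p", 1:n)
  grp <- feat[, 1] > median(feat[, 1])
  tt <- rexp(n, 0.01 * ifelse(grp, 0.3, 1))
  ftme <- grp & feat[, 2] < median(feat[, 2])
  expect_warning(
    sw <- profileSweep(feat, tt, rep(1, n), ftme = ftme),
    "dead_feature")
  expect_true("ki67_trm_cd8_density_tn" %in% sw$feature)
  expect_true("ftme_cluster" %in% sw$feature)
  expect_false("dead_feature" %in% sw$feature)
  ## the planted protective feature shows HR > 1 for its low group
  expect_gt(sw$hr[sw$feature == "ki67_trm_cd8_density_tn"], 1)
})
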