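test_that("ventilation segmentation thresholds at 10% of maximum", {
  v <- array(5, c(4, 4, 2))
  expect_true(all(segmentVentilated(v)))
  v2 <- array(0.05, c(4, 4, 2)); v2[1, 1, 1] <- 1.0
  expect_equal(sum(segmentVentilated(v2, 0.10)), 1L)
  set.seed(14)
  v3 <- array(runif(64), c(4, 4, 4))
  expect_equal(sum(segmentVentilated(v3, 0.3)),
               sum(v3 >= 0.3 * max(v3)))   # brute-force count
  expect_error(segmentVentilated(array(0, c(2, 2, 2))), "all-zero")
  expect_error(segmentVentilated(v, 1.2), "thresholdFrac")
})

test_that("VDP arithmetic and bounds", {
  expect_equal(computeVdp(1000, 1000), 0)
  expect_equal(computeVdp(931, 1000), 6.9)
  expect_equal(computeVdp(0, 1000), 100)
  expect_error(computeVdp(10, 0), "empty")
  expect_error(computeVdp(1001, 1000), "exceeds")
  # mask forms always land in [0, 100] because of the intersection
  set.seed(3)
  for (i in 1:20) {
    vv <- array(runif(64) > 0.4, c(4, 4, 4))
    tcv <- array(runif(64) > 0.3, c(4, 4, 4))
    if (!any(tcv)) next
    v <- computeVdp(vv, tcv)
    expect_gte(v, 0); expect_lte(v, 100)
  }
})

test_that("regional summaries restrict to lobes and partition the mask", {
  vol <- noiselessVolume()
  qm <- vol$maps
  lobes <- vol$phantom@lobes
  reg <- regionalSummaries(qm, lobes, vol$phantom@lobeLabels,
                           animal = 1, fio2 = 0.4)
  # disjoint lobes partition the masked lung
  counts <- reg[reg$metric == "cs_rbc", "n_voxels"]
  expect_equal(sum(counts), sum(qm@mask & lobes > 0))
  # single-lobe atlas reproduces the whole-lung mean
  one <- array(1L, dim(lobes))
  regOne <- regionalSummaries(qm, one, "ALL")
  s <- summarizeMaps(qm)
  for (m in c("cs_rbc", "rbc_m")) {
    expect_equal(regOne$mean[regOne$metric == m & regOne$lobe == "ALL"],
                 s$mean[s$metric == m], tolerance = 1e-6)
  }
})

test_that("a lobe-specific shift offset appears only in that lobe", {
  acq <- smallAcq()
  ph <- homogeneousPhantom(0.40, acq = acq)
  sel <- ph@lobes == 6L            # L2
  cs <- ph@cs
  csRbc <- cs[, , , 3]; csRbc[sel] <- csRbc[sel] + 1
  cs[, , , 3] <- csRbc
  ph@cs <- cs
  ksp <- simulateAcquisition(ph, acq, "full")
  fidImg <- reconstructMRSI(ksp, acq, spectralTransform = FALSE)
  fit <- fitVolume(fidImg, defaultPrior(0.40))
  qm <- makeQuantMaps(fit, buildAnalysisMask(fit), t2star = ph@t2star)
  reg <- regionalSummaries(qm, ph@lobes, ph@lobeLabels)
  csReg <- reg[reg$metric == "cs_rbc", ]
  l2 <- csReg$mean[csReg$lobe == "L2"]
  others <- csReg$mean[csReg$lobe != "L2" & csReg$n_voxels > 0]
  expect_equal(l2 - mean(others), 1, tolerance = 0.05)
})

test_that("empty lobes yield zero-count rows, not errors", {
  vol <- noiselessVolume()
  lobes <- vol$phantom@lobes
  lobes[lobes == 4L] <- 3L                       # drop R4 entirely
  reg <- regionalSummaries(vol$maps, lobes, vol$phantom@lobeLabels)
  r4 <- reg[reg$lobe == "R4", ]
  expect_true(all(r4$n_voxels == 0L))
  expect_true(all(is.na(r4$mean)))
})

test_that("paired t matches hand computation and flags degeneracy", {
  same <- pairedT(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_true(same$flagged)
  expect_equal(same$p, 1)
  a <- c(5.1, 6.2, 4.8, 5.9); b <- c(4.0, 5.1, 4.1, 4.6)
  res <- pairedT(a, b)
  d <- a - b
  tHand <- mean(d) / (stats::sd(d) / sqrt(4))
  expect_equal(res$t, tHand)
  expect_equal(res$df, 3)
  expect_equal(res$p, 2 * stats::pt(-abs(tHand), 3))
})

test_that("paired t holds its nominal type-I error under the null", {
  nrep <- 4000
  rej <- 0
  set.seed(77)
  for (i in seq_len(nrep)) {
    a <- rnorm(4); b <- rnorm(4)
    if (pairedT(a, b)$p < 0.05) rej <- rej + 1
  }
  rate <- rej / nrep
  expect_lt(abs(rate - 0.05), 0.012)   # ~3.5 binomial SDs
})

test_that("two-way ANOVA flags degeneracy and missing cells", {
  g <- expand.grid(animal = 1:4, lobe = c("R1", "R2", "R3", "R4", "L1", "L2"),
                   fio2 = c(0.4, 1.0))
  # pure additive lobe effect, zero noise: degenerate residual
  g$value <- as.numeric(factor(g$lobe))
  res <- regionalAnova(g)
  expect_true(res$degenerate)
  # with noise: strong region effect, no oxygen effect
  set.seed(9)
  g$value <- as.numeric(factor(g$lobe)) * 2 + rnorm(nrow(g))
  res2 <- regionalAnova(g)
  expect_lt(res2$pRegion, 0.001)
  expect_gt(res2$pOxygen, 0.05)
  # single observation per cell: interaction untestable
  one <- g[g$animal == 1, ]
  expect_error(regionalAnova(one), "untestable")
  # empty cell is named
  holed <- g[!(g$lobe == "L2" & g$fio2 == 1.0), ]
  expect_error(regionalAnova(holed), "L2")
})

test_that("ANOVA p-values are uniform under an exchangeable null", {
  nrep <- 1500
  ps <- matrix(NA_real_, nrep, 3)
  g <- expand.grid(animal = 1:4,
                   lobe = c("R1", "R2", "R3", "R4", "L1", "L2"),
                   fio2 = c(0.4, 1.0))
  set.seed(123)
  for (i in seq_len(nrep)) {
    g$value <- rnorm(nrow(g))
    a <- regionalAnova(g)
    ps[i, ] <- c(a$pRegion, a$pOxygen, a$pInteraction)
  }
  for (j in 1:3) {
    ks <- stats::ks.test(ps[, j], "punif")
    expect_gt(ks$p.value, 0.001)
    expect_lt(abs(mean(ps[, j] < 0.05) - 0.05), 0.02)
  }
})

test_that("the configured regional effect pattern is recovered", {
  effects <- regionalEffectDefaults()
  nSeeds <- 60
  hits <- array(0L, c(nrow(effects), 3))
  for (s in seq_len(nSeeds)) {
    dat <- simulateRegionalData(nAnimals = 4, metrics = effects,
                                seed = 3000 + s)
    tab <- regionalAnovaTable(dat)
    tab <- tab[match(effects$metric, tab$metric), ]
    sig <- cbind(tab$p_region < 0.05, tab$p_oxygen < 0.05,
                 tab$p_interaction < 0.05)
    expected <- cbind(effects$region > 0, effects$oxygen > 0,
                      effects$interaction > 0)
    hits <- hits + (sig == expected)
  }
  rate <- hits / nSeeds
  # every metric-effect cell matches its expected call in >= 90% of seeds
  expect_true(all(rate >= 0.9))
})

test_that("regional means are invariant to voxel order and relabeling", {
  vol <- noiselessVolume()
  lobes <- vol$phantom@lobes
  reg <- regionalSummaries(vol$maps, lobes, vol$phantom@lobeLabels)
  # relabel lobes by a permutation: per-lobe means travel with the label
  perm <- c(3L, 1L, 2L, 6L, 4L, 5L)
  lobes2 <- array(0L, dim(lobes))
  for (k in 1:6) lobes2[lobes == k] <- perm[k]
  reg2 <- regionalSummaries(vol$maps, lobes2, vol$phantom@lobeLabels)
  for (k in 1:6) {
    a <- reg[reg$metric == "cs_rbc" & reg$lobe == vol$phantom@lobeLabels[k], ]
    b <- reg2[reg2$metric == "cs_rbc" &
                reg2$lobe == vol$phantom@lobeLabels[perm[k]], ]
    expect_equal(a$mean, b$mean)
    expect_equal(a$n_voxels, b$n_voxels)
  }
})
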