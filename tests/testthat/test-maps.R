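test_that("amplitude correction applies flip and T2* factors", {
  acq0 <- XeAcquisition(te = 0)
  out <- correctAmplitudes(c(1, 1, 1), acq0, t2star = c(14.1, 4.8, 4.0))
  expect_equal(out, 1 / sin(c(0.1, 10, 10) * pi / 180))
  acq <- XeAcquisition(te = 0.5)
  one <- correctAmplitudes(c(0, 0, 1), acq, t2star = c(1, 1, 1))
  expect_equal(one[3], exp(0.5) / sin(10 * pi / 180))
  # equal raw gas and RBC amplitudes: corrected gas/RBC scales by the
  # flip-angle sine ratio
  eq <- correctAmplitudes(c(1, 1, 1), acq0, t2star = c(1, 1, 1))
  expect_equal(eq[1] / eq[3], sin(10 * pi / 180) / sin(0.1 * pi / 180),
               tolerance = 1e-10)
  expect_error(correctAmplitudes(c(1, 1, 1), acq, t2star = c(1, -1, 1)),
               "positive")
})

mockFitVolume <- function(gas, converged = NULL) {
  d <- dim(gas)
  amp <- array(NA_real_, c(d, 3))
  amp[, , , 1] <- gas
  amp[, , , 2] <- gas * 0.1
  amp[, , , 3] <- gas * 0.03
  cs <- array(NA_real_, c(d, 3))
  cs[, , , 1] <- 0.06; cs[, , , 2] <- 196.97; cs[, , , 3] <- 208.80
  lw <- array(70, c(d, 3))
  conv <- if (is.null(converged)) array(TRUE, d) else converged
  new("VoxelFitVolume", amp = amp, cs = cs, lw = lw,
      phase = array(0, c(d, 3)), lwG = array(40, d),
      crlbAmp = array(NA_real_, c(d, 3)), crlbCs = array(NA_real_, c(d, 3)),
      crlbLw = array(NA_real_, c(d, 3)), phase0 = array(0, d),
      delay = array(0, d), residual = array(0, d), converged = conv,
      fitted = array(TRUE, d), acq = smallAcq(c(4L, 4L, 2L)),
      prior = defaultPrior(0.40), noiseSd = 0.0)
}

test_that("gas-mean mask follows its arithmetic exactly", {
  gas <- array(1, c(4, 4, 2))
  fit <- mockFitVolume(gas)
  expect_true(all(buildAnalysisMask(fit)))        # uniform: all pass
  gas2 <- array(0, c(4, 4, 2)); gas2[, , 1] <- 1  # half 1, half 0
  fit2 <- mockFitVolume(gas2)
  m <- buildAnalysisMask(fit2, factor = 0.6)      # mean 0.5, thr 0.3
  expect_equal(sum(m), 16L)
  expect_true(all(m[, , 1]) && !any(m[, , 2]))
  m0 <- buildAnalysisMask(fit2, factor = 0)
  expect_equal(sum(m0), sum(gas2 > 0))
})

test_that("mask is monotone in the threshold factor", {
  set.seed(4)
  gas <- array(runif(32), c(4, 4, 2))
  fit <- mockFitVolume(gas)
  prev <- buildAnalysisMask(fit, factor = 0)
  for (f in c(0.3, 0.6, 0.9, 1.2)) {
    cur <- buildAnalysisMask(fit, factor = f)
    expect_true(all(prev | !cur))   # cur subset of prev
    prev <- cur
  }
})

test_that("quantitative maps satisfy their defining identities", {
  gas <- array(2, c(4, 4, 2))
  fit <- mockFitVolume(gas)
  mask <- buildAnalysisMask(fit)
  qm <- makeQuantMaps(fit, mask, t2star = c(14.1, 4.8, 4.0))
  mp <- maps(qm)
  expect_equal(unique(as.vector(mp$cs_rbc_m_diff[mask])), 208.80 - 196.97)
  # difference map equals RBC - membrane everywhere in the mask
  expect_equal(mp$cs_rbc_m_diff[mask], (mp$cs_rbc - mp$cs_membrane)[mask])
  expect_true(all(is.na(mp$rbc_m[!mask])))
  # ratios reflect flip/T2* correction of raw amplitude ratios
  acq <- fit@acq
  corrFac <- exp(acq@te / c(14.1, 4.8, 4.0)) / sin(c(0.1, 10, 10) * pi / 180)
  expect_equal(unique(as.vector(mp$m_gas[mask])),
               0.1 * corrFac[2] / corrFac[1], tolerance = 1e-12)
})

test_that("zero-amplitude denominators are flagged, not fatal", {
  gas <- array(1, c(4, 4, 2)); gas[1, 1, 1] <- 0
  fit <- mockFitVolume(gas)
  mask <- array(TRUE, c(4, 4, 2))
  qm <- makeQuantMaps(fit, mask, t2star = c(14.1, 4.8, 4.0))
  expect_true(is.nan(maps(qm)$m_gas[1, 1, 1]))
  s <- summarizeMaps(qm)
  expect_equal(s$n_voxels[s$metric == "m_gas"], 31L)  # NaN excluded
})

test_that("summaries agree with direct arithmetic", {
  gas <- array(1, c(4, 4, 2))
  fit <- mockFitVolume(gas)
  mask <- array(TRUE, c(4, 4, 2))
  qm <- makeQuantMaps(fit, mask, t2star = c(14.1, 4.8, 4.0))
  qm@maps$two_val <- array(c(1, 3), c(4, 4, 2))
  s <- summarizeMaps(qm)
  expect_equal(s$mean[s$metric == "two_val"], 2)
  expect_equal(s$sd[s$metric == "two_val"], stats::sd(rep(c(1, 3), 16)))
  expect_equal(s$sd[s$metric == "cs_rbc"], 0)
  # all-false mask: empty summaries, no exception
  sEmpty <- summarizeMaps(qm, mask = array(FALSE, c(4, 4, 2)))
  expect_true(all(sEmpty$n_voxels == 0L))
  expect_true(all(is.na(sEmpty$mean)))
})

test_that("ratio maps are invariant to global amplitude rescaling", {
  vol <- noiselessVolume()
  ksp <- vol$ksp
  acq <- acquisition(ksp)
  scaled <- new("KSpaceMRSI", locations = kLocations(ksp),
                fids = fids(ksp) * 37, acq = acq)
  fidImg <- reconstructMRSI(scaled, acq, spectralTransform = FALSE)
  prior <- defaultPrior(0.40)
  fit <- fitVolume(fidImg, prior)
  mask <- buildAnalysisMask(fit)
  qm <- makeQuantMaps(fit, mask, t2star = vol$phantom@t2star)
  s <- summarizeMaps(qm)
  s0 <- vol$summary
  for (m in c("m_gas", "rbc_gas", "rbc_m")) {
    expect_equal(s$mean[s$metric == m], s0$mean[s0$metric == m],
                 tolerance = 1e-6)
  }
})

test_that("noiseless maps equal the phantom truth inside the mask", {
  vol <- noiselessVolume()
  mp <- maps(vol$maps)
  mask <- analysisMask(vol$maps)
  expect_gt(sum(mask), 20)
  expect_lt(max(abs(mp$cs_rbc[mask] - 208.80)), 1e-3)
  expect_lt(max(abs(mp$cs_membrane[mask] - 196.97)), 1e-3)
  expect_lt(max(abs(mp$lw_rbc[mask] - 71)), 0.1)
  expect_lt(max(abs(mp$rbc_m[mask] - 0.275)), 1e-3)
  expect_equal(vol$summary$mean[vol$summary$metric == "rbc_m"], 0.275,
               tolerance = 1e-4)
})

test_that("SNR definitions scale and guard as specified", {
  vol <- noiselessVolume()
  fit <- vol$fit
  noise <- list(sd = 0.01, sdTime = 0.01, window = c(-250, -150))
  snr1 <- computeSnr(fit, noise)
  doubled <- fit
  doubled@amp <- fit@amp * 2
  expect_equal(computeSnr(doubled, noise), snr1 * 2)
  pv <- computeSnr(fit, noise, perVoxel = TRUE)
  expect_equal(names(pv), c("gas", "membrane", "rbc"))
  # a signal-free volume has zero window SD, so SNR is infinite
  spec <- reconstructMRSI(vol$ksp, spectralTransform = TRUE)
  silent <- spec
  silent@data[] <- 0i
  nz <- estimateNoise(silent)
  expect_equal(nz$sd, 0)
  expect_true(all(is.infinite(computeSnr(fit, nz))))
  expect_error(estimateNoise(spec, window = c(-30, 30)), "overlaps")
  # truncation sidelobes of strong peaks leave a small nonzero floor in
  # the noise window even for noiseless data
  expect_gt(estimateNoise(spec)$sd, 0)
})
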