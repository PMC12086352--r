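test_that("zero-order phase is recovered after a known rotation", {
  acq <- XeAcquisition()
  fid <- simulateFid(data.frame(amp = c(1, 0.3), cs = c(196.91, 206.81),
                                lw = c(60, 80)), acq,
                     applyExcitation = FALSE)
  pc0 <- phaseCorrect(fid, acq)
  # small residual from overlapping-peak tail phase is expected
  expect_lt(abs(pc0$phase0), 0.05)
  pc <- phaseCorrect(fid * exp(1i * 0.7), acq)
  # the rotation round trip is exact: recovered phase moves by 0.7
  expect_equal(pc$phase0 - pc0$phase0, 0.7, tolerance = 1e-6)
  expect_equal(pc$fid, pc0$fid, tolerance = 1e-6)
  expect_equal(pc$fid, fid, tolerance = 0.05)
})

test_that("a two-sample acquisition delay is recovered", {
  acq <- XeAcquisition()
  dt <- 1 / acq@bandwidth
  t <- (seq_len(acq@nSpectral) - 1) * dt + 2 * dt   # delayed time base
  mk <- function(amp, cs, lw)
    amp * exp(2i * pi * cs * acq@refFrequency * t - pi * lw * t)
  fid <- mk(1, 0.06, 5) + mk(1, 196.91, 60) + mk(0.5, 206.81, 80)
  pc <- phaseCorrect(fid, acq)
  expect_equal(pc$delay, 2 * dt, tolerance = 0.1)
  expect_true(!pc$degenerate)
  z <- phaseCorrect(complex(real = numeric(10)), acq)
  expect_true(z$degenerate)
  expect_equal(z$phase0, 0)
})

test_that("noiseless recovery over the prior range is sharp", {
  acq <- XeAcquisition()
  prior <- singlePeakPrior()
  for (cs in c(203.5, 206.81, 210.0)) {
    for (lw in c(40, 80, 150)) {
      pr <- singlePeakPrior(cs0 = 207, lw0 = 90)
      pr@peaks$lwMax <- 300
      fid <- simulateFid(data.frame(amp = 1.3, cs = cs, lw = lw), acq,
                         applyExcitation = FALSE)
      fit <- fitVoxel(fid, pr, acq)
      expect_lt(abs(fit$cs - cs), 1e-3)
      expect_lt(abs(fit$lw - lw), 0.1)
      expect_equal(fit$amp, 1.3, tolerance = 1e-4)
    }
  }
})

test_that("three-peak noiseless fit recovers every parameter", {
  acq <- XeAcquisition()
  prior <- defaultPrior(1.00)
  d <- xeDefaults(1.00)
  peaks <- data.frame(
    amp = c(0.17, 0.19, 0.06),
    cs = unname(d$cs), lw = c(d$lw[["gas"]], d$lwLMembrane, d$lw[["rbc"]]),
    lwG = c(0, d$lwGMembrane, 0))
  fid <- simulateFid(peaks, acq, applyExcitation = FALSE)
  fit <- fitVoxel(fid, prior, acq)
  expect_true(attr(fit, "converged"))
  expect_equal(fit$cs, unname(d$cs), tolerance = 1e-3)
  expect_equal(fit$amp, peaks$amp, tolerance = 1e-3)
  expect_lt(abs(fit$lw[3] - 80), 0.1)
  # membrane reported linewidth is the combined Voigt FWHM
  expect_equal(fit$lw[2], 71, tolerance = 0.2)
})

test_that("fitting is equivariant to a global phase rotation", {
  acq <- XeAcquisition()
  prior <- defaultPrior(0.40)
  d <- xeDefaults(0.40)
  peaks <- data.frame(amp = c(0.17, 0.19, 0.05), cs = unname(d$cs),
                      lw = c(5, d$lwLMembrane, 71),
                      lwG = c(0, d$lwGMembrane, 0))
  fid <- simulateFid(peaks, acq, applyExcitation = FALSE)
  f0 <- fitVoxel(fid, prior, acq)
  f1 <- fitVoxel(fid * exp(1i * 0.9), prior, acq)
  expect_equal(f1$amp, f0$amp, tolerance = 1e-6)
  expect_equal(f1$cs, f0$cs, tolerance = 1e-8)
  expect_equal(f1$lw, f0$lw, tolerance = 1e-6)
  expect_equal(unique(f1$phase - f0$phase), 0.9, tolerance = 1e-6)
})

test_that("optimizer never worsens the starting residual", {
  acq <- XeAcquisition()
  prior <- defaultPrior(0.40)
  set.seed(31)
  for (i in 1:5) {
    d <- xeDefaults(0.40)
    peaks <- data.frame(amp = c(0.17, 0.19, 0.05),
                        cs = unname(d$cs) + rnorm(3, 0, 0.3),
                        lw = c(5, d$lwLMembrane, 71) + rnorm(3, 0, 3),
                        lwG = c(0, d$lwGMembrane, 0))
    fid <- simulateFid(peaks, acq, noiseSd = 0.01, applyExcitation = FALSE)
    fit <- fitVoxel(fid, prior, acq)
    expect_lte(attr(fit, "residual"), attr(fit, "startResidual") + 1e-12)
  }
})

test_that("prior optimization moves starts to the data and flags noise", {
  acq <- XeAcquisition()
  prior <- defaultPrior(0.40)
  d <- xeDefaults(0.40)
  # fixed point: data generated at the prior's own initial values
  atPrior <- simulateFid(
    data.frame(amp = prior@peaks$amp0, cs = prior@peaks$cs0,
               lw = prior@peaks$lw0, lwG = prior@peaks$lwG0), acq,
    applyExcitation = FALSE)
  opt <- optimizePrior(atPrior, prior, acq)
  expect_false(opt@warningFlag)
  expect_equal(opt@peaks$cs0, prior@peaks$cs0, tolerance = 1e-4)
  expect_equal(opt@peaks$csMin, prior@peaks$csMin)   # bounds untouched
  # RBC moved +1 ppm: the optimized start follows
  shifted <- simulateFid(
    data.frame(amp = prior@peaks$amp0, cs = prior@peaks$cs0 + c(0, 0, 1),
               lw = prior@peaks$lw0, lwG = prior@peaks$lwG0), acq,
    applyExcitation = FALSE)
  opt2 <- optimizePrior(shifted, prior, acq)
  expect_equal(opt2@peaks$cs0[3] - prior@peaks$cs0[3], 1, tolerance = 1e-2)
  # pure noise: warning flag, prior unchanged
  rng <- stats::rnorm
  set.seed(8)
  noiseFid <- complex(real = rng(88, 0, 1), imaginary = rng(88, 0, 1))
  opt3 <- optimizePrior(noiseFid, prior, acq)
  expect_true(opt3@warningFlag)
  expect_equal(opt3@peaks, prior@peaks)
})

test_that("pure-noise voxels give near-zero amplitudes and large CRLBs", {
  acq <- XeAcquisition()
  prior <- defaultPrior(0.40)
  set.seed(21)
  sd <- 0.02
  fid <- complex(real = rnorm(88, 0, sd), imaginary = rnorm(88, 0, sd))
  fit <- fitVoxel(fid, prior, acq, noise = list(sd = sd, sdTime = sd))
  expect_true(all(fit$amp < 6 * sd))
  expect_true(all(fit$crlbAmp / pmax(fit$amp, 1e-12) > 0.2))
})

test_that("parameter estimates are unbiased at matched SNR", {
  # three peaks at the 40%-oxygen means, noise at the study SNR scale
  acq <- XeAcquisition()
  prior <- defaultPrior(0.40)
  d <- xeDefaults(0.40)
  amps <- c(0.17, 0.19, 0.05)
  peaks <- data.frame(amp = amps, cs = unname(d$cs),
                      lw = c(5, d$lwLMembrane, 71),
                      lwG = c(0, d$lwGMembrane, 0))
  sdTime <- amps[3] / 5 / sqrt(88 / 256)   # RBC spectral SNR 5
  nrep <- 60
  res <- vapply(seq_len(nrep), function(i) {
    fid <- simulateFid(peaks, acq, noiseSd = sdTime, seed = 500 + i,
                       applyExcitation = FALSE)
    fit <- fitVoxel(fid, prior, acq)
    c(fit$cs[3], fit$lw[3])
  }, numeric(2))
  se <- apply(res, 1, stats::sd) / sqrt(nrep)
  expect_lt(abs(mean(res[1, ]) - 208.80), 3 * se[1])
  expect_lt(abs(mean(res[2, ]) - 71), 3 * se[2] + 1.5)
})

test_that("CRLB matches the Monte-Carlo estimator spread", {
  acq <- XeAcquisition()
  pr <- singlePeakPrior(206.81, 80)
  amp <- 1
  sdTime <- amp / 30 / sqrt(88 / 256)     # spectral SNR 30
  truthFid <- simulateFid(data.frame(amp = amp, cs = 206.81, lw = 80),
                          acq, applyExcitation = FALSE)
  nrep <- 500
  sim <- vapply(seq_len(nrep), function(i) {
    fid <- simulateFid(data.frame(amp = amp, cs = 206.81, lw = 80), acq,
                       noiseSd = sdTime, seed = 9000 + i,
                       applyExcitation = FALSE)
    fit <- fitVoxel(fid, pr, acq)
    c(fit$amp, fit$cs, fit$lw)
  }, numeric(3))
  mcSd <- apply(sim, 1, stats::sd)
  refFit <- fitVoxel(truthFid, pr, acq)
  cr <- computeCrlb(refFit, acq, sdTime)
  expect_lt(abs(cr$amp - mcSd[1]) / mcSd[1], 0.15)
  expect_lt(abs(cr$cs - mcSd[2]) / mcSd[2], 0.15)
  expect_lt(abs(cr$lw - mcSd[3]) / mcSd[3], 0.15)
})

test_that("CRLB limits and degeneracies behave", {
  acq <- XeAcquisition()
  pr <- singlePeakPrior()
  fid <- simulateFid(data.frame(amp = 1, cs = 206.81, lw = 80), acq,
                     applyExcitation = FALSE)
  fit <- fitVoxel(fid, pr, acq)
  cr0 <- computeCrlb(fit, acq, 0)
  expect_equal(cr0$amp, 0)
  cr1 <- computeCrlb(fit, acq, 0.01)
  cr2 <- computeCrlb(fit, acq, 0.02)
  expect_equal(cr2$amp / cr1$amp, 2, tolerance = 1e-10)
})
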