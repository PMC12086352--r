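# shared fixtures; everything is generated in code at test time

smallAcq <- function(grid = c(12L, 12L, 4L), zf = 1L) {
  XeAcquisition(matrixSize = grid, fov = c(24, 24, 8), spatialZf = zf)
}

homogeneousPhantom <- function(fio2 = 0.40, grid = c(12L, 12L, 4L),
                               seed = 1L, acq = smallAcq(grid)) {
  generatePhantom(grid, fio2 = fio2,
                  heterogeneity = heterogeneityConfig(scale = 0),
                  seed = seed, acq = acq)
}

# a phantom with uniform signal over the whole grid (single "lobe")
uniformPhantom <- function(grid = c(8L, 8L, 4L), amp = c(1, 0, 0),
                           cs = c(0, 197, 207), lw = c(10, 60, 70)) {
  mk4 <- function(v) {
    a <- array(0, c(grid, 3))
    for (k in 1:3) a[, , , k] <- v[k]
    a
  }
  new("PhantomTruth", amp = mk4(amp), cs = mk4(cs), lw = mk4(lw),
      lwG = array(0, grid), phase = mk4(c(0, 0, 0)),
      lungMask = array(TRUE, grid), lobes = array(1L, grid),
      lobeLabels = c("R1", "R2", "R3", "R4", "L1", "L2"),
      t2star = c(14.1, 4.8, 4.0), fio2 = 0.40, paO2 = 180, sO2 = 0.99)
}

# single-peak Lorentzian prior for estimator-theory tests
singlePeakPrior <- function(cs0 = 206.81, lw0 = 80) {
  peaks <- data.frame(peak = "rbc", lineshape = "lorentzian",
                      cs0 = cs0, csMin = cs0 - 5, csMax = cs0 + 5,
                      lw0 = lw0, lwMin = 5, lwMax = 300,
                      lwG0 = 0, lwGMin = 0, lwGMax = 0, amp0 = 1)
  new("PriorKnowledge", peaks = peaks, sharedPhase = TRUE,
      optimized = FALSE, warningFlag = FALSE)
}

# brute-force dense DTFT magnitude scan: the independent frequency oracle
densePeakSearch <- function(fid, acq, ppmRange, stepPpm = 0.001) {
  ppm <- seq(ppmRange[1], ppmRange[2], by = stepPpm)
  t <- (seq_along(fid) - 1) / acq@bandwidth
  f <- ppm * acq@refFrequency
  mag <- abs(exp(-2i * pi * outer(f, t)) %*% fid)
  ppm[which.max(mag)]
}

# small cached end-to-end noiseless volume shared between test files
.cache <- new.env()
noiselessVolume <- function() {
  if (is.null(.cache$nv)) {
    acq <- smallAcq()
    cfg <- experimentConfig(acq = acq, fio2Levels = 0.40, nAnimals = 1L,
                            heterogeneity = heterogeneityConfig(scale = 0),
                            noise = 0, seed = 7L)
    .cache$nv <- runAnimalVolume(cfg, 0.40, 1L)
  }
  .cache$nv
}
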