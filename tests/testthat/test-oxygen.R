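test_that("group-mean calibration slopes round to the published values", {
  # two oxygen levels, four animals each, zero within-group spread
  pao2 <- rep(c(181.74, 386.13), each = 4)
  cs <- rep(c(208.80, 206.81), each = 4)
  lw <- rep(c(71, 80), each = 4)
  mCs <- fitSlr(pao2, cs, response = "shift")
  expect_equal(round(mCs@slope, 2), -0.01)
  expect_equal(mCs@slope, (206.81 - 208.80) / (386.13 - 181.74),
               tolerance = 1e-12)
  mLw <- fitSlr(pao2, lw, response = "linewidth")
  expect_equal(round(mLw@slope, 2), 0.04)
})

test_that("simple linear fit is exact on exact data", {
  x <- c(100, 200, 300, 400)
  m <- fitSlr(x, 2 * x + 1)
  expect_equal(m@slope, 2)
  expect_equal(m@intercept, 1)
  expect_equal(m@r2, 1)
  set.seed(10)
  m0 <- fitSlr(seq(100, 400, length.out = 400), rnorm(400))
  expect_lt(abs(m0@slope), 0.01)
  expect_lt(m0@r2, 0.02)
  expect_error(fitSlr(rep(1, 5), rnorm(5)), "constant")
  expect_error(fitSlr(1:2, 1:2), "3 calibration points")
})

test_that("calibration and inversion are mutually consistent", {
  pao2 <- c(170, 185, 195, 360, 380, 400)
  cs <- -0.0097 * pao2 + 210.5
  m <- fitSlr(pao2, cs, response = "shift")
  # QuantMaps carrying exactly the calibration shifts inverts to the
  # calibration paO2 values
  d <- c(3L, 2L, 1L)
  qmaps <- new("QuantMaps",
               maps = list(cs_rbc = array(cs, d), lw_rbc = array(70, d)),
               mask = array(TRUE, d), snr = c(gas = 1, membrane = 1, rbc = 1),
               voxelSize = c(1, 1, 1), fio2 = 0.4)
  pred <- predictPao2(qmaps, m)
  expect_equal(as.vector(pred), pao2, tolerance = 1e-9)
  # constant map gives a constant prediction
  qmaps@maps$cs_rbc <- array(208.0, d)
  expect_equal(length(unique(as.vector(predictPao2(qmaps, m)))), 1L)
  mZero <- m; mZero@slope <- 0
  expect_error(predictPao2(qmaps, mZero), "not invertible")
})

test_that("MLR identifies exact coefficients and flags collinearity", {
  set.seed(2)
  cs <- 206 + runif(8, 0, 3)
  lw <- 70 + runif(8, 0, 12)
  truth <- c(-540, -1100, 5.5, 113000)    # cs, lw, cs:lw, intercept
  pao2 <- truth[4] + truth[1] * cs + truth[2] * lw + truth[3] * cs * lw
  m <- fitMlr(cs, lw, pao2)
  expect_equal(unname(m@coef["cs"]), truth[1], tolerance = 1e-6)
  expect_equal(unname(m@coef["lw"]), truth[2], tolerance = 1e-6)
  expect_equal(unname(m@coef["cs:lw"]), truth[3], tolerance = 1e-6)
  expect_equal(unname(m@coef["intercept"]), truth[4], tolerance = 1e-6)
  expect_equal(m@r2, 1)
  # inversion round trip on a held-out map
  d <- c(2L, 2L, 1L)
  csMap <- array(c(206.5, 207.2, 208.0, 206.9), d)
  lwMap <- array(c(72, 75, 80, 78), d)
  qmaps <- new("QuantMaps", maps = list(cs_rbc = csMap, lw_rbc = lwMap),
               mask = array(TRUE, d), snr = c(gas = 1, membrane = 1, rbc = 1),
               voxelSize = c(1, 1, 1), fio2 = 0.4)
  pred <- predictPao2(qmaps, m)
  expected <- truth[4] + truth[1] * csMap + truth[2] * lwMap +
    truth[3] * csMap * lwMap
  expect_equal(pred, expected, tolerance = 1e-9)
  expect_error(fitMlr(cs, 2 * cs, pao2), "collinear")
})

test_that("MLR recovery is unbiased at n = 8 across seeds", {
  truth <- c(-540, -1100, 5.5, 113000)
  est <- matrix(NA_real_, 500, 4)
  for (i in seq_len(500)) {
    set.seed(1200 + i)
    cs <- 206 + runif(8, 0, 3)
    lw <- 70 + runif(8, 0, 12)
    pao2 <- truth[4] + truth[1] * cs + truth[2] * lw +
      truth[3] * cs * lw + rnorm(8, 0, 10)
    m <- fitMlr(cs, lw, pao2)
    est[i, ] <- m@coef[c("cs", "lw", "cs:lw", "intercept")]
  }
  bias <- colMeans(est) - truth
  se <- apply(est, 2, stats::sd) / sqrt(nrow(est))
  expect_true(all(abs(bias) < 3.5 * se))
})

test_that("MLR never fits worse than the nested simple model", {
  for (i in 1:10) {
    set.seed(40 + i)
    pao2 <- c(rnorm(4, 182, 11), rnorm(4, 386, 32))
    cs <- -0.0097 * pao2 + 210.5 + rnorm(8, 0, 0.2)
    lw <- 0.044 * pao2 + 64 + rnorm(8, 0, 3)
    slr <- fitSlr(pao2, cs)
    # R2 of predicting pao2 from cs equals the correlation-squared, which
    # is the SLR R2; MLR adds regressors to the same response
    mlr <- fitMlr(cs, lw, pao2)
    expect_gte(mlr@r2, slr@r2 - 1e-12)
  }
})

test_that("exponential shift model evaluates and bounds its domain", {
  m <- expShiftModel()     # human whole-blood defaults
  expect_equal(evalExpShiftModel(0, m), 9.3e-4 + 20.4)
  expect_equal(evalExpShiftModel(1, m), 9.3e-4 * exp(8.62) + 20.4)
  expect_equal(evalExpShiftModel(1, m), 25.5536, tolerance = 2e-3)
  flat <- expShiftModel(beta = 0)
  expect_equal(evalExpShiftModel(c(0, 0.5, 1), flat),
               rep(9.3e-4 + 20.4, 3))
  expect_error(evalExpShiftModel(1.5, m), "domain")
})

test_that("exponential model fit recovers direction and parameters", {
  so2 <- seq(0.55, 1.0, length.out = 20)
  human <- evalExpShiftModel(so2, expShiftModel())
  fh <- fitExpShiftModel(so2, human)
  expect_equal(fh@direction, "increasing")
  expect_equal(fh@beta, 8.62, tolerance = 0.05)
  porcLike <- -5e-4 * exp(9 * so2) + 212
  fp <- fitExpShiftModel(so2, porcLike)
  expect_equal(fp@direction, "decreasing")
})

test_that("logarithmic calibration is exact and near-linear in range", {
  pao2 <- seq(180, 390, length.out = 12)
  cs <- -2 * log(pao2) + 220
  m <- fitLogModel(pao2, cs)
  expect_equal(m@a, -2, tolerance = 1e-10)
  expect_equal(m@b, 220, tolerance = 1e-9)
  expect_error(fitLogModel(c(-1, 100, 200), c(1, 2, 3)), "positive")
  # over the studied range a log fit and a linear fit agree closely
  csData <- -0.0097 * pao2 + 210.5
  lin <- fitSlr(pao2, csData)
  logm <- fitLogModel(pao2, csData)
  grid <- seq(180, 390, by = 5)
  dev <- abs(predictShift(logm, grid) - predictShift(lin, grid))
  expect_lt(max(dev), 0.2)
})

test_that("dissociation curve has Hill-function structure", {
  porc <- odcModel("porcine")
  expect_equal(odc(porc@p50, porc), 0.5)
  expect_equal(odc(1e7, porc), 1, tolerance = 1e-4)
  x <- seq(0, 600, by = 5)
  y <- odc(x, porc)
  expect_true(all(diff(y) > 0))
  expect_true(all(y >= 0 & y < 1))
  # human and porcine curves are close in the hyperoxic regime
  hum <- odcModel("human")
  hi <- seq(150, 600, by = 10)
  expect_lt(max(abs(odc(hi, hum) - odc(hi, porc))), 0.02)
  expect_error(odcModel("custom"), "p50")
})

test_that("model serialization round-trips", {
  m <- fitSlr(c(180, 280, 390), c(208.8, 207.9, 206.8))
  path <- tempfile(fileext = ".json")
  writeModel(m, path)
  m2 <- readModel(path)
  expect_equal(modelCoef(m2), modelCoef(m))
  expect_equal(m2@r2, m@r2)
})
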