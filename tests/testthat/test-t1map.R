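test_that("gradient map: constant, step edge and linear ramp", {
  expect_true(all(gradientMap(matrix(5, 10, 12)) == 0))

  ## central differences see a step between columns 5 and 6 only
  step <- matrix(0, 10, 10); step[, 6:10] <- 4
  g <- gradientMap(step)
  expect_true(all(g[, c(1:4, 7:10)] == 0))
  expect_true(all(g[, 5:6] > 0))

  a <- 0.7
  ramp <- outer(rep(1, 15), a * (1:20))
  g2 <- gradientMap(ramp)
  expect_equal(g2[2:14, 2:19], matrix(a, 13, 18), tolerance = 1e-12)

  expect_error(gradientMap(matrix(1, 2, 5)), "3x3")
})

test_that("motion estimation recovers injected integer shifts exactly", {
  sim <- simulatedPhantom()
  p <- smallParams()
  ## identity case
  ser0 <- renderPhantomScan(sim$truth, 8, p)
  est0 <- estimateMotion(ser0)
  expect_true(all(motionShifts(est0) == 0L))

  ## known shift at one TI, noiseless; agrees with the exhaustive oracle
  sh <- matrix(0L, 9, 2); sh[3, ] <- c(2L, 3L)
  ser <- renderPhantomScan(sim$truth, 8, p, motionShifts = sh)
  est <- estimateMotion(ser)
  expect_equal(unname(motionShifts(est)[3, ]), c(2L, 3L))
  gref <- Reduce(`+`, lapply(1:3, function(s) gradientMap(imageArray(ser)[s, 9, , ])))
  g3 <- Reduce(`+`, lapply(1:3, function(s) gradientMap(imageArray(ser)[s, 3, , ])))
  expect_equal(oracleShift(gref, g3), c(2L, 3L))

  ## property: random shift sets in the window, exact recovery
  set.seed(11)
  for (rep in 1:5) {
    shr <- matrix(sample(-8:8, 18, replace = TRUE), 9, 2)
    shr[9, ] <- 0L
    serr <- renderPhantomScan(sim$truth, 8, p, motionShifts = shr)
    expect_equal(unname(motionShifts(estimateMotion(serr))), unname(shr))
  }

  expect_error(estimateMotion(ser0, window = 40), "window")
})

test_that("applying estimated motion is idempotent and flags border pixels", {
  sim <- simulatedPhantom()
  p <- smallParams()
  sh <- matrix(0L, 9, 2); sh[2, ] <- c(-3L, 1L); sh[5, ] <- c(2L, -4L)
  ser <- renderPhantomScan(sim$truth, 8, p, motionShifts = sh)
  est <- estimateMotion(ser)
  corr <- applyMotion(ser, est)
  ## residual motion re-estimates as zero
  expect_true(all(motionShifts(estimateMotion(corr)) == 0L))
  ## interior pixels of a shifted TI equal the unshifted render
  ser0 <- renderPhantomScan(sim$truth, 8, p)
  v <- validMask(corr)
  for (s in 1:3)
    expect_equal(imageArray(corr)[s, 5, , ][v], imageArray(ser0)[s, 5, , ][v])
  ## pixels dragged in from outside are invalid: shift (2,-4) invalidates
  ## the last 2 rows and first 4 columns
  expect_false(any(validMask(corr)[47:48, ]))
  expect_false(any(validMask(corr)[, 1:4]))

  ## zero shifts leave the series untouched
  idm <- new("MotionEstimate", shifts = matrix(0L, 9, 2),
             referenceTiIndex = 9L)
  expect_identical(imageArray(applyMotion(ser0, idm)), imageArray(ser0))
})

test_that("pixel fit inverts the forward model, including sub-TI null points", {
  ti <- tiDefault
  for (t1true in c(300, 700, 1000, 1600, 2400)) {
    f <- fitT1Pixel(irSignal(t1true, ti, 100), ti)
    expect_true(f$converged)
    expect_lt(abs(f$t1 - t1true), 1)
    expect_lt(abs(f$s0 - 100), 0.1)
    expect_lt(f$rss, 1e-6)
    ## brute-force 2-D grid enumeration agrees within its resolution
    o <- bruteFitT1(irSignal(t1true, ti, 100), ti)
    expect_lt(abs(o$t1 - f$t1), 1)
  }
})

test_that("pixel fit is invariant to global signal scaling", {
  ti <- tiDefault
  set.seed(4)
  for (rep in 1:6) {
    t1true <- runif(1, 200, 2500)
    sig <- irSignal(t1true, ti, 100) + rnorm(9, 0, 1.5)
    sig <- pmax(sig, 0)
    f1 <- fitT1Pixel(sig, ti)
    k <- runif(1, 0.1, 40)
    f2 <- fitT1Pixel(sig * k, ti)
    expect_equal(f2$t1, f1$t1, tolerance = 1e-6)
    expect_equal(f2$s0, f1$s0 * k, tolerance = 1e-6)
  }
})

test_that("pixel fit rejects degenerate input", {
  ti <- tiDefault
  z <- fitT1Pixel(rep(0, 9), ti)
  expect_false(z$converged)
  expect_true(is.na(z$t1))
  expect_error(fitT1Pixel(1:3, c(100, 200)), "lengths differ")
  expect_error(fitT1Pixel(1:2, c(100, 200)), "at least 3")
  expect_error(fitT1Pixel(1:9, ti, t1Bounds = c(500, 50)), "t1Bounds")
})

test_that("noiseless map fit recovers truth; air is invalid; noisy error is small", {
  sim <- simulatedPhantom()
  p <- smallParams()
  ser <- renderPhantomScan(sim$truth, 15, p)
  map <- fitT1Map(ser)
  tru <- truthT1Grid(sim$truth, 15)
  expect_false(any(validMask(map)[labelMap(sim$truth) == 0L]))
  v <- validMask(map)
  expect_gt(sum(v), 1000)
  relErr <- abs(t1Array(map)[v] - tru[v]) / tru[v]
  expect_lt(max(relErr), 0.01)

  ## default Rician noise: median relative T1 error under 5%
  serN <- renderPhantomScan(sim$truth, 15, p, noiseSigma = 2, seed = 7)
  mapN <- fitT1Map(serN)
  vN <- validMask(mapN)
  relErrN <- abs(t1Array(mapN)[vN] - tru[vN]) / tru[vN]
  expect_lt(median(relErrN), 0.05)

  expect_error(fitT1Map(irSeries(array(0, c(1, 3, 0, 0)),
                                 acquisitionParams(tiList = c(1, 2, 3),
                                                   nSlices = 1))),
               "empty series")
})

test_that("fitting TR-corrected data with the two-parameter model biases T1 low", {
  ti <- tiDefault
  for (t1true in c(800, 1200, 1800)) {
    f <- fitT1Pixel(irSignal(t1true, ti, 100, tr = 5000), ti)
    expect_lt(f$t1, t1true)
  }
  ## and the TR-corrected fit removes the bias
  f3 <- fitT1Pixel(irSignal(1200, ti, 100, tr = 5000), ti, tr = 5000)
  expect_lt(abs(f3$t1 - 1200), 1)
})
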