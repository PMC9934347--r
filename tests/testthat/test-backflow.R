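## Small hand-built maps for the segmentation unit tests.
mkMap <- function(t1, valid = NULL, time = 0, pressure = 0) {
  if (is.null(valid)) valid <- array(TRUE, dim(t1))
  new("T1Map", t1 = t1, s0 = array(100, dim(t1)),
      rss = array(0, dim(t1)), valid = valid,
      timeMin = time, pressureMmHg = pressure)
}

test_that("segmentation thresholds relative T1 drop and filters small clusters", {
  d <- c(1L, 20L, 20L)
  cortex <- array(TRUE, d)
  base <- mkMap(array(1000, d))

  ## no change -> empty mask
  expect_equal(sum(segmentAffected(base, base, cortex)), 0)

  ## a 30-pixel blob at 500 ms survives; threshold is T1 < 700
  cur <- array(1000, d)
  cur[1, 5:10, 5:9] <- 500
  got <- segmentAffected(mkMap(cur), base, cortex, relDrop = 0.3,
                         minCluster = 5)
  expect_equal(sum(got), 30)
  expect_true(all(got[1, 5:10, 5:9]))

  ## scattered single pixels below threshold are removed
  cur2 <- array(1000, d)
  for (i in c(2, 6, 10, 14, 18)) cur2[1, i, i] <- 400
  expect_equal(sum(segmentAffected(mkMap(cur2), base, cortex,
                                   minCluster = 5)), 0)
  ## ... but kept when the cluster filter is off
  expect_equal(sum(segmentAffected(mkMap(cur2), base, cortex,
                                   minCluster = 1)), 5)

  ## invalid pixels can never be affected
  v <- array(TRUE, d); v[1, 5:10, 5:9] <- FALSE
  expect_equal(sum(segmentAffected(mkMap(cur, valid = v), base, cortex)), 0)

  expect_error(segmentAffected(base, base, array(FALSE, d)), "empty cortex")
  expect_error(segmentAffected(base, base, cortex, relDrop = 1.2), "relDrop")
})

test_that("affected fraction is the pooled cortical pixel ratio", {
  d <- c(2L, 10L, 10L)
  cortex <- array(FALSE, d); cortex[, 3:8, 3:8] <- TRUE
  expect_equal(affectedFraction(cortex, cortex), 1.0)
  half <- cortex; half[2, , ] <- FALSE
  expect_equal(affectedFraction(half, cortex), 0.5)
  expect_equal(affectedFraction(array(FALSE, d), cortex), 0.0)
  expect_error(affectedFraction(half, array(FALSE, d)), "empty cortex")
})

test_that("first-change detection reports the first scan meeting the area criterion", {
  d <- c(1L, 10L, 10L)
  empty <- array(FALSE, d)
  big <- empty; big[1, 2:4, 2:4] <- TRUE      # 9 px
  tiny <- empty; tiny[1, 1, 1:3] <- TRUE      # 3 px, below minArea
  times <- c(0, 5, 10, 15, 20)
  press <- c(10, 12, 18, 22, 30)

  none <- detectFirstChange(rep(list(empty), 5), times, press)
  expect_true(is.na(none$scan))

  fc <- detectFirstChange(list(empty, empty, tiny, big, big), times, press,
                          minArea = 5)
  expect_equal(fc$scan, 4)
  expect_equal(fc$timeMin, 15)
  expect_equal(fc$pressureMmHg, 22)

  ## truncating the series after the detected scan does not change it
  fc2 <- detectFirstChange(list(empty, empty, tiny, big), times[1:4],
                           press[1:4], minArea = 5)
  expect_equal(fc2[c("scan", "timeMin", "pressureMmHg")],
               fc[c("scan", "timeMin", "pressureMmHg")])
})

test_that("noiseless pipeline recovers truth masks, monotone fractions and endpoints", {
  sim <- simulatedPhantom(seed = 9)
  p <- smallParams()
  maps <- lapply(seq_along(sim$scanTimes), function(k)
    fitT1Map(renderPhantomScan(sim$truth, k, p,
                               pressureMmHg = pressureAtTime(sim$log,
                                                             sim$scanTimes[k]))))
  cortex <- labelMap(sim$truth) == 1L
  res <- analyzeBackflow(maps, maps[[1]], cortex)

  aff <- affectedTruth(sim$truth)
  for (k in seq_along(sim$scanTimes)) {
    tm <- aff[k, , , ]
    if (!any(tm)) next
    est <- affectedMasks(res)[[k]]
    jac <- sum(est & tm) / sum(est | tm)
    expect_gte(jac, 0.9)
  }
  expect_true(all(diff(affectedFractions(res)) >= -1e-12))

  truthFrac <- sum(aff[length(sim$scanTimes), , , ]) / sum(cortex)
  expect_lt(abs(affectedFractions(res)[length(sim$scanTimes)] - truthFrac),
            0.02)

  ## first change matches the truth activation scan
  on <- min(wedgeOnsets(sim$truth))
  kTruth <- min(which(aupiAtScan(sim$truth) >= on))
  expect_equal(firstChange(res)$scan, kTruth)
  expect_equal(firstChange(res)$timeMin, sim$scanTimes[kTruth])
})

test_that("affected-fraction recovery holds under default noise and motion", {
  p <- smallParams()
  for (seed in c(21, 22, 23)) {
    sim <- simulatedPhantom(seed = seed)
    nEnd <- length(sim$scanTimes)
    maps <- lapply(c(1L, nEnd), function(k) {
      shifts <- withSeed(seed * 10 + k,
                         matrix(sample(-3:3, 18, replace = TRUE), 9, 2))
      shifts[9, ] <- 0L
      ser <- renderPhantomScan(sim$truth, k, p, noiseSigma = 2,
                               motionShifts = shifts, seed = seed * 100 + k)
      fitT1Map(applyMotion(ser, estimateMotion(ser)))
    })
    cortex <- labelMap(sim$truth) == 1L
    est <- affectedFraction(
      segmentAffected(maps[[2]], maps[[1]], cortex), cortex)
    tru <- sum(affectedTruth(sim$truth)[nEnd, , , ]) / sum(cortex)
    expect_lt(abs(est - tru), 0.05)
  }
})

test_that("ROI mean-T1 series behave as the physiology dictates", {
  sim <- simulatedPhantom(seed = 9)
  p <- smallParams()
  maps <- lapply(seq_along(sim$scanTimes), function(k)
    fitT1Map(renderPhantomScan(sim$truth, k, p)))
  rois <- phantomROISet(sim$truth)
  ser <- roiT1Series(maps, rois)

  ## muscle: no gadolinium, constant T1
  expect_lt(max(ser[, "dorsal_muscle"]) - min(ser[, "dorsal_muscle"]), 1e-3)
  ## earliest-activating wedge: constant at baseline then non-increasing,
  ## with a strict drop at activation
  c1 <- ser[, "cortex_1"]
  expect_true(all(diff(c1) <= 1e-9))
  expect_lt(min(c1), 0.5 * c1[1])
  ## remote cortex stays at baseline
  expect_lt(max(ser[, "cortex_remote"]) - min(ser[, "cortex_remote"]), 1e-3)

  ## an ROI with no valid pixels yields NA, not zero
  bad <- roiSet(list(outside = array(c(TRUE, rep(FALSE, length(labelMap(sim$truth)) - 1)),
                                     dim(labelMap(sim$truth)))))
  expect_true(all(is.na(roiT1Series(maps, bad))))
})
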