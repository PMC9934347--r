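test_that("phantom geometry has all tissues and a complete wedge partition", {
  ph <- makeKidneyPhantom(7, c(64, 64), 8, seed = 1)
  lab <- labelMap(ph)
  for (l in 1:4) expect_gt(sum(lab == l), 0)
  cortex <- lab == 1L
  expect_true(all(wedgeIds(ph)[cortex] >= 1L))
  expect_true(all(wedgeIds(ph)[cortex] <= 8L))
  expect_true(all(wedgeIds(ph)[!cortex] == 0L))
  expect_setequal(unique(as.vector(wedgeIds(ph)[cortex])), 1:8)
})

test_that("phantom generation is seed-deterministic and seed-sensitive", {
  a <- makeKidneyPhantom(7, c(64, 64), 8, seed = 1)
  b <- makeKidneyPhantom(7, c(64, 64), 8, seed = 1)
  c <- makeKidneyPhantom(7, c(64, 64), 8, seed = 2)
  expect_identical(labelMap(a), labelMap(b))
  expect_identical(wedgeIds(a), wedgeIds(b))
  expect_false(identical(labelMap(a), labelMap(c)))
})

test_that("polar wedges always get strictly smaller onsets than equatorial", {
  for (seed in c(1, 7, 23, 101)) {
    ph <- makeKidneyPhantom(3, c(48, 48), 8, seed = seed)
    on <- wedgeOnsets(ph)
    ## sectors 1 and 5 sit on the poles, 3 and 7 on the equator (8 wedges)
    expect_lt(max(on[c(1, 5)]), min(on[c(3, 7)]))
  }
})

test_that("degenerate phantom requests are rejected with informative errors", {
  expect_error(makeKidneyPhantom(3, c(20, 64), 8), "32x32")
  expect_error(makeKidneyPhantom(3, c(48, 48), 1), "nWedges")
  expect_error(makeKidneyPhantom(3, c(48, 48), 10000), "cortical pixel count")
})

test_that("wedge activation follows the accumulated-pressure threshold rule", {
  ## constant 20 mmHg: AUPI(t) = 20 t, so onset 70 crosses at t = 3.5 min
  ## and the first 5-min-grid scan at or past it is t = 5
  log <- pressureLog(c(0, 60), c(20, 20))
  st <- seq(0, 60, by = 5)
  ph <- smallPhantom()
  on <- wedgeOnsets(ph)
  polar <- which.min(on)
  ph@wedgeOnsetAupi[polar] <- 70
  tr <- simulateBackflow(ph, log, st)
  wpx <- wedgeIds(tr) == polar
  active <- vapply(seq_along(st), function(k) any(affectedTruth(tr)[k, , , ][wpx]), TRUE)
  expect_identical(st[min(which(active))], 5)

  ## onsets beyond the protocol's final AUPI: never any affected pixel
  ph2 <- smallPhantom()
  ph2@wedgeOnsetAupi <- rep(1e6, length(wedgeOnsets(ph2)))
  tr2 <- simulateBackflow(ph2, log, st)
  expect_equal(sum(affectedTruth(tr2)), 0)
})

test_that("simulated backflow matches an independent scalar evaluation of the rule", {
  sim <- simulatedPhantom(seed = 3)
  tr <- sim$truth
  ## independent: staircase AUPI by rectangle sums, activation by comparison
  aupiHand <- vapply(sim$scanTimes, function(t) {
    lev <- c(10, 20, 30, 40, 50)
    full <- pmin(pmax(t - (0:4) * 14, 0), 14)
    sum(lev * full)
  }, 0.0)
  expect_equal(aupiAtScan(tr), aupiHand)
  on <- wedgeOnsets(tr)
  for (w in seq_along(on)) {
    wpx <- wedgeIds(tr) == w
    if (!any(wpx)) next
    for (k in seq_along(sim$scanTimes)) {
      expect_identical(all(affectedTruth(tr)[k, , , ][wpx]),
                       aupiHand[k] >= on[w])
    }
  }
})

test_that("affected truth masks are nested over time and concentration stays in bounds", {
  sim <- simulatedPhantom(seed = 5)
  tr <- sim$truth
  aff <- affectedTruth(tr)
  for (k in seq_len(dim(aff)[1] - 1))
    expect_false(any(aff[k, , , ] & !aff[k + 1, , , ]))
  conc <- concentrationArray(tr)
  lab <- labelMap(tr)
  for (k in seq_len(dim(conc)[1])) {
    ck <- conc[k, , , ]
    ## no gadolinium outside affected cortex and pelvis
    expect_true(all(ck[!aff[k, , , ] & array(lab != 3L, dim(lab))] == 0))
    expect_true(all(ck <= 1.5 + 1e-12))
  }
})

test_that("onset calibration hits the nearest achievable end fraction", {
  log <- staircaseLog(); st <- seq(0, 70, by = 5)
  ph <- calibrateWedgeOnsets(smallPhantom(2), log, st, targetFraction = 0.66)
  tr <- simulateBackflow(ph, log, st)
  endFrac <- sum(affectedTruth(tr)[length(st), , , ]) / sum(labelMap(tr) == 1L)
  ## 8 wedges of near-equal size: nearest achievable fractions bracket 0.66
  expect_gt(endFrac, 0.66 - 1 / 8)
  expect_lt(endFrac, 0.66 + 1 / 8)
  expect_error(calibrateWedgeOnsets(smallPhantom(2), log, st,
                                    firstOnset = 1e6),
               "firstOnset")
})

test_that("simulateBackflow validates its inputs", {
  ph <- smallPhantom()
  log <- pressureLog(c(0, 60), c(20, 20))
  expect_error(simulateBackflow(ph, log, c(10, 5)), "sorted")
  expect_error(simulateBackflow(ph, log, c(0, 90)), "span")
  expect_error(simulateBackflow(ph, log, seq(0, 60, 5), spreadRate = 0),
               "spreadRate")
})

test_that("relaxivity model matches its closed form and is strictly decreasing", {
  expect_identical(concentrationToT1(0, 1000, 4), 1000)
  expect_equal(concentrationToT1(0.25, 1000, 4), 500)
  cs <- seq(0, 2, by = 0.05)
  t1s <- concentrationToT1(cs, 1200, 4)
  expect_true(all(diff(t1s) < 0))
  expect_error(concentrationToT1(-0.1, 1000, 4), ">= 0")
  expect_error(concentrationToT1(0.1, -5, 4), "t1Baseline")
})
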