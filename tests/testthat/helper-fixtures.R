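## Shared fixtures and independent oracles. Fixtures are built in code;
## nothing is read from disk.

tiDefault <- seq(200, 1800, by = 200)

smallParams <- function(nSlices = 3L) acquisitionParams(nSlices = nSlices)

## A compact phantom: 3 slices, 48x48, 8 wedges.
smallPhantom <- function(seed = 1L, nSlices = 3L, grid = c(48L, 48L),
                         nWedges = 8L) {
  makeKidneyPhantom(nSlices, grid, nWedges, seed = seed)
}

## Phantom calibrated and simulated on the default staircase protocol.
simulatedPhantom <- function(seed = 1L, nSlices = 3L, grid = c(48L, 48L),
                             target = 0.66) {
  log <- staircaseLog()
  st <- seq(0, 70, by = 5)
  ph <- smallPhantom(seed, nSlices, grid)
  ph <- calibrateWedgeOnsets(ph, log, st, targetFraction = target)
  list(truth = simulateBackflow(ph, log, st), log = log, scanTimes = st)
}

## Independent pixel-fit oracle: exhaustive enumeration over a T1 grid with
## S0 quantised to s0step (a 2-D grid search; no golden section, no
## profiled refinement).
bruteFitT1 <- function(signal, ti, t1lo = 50, t1hi = 5000, t1step = 1,
                       s0step = 0.1) {
  t1g <- seq(t1lo, t1hi, by = t1step)
  f <- abs(1 - 2 * exp(-outer(1 / t1g, ti)))
  a <- rowSums(f * f)
  b <- as.vector(f %*% signal)
  s0 <- pmax(round((b / a) / s0step) * s0step, 0)
  rss <- sum(signal^2) - 2 * s0 * b + s0^2 * a
  i <- which.min(rss)
  list(t1 = t1g[i], s0 = s0[i], rss = rss[i])
}

## Independent motion oracle: nested-loop exhaustive correlation search on
## two gradient maps with explicit index arithmetic.
oracleShift <- function(gref, g, window = 8L) {
  nr <- nrow(gref); nc <- ncol(gref)
  best <- c(0L, 0L); bestScore <- -Inf
  for (dy in -window:window) {
    for (dx in -window:window) {
      ## overlap of gref[r, c] with g[r + dy, c + dx]
      r1 <- max(1, 1 + dy); r2 <- min(nr, nr + dy)
      c1 <- max(1, 1 + dx); c2 <- min(nc, nc + dx)
      if (r1 > r2 || c1 > c2) next
      sc <- sum(gref[(r1:r2) - dy, (c1:c2) - dx] * g[r1:r2, c1:c2])
      better <- sc > bestScore + 1e-9 ||
        (abs(sc - bestScore) <= 1e-9 &&
           dy^2 + dx^2 < best[1]^2 + best[2]^2)
      if (better) { bestScore <- sc; best <- c(dy, dx) }
    }
  }
  best
}
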