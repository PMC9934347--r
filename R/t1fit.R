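## Pixel-wise T1 estimation from magnitude inversion-recovery signals.
##
## The magnitude model S(TI) = S0 |1 - 2 exp(-TI/T1)| is non-convex in T1
## (the null-point fold), but for fixed T1 the optimal S0 >= 0 has a closed
## form, so the fit reduces to maximising the 1-D profiled objective
## q(T1) = (sum_i s_i f_i)^2 / sum_i f_i^2 with f_i = |1 - 2 exp(-TI_i/T1)|.
## A multi-start log-spaced T1 grid brackets the global maximum and a
## vectorised golden-section refinement polishes it for all pixels at once.

## f_i values for a vector of T1s: returns length(t1) x length(ti) matrix.
.irBasis <- function(t1, ti, tr = NULL) {
  m <- 1 - 2 * exp(-outer(1 / t1, ti))
  if (!is.null(tr)) m <- m + exp(-tr / t1)
  abs(m)
}

## Profiled objective and its ingredients for per-pixel T1 values.
## sigMat: nPix x nTI; t1: length nPix.
.profiledQ <- function(sigMat, t1, ti, tr = NULL) {
  m <- .irBasis(t1, ti, tr)
  b <- rowSums(sigMat * m)
  a <- rowSums(m * m)
  list(q = ifelse(a > 0, b^2 / a, 0), b = b, a = a)
}

## Vectorised fit of many pixels. Returns list(t1, s0, rss, converged).
.fitT1Engine <- function(sigMat, ti, t1Bounds = c(50, 5000), nStarts = 24L,
                         tr = NULL, refineIter = 36L) {
  nPix <- nrow(sigMat)
  if (nPix == 0L)
    return(list(t1 = numeric(), s0 = numeric(), rss = numeric(),
                converged = logical()))
  t1g <- exp(seq(log(t1Bounds[1]), log(t1Bounds[2]), length.out = nStarts))
  fg <- .irBasis(t1g, ti, tr)              # nStarts x nTI
  a <- rowSums(fg * fg)                    # per start
  bmat <- sigMat %*% t(fg)                 # nPix x nStarts
  q <- sweep(bmat^2, 2L, a, "/")
  j <- max.col(q, ties.method = "first")
  lo <- t1g[pmax(j - 1L, 1L)]
  hi <- t1g[pmin(j + 1L, nStarts)]

  gr <- (sqrt(5) - 1) / 2
  x1 <- hi - gr * (hi - lo)
  x2 <- lo + gr * (hi - lo)
  f1 <- .profiledQ(sigMat, x1, ti, tr)$q
  f2 <- .profiledQ(sigMat, x2, ti, tr)$q
  for (it in seq_len(refineIter)) {
    cond <- f1 < f2
    lo[cond] <- x1[cond]; x1[cond] <- x2[cond]; f1[cond] <- f2[cond]
    hi[!cond] <- x2[!cond]; x2[!cond] <- x1[!cond]; f2[!cond] <- f1[!cond]
    xnew <- ifelse(cond, lo + gr * (hi - lo), hi - gr * (hi - lo))
    fnew <- .profiledQ(sigMat, xnew, ti, tr)$q
    x2[cond] <- xnew[cond]; f2[cond] <- fnew[cond]
    x1[!cond] <- xnew[!cond]; f1[!cond] <- fnew[!cond]
  }
  t1 <- (lo + hi) / 2
  fin <- .profiledQ(sigMat, t1, ti, tr)
  s0 <- pmax(fin$b, 0) / fin$a
  rss <- pmax(rowSums(sigMat^2) - pmax(fin$b, 0)^2 / fin$a, 0)
  converged <- is.finite(t1) & fin$a > 0 & fin$b > 0
  t1[!converged] <- NA_real_
  s0[!converged] <- NA_real_
  list(t1 = t1, s0 = s0, rss = rss, converged = converged)
}

#' Fit T1 and S0 for a single pixel
#'
#' Least-squares fit of the magnitude inversion-recovery model
#' `S(TI) = S0 |1 - 2 exp(-TI/T1)|` to one pixel's signal over all
#' inversion times, minimising the residual sum of squares over `S0 >= 0`
#' and T1 within bounds. Initialisation is multi-start over a log-spaced T1
#' grid (the magnitude model folds at the null point `TI = T1 ln 2`, so a
#' single start is unreliable), followed by golden-section refinement of
#' the profiled 1-D objective.
#'
#' @param signal per-TI magnitudes.
#' @param tiList inversion times, ms (>= 3 points).
#' @param t1Bounds numeric(2), admissible T1 interval in ms.
#' @param nStarts number of log-spaced grid starts.
#' @param tr repetition time in ms to fit the TR-corrected model, or `NULL`.
#' @return A list with `t1` (ms), `s0`, `rss` and `converged`. An all-zero
#'   signal returns `converged = FALSE` and `NA` estimates.
#' @examples
#' s <- irSignal(1000, seq(200, 1800, 200), s0 = 100)
#' fitT1Pixel(s, seq(200, 1800, 200))$t1
#' @export
fitT1Pixel <- function(signal, tiList, t1Bounds = c(50, 5000),
                       nStarts = 24L, tr = NULL) {
  if (length(signal) != length(tiList))
    stop("signal and tiList lengths differ")
  if (length(tiList) < 3L) stop("need at least 3 TI points")
  if (any(t1Bounds <= 0) || t1Bounds[1] >= t1Bounds[2])
    stop("t1Bounds must be a positive increasing interval")
  fit <- .fitT1Engine(matrix(signal, 1L), tiList, t1Bounds, nStarts, tr)
  lapply(fit, `[`, 1L)
}

#' Fit a per-pixel T1 map from an inversion-recovery series
#'
#' Runs the pixel fit over every pixel whose peak signal across inversion
#' times exceeds `signalFloor` times the series maximum (air and other
#' signal-free pixels are marked invalid, not fitted), honouring the
#' series' validity mask from motion correction. Deterministic given its
#' input.
#'
#' @param series a motion-corrected [IRSeries-class].
#' @param signalFloor fraction of the series maximum below which a pixel is
#'   considered signal-free.
#' @param t1Bounds admissible T1 interval, ms.
#' @param nStarts number of multi-start grid points.
#' @param trCorrected logical; fit the TR-corrected three-parameter model
#'   using the series' TR.
#' @return A [T1Map-class].
#' @export
fitT1Map <- function(series, signalFloor = 0.10, t1Bounds = c(50, 5000),
                     nStarts = 24L, trCorrected = FALSE) {
  d <- dim(series@images)
  if (length(series@images) == 0L || any(d == 0L)) stop("empty series")
  ti <- series@params@tiList
  tr <- if (trCorrected) series@params@tr else NULL
  floorVal <- signalFloor * max(series@images)

  shape <- d[c(1, 3, 4)]
  t1 <- array(NA_real_, shape)
  s0 <- array(NA_real_, shape)
  rss <- array(NA_real_, shape)
  valid <- array(FALSE, shape)
  for (s in seq_len(d[1])) {
    ## [ti, row, col] -> pixels x nTI
    sl <- matrix(aperm(series@images[s, , , , drop = FALSE][1, , , ],
                       c(2, 3, 1)), ncol = d[2])
    peak <- apply(sl, 1L, max)
    cand <- peak > floorVal & as.vector(series@valid)
    fit <- .fitT1Engine(sl[cand, , drop = FALSE], ti, t1Bounds, nStarts, tr)
    t1s <- rep(NA_real_, nrow(sl)); s0s <- t1s; rsss <- t1s
    vs <- rep(FALSE, nrow(sl))
    t1s[cand] <- fit$t1; s0s[cand] <- fit$s0; rsss[cand] <- fit$rss
    vs[cand] <- fit$converged
    t1[s, , ] <- t1s; s0[s, , ] <- s0s; rss[s, , ] <- rsss
    valid[s, , ] <- vs
  }
  new("T1Map", t1 = t1, s0 = s0, rss = rss, valid = valid,
      timeMin = series@timeMin, pressureMmHg = series@pressureMmHg)
}
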