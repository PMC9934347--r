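## Digital kidney phantom: ground-truth geometry, wedge decomposition of the
## cortex, and pressure-driven backflow simulation.

.tissueNames <- c("background", "cortex", "medulla", "renal_pelvis",
                  "dorsal_muscle")

#' Default baseline T1 per tissue (ms)
#'
#' Native longitudinal relaxation times used by the phantom: renal cortex
#' 1000 ms, medulla 1400 ms, pelvic fluid 2400 ms, dorsal muscle 900 ms.
#' Background (air) has no signal and carries `NA`.
#'
#' @return Named numeric vector, one entry per tissue label name.
#' @export
defaultBaselineT1 <- function() {
  c(background = NA_real_, cortex = 1000, medulla = 1400,
    renal_pelvis = 2400, dorsal_muscle = 900)
}

#' Default equilibrium signal per tissue (arbitrary units)
#' @return Named numeric vector, one entry per tissue label name.
#' @export
defaultS0 <- function() {
  c(background = 0, cortex = 100, medulla = 95,
    renal_pelvis = 90, dorsal_muscle = 85)
}

#' Generate a ground-truth digital kidney phantom
#'
#' Builds a multi-slice ellipsoidal kidney with a cortical shell, medulla,
#' central renal pelvis, and a dorsal muscle slab near one image edge. The
#' cortical shell is partitioned into `nWedges` contiguous angular wedges
#' (digital stand-ins for the pyramid/calyceal units through which backflow
#' enters), and every wedge receives an activation threshold in accumulated
#' pressure (mmHg·min). Thresholds are ordered so the two polar wedges (the
#' upper and lower pole, where backflow appears first) have the lowest
#' values and equatorial wedges the highest.
#'
#' The kidney long axis runs along image rows; slice cross-sections shrink
#' towards the outer slices. The seed jitters the kidney centre and axes so
#' different subjects differ geometrically.
#'
#' @param nSlices number of slices.
#' @param gridShape integer(2), rows x cols; at least 32 x 32.
#' @param nWedges number of cortical wedges, >= 2.
#' @param seed integer seed for the geometric jitter.
#' @param baselineT1 named per-tissue baseline T1 table, ms.
#' @param s0Table named per-tissue equilibrium signal table.
#' @param onsetRange numeric(2), default span of wedge activation thresholds
#'   in mmHg·min (lowest wedge near the accumulated pressure at which first
#'   visual change is expected).
#' @return A [PhantomTruth-class] (time-resolved fields empty until
#'   [simulateBackflow()] is run).
#' @examples
#' ph <- makeKidneyPhantom(3, c(48, 48), 8, seed = 1)
#' table(labelMap(ph))
#' @export
makeKidneyPhantom <- function(nSlices = 7L, gridShape = c(64L, 64L),
                              nWedges = 8L, seed = 1L,
                              baselineT1 = defaultBaselineT1(),
                              s0Table = defaultS0(),
                              onsetRange = c(70, 3200)) {
  nr <- gridShape[1]; nc <- gridShape[2]
  if (nr < 32L || nc < 32L)
    stop("gridShape must be at least 32x32 (got ", nr, "x", nc, ")")
  if (nWedges < 2L) stop("nWedges must be >= 2")
  stopifnot(nSlices >= 1L)

  jit <- withSeed(seed, list(
    dr = runif(1, -1.5, 1.5), dc = runif(1, -1.5, 1.5),
    ar = runif(1, 0.95, 1.05), ac = runif(1, 0.95, 1.05)
  ))
  cr <- (nr + 1) / 2 + jit$dr
  cc <- (nc + 1) / 2 + jit$dc
  semiRow <- 0.31 * nr * jit$ar   # long axis along rows
  semiCol <- 0.16 * nc * jit$ac

  labels <- array(0L, c(nSlices, nr, nc))
  wedges <- array(0L, c(nSlices, nr, nc))
  rowIdx <- matrix(seq_len(nr), nr, nc)
  colIdx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  width <- 2 * pi / nWedges
  cs <- (nSlices + 1) / 2
  hs <- (nSlices + 1) / 2

  for (s in seq_len(nSlices)) {
    scale <- sqrt(pmax(0, 1 - ((s - cs) / hs)^2))
    if (scale <= 0) next
    drn <- (rowIdx - cr) / (semiRow * scale)
    dcn <- (colIdx - cc) / (semiCol * scale)
    r <- sqrt(drn^2 + dcn^2)
    sl <- matrix(0L, nr, nc)
    sl[r <= 1] <- 1L                    # cortex (outer shell)
    sl[r <= 0.62] <- 2L                 # medulla
    sl[r <= 0.25] <- 3L                 # renal pelvis
    ## dorsal muscle slab along the left image edge
    mrow <- rowIdx >= round(0.2 * nr) & rowIdx <= round(0.8 * nr)
    mcol <- colIdx >= 3 & colIdx <= 6
    sl[mrow & mcol & sl == 0L] <- 4L
    labels[s, , ] <- sl
    ## angular wedge id for cortical pixels; sector centres at multiples of
    ## 2*pi/nWedges so sectors 1 and nWedges/2+1 sit on the poles
    theta <- atan2(dcn, drn)
    wid <- (round(theta / width) %% nWedges) + 1L
    w <- matrix(as.integer(wid), nr, nc)
    w[sl != 1L] <- 0L
    wedges[s, , ] <- w
  }

  nCortex <- sum(labels == 1L)
  if (nCortex < nWedges)
    stop("nWedges (", nWedges, ") exceeds cortical pixel count (", nCortex, ")")
  ## guarantee every wedge id occurs; degenerate geometries reject
  if (length(unique(wedges[wedges > 0L])) < nWedges)
    stop("grid too small to resolve ", nWedges,
         " wedges; enlarge gridShape (minimum 32x32) or reduce nWedges")

  ## onset thresholds: rank wedges by polarity of their sector centre
  centres <- ((seq_len(nWedges) - 1L) * width)
  centres <- ifelse(centres > pi, centres - 2 * pi, centres)
  rank <- order(-abs(cos(centres)), seq_len(nWedges))
  onsets <- numeric(nWedges)
  onsets[rank] <- seq(onsetRange[1], onsetRange[2], length.out = nWedges)

  names(baselineT1) <- .tissueNames[seq_along(baselineT1)]
  names(s0Table) <- .tissueNames[seq_along(s0Table)]
  new("PhantomTruth", labelMap = labels, baselineT1 = baselineT1,
      s0Table = s0Table, wedgeIds = wedges, wedgeOnsetAupi = onsets)
}

#' Recalibrate wedge onsets to reach a target end-scan affected fraction
#'
#' Keeps the wedge activation order (polar wedges first) but respaces the
#' thresholds so that, under the given pressure log and scan schedule, the
#' wedges affected by the final scan cover a cortical pixel fraction as
#' close as possible to `targetFraction`. Activated wedges get thresholds
#' spread linearly from `firstOnset` to `spreadFraction` times the final
#' accumulated pressure; the remaining wedges get thresholds beyond reach.
#'
#' @param truth a [PhantomTruth-class].
#' @param log a [PressureLog-class].
#' @param scanTimes scan times in minutes.
#' @param targetFraction target affected fraction of cortex at the last scan.
#' @param firstOnset threshold of the first (polar) wedge, mmHg·min.
#' @param spreadFraction highest activated threshold as a fraction of the
#'   final accumulated pressure.
#' @return The phantom with `wedgeOnsetAupi` replaced.
#' @export
calibrateWedgeOnsets <- function(truth, log, scanTimes, targetFraction = 0.66,
                                 firstOnset = 70, spreadFraction = 0.85) {
  aupiEnd <- accumulatedPressure(log, max(scanTimes))
  if (firstOnset > aupiEnd)
    stop("firstOnset exceeds the accumulated pressure at the last scan")
  onsets <- truth@wedgeOnsetAupi
  ord <- order(onsets, seq_along(onsets))
  counts <- tabulate(truth@wedgeIds[truth@wedgeIds > 0L], length(onsets))
  cumfrac <- cumsum(counts[ord]) / sum(counts)
  k <- which.min(abs(cumfrac - targetFraction))
  newOnsets <- numeric(length(onsets))
  hi <- max(firstOnset, spreadFraction * aupiEnd)
  newOnsets[ord] <- c(
    if (k == 1L) firstOnset else seq(firstOnset, hi, length.out = k),
    rep(2 * aupiEnd + seq_len(length(onsets) - k) * aupiEnd,
        length.out = length(onsets) - k)
  )
  truth@wedgeOnsetAupi <- newOnsets
  validObject(truth)
  truth
}

#' Simulate pressure-driven backflow into the phantom cortex
#'
#' Accumulated pressure (AUPI, the time integral of intrarenal pressure in
#' mmHg·min) drives wedge activation: wedge `w` becomes affected at the
#' first scan time where AUPI >= its onset threshold and stays affected
#' thereafter. Once active, the wedge's gadolinium concentration rises
#' linearly in excess accumulated pressure and saturates at `cMax`:
#' `c = min(cMax, spreadRate * (AUPI - onset))`. The renal pelvis holds
#' irrigation fluid at `pelvisConc` from the first post-baseline scan
#' onwards; all other tissue stays gadolinium-free.
#'
#' @param truth a [PhantomTruth-class].
#' @param log a [PressureLog-class] covering all scan times.
#' @param scanTimes strictly increasing scan times, minutes.
#' @param spreadRate concentration growth per excess mmHg·min, mmol/L.
#' @param cMax saturation concentration in affected tissue, mmol/L.
#' @param pelvisConc irrigation-fluid concentration in the pelvis, mmol/L.
#' @return The phantom with `scanTimes`, `aupiAtScan`, `concentration` and
#'   `affectedTruth` filled.
#' @export
simulateBackflow <- function(truth, log, scanTimes, spreadRate = 0.5,
                             cMax = 1.0, pelvisConc = 1.5) {
  if (nrow(logSamples(log)) == 0L) stop("empty pressure log")
  if (length(scanTimes) == 0L) stop("scanTimes must be non-empty")
  if (is.unsorted(scanTimes, strictly = TRUE))
    stop("scanTimes must be strictly increasing (sorted)")
  if (spreadRate <= 0) stop("spreadRate must be > 0")
  tms <- logSamples(log)$time_min
  if (min(scanTimes) < min(tms) || max(scanTimes) > max(tms))
    stop("scanTimes must lie within the pressure log time span")

  aupi <- vapply(scanTimes, function(t) accumulatedPressure(log, t), 0.0)
  d <- dim(truth@labelMap)
  nScan <- length(scanTimes)
  conc <- array(0, c(nScan, d))
  aff <- array(FALSE, c(nScan, d))
  pelvis <- truth@labelMap == 3L
  for (k in seq_len(nScan)) {
    ck <- array(0, d)
    ak <- array(FALSE, d)
    for (w in seq_along(truth@wedgeOnsetAupi)) {
      onset <- truth@wedgeOnsetAupi[w]
      if (aupi[k] >= onset) {
        px <- truth@wedgeIds == w
        ak[px] <- TRUE
        ck[px] <- min(cMax, spreadRate * (aupi[k] - onset))
      }
    }
    if (scanTimes[k] > 0) ck[pelvis] <- pelvisConc
    conc[k, , , ] <- ck
    aff[k, , , ] <- ak
  }
  truth@scanTimes <- as.numeric(scanTimes)
  truth@aupiAtScan <- aupi
  truth@concentration <- conc
  truth@affectedTruth <- aff
  validObject(truth)
  truth
}

#' Gadolinium-shortened T1 from concentration
#'
#' Standard fast-exchange longitudinal relaxivity model:
#' `1/T1 = 1/T1_baseline + r1 * c`, with `r1` in L·mmol⁻¹·s⁻¹ and T1 in ms
#' (the `/1000` converts the relaxivity term to per-ms). Strictly
#' decreasing in concentration.
#'
#' @param c gadolinium concentration, mmol/L (vectorised, >= 0).
#' @param t1Baseline native T1, ms (> 0).
#' @param r1 longitudinal relaxivity, L·mmol⁻¹·s⁻¹ (> 0).
#' @return T1 in ms.
#' @examples
#' concentrationToT1(0.25, 1000, 4)  # 500 ms
#' @export
concentrationToT1 <- function(c, t1Baseline, r1 = 4.0) {
  if (any(c < 0, na.rm = TRUE)) stop("concentration must be >= 0")
  if (any(t1Baseline <= 0, na.rm = TRUE)) stop("t1Baseline must be > 0")
  if (any(r1 <= 0)) stop("r1 must be > 0")
  1 / (1 / t1Baseline + r1 * c / 1000)
}

#' Ground-truth T1 grid at one scan
#'
#' Per-pixel T1 combining each tissue's baseline with gadolinium shortening
#' from the simulated concentration at the requested scan. Background is
#' `NA` (no signal).
#'
#' @param truth a simulated [PhantomTruth-class].
#' @param scanIndex scan index into `scanTimes(truth)`.
#' @param r1 longitudinal relaxivity, L·mmol⁻¹·s⁻¹.
#' @return Numeric `[slice, row, col]` array of T1 in ms.
#' @export
truthT1Grid <- function(truth, scanIndex, r1 = 4.0) {
  d <- dim(truth@labelMap)
  base <- array(truth@baselineT1[truth@labelMap + 1L], d)
  if (length(truth@scanTimes) == 0L)
    stop("phantom has no simulated scans; run simulateBackflow() first")
  stopifnot(scanIndex >= 1L, scanIndex <= length(truth@scanTimes))
  conc <- array(truth@concentration[scanIndex, , , ], d)
  out <- base
  hasGd <- conc > 0 & !is.na(base)
  out[hasGd] <- concentrationToT1(conc[hasGd], base[hasGd], r1)
  out
}

#' Ground-truth equilibrium-signal grid
#'
#' @param truth a [PhantomTruth-class].
#' @return Numeric `[slice, row, col]` array of S0 (0 in background).
#' @export
truthS0Grid <- function(truth) {
  d <- dim(truth@labelMap)
  array(truth@s0Table[truth@labelMap + 1L], d)
}

#' Regions of interest from phantom ground truth
#'
#' Builds the conventional backflow ROI set from truth labels: total cortex,
#' medulla, renal pelvis and dorsal muscle from the tissue labels;
#' `cortex_1..4` as the (up to) four earliest-activating cortical wedges;
#' and `cortex_remote` as the cortex belonging to wedges that never activate
#' within the simulated scan window (the visibly non-affected area).
#'
#' @param truth a [PhantomTruth-class], simulated if remote/affected ROIs are
#'   wanted.
#' @return An [ROISet-class].
#' @export
phantomROISet <- function(truth) {
  lab <- truth@labelMap
  masks <- list(
    cortex_total = lab == 1L,
    medulla = lab == 2L,
    renal_pelvis = lab == 3L,
    dorsal_muscle = lab == 4L
  )
  onsets <- truth@wedgeOnsetAupi
  if (length(truth@aupiAtScan)) {
    maxAupi <- max(truth@aupiAtScan)
    act <- which(onsets <= maxAupi)
    act <- act[order(onsets[act])]
    for (i in seq_len(min(4L, length(act)))) {
      masks[[paste0("cortex_", i)]] <- truth@wedgeIds == act[i]
    }
    never <- which(onsets > maxAupi)
    masks[["cortex_remote"]] <-
      array(truth@wedgeIds %in% never, dim(lab)) & masks[["cortex_total"]]
  }
  roiSet(masks)
}
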