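## Identification and quantification of backflow-affected renal cortex from
## serial T1 maps. Gadolinium shortens T1, so affected cortex shows a
## relative T1 DROP versus the pre-irrigation baseline scan and appears dark
## on T1 maps.

#' Segment backflow-affected cortex in one scan
#'
#' A pixel is affected iff it is valid in both maps, lies within the cortex
#' mask, and its T1 has dropped below `(1 - relDrop)` times its baseline
#' value. Connected components smaller than `minCluster` pixels are removed
#' (4-connectivity, in-plane per slice) to suppress isolated noise pixels.
#'
#' @param current [T1Map-class] of the scan under test.
#' @param baseline [T1Map-class] of the pre-irrigation baseline scan.
#' @param cortex logical `[slice, row, col]` cortex mask (non-empty).
#' @param relDrop relative T1 drop defining "affected", in (0, 1).
#' @param minCluster minimum connected-component size in pixels.
#' @return Logical `[slice, row, col]` affected mask.
#' @export
segmentAffected <- function(current, baseline, cortex, relDrop = 0.30,
                            minCluster = 5L) {
  stopifnot(identical(dim(current@t1), dim(baseline@t1)))
  if (!identical(dim(cortex), dim(current@t1)))
    stop("cortex mask shape does not match the maps")
  if (!any(cortex)) stop("empty cortex mask")
  if (relDrop <= 0 || relDrop >= 1) stop("relDrop must lie in (0, 1)")

  ok <- current@valid & baseline@valid & cortex
  mask <- array(FALSE, dim(cortex))
  mask[ok] <- current@t1[ok] < (1 - relDrop) * baseline@t1[ok]
  if (minCluster > 1L) {
    for (s in seq_len(dim(mask)[1])) {
      sl <- mask[s, , ]
      if (!any(sl)) next
      lab <- EBImage::bwlabel(sl * 1)
      keep <- which(tabulate(lab[lab > 0]) >= minCluster)
      mask[s, , ] <- array(lab %in% keep, dim(sl))
    }
  }
  mask
}

#' Affected fraction of cortex
#'
#' `|mask ∩ cortex| / |cortex|`, pooled over all slices.
#'
#' @param mask logical affected mask.
#' @param cortex logical cortex mask, non-empty.
#' @return Fraction in `[0, 1]`.
#' @export
affectedFraction <- function(mask, cortex) {
  if (!any(cortex)) stop("empty cortex mask")
  sum(mask & cortex) / sum(cortex)
}

#' Detect the first scan with visible change
#'
#' Scans are assumed time-ordered; the first scan whose affected mask holds
#' at least `minArea` pixels is reported together with its time and the
#' concurrent pressure. Returns `NA` fields if the criterion is never met.
#'
#' @param masks list of logical affected masks, one per scan, time-ordered.
#' @param timesMin per-scan times, minutes.
#' @param pressuresMmHg per-scan concurrent pressures.
#' @param minArea minimum affected area in pixels.
#' @return List with `scan`, `timeMin`, `pressureMmHg` (all `NA` if never
#'   reached).
#' @export
detectFirstChange <- function(masks, timesMin, pressuresMmHg, minArea = 5L) {
  stopifnot(length(masks) == length(timesMin),
            length(masks) == length(pressuresMmHg))
  for (k in seq_along(masks)) {
    if (sum(masks[[k]]) >= minArea)
      return(list(scan = k, timeMin = timesMin[k],
                  pressureMmHg = pressuresMmHg[k]))
  }
  list(scan = NA_integer_, timeMin = NA_real_, pressureMmHg = NA_real_)
}

#' Full backflow quantification over a scan series
#'
#' Segments every scan against the baseline, computes the affected cortical
#' fraction per scan, and detects the first scan with visible change.
#'
#' @param maps list of [T1Map-class], time-ordered (including the baseline
#'   scan itself, whose mask is empty by construction).
#' @param baseline the baseline (pre-irrigation) [T1Map-class].
#' @param cortex logical cortex mask.
#' @inheritParams segmentAffected
#' @inheritParams detectFirstChange
#' @return An [AffectedResult-class].
#' @export
analyzeBackflow <- function(maps, baseline, cortex, relDrop = 0.30,
                            minCluster = 5L, minArea = 5L) {
  masks <- lapply(maps, segmentAffected, baseline = baseline,
                  cortex = cortex, relDrop = relDrop,
                  minCluster = minCluster)
  times <- vapply(maps, scanTime, 0.0)
  press <- vapply(maps, scanPressure, 0.0)
  fc <- detectFirstChange(masks, times, press, minArea)
  new("AffectedResult", affectedMasks = masks,
      fraction = vapply(masks, affectedFraction, 0.0, cortex = cortex),
      timesMin = times, pressuresMmHg = press,
      firstChangeScan = as.integer(fc$scan),
      firstChangeTime = as.numeric(fc$timeMin),
      firstChangePressure = as.numeric(fc$pressureMmHg))
}

#' Mean T1 per region of interest over serial scans
#'
#' Mean T1 over the valid pixels of each ROI for every scan. An ROI with no
#' valid pixel in a given map yields `NA` for that scan (missing, not
#' zero).
#'
#' @param maps list of [T1Map-class], time-ordered.
#' @param rois an [ROISet-class] on the maps' grid.
#' @return Numeric matrix, scans x ROIs, with scan times as rownames.
#' @export
roiT1Series <- function(maps, rois) {
  masks <- roiMasks(rois)
  out <- matrix(NA_real_, length(maps), length(masks),
                dimnames = list(vapply(maps, scanTime, 0.0), names(masks)))
  for (k in seq_along(maps)) {
    m <- maps[[k]]
    for (j in seq_along(masks)) {
      sel <- masks[[j]] & m@valid
      if (any(sel)) out[k, j] <- mean(m@t1[sel])
    }
  }
  out
}
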