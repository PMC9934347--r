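#' @import methods
#' @importFrom stats approx optimize rnorm runif setNames
#' @importFrom utils read.csv write.csv packageVersion head tail
NULL

## Arrays follow the (slice, row, col) convention, 0 time/TI axes prepended
## where needed; row 1 is the image top and the kidney long axis runs along
## rows, so "upper pole" means low row indices.

#' Acquisition parameters of an inversion-recovery series
#'
#' Geometry and timing of a single-shot inversion-recovery spin-echo
#' acquisition: the inversion times sampled, repetition and echo time, slice
#' geometry and the interval between serial scans.
#'
#' @slot tiList numeric, inversion times in ms, strictly increasing.
#' @slot tr numeric(1), repetition time in ms.
#' @slot te numeric(1), echo time in ms.
#' @slot nSlices integer(1), number of slices.
#' @slot sliceThickness numeric(1), slice thickness in mm.
#' @slot pixelSize numeric(1), in-plane pixel size in mm (square pixels).
#' @slot scanInterval numeric(1), minutes between serial scans.
#'
#' @export
setClass("AcquisitionParams",
  representation(
    tiList = "numeric", tr = "numeric", te = "numeric",
    nSlices = "integer", sliceThickness = "numeric",
    pixelSize = "numeric", scanInterval = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character()
  if (length(object@tiList) < 1L || any(object@tiList <= 0))
    msg <- c(msg, "tiList must be positive")
  if (is.unsorted(object@tiList, strictly = TRUE))
    msg <- c(msg, "tiList must be strictly increasing")
  for (s in c("tr", "te", "sliceThickness", "pixelSize", "scanInterval")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number", s))
  }
  if (object@nSlices < 1L) msg <- c(msg, "nSlices must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct acquisition parameters
#'
#' Defaults reproduce the acquisition used throughout the package: TI sampled
#' from 200 to 1800 ms, TR 5 s, TE 20 ms, seven 5 mm slices with 3x3 mm
#' pixels, and scans repeated every 5 minutes.
#'
#' @param tiList inversion times in ms, strictly increasing.
#' @param tr repetition time, ms.
#' @param te echo time, ms.
#' @param nSlices number of slices.
#' @param sliceThickness slice thickness, mm.
#' @param pixelSize in-plane pixel size, mm.
#' @param scanInterval minutes between serial scans.
#' @return An [AcquisitionParams-class] object.
#' @examples
#' acquisitionParams()
#' @export
acquisitionParams <- function(tiList = seq(200, 1800, by = 200), tr = 5000,
                              te = 20, nSlices = 7L, sliceThickness = 5,
                              pixelSize = 3, scanInterval = 5) {
  new("AcquisitionParams",
    tiList = as.numeric(tiList), tr = as.numeric(tr), te = as.numeric(te),
    nSlices = as.integer(nSlices), sliceThickness = as.numeric(sliceThickness),
    pixelSize = as.numeric(pixelSize), scanInterval = as.numeric(scanInterval)
  )
}

#' One inversion-recovery scan
#'
#' Magnitude images of one scan over all inversion times, indexed
#' `[slice, tiIndex, row, col]`, together with acquisition parameters, the
#' scan's time since irrigation start and the concurrent intrarenal pressure.
#' `valid` is an in-plane logical matrix marking pixels whose value is
#' trustworthy at every TI (motion correction marks pixels dragged in from
#' outside the field of view invalid).
#'
#' @slot images 4-D numeric array `[slice, ti, row, col]`, non-negative.
#' @slot params an [AcquisitionParams-class].
#' @slot timeMin numeric(1), minutes since irrigation start.
#' @slot pressureMmHg numeric(1), concurrent intrarenal pressure.
#' @slot valid logical matrix `[row, col]`.
#'
#' @export
setClass("IRSeries",
  representation(
    images = "array", params = "AcquisitionParams",
    timeMin = "numeric", pressureMmHg = "numeric", valid = "matrix"
  )
)

setValidity("IRSeries", function(object) {
  d <- dim(object@images)
  if (length(d) != 4L)
    return("images must be a 4-D array [slice, ti, row, col]")
  if (d[2] != length(object@params@tiList))
    return("images ti axis length must equal length(tiList)")
  if (d[1] != object@params@nSlices)
    return("images slice axis length must equal nSlices")
  if (any(object@images < 0, na.rm = TRUE))
    return("magnitude images must be non-negative")
  if (!identical(dim(object@valid), d[3:4]))
    return("valid mask must be a [row, col] matrix matching the images")
  TRUE
})

#' Construct an inversion-recovery series
#'
#' @param images 4-D array `[slice, ti, row, col]` of magnitudes.
#' @param params an [AcquisitionParams-class].
#' @param timeMin scan time, minutes since irrigation start.
#' @param pressureMmHg concurrent intrarenal pressure.
#' @param valid optional `[row, col]` logical validity matrix (default all
#'   `TRUE`).
#' @return An [IRSeries-class] object.
#' @export
irSeries <- function(images, params, timeMin = 0, pressureMmHg = 0,
                     valid = NULL) {
  if (is.null(valid))
    valid <- matrix(TRUE, dim(images)[3], dim(images)[4])
  new("IRSeries", images = images, params = params,
      timeMin = as.numeric(timeMin), pressureMmHg = as.numeric(pressureMmHg),
      valid = valid)
}

#' Ground truth of a digital kidney phantom
#'
#' Tissue labels, wedge decomposition of the cortex, per-tissue baseline T1,
#' and (after [simulateBackflow()]) time-resolved gadolinium concentration and
#' affected masks at each scan time.
#'
#' Labels: 0 background, 1 cortex, 2 medulla, 3 renal pelvis, 4 dorsal muscle.
#'
#' @slot labelMap integer array `[slice, row, col]`.
#' @slot baselineT1 named numeric, baseline T1 in ms per tissue label name.
#' @slot s0Table named numeric, equilibrium signal per tissue label name.
#' @slot wedgeIds integer array `[slice, row, col]`; cortical pixels carry a
#'   wedge id in `1..nWedges`, all other pixels 0.
#' @slot wedgeOnsetAupi numeric, per-wedge activation threshold in mmHg·min.
#' @slot scanTimes numeric, scan times in minutes (filled by simulation).
#' @slot aupiAtScan numeric, accumulated pressure at each scan time.
#' @slot concentration 4-D numeric array `[scan, slice, row, col]`, mmol/L.
#' @slot affectedTruth 4-D logical array `[scan, slice, row, col]`.
#'
#' @export
setClass("PhantomTruth",
  representation(
    labelMap = "array", baselineT1 = "numeric", s0Table = "numeric",
    wedgeIds = "array", wedgeOnsetAupi = "numeric",
    scanTimes = "numeric", aupiAtScan = "numeric",
    concentration = "array", affectedTruth = "array"
  ),
  prototype(
    scanTimes = numeric(), aupiAtScan = numeric(),
    concentration = array(0, c(0, 0, 0, 0)),
    affectedTruth = array(FALSE, c(0, 0, 0, 0))
  )
)

setValidity("PhantomTruth", function(object) {
  msg <- character()
  cortex <- object@labelMap == 1L
  if (!all(object@wedgeIds[cortex] >= 1L))
    msg <- c(msg, "every cortical pixel must belong to a wedge")
  if (!all(object@wedgeIds[!cortex] == 0L))
    msg <- c(msg, "non-cortical pixels must have wedge id 0")
  if (length(object@wedgeOnsetAupi) > 0 &&
      max(object@wedgeIds) > length(object@wedgeOnsetAupi))
    msg <- c(msg, "wedge ids exceed onset table length")
  if (length(object@scanTimes) &&
      dim(object@affectedTruth)[1] == length(object@scanTimes)) {
    nS <- length(object@scanTimes)
    if (nS > 1) {
      for (k in seq_len(nS - 1)) {
        if (any(object@affectedTruth[k, , , ] & !object@affectedTruth[k + 1, , , ]))
          msg <- c(msg, "affectedTruth must be monotone non-decreasing in time")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Per-pixel T1 map
#'
#' Result of fitting the magnitude inversion-recovery signal model pixel by
#' pixel: estimated T1 and S0, residual sum of squares, and a validity mask
#' (false where the fit failed, the signal sat below the floor, or motion
#' correction invalidated the pixel).
#'
#' @slot t1 numeric array `[slice, row, col]`, ms; `NA` where invalid.
#' @slot s0 numeric array `[slice, row, col]`, signal units.
#' @slot rss numeric array `[slice, row, col]`, residual sum of squares.
#' @slot valid logical array `[slice, row, col]`.
#' @slot timeMin numeric(1), scan time of the underlying series.
#' @slot pressureMmHg numeric(1), concurrent pressure.
#'
#' @export
setClass("T1Map",
  representation(
    t1 = "array", s0 = "array", rss = "array", valid = "array",
    timeMin = "numeric", pressureMmHg = "numeric"
  )
)

setValidity("T1Map", function(object) {
  if (!identical(dim(object@t1), dim(object@valid)) ||
      !identical(dim(object@t1), dim(object@s0)) ||
      !identical(dim(object@t1), dim(object@rss)))
    return("t1, s0, rss and valid must share one [slice, row, col] shape")
  if (any(object@t1[object@valid] <= 0, na.rm = TRUE))
    return("t1 must be positive wherever valid")
  TRUE
})

#' Rigid in-plane motion estimate for one series
#'
#' Integer-pixel (dy, dx) translation of every TI frame relative to the
#' reference TI frame; the reference frame's shift is (0, 0) by construction.
#'
#' @slot shifts integer matrix `[nTI, 2]`, columns `dy`, `dx`.
#' @slot referenceTiIndex integer(1).
#'
#' @export
setClass("MotionEstimate",
  representation(shifts = "matrix", referenceTiIndex = "integer")
)

setValidity("MotionEstimate", function(object) {
  if (ncol(object@shifts) != 2L) return("shifts must have two columns (dy, dx)")
  r <- object@referenceTiIndex
  if (r < 1L || r > nrow(object@shifts))
    return("referenceTiIndex out of range")
  if (any(object@shifts[r, ] != 0L))
    return("shift at the reference TI must be (0, 0)")
  TRUE
})

#' Named regions of interest over the image grid
#'
#' Masks are logical `[slice, row, col]` arrays. The conventional set for a
#' backflow study holds `cortex_total`, `cortex_remote` (visibly non-affected
#' cortex), `cortex_1`..`cortex_4` (visibly affected cortical areas),
#' `medulla`, `renal_pelvis` and `dorsal_muscle`.
#'
#' @slot masks named list of logical arrays sharing one shape.
#'
#' @export
setClass("ROISet", representation(masks = "list"))

setValidity("ROISet", function(object) {
  if (length(object@masks) == 0) return("at least one ROI mask required")
  if (is.null(names(object@masks)) || any(!nzchar(names(object@masks))))
    return("all ROI masks must be named")
  d <- dim(object@masks[[1]])
  for (m in object@masks) {
    if (!is.logical(m) || !identical(dim(m), d))
      return("ROI masks must be logical arrays of one common shape")
  }
  nm <- names(object@masks)
  sub <- grep("^cortex_[0-9]+$", nm, value = TRUE)
  if ("cortex_total" %in% nm) {
    tot <- object@masks[["cortex_total"]]
    for (s in c(sub, intersect("cortex_remote", nm))) {
      if (any(object@masks[[s]] & !tot))
        return(sprintf("%s must be a subset of cortex_total", s))
    }
  }
  if ("cortex_remote" %in% nm) {
    rem <- object@masks[["cortex_remote"]]
    for (s in sub) {
      if (any(object@masks[[s]] & rem))
        return(sprintf("cortex_remote overlaps %s", s))
    }
  }
  TRUE
})

#' @rdname ROISet-class
#' @param masks named list of logical `[slice, row, col]` arrays.
#' @return An [ROISet-class].
#' @export
roiSet <- function(masks) new("ROISet", masks = masks)

#' Intrarenal pressure log of one subject
#'
#' Sampled intrarenal pressure versus time since irrigation start. Pressure
#' between samples is interpreted as piecewise linear, which makes the
#' accumulated pressure (AUPI) integral exact for staircase protocols with
#' linear transitions.
#'
#' @slot samples data.frame with columns `time_min` (strictly increasing) and
#'   `pressure_mmHg` (non-negative).
#' @slot subjectId character(1).
#'
#' @export
setClass("PressureLog",
  representation(samples = "data.frame", subjectId = "character")
)

setValidity("PressureLog", function(object) {
  s <- object@samples
  if (!all(c("time_min", "pressure_mmHg") %in% names(s)))
    return("samples needs columns time_min and pressure_mmHg")
  if (nrow(s) < 1L) return("log must contain at least one sample")
  if (is.unsorted(s$time_min, strictly = TRUE))
    return("sample times must be strictly increasing")
  if (any(s$pressure_mmHg < 0)) return("pressures must be >= 0")
  TRUE
})

#' Construct a pressure log
#'
#' @param timeMin sample times in minutes, strictly increasing.
#' @param pressureMmHg pressures in mmHg, non-negative.
#' @param subjectId subject label.
#' @return A [PressureLog-class].
#' @examples
#' pressureLog(c(0, 60), c(20, 20))
#' @export
pressureLog <- function(timeMin, pressureMmHg, subjectId = "") {
  new("PressureLog",
    samples = data.frame(time_min = as.numeric(timeMin),
                         pressure_mmHg = as.numeric(pressureMmHg)),
    subjectId = as.character(subjectId))
}

#' Backflow quantification over a scan series
#'
#' Per-scan affected masks, the affected fraction of cortex, and the first
#' scan at which the affected area reached the minimum-area criterion (with
#' that scan's time and concurrent pressure); the first-change fields are
#' `NA` if the criterion is never met.
#'
#' @slot affectedMasks list of logical `[slice, row, col]` arrays, one per scan.
#' @slot fraction numeric per-scan affected fraction in `[0, 1]`.
#' @slot timesMin numeric per-scan times.
#' @slot pressuresMmHg numeric per-scan pressures.
#' @slot firstChangeScan integer(1) or `NA`.
#' @slot firstChangeTime numeric(1) or `NA`.
#' @slot firstChangePressure numeric(1) or `NA`.
#'
#' @export
setClass("AffectedResult",
  representation(
    affectedMasks = "list", fraction = "numeric", timesMin = "numeric",
    pressuresMmHg = "numeric", firstChangeScan = "integer",
    firstChangeTime = "numeric", firstChangePressure = "numeric"
  )
)

setValidity("AffectedResult", function(object) {
  if (any(object@fraction < 0 | object@fraction > 1, na.rm = TRUE))
    return("fractions must lie in [0, 1]")
  n <- length(object@affectedMasks)
  if (length(object@fraction) != n || length(object@timesMin) != n)
    return("per-scan fields must have one entry per scan")
  TRUE
})

#' Cross-subject study summary
#'
#' Per-subject endpoint records plus, for every numeric endpoint, the
#' arithmetic mean, the (min, max) range, and the mean rounded to reporting
#' precision (nearest integer for minutes and mmHg, nearest percent for
#' fractions).
#'
#' @slot perSubject data.frame, one row per subject.
#' @slot means named numeric, unrounded endpoint means.
#' @slot roundedMeans named numeric, means at reporting precision.
#' @slot ranges data.frame with rows `min`, `max`.
#'
#' @export
setClass("StudySummary",
  representation(
    perSubject = "data.frame", means = "numeric",
    roundedMeans = "numeric", ranges = "data.frame"
  )
)

setValidity("StudySummary", function(object) {
  for (nm in names(object@means)) {
    lo <- object@ranges["min", nm]
    hi <- object@ranges["max", nm]
    m <- object@means[[nm]]
    if (is.finite(m) && is.finite(lo) && is.finite(hi) && (m < lo || m > hi))
      return(sprintf("mean of %s outside its range", nm))
  }
  TRUE
})

#' Pipeline configuration
#'
#' Flat, schema-validated key-value configuration of the synthetic study
#' pipeline. Unknown keys are rejected; see [pipelineConfig()] for the
#' schema and defaults.
#'
#' @slot values named list of configuration values.
#'
#' @export
setClass("PipelineConfig", representation(values = "list"))
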