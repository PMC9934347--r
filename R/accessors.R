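#' @name accessors
#' @title Accessors for renalIRB classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param x the object.
#' @param object the object (for `show`).
NULL

#' @rdname accessors
#' @export
setGeneric("tiList", function(x) standardGeneric("tiList"))
#' @rdname accessors
#' @export
setMethod("tiList", "AcquisitionParams", function(x) x@tiList)
#' @rdname accessors
#' @export
setMethod("tiList", "IRSeries", function(x) x@params@tiList)

#' @rdname accessors
#' @export
setGeneric("acqParams", function(x) standardGeneric("acqParams"))
#' @rdname accessors
#' @export
setMethod("acqParams", "IRSeries", function(x) x@params)

#' @rdname accessors
#' @export
setGeneric("imageArray", function(x) standardGeneric("imageArray"))
#' @rdname accessors
#' @export
setMethod("imageArray", "IRSeries", function(x) x@images)

#' @rdname accessors
#' @export
setGeneric("scanTime", function(x) standardGeneric("scanTime"))
#' @rdname accessors
#' @export
setMethod("scanTime", "IRSeries", function(x) x@timeMin)
#' @rdname accessors
#' @export
setMethod("scanTime", "T1Map", function(x) x@timeMin)

#' @rdname accessors
#' @export
setGeneric("scanPressure", function(x) standardGeneric("scanPressure"))
#' @rdname accessors
#' @export
setMethod("scanPressure", "IRSeries", function(x) x@pressureMmHg)
#' @rdname accessors
#' @export
setMethod("scanPressure", "T1Map", function(x) x@pressureMmHg)

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setMethod("validMask", "IRSeries", function(x) x@valid)
#' @rdname accessors
#' @export
setMethod("validMask", "T1Map", function(x) x@valid)

#' @rdname accessors
#' @export
setGeneric("t1Array", function(x) standardGeneric("t1Array"))
#' @rdname accessors
#' @export
setMethod("t1Array", "T1Map", function(x) x@t1)

#' @rdname accessors
#' @export
setGeneric("s0Array", function(x) standardGeneric("s0Array"))
#' @rdname accessors
#' @export
setMethod("s0Array", "T1Map", function(x) x@s0)

#' @rdname accessors
#' @export
setGeneric("rssArray", function(x) standardGeneric("rssArray"))
#' @rdname accessors
#' @export
setMethod("rssArray", "T1Map", function(x) x@rss)

#' @rdname accessors
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))
#' @rdname accessors
#' @export
setMethod("labelMap", "PhantomTruth", function(x) x@labelMap)

#' @rdname accessors
#' @export
setGeneric("wedgeIds", function(x) standardGeneric("wedgeIds"))
#' @rdname accessors
#' @export
setMethod("wedgeIds", "PhantomTruth", function(x) x@wedgeIds)

#' @rdname accessors
#' @export
setGeneric("wedgeOnsets", function(x) standardGeneric("wedgeOnsets"))
#' @rdname accessors
#' @export
setMethod("wedgeOnsets", "PhantomTruth", function(x) x@wedgeOnsetAupi)

#' @rdname accessors
#' @export
setGeneric("baselineT1", function(x) standardGeneric("baselineT1"))
#' @rdname accessors
#' @export
setMethod("baselineT1", "PhantomTruth", function(x) x@baselineT1)

#' @rdname accessors
#' @export
setGeneric("scanTimes", function(x) standardGeneric("scanTimes"))
#' @rdname accessors
#' @export
setMethod("scanTimes", "PhantomTruth", function(x) x@scanTimes)

#' @rdname accessors
#' @export
setGeneric("aupiAtScan", function(x) standardGeneric("aupiAtScan"))
#' @rdname accessors
#' @export
setMethod("aupiAtScan", "PhantomTruth", function(x) x@aupiAtScan)

#' @rdname accessors
#' @export
setGeneric("affectedTruth", function(x) standardGeneric("affectedTruth"))
#' @rdname accessors
#' @export
setMethod("affectedTruth", "PhantomTruth", function(x) x@affectedTruth)

#' @rdname accessors
#' @export
setGeneric("concentrationArray", function(x) standardGeneric("concentrationArray"))
#' @rdname accessors
#' @export
setMethod("concentrationArray", "PhantomTruth", function(x) x@concentration)

#' @rdname accessors
#' @export
setGeneric("motionShifts", function(x) standardGeneric("motionShifts"))
#' @rdname accessors
#' @export
setMethod("motionShifts", "MotionEstimate", function(x) x@shifts)

#' @rdname accessors
#' @export
setGeneric("roiMasks", function(x) standardGeneric("roiMasks"))
#' @rdname accessors
#' @export
setMethod("roiMasks", "ROISet", function(x) x@masks)

#' @rdname accessors
#' @export
setGeneric("logSamples", function(x) standardGeneric("logSamples"))
#' @rdname accessors
#' @export
setMethod("logSamples", "PressureLog", function(x) x@samples)

#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setMethod("subjectId", "PressureLog", function(x) x@subjectId)

#' @rdname accessors
#' @export
setGeneric("affectedMasks", function(x) standardGeneric("affectedMasks"))
#' @rdname accessors
#' @export
setMethod("affectedMasks", "AffectedResult", function(x) x@affectedMasks)

#' @rdname accessors
#' @export
setGeneric("affectedFractions", function(x) standardGeneric("affectedFractions"))
#' @rdname accessors
#' @export
setMethod("affectedFractions", "AffectedResult", function(x) x@fraction)

#' @rdname accessors
#' @export
setGeneric("firstChange", function(x) standardGeneric("firstChange"))
#' @rdname accessors
#' @export
setMethod("firstChange", "AffectedResult", function(x) {
  list(scan = x@firstChangeScan, timeMin = x@firstChangeTime,
       pressureMmHg = x@firstChangePressure)
})

#' @rdname accessors
#' @export
setGeneric("perSubject", function(x) standardGeneric("perSubject"))
#' @rdname accessors
#' @export
setMethod("perSubject", "StudySummary", function(x) x@perSubject)

#' @rdname accessors
#' @export
setGeneric("studyMeans", function(x) standardGeneric("studyMeans"))
#' @rdname accessors
#' @export
setMethod("studyMeans", "StudySummary", function(x) x@means)

#' @rdname accessors
#' @export
setGeneric("studyRoundedMeans", function(x) standardGeneric("studyRoundedMeans"))
#' @rdname accessors
#' @export
setMethod("studyRoundedMeans", "StudySummary", function(x) x@roundedMeans)

#' @rdname accessors
#' @export
setGeneric("studyRanges", function(x) standardGeneric("studyRanges"))
#' @rdname accessors
#' @export
setMethod("studyRanges", "StudySummary", function(x) x@ranges)

#' @rdname accessors
#' @export
setGeneric("configValues", function(x) standardGeneric("configValues"))
#' @rdname accessors
#' @export
setMethod("configValues", "PipelineConfig", function(x) x@values)

## show methods -------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("show", "AcquisitionParams", function(object) {
  cat("AcquisitionParams:", length(object@tiList), "TIs",
      sprintf("[%g..%g ms]", min(object@tiList), max(object@tiList)),
      sprintf("TR %g ms, TE %g ms, %d slices (%g mm, %gx%g mm px)\n",
              object@tr, object@te, object@nSlices, object@sliceThickness,
              object@pixelSize, object@pixelSize))
})

#' @rdname accessors
#' @export
setMethod("show", "IRSeries", function(object) {
  d <- dim(object@images)
  cat(sprintf(
    "IRSeries: %d slices x %d TIs x %dx%d px, t = %g min, P = %g mmHg\n",
    d[1], d[2], d[3], d[4], object@timeMin, object@pressureMmHg))
})

#' @rdname accessors
#' @export
setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labelMap)
  cat(sprintf("PhantomTruth: %d slices x %dx%d px, %d wedges",
              d[1], d[2], d[3], length(object@wedgeOnsetAupi)))
  if (length(object@scanTimes))
    cat(sprintf(", simulated at %d scan times", length(object@scanTimes)))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("show", "T1Map", function(object) {
  d <- dim(object@t1)
  cat(sprintf("T1Map: %d slices x %dx%d px, %d valid px, t = %g min\n",
              d[1], d[2], d[3], sum(object@valid), object@timeMin))
})

#' @rdname accessors
#' @export
setMethod("show", "MotionEstimate", function(object) {
  cat(sprintf("MotionEstimate: %d TIs, reference TI %d, max |shift| %d px\n",
              nrow(object@shifts), object@referenceTiIndex,
              max(abs(object@shifts))))
})

#' @rdname accessors
#' @export
setMethod("show", "ROISet", function(object) {
  cat("ROISet:", paste(names(object@masks), collapse = ", "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "PressureLog", function(object) {
  s <- object@samples
  cat(sprintf("PressureLog%s: %d samples, t %g..%g min, P %g..%g mmHg\n",
              if (nzchar(object@subjectId))
                paste0(" [", object@subjectId, "]") else "",
              nrow(s), min(s$time_min), max(s$time_min),
              min(s$pressure_mmHg), max(s$pressure_mmHg)))
})

#' @rdname accessors
#' @export
setMethod("show", "AffectedResult", function(object) {
  cat(sprintf("AffectedResult: %d scans, end fraction %.3f",
              length(object@fraction),
              if (length(object@fraction)) object@fraction[length(object@fraction)]
              else NA_real_))
  if (!is.na(object@firstChangeScan))
    cat(sprintf(", first change at scan %d (t = %g min, P = %g mmHg)",
                object@firstChangeScan, object@firstChangeTime,
                object@firstChangePressure))
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("show", "StudySummary", function(object) {
  cat(sprintf("StudySummary: %d subjects\n", nrow(object@perSubject)))
  for (nm in names(object@means)) {
    cat(sprintf("  %s: mean %.4g (rounded %g, range %g..%g)\n", nm,
                object@means[[nm]], object@roundedMeans[[nm]],
                object@ranges["min", nm], object@ranges["max", nm]))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "PipelineConfig", function(object) {
  cat("PipelineConfig with", length(object@values), "keys\n")
})
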