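## NIfTI + JSON-sidecar serialisation of series and maps.
##
## On disk a series is <prefix>.nii.gz (4-D, axes row, col, slice, TI),
## <prefix>_valid.nii.gz (the in-plane validity mask) and <prefix>.json
## (acquisition parameters, scan time and pressure). In-memory arrays use
## [slice, ti, row, col].

.sidecarKeys <- c("ti_list", "tr", "te", "slice_thickness", "pixel_size",
                  "scan_interval", "time_min", "pressure_mmHg")

#' Write an inversion-recovery series to NIfTI + JSON sidecar
#'
#' @param series an [IRSeries-class].
#' @param prefix output path prefix (no extension); writes `<prefix>.nii.gz`,
#'   `<prefix>_valid.nii.gz` and `<prefix>.json`.
#' @return `prefix`, invisibly.
#' @export
writeIRSeries <- function(series, prefix) {
  p <- series@params
  vol <- aperm(series@images, c(3, 4, 1, 2))  # row, col, slice, ti
  img <- RNifti::asNifti(vol)
  RNifti::pixdim(img) <- c(p@pixelSize, p@pixelSize, p@sliceThickness, 1)
  RNifti::writeNifti(img, paste0(prefix, ".nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(array(series@valid * 1L,
                                           dim(series@valid))),
                     paste0(prefix, "_valid.nii.gz"))
  sidecar <- list(
    ti_list = p@tiList, tr = p@tr, te = p@te,
    slice_thickness = p@sliceThickness, pixel_size = p@pixelSize,
    scan_interval = p@scanInterval, time_min = series@timeMin,
    pressure_mmHg = series@pressureMmHg
  )
  jsonlite::write_json(sidecar, paste0(prefix, ".json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(prefix)
}

#' Read an inversion-recovery series written by [writeIRSeries()]
#'
#' @param prefix path prefix used at write time.
#' @return An [IRSeries-class].
#' @export
readIRSeries <- function(prefix) {
  sidecarPath <- paste0(prefix, ".json")
  if (!file.exists(sidecarPath))
    stop("missing sidecar ", sidecarPath, "; required keys: ",
         paste(.sidecarKeys, collapse = ", "))
  sc <- jsonlite::read_json(sidecarPath, simplifyVector = TRUE)
  missing <- setdiff(.sidecarKeys, names(sc))
  if (length(missing))
    stop("sidecar ", sidecarPath, " missing required keys: ",
         paste(missing, collapse = ", "))
  vol <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  vol <- array(as.numeric(vol), dim(vol))
  if (length(dim(vol)) != 4L)
    stop("expected a 4-D volume with axes (row, col, slice, TI); got ",
         length(dim(vol)), " dims")
  params <- acquisitionParams(
    tiList = sc$ti_list, tr = sc$tr, te = sc$te,
    nSlices = dim(vol)[3], sliceThickness = sc$slice_thickness,
    pixelSize = sc$pixel_size, scanInterval = sc$scan_interval
  )
  validPath <- paste0(prefix, "_valid.nii.gz")
  valid <- if (file.exists(validPath)) {
    v <- RNifti::readNifti(validPath)
    matrix(as.numeric(v) > 0, dim(v)[1], dim(v)[2])
  } else matrix(TRUE, dim(vol)[1], dim(vol)[2])
  irSeries(aperm(vol, c(3, 4, 1, 2)), params,
           timeMin = sc$time_min, pressureMmHg = sc$pressure_mmHg,
           valid = valid)
}

#' Write a T1 map as NIfTI volumes
#'
#' Writes `<prefix>_t1.nii.gz`, `<prefix>_s0.nii.gz` and
#' `<prefix>_valid.nii.gz` (axes row, col, slice) plus `<prefix>.json` with
#' the scan time and pressure. Invalid pixels hold zero in the T1 volume.
#'
#' @param map a [T1Map-class].
#' @param prefix output path prefix.
#' @return `prefix`, invisibly.
#' @export
writeT1Map <- function(map, prefix) {
  put <- function(a, suffix) {
    a[is.na(a)] <- 0
    RNifti::writeNifti(RNifti::asNifti(aperm(a, c(2, 3, 1))),
                       paste0(prefix, "_", suffix, ".nii.gz"))
  }
  put(map@t1, "t1")
  put(map@s0, "s0")
  put(map@valid * 1, "valid")
  jsonlite::write_json(list(time_min = map@timeMin,
                            pressure_mmHg = map@pressureMmHg),
                       paste0(prefix, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(prefix)
}
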