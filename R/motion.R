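## Rigid in-plane motion correction by cross-correlation of image gradient
## maps. Gradients rather than raw magnitudes: inversion-recovery contrast
## inverts across the null point, but edge structure does not.

#' Gradient-magnitude map of an image
#'
#' Per-pixel gradient magnitude via central differences (one-sided at the
#' image borders). A constant image maps to all zeros; a linear ramp of
#' slope `a` per pixel maps to a uniform value `a`.
#'
#' @param image numeric matrix, at least 3x3.
#' @return Non-negative numeric matrix of the same shape.
#' @export
gradientMap <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  if (is.null(nr) || nr < 3L || nc < 3L) stop("image must be at least 3x3")
  gr <- image; gc <- image
  gr[2:(nr - 1), ] <- (image[3:nr, ] - image[1:(nr - 2), ]) / 2
  gr[1, ] <- image[2, ] - image[1, ]
  gr[nr, ] <- image[nr, ] - image[nr - 1, ]
  gc[, 2:(nc - 1)] <- (image[, 3:nc] - image[, 1:(nc - 2)]) / 2
  gc[, 1] <- image[, 2] - image[, 1]
  gc[, nc] <- image[, nc] - image[, nc - 1]
  sqrt(gr^2 + gc^2)
}

## Slice-aggregated gradient template of one TI frame.
.gradientTemplate <- function(images, tiIndex) {
  nSlices <- dim(images)[1]
  g <- 0
  for (s in seq_len(nSlices)) g <- g + gradientMap(images[s, tiIndex, , ])
  g
}

#' Estimate per-TI rigid motion of an inversion-recovery series
#'
#' For every inversion time, finds the integer (dy, dx) translation that
#' maximises the cross-correlation between that TI's gradient map and the
#' reference TI's gradient map, searched exhaustively over a bounded window.
#' Gradient maps are aggregated over slices (motion is modelled as one
#' in-plane shift per TI). Ties are broken towards the smallest-magnitude
#' shift. The default reference is the longest TI, where tissue signal has
#' recovered most.
#'
#' @param series an [IRSeries-class].
#' @param referenceTiIndex reference TI index (default: last, the longest TI).
#' @param window half-width of the search window in pixels.
#' @return A [MotionEstimate-class] with one (dy, dx) row per TI.
#' @export
estimateMotion <- function(series, referenceTiIndex = NULL, window = 8L) {
  d <- dim(series@images)
  nTI <- d[2]
  referenceTiIndex <- as.integer(referenceTiIndex %||% nTI)
  stopifnot(referenceTiIndex >= 1L, referenceTiIndex <= nTI)
  if (2L * window + 1L > min(d[3], d[4]))
    stop("search window (±", window, " px) larger than the image")

  ref <- .gradientTemplate(series@images, referenceTiIndex)
  ## candidates in tie-break priority order: smallest |shift| first
  cand <- expand.grid(dy = -window:window, dx = -window:window)
  cand <- cand[order(cand$dy^2 + cand$dx^2, abs(cand$dy), abs(cand$dx),
                     cand$dy, cand$dx), ]
  shifts <- matrix(0L, nTI, 2L, dimnames = list(NULL, c("dy", "dx")))
  for (j in seq_len(nTI)) {
    if (j == referenceTiIndex) next
    g <- .gradientTemplate(series@images, j)
    scores <- vapply(seq_len(nrow(cand)), function(i) {
      sum(ref * shiftMatrix(g, -cand$dy[i], -cand$dx[i]))
    }, 0.0)
    best <- which.max(scores)   # first max in priority order
    shifts[j, ] <- c(cand$dy[best], cand$dx[best])
  }
  new("MotionEstimate", shifts = shifts,
      referenceTiIndex = referenceTiIndex)
}

#' Undo estimated motion in a series
#'
#' Translates each TI image by minus its estimated shift, aligning all TIs
#' to the reference frame. Pixels dragged in from outside the field of view
#' are flagged invalid in the series' validity mask (and propagate into
#' `T1Map` validity downstream).
#'
#' @param series an [IRSeries-class].
#' @param motion a [MotionEstimate-class] for this series.
#' @return A motion-corrected [IRSeries-class].
#' @export
applyMotion <- function(series, motion) {
  d <- dim(series@images)
  if (nrow(motion@shifts) != d[2])
    stop("motion estimate has ", nrow(motion@shifts),
         " shifts but series has ", d[2], " TIs")
  out <- series@images
  valid <- series@valid
  for (j in seq_len(d[2])) {
    dy <- motion@shifts[j, 1]; dx <- motion@shifts[j, 2]
    if (dy == 0L && dx == 0L) next
    for (s in seq_len(d[1]))
      out[s, j, , ] <- shiftMatrix(series@images[s, j, , ], -dy, -dx)
    valid <- valid & shiftValidMask(d[3], d[4], -dy, -dx)
  }
  irSeries(out, series@params, timeMin = series@timeMin,
           pressureMmHg = series@pressureMmHg, valid = valid)
}
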