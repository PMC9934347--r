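## Forward rendering of inversion-recovery magnitude series from T1/S0
## ground truth, with rigid in-plane motion and Rician noise.

#' Magnitude inversion-recovery signal
#'
#' The two-parameter magnitude model `S0 * |1 - 2 exp(-TI/T1)|`. With
#' `tr` supplied, the TR-corrected three-parameter variant
#' `S0 * |1 - 2 exp(-TI/T1) + exp(-TR/T1)|` is used instead (the correction
#' matters for long T1 relative to TR; at TR = 5 s and T1 <= 1800 ms the
#' omitted term is below ~7%).
#'
#' @param t1 longitudinal relaxation time, ms (vectorised).
#' @param ti inversion time, ms (vectorised).
#' @param s0 equilibrium signal.
#' @param tr repetition time in ms for the TR-corrected model, or `NULL`
#'   for the two-parameter model.
#' @return Signal magnitude, same shape as the broadcast inputs.
#' @examples
#' irSignal(1000, 1000 * log(2))  # null point, ~0
#' @export
irSignal <- function(t1, ti, s0 = 1, tr = NULL) {
  e <- 1 - 2 * exp(-ti / t1)
  if (!is.null(tr)) e <- e + exp(-tr / t1)
  s0 * abs(e)
}

#' Render a noisy, motion-corrupted inversion-recovery series
#'
#' Applies the forward signal model pixel-wise to a T1/S0 ground-truth grid
#' for every inversion time, translates each TI image by its motion shift
#' (integer pixels, zero fill), and adds Rician noise: the output magnitude
#' is `sqrt((S + n1)^2 + n2^2)` with `n1, n2 ~ N(0, noiseSigma)`, the
#' magnitude of a complex Gaussian perturbation. Pixels with `S0 = 0` or
#' undefined T1 render as zero signal.
#'
#' @param t1Grid numeric `[slice, row, col]` array of T1 in ms (`NA` where
#'   signal-free).
#' @param s0Grid numeric `[slice, row, col]` array of S0.
#' @param params an [AcquisitionParams-class].
#' @param noiseSigma Rician noise scale in signal units, >= 0.
#' @param motionShifts integer `[nTI, 2]` matrix of (dy, dx) per TI, or
#'   `NULL` for no motion.
#' @param seed integer seed for the noise, or `NULL`.
#' @param trCorrected logical; use the TR-corrected three-parameter signal
#'   model.
#' @param timeMin,pressureMmHg scan metadata stored on the series.
#' @return An [IRSeries-class].
#' @export
renderIRSeries <- function(t1Grid, s0Grid, params, noiseSigma = 0,
                           motionShifts = NULL, seed = NULL,
                           trCorrected = FALSE, timeMin = 0,
                           pressureMmHg = 0) {
  d <- dim(t1Grid)
  stopifnot(length(d) == 3L, identical(d, dim(s0Grid)))
  if (d[1] != params@nSlices)
    stop("t1Grid slice count does not match params@nSlices")
  if (noiseSigma < 0) stop("noiseSigma must be >= 0")
  nTI <- length(params@tiList)
  if (is.null(motionShifts))
    motionShifts <- matrix(0L, nTI, 2L)
  motionShifts <- matrix(as.integer(round(motionShifts)), nrow(motionShifts), 2L)
  if (nrow(motionShifts) != nTI)
    stop("need one motion shift per TI (", nTI, " TIs, got ",
         nrow(motionShifts), " shifts)")

  tr <- if (trCorrected) params@tr else NULL
  images <- array(0, c(d[1], nTI, d[2], d[3]))
  withSeed(seed, {
    for (j in seq_len(nTI)) {
      for (s in seq_len(d[1])) {
        t1 <- t1Grid[s, , ]; s0 <- s0Grid[s, , ]
        sig <- matrix(0, d[2], d[3])
        ok <- !is.na(t1) & t1 > 0 & s0 > 0
        sig[ok] <- irSignal(t1[ok], params@tiList[j], s0[ok], tr)
        sig <- shiftMatrix(sig, motionShifts[j, 1], motionShifts[j, 2])
        if (noiseSigma > 0) {
          n1 <- matrix(rnorm(length(sig), 0, noiseSigma), d[2], d[3])
          n2 <- matrix(rnorm(length(sig), 0, noiseSigma), d[2], d[3])
          sig <- sqrt((sig + n1)^2 + n2^2)
        }
        images[s, j, , ] <- sig
      }
    }
  })
  irSeries(images, params, timeMin = timeMin, pressureMmHg = pressureMmHg)
}

#' Render one phantom scan
#'
#' Convenience wrapper: takes the ground-truth T1/S0 at a simulated scan and
#' renders the inversion-recovery series with the scan's time stamp.
#'
#' @param truth a simulated [PhantomTruth-class].
#' @param scanIndex scan index.
#' @param params an [AcquisitionParams-class].
#' @param pressureMmHg concurrent pressure to stamp on the series.
#' @param r1 longitudinal relaxivity, L·mmol⁻¹·s⁻¹.
#' @inheritParams renderIRSeries
#' @return An [IRSeries-class].
#' @export
renderPhantomScan <- function(truth, scanIndex, params, noiseSigma = 0,
                              motionShifts = NULL, seed = NULL, r1 = 4.0,
                              trCorrected = FALSE, pressureMmHg = 0) {
  renderIRSeries(truthT1Grid(truth, scanIndex, r1), truthS0Grid(truth),
                 params, noiseSigma = noiseSigma,
                 motionShifts = motionShifts, seed = seed,
                 trCorrected = trCorrected,
                 timeMin = truth@scanTimes[scanIndex],
                 pressureMmHg = pressureMmHg)
}
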