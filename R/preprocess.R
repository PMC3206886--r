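# Subject-level temporal preprocessing: motion screening, zero-phase
# band-pass filtering, nuisance regression, ROI aggregation.

#' Screen a subject's head motion
#'
#' A subject fails when the absolute translation on any axis exceeds the
#' displacement limit, or the absolute rotation on any axis exceeds the
#' rotation limit. The comparisons are strict ("larger than"), so a
#' maximum of exactly 1.5 mm passes at the default limits. Maxima are
#' taken per parameter; no composite framewise displacement is used.
#'
#' @param nuisance a \linkS4class{NuisanceSet}, or a 6 x timepoints motion
#'   matrix (rows: 3 translations in mm, then 3 rotations in degrees).
#' @param displacementLimitMm translation limit, default 1.5 mm.
#' @param rotationLimitDeg rotation limit, default 1.5 degrees.
#' @return List with \code{pass} (logical) and \code{summary}, a data.frame
#'   of per-axis maxima (\code{max_displacement_mm}, \code{max_rotation_deg}).
#' @examples
#' m <- matrix(0, 6, 50)
#' screenMotion(m)$pass  # TRUE
#' @export
screenMotion <- function(nuisance, displacementLimitMm = 1.5,
                         rotationLimitDeg = 1.5) {
  motion <- if (is(nuisance, "NuisanceSet")) nuisance@motion else nuisance
  if (!is.matrix(motion) || nrow(motion) != 6L)
    stop("motion must be a 6-row matrix (3 translations, 3 rotations)")
  maxDisp <- apply(abs(motion[1:3, , drop = FALSE]), 1, max)
  maxRot <- apply(abs(motion[4:6, , drop = FALSE]), 1, max)
  pass <- !(any(maxDisp > displacementLimitMm) ||
            any(maxRot > rotationLimitDeg))
  list(pass = pass,
       summary = data.frame(axis = c("x", "y", "z"),
                            max_displacement_mm = maxDisp,
                            max_rotation_deg = maxRot,
                            row.names = NULL))
}

#' Zero-phase band-pass filter regional time series
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass filter to
#' each region's series; the default 0.01-0.08 Hz band removes scanner
#' drift and high-frequency physiological noise before connectivity
#' estimation. Forward-backward application squares the magnitude response
#' and cancels phase distortion, which would otherwise bias Pearson
#' correlations.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   \code{0 < lowHz < highHz < 1/(2 TR)}.
#' @param order Butterworth prototype order (default 2; effective order is
#'   doubled by the forward-backward pass).
#' @return A filtered \linkS4class{RoiTimeSeries} of identical shape.
#' @export
bandpassFilter <- function(ts, lowHz = 0.01, highHz = 0.08, order = 2) {
  stopifnot(is(ts, "RoiTimeSeries"))
  fs <- 1 / ts@trSeconds
  nyquist <- fs / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyquist))
    stop(sprintf(
      "invalid band [%g, %g] Hz for TR = %g s (Nyquist %g Hz)",
      lowHz, highHz, ts@trSeconds, nyquist))
  bf <- signal::butter(order, c(lowHz, highHz) / nyquist, type = "pass")
  x <- ts@data
  filtered <- t(apply(x, 1, function(row) {
    signal::filtfilt(bf, row - mean(row))
  }))
  RoiTimeSeries(filtered, ts@regionLabels, ts@trSeconds)
}

#' Regress nuisance signals out of regional time series
#'
#' Removes, by ordinary least squares with an intercept, the six motion
#' parameters plus white-matter and ventricle signals from every region's
#' series. Residuals are exactly orthogonal to every regressor (and
#' mean-zero). A rank-deficient nuisance matrix triggers a warning and the
#' projection falls back to the pseudo-inverse fit.
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param nuisance a \linkS4class{NuisanceSet} with the same time length,
#'   or a regressors x timepoints matrix.
#' @return The residual \linkS4class{RoiTimeSeries}.
#' @export
regressNuisance <- function(ts, nuisance) {
  stopifnot(is(ts, "RoiTimeSeries"))
  nmat <- if (is(nuisance, "NuisanceSet"))
    rbind(nuisance@motion, wm = nuisance@wmSignal, csf = nuisance@csfSignal)
  else nuisance
  nt <- ncol(ts@data)
  if (ncol(nmat) != nt)
    stop("nuisance time length does not match the time series")
  x <- cbind(1, t(nmat))
  qrx <- qr(x)
  if (qrx$rank < ncol(x))
    warning("rank-deficient nuisance matrix; projecting onto its column space")
  resid <- t(qr.resid(qrx, t(ts@data)))
  RoiTimeSeries(resid, ts@regionLabels, ts@trSeconds)
}

#' Aggregate voxel series into regional mean series
#'
#' Each region's series is the arithmetic mean of its member voxel series,
#' ordered by the canonical region label list.
#'
#' @param voxelData voxels x timepoints numeric matrix.
#' @param voxelRegions character vector mapping each voxel (row) to a
#'   region label.
#' @param regionLabels canonical ordered label list; defaults to the order
#'   of first appearance in \code{voxelRegions}. Every listed region must
#'   own at least one voxel.
#' @param trSeconds sampling interval of the output (default 2).
#' @return A \linkS4class{RoiTimeSeries} with one row per region.
#' @examples
#' v <- rbind(c(1, 2, 3), c(3, 4, 5))
#' seriesMatrix(aggregateRois(v, c("A", "A")))  # region mean c(2, 3, 4)
#' @export
aggregateRois <- function(voxelData, voxelRegions, regionLabels = NULL,
                          trSeconds = 2) {
  stopifnot(nrow(voxelData) == length(voxelRegions))
  if (is.null(regionLabels)) regionLabels <- unique(voxelRegions)
  missing <- setdiff(regionLabels, voxelRegions)
  if (length(missing))
    stop("no voxels assigned to region(s): ", paste(missing, collapse = ", "))
  out <- t(vapply(regionLabels, function(lab) {
    colMeans(voxelData[voxelRegions == lab, , drop = FALSE])
  }, numeric(ncol(voxelData))))
  RoiTimeSeries(out, regionLabels, trSeconds)
}

#' Run the subject-level preprocessing chain
#'
#' Band-pass filters then regresses nuisance signals, in that order (the
#' filtering is applied first so the regression removes the nuisance
#' structure that survives the band).
#'
#' @param ts a \linkS4class{RoiTimeSeries}.
#' @param nuisance a \linkS4class{NuisanceSet}.
#' @param lowHz,highHz band edges, defaults 0.01 and 0.08 Hz.
#' @param filterNuisance filter the nuisance regressors through the same
#'   band before regression (default TRUE), so regressor and signal
#'   spectra match.
#' @return The preprocessed \linkS4class{RoiTimeSeries}.
#' @export
preprocessSubject <- function(ts, nuisance, lowHz = 0.01, highHz = 0.08,
                              filterNuisance = TRUE) {
  filtered <- bandpassFilter(ts, lowHz, highHz)
  nmat <- rbind(nuisance@motion, wm = nuisance@wmSignal,
                csf = nuisance@csfSignal)
  if (filterNuisance) {
    ntmp <- RoiTimeSeries(nmat, sprintf("N%d", 1:8), ts@trSeconds)
    nmat <- bandpassFilter(ntmp, lowHz, highHz)@data
  }
  regressNuisance(filtered, nmat)
}
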