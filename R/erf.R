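# Sustained event-related field (ERF) amplitude extraction: DC offset
# correction, epoch averaging, baseline z-scoring, rectified window
# averaging and spatial Gaussian smoothing.

#' DC offset correction of subject epochs
#'
#' Subtracts, per trial and vertex, the mean over a short pre-stimulus
#' window (default -100 to -2 ms), removing slow drifts and any constant
#' offset before averaging.
#'
#' @param epochs a `subject_epochs`.
#' @param window_s closed correction window in seconds.
#' @return the corrected `subject_epochs`.
#' @export
dc_offset_correct <- function(epochs, window_s = c(-0.1, -0.002)) {
  stopifnot(inherits(epochs, "subject_epochs"))
  idx <- idx_window(epochs$times_s, window_s)
  if (length(idx) == 0L)
    stop_assr("DC window [%g, %g] s contains no samples", window_s[1], window_s[2])
  base <- rowMeans(epochs$data[, , idx, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - as.vector(base)  # recycles over the time dim
  epochs
}

#' Average epochs into an evoked response
#'
#' Arithmetic mean across trials, per vertex and time point. Phase-jittered
#' oscillatory components attenuate by the mean resultant length of their
#' trial phases (`I1(kappa)/I0(kappa)` under a von Mises model), while
#' phase-locked components survive.
#'
#' @param epochs a `subject_epochs` with at least one trial.
#' @return object of class `evoked`: list with `values` (vertices x times),
#'   `times_s`, `vertices`.
#' @export
average_evoked <- function(epochs) {
  stopifnot(inherits(epochs, "subject_epochs"))
  if (dim(epochs$data)[1] < 1L) stop_assr("no trials to average")
  structure(list(values = colMeans(epochs$data),   # mean over trials
                 times_s = epochs$times_s, vertices = epochs$vertices),
            class = "evoked")
}

#' Baseline z-score normalization of an evoked map
#'
#' Per vertex, `z(t) = (x(t) - mu_base) / sd_base`, with mean and sample SD
#' (denominator n-1) taken over the pre-stimulus baseline (default -100 to
#' -2 ms). Invariant to any per-vertex affine rescaling of the input.
#'
#' @param evoked an `evoked` (or a plain vertices x times matrix plus
#'   `times_s`).
#' @param baseline_s closed baseline interval in seconds.
#' @param times_s time axis, required only when `evoked` is a bare matrix.
#' @return object of class `erf_map`: list with `zmap` (vertices x times,
#'   z units), `times_s`, `vertices`.
#' @export
zscore_normalize <- function(evoked, baseline_s = c(-0.1, -0.002), times_s = NULL) {
  if (inherits(evoked, "evoked")) {
    vals <- evoked$values; times_s <- evoked$times_s; verts <- evoked$vertices
  } else {
    vals <- as.matrix(evoked); verts <- NULL
    if (is.null(times_s)) stop_assr("times_s required for a bare matrix input")
  }
  idx <- idx_window(times_s, baseline_s)
  if (length(idx) < 2L)
    stop_assr("baseline [%g, %g] s needs at least 2 samples for an SD", baseline_s[1],
              baseline_s[2])
  mu <- rowMeans(vals[, idx, drop = FALSE])
  sd <- apply(vals[, idx, drop = FALSE], 1L, stats::sd)
  zero <- which(sd == 0)
  if (length(zero) > 0L)
    stop_assr("zero baseline SD at vertex %d: z-score undefined", zero[1])
  structure(list(zmap = (vals - mu) / sd, times_s = times_s, vertices = verts),
            class = "erf_map")
}

#' Sustained-field amplitude per vertex
#'
#' Mean of the rectified z-scores, `mean(|z(t)|)`, over the sustained window
#' (default 200-1000 ms, where the sustained component has stabilized and
#' persists until stimulus offset). Rectification makes the measure
#' polarity-free.
#'
#' @param erf an `erf_map` (or a bare z matrix plus `times_s`).
#' @param window_s closed averaging window in seconds.
#' @param times_s time axis for bare matrix input.
#' @return numeric vector, one amplitude (z units) per vertex.
#' @export
sustained_amplitude <- function(erf, window_s = c(0.2, 1.0), times_s = NULL) {
  if (inherits(erf, "erf_map")) {
    z <- erf$zmap; times_s <- erf$times_s
  } else {
    z <- as.matrix(erf)
    if (is.null(times_s)) stop_assr("times_s required for a bare matrix input")
  }
  idx <- idx_window(times_s, window_s)
  if (length(idx) == 0L)
    stop_assr("window [%g, %g] s contains no samples", window_s[1], window_s[2])
  rowMeans(abs(z[, idx, drop = FALSE]))
}

#' Gaussian spatial smoothing over a vertex cloud
#'
#' Kernel-weighted average of per-vertex values using Euclidean distances
#' between vertex coordinates, with `sigma = fwhm / (2*sqrt(2*log 2))` and
#' weights renormalized to sum to one per vertex. Constant fields are left
#' unchanged exactly. (On a synthetic vertex cloud there is no cortical
#' mesh, so distances are Euclidean rather than geodesic.)
#'
#' @param values numeric vector, one value per vertex.
#' @param coords_mm vertices x 3 coordinate matrix (mm).
#' @param fwhm_mm kernel full width at half maximum (mm); `0` returns the
#'   input untouched.
#' @param hemisphere optional per-vertex labels; when given, smoothing is
#'   confined within each hemisphere.
#' @return smoothed numeric vector.
#' @export
spatial_smooth <- function(values, coords_mm, fwhm_mm = 3, hemisphere = NULL) {
  coords_mm <- as.matrix(coords_mm)
  stopifnot(length(values) == nrow(coords_mm))
  if (!all(is.finite(coords_mm))) stop_assr("non-finite vertex coordinates")
  if (fwhm_mm == 0) return(values)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d2 <- as.matrix(stats::dist(coords_mm))^2
  w <- exp(-d2 / (2 * sigma^2))
  if (!is.null(hemisphere)) {
    same <- outer(hemisphere, hemisphere, "==")
    w <- w * same
  }
  as.vector((w %*% values) / rowSums(w))
}

#' @export
print.erf_map <- function(x, ...) {
  d <- dim(x$zmap)
  cat(sprintf("erf_map: %d vertices x %d samples [%g, %g] s (z units)\n",
              d[1], d[2], x$times_s[1], x$times_s[length(x$times_s)]))
  invisible(x)
}
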