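# Morlet-wavelet time-frequency decomposition and inter-trial phase
# consistency (ITPC).
#
# The wavelet "time resolution" is the FWHM of the Gaussian envelope at the
# central frequency (sigma_t = FWHM / (2*sqrt(2*log 2))); envelopes scale
# with frequency as sigma_t(f) = sigma_t(f0) * f0 / f (constant cycles).
# Convolution is frequency-domain with zero padding; coefficients within one
# envelope FWHM of an epoch edge are marked invalid (NA downstream) so edge
# effects never enter analysis windows.

#' Morlet wavelet specification
#'
#' @param center_freq_hz central frequency in Hz (the frequency at which
#'   `time_resolution_s` is defined).
#' @param time_resolution_s FWHM of the wavelet's Gaussian envelope at the
#'   central frequency, in seconds.
#' @param freq_grid_hz increasing frequency grid for the decomposition; the
#'   default 35-45 Hz in 1 Hz steps guarantees exact bins at 39, 40 and
#'   41 Hz for the steady-state band average.
#' @return object of class `morlet_spec`.
#' @export
morlet_spec <- function(center_freq_hz = 40, time_resolution_s = 0.3,
                        freq_grid_hz = 35:45) {
  if (center_freq_hz <= 0 || time_resolution_s <= 0)
    stop_assr("center frequency and time resolution must be positive")
  freq_grid_hz <- as.numeric(freq_grid_hz)
  if (any(diff(freq_grid_hz) <= 0) || any(freq_grid_hz <= 0))
    stop_assr("freq_grid_hz must be a positive increasing vector")
  # cycles inside one FWHM are constant across the grid: f * FWHM(f) = f0 * FWHM(f0)
  if (center_freq_hz * time_resolution_s < 3)
    warning(sprintf("wavelet has only %.1f cycles per FWHM (< 3); estimates will be unstable",
                    center_freq_hz * time_resolution_s))
  structure(list(center_freq_hz = center_freq_hz,
                 time_resolution_s = time_resolution_s,
                 freq_grid_hz = freq_grid_hz),
            class = "morlet_spec")
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' Construct a complex Morlet kernel on the sample grid
#'
#' @param freq_hz kernel frequency.
#' @param sample_rate_hz sampling rate.
#' @param spec a [morlet_spec()] giving the envelope width convention.
#' @param n_sigma half-support of the kernel in units of the envelope sigma.
#' @return list with `kernel` (complex, energy-normalized), `t` (seconds,
#'   centered on 0) and `sigma_t`.
#' @export
morlet_kernel <- function(freq_hz, sample_rate_hz, spec = morlet_spec(),
                          n_sigma = 5) {
  sigma0 <- fwhm_to_sigma(spec$time_resolution_s)
  sigma_t <- sigma0 * spec$center_freq_hz / freq_hz
  half <- ceiling(n_sigma * sigma_t * sample_rate_hz)
  t <- (-half:half) / sample_rate_hz
  k <- exp(2i * pi * freq_hz * t) * exp(-t^2 / (2 * sigma_t^2))
  k <- k / sqrt(sum(Mod(k)^2))
  list(kernel = k, t = t, sigma_t = sigma_t)
}

# FFT engine: complex wavelet coefficients of each column of x_mat
# (n_time x n_series) for one kernel, output aligned to the input time axis.
# With decim = D > 1, the product spectrum is alias-folded onto npad/D bins
# before the inverse transform, which yields exactly the samples y[1],
# y[1+D], y[1+2D], ... of the full convolution at 1/D of the cost.
tf_filter <- function(x_fft, npad, n_time, kern, decim = 1L) {
  kl <- length(kern$kernel)
  half <- (kl - 1L) %/% 2L
  kp <- complex(length.out = npad)
  # kernel center at index 1; negative lags wrapped to the tail
  kp[1:(half + 1L)] <- kern$kernel[(half + 1L):kl]
  kp[(npad - half + 1L):npad] <- kern$kernel[1:half]
  kf <- stats::fft(kp)
  y <- x_fft * Conj(kf)
  if (decim > 1L) {
    stopifnot(npad %% decim == 0L)
    m <- npad %/% decim
    fold <- y[seq_len(m), , drop = FALSE]
    for (j in seq_len(decim - 1L))
      fold <- fold + y[j * m + seq_len(m), , drop = FALSE]
    out <- stats::mvfft(fold, inverse = TRUE) / npad
    n_keep <- length(seq.int(1L, n_time, by = decim))
    return(out[seq_len(n_keep), , drop = FALSE])
  }
  out <- stats::mvfft(y, inverse = TRUE) / npad
  out[seq_len(n_time), , drop = FALSE]
}

# Per-frequency mask of time samples farther than one envelope FWHM from
# either epoch edge (valid region). `epoch_range` defaults to the span of
# `times` but must be passed explicitly when `times` is a restricted axis.
tf_valid_mask <- function(times, spec, epoch_range = range(times)) {
  fwhm_f <- spec$time_resolution_s * spec$center_freq_hz / spec$freq_grid_hz
  t0 <- epoch_range[1]; t1 <- epoch_range[2]
  vapply(fwhm_f, function(w) times >= t0 + w - .win_eps & times <= t1 - w + .win_eps,
         logical(length(times)))   # times x freqs
}

check_nyquist <- function(spec, sample_rate_hz) {
  if (max(spec$freq_grid_hz) >= sample_rate_hz / 2)
    stop_assr("frequency grid reaches %g Hz >= Nyquist (%g Hz)",
              max(spec$freq_grid_hz), sample_rate_hz / 2)
}

check_support <- function(spec, times, sample_rate_hz) {
  kern <- morlet_kernel(min(spec$freq_grid_hz), sample_rate_hz, spec)
  if (length(kern$kernel) > length(times))
    stop_assr("epoch (%d samples) shorter than wavelet support at %g Hz (%d samples)",
              length(times), min(spec$freq_grid_hz), length(kern$kernel))
}

#' Morlet-wavelet transform of subject epochs
#'
#' Convolves every trial/vertex time course with complex Morlet kernels on
#' the frequency grid and returns the full coefficient array. Intended for
#' small inputs (oracle tests, inspection); the pipeline uses the
#' memory-bounded [itpc_tfr()], which produces identical phases frequency by
#' frequency.
#'
#' @param epochs a `subject_epochs`.
#' @param spec a [morlet_spec()].
#' @return complex array trials x vertices x freqs x times, with attributes
#'   `freqs_hz`, `times_s` and `valid` (times x freqs logical mask of
#'   samples clear of edge effects).
#' @export
morlet_transform <- function(epochs, spec = morlet_spec()) {
  stopifnot(inherits(epochs, "subject_epochs"), inherits(spec, "morlet_spec"))
  check_nyquist(spec, epochs$sample_rate_hz)
  check_support(spec, epochs$times_s, epochs$sample_rate_hz)
  d <- dim(epochs$data)
  n_trials <- d[1]; n_vert <- d[2]; n_time <- d[3]
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_time)  # cols: trial fastest
  max_kl <- length(morlet_kernel(min(spec$freq_grid_hz),
                                 epochs$sample_rate_hz, spec)$kernel)
  npad <- stats::nextn(n_time + max_kl, 2)
  xp <- matrix(0, npad, ncol(x)); xp[seq_len(n_time), ] <- x
  x_fft <- stats::mvfft(xp)
  nf <- length(spec$freq_grid_hz)
  out <- array(complex(1), dim = c(n_trials, n_vert, nf, n_time))
  for (j in seq_len(nf)) {
    kern <- morlet_kernel(spec$freq_grid_hz[j], epochs$sample_rate_hz, spec)
    cf <- tf_filter(x_fft, npad, n_time, kern)        # n_time x (trial,vertex)
    out[, , j, ] <- aperm(array(cf, dim = c(n_time, n_trials, n_vert)), c(2, 3, 1))
  }
  attr(out, "freqs_hz") <- spec$freq_grid_hz
  attr(out, "times_s") <- epochs$times_s
  attr(out, "valid") <- tf_valid_mask(epochs$times_s, spec)
  out
}

new_tf_map <- function(values, freqs, times, kind, n_trials) {
  structure(list(values = values, freqs_hz = freqs, times_s = times,
                 kind = kind, n_trials = n_trials),
            class = "tf_map")
}

#' Inter-trial phase consistency from wavelet coefficients
#'
#' ITPC at a (vertex, frequency, time) bin is the resultant length of the
#' unit phase vectors across trials,
#' \deqn{\mathrm{ITPC} = n^{-1} \left| \sum_{r=1}^{n} e^{i k_{tr}} \right|,}
#' taking values in `[0, 1]`: 0 for uniformly scattered phases, 1 for
#' perfect phase locking. Amplitude information is discarded by
#' construction.
#'
#' @param coefficients complex array trials x vertices x freqs x times, as
#'   from [morlet_transform()].
#' @param zero_phase what to do with zero-magnitude coefficients (undefined
#'   phase): `"error"` (default) or `"exclude"`, which drops the offending
#'   trial at that bin and renormalizes by the remaining count. The check is
#'   applied inside the edge-valid region only.
#' @return a `tf_map` of kind `"raw_itpc"` (vertices x freqs x times);
#'   edge-contaminated bins are `NA`.
#' @export
compute_itpc <- function(coefficients, zero_phase = c("error", "exclude")) {
  zero_phase <- match.arg(zero_phase)
  d <- dim(coefficients)
  if (length(d) != 4L) stop_assr("coefficients must be trials x vertices x freqs x times")
  n_trials <- d[1]
  if (n_trials < 2L) stop_assr("ITPC requires at least 2 trials (got %d)", n_trials)
  mod <- Mod(coefficients)
  valid <- attr(coefficients, "valid")
  zero <- mod == 0
  if (!is.null(valid)) {
    # only flag zeros inside the edge-valid region
    vmask <- aperm(array(valid, dim = c(d[4], d[3], d[1], d[2])), c(3, 4, 2, 1))
    zero <- zero & vmask
  }
  if (any(zero)) {
    if (zero_phase == "error")
      stop_assr("zero-magnitude wavelet coefficient: phase undefined (%d bins); see zero_phase=",
                sum(zero))
    mod[zero] <- 1  # placeholder; contribution removed below
  }
  u <- coefficients / mod
  if (any(zero)) u[zero] <- 0i
  s <- apply(u, c(2, 3, 4), sum)
  denom <- if (any(zero)) n_trials - apply(zero, c(2, 3, 4), sum) else n_trials
  itpc <- Mod(s) / denom
  if (!is.null(valid)) {
    nvmask <- aperm(array(!valid, dim = c(d[4], d[3], d[2])), c(3, 2, 1))
    itpc[nvmask] <- NA_real_
  }
  new_tf_map(itpc, attr(coefficients, "freqs_hz") %||% seq_len(d[3]),
             attr(coefficients, "times_s") %||% seq_len(d[4]),
             "raw_itpc", n_trials)
}

#' Memory-bounded ITPC of subject epochs
#'
#' Computes the same raw ITPC map as
#' `compute_itpc(morlet_transform(epochs, spec))` but streams over
#' frequencies, so only one frequency's coefficient block is in memory at a
#' time. This is the pipeline's workhorse for realistic trial and vertex
#' counts.
#'
#' @inheritParams morlet_transform
#' @inheritParams compute_itpc
#' @param time_decim integer output-time decimation factor. The decimated
#'   coefficients are computed exactly (spectral folding), so every retained
#'   bin is identical to the corresponding bin at `time_decim = 1`; only the
#'   map's time axis gets coarser. The wavelet output is band-limited with a
#'   ~0.3 s envelope, so window averages are insensitive to moderate
#'   decimation (factor 4 keeps > 10 samples per envelope width at the
#'   default rates).
#' @param time_keep_s optional list of closed time intervals (each
#'   `c(lo, hi)`, seconds); when given, only decimated bins falling in one
#'   of the intervals are computed (by direct kernel correlation rather
#'   than FFT convolution) and the returned map's time axis is restricted
#'   accordingly. Bin values are identical to the full transform. Used by
#'   the pipeline, which only consumes the baseline and analysis windows.
#' @return a `tf_map` of kind `"raw_itpc"`.
#' @export
itpc_tfr <- function(epochs, spec = morlet_spec(),
                     zero_phase = c("error", "exclude"), time_decim = 1L,
                     time_keep_s = NULL) {
  stopifnot(inherits(epochs, "subject_epochs"), inherits(spec, "morlet_spec"),
            time_decim >= 1L)
  zero_phase <- match.arg(zero_phase)
  time_decim <- as.integer(time_decim)
  check_nyquist(spec, epochs$sample_rate_hz)
  check_support(spec, epochs$times_s, epochs$sample_rate_hz)
  d <- dim(epochs$data)
  n_trials <- d[1]; n_vert <- d[2]; n_time <- d[3]
  if (n_trials < 2L) stop_assr("ITPC requires at least 2 trials (got %d)", n_trials)
  x <- matrix(aperm(epochs$data, c(3, 1, 2)), nrow = n_time)
  keep <- seq.int(1L, n_time, by = time_decim)
  if (!is.null(time_keep_s)) {
    tk <- epochs$times_s[keep]
    sel <- Reduce(`|`, lapply(time_keep_s, function(w) in_window(tk, w)))
    if (!any(sel)) stop_assr("time_keep_s selects no samples")
    keep <- keep[sel]
  }
  times_out <- epochs$times_s[keep]
  valid <- tf_valid_mask(times_out, spec,
                         epoch_range = range(epochs$times_s))  # kept times x freqs
  nf <- length(spec$freq_grid_hz)
  n_keep <- length(keep)
  use_fft <- is.null(time_keep_s)
  if (use_fft) {
    max_kl <- length(morlet_kernel(min(spec$freq_grid_hz),
                                   epochs$sample_rate_hz, spec)$kernel)
    npad <- stats::nextn(n_time + max_kl, 2)
    if (npad %% time_decim != 0L) npad <- npad * time_decim / gcd_int(npad, time_decim)
    xp <- matrix(0, npad, ncol(x)); xp[seq_len(n_time), ] <- x
    x_fft <- stats::mvfft(xp)
  }
  itpc <- array(NA_real_, dim = c(n_vert, nf, n_keep))
  for (j in seq_len(nf)) {
    kern <- morlet_kernel(spec$freq_grid_hz[j], epochs$sample_rate_hz, spec)
    cf <- if (use_fft) tf_filter(x_fft, npad, n_time, kern, decim = time_decim)
          else tf_correlate(x, keep, kern)
    mod <- Mod(cf)
    zero <- mod == 0 & valid[, j]
    if (any(zero)) {
      if (zero_phase == "error")
        stop_assr("zero-magnitude wavelet coefficient at %g Hz: phase undefined (%d bins)",
                  spec$freq_grid_hz[j], sum(zero))
      mod[zero] <- 1
    }
    u <- cf / mod
    if (any(zero)) u[zero] <- 0i
    dim(u) <- c(n_keep, n_trials, n_vert)
    s <- u[, 1, ]
    for (r in seq(2, n_trials)) s <- s + u[, r, ]
    denom <- n_trials
    if (any(zero)) {
      z <- array(zero, dim = c(n_keep, n_trials, n_vert))
      denom <- n_trials - rowSums(aperm(z, c(1, 3, 2)), dims = 2)
    }
    vals <- Mod(s) / denom                       # n_keep x n_vert
    vals[!valid[, j], ] <- NA_real_
    itpc[, j, ] <- t(vals)
  }
  new_tf_map(itpc, spec$freq_grid_hz, times_out, "raw_itpc", n_trials)
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

# Direct banded kernel correlation: coefficients at the requested absolute
# sample positions only, via two real matrix products (BLAS). Samples
# outside the epoch are treated as zeros, exactly as the zero-padded FFT
# path does, so both engines agree bin for bin.
tf_correlate <- function(x, out_idx, kern) {
  n_time <- nrow(x)
  kl <- length(kern$kernel)
  half <- (kl - 1L) %/% 2L
  kc <- Conj(kern$kernel)
  n_out <- length(out_idx)
  Kre <- matrix(0, n_out, n_time)
  Kim <- matrix(0, n_out, n_time)
  for (a in seq_len(n_out)) {
    p <- out_idx[a]
    s0 <- max(1L, p - half); s1 <- min(n_time, p + half)
    dd <- (s0:s1) - p                     # kernel offsets
    Kre[a, s0:s1] <- Re(kc)[dd + half + 1L]
    Kim[a, s0:s1] <- Im(kc)[dd + half + 1L]
  }
  cre <- Kre %*% x
  cim <- Kim %*% x
  matrix(complex(real = cre, imaginary = cim), n_out, ncol(x))
}

#' Percent-change baseline normalization of a time-frequency map
#'
#' Event-related perturbation scaling: for every vertex and frequency, each
#' time point is expressed as percent deviation from that vertex/frequency's
#' mean over the pre-stimulus baseline window,
#' `(x - mean_baseline) / mean_baseline * 100`. The default baseline of
#' -500 to -200 ms stays clear of wavelet edge effects and of smearing from
#' post-onset activity.
#'
#' @param map a `tf_map` (kind `"raw_itpc"`).
#' @param baseline_window_s closed baseline interval in seconds.
#' @return a `tf_map` of kind `"normalized_itpc"`, in percent units.
#' @export
normalize_percent_change <- function(map, baseline_window_s = c(-0.5, -0.2)) {
  stopifnot(inherits(map, "tf_map"))
  bidx <- idx_window(map$times_s, baseline_window_s)
  if (length(bidx) == 0L) stop_assr("baseline window [%g, %g] s contains no samples",
                                    baseline_window_s[1], baseline_window_s[2])
  vals <- map$values
  base <- rowMeans(vals[, , bidx, drop = FALSE], dims = 2)    # vertices x freqs
  if (anyNA(base))
    stop_assr("baseline window overlaps edge-invalidated samples; shrink it or enlarge the epoch")
  bad <- which(base <= .Machine$double.eps, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_assr("baseline mean is ~0 at vertex %d, frequency %g Hz: cannot normalize",
              bad[1, 1], map$freqs_hz[bad[1, 2]])
  out <- 100 * sweep(sweep(vals, c(1, 2), base, "-"), c(1, 2), base, "/")
  new_tf_map(out, map$freqs_hz, map$times_s, "normalized_itpc", map$n_trials)
}

#' Band/time window average of a time-frequency map
#'
#' Arithmetic mean over all (frequency, time) bins whose centers lie in the
#' closed band and window; defaults select the 39-41 Hz steady-state band in
#' the 200-900 ms interval where 40 Hz entrainment has stabilized.
#'
#' @param map a `tf_map`.
#' @param freq_band_hz closed frequency band.
#' @param time_window_s closed time window (s).
#' @return named numeric vector, one value per vertex.
#' @export
window_average <- function(map, freq_band_hz = c(39, 41),
                           time_window_s = c(0.2, 0.9)) {
  stopifnot(inherits(map, "tf_map"))
  fi <- idx_window(map$freqs_hz, freq_band_hz)
  ti <- idx_window(map$times_s, time_window_s)
  if (length(fi) == 0L || length(ti) == 0L)
    stop_assr("empty selection: band [%g, %g] Hz x window [%g, %g] s",
              freq_band_hz[1], freq_band_hz[2], time_window_s[1], time_window_s[2])
  sel <- map$values[, fi, ti, drop = FALSE]
  if (anyNA(sel))
    stop_assr("window [%g, %g] s overlaps edge-invalidated samples", time_window_s[1],
              time_window_s[2])
  out <- rowMeans(matrix(sel, nrow = dim(sel)[1]))
  names(out) <- seq_along(out)
  out
}

#' @export
print.tf_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("tf_map (%s): %d vertices x %d freqs (%g-%g Hz) x %d times [%g, %g] s, %d trials\n",
              x$kind, d[1], d[2], min(x$freqs_hz), max(x$freqs_hz), d[3],
              x$times_s[1], x$times_s[length(x$times_s)], x$n_trials))
  invisible(x)
}

#' Image plot of one vertex's time-frequency map
#'
#' @param x a `tf_map`.
#' @param vertex vertex index to display.
#' @param ... passed to [graphics::image()].
#' @export
plot.tf_map <- function(x, vertex = 1L, ...) {
  m <- t(x$values[vertex, , ])
  graphics::image(x$times_s, x$freqs_hz, m, xlab = "time (s)",
                  ylab = "frequency (Hz)",
                  main = sprintf("%s, vertex %d", x$kind, vertex),
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
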