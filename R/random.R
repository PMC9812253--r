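#' Draw from the von Mises circular distribution
#'
#' Samples angles from the von Mises distribution with mean direction `mu`
#' and concentration `kappa`, the standard circular analogue of the Gaussian.
#' Used by the cohort generator to model trial-to-trial phase jitter of the
#' 40 Hz steady-state component: `kappa = 0` gives uniform phases (no
#' locking), large `kappa` gives tightly concentrated phases, and
#' `kappa = Inf` is treated as perfect locking (all angles equal `mu`).
#'
#' Implements the Best-Fisher (1979) rejection sampler; draws are generated
#' in vectorised batches.
#'
#' @param n number of draws.
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`; `Inf` allowed.
#' @return numeric vector of `n` angles in `(-pi, pi]`.
#' @examples
#' set.seed(1)
#' th <- rvonmises(1000, 0, 4)
#' # mean resultant length approximates I1(kappa)/I0(kappa)
#' Mod(mean(exp(1i * th)))
#' besselI(4, 1) / besselI(4, 0)
#' @export
rvonmises <- function(n, mu = 0, kappa) {
  stopifnot(length(kappa) == 1L, kappa >= 0, n >= 0)
  if (n == 0L) return(numeric(0))
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (!is.finite(kappa))
    return(rep(if (mu > -pi && mu <= pi) mu else wrap_pi(mu), n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling(1.3 * (n - length(out))))
    u1 <- stats::runif(m)
    u2 <- stats::runif(m)
    u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    keep <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    theta <- sign(u3[keep] - 0.5) * acos(pmin(1, pmax(-1, f[keep])))
    out <- c(out, theta)
  }
  wrap_pi(out[seq_len(n)] + mu)
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  # map -pi to pi for a (-pi, pi] convention
  y[y == -pi] <- pi
  y
}

#' Generate 1/f ("pink") noise series
#'
#' Spectrally shaped Gaussian noise whose amplitude spectrum falls off as
#' 1/sqrt(f), giving the approximately 1/f power spectrum typical of
#' resting electrophysiological background activity. Generated by scaling a
#' white Gaussian spectrum in the frequency domain and inverse transforming;
#' each column is standardised to the requested standard deviation.
#'
#' @param n_time samples per series.
#' @param n_series number of independent series (columns).
#' @param sd target standard deviation of each series.
#' @return `n_time` x `n_series` numeric matrix.
#' @export
pink_noise <- function(n_time, n_series = 1L, sd = 1) {
  stopifnot(n_time >= 2L, n_series >= 1L, sd >= 0)
  if (sd == 0) return(matrix(0, n_time, n_series))
  # synthesize the Hermitian spectrum directly (independent complex
  # Gaussians on positive frequencies scaled by 1/sqrt(f), zero DC) on a
  # 2-3-5-smooth length >= n_time, then truncate: stationarity makes the
  # truncated block a valid realization, and smooth lengths keep the
  # inverse FFT fast for awkward (e.g. prime) epoch lengths
  m <- stats::nextn(n_time, c(2, 3, 5))
  nh <- (m - 1L) %/% 2L                    # strictly positive, non-Nyquist bins
  W <- matrix(complex(real = 0), m, n_series)
  g <- matrix(complex(real = stats::rnorm(nh * n_series),
                      imaginary = stats::rnorm(nh * n_series)), nh, n_series)
  W[1L + seq_len(nh), ] <- g / sqrt(seq_len(nh))
  if (m %% 2L == 0L)                       # real Nyquist bin
    W[m %/% 2L + 1L, ] <- stats::rnorm(n_series) / sqrt(m / 2)
  W[m + 1L - seq_len(nh), ] <- Conj(W[1L + seq_len(nh), , drop = FALSE])
  x <- Re(stats::mvfft(W, inverse = TRUE))[seq_len(n_time), , drop = FALSE] / m
  sds <- sqrt(colMeans(x^2) - colMeans(x)^2)
  sds[sds == 0] <- 1
  sweep(x, 2L, sds / sd, "/")
}
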