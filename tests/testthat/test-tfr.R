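test_that("Morlet kernel envelope has the specified FWHM and constant-cycle scaling", {
  spec <- morlet_spec()
  k40 <- morlet_kernel(40, 500, spec)
  expect_equal(sum(Mod(k40$kernel)^2), 1, tolerance = 1e-12)   # energy norm
  # sigma scales as f0/f: FWHM at 20 Hz is twice that at 40 Hz
  k20 <- morlet_kernel(20, 500, spec)
  fwhm <- function(k) {
    env <- Mod(k$kernel)
    diff(range(k$t[env >= max(env) / 2]))
  }
  expect_equal(fwhm(k20), 0.6, tolerance = 1 / 500 + 1e-9)
  expect_equal(k20$sigma_t, 2 * k40$sigma_t, tolerance = 1e-12)
})

test_that("morlet_spec validates its grid and warns on too few cycles", {
  expect_error(morlet_spec(freq_grid_hz = c(40, 39)), "increasing")
  expect_error(morlet_spec(center_freq_hz = -40), "positive")
  expect_warning(morlet_spec(center_freq_hz = 5, time_resolution_s = 0.3,
                             freq_grid_hz = 4:6), "cycles")
})

test_that("stationary sinusoid has constant magnitude and demodulated phase", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(2L, 2L),
                    n_vertices_per_hemisphere = 2L)
  s <- simulate_subject(p, 1)
  for (r in 1:2) for (v in 1:4) s$data[r, v, ] <- cos(2 * pi * 40 * s$times_s)
  co <- morlet_transform(s, smoke_morlet())
  f40 <- which(attr(co, "freqs_hz") == 40)
  # interior: clear of the full (5 sigma) kernel support, where truncation
  # against the epoch edge cannot ripple the magnitude
  interior <- s$times_s > -0.9 + 0.75 & s$times_s < 1.3 - 0.75
  cf <- co[1, 1, f40, interior]
  expect_lt(sd(Mod(cf)) / mean(Mod(cf)), 1e-6)
  demod <- Arg(cf * exp(-2i * pi * 40 * s$times_s[interior]))
  expect_lt(diff(range(demod)), 1e-3)
})

test_that("transform is linear: scaling amplitudes scales magnitudes, not phases", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(3L, 3L),
                    n_vertices_per_hemisphere = 2L)
  s <- simulate_subject(p, 1)
  s3 <- s; s3$data <- 3 * s$data
  a <- morlet_transform(s, smoke_morlet())
  b <- morlet_transform(s3, smoke_morlet())
  expect_equal(Mod(b), 3 * Mod(a), tolerance = 1e-10)
  expect_equal(Arg(b[, , , 100:200]), Arg(a[, , , 100:200]), tolerance = 1e-9)
})

test_that("ITPC closed forms: aligned, symmetric-cancelling, and two-phase cases", {
  aligned <- array(rep(exp(1i * 0.8), 4), c(4, 1, 1, 1))
  expect_equal(compute_itpc(aligned)$values[1, 1, 1], 1, tolerance = 1e-12)
  sym <- array(exp(1i * c(0, 2 * pi / 3, 4 * pi / 3)), c(3, 1, 1, 1))
  expect_equal(compute_itpc(sym)$values[1, 1, 1], 0, tolerance = 1e-12)
  two <- array(exp(1i * c(0, pi / 2)), c(2, 1, 1, 1))
  expect_equal(compute_itpc(two)$values[1, 1, 1], sqrt(2) / 2, tolerance = 1e-12)
  expect_error(compute_itpc(array(1 + 0i, c(1, 1, 1, 1))), "2 trials")
})

test_that("ITPC ignores per-trial amplitude scaling (phases only)", {
  set.seed(11)
  coef <- array(complex(real = rnorm(5 * 2 * 2 * 6), imaginary = rnorm(120)),
                c(5, 2, 2, 6))
  scaled <- coef * rep(runif(5, 0.1, 10), times = 24)  # per-trial gains
  expect_equal(compute_itpc(coef)$values, compute_itpc(scaled)$values,
               tolerance = 1e-12)
})

test_that("zero-magnitude coefficients error by default and can be excluded", {
  coef <- array(exp(1i * c(0, 0.1, 0.2)), c(3, 1, 1, 2))
  coef[2, 1, 1, 1] <- 0 + 0i
  expect_error(compute_itpc(coef), "zero-magnitude")
  m <- compute_itpc(coef, zero_phase = "exclude")
  # bin 1 averages the remaining two trials
  expect_equal(m$values[1, 1, 1], Mod(mean(exp(1i * c(0, 0.2)))), tolerance = 1e-12)
  expect_equal(m$values[1, 1, 2], Mod(mean(exp(1i * c(0, 0.1, 0.2)))), tolerance = 1e-12)
})

test_that("streaming, materialized, decimated and windowed ITPC engines agree", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(6L, 6L),
                    n_vertices_per_hemisphere = 3L)
  s <- simulate_subject(p, 1)
  spec <- smoke_morlet()
  full <- itpc_tfr(s, spec)
  mat <- compute_itpc(morlet_transform(s, spec))
  expect_equal(full$values, mat$values, tolerance = 1e-12)
  dec <- itpc_tfr(s, spec, time_decim = 3L)
  keep <- seq(1, length(full$times_s), by = 3)
  expect_equal(full$values[, , keep], dec$values, tolerance = 1e-12)
  win <- itpc_tfr(s, spec, time_decim = 3L,
                  time_keep_s = list(c(-0.5, -0.2), c(0.2, 0.9)))
  idx <- match(round(win$times_s, 10), round(dec$times_s, 10))
  expect_equal(dec$values[, , idx], win$values, tolerance = 1e-12)
})

test_that("edge bins are invalidated per frequency; grid beyond Nyquist errors", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(3L, 3L),
                    n_vertices_per_hemisphere = 2L)
  s <- simulate_subject(p, 1)
  m <- itpc_tfr(s, smoke_morlet())
  f39 <- which(m$freqs_hz == 39)
  fw <- 0.3 * 40 / 39
  expect_true(all(is.na(m$values[, f39, m$times_s < -0.9 + fw - 1e-9])))
  expect_false(anyNA(m$values[, f39, m$times_s > -0.9 + fw + 0.01 &
                                m$times_s < 1.3 - fw - 0.01]))
  expect_error(itpc_tfr(s, morlet_spec(freq_grid_hz = c(40, 80))), "Nyquist")
})

test_that("percent-change normalization arithmetic", {
  times <- seq(-0.6, 1, by = 0.02)
  vals <- array(0.25, c(2, 1, length(times)))
  m <- toy_tf_map(vals, 40, times)
  nm <- normalize_percent_change(m)
  expect_true(all(nm$values == 0))
  expect_identical(nm$kind, "normalized_itpc")

  v2 <- vals
  v2[, , times > 0] <- 0.5                 # doubling the baseline mean
  nm2 <- normalize_percent_change(toy_tf_map(v2, 40, times))
  expect_equal(unique(as.vector(nm2$values[, , times > 0])), 100)

  # baseline {2,2,2}, in-window value 3 -> 50
  t3 <- c(-0.5, -0.35, -0.2, 0.5)
  v3 <- array(c(2, 2, 2, 3), c(1, 1, 4))
  nm3 <- normalize_percent_change(toy_tf_map(v3, 40, t3))
  expect_equal(nm3$values[1, 1, 4], 50)

  vz <- array(0, c(1, 1, length(times)))
  expect_error(normalize_percent_change(toy_tf_map(vz, 40, times)), "cannot normalize")
  expect_error(normalize_percent_change(m, baseline_window_s = c(-2, -1.8)),
               "no samples")
})

test_that("window averaging selects exactly the 39-41 Hz bins on the default grid", {
  times <- seq(-0.6, 1, by = 0.02)
  freqs <- 35:45
  vals <- array(rep(freqs, each = 3), c(3, 11, length(times)))  # value = frequency
  m <- toy_tf_map(vals, freqs, times)
  wa <- window_average(m)
  expect_equal(unname(wa), rep(40, 3))      # mean of {39, 40, 41}
  expect_equal(unname(window_average(m, c(35, 45), c(0.2, 0.9))), rep(40, 3))
  expect_error(window_average(m, c(50, 60)), "empty selection")
})

test_that("normalize-then-average equals average-then-normalize only for equal baselines", {
  times <- c(-0.5, -0.35, -0.2, 0.4, 0.6)
  freqs <- c(39, 40)
  # baseline 0.2 at both freqs; in-window 0.4 (39 Hz), 0.6 (40 Hz)
  v <- array(0, c(1, 2, 5))
  v[1, , 1:3] <- 0.2
  v[1, 1, 4:5] <- 0.4; v[1, 2, 4:5] <- 0.6
  m <- toy_tf_map(v, freqs, times)
  a <- window_average(normalize_percent_change(m, c(-0.5, -0.2)), c(39, 40), c(0.4, 0.6))
  manual <- mean(c((0.4 - 0.2) / 0.2, (0.6 - 0.2) / 0.2)) * 100
  expect_equal(unname(a), manual)
  # unequal baselines: normalizing after band-averaging gives a different number
  v2 <- v; v2[1, 2, 1:3] <- 0.1
  m2 <- toy_tf_map(v2, freqs, times)
  a2 <- window_average(normalize_percent_change(m2, c(-0.5, -0.2)), c(39, 40), c(0.4, 0.6))
  collapsed <- apply(v2, c(1, 3), mean)     # average bands first
  b2 <- (mean(collapsed[1, 4:5]) - mean(collapsed[1, 1:3])) / mean(collapsed[1, 1:3]) * 100
  expect_false(isTRUE(all.equal(unname(a2), b2)))
})
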