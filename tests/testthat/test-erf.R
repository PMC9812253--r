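make_epochs <- function(data, times, hemi = NULL) {
  nv <- dim(data)[2]
  if (is.null(hemi)) hemi <- rep(c("left", "right"), length.out = nv)
  structure(list(subject_id = "T01", age_years = 9, data = data,
                 times_s = times, sample_rate_hz = 1 / diff(times[1:2]),
                 vertices = data.frame(vertex = seq_len(nv), hemisphere = hemi,
                                       x = seq_len(nv), y = 0, z = 0),
                 ground_truth = NULL),
            class = "subject_epochs")
}

test_that("DC offset correction zeroes the correction-window mean per trial and vertex", {
  times <- seq(-0.5, 1.2, by = 0.01)
  set.seed(21)
  data <- array(rnorm(3 * 2 * length(times)), c(3, 2, length(times)))
  # constant trial becomes all zeros
  data[1, 1, ] <- 4.2
  out <- dc_offset_correct(make_epochs(data, times))
  expect_equal(out$data[1, 1, ], rep(0, length(times)), tolerance = 1e-12)
  idx <- which(times >= -0.1 & times <= -0.002)
  expect_lt(max(abs(apply(out$data[, , idx], c(1, 2), mean))), 1e-12)
  # additive per-trial constants are removed entirely
  shifted <- data + rep(c(5, -3, 0.7), times = 2 * length(times))
  out2 <- dc_offset_correct(make_epochs(shifted, times))
  expect_equal(out2$data, out$data, tolerance = 1e-12)
  expect_error(dc_offset_correct(make_epochs(data, times), c(5, 6)), "no samples")
})

test_that("epoch averaging is the arithmetic trial mean", {
  times <- seq(-0.2, 0.5, by = 0.01)
  one <- outer(1:2, sin(times * 3))
  data <- array(NA_real_, c(4, 2, length(times)))
  for (r in 1:4) data[r, , ] <- one
  ev <- average_evoked(make_epochs(data, times))
  expect_equal(ev$values, one, tolerance = 1e-12)
  data2 <- data
  data2[2, , ] <- -one; data2[4, , ] <- -one
  ev2 <- average_evoked(make_epochs(data2[1:2, , ], times))
  expect_equal(ev2$values, matrix(0, 2, length(times)), tolerance = 1e-12)
})

test_that("phase-jittered oscillations attenuate by the Bessel-ratio factor", {
  # links averaging to the same circular statistic as ITPC
  kappa <- 3
  p <- smoke_params(n_subjects = 3L, trials_range = c(60L, 60L),
                    n_vertices_per_hemisphere = 2L,
                    kappa0 = kappa, kappa_age_slope = 0, kappa_right_bonus = 0,
                    kappa_subject_sd = 0, erf_amp0 = 0, erf_subject_sd = 0,
                    noise_white_sd = 0, noise_pink_sd = 0, assr_amp = 1)
  co <- quiet_run(simulate_cohort(p))
  amps <- vapply(co$subjects, function(s) {
    ev <- average_evoked(s)
    pk <- s$ground_truth$peak_vertex[["right"]]
    idx <- which(s$times_s >= 0.3 & s$times_s <= 0.9)
    sqrt(2 * mean(ev$values[pk, idx]^2))   # sinusoid amplitude from RMS
  }, numeric(1))
  expect_equal(mean(amps), vm_resultant(kappa), tolerance = 0.08)
})

test_that("z-score normalization arithmetic and affine invariance", {
  times <- c(-0.09, -0.05, 0.5)
  x <- matrix(c(0, 2, 3), 1)               # baseline {0, 2}: mu 1, sd sqrt(2)
  z <- zscore_normalize(x, baseline_s = c(-0.1, -0.002), times_s = times)
  expect_equal(z$zmap[1, 3], sqrt(2), tolerance = 1e-12)
  # x(t) equal to the baseline mean maps to 0
  const <- zscore_normalize(matrix(c(0, 2, 1), 1), baseline_s = c(-0.1, -0.002),
                            times_s = times)
  expect_equal(const$zmap[1, 3], 0, tolerance = 1e-12)
  # affine transforms of the input leave the z map unchanged
  set.seed(31)
  ev <- matrix(rnorm(300), 2)
  tt <- seq(-0.12, 1.3, length.out = 150)
  z1 <- zscore_normalize(ev, times_s = tt)
  z2 <- zscore_normalize(3.7 * ev + 11, times_s = tt)
  expect_equal(z1$zmap, z2$zmap, tolerance = 1e-10)
  # zero baseline SD errors with the vertex named
  bad <- ev; bad[2, tt >= -0.1 & tt <= -0.002] <- 5
  expect_error(zscore_normalize(bad, times_s = tt), "vertex 2")
})

test_that("z-scored baseline has mean ~0 and sample SD ~1", {
  set.seed(32)
  tt <- seq(-0.5, 1.2, by = 0.002)
  ev <- matrix(rnorm(5 * length(tt), mean = 3, sd = 2), 5)
  z <- zscore_normalize(ev, times_s = tt)
  idx <- which(tt >= -0.1 & tt <= -0.002)
  expect_lt(max(abs(rowMeans(z$zmap[, idx]))), 1e-10)
  expect_lt(max(abs(apply(z$zmap[, idx], 1, sd) - 1)), 1e-10)
})

test_that("sustained amplitude is the rectified window mean", {
  tt <- seq(-0.2, 1.2, by = 0.001)
  zc <- rbind(rep(1.3, length(tt)), rep(-1.3, length(tt)))
  expect_equal(unname(sustained_amplitude(zc, times_s = tt)), c(1.3, 1.3),
               tolerance = 1e-12)
  # 1 Hz sinusoid: numeric-integration oracle of mean |sin(2 pi t)| over
  # the closed 0.2-1.0 s window (1.6 half-periods, so not exactly 2/pi)
  zs <- matrix(sin(2 * pi * 1 * tt), 1)
  tfine <- seq(0.2, 1.0, length.out = 200001)
  f <- abs(sin(2 * pi * tfine))
  oracle <- sum((f[-1] + f[-length(f)]) / 2) / (length(tfine) - 1)
  expect_equal(unname(sustained_amplitude(zs, times_s = tt)), oracle,
               tolerance = 2e-3)
})

test_that("spatial smoothing: normalization, locality, coincident vertices", {
  coords <- matrix(c(0, 0, 0,  1, 0, 0,  0, 1, 0,  100, 0, 0), 4, byrow = TRUE)
  const <- spatial_smooth(rep(2.5, 4), coords, fwhm_mm = 3)
  expect_equal(const, rep(2.5, 4), tolerance = 1e-12)
  spike <- spatial_smooth(c(0, 0, 0, 1), coords, fwhm_mm = 3)
  expect_equal(spike[4], 1, tolerance = 1e-6)        # >= 5 sigma from others
  expect_lt(max(spike[1:3]), 1e-6)
  co2 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_equal(spatial_smooth(c(0, 2), co2, fwhm_mm = 3), c(1, 1),
               tolerance = 1e-12)
  expect_error(spatial_smooth(c(1, NA_real_, 3)[1:2], rbind(c(0, 0, 0), c(NA, 0, 0)), 3),
               "non-finite")
  expect_identical(spatial_smooth(c(1, 2), co2, fwhm_mm = 0), c(1, 2))
})

test_that("smoothing approximately conserves the field mean on a uniform lattice", {
  g <- as.matrix(expand.grid(x = 0:4, y = 0:4, z = 0))
  set.seed(33)
  vals <- rnorm(nrow(g))
  sm <- spatial_smooth(vals, g, fwhm_mm = 1.5)
  expect_lt(abs(mean(sm) - mean(vals)), 0.1)   # boundary renormalization only
})
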