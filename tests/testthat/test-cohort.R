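test_that("cohort simulation is deterministic subject by subject", {
  p <- smoke_params(n_subjects = 3L)
  c1 <- quiet_run(simulate_cohort(p))
  c2 <- quiet_run(simulate_cohort(p))
  expect_identical(c1$ground_truth, c2$ground_truth)
  for (i in 1:3) expect_identical(c1$subjects[[i]]$data, c2$subjects[[i]]$data)
  # a different seed changes the data
  p2 <- smoke_params(n_subjects = 3L, seed = 999L)
  c3 <- quiet_run(simulate_cohort(p2))
  expect_false(identical(c1$subjects[[1]]$data, c3$subjects[[1]]$data))
})

test_that("structural invariants: trials, ages, time axis, labels", {
  p <- smoke_params(n_subjects = 5L, trials_range = c(5L, 9L))
  co <- quiet_run(simulate_cohort(p))
  nt <- co$ground_truth$n_trials
  expect_true(all(nt >= 5L & nt <= 9L))
  expect_true(sum(nt) >= 5 * 5 && sum(nt) <= 5 * 9)
  expect_true(all(co$ground_truth$age >= 7.06 & co$ground_truth$age <= 12.03))
  s <- co$subjects[[1]]
  expect_true(all(diff(s$times_s) > 0))
  expect_true(0 %in% s$times_s)
  expect_true(all(s$vertices$hemisphere %in% c("left", "right")))
  expect_identical(sum(s$vertices$hemisphere == "left"), 8L)
})

test_that("ground-truth kappa is strictly age-ordered without subject scatter", {
  p <- smoke_params(n_subjects = 8L, kappa_subject_sd = 0)
  co <- quiet_run(simulate_cohort(p))
  gt <- co$ground_truth
  expect_identical(cor(gt$age, gt$kappa_right, method = "spearman"), 1)
  expect_identical(cor(gt$age, gt$kappa_left, method = "spearman"), 1)
  expect_true(all(gt$kappa_right > gt$kappa_left))
})

test_that("perfect phase locking yields raw ITPC of exactly 1 in the stimulation window", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(10L, 10L),
                    n_vertices_per_hemisphere = 4L,
                    kappa0 = Inf, kappa_age_slope = 0, kappa_right_bonus = 0,
                    kappa_subject_sd = 0, noise_white_sd = 0, noise_pink_sd = 0,
                    erf_subject_sd = 0, erf_latency_jitter_s = 0)
  s <- simulate_subject(p, 1)
  m <- itpc_tfr(s, smoke_morlet(), zero_phase = "exclude")
  wa <- window_average(m)
  expect_equal(unname(wa), rep(1, 8), tolerance = 1e-9)
})

test_that("uniform trial phases give the closed-form expected resultant", {
  # E[R] for n uniform phases is ~ sqrt(pi / (4 n)); per subject the window
  # holds a single resultant realization, so average across subjects
  p <- smoke_params(n_subjects = 60L, trials_range = c(80L, 80L),
                    n_vertices_per_hemisphere = 2L,
                    kappa0 = 0, kappa_age_slope = 0, kappa_right_bonus = 0,
                    kappa_subject_sd = 0, erf_amp0 = 0, erf_subject_sd = 0,
                    noise_white_sd = 0, noise_pink_sd = 0)
  co <- quiet_run(simulate_cohort(p))
  vals <- vapply(co$subjects, function(s) {
    m <- itpc_tfr(s, smoke_morlet(), zero_phase = "exclude",
                  time_keep_s = list(c(0.3, 0.8)))
    mean(window_average(m, time_window_s = c(0.3, 0.8)))
  }, numeric(1))
  expect_equal(mean(vals), sqrt(pi / (4 * 80)), tolerance = 0.12)
})

test_that("simulated trials carry a 40 Hz spectral peak only when the ASSR is on", {
  spec_power <- function(a_assr) {
    p <- smoke_params(n_subjects = 1L, trials_range = c(12L, 12L),
                      n_vertices_per_hemisphere = 2L, assr_amp = a_assr,
                      erf_amp0 = 0, erf_subject_sd = 0, seed = 7L)
    s <- simulate_subject(p, 1)
    pk <- s$ground_truth$peak_vertex[["right"]]
    idx <- which(s$times_s >= 0.25 & s$times_s <= 1.0)
    seg <- s$data[, pk, idx]
    n <- length(idx)
    freqs <- (seq_len(n) - 1) * s$sample_rate_hz / n
    pw <- rowMeans(apply(seg, 1, function(tr) Mod(fft(tr))^2))
    c(band = mean(pw[freqs >= 38 & freqs <= 42]),
      ref = mean(pw[freqs >= 25 & freqs <= 33]))
  }
  on <- spec_power(2)
  off <- spec_power(0)
  expect_gt(on[["band"]] / on[["ref"]], 3)
  expect_lt(off[["band"]] / off[["ref"]], 1.5)
})

test_that("no-signal data leave in-window ITPC at the baseline level", {
  p <- smoke_params(n_subjects = 1L, trials_range = c(60L, 60L),
                    n_vertices_per_hemisphere = 6L, assr_amp = 0,
                    erf_amp0 = 0, erf_subject_sd = 0, seed = 31L)
  s <- simulate_subject(p, 1)
  m <- itpc_tfr(s, smoke_morlet(), time_decim = 3L)
  win <- window_average(m)
  base <- window_average(m, time_window_s = c(-0.5, -0.2))
  expect_lt(abs(mean(win) - mean(base)), 0.05)
})

test_that("higher kappa never lowers expected downstream ITPC (matched seeds)", {
  grid <- c(0.5, 1, 2, 4)
  means <- vapply(grid, function(k) {
    p <- smoke_params(n_subjects = 4L, trials_range = c(24L, 24L),
                      n_vertices_per_hemisphere = 4L,
                      kappa0 = k, kappa_age_slope = 0, kappa_right_bonus = 0,
                      kappa_subject_sd = 0, seed = 555L)
    co <- quiet_run(simulate_cohort(p))
    mean(vapply(co$subjects, function(s) {
      m <- itpc_tfr(s, smoke_morlet(), time_decim = 3L,
                    time_keep_s = list(c(0.2, 0.9)))
      pk <- s$ground_truth$peak_vertex[["right"]]
      window_average(m)[[pk]]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("parameter validation rejects inconsistent cohorts", {
  expect_error(smoke_params(epoch_window_s = c(-0.3, 1.2)), "contain")
  expect_error(smoke_params(trials_range = c(0L, 5L)), "trials_range")
  expect_error(smoke_params(kappa0 = -1), "kappa")
  expect_error(smoke_params(sample_rate_hz = 60), "Nyquist|exceed")
  expect_no_warning(cohort_params(n_subjects = 2L))  # warned only at simulate
  expect_warning(simulate_cohort(cohort_params(
    n_subjects = 2L, trials_range = c(3L, 3L), n_vertices_per_hemisphere = 2L,
    epoch_window_s = c(-0.9, 1.3), sample_rate_hz = 150)), "fewer than 3")
})
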