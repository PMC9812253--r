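# Synthetic source-space cohort generator.
#
# Emulates the data structure the downstream analysis assumes: per-child
# source-space epochs (trials x vertices x time) carrying a 40 Hz
# steady-state component whose trial-phase concentration (von Mises kappa)
# grows with age and is larger on the right, a sustained evoked component
# whose amplitude declines with age, a spatial Gaussian profile over a
# vertex cloud anchored at canonical auditory-cortex locations, and
# white + 1/f background noise. Ground truth is recorded per subject for
# parameter-recovery tests.

# Anchors for the per-hemisphere vertex clouds: canonical MNI-scale
# auditory-cortex locations, so synthetic coordinate summaries are on a
# realistic scale.
.hemi_centers <- list(left  = c(-49.47, -22.25, 6.53),
                      right = c( 52.46, -23.85, 10.51))

#' Parameters of a synthetic ASSR cohort
#'
#' Defines the generative conditions for [simulate_cohort()]. Defaults
#' describe a cohort of 30 children aged 7.06-12.03 years with 72-87
#' artifact-free trials each, 3 s epochs (-1.5 to +1.5 s around stimulus
#' onset) at 500 Hz, 50 source vertices per hemisphere, an age-increasing
#' and right-dominant trial-phase concentration, an age-decreasing sustained
#' field, and a posterior drift of the right-hemisphere response peak with
#' age.
#'
#' @param n_subjects number of children.
#' @param age_range_years age interval sampled uniformly.
#' @param trials_range inclusive integer range of artifact-free trials per
#'   subject.
#' @param n_vertices_per_hemisphere vertices per hemisphere in the synthetic
#'   source cloud.
#' @param epoch_window_s epoch limits in seconds around stimulus onset; must
#'   contain `[-0.5, 1.0]` so all analysis windows fit.
#' @param sample_rate_hz source sampling rate (Hz).
#' @param kappa0 baseline von Mises concentration of 40 Hz trial phases at
#'   age 7 (left hemisphere).
#' @param kappa_age_slope increase of kappa per year of age.
#' @param kappa_right_bonus additive right-hemisphere kappa increment.
#' @param kappa_subject_sd SD of a lognormal subject-level multiplier on
#'   kappa, shared across hemispheres (drives the subject random intercept
#'   downstream). Set to 0 for a purely age-determined kappa.
#' @param age_effect_left_frac fraction of the age slopes (`kappa_age_slope`
#'   and `erf_age_slope`) expressed in the left hemisphere. Developmental
#'   change of both responses is right-lateralized in this paradigm; the
#'   default 0.4 leaves a weaker, typically non-significant left-hemisphere
#'   age dependence. Set to 1 for symmetric age effects.
#' @param assr_amp amplitude of the 40 Hz steady-state component at the peak
#'   vertex (arbitrary source units).
#' @param assr_freq_hz steady-state frequency (Hz).
#' @param erf_amp0 sustained-field amplitude at age 7 (arbitrary source
#'   units).
#' @param erf_age_slope change of sustained-field amplitude per year
#'   (negative by default).
#' @param erf_subject_sd SD of additive scatter on the sustained-field
#'   amplitude, drawn independently per hemisphere.
#' @param erf_latency_jitter_s half-width of the uniform per-trial latency
#'   jitter of the evoked envelope (seconds).
#' @param topo_shift_mm_per_year posterior (negative Y) shift of the
#'   right-hemisphere response peak per year of age.
#' @param spatial_fwhm_mm FWHM of the Gaussian spatial profile of the
#'   response around the peak vertex.
#' @param vertex_spacing_mm lattice spacing of the synthetic vertex cloud.
#' @param noise_white_sd,noise_pink_sd standard deviations of the white and
#'   1/f noise added per trial and vertex.
#' @param seed master seed; per-subject streams are derived from it by a
#'   fixed offset rule so cohorts are reproducible subject by subject.
#' @return object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 30L,
                          age_range_years = c(7.06, 12.03),
                          trials_range = c(72L, 87L),
                          n_vertices_per_hemisphere = 50L,
                          epoch_window_s = c(-1.5, 1.5),
                          sample_rate_hz = 500,
                          kappa0 = 0.5,
                          kappa_age_slope = 0.5,
                          kappa_right_bonus = 0.8,
                          kappa_subject_sd = 0.15,
                          age_effect_left_frac = 0.4,
                          assr_amp = 2,
                          assr_freq_hz = 40,
                          erf_amp0 = 3,
                          erf_age_slope = -0.35,
                          erf_subject_sd = 0.4,
                          erf_latency_jitter_s = 0.005,
                          topo_shift_mm_per_year = -2,
                          spatial_fwhm_mm = 20,
                          vertex_spacing_mm = 5,
                          noise_white_sd = 1,
                          noise_pink_sd = 1,
                          seed = 1L) {
  p <- list(n_subjects = as.integer(n_subjects),
            age_range_years = as.numeric(age_range_years),
            trials_range = as.integer(round(trials_range)),
            n_vertices_per_hemisphere = as.integer(n_vertices_per_hemisphere),
            epoch_window_s = as.numeric(epoch_window_s),
            sample_rate_hz = as.numeric(sample_rate_hz),
            kappa0 = kappa0, kappa_age_slope = kappa_age_slope,
            kappa_right_bonus = kappa_right_bonus,
            kappa_subject_sd = kappa_subject_sd,
            age_effect_left_frac = age_effect_left_frac,
            assr_amp = assr_amp, assr_freq_hz = assr_freq_hz,
            erf_amp0 = erf_amp0, erf_age_slope = erf_age_slope,
            erf_subject_sd = erf_subject_sd,
            erf_latency_jitter_s = erf_latency_jitter_s,
            topo_shift_mm_per_year = topo_shift_mm_per_year,
            spatial_fwhm_mm = spatial_fwhm_mm,
            vertex_spacing_mm = vertex_spacing_mm,
            noise_white_sd = noise_white_sd, noise_pink_sd = noise_pink_sd,
            seed = as.integer(seed))
  if (p$n_subjects < 1L) stop_assr("n_subjects must be >= 1")
  if (p$trials_range[1] < 1L || p$trials_range[2] < p$trials_range[1])
    stop_assr("trials_range must be an increasing integer interval within [1, Inf)")
  if (!interval_inside(c(-0.5, 1.0), p$epoch_window_s))
    stop_assr("epoch_window_s must contain [-0.5, 1.0] s; got [%g, %g]",
              p$epoch_window_s[1], p$epoch_window_s[2])
  if (p$kappa0 < 0 || p$kappa_right_bonus < 0 || p$kappa_subject_sd < 0)
    stop_assr("kappa parameters must be non-negative")
  if (p$age_effect_left_frac < 0)
    stop_assr("age_effect_left_frac must be non-negative")
  if (p$assr_amp < 0 || p$erf_amp0 < 0 || p$noise_white_sd < 0 || p$noise_pink_sd < 0)
    stop_assr("amplitudes and noise SDs must be non-negative")
  if (p$sample_rate_hz <= 2 * 45)
    stop_assr("sample_rate_hz must exceed twice the top analysis frequency (45 Hz)")
  class(p) <- "cohort_params"
  p
}

#' Build the shared synthetic vertex cloud
#'
#' Vertices lie on a jittered cubic lattice (spacing `vertex_spacing_mm`)
#' around per-hemisphere centroids at canonical auditory-cortex MNI-scale
#' locations. The cloud is shared by all subjects of a cohort (as when
#' individual source maps are projected to a common template) and is
#' deterministic given the cohort seed.
#'
#' @param params a [cohort_params()].
#' @return data.frame with columns `vertex` (integer id), `hemisphere`
#'   (`"left"`/`"right"`), `x`, `y`, `z` (mm).
#' @export
build_vertex_cloud <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n_vertices_per_hemisphere
  s <- params$vertex_spacing_mm
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(subject_seed(params$seed, 0L))
  one_hemi <- function(center) {
    r <- 0L
    repeat {
      g <- expand.grid(x = -r:r, y = -r:r, z = -r:r)
      if (nrow(g) >= n) break
      r <- r + 1L
    }
    d2 <- g$x^2 + g$y^2 + g$z^2
    g <- g[order(d2, g$x, g$y, g$z), , drop = FALSE][seq_len(n), ]
    jit <- matrix(stats::runif(3L * n, -0.2 * s, 0.2 * s), n, 3L)
    cbind(center[1] + g$x * s + jit[, 1],
          center[2] + g$y * s + jit[, 2],
          center[3] + g$z * s + jit[, 3])
  }
  left <- one_hemi(.hemi_centers$left)
  right <- one_hemi(.hemi_centers$right)
  data.frame(vertex = seq_len(2L * n),
             hemisphere = rep(c("left", "right"), each = n),
             x = c(left[, 1], right[, 1]),
             y = c(left[, 2], right[, 2]),
             z = c(left[, 3], right[, 3]))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# Evoked-response envelope: sigmoidal (smoothstep) rise over 0-200 ms,
# plateau at 1 until stimulus offset (1 s), cosine fall over 100 ms.
erf_envelope <- function(t, stim_dur = 1, rise = 0.2, fall = 0.1) {
  env <- numeric(length(t))
  up <- t > 0 & t < rise
  env[up] <- 0.5 * (1 - cos(pi * t[up] / rise))
  env[t >= rise & t <= stim_dur] <- 1
  dn <- t > stim_dur & t < stim_dur + fall
  env[dn] <- 0.5 * (1 + cos(pi * (t[dn] - stim_dur) / fall))
  env
}

# Steady-state ramp: entrainment builds linearly over the first 200 ms of
# stimulation, holds at 1 during the stimulus, decays quickly after offset.
assr_ramp <- function(t, stim_dur = 1, rise = 0.2, tau_off = 0.05) {
  r <- pmin(pmax(t / rise, 0), 1)
  off <- t > stim_dur
  r[off] <- exp(-(t[off] - stim_dur) / tau_off)
  r
}

#' Simulate one subject's source-space epochs
#'
#' Draws the subject's realized generative parameters (hemisphere-specific
#' von Mises kappa, sustained-field amplitude, trial count, peak vertices)
#' and builds the trials x vertices x time epoch array:
#' `G(v) * [a_erf * env(t - jitter) + a_assr * ramp(t) * sin(2*pi*f*t + phi_trial)]`
#' plus white and 1/f noise, where `G(v)` is a spatial Gaussian profile
#' centered on the subject's true peak vertex of each hemisphere and
#' `phi_trial ~ vonMises(0, kappa_hemisphere)`. The right-hemisphere peak is
#' shifted along Y by `topo_shift_mm_per_year * (age - 7)`.
#'
#' @param params a [cohort_params()].
#' @param subject_index integer index within the cohort (drives the derived
#'   seed).
#' @param age age in years; drawn uniformly from `age_range_years` if `NULL`.
#' @param vertices vertex cloud from [build_vertex_cloud()]; rebuilt if
#'   `NULL`.
#' @param seed RNG seed for this subject's stream; derived from the master
#'   seed and `subject_index` if `NULL`.
#' @return object of class `subject_epochs`: list with `subject_id`,
#'   `age_years`, `data` (trials x vertices x time array), `times_s`,
#'   `sample_rate_hz`, `vertices` (coordinate/hemisphere table) and
#'   `ground_truth` (realized kappas, amplitude, peak vertices).
#' @export
simulate_subject <- function(params, subject_index, age = NULL,
                             vertices = NULL, seed = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (is.null(vertices)) vertices <- build_vertex_cloud(params)
  if (is.null(seed)) seed <- subject_seed(params$seed, subject_index)
  set.seed(seed)
  if (is.null(age))
    age <- stats::runif(1, params$age_range_years[1], params$age_range_years[2])

  lf <- params$age_effect_left_frac
  k_base_l <- max(0, params$kappa0 + lf * params$kappa_age_slope * (age - 7))
  k_base_r <- max(0, params$kappa0 + params$kappa_right_bonus +
                    params$kappa_age_slope * (age - 7))
  e_kappa <- if (params$kappa_subject_sd > 0)
    exp(stats::rnorm(1, 0, params$kappa_subject_sd)) else 1
  kappa_l <- k_base_l * e_kappa
  kappa_r <- k_base_r * e_kappa
  e_erf <- if (params$erf_subject_sd > 0)
    stats::rnorm(2, 0, params$erf_subject_sd) else c(0, 0)
  a_erf_l <- max(0, params$erf_amp0 + lf * params$erf_age_slope * (age - 7) + e_erf[1])
  a_erf_r <- max(0, params$erf_amp0 + params$erf_age_slope * (age - 7) + e_erf[2])
  n_trials <- if (params$trials_range[1] == params$trials_range[2])
    params$trials_range[1] else
      sample(seq(params$trials_range[1], params$trials_range[2]), 1L)

  sr <- params$sample_rate_hz
  i0 <- round(params$epoch_window_s[1] * sr)
  i1 <- round(params$epoch_window_s[2] * sr)
  times <- (i0:i1) / sr
  n_time <- length(times)
  coords <- as.matrix(vertices[, c("x", "y", "z")])
  hemi <- vertices$hemisphere
  n_vert <- nrow(vertices)

  # true peak vertices: nearest cloud vertex to the (age-shifted) target
  target_l <- .hemi_centers$left
  target_r <- .hemi_centers$right +
    c(0, params$topo_shift_mm_per_year * (age - 7), 0)
  nearest <- function(target, side) {
    idx <- which(hemi == side)
    d2 <- colSums((t(coords[idx, , drop = FALSE]) - target)^2)
    idx[which.min(d2)]
  }
  peak_l <- nearest(target_l, "left")
  peak_r <- nearest(target_r, "right")

  sigma_s <- params$spatial_fwhm_mm / (2 * sqrt(2 * log(2)))
  gprof <- numeric(n_vert)
  for (side in c("left", "right")) {
    idx <- which(hemi == side)
    pk <- if (side == "left") peak_l else peak_r
    d2 <- colSums((t(coords[idx, , drop = FALSE]) - coords[pk, ])^2)
    gprof[idx] <- exp(-d2 / (2 * sigma_s^2))
  }

  phi_l <- rvonmises(n_trials, 0, kappa_l)
  phi_r <- rvonmises(n_trials, 0, kappa_r)
  jit <- if (params$erf_latency_jitter_s > 0)
    stats::runif(n_trials, -params$erf_latency_jitter_s,
                 params$erf_latency_jitter_s) else numeric(n_trials)

  data <- array(
    if (params$noise_white_sd > 0)
      stats::rnorm(n_trials * n_vert * n_time, 0, params$noise_white_sd) else 0,
    dim = c(n_trials, n_vert, n_time))
  if (params$noise_pink_sd > 0) {
    pk <- pink_noise(n_time, n_vert * n_trials, sd = params$noise_pink_sd)
    # columns ordered vertex-fastest, trial-slowest
    data <- data + aperm(array(pk, dim = c(n_time, n_vert, n_trials)), c(3, 2, 1))
  }

  ramp <- assr_ramp(times)
  gl <- gprof * (hemi == "left")
  gr <- gprof * (hemi == "right")
  omega <- 2 * pi * params$assr_freq_hz
  for (r in seq_len(n_trials)) {
    env_r <- erf_envelope(times - jit[r])
    s_l <- a_erf_l * env_r +
      params$assr_amp * ramp * sin(omega * times + phi_l[r])
    s_r <- a_erf_r * env_r +
      params$assr_amp * ramp * sin(omega * times + phi_r[r])
    data[r, , ] <- data[r, , ] + gl %o% s_l + gr %o% s_r
  }

  structure(list(
    subject_id = sprintf("S%03d", subject_index),
    age_years = age,
    data = data,
    times_s = times,
    sample_rate_hz = sr,
    vertices = vertices,
    ground_truth = list(kappa_left = kappa_l, kappa_right = kappa_r,
                        erf_left = a_erf_l, erf_right = a_erf_r,
                        n_trials = n_trials,
                        peak_vertex = c(left = peak_l, right = peak_r),
                        seed = seed)),
    class = "subject_epochs")
}

#' Simulate a full synthetic cohort
#'
#' Ages are drawn uniformly from `age_range_years` under the master seed
#' (or supplied explicitly for a fixed design), then each subject is
#' simulated on an independent derived stream, so the same seed always
#' reproduces the identical cohort subject by subject.
#'
#' @param params a [cohort_params()].
#' @param ages optional numeric vector of length `n_subjects` overriding the
#'   uniform age draw.
#' @return object of class `assr_cohort`: list with `subjects` (list of
#'   [simulate_subject()] results), `vertices`, `ground_truth` (one row per
#'   subject: age, kappas, ERF amplitude, trial count, peak vertex ids) and
#'   `params`.
#' @export
simulate_cohort <- function(params, ages = NULL) {
  stopifnot(inherits(params, "cohort_params"))
  if (params$n_subjects < 3L)
    warning("fewer than 3 subjects: downstream statistics will be unreliable")
  vertices <- build_vertex_cloud(params)
  if (is.null(ages)) {
    set.seed(params$seed)
    ages <- stats::runif(params$n_subjects, params$age_range_years[1],
                         params$age_range_years[2])
  }
  stopifnot(length(ages) == params$n_subjects)
  subjects <- lapply(seq_len(params$n_subjects), function(i)
    simulate_subject(params, i, age = ages[i], vertices = vertices))
  gt <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject = s$subject_id, age = s$age_years,
               kappa_left = s$ground_truth$kappa_left,
               kappa_right = s$ground_truth$kappa_right,
               erf_left = s$ground_truth$erf_left,
               erf_right = s$ground_truth$erf_right,
               n_trials = s$ground_truth$n_trials,
               peak_left = s$ground_truth$peak_vertex[["left"]],
               peak_right = s$ground_truth$peak_vertex[["right"]])))
  structure(list(subjects = subjects, vertices = vertices,
                 ground_truth = gt, params = params),
            class = "assr_cohort")
}

#' @export
print.assr_cohort <- function(x, ...) {
  cat(sprintf("Synthetic ASSR cohort: %d subjects, %d vertices, %g Hz, epochs [%g, %g] s\n",
              length(x$subjects), nrow(x$vertices), x$params$sample_rate_hz,
              x$params$epoch_window_s[1], x$params$epoch_window_s[2]))
  cat(sprintf("  ages %.2f-%.2f y, trials %d-%d, seed %d\n",
              min(x$ground_truth$age), max(x$ground_truth$age),
              min(x$ground_truth$n_trials), max(x$ground_truth$n_trials),
              x$params$seed))
  invisible(x)
}

#' @export
print.subject_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("subject_epochs %s: age %.2f y, %d trials x %d vertices x %d samples (%g Hz)\n",
              x$subject_id, x$age_years, d[1], d[2], d[3], x$sample_rate_hz))
  invisible(x)
}
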