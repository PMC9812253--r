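# Independent oracles and miniature study conditions shared across tests.

# Brute-force ITPC: explicit loops over bins and trials, independent of the
# package's vectorised implementation.
itpc_bruteforce <- function(coef) {
  d <- dim(coef)
  out <- array(NA_real_, dim = d[2:4])
  for (v in seq_len(d[2])) for (f in seq_len(d[3])) for (t in seq_len(d[4])) {
    cs <- 0; sn <- 0
    for (r in seq_len(d[1])) {
      k <- Arg(coef[r, v, f, t])
      cs <- cs + cos(k); sn <- sn + sin(k)
    }
    out[v, f, t] <- sqrt(cs^2 + sn^2) / d[1]
  }
  out
}

# Mean resultant length of the von Mises distribution (population value).
vm_resultant <- function(kappa) besselI(kappa, 1) / besselI(kappa, 0)

# Hand-built tf_map for normalization arithmetic tests.
toy_tf_map <- function(values, freqs, times, n_trials = 10L) {
  structure(list(values = values, freqs_hz = freqs, times_s = times,
                 kind = "raw_itpc", n_trials = n_trials),
            class = "tf_map")
}

# Miniature study conditions: full analysis structure, small epoch/vertex
# counts so individual tests run in seconds.
smoke_morlet <- function() morlet_spec(freq_grid_hz = 39:41)

smoke_config <- function(k = 5L, decim = 3L)
  assr_config(morlet = smoke_morlet(), k_vertices = k, time_decim = decim)

smoke_params <- function(...) {
  defaults <- list(n_subjects = 4L, trials_range = c(16L, 20L),
                   n_vertices_per_hemisphere = 8L,
                   epoch_window_s = c(-0.9, 1.3), sample_rate_hz = 150,
                   seed = 123L)
  args <- utils::modifyList(defaults, list(...))
  do.call(cohort_params, args)
}

quiet_run <- function(expr) suppressWarnings(suppressMessages(expr))
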