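# Internal helpers shared across modules.

# Numerical tolerance used when testing window membership on floating-point
# time/frequency axes (bin centers are compared against closed intervals).
.win_eps <- 1e-9

# Logical mask: which axis values fall in the closed interval w = c(lo, hi).
in_window <- function(x, w) {
  stopifnot(length(w) == 2L, w[1] <= w[2])
  x >= w[1] - .win_eps & x <= w[2] + .win_eps
}

idx_window <- function(x, w) which(in_window(x, w))

# Interval containment check (a inside b, closed).
interval_inside <- function(a, b) {
  a[1] >= b[1] - .win_eps && a[2] <= b[2] + .win_eps
}

# FNV-1a 32-bit hash of a serialized R object; stable fingerprint for configs.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

# Derive a per-subject RNG seed from the master seed by a fixed offset rule.
# Kept below 2^31 - 1 so set.seed() always accepts it.
subject_seed <- function(master_seed, subject_index) {
  as.integer((as.numeric(master_seed) + 7919 * as.numeric(subject_index)) %% 2147483629)
}

# Round-trip-exact numeric CSV writer/reader ("%.17g" preserves doubles bit
# for bit). Used by the epoch container so a written cohort reads back
# bitwise identical.
write_num_matrix <- function(m, path, col_names = NULL) {
  m <- as.matrix(m)
  lines <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  if (!is.null(col_names)) lines <- c(paste(col_names, collapse = ","), lines)
  writeLines(lines, path)
}

read_num_matrix <- function(path, header = FALSE) {
  dt <- data.table::fread(path, header = header, sep = ",", data.table = FALSE)
  as.matrix(dt)
}

stop_assr <- function(...) stop(sprintf(...), call. = FALSE)
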