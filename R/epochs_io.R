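# Plain-text epoch container.
#
# Directory layout (one directory per cohort):
#   <path>/cohort.json              {"format":"assr-epochs","version":1,"subjects":[...]}
#   <path>/<id>/meta.json           subject_id, age_years, sample_rate_hz, dims
#   <path>/<id>/times.csv           one time value per line (s)
#   <path>/<id>/vertices.csv        vertex,hemisphere,x,y,z (header)
#   <path>/<id>/data.csv            n_trials*n_vertices rows x n_times cols;
#                                   row index = (trial-1)*n_vertices + vertex
#   <path>/<id>/ground_truth.json   optional (absent for real data)
#
# Numbers are written as "%.17g", so doubles round-trip bit for bit.
# Externally preprocessed source epochs following this schema (without
# ground_truth.json) enter the identical pipeline via read_epochs().

#' Write a cohort of subject epochs to a plain-text container
#'
#' @param subjects an `assr_cohort` or a list of `subject_epochs`.
#' @param path directory to create.
#' @param overwrite allow writing into an existing directory.
#' @return `path`, invisibly.
#' @seealso [read_epochs()] for the schema and the re-import path.
#' @export
write_epochs <- function(subjects, path, overwrite = FALSE) {
  if (inherits(subjects, "assr_cohort")) subjects <- subjects$subjects
  stopifnot(is.list(subjects), length(subjects) >= 1L,
            all(vapply(subjects, inherits, TRUE, "subject_epochs")))
  if (dir.exists(path) && !overwrite)
    stop_assr("directory %s already exists (use overwrite = TRUE)", path)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- vapply(subjects, `[[`, "", "subject_id")
  jsonlite::write_json(list(format = "assr-epochs", version = 1L, subjects = ids),
                       file.path(path, "cohort.json"), auto_unbox = TRUE)
  for (s in subjects) {
    d <- file.path(path, s$subject_id)
    dir.create(d, showWarnings = FALSE)
    dm <- dim(s$data)
    jsonlite::write_json(
      list(subject_id = s$subject_id, age_years = sprintf("%.17g", s$age_years),
           sample_rate_hz = s$sample_rate_hz,
           n_trials = dm[1], n_vertices = dm[2], n_times = dm[3]),
      file.path(d, "meta.json"), auto_unbox = TRUE)
    write_num_matrix(matrix(s$times_s, ncol = 1), file.path(d, "times.csv"))
    v <- s$vertices
    writeLines(c("vertex,hemisphere,x,y,z",
                 sprintf("%d,%s,%.17g,%.17g,%.17g",
                         v$vertex, v$hemisphere, v$x, v$y, v$z)),
               file.path(d, "vertices.csv"))
    flat <- matrix(aperm(s$data, c(3, 2, 1)), nrow = dm[3])  # times x (vert,trial)
    write_num_matrix(t(flat), file.path(d, "data.csv"))
    if (!is.null(s$ground_truth)) {
      gt <- s$ground_truth
      gt_chr <- lapply(gt, function(x)
        if (is.numeric(x)) stats::setNames(sprintf("%.17g", x), names(x)) else x)
      jsonlite::write_json(gt_chr, file.path(d, "ground_truth.json"), auto_unbox = TRUE)
    }
  }
  invisible(path)
}

#' Read a cohort of subject epochs from a plain-text container
#'
#' Validates the container written by [write_epochs()] (or produced by an
#' external preprocessing tool following the same schema) and reconstructs
#' the `subject_epochs` list. `ground_truth.json` is optional; containers
#' without it load with `ground_truth = NULL`.
#'
#' @param path container directory.
#' @return list of `subject_epochs`.
#' @export
read_epochs <- function(path) {
  man_file <- file.path(path, "cohort.json")
  if (!file.exists(man_file)) stop_assr("not an epoch container: missing cohort.json in %s", path)
  man <- jsonlite::read_json(man_file, simplifyVector = TRUE)
  if (!identical(man$format, "assr-epochs"))
    stop_assr("unrecognized container format field: %s", man$format %||% "<missing>")
  lapply(man$subjects, function(id) read_one_subject(file.path(path, id)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_one_subject <- function(d) {
  need <- function(f) {
    p <- file.path(d, f)
    if (!file.exists(p)) stop_assr("malformed epoch container: missing %s in %s", f, d)
    p
  }
  meta <- jsonlite::read_json(need("meta.json"), simplifyVector = TRUE)
  for (f in c("subject_id", "age_years", "sample_rate_hz",
              "n_trials", "n_vertices", "n_times"))
    if (is.null(meta[[f]])) stop_assr("malformed epoch container: meta.json lacks field '%s'", f)
  times <- as.numeric(read_num_matrix(need("times.csv"))[, 1])
  vert <- utils::read.csv(need("vertices.csv"), colClasses =
                            c("integer", "character", "numeric", "numeric", "numeric"))
  for (f in c("vertex", "hemisphere", "x", "y", "z"))
    if (is.null(vert[[f]])) stop_assr("malformed epoch container: vertices.csv lacks column '%s'", f)
  if (!all(vert$hemisphere %in% c("left", "right")))
    stop_assr("malformed epoch container: hemisphere labels must be 'left'/'right'")
  flat <- read_num_matrix(need("data.csv"))
  nt <- as.integer(meta$n_trials); nv <- as.integer(meta$n_vertices)
  ns <- as.integer(meta$n_times)
  if (!all(dim(flat) == c(nt * nv, ns)))
    stop_assr("malformed epoch container: data.csv is %dx%d, expected %dx%d",
              nrow(flat), ncol(flat), nt * nv, ns)
  if (length(times) != ns)
    stop_assr("malformed epoch container: times.csv length %d != n_times %d",
              length(times), ns)
  data <- aperm(array(t(flat), dim = c(ns, nv, nt)), c(3, 2, 1))
  gt_file <- file.path(d, "ground_truth.json")
  gt <- NULL
  if (file.exists(gt_file)) {
    gt <- jsonlite::read_json(gt_file, simplifyVector = TRUE)
    num_fields <- c("kappa_left", "kappa_right", "erf_left", "erf_right",
                    "n_trials", "peak_vertex", "seed")
    for (f in intersect(num_fields, names(gt))) {
      nm <- names(gt[[f]])
      gt[[f]] <- stats::setNames(as.numeric(gt[[f]]), nm)
    }
  }
  structure(list(subject_id = meta$subject_id,
                 age_years = as.numeric(meta$age_years),
                 data = data, times_s = times,
                 sample_rate_hz = as.numeric(meta$sample_rate_hz),
                 vertices = vert, ground_truth = gt),
            class = "subject_epochs")
}
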