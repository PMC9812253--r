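# Individual peak-vertex ROI selection and cohort table assembly.

#' Select peak vertices per hemisphere
#'
#' Picks, within each hemisphere, the `k` vertices with the largest
#' window-averaged normalized 40 Hz ITPC (default `k = 15`, i.e. 30
#' vertices across both hemispheres). Ties are broken by ascending vertex
#' id. If a hemisphere holds fewer than `k` vertices, all are taken with a
#' warning.
#'
#' @param values numeric vector of per-vertex scores (e.g. from
#'   [window_average()]).
#' @param hemisphere per-vertex `"left"`/`"right"` labels.
#' @param k vertices to select per hemisphere.
#' @return named list with integer vertex indices `left` and `right`,
#'   each sorted by decreasing score.
#' @export
select_peak_vertices <- function(values, hemisphere, k = 15L) {
  stopifnot(length(values) == length(hemisphere), k >= 1L)
  out <- list()
  for (side in c("left", "right")) {
    idx <- which(hemisphere == side)
    if (length(idx) == 0L) stop_assr("no vertices in %s hemisphere", side)
    kk <- k
    if (length(idx) < k) {
      warning(sprintf("%s hemisphere has only %d vertices (< k = %d): taking all",
                      side, length(idx), k))
      kk <- length(idx)
    }
    ord <- idx[order(-values[idx], idx)]
    out[[side]] <- ord[seq_len(kk)]
  }
  out
}

#' Summarize a subject's ROI per hemisphere
#'
#' Arithmetic means of the normalized ITPC, the sustained-field amplitude
#' and the vertex coordinates over the selected vertex set of each
#' hemisphere. The ERF amplitude is read at the identical vertex set
#' selected by the ITPC criterion (no independent ERF peak-picking).
#'
#' @param subject_id subject identifier.
#' @param age_years subject age.
#' @param vertex_sets list from [select_peak_vertices()].
#' @param itpc_vals per-vertex normalized ITPC window averages.
#' @param erf_vals per-vertex sustained-field amplitudes.
#' @param vertices vertex table with `vertex`, `hemisphere`, `x`, `y`, `z`.
#' @return data.frame with one row per hemisphere: `subject`, `age`,
#'   `hemisphere`, `itpc`, `erf`, `x`, `y`, `z` and a list-column
#'   `selected` of vertex ids.
#' @export
summarize_roi <- function(subject_id, age_years, vertex_sets, itpc_vals,
                          erf_vals, vertices) {
  stopifnot(length(itpc_vals) == nrow(vertices),
            length(erf_vals) == nrow(vertices))
  rows <- lapply(c("left", "right"), function(side) {
    sel <- vertex_sets[[side]]
    if (!all(vertices$hemisphere[sel] == side))
      stop_assr("selected vertices for %s hemisphere carry mixed labels", side)
    data.frame(subject = subject_id, age = age_years, hemisphere = side,
               itpc = mean(itpc_vals[sel]), erf = mean(erf_vals[sel]),
               x = mean(vertices$x[sel]), y = mean(vertices$y[sel]),
               z = mean(vertices$z[sel]))
  })
  out <- do.call(rbind, rows)
  out$selected <- I(lapply(c("left", "right"), function(side) vertex_sets[[side]]))
  out
}

#' Assemble the cohort analysis table
#'
#' Binds per-subject ROI summaries into the long-format table consumed by
#' the statistical layer: one row per subject x hemisphere with columns
#' `subject`, `age`, `hemisphere`, `itpc`, `erf`, `x`, `y`, `z`.
#'
#' @param summaries list of data.frames from [summarize_roi()], or a single
#'   pre-bound data.frame.
#' @return data.frame of class `assr_table`.
#' @export
cohort_table <- function(summaries) {
  if (is.data.frame(summaries)) summaries <- list(summaries)
  if (length(summaries) == 0L) stop_assr("no ROI summaries supplied")
  tab <- do.call(rbind, summaries)
  tab$selected <- NULL
  need <- c("subject", "age", "hemisphere", "itpc", "erf", "x", "y", "z")
  miss <- setdiff(need, names(tab))
  if (length(miss) > 0L) stop_assr("analysis table lacks columns: %s",
                                   paste(miss, collapse = ", "))
  key <- paste(tab$subject, tab$hemisphere)
  if (anyDuplicated(key))
    stop_assr("duplicated subject/hemisphere rows: %s", key[duplicated(key)][1])
  rownames(tab) <- NULL
  class(tab) <- c("assr_table", "data.frame")
  tab
}

#' Write / read the analysis table as CSV
#'
#' @param table an `assr_table`.
#' @param path CSV path.
#' @return `read_cohort_table` returns the table; `write_cohort_table`
#'   returns `path` invisibly.
#' @export
write_cohort_table <- function(table, path) {
  df <- as.data.frame(table)
  lines <- c("subject,age,hemisphere,itpc,erf,x,y,z",
             sprintf("%s,%.17g,%s,%.17g,%.17g,%.17g,%.17g,%.17g",
                     df$subject, df$age, df$hemisphere, df$itpc, df$erf,
                     df$x, df$y, df$z))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_table
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, colClasses = c("character", "numeric", "character",
                                             rep("numeric", 5)))
  cohort_table(df)
}
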