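# Statistical layer: hemisphere/nested-amplitude linear mixed model,
# Pearson age correlations with Bonferroni correction, and descriptive
# summaries.

#' Fit the hemisphere / nested-amplitude mixed model
#'
#' Linear mixed-effects model of the normalized 40 Hz ITPC with an
#' intercept (reference level: right hemisphere), a left-hemisphere main
#' effect, the sustained-field amplitude (ERF) nested as a separate slope
#' within each hemisphere, and a per-subject random intercept:
#' `itpc ~ 1 + hemisphere / erf + (1 | subject)`, i.e. the fixed-effect
#' design {intercept, 1(left), erf x 1(left), erf x 1(right)}. Fitted by
#' REML (bobyqa optimizer). p-values use a t distribution; by default the
#' residual degrees-of-freedom approximation `df = n_obs - n_fixed`,
#' optionally Satterthwaite via the lmerTest package.
#'
#' @param table an analysis table from [cohort_table()] with columns
#'   `subject`, `hemisphere`, `itpc`, `erf`.
#' @param ddf degrees-of-freedom method for fixed-effect t tests:
#'   `"residual"` (default) or `"satterthwaite"` (requires lmerTest).
#' @return object of class `assr_lmm`: list with `fixed_effects`
#'   (term/estimate/std_error/t_value/p_value), variance components
#'   `tau2` (subject intercept) and `sigma2` (residual), `icc`
#'   (`tau2 / (tau2 + sigma2)`), `r2_marginal` and `r2_conditional`
#'   (Nakagawa), `n_subjects`, `n_observations`, and the underlying
#'   `lmerMod` fit.
#' @export
fit_itpc_model <- function(table, ddf = c("residual", "satterthwaite")) {
  ddf <- match.arg(ddf)
  need <- c("subject", "hemisphere", "itpc", "erf")
  miss <- setdiff(need, names(table))
  if (length(miss) > 0L) stop_assr("table lacks columns: %s", paste(miss, collapse = ", "))
  d <- as.data.frame(table)
  d$hemisphere <- factor(d$hemisphere, levels = c("right", "left"))
  if (nlevels(droplevels(d$hemisphere)) < 2L)
    stop_assr("both hemispheres are required to fit the model")
  mm <- stats::model.matrix(~hemisphere / erf, data = d)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1L):ncol(mm)]]
    stop_assr("rank-deficient fixed-effect design; aliased terms: %s",
              paste(aliased, collapse = ", "))
  }
  fit <- lme4::lmer(itpc ~ hemisphere / erf + (1 | subject), data = d,
                    REML = TRUE,
                    control = lme4::lmerControl(optimizer = "bobyqa"))
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  tau2 <- vc$vcov[vc$grp == "subject"]
  sigma2 <- stats::sigma(fit)^2
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- beta / se
  n_obs <- nrow(d)
  if (ddf == "satterthwaite") {
    if (!requireNamespace("lmerTest", quietly = TRUE))
      stop_assr("ddf = 'satterthwaite' requires the lmerTest package")
    lt <- lmerTest::lmer(itpc ~ hemisphere / erf + (1 | subject), data = d,
                         REML = TRUE,
                         control = lme4::lmerControl(optimizer = "bobyqa"))
    ct <- stats::coef(summary(lt))
    df_t <- ct[, "df"]
    pval <- ct[, "Pr(>|t|)"]
  } else {
    df_t <- rep(n_obs - length(beta), length(beta))
    pval <- 2 * stats::pt(-abs(tval), df = df_t)
  }
  X <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.vector(X %*% beta))
  denom <- var_fixed + tau2 + sigma2
  structure(list(
    fixed_effects = data.frame(term = names(beta), estimate = unname(beta),
                               std_error = unname(se), t_value = unname(tval),
                               df = unname(df_t), p_value = unname(pval)),
    tau2 = tau2, sigma2 = sigma2, icc = tau2 / (tau2 + sigma2),
    r2_marginal = var_fixed / denom,
    r2_conditional = (var_fixed + tau2) / denom,
    n_subjects = length(unique(d$subject)), n_observations = n_obs,
    ddf = ddf, fit = fit),
    class = "assr_lmm")
}

#' @export
print.assr_lmm <- function(x, ...) {
  cat("Linear mixed model: itpc ~ 1 + hemisphere/erf + (1 | subject)  [REML]\n")
  cat(sprintf("  %d observations, %d subjects; ddf: %s\n",
              x$n_observations, x$n_subjects, x$ddf))
  fe <- x$fixed_effects
  fe[, 2:6] <- signif(fe[, 2:6], 4)
  print(fe, row.names = FALSE)
  cat(sprintf("  sigma^2 = %.4g, tau00 = %.4g, ICC = %.3f\n", x$sigma2, x$tau2, x$icc))
  cat(sprintf("  Marginal R2 / Conditional R2 = %.3f / %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

#' @export
summary.assr_lmm <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.assr_lmm <- function(object, ...) {
  stats::setNames(object$fixed_effects$estimate, object$fixed_effects$term)
}

#' Pearson correlations with age, per hemisphere
#'
#' Correlates the requested per-subject variables with age separately in
#' each hemisphere, with two-sided t tests and Bonferroni adjustment within
#' the declared family. The coordinate family (X, Y, Z in two hemispheres)
#' uses `family_size = 6`; response/age correlations are conventionally
#' reported unadjusted (`family_size = 1`).
#'
#' @param table an analysis table with columns `age`, `hemisphere` and the
#'   requested variables.
#' @param variables character vector of column names to correlate with age.
#' @param family_size Bonferroni family size; defaults to the number of
#'   tests performed (`length(variables) * number of hemispheres`). Use 1
#'   for unadjusted reporting.
#' @return data.frame of class `assr_correlations` with columns
#'   `hemisphere`, `variable`, `n`, `r`, `p_raw`, `p_adjusted`,
#'   `family_size`, `method`.
#' @export
correlate_with_age <- function(table, variables = c("itpc", "erf"),
                               family_size = NULL) {
  stopifnot(all(variables %in% names(table)), "age" %in% names(table))
  d <- as.data.frame(table)
  hemis <- sort(unique(d$hemisphere))
  if (is.null(family_size)) family_size <- length(variables) * length(hemis)
  rows <- list()
  for (h in hemis) {
    dh <- d[d$hemisphere == h, , drop = FALSE]
    for (v in variables) {
      ok <- stats::complete.cases(dh$age, dh[[v]])
      n <- sum(ok)
      if (n < 3L) stop_assr("fewer than 3 complete pairs for %s / %s", h, v)
      if (stats::sd(dh$age[ok]) == 0 || stats::sd(dh[[v]][ok]) == 0)
        stop_assr("zero variance in %s / %s: correlation undefined", h, v)
      ct <- stats::cor.test(dh$age[ok], dh[[v]][ok], method = "pearson")
      rows[[length(rows) + 1L]] <- data.frame(
        hemisphere = h, variable = v, n = n, r = unname(ct$estimate),
        p_raw = ct$p.value, p_adjusted = min(1, ct$p.value * family_size),
        family_size = family_size, method = "pearson")
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("assr_correlations", "data.frame")
  out
}

#' Per-hemisphere descriptive summary
#'
#' Sample mean and SD (denominator n-1) of the normalized ITPC and the
#' sustained-field amplitude per hemisphere. With a single observation the
#' SD is reported as `NA`.
#'
#' @param table an analysis table.
#' @return data.frame with one row per hemisphere.
#' @export
hemispheric_summary <- function(table) {
  d <- as.data.frame(table)
  hemis <- sort(unique(d$hemisphere))
  do.call(rbind, lapply(hemis, function(h) {
    dh <- d[d$hemisphere == h, , drop = FALSE]
    data.frame(hemisphere = h, n = nrow(dh),
               mean_itpc = mean(dh$itpc),
               sd_itpc = if (nrow(dh) > 1L) stats::sd(dh$itpc) else NA_real_,
               mean_erf = mean(dh$erf),
               sd_erf = if (nrow(dh) > 1L) stats::sd(dh$erf) else NA_real_)
  }))
}

#' Write a machine- and human-readable results report
#'
#' Emits `results.json` (all estimates, p-values, families, run
#' configuration fingerprint and seed) and `report.md` (formatted summary)
#' into a directory.
#'
#' @param analysis an `assr_analysis` from [assr_analyze()] / [run_assr()].
#' @param dir output directory (created if needed).
#' @return invisible list with the two file paths.
#' @export
assr_report <- function(analysis, dir) {
  if (!inherits(analysis, "assr_analysis"))
    stop_assr("assr_report expects an assr_analysis object")
  if (is.null(analysis$model) && is.null(analysis$correlations))
    stop_assr("nothing to report: analysis carries no statistical results")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  payload <- list(
    schema_version = 1L,
    seed = analysis$seed,
    config_hash = analysis$config_hash,
    n_subjects = length(unique(analysis$table$subject)),
    n_observations = nrow(analysis$table),
    hemispheric_summary = analysis$hemispheres,
    mixed_model = if (!is.null(analysis$model)) list(
      fixed_effects = analysis$model$fixed_effects,
      sigma2 = analysis$model$sigma2, tau2 = analysis$model$tau2,
      icc = analysis$model$icc,
      r2_marginal = analysis$model$r2_marginal,
      r2_conditional = analysis$model$r2_conditional),
    age_correlations = analysis$correlations,
    coordinate_age_correlations = analysis$coord_correlations)
  json_path <- file.path(dir, "results.json")
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  md <- c("# ASSR / sustained-field analysis report", "",
          sprintf("- seed: %s", analysis$seed %||% "<none>"),
          sprintf("- config hash: %s", analysis$config_hash),
          sprintf("- observations: %d rows (%d subjects x hemispheres)",
                  nrow(analysis$table), length(unique(analysis$table$subject))),
          "", "## Hemispheric summary", "",
          utils::capture.output(print(analysis$hemispheres, row.names = FALSE)))
  if (!is.null(analysis$model))
    md <- c(md, "", "## Mixed model", "",
            utils::capture.output(print(analysis$model)))
  if (!is.null(analysis$correlations))
    md <- c(md, "", "## Age correlations", "",
            utils::capture.output(print(as.data.frame(analysis$correlations),
                                        row.names = FALSE)))
  if (!is.null(analysis$coord_correlations))
    md <- c(md, "", "## Coordinate/age correlations (Bonferroni family of 6)", "",
            utils::capture.output(print(as.data.frame(analysis$coord_correlations),
                                        row.names = FALSE)))
  md_path <- file.path(dir, "report.md")
  writeLines(md, md_path)
  invisible(list(json = json_path, markdown = md_path))
}
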