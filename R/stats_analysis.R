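# Covariate residualization, partial correlations with Bonferroni
# correction, clinical group splits, and three-group ANOVA with Tukey HSD.

#' Residualize a variable on covariates
#'
#' Removes the least-squares projection of `y` on an intercept plus the given
#' covariate columns; the residuals have mean (numerically) zero.
#'
#' @param y numeric vector.
#' @param covariates numeric matrix / data frame of design columns (no
#'   intercept), or `NULL` for plain centering. Factors are dummy-coded.
#' @return residual vector.
#' @export
residualize <- function(y, covariates = NULL) {
  n <- length(y)
  if (is.null(covariates) || NCOL(covariates) == 0) return(y - mean(y))
  x <- design_columns(covariates)
  design <- cbind(`(Intercept)` = 1, x)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[
      qr_d$pivot[seq.int(qr_d$rank + 1, ncol(design))]]
    stop("collinear covariate design (columns: ",
         paste(dropped, collapse = ", "), ")", call. = FALSE)
  }
  if (n <= qr_d$rank + 1)
    stop("too few observations for the covariate design", call. = FALSE)
  as.numeric(qr.resid(qr_d, y))
}

# Dummy-code any factor/character columns; pass numeric through.
design_columns <- function(covariates) {
  if (is.matrix(covariates) && is.numeric(covariates)) return(covariates)
  df <- as.data.frame(covariates, stringsAsFactors = FALSE)
  df[] <- lapply(df, function(col) if (is.factor(col)) droplevels(col) else col)
  mm <- stats::model.matrix(~ ., data = df)
  mm[, -1, drop = FALSE]
}

#' Partial correlation of two variables given covariates
#'
#' Pearson correlation of the two covariate-residualized vectors, with a
#' two-sided p-value from the t transform on `n - 2 - k` degrees of freedom
#' (`k` = covariate rank). With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y numeric vectors.
#' @param covariates as in [residualize()].
#' @param label optional variable-pair label carried into the result.
#' @return one-row `data.frame`: `pair`, `r`, `n`, `df`, `p_raw`, plus
#'   `p_corrected = NA` (filled by [bonferroni()] at the family level) and
#'   `covariates`.
#' @export
partial_correlation <- function(x, y, covariates = NULL, label = NULL) {
  ok <- stats::complete.cases(x, y,
                              if (is.null(covariates)) rep(TRUE, length(x))
                              else as.data.frame(covariates))
  x <- x[ok]
  y <- y[ok]
  cov_ok <- if (is.null(covariates)) NULL else
    as.data.frame(covariates)[ok, , drop = FALSE]
  k <- if (is.null(cov_ok)) 0L else qr(design_columns(cov_ok))$rank
  rx <- residualize(x, cov_ok)
  ry <- residualize(y, cov_ok)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("undefined correlation: zero-variance residuals", call. = FALSE)
  r <- stats::cor(rx, ry)
  n <- length(rx)
  df <- n - 2L - k
  tt <- r * sqrt(df / (1 - r^2))
  p <- 2 * stats::pt(-abs(tt), df)
  data.frame(pair = if (is.null(label)) NA_character_ else label,
             r = r, n = n, df = df, p_raw = p, p_corrected = NA_real_,
             covariates = if (is.null(cov_ok)) "" else
               paste(colnames(as.data.frame(cov_ok)), collapse = "+"),
             stringsAsFactors = FALSE)
}

#' Bonferroni correction
#'
#' `min(1, m * p)` for a stated family size `m` (at least the number of
#' tests).
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param family_size family size `m`; defaults to `length(p_values)`.
#' @return corrected p-values.
#' @export
bonferroni <- function(p_values, family_size = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values outside [0, 1]", call. = FALSE)
  if (family_size < length(p_values))
    stop("family_size smaller than the number of tests", call. = FALSE)
  pmin(1, family_size * p_values)
}

#' Clinical group splits
#'
#' Assigns each subject to `HC`, low or high EDSS (cutoff 3; the cutoff value
#' itself counts as high) and to `HC`, low or high SDMT (cutoff 40; a score
#' of 40 counts as high/preserved, below 40 as low/impaired). MS subjects
#' missing the relevant score are excluded from that split (count reported as
#' an attribute); HC are always kept as their own group.
#'
#' @param records subject table with `diagnosis`, `edss`, `sdmt`.
#' @param edss_cutoff,sdmt_cutoff cutoffs.
#' @param edss_high_inclusive if `TRUE` (default) `edss >= cutoff` is high.
#' @param sdmt_high_inclusive if `TRUE` (default) `sdmt >= cutoff` is
#'   high/preserved.
#' @return list with factors `edss_group` and `sdmt_group` (levels `HC`,
#'   `low_*`, `high_*`; `NA` = excluded), each with attribute `n_excluded`.
#' @export
split_groups <- function(records, edss_cutoff = 3, sdmt_cutoff = 40,
                         edss_high_inclusive = TRUE,
                         sdmt_high_inclusive = TRUE) {
  is_ms <- records$diagnosis == "MS"
  cut_split <- function(score, cutoff, inclusive, low, high) {
    g <- rep(NA_character_, nrow(records))
    g[!is_ms] <- "HC"
    hi <- if (inclusive) score >= cutoff else score > cutoff
    g[is_ms & !is.na(score) & hi] <- high
    g[is_ms & !is.na(score) & !hi] <- low
    out <- factor(g, levels = c("HC", low, high))
    attr(out, "n_excluded") <- sum(is_ms & is.na(score))
    out
  }
  list(edss_group = cut_split(records$edss, edss_cutoff,
                              edss_high_inclusive, "low_edss", "high_edss"),
       sdmt_group = cut_split(records$sdmt, sdmt_cutoff,
                              sdmt_high_inclusive, "low_sdmt", "high_sdmt"))
}

#' One-way ANOVA with Tukey HSD post hoc tests
#'
#' One-way analysis of variance across the supplied groups followed by
#' all-pairs Tukey honestly-significant-difference comparisons (studentized
#' range distribution; Tukey-Kramer adjustment under unequal group sizes).
#'
#' @param values numeric vector.
#' @param group_labels factor of group assignments (`NA` rows dropped).
#' @param alpha significance level recorded for convenience.
#' @return list with `F`, `p`, `df`, group sizes `n`, and `tukey`
#'   (`data.frame`: pair, mean difference, confidence bounds, adjusted p).
#' @export
anova_tukey <- function(values, group_labels, alpha = 0.05) {
  g <- factor(group_labels)
  ok <- !is.na(values) & !is.na(g)
  values <- values[ok]
  g <- droplevels(g[ok])
  if (nlevels(g) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2))
    stop("group(s) with < 2 values: ",
         paste(levels(g)[table(g) < 2], collapse = ", "), call. = FALSE)
  fit <- stats::aov(values ~ g)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], row.names = NULL,
                      stringsAsFactors = FALSE)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1],
       df = c(between = an[["Df"]][1], within = an[["Df"]][2]),
       n = table(g), alpha = alpha, tukey = tukey)
}

#' The full correlation battery
#'
#' Reproduces the analysis families relating connectivity to structure and
#' clinical status, each Bonferroni-corrected within itself:
#' \describe{
#'   \item{inter_vs_intra}{the 4 inter/intra measure pairs (commissural
#'     ratio, CC ratio x mean SPL, efficiency), separately for HC and MS
#'     (family size 8); covariates age + sex.}
#'   \item{inter_agreement}{agreement between the two interhemispheric
#'     measures (commissural ratio vs CC ratio and vs raw CC area),
#'     separately per group (family size 4); covariates age + sex.}
#'   \item{clinical}{the 8 measures/ratios against GMF, WMF, LVF, EDSS and
#'     SDMT in MS subjects (family size 40); covariates age + sex, plus
#'     center dummies when `center_covariate = TRUE`.}
#' }
#'
#' @param metrics per-subject measure table (from [cohort_metrics()], possibly
#'   harmonized) keyed by `id`.
#' @param records subject table keyed by `id`.
#' @param center_covariate add center dummies to the clinical family's
#'   covariates (used on non-harmonized input).
#' @return `data.frame` of [partial_correlation()] rows with `family` and
#'   `family_size` columns; `p_corrected` filled per family.
#' @export
run_correlation_battery <- function(metrics, records,
                                    center_covariate = FALSE) {
  if (!setequal(metrics$id, records$id) ||
      nrow(metrics) != nrow(records))
    stop("metrics and records are not aligned on subject id", call. = FALSE)
  records <- records[match(metrics$id, records$id), ]
  base_cov <- records[, c("age", "sex")]
  rows <- list()
  add <- function(family, label, x, y, covariates, subset = NULL) {
    if (is.null(subset)) subset <- rep(TRUE, nrow(records))
    res <- partial_correlation(x[subset], y[subset],
                               covariates[subset, , drop = FALSE],
                               label = label)
    res$family <- family
    rows[[length(rows) + 1]] <<- res
  }
  inter <- c("commissural_ratio", "cc_ratio")
  intra <- c("spl_mean", "eff_mean")
  for (grp in c("HC", "MS")) {
    sel <- records$diagnosis == grp
    for (iv in inter) for (jv in intra) {
      add("inter_vs_intra", paste(iv, "vs", jv, "|", grp),
          metrics[[iv]], metrics[[jv]], base_cov, sel)
    }
    add("inter_agreement", paste("commissural_ratio vs cc_ratio |", grp),
        metrics$commissural_ratio, metrics$cc_ratio, base_cov, sel)
    add("inter_agreement", paste("commissural_ratio vs cc_area |", grp),
        metrics$commissural_ratio, records$cc_area, base_cov, sel)
  }
  measures <- c("commissural_ratio", "cc_ratio", "spl_mean", "eff_mean",
                "ratio_commissural_spl", "ratio_commissural_eff",
                "ratio_ccratio_spl", "ratio_ccratio_eff")
  clinical <- c("gmf", "wmf", "lvf", "edss", "sdmt")
  ms <- records$diagnosis == "MS"
  clin_cov <- if (center_covariate)
    cbind(base_cov, center = factor(records$center)) else base_cov
  for (mv in measures) for (cv in clinical) {
    add("clinical", paste(mv, "vs", cv), metrics[[mv]], records[[cv]],
        clin_cov, ms)
  }
  out <- do.call(rbind, rows)
  out$family_size <- as.numeric(table(out$family)[out$family])
  for (f in unique(out$family)) {
    idx <- out$family == f
    out$p_corrected[idx] <- bonferroni(out$p_raw[idx], sum(idx))
  }
  rownames(out) <- NULL
  out[, c("family", "pair", "r", "n", "df", "p_raw", "p_corrected",
          "family_size", "covariates")]
}
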