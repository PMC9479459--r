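# Between-subjects factorial ANOVA machinery, the per-ROI focal-ROI scan,
# post-hoc contrasts, and correlation diagnostics.
#
# The scan fits the same 3-factor design to every ROI x tissue dependent
# variable, so the Type-III sums of squares are computed from one QR
# factorization per reduced model applied to the whole DV matrix at once.
# Unbalanced cells (focal/non-focal group sizes are never equal) are
# handled with Type-III SS under sum-to-zero contrasts.

FOCALITY_FACTORS <- c("age_group", "sex", "focality")

#' @keywords internal
#' @noRd
anova_design <- function(data, factors = FOCALITY_FACTORS) {
  for (f in factors) {
    if (!f %in% names(data)) stop_ff("design_error", "missing factor %s", f)
    data[[f]] <- droplevels(factor(data[[f]]))
    if (nlevels(data[[f]]) < 2L)
      stop_ff("design_error", "factor %s has fewer than 2 levels present", f)
  }
  fml <- stats::as.formula(paste("~", paste(factors, collapse = " * ")))
  contr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)
  X <- stats::model.matrix(fml, data, contrasts.arg = contr)
  asgn <- attr(X, "assign")
  terms_obj <- stats::terms(fml)
  labels <- attr(terms_obj, "term.labels")
  if (qr(X)$rank < ncol(X))
    stop_ff("design_error", "design matrix is rank deficient (empty cells?)")
  list(X = X, assign = asgn, labels = labels, n = nrow(X))
}

# Type-III decomposition for a matrix of dependent variables sharing one
# design. Returns per-effect SS/df/F/p matrices (effects x DVs).
#' @keywords internal
#' @noRd
anova_engine <- function(design, Y) {
  Y <- as.matrix(Y)
  X <- design$X
  n <- nrow(X)
  df_res <- n - ncol(X)
  if (df_res <= 0L) stop_ff("saturated_design_error", "zero residual degrees of freedom")
  qr_full <- qr(X)
  rss_full <- colSums(qr.resid(qr_full, Y)^2)
  tss <- colSums(scale(Y, scale = FALSE)^2)
  k <- length(design$labels)
  SS <- matrix(NA_real_, k, ncol(Y), dimnames = list(design$labels, colnames(Y)))
  df1 <- integer(k)
  for (t in seq_len(k)) {
    keep <- design$assign != t
    rss_red <- colSums(qr.resid(qr(X[, keep, drop = FALSE]), Y)^2)
    SS[t, ] <- pmax(rss_red - rss_full, 0)
    df1[t] <- sum(design$assign == t)
  }
  ms_res <- rss_full / df_res
  Fmat <- sweep(SS, 1, df1, "/") / rep(ms_res, each = k)
  Pmat <- matrix(stats::pf(Fmat, df1, df_res, lower.tail = FALSE), k,
                 dimnames = dimnames(SS))
  list(SS = SS, F = Fmat, p = Pmat, df1 = df1, df_res = df_res,
       rss = rss_full, tss = tss, ms_res = ms_res)
}

#' Three-way between-subjects ANOVA (Type III)
#'
#' Factorial ANOVA of one dependent variable on age group, sex and
#' focality, reporting all seven effects (three mains, three two-way
#' interactions, the three-way interaction) with Type-III sums of squares
#' under sum-to-zero contrasts — the decomposition that remains
#' interpretable when cell sizes are unequal, as focal/non-focal splits
#' always are. On balanced data it coincides with the sequential
#' decomposition.
#'
#' @param data cohort data.frame.
#' @param dv name of the dependent-variable column.
#' @param factors the three between-subject factors.
#' @return data.frame with `effect`, `df1`, `df2`, `ss`, `F`, `p`;
#'   attributes `rss` and `ms_res` carry the residual fit.
#' @export
three_way_anova <- function(data, dv, factors = FOCALITY_FACTORS) {
  stopifnot(is.data.frame(data), dv %in% names(data))
  design <- anova_design(data, factors)
  y <- data[[dv]]
  if (!is.numeric(y)) stop_ff("design_error", "dependent variable must be numeric")
  fit <- anova_engine(design, matrix(y, dimnames = list(NULL, dv)))
  if (fit$rss[1] <= 1e-12 * max(fit$tss[1], 1))
    stop_ff("saturated_design_error",
            "residual sum of squares is (near) zero; saturated or degenerate fit")
  out <- data.frame(effect = design$labels, df1 = fit$df1,
                    df2 = fit$df_res, ss = fit$SS[, 1],
                    F = fit$F[, 1], p = fit$p[, 1])
  rownames(out) <- NULL
  attr(out, "rss") <- fit$rss[1]
  attr(out, "ms_res") <- fit$ms_res[1]
  out
}

#' @keywords internal
#' @noRd
scan_dv_columns <- function(cohort) {
  cols <- grep("_(csf|gm|wm)_ml$", names(cohort), value = TRUE)
  if (!length(cols)) stop_ff("design_error", "no regional volume columns in cohort")
  m <- regmatches(cols, regexec("^(.*)_(csf|gm|wm)_ml$", cols))
  data.frame(column = cols,
             roi = vapply(m, `[`, "", 2L),
             tissue = vapply(m, `[`, "", 3L),
             stringsAsFactors = FALSE)
}

#' Per-ROI focal-ROI scan
#'
#' Runs the three-way ANOVA for every ROI x tissue volume column, applies
#' a Bonferroni correction, and flags an ROI as a "focal ROI" when any
#' tissue shows a corrected-significant focality main effect or any
#' interaction involving focality. Age- or sex-only effects never flag.
#'
#' The correction family is configurable: `"per_tissue"` divides alpha by
#' the number of ROIs within each tissue (the default),
#' `"rois_by_tissues"` by ROIs x tissues, and `"scanwide"` additionally by
#' the four focality-involving effects, which controls the family-wise
#' error of the entire scan.
#'
#' @param cohort cohort data.frame with factors and `roiNN_{tissue}_ml`
#'   columns.
#' @param alpha significance level after correction (default 0.05).
#' @param family Bonferroni family definition.
#' @return Object of class `focal_roi_scan`: `table` (all ROI x tissue x
#'   effect statistics with corrected p), `focal_rois`, `triggers`
#'   (the flagging rows), `m` (the Bonferroni multiplier) and settings.
#' @export
focal_roi_scan <- function(cohort, alpha = 0.05,
                           family = c("per_tissue", "rois_by_tissues",
                                      "scanwide")) {
  family <- match.arg(family)
  dvs <- scan_dv_columns(cohort)
  design <- anova_design(cohort, FOCALITY_FACTORS)
  fit <- tryCatch(anova_engine(design, cohort[dvs$column]),
                  error = function(e) stop_ff("design_error",
                    "ANOVA scan failed: %s", conditionMessage(e)))
  n_rois <- length(unique(dvs$roi))
  focal_effects <- grep("focality", design$labels, value = TRUE)
  m <- switch(family,
              per_tissue = n_rois,
              rois_by_tissues = n_rois * length(unique(dvs$tissue)),
              scanwide = n_rois * length(unique(dvs$tissue)) *
                length(focal_effects))

  k <- length(design$labels)
  tab <- data.frame(
    roi = rep(dvs$roi, each = k),
    tissue = rep(dvs$tissue, each = k),
    effect = rep(design$labels, times = nrow(dvs)),
    df1 = rep(fit$df1, times = nrow(dvs)),
    df2 = fit$df_res,
    F = as.vector(fit$F),
    p = as.vector(fit$p),
    stringsAsFactors = FALSE)
  tab$involves_focality <- grepl("focality", tab$effect)
  tab$p_corrected <- ifelse(tab$involves_focality, pmin(1, tab$p * m), NA_real_)
  tab$significant <- tab$involves_focality & tab$p_corrected < alpha

  triggers <- tab[tab$significant, c("roi", "tissue", "effect", "F", "p",
                                     "p_corrected")]
  rownames(triggers) <- NULL
  structure(list(table = tab, triggers = triggers,
                 focal_rois = sort(unique(triggers$roi)),
                 alpha = alpha, family = family, m = m,
                 n_rois = n_rois), class = "focal_roi_scan")
}

#' @export
print.focal_roi_scan <- function(x, ...) {
  cat(sprintf("focal-ROI scan: %d ROIs x 3 tissues, Bonferroni m = %d (%s), alpha = %g\n",
              x$n_rois, x$m, x$family, x$alpha))
  if (length(x$focal_rois)) {
    cat("focal ROIs:", paste(x$focal_rois, collapse = ", "), "\n")
    print(x$triggers)
  } else cat("no focal ROI flagged\n")
  invisible(x)
}

#' Post-hoc focality contrasts within age groups
#'
#' Decomposes a focality main effect or age x focality interaction:
#' within each age group, the focal vs non-focal difference in estimated
#' marginal means (averaged over sex) is tested against the pooled ANOVA
#' error term, with Bonferroni correction over the three age groups. Age
#' groups with an empty sex x focality cell are skipped with a warning.
#'
#' @param cohort cohort data.frame.
#' @param roi ROI id or `roiNN` name.
#' @param tissue `"csf"`, `"gm"` or `"wm"`.
#' @param alpha corrected significance level.
#' @return data.frame with per-age-group estimate (focal minus
#'   non-focal), SE, t, df, p, Bonferroni-corrected p, significance and
#'   direction.
#' @export
posthoc_focality <- function(cohort, roi, tissue, alpha = 0.05) {
  dv <- roi_col(roi, tissue)
  if (!dv %in% names(cohort)) stop_ff("lookup_error", "no column %s", dv)
  design <- anova_design(cohort, FOCALITY_FACTORS)
  fit <- anova_engine(design, matrix(cohort[[dv]], dimnames = list(NULL, dv)))
  beta <- qr.coef(qr(design$X), cohort[[dv]])
  XtX_inv <- solve(crossprod(design$X))

  grid <- expand.grid(age_group = levels(droplevels(factor(cohort$age_group))),
                      sex = SEX_LEVELS, focality = c("focal", "nonfocal"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$age_group <- factor(grid$age_group, levels = levels(factor(cohort$age_group)))
  grid$sex <- factor(grid$sex, levels = SEX_LEVELS)
  grid$focality <- factor(grid$focality, levels = levels(factor(cohort$focality)))
  contr <- stats::setNames(rep(list("contr.sum"), 3), FOCALITY_FACTORS)
  Xg <- stats::model.matrix(~ age_group * sex * focality, grid,
                            contrasts.arg = contr)

  ages <- levels(droplevels(factor(cohort$age_group)))
  rows <- lapply(ages, function(a) {
    cells <- table(factor(cohort$sex)[cohort$age_group == a],
                   factor(cohort$focality)[cohort$age_group == a])
    if (any(cells == 0)) {
      warning(sprintf("age group %s has an empty cell; contrast skipped", a))
      return(NULL)
    }
    Lf <- colMeans(Xg[grid$age_group == a & grid$focality == "focal", , drop = FALSE])
    Ln <- colMeans(Xg[grid$age_group == a & grid$focality == "nonfocal", , drop = FALSE])
    L <- Lf - Ln
    est <- sum(L * beta)
    se <- sqrt(fit$ms_res[1] * drop(t(L) %*% XtX_inv %*% L))
    tval <- est / se
    p <- 2 * stats::pt(-abs(tval), fit$df_res)
    data.frame(age_group = a, estimate = est, se = se, t = tval,
               df = fit$df_res, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$p_corrected <- pmin(1, out$p * length(ages))
  out$significant <- out$p_corrected < alpha
  out$direction <- ifelse(out$estimate > 0, "focal_higher", "nonfocal_higher")
  rownames(out) <- NULL
  out
}

#' Pearson correlation with heteroscedasticity diagnostics
#'
#' Pearson r with its two-sided t-test, plus White's test for
#' heteroscedasticity of the regression of `y` on `x` (the Lagrange
#' multiplier form n R-squared of the auxiliary regression of squared
#' residuals on x and x^2, referred to chi-squared with 2 df). When a
#' two-level grouping is supplied, per-group correlations and their
#' Fisher-z comparison are included.
#'
#' @param x,y numeric vectors (n >= 4, non-constant).
#' @param by optional two-level factor (e.g. focality class) for the
#'   per-group comparison.
#' @return Object of class `correlation_result`.
#' @export
pearson_with_diagnostics <- function(x, y, by = NULL) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop_ff("domain_error", "need at least 4 complete observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop_ff("undefined_correlation_error", "constant input; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  fit <- stats::lm(y ~ x)
  # Lagrange-multiplier form of White's test: n R^2 of the auxiliary
  # regression of squared residuals on {x, x^2}, chi-squared with 2 df
  white <- lmtest::bptest(fit, ~ x + I(x^2), studentize = TRUE)

  groups <- comparison <- NULL
  if (!is.null(by)) {
    by <- droplevels(factor(by[ok]))
    if (nlevels(by) != 2L)
      stop_ff("domain_error", "grouping must have exactly 2 levels")
    per <- lapply(levels(by), function(g) {
      xs <- x[by == g]; ys <- y[by == g]
      if (length(xs) < 4L)
        stop_ff("domain_error", "group %s has fewer than 4 observations", g)
      data.frame(group = g, r = stats::cor(xs, ys), n = length(xs))
    })
    groups <- do.call(rbind, per)
    comparison <- compare_group_correlations(groups$r[1], groups$n[1],
                                             groups$r[2], groups$n[2])
  }
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = n,
                 conf_int = unname(ct$conf.int),
                 white_stat = unname(white$statistic),
                 white_df = unname(white$parameter),
                 white_p = unname(white$p.value),
                 groups = groups, comparison = comparison),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (n = %d, p = %.3g); White test LM = %.2f (p = %.3g)\n",
              x$r, x$n, x$p, x$white_stat, x$white_p))
  if (!is.null(x$groups)) {
    print(x$groups)
    cat(sprintf("group comparison: z = %.3f, p = %.3g\n",
                x$comparison$z, x$comparison$p))
  }
  invisible(x)
}

#' Compare two independent correlations (Fisher z)
#'
#' Tests r1 vs r2 from independent samples via the Fisher z-transform:
#' z = (atanh r1 - atanh r2) / sqrt(1/(n1-3) + 1/(n2-3)).
#'
#' @param r1,r2 sample correlations with |r| < 1.
#' @param n1,n2 sample sizes (>= 4).
#' @param alternative two-sided by default; one-sided options refer to
#'   r1 - r2.
#' @return List with `z` and `p`.
#' @export
compare_group_correlations <- function(r1, n1, r2, n2,
                                       alternative = c("two.sided", "greater",
                                                       "less")) {
  alternative <- match.arg(alternative)
  if (abs(r1) >= 1 || abs(r2) >= 1)
    stop_ff("transform_overflow_error", "|r| = 1; Fisher transform overflows")
  if (n1 < 4L || n2 < 4L) stop_ff("domain_error", "need n >= 4 in each group")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(z = z, p = p, alternative = alternative)
}

#' Shapiro-Wilk normality check
#'
#' Thin wrapper around the standard Shapiro-Wilk test, used as the
#' per-group normality gate before the ANOVA scan.
#'
#' @param values numeric sample, 3 <= n <= 5000, non-constant.
#' @return List with `W` and `p`.
#' @export
shapiro_normality <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 3L || length(values) > 5000L)
    stop_ff("domain_error", "Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::sd(values) == 0)
    stop_ff("undefined_w_error", "constant sample; W undefined")
  sw <- stats::shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Homogeneity-of-variance check (Brown-Forsythe / Levene)
#'
#' Levene's test with group medians as centers: a one-way ANOVA of the
#' absolute deviations from the group median — the robust homogeneity
#' companion to the between-subjects factorial ANOVA.
#'
#' @param values numeric vector.
#' @param groups factor of group memberships.
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
levene_homogeneity <- function(values, groups) {
  groups <- droplevels(factor(groups))
  if (nlevels(groups) < 2L) stop_ff("design_error", "need >= 2 groups")
  med <- tapply(values, groups, stats::median)
  dev <- abs(values - med[groups])
  fit <- stats::anova(stats::lm(dev ~ groups))
  list(F = fit$`F value`[1], df1 = fit$Df[1], df2 = fit$Df[2],
       p = fit$`Pr(>F)`[1])
}
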