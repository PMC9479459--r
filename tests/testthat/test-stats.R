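# Factorial ANOVA engine, focal-ROI scan, post-hoc contrasts and
# correlation machinery, checked against independent oracles.

test_that("balanced 2x2x2 fixture reproduces the textbook decomposition", {
  g <- balanced_222_fixture()
  out <- three_way_anova(g, "y")
  oracle <- balanced_anova_oracle(g, "y", c("age_group", "sex", "focality"))

  expect_equal(out$F[out$effect == "age_group"], 8, tolerance = 1e-10)
  expect_equal(out$df1[out$effect == "age_group"], 1L)
  expect_equal(out$df2[out$effect == "age_group"], 8L)
  other <- setdiff(out$effect, "age_group")
  expect_lt(max(out$F[out$effect %in% other]), 1e-10)

  m <- match(out$effect, oracle$effect)
  expect_equal(out$ss, oracle$ss[m], tolerance = 1e-10)
  expect_equal(out$F, oracle$F[m], tolerance = 1e-10)
})

test_that("Type-III results agree with car::Anova on unbalanced data", {
  skip_if_not_installed("car")
  set.seed(42)
  ch <- sample_cohort_tables(effect_spec(n_per_cell = 20, seed = 42,
                                         interaction_delta = 1))
  # drop rows to unbalance all cells
  ch <- ch[-sample(nrow(ch), 17), ]
  out <- three_way_anova(ch, "roi05_csf_ml")

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(roi05_csf_ml ~ age_group * sex * focality, data = ch)
  ca <- car::Anova(fit, type = 3)
  ca <- ca[rownames(ca) != "(Intercept)" & rownames(ca) != "Residuals", ]
  m <- match(gsub(" ", "", out$effect), gsub(" ", "", rownames(ca)))
  expect_equal(out$ss, ca$`Sum Sq`[m], tolerance = 1e-10)
  expect_equal(out$F, ca$`F value`[m], tolerance = 1e-10)
  expect_equal(out$p, ca$`Pr(>F)`[m], tolerance = 1e-10)
})

test_that("on balanced data Type III equals the sequential decomposition", {
  set.seed(8)
  g <- expand.grid(rep = 1:5, age_group = c("young", "middle", "older"),
                   sex = c("M", "F"), focality = c("focal", "nonfocal"),
                   stringsAsFactors = FALSE)
  g$y <- rnorm(nrow(g)) + (g$age_group == "older") * 0.5
  out <- three_way_anova(g, "y")
  seq_fit <- stats::anova(stats::lm(y ~ age_group * sex * focality, data = g))
  seq_fit <- seq_fit[rownames(seq_fit) != "Residuals", ]
  m <- match(out$effect, rownames(seq_fit))
  expect_equal(out$ss, seq_fit$`Sum Sq`[m], tolerance = 1e-10)
  expect_equal(out$F, seq_fit$`F value`[m], tolerance = 1e-10)
})

test_that("degenerate designs raise the documented errors", {
  g <- balanced_222_fixture()
  g$y <- 1
  expect_error(three_way_anova(g, "y"), class = "saturated_design_error")
  g2 <- balanced_222_fixture()
  g2$focality <- "focal"
  expect_error(three_way_anova(g2, "y"), class = "design_error")
})

test_that("the scan flags the seeded ROI through the CSF age x focality interaction", {
  ch <- sample_cohort_tables(effect_spec(n_per_cell = 50, seed = 42,
                                         interaction_delta = 1.5))
  scan <- focal_roi_scan(ch)
  expect_true("roi05" %in% scan$focal_rois)
  tr <- scan$triggers[scan$triggers$roi == "roi05", ]
  expect_true(any(tr$tissue == "csf" & tr$effect == "age_group:focality"))
  # age main effects are corrected-significant everywhere but never flag
  age_p <- scan$table[scan$table$effect == "age_group" &
                        scan$table$tissue == "csf", "p"]
  expect_true(all(age_p < 0.05 / 12))
  expect_false(any(scan$table$significant[!scan$table$involves_focality]))
})

test_that("single-ROI scan applies no correction", {
  ch <- sample_cohort_tables(effect_spec(n_per_cell = 30, seed = 5,
                                         n_rois = 1, interaction_roi = 1))
  scan <- focal_roi_scan(ch)
  expect_equal(scan$m, 1L)
  expect_equal(scan$table$p_corrected[scan$table$involves_focality],
               scan$table$p[scan$table$involves_focality])
})

test_that("post-hoc contrasts localize the injected older-group effect and match emmeans", {
  skip_if_not_installed("emmeans")
  ch <- sample_cohort_tables(effect_spec(n_per_cell = 50, seed = 42,
                                         interaction_delta = 1.5))
  ph <- posthoc_focality(ch, "roi05", "csf")
  expect_equal(nrow(ph), 3L)
  older <- ph[ph$age_group == "older", ]
  expect_true(older$significant)
  expect_identical(older$direction, "focal_higher")
  expect_false(any(ph$significant[ph$age_group != "older"]))

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old))
  fit <- stats::lm(roi05_csf_ml ~ age_group * sex * focality, data = ch)
  emm <- emmeans::emmeans(fit, ~ focality | age_group)
  cmp <- as.data.frame(emmeans::contrast(emm, method = "revpairwise"))
  # emmeans reports nonfocal - focal or focal - nonfocal depending on level
  # order; compare magnitudes and t statistics
  m <- match(ph$age_group, cmp$age_group)
  expect_equal(abs(ph$estimate), abs(cmp$estimate[m]), tolerance = 1e-8)
  expect_equal(abs(ph$t), abs(cmp$t.ratio[m]), tolerance = 1e-8)
  expect_equal(ph$df, cmp$df[m], tolerance = 1e-8)
})

test_that("null post-hoc contrasts are rarely significant", {
  hits <- vapply(1:200, function(s) {
    ch <- sample_cohort_tables(effect_spec(n_per_cell = 20, seed = 5000 + s))
    any(posthoc_focality(ch, "roi03", "gm")$significant)
  }, NA)
  # familywise level 0.05 plus three-sigma binomial slack at 200 replicates
  expect_lte(mean(hits), 0.05 + 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("pearson_with_diagnostics reproduces hand-computed values", {
  expect_equal(pearson_with_diagnostics(c(1, 2, 3, 4), c(2, 4, 6, 8))$r, 1)
  res <- pearson_with_diagnostics(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  expect_equal(res$n, 4L)

  # White statistic equals the hand-rolled auxiliary regression n * R^2
  set.seed(10)
  x <- rnorm(200); y <- 1 + 2 * x + rnorm(200) * (1 + 0.5 * abs(x))
  res <- pearson_with_diagnostics(x, y)
  e2 <- stats::residuals(stats::lm(y ~ x))^2
  aux <- stats::lm(e2 ~ x + I(x^2))
  lm_stat <- length(x) * summary(aux)$r.squared
  expect_equal(res$white_stat, lm_stat, tolerance = 1e-10)
  expect_equal(res$white_df, 2)
  expect_equal(res$white_p, stats::pchisq(lm_stat, 2, lower.tail = FALSE),
               tolerance = 1e-10)

  expect_error(pearson_with_diagnostics(rep(1, 10), rnorm(10)),
               class = "undefined_correlation_error")
  expect_error(pearson_with_diagnostics(1:3, 3:1), class = "domain_error")
})

test_that("White test is calibrated under homoscedasticity", {
  rej <- vapply(1:1000, function(s) {
    set.seed(9000 + s)
    x <- rnorm(500); y <- 1 + x + rnorm(500)
    pearson_with_diagnostics(x, y)$white_p < 0.05
  }, NA)
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("Fisher-z comparison matches the closed form and is antisymmetric", {
  cmp <- compare_group_correlations(0.28, 138, 0.09, 162)
  z_hand <- (atanh(0.28) - atanh(0.09)) / sqrt(1 / 135 + 1 / 159)
  expect_equal(cmp$z, z_hand, tolerance = 1e-12)
  expect_lt(abs(cmp$z - 1.69), 0.01)
  expect_lt(abs(cmp$p - 0.0916), 0.002)

  expect_equal(compare_group_correlations(0.3, 50, 0.3, 60)$z, 0)
  expect_equal(compare_group_correlations(0.3, 50, 0.3, 60)$p, 1)
  a <- compare_group_correlations(0.4, 80, 0.1, 90)
  b <- compare_group_correlations(0.1, 90, 0.4, 80)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  one <- compare_group_correlations(0.4, 80, 0.1, 90, alternative = "greater")
  expect_equal(one$p, a$p / 2, tolerance = 1e-12)
  expect_error(compare_group_correlations(1, 50, 0.2, 50),
               class = "transform_overflow_error")
})

test_that("Shapiro-Wilk gate accepts Gaussians and rejects exponentials", {
  res <- vapply(1:200, function(s) {
    set.seed(s)
    c(gauss = shapiro_normality(rnorm(100))$p > 0.05,
      expo = shapiro_normality(rexp(100))$p < 0.05)
  }, c(gauss = NA, expo = NA))
  expect_gte(mean(res["gauss", ]), 0.90)
  expect_gte(mean(res["expo", ]), 0.90)
  expect_error(shapiro_normality(rep(2, 10)), class = "undefined_w_error")
})

test_that("Levene homogeneity check agrees with car::leveneTest", {
  skip_if_not_installed("car")
  set.seed(3)
  v <- c(rnorm(40, sd = 1), rnorm(40, sd = 2))
  g <- rep(c("a", "b"), each = 40)
  mine <- levene_homogeneity(v, g)
  ref <- car::leveneTest(v ~ factor(g), center = median)
  expect_equal(mine$F, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(mine$p, ref$`Pr(>F)`[1], tolerance = 1e-10)
})
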