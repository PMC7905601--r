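stage3 <- function(n = c(9, 10, 14)) rep(c("breeding", "molt", "nonbreeding"), n)

test_that("stage linear models report F, p and adjusted R2, with degenerate conventions", {
  set.seed(1)
  d <- data.frame(stage = stage3(), y = rnorm(33))
  m <- fit_stage_lm(d, "y")
  ref <- summary(stats::lm(y ~ stage, d))
  expect_equal(m$tests$statistic, unname(ref$fstatistic[1]))
  expect_equal(m$adj_r2, ref$adj.r.squared)
  expect_equal(m$tests[, c("df1", "df2")], data.frame(df1 = 2, df2 = 30),
               ignore_attr = TRUE)
  # constant response: F = 0, p = 1 by convention
  d$y <- 5
  m0 <- fit_stage_lm(d, "y")
  expect_equal(m0$tests$statistic, 0)
  expect_equal(m0$tests$p, 1)
  # a stage with < 2 observations errors, naming the stage
  d2 <- data.frame(stage = c("breeding", rep(c("molt", "nonbreeding"), 5)), y = rnorm(11))
  expect_error(fit_stage_lm(d2, "y"), "breeding", class = "seasong_invalid_argument")
})

test_that("transforms are applied before fitting", {
  set.seed(2)
  d <- data.frame(stage = stage3(), y = rlnorm(33))
  m <- fit_stage_lm(d, "y", transform = "log")
  ref <- summary(stats::lm(log(y) ~ stage, d))
  expect_equal(m$tests$statistic, unname(ref$fstatistic[1]))
  d$y[1] <- -1
  expect_error(fit_stage_lm(d, "y", transform = "sqrt"), class = "seasong_invalid_argument")
})

test_that("mixed-model LRTs are non-negative, nested and sensitive to a true interaction", {
  cfg <- stage_effect_config()
  tab <- synth_stage_table(cfg, seed = 42)
  m <- suppressWarnings(fit_stage_area_lmm(
    stage_table_long(tab, c("ar_hvc", "ar_lman"), c("HVC", "lMAN"))))
  expect_true(all(m$tests$chisq >= 0))
  expect_equal(m$tests$df, c(2, 1, 2))
  # one individual only errors
  one <- stage_table_long(tab[1, ], c("ar_poa", "ar_h"))
  expect_error(suppressWarnings(fit_stage_area_lmm(one)), class = "seasong_invalid_argument")
})

test_that("post hoc corrections match hand-computed Bonferroni and BH tables", {
  # contrast machinery on a real fit
  set.seed(3)
  d <- data.frame(stage = stage3(), y = rnorm(33) + rep(c(2, 0, 0), c(9, 10, 14)))
  m <- fit_stage_lm(d, "y")
  ph <- posthoc_pairwise(m, "bonferroni")
  expect_equal(nrow(ph), 3)
  expect_equal(ph$adj_p, pmin(ph$p * 3, 1))
  ph_fdr <- posthoc_pairwise(m, "fdr")
  expect_equal(ph_fdr$adj_p, stats::p.adjust(ph_fdr$p, "BH"))
  # hand-computed reference tables
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), "bonferroni"), c(0.03, 0.06, 1.0))
  expect_equal(stats::p.adjust(c(0.01, 0.02, 0.9), "BH"), c(0.03, 0.03, 0.9))
  expect_equal(stats::p.adjust(c(1, 1, 1), "BH"), c(1, 1, 1))
  # monotonicity of BH in the raw p-rank
  p <- sort(stats::runif(8))
  expect_true(all(diff(stats::p.adjust(p, "BH")) >= 0))
})

test_that("Cohen's d matches hand arithmetic and is antisymmetric and shift invariant", {
  d <- cohens_d(c(0, 2), c(-1, 1))
  expect_equal(d$estimate, 1 / sqrt(2))
  set.seed(4)
  a <- rnorm(40, 1)
  b <- rnorm(50)
  expect_equal(cohens_d(a, b)$estimate, -cohens_d(b, a)$estimate)
  expect_equal(cohens_d(a + 100, b + 100)$estimate, cohens_d(a, b)$estimate)
  expect_true(d$ci[1] < d$estimate && d$estimate < d$ci[2])
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "seasong_undefined_input")
  expect_error(cohens_d(1, c(1, 2)), class = "seasong_invalid_argument")
  # large-sample: d converges to the standardized mean difference
  set.seed(5)
  big <- cohens_d(rnorm(1e5, 1), rnorm(1e5))
  expect_equal(big$estimate, 1, tolerance = 0.01)
  # noncentral-t and normal intervals agree closely at moderate n
  nct <- cohens_d(a, b, ci = "nct")
  nrm <- cohens_d(a, b, ci = "normal")
  expect_equal(nct$ci, nrm$ci, tolerance = 0.05)
})

test_that("Pearson effect sizes carry Fisher-z intervals and the sign-convention hook", {
  x <- 1:10
  r <- pearson_r_ci(x, 2 * x + 1)
  expect_equal(r$estimate, 1)
  set.seed(6)
  xx <- rnorm(50)
  yy <- 0.5 * xx + rnorm(50)
  r2 <- pearson_r_ci(xx, yy)
  ref <- stats::cor.test(xx, yy)
  expect_equal(r2$estimate, unname(ref$estimate))
  expect_equal(r2$ci, as.numeric(ref$conf.int))
  fl <- pearson_r_ci(xx, yy, flip_sign = TRUE)
  expect_equal(fl$estimate, -r2$estimate)
  expect_equal(fl$ci, rev(-r2$ci))
  expect_error(pearson_r_ci(rep(1, 10), rnorm(10)), class = "seasong_undefined_input")
  expect_error(pearson_r_ci(1:3, 1:3), class = "seasong_invalid_argument")
})

test_that("Poisson song-rate models recover a log-linear covariate effect", {
  set.seed(7)
  n <- 200
  d <- data.frame(stage = sample(c("breeding", "molt", "nonbreeding"), n, TRUE),
                  od = rnorm(n))
  d$songrate <- rpois(n, exp(1 + 0.5 * d$od))
  m <- fit_poisson_glm(d, "songrate", covariate = "od")
  expect_equal(unname(stats::coef(m$fit)["covariate"]), 0.5, tolerance = 0.1)
  expect_lt(m$tests$p[m$tests$term == "covariate"], 1e-6)
  d$bad <- d$songrate + 0.5
  expect_error(fit_poisson_glm(d, "bad"), class = "seasong_invalid_argument")
  d$zero <- 0L
  expect_error(fit_poisson_glm(d, "zero"), class = "seasong_degenerate_fit")
})

test_that("ANCOVA detects a covariate effect, drops ns interactions, and reports partial R2", {
  set.seed(8)
  d <- data.frame(stage = stage3(), x = rnorm(33))
  d$y <- 0.6 * d$x + rep(c(1, 0, 0.5), c(9, 10, 14)) + rnorm(33, sd = 0.5)
  m <- ancova_behavior(d, "y", "x")
  expect_false(m$interaction_kept)
  expect_lt(m$tests$p[m$tests$term == "covariate"], 0.01)
  expect_true(m$partial_r2 > 0 && m$partial_r2 < 1)
  # collinear covariate warns
  d$x2 <- as.numeric(factor(d$stage))
  expect_warning(ancova_behavior(d, "y", "x2"), class = "seasong_collinear")
})
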