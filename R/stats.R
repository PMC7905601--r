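apply_transform <- function(y, transform) {
  switch(transform,
         none = y,
         sqrt = {
           if (any(y < 0, na.rm = TRUE)) ss_stop("invalid_argument", "sqrt transform needs y >= 0")
           sqrt(y)
         },
         log = {
           if (any(y <= 0, na.rm = TRUE)) ss_stop("invalid_argument", "log transform needs y > 0")
           log(y)
         },
         ss_stop("invalid_argument", sprintf("unknown transform '%s'", transform)))
}

model_result <- function(family, response, tests, fit, transform = "none", extra = list()) {
  structure(c(list(family = family, response = response, tests = tests,
                   fit = fit, transform = transform), extra),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result: %s> response %s%s\n", x$family, x$response,
              if (x$transform != "none") sprintf(" (%s-transformed)", x$transform) else ""))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

#' Stage comparison by general linear model
#'
#' Least-squares fit of a (possibly transformed) measure on life-cycle
#' stage, reported as the omnibus F with degrees of freedom, p value and
#' adjusted R-squared — the form used for behaviors, testosterone and
#' repertoire summaries. A response with no variance at all yields F = 0,
#' p = 1 by convention.
#'
#' @param data data frame containing `response` and `stage`.
#' @param response name of the dependent variable.
#' @param stage name of the stage factor column.
#' @param transform `"none"`, `"sqrt"` or `"log"`.
#' @return a `model_result` with `tests` row `stage` (`F`, `df1`, `df2`,
#'   `p`) and `adj_r2`.
#' @export
fit_stage_lm <- function(data, response, stage = "stage", transform = "none") {
  y <- apply_transform(data[[response]], transform)
  g <- droplevels(factor(data[[stage]]))
  counts <- table(g)
  if (length(counts) < 2L) ss_stop("invalid_argument", "need at least 2 stages")
  if (any(counts < 2L)) {
    ss_stop("invalid_argument",
            sprintf("stage '%s' has fewer than 2 observations",
                    names(counts)[which(counts < 2L)[1]]))
  }
  d <- data.frame(y = y, stage = g)
  fit <- stats::lm(y ~ stage, data = d)
  if (stats::var(y) == 0) {
    tests <- data.frame(term = "stage", statistic = 0, df1 = length(counts) - 1L,
                        df2 = length(y) - length(counts), p = 1)
    adj_r2 <- 0
  } else {
    s <- summary(fit)
    fs <- s$fstatistic
    tests <- data.frame(term = "stage", statistic = unname(fs[1]),
                        df1 = unname(fs[2]), df2 = unname(fs[3]),
                        p = stats::pf(fs[1], fs[2], fs[3], lower.tail = FALSE))
    adj_r2 <- s$adj.r.squared
  }
  model_result("lm", response, tests, fit, transform,
               list(adj_r2 = adj_r2, data = d))
}

lrt <- function(m0, m1) {
  chisq <- max(0, 2 * (as.numeric(stats::logLik(m1)) - as.numeric(stats::logLik(m0))))
  df <- attr(stats::logLik(m1), "df") - attr(stats::logLik(m0), "df")
  c(chisq = chisq, df = df, p = stats::pchisq(chisq, df, lower.tail = FALSE))
}

#' Stage-by-brain-area linear mixed model
#'
#' Random-intercept model for repeated measures of mRNA expression across
#' brain areas within individuals: `value ~ stage * area + (1 | id)`,
#' fitted by maximum likelihood. Stage, area, and the stage-by-area
#' interaction are each tested by likelihood-ratio chi-square between
#' nested fits (main effects against the additive model, the interaction
#' against the additive model). If the interaction is not significant at
#' `alpha_interaction` it is dropped from the reported model. A singular
#' random-effect fit is downgraded to a fixed-effects model with a warning.
#'
#' @param data long-format data frame (see [stage_table_long()]).
#' @param response,stage,area,id column names.
#' @param alpha_interaction threshold for keeping the interaction.
#' @return a `model_result` with one `tests` row per term (`chisq`, `df`,
#'   `p`) and fields `interaction_kept`, `singular`.
#' @export
fit_stage_area_lmm <- function(data, response = "value", stage = "stage",
                               area = "area", id = "id", alpha_interaction = 0.05) {
  d <- data.frame(y = data[[response]], stage = droplevels(factor(data[[stage]])),
                  area = droplevels(factor(data[[area]])), id = factor(data[[id]]))
  if (nlevels(d$area) < 2L) ss_stop("invalid_argument", "need at least 2 brain areas")
  if (nlevels(d$id) < 2L) ss_stop("invalid_argument", "need more than one individual")
  singular <- FALSE
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fits <- withCallingHandlers(
    {
      m_int <- lme4::lmer(y ~ stage * area + (1 | id), data = d, REML = FALSE, control = ctrl)
      m_add <- lme4::lmer(y ~ stage + area + (1 | id), data = d, REML = FALSE, control = ctrl)
      m_s0 <- lme4::lmer(y ~ area + (1 | id), data = d, REML = FALSE, control = ctrl)
      m_a0 <- lme4::lmer(y ~ stage + (1 | id), data = d, REML = FALSE, control = ctrl)
      list(m_int = m_int, m_add = m_add, m_s0 = m_s0, m_a0 = m_a0)
    },
    warning = function(w) {
      singular <<- TRUE
      invokeRestart("muffleWarning")
    }
  )
  if (lme4::isSingular(fits$m_add, tol = 1e-4)) singular <- TRUE
  if (singular) {
    ss_warn("singular_fit", "random-intercept variance is (near) zero; refitting without random effect")
    fits <- list(m_int = stats::lm(y ~ stage * area, data = d),
                 m_add = stats::lm(y ~ stage + area, data = d),
                 m_s0 = stats::lm(y ~ area, data = d),
                 m_a0 = stats::lm(y ~ stage, data = d))
  }
  t_stage <- lrt(fits$m_s0, fits$m_add)
  t_area <- lrt(fits$m_a0, fits$m_add)
  t_int <- lrt(fits$m_add, fits$m_int)
  tests <- data.frame(term = c("stage", "area", "stage:area"),
                      chisq = c(t_stage["chisq"], t_area["chisq"], t_int["chisq"]),
                      df = c(t_stage["df"], t_area["df"], t_int["df"]),
                      p = c(t_stage["p"], t_area["p"], t_int["p"]))
  keep_int <- tests$p[3] < alpha_interaction
  model_result(if (singular) "lmm_downgraded" else "lmm", response, tests,
               if (keep_int) fits$m_int else fits$m_add,
               extra = list(interaction_kept = keep_int, singular = singular,
                            data = d))
}

#' Pairwise post-hoc stage contrasts
#'
#' All pairwise stage contrasts from a fitted omnibus model, with p values
#' adjusted by Bonferroni (multiply by the number of contrasts, capped at
#' 1) or the Benjamini-Hochberg false discovery rate.
#'
#' @param model a `model_result` whose fit contains a `stage` factor with
#'   at least 3 levels.
#' @param method `"bonferroni"` or `"fdr"`.
#' @return data frame: `contrast`, `estimate`, `se`, `df`, `t`, `p`,
#'   `adj_p`, `method`.
#' @export
posthoc_pairwise <- function(model, method = c("bonferroni", "fdr")) {
  method <- match.arg(method)
  stopifnot(inherits(model, "model_result"))
  fit <- model$fit
  nl <- tryCatch(nlevels(stats::model.frame(fit)$stage), error = function(e) 0L)
  if (nl < 3L) ss_stop("invalid_argument", "post hoc needs an omnibus factor with >= 3 levels")
  em <- emmeans::emmeans(fit, "stage")
  ctr <- as.data.frame(emmeans::contrast(em, "pairwise", adjust = "none"))
  p_col <- ctr$p.value
  data.frame(contrast = as.character(ctr$contrast), estimate = ctr$estimate,
             se = ctr$SE, df = ctr$df,
             t = ctr$t.ratio, p = p_col,
             adj_p = stats::p.adjust(p_col, method = if (method == "fdr") "BH" else "bonferroni"),
             method = method)
}

#' Cohen's d with confidence interval
#'
#' Standardized mean difference `(mean_a - mean_b) / pooled SD` with the
#' pooled SD using n-1 weighting. The confidence interval is computed from
#' the noncentral-t distribution by default, or by the normal
#' approximation. The small-sample (Hedges) correction is off by default.
#'
#' @param a,b numeric vectors (each >= 2 values).
#' @param level confidence level.
#' @param ci `"nct"` (noncentral t) or `"normal"`.
#' @param hedges apply the Hedges small-sample correction.
#' @return an object of class `effect_size` with `kind = "cohens_d"`,
#'   `estimate`, `ci`, `level`.
#' @export
cohens_d <- function(a, b, level = 0.95, ci = c("nct", "normal"), hedges = FALSE) {
  ci <- match.arg(ci)
  na <- as.numeric(length(a))
  nb <- as.numeric(length(b))
  if (na < 2L || nb < 2L) ss_stop("invalid_argument", "both groups need >= 2 values")
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 == 0) ss_stop("undefined_input", "pooled SD is zero; d is undefined")
  d <- (mean(a) - mean(b)) / sqrt(sp2)
  if (hedges) d <- d * (1 - 3 / (4 * (na + nb - 2) - 1))
  nfac <- sqrt(na * nb / (na + nb))
  alpha <- 1 - level
  normal_ci <- function() {
    se <- sqrt((na + nb) / (na * nb) + d^2 / (2 * (na + nb - 2)))
    d + stats::qnorm(c(alpha / 2, 1 - alpha / 2)) * se
  }
  if (ci == "normal" || abs(d * nfac) > 40) {
    # the noncentral-t CDF is numerically unusable far in its tails; the
    # normal approximation is exact to working precision there anyway
    lims <- normal_ci()
  } else {
    tobs <- d * nfac
    df <- na + nb - 2
    ncp_limit <- function(target) {
      # pt() warns about reduced tail precision for large ncp; immaterial here
      f <- function(ncp) suppressWarnings(stats::pt(tobs, df, ncp)) - target
      lo <- tobs - 10 * (1 + abs(tobs))
      hi <- tobs + 10 * (1 + abs(tobs))
      stats::uniroot(f, c(lo, hi), extendInt = "yes")$root
    }
    lims <- c(ncp_limit(1 - alpha / 2), ncp_limit(alpha / 2)) / nfac
  }
  structure(list(kind = "cohens_d", estimate = d, ci = lims, level = level,
                 n = c(na, nb)),
            class = "effect_size")
}

#' Pearson correlation with Fisher-z confidence interval
#'
#' Product-moment correlation with its confidence interval from the Fisher
#' z transform. `flip_sign` negates the coefficient and mirrors the
#' interval, for measures where smaller raw values mean a stronger trait
#' (e.g. approach latency and closest approach as aggression measures).
#'
#' @param x,y numeric vectors (n >= 4, finite, non-constant).
#' @param level confidence level.
#' @param flip_sign negate the reported effect.
#' @return an object of class `effect_size` with `kind = "pearson_r"`.
#' @export
pearson_r_ci <- function(x, y, level = 0.95, flip_sign = FALSE) {
  if (length(x) != length(y) || length(x) < 4L) {
    ss_stop("invalid_argument", "need paired vectors of length >= 4")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    ss_stop("invalid_argument", "values must be finite")
  }
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    ss_stop("undefined_input", "zero variance; correlation undefined")
  }
  ct <- stats::cor.test(x, y, conf.level = level)
  est <- unname(ct$estimate)
  ci <- as.numeric(ct$conf.int)
  if (flip_sign) {
    est <- -est
    ci <- rev(-ci)
  }
  structure(list(kind = "pearson_r", estimate = est, ci = ci, level = level,
                 n = length(x), p = ct$p.value),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> %s = %.3f, %d%% CI [%.3f, %.3f]\n", x$kind,
              x$estimate, round(100 * x$level), x$ci[1], x$ci[2]))
  invisible(x)
}

#' Poisson model of song rate
#'
#' Log-link Poisson regression of a song count on stage and (optionally) a
#' covariate such as a net optical density. Tests are deviance differences
#' (likelihood-ratio chi-square) against the model without the term.
#'
#' @param data data frame.
#' @param count name of the count response (non-negative integers).
#' @param stage stage factor column.
#' @param covariate optional covariate column name.
#' @return a `model_result` with family `"poisson"`, the residual
#'   `deviance` field, and one `tests` row per term.
#' @export
fit_poisson_glm <- function(data, count, stage = "stage", covariate = NULL) {
  y <- data[[count]]
  if (any(y < 0) || any(y != round(y))) {
    ss_stop("invalid_argument", "counts must be non-negative integers")
  }
  if (all(y == 0)) ss_stop("degenerate_fit", "all counts are zero; rate model is degenerate")
  d <- data.frame(y = y, stage = droplevels(factor(data[[stage]])))
  if (!is.null(covariate)) d$covariate <- data[[covariate]]
  rhs <- if (is.null(covariate)) "stage" else "stage + covariate"
  fit <- stats::glm(stats::reformulate(rhs, "y"), data = d, family = stats::poisson())
  tests <- list()
  m_nostage <- stats::glm(stats::reformulate(if (is.null(covariate)) "1" else "covariate", "y"),
                          data = d, family = stats::poisson())
  dev_stage <- stats::deviance(m_nostage) - stats::deviance(fit)
  df_stage <- m_nostage$df.residual - fit$df.residual
  tests[[1]] <- data.frame(term = "stage", deviance = dev_stage, df = df_stage,
                           p = stats::pchisq(dev_stage, df_stage, lower.tail = FALSE))
  if (!is.null(covariate)) {
    m_nocov <- stats::glm(y ~ stage, data = d, family = stats::poisson())
    dev_cov <- stats::deviance(m_nocov) - stats::deviance(fit)
    tests[[2]] <- data.frame(term = "covariate", deviance = dev_cov, df = 1,
                             p = stats::pchisq(dev_cov, 1, lower.tail = FALSE))
  }
  model_result("poisson", count, do.call(rbind, tests), fit,
               extra = list(deviance = stats::deviance(fit), data = d))
}

#' Behavior on a physiological covariate, controlling for stage
#'
#' Analysis of covariance: behavior regressed on a hormone or expression
#' covariate plus stage. The covariate-by-stage interaction is tested first
#' and dropped when not significant. The covariate and stage F statistics
#' (type II) are reported together with the covariate's partial R-squared.
#'
#' @param data data frame.
#' @param response behavior column name.
#' @param covariate hormone or net-OD column name.
#' @param stage stage factor column.
#' @param transform response transform (`"none"`, `"sqrt"`, `"log"`).
#' @param alpha_interaction threshold for keeping the interaction.
#' @return a `model_result` with family `"ancova"`, `tests` rows for
#'   `covariate` and `stage` (`F`, `df1`, `df2`, `p`), `partial_r2`,
#'   `interaction_kept`.
#' @export
ancova_behavior <- function(data, response, covariate, stage = "stage",
                            transform = "none", alpha_interaction = 0.05) {
  d <- data.frame(y = apply_transform(data[[response]], transform),
                  x = data[[covariate]],
                  stage = droplevels(factor(data[[stage]])))
  if (any(!is.finite(d$x))) ss_stop("invalid_argument", "covariate must be finite")
  within_var <- tapply(d$x, d$stage, stats::var)
  if (all(within_var < .Machine$double.eps)) {
    ss_warn("collinear", "covariate is constant within stages; it is confounded with stage")
  }
  m_add <- stats::lm(y ~ x + stage, data = d)
  m_int <- stats::lm(y ~ x * stage, data = d)
  a_int <- stats::anova(m_add, m_int)
  keep_int <- !is.na(a_int$`Pr(>F)`[2]) && a_int$`Pr(>F)`[2] < alpha_interaction
  fit <- if (keep_int) m_int else m_add
  a2 <- car::Anova(fit, type = 2)
  rn <- rownames(a2)
  df_res <- a2$Df[rn == "Residuals"]
  row_of <- function(label, term) {
    i <- which(rn == term)
    data.frame(term = label, statistic = a2$`F value`[i], df1 = a2$Df[i],
               df2 = df_res, p = a2$`Pr(>F)`[i])
  }
  tests <- rbind(row_of("covariate", "x"), row_of("stage", "stage"))
  if (keep_int) tests <- rbind(tests, row_of("covariate:stage", "x:stage"))
  ss_cov <- a2$`Sum Sq`[rn == "x"]
  ss_res <- a2$`Sum Sq`[rn == "Residuals"]
  model_result("ancova", response, tests, fit, transform,
               list(partial_r2 = ss_cov / (ss_cov + ss_res),
                    interaction_kept = keep_int, adj_r2 = summary(fit)$adj.r.squared,
                    data = d))
}
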