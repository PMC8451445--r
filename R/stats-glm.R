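## GLM likelihood-ratio tests for the diversity and coverage responses.
## For the Poisson family the test statistic is the deviance difference,
## which equals 2 * sum(y * log(mu_full / mu_null)) with the 0 * log 0 := 0
## convention -- exact even when a group has all-zero counts, with no
## pseudo-count offset.

#' GLM fit with a likelihood-ratio test of the grouping factor
#'
#' Fits `y ~ group (+ covariate)` and the nested null model without the
#' group term, and compares them with a likelihood-ratio chi-square test
#' (the statistic is referred to the upper tail of the chi-square
#' distribution with `df = nlevels(group) - 1`).
#'
#' @param y response vector (counts for `poisson`, numeric for `gaussian`).
#' @param group factor (or coercible) whose effect is tested.
#' @param covariate optional numeric covariate kept in both models.
#' @param family `"poisson"` (log link) or `"gaussian"`.
#' @param link link function; defaults to the family's canonical link
#'   (`"log"` for Poisson, `"identity"` for Gaussian; `"log"` is also
#'   accepted for Gaussian, e.g. for damage-versus-coverage regressions).
#' @return object of class `bv_glm_lrt`: list with `chi2`, `df`, `p_value`,
#'   `coefficients`, and the full/null `glm` fits.
#' @export
#' @examples
#' glm_lrt(c(2, 2, 8, 8), rep(c("a", "b"), each = 2), family = "poisson")
glm_lrt <- function(y, group, covariate = NULL,
                    family = c("poisson", "gaussian"), link = NULL) {
  family <- match.arg(family)
  group <- as.factor(group)
  fam <- switch(family,
    poisson = poisson(link = if (is.null(link)) "log" else link),
    gaussian = gaussian(link = if (is.null(link)) "identity" else link))

  dat <- data.frame(y = y, group = group)
  if (!is.null(covariate)) {
    dat$covariate <- covariate
    full <- glm(y ~ group + covariate, data = dat, family = fam,
                control = list(maxit = 100))
    null <- glm(y ~ covariate, data = dat, family = fam,
                control = list(maxit = 100))
  } else {
    full <- glm(y ~ group, data = dat, family = fam,
                control = list(maxit = 100))
    null <- glm(y ~ 1, data = dat, family = fam,
                control = list(maxit = 100))
  }
  if (!full$converged || !null$converged) {
    stop("glm_lrt: IRLS did not converge within 100 iterations")
  }
  chi2 <- if (family == "poisson") {
    ## deviance difference == 2 * (ll_full - ll_null), robust to zero groups
    null$deviance - full$deviance
  } else {
    2 * (as.numeric(logLik(full)) - as.numeric(logLik(null)))
  }
  chi2 <- max(chi2, 0)
  df <- null$df.residual - full$df.residual
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 coefficients = stats::coef(full), family = family,
                 full = full, null = null),
            class = "bv_glm_lrt")
}

#' @export
print.bv_glm_lrt <- function(x, ...) {
  cat(sprintf("GLM LRT (%s): chi2 = %.4f, df = %d, p = %.4g\n",
              x$family, x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Poisson GLMM with a site random intercept (fidelity mode)
#'
#' Optional Laplace-approximated mixed model for plot-level responses,
#' `y ~ group + (1 | site)`, matching the study design where plots are
#' nested in sites.  Requires the `lme4` package.  With zero between-site
#' variance the fit shrinks to the fixed-effect GLM.
#'
#' @param y plot-level counts.
#' @param group establishment-class factor (one value per plot).
#' @param site site factor (random intercept).
#' @return list of class `bv_glmm` with `chi2`, `df`, `p_value`,
#'   `site_variance` and the `lme4` fits.
#' @export
glmm_poisson <- function(y, group, site) {
  if (!requireNamespace("lme4", quietly = TRUE)) {
    stop("glmm_poisson requires the lme4 package")
  }
  dat <- data.frame(y = y, group = as.factor(group), site = as.factor(site))
  if (nlevels(dat$site) < 2L) stop("glmm_poisson: need at least 2 sites")
  full <- lme4::glmer(y ~ group + (1 | site), data = dat, family = poisson)
  null <- lme4::glmer(y ~ 1 + (1 | site), data = dat, family = poisson)
  chi2 <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(null))))
  df <- nlevels(dat$group) - 1L
  vc <- as.data.frame(lme4::VarCorr(full))
  structure(list(chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE),
                 site_variance = vc$vcov[1L], full = full, null = null),
            class = "bv_glmm")
}

#' @export
print.bv_glmm <- function(x, ...) {
  cat(sprintf("Poisson GLMM LRT: chi2 = %.4f, df = %d, p = %.4g (site var %.4f)\n",
              x$chi2, x$df, x$p_value, x$site_variance))
  invisible(x)
}
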