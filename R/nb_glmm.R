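#' Negative-binomial mixed model for count responses
#'
#' Fits a log-link negative-binomial regression of a count response on a
#' single covariate with a Gaussian random intercept per group, maximizing
#' the Laplace-approximated marginal likelihood (via glmmTMB, NB2
#' parameterization: `Var(y) = mu + mu^2 / theta`). With fewer than two
#' groups the model reduces to a plain negative-binomial GLM; a constant (or
#' absent) covariate drops the slope and fits an intercept-only model.
#'
#' @param counts Nonnegative integer response.
#' @param covariate Numeric fixed-effect covariate (e.g. induced condensed
#'   tannin concentration, mg/g DW), or `NULL` for an intercept-only model.
#' @param group Grouping factor for the random intercept (e.g. host
#'   genotype), or `NULL`.
#' @return Object of class `nb_glmm`: fixed-effect table (`coefficients`:
#'   estimate, SE, z, p), `theta` (NB dispersion), `sigma2_group`
#'   (random-intercept variance), `n_obs`, `n_groups`, `logLik`,
#'   `converged`, and the underlying `model` fit.
#' @export
fit_nb_glmm <- function(counts, covariate = NULL, group = NULL) {
  if (any(counts < 0) || any(counts != round(counts)) || anyNA(counts))
    stop("counts must be nonnegative integers")
  n <- length(counts)
  d <- data.frame(y = as.numeric(counts))
  has_cov <- !is.null(covariate) && length(unique(covariate)) > 1L
  if (!is.null(covariate)) {
    stopifnot(length(covariate) == n)
    d$x <- as.numeric(covariate)
    if (!has_cov)
      message("covariate is constant; fitting intercept-only model")
  }
  has_re <- !is.null(group) && nlevels(factor(group)) >= 2L
  if (has_re) d$g <- factor(group)

  rhs <- if (has_cov) "x" else "1"
  if (has_re) {
    form <- stats::as.formula(paste("y ~", rhs, "+ (1 | g)"))
    fit <- glmmTMB::glmmTMB(form, data = d, family = glmmTMB::nbinom2())
    sm <- summary(fit)
    ctab <- sm$coefficients$cond
    theta <- stats::sigma(fit)
    vc <- glmmTMB::VarCorr(fit)$cond
    sigma2 <- as.numeric(vc$g[1L, 1L])
    conv <- isTRUE(fit$fit$convergence == 0) && isTRUE(fit$sdr$pdHess)
    ll <- as.numeric(stats::logLik(fit))
    n_groups <- nlevels(d$g)
  } else {
    form <- stats::as.formula(paste("y ~", rhs))
    fit <- MASS::glm.nb(form, data = d)
    ctab <- summary(fit)$coefficients
    theta <- fit$theta
    sigma2 <- 0
    conv <- fit$converged
    ll <- as.numeric(stats::logLik(fit))
    n_groups <- if (is.null(group)) 0L else 1L
  }
  colnames(ctab) <- c("estimate", "se", "z", "p.value")
  rn <- rownames(ctab)
  rn[rn == "(Intercept)"] <- "intercept"
  rn[rn == "x"] <- "covariate"
  rownames(ctab) <- rn
  if (!conv)
    warning("NB-GLMM did not converge cleanly; inspect $model diagnostics")
  structure(list(coefficients = ctab, theta = theta, sigma2_group = sigma2,
                 n_obs = n, n_groups = n_groups, logLik = ll,
                 converged = conv, model = fit),
            class = "nb_glmm")
}

#' @export
print.nb_glmm <- function(x, ...) {
  cat(sprintf("Negative-binomial %s (n = %d%s)\n",
              if (x$n_groups >= 2L) "GLMM (log link, random intercept)"
              else "GLM (log link)",
              x$n_obs,
              if (x$n_groups >= 2L) sprintf(", groups = %d", x$n_groups)
              else ""))
  stats::printCoefmat(x$coefficients, digits = 4, cs.ind = 1:2, tst.ind = 3,
               P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("dispersion theta = %.3f; random-intercept variance = %.3f; logLik = %.2f\n",
              x$theta, x$sigma2_group, x$logLik))
  if (!x$converged) cat("WARNING: fit flagged as non-converged\n")
  invisible(x)
}

#' @export
coef.nb_glmm <- function(object, ...) object$coefficients[, "estimate"]

#' @export
confint.nb_glmm <- function(object, parm, level = 0.95, ...) {
  ct <- object$coefficients
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- cbind(lower = ct[, "estimate"] - z * ct[, "se"],
              upper = ct[, "estimate"] + z * ct[, "se"])
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' Pearson residual overdispersion check
#'
#' Computes the Pearson chi-square statistic of a fitted count model,
#' `sum((y - mu)^2 / Var(y))` with the fitted NB variance, its ratio to the
#' residual degrees of freedom (`n_obs` minus the number of estimated
#' parameters), and an upper-tail chi-square p-value. A ratio near 1 (large
#' p) indicates the count model's variance assumption is adequate.
#'
#' @param fit An `nb_glmm` fit, or any `glm` object (e.g. a Poisson fit, for
#'   which the check exposes variance misspecification).
#' @return List of class `overdispersion_report` with `pearson_chi_sq`,
#'   `residual_df`, `ratio`, `p.value`.
#' @export
check_overdispersion <- function(fit) {
  if (inherits(fit, "nb_glmm")) {
    r <- stats::residuals(fit$model, type = "pearson")
    chisq <- sum(r^2)
    n_par <- nrow(fit$coefficients) + 1L + (fit$n_groups >= 2L)
    df <- fit$n_obs - n_par
  } else if (inherits(fit, "glm")) {
    r <- stats::residuals(fit, type = "pearson")
    chisq <- sum(r^2)
    df <- stats::df.residual(fit)
  } else stop("fit must be an nb_glmm or glm object")
  structure(list(pearson_chi_sq = chisq, residual_df = df,
                 ratio = chisq / df,
                 p.value = stats::pchisq(chisq, df, lower.tail = FALSE)),
            class = "overdispersion_report")
}

#' @export
print.overdispersion_report <- function(x, ...) {
  cat(sprintf("Overdispersion check: Pearson chi-sq = %.2f on %d df (ratio %.3f), p = %.3f\n",
              x$pearson_chi_sq, x$residual_df, x$ratio, x$p.value))
  cat(if (x$p.value < 0.05) "  overdispersion detected\n"
      else "  no overdispersion detected\n")
  invisible(x)
}
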