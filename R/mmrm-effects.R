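# Contrast vector for the adjusted (LS) mean of one arm at one visit,
# with the baseline covariate at the all-arms grand mean (i.e. the
# centered baseline columns at zero).
lsmean_contrast <- function(fit, arm, visit) {
  d <- fit$design
  if (!visit %in% d$visits) stopf("visit '%s' not in the model", visit)
  if (!arm %in% d$arms) stopf("arm '%s' not in the model", arm)
  cvec <- stats::setNames(numeric(length(fit$beta)), names(fit$beta))
  cvec[paste0("visit.", visit)] <- 1
  if (arm != d$placebo_arm) cvec[paste0(arm, ":", visit)] <- 1
  cvec
}

#' Least-squares (adjusted) means by arm at a visit
#'
#' Model-predicted mean change from baseline per arm, with the baseline
#' covariate held at the grand mean over all analyzed subjects; standard
#' errors from the fixed-effect variance matrix.
#'
#' @param fit a [mmrm_fit()] result.
#' @param visit visit label (default: last modeled visit).
#' @return data.frame: `arm`, `visit`, `lsmean`, `se`.
#' @export
ls_means <- function(fit, visit = NULL) {
  visit <- visit %||% fit$design$visits[length(fit$design$visits)]
  rows <- lapply(fit$design$arms, function(a) {
    cv <- lsmean_contrast(fit, a, visit)
    data.frame(arm = a, visit = visit,
               lsmean = sum(cv * fit$beta),
               se = sqrt(drop(cv %*% fit$vcov_beta %*% cv)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Satterthwaite denominator df for the contrast c'beta:
# df = 2 g^2 / (grad_g' Vtheta grad_g), g(theta) = c' B(theta)^-1 c,
# Vtheta = 2 H^-1 with H the Hessian of the -2 REML log-likelihood.
satterthwaite_df <- function(fit, cvec) {
  core <- fit$objective$core
  th <- fit$theta
  g_of <- function(t) {
    res <- core(t, want_fit = TRUE)
    if (isTRUE(res$bad)) return(NA_real_)
    drop(cvec %*% res$Binv %*% cvec)
  }
  q <- length(th)
  h <- 1e-4
  grad_g <- vapply(seq_len(q), function(k) {
    e <- numeric(q); e[k] <- h
    (g_of(th + e) - g_of(th - e)) / (2 * h)
  }, numeric(1))
  H <- tryCatch(
    stats::optimHess(th, function(t) core(t)$value,
                     function(t) {
                       r <- core(t, want_grad = TRUE)
                       if (isTRUE(r$bad)) rep(0, q) else r$grad
                     }),
    error = function(e) NULL)
  g <- drop(cvec %*% fit$vcov_beta %*% cvec)
  if (is.null(H) || any(!is.finite(grad_g))) return(resid_df(fit))
  Vt <- tryCatch(2 * solve(H), error = function(e) NULL)
  if (is.null(Vt)) return(resid_df(fit))
  den <- drop(grad_g %*% Vt %*% grad_g)
  if (!is.finite(den) || den <= 0) return(resid_df(fit))
  df <- 2 * g^2 / den
  # guard against degenerate curvature estimates
  if (!is.finite(df) || df < 1) resid_df(fit) else df
}

resid_df <- function(fit) fit$n_obs_used - length(fit$beta)

#' Drug-placebo treatment effect, p-value and effect size
#'
#' The treatment effect (TE) is the LS-mean difference, active minus
#' placebo, of the change from baseline at the analysis visit. The
#' two-sided p-value uses a t reference with Satterthwaite (default) or
#' residual degrees of freedom. The effect size is |TE| divided by the
#' pooled SD reconstructed from the contrast's standard error:
#' `pooled_sd = se / sqrt(1/n1 + 1/n2)`.
#'
#' @param fit a [mmrm_fit()] result.
#' @param active active arm label.
#' @param placebo comparator arm (default: the placebo arm).
#' @param visit analysis visit (default: last modeled).
#' @param alpha significance level carried into the report.
#' @return A `treatment_effect` list: `comparison`, `visit`, `te`, `se`,
#'   `df`, `p`, `effect_size`, `n_active`, `n_placebo`, `significant`.
#' @export
treatment_effect <- function(fit, active, placebo = NULL, visit = NULL,
                             alpha = fit$spec$alpha) {
  d <- fit$design
  placebo <- placebo %||% d$placebo_arm
  visit <- visit %||% d$visits[length(d$visits)]
  cvec <- lsmean_contrast(fit, active, visit) -
    lsmean_contrast(fit, placebo, visit)
  te <- sum(cvec * fit$beta)
  se <- sqrt(max(drop(cvec %*% fit$vcov_beta %*% cvec), 0))
  n1 <- sum(d$arm == active); n2 <- sum(d$arm == placebo)
  if (all(cvec == 0)) {  # an arm contrasted with itself
    out <- list(comparison = paste0(active, "_vs_", placebo), visit = visit,
                te = 0, se = 0, df = NA_real_, p = 1, effect_size = 0,
                n_active = n1, n_placebo = n2, significant = FALSE)
    class(out) <- "treatment_effect"
    return(out)
  }
  df <- if (fit$spec$df_method == "satterthwaite") satterthwaite_df(fit, cvec)
  else resid_df(fit)
  p <- 2 * stats::pt(-abs(te / se), df)
  out <- list(comparison = paste0(active, "_vs_", placebo), visit = visit,
              te = te, se = se, df = df, p = p,
              effect_size = effect_size(te, se, n1, n2),
              n_active = n1, n_placebo = n2, significant = p < alpha)
  class(out) <- "treatment_effect"
  out
}

#' @export
print.treatment_effect <- function(x, ...) {
  cat(sprintf("%s at %s: TE %.3f (SE %.3f, df %.1f), p %s, effect size %.3f\n",
              x$comparison, x$visit, x$te, x$se, x$df %||% NA,
              format.pval(x$p, digits = 3), x$effect_size))
  invisible(x)
}

#' @export
as.data.frame.treatment_effect <- function(x, ...) {
  data.frame(comparison = x$comparison, visit = x$visit, te = x$te,
             se = x$se, df = x$df, p = x$p, effect_size = x$effect_size,
             n_active = x$n_active, n_placebo = x$n_placebo,
             stringsAsFactors = FALSE)
}

#' Standardized effect size from an LS-mean difference
#'
#' The pooled SD is the standard error of the LS-mean difference divided
#' by the square root of the sum of inverse group sample sizes; the
#' effect size is the absolute LS-mean difference over that pooled SD.
#'
#' @param te LS-mean difference.
#' @param se its standard error (> 0).
#' @param n1,n2 group sample sizes (>= 1).
#' @return Nonnegative effect size.
#' @export
effect_size <- function(te, se, n1, n2) {
  if (se <= 0) stopf("standard error must be positive")
  if (n1 < 1 || n2 < 1) stopf("group sizes must be >= 1")
  pooled_sd <- se / sqrt(1 / n1 + 1 / n2)
  abs(te) / pooled_sd
}
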