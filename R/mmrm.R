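#' Specification of the repeated-measures analysis model
#'
#' The analysis model for the change from baseline of the total score:
#' visit as a classification variable (cell-mean visit intercepts),
#' treatment-by-visit interaction with the placebo arm as reference,
#' centered baseline total and baseline-by-visit interaction as
#' covariates, and an unstructured T x T within-subject covariance
#' estimated by REML. Per-subject analysis weights divide the residual
#' covariance (the weighted-regression convention), so a common weight for
#' every subject reproduces the unweighted analysis exactly.
#'
#' @param visits post-baseline visit labels to model (default: all
#'   scheduled).
#' @param alpha two-sided significance level for treatment contrasts.
#' @param df_method `"satterthwaite"` (default) or `"residual"`
#'   (N_obs - rank(X)).
#' @param baseline_covariate include the centered baseline total and its
#'   interaction with visit (default TRUE).
#' @return An `mmrm_spec` list.
#' @export
mmrm_spec <- function(visits = NULL, alpha = 0.05,
                      df_method = c("satterthwaite", "residual"),
                      baseline_covariate = TRUE) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  structure(list(visits = visits, alpha = alpha,
                 df_method = match.arg(df_method),
                 baseline_covariate = isTRUE(baseline_covariate)),
            class = "mmrm_spec")
}

#' Build the response vector and fixed-effects design for the MMRM
#'
#' One row per observed subject x visit, ordered by subject then visit.
#' Full-rank coding: a per-visit intercept, an indicator per active arm x
#' visit (placebo reference within each visit), the grand-mean-centered
#' baseline, and baseline x visit for visits after the first. Subjects
#' with no post-baseline observation are dropped and counted; visits
#' observed for no subject are dropped from T with a warning.
#'
#' @param dataset a [trial_dataset()].
#' @param spec an [mmrm_spec()].
#' @return An `mmrm_design` list (response `y`, design `X`, per-row
#'   subject/visit indices, per-subject metadata).
#' @export
build_design <- function(dataset, spec = mmrm_spec()) {
  cl <- changes_long(dataset)
  visits <- spec$visits %||% dataset$visits$visit
  cl <- cl[cl$visit %in% visits, ]
  if (nrow(cl) == 0) stopf("no post-baseline observations to model")
  empty <- setdiff(visits, unique(cl$visit))
  if (length(empty)) {
    warnf("visit(s) observed for no subject dropped: %s",
          paste(empty, collapse = ", "))
    visits <- setdiff(visits, empty)
  }
  subj_ids <- unique(dataset$subjects$subject_id)
  used <- subj_ids[subj_ids %in% cl$subject_id]
  n_dropped <- length(subj_ids) - length(used)
  cl <- cl[order(match(cl$subject_id, used), match(cl$visit, visits)), ]

  arm_of <- stats::setNames(dataset$subjects$arm, dataset$subjects$subject_id)
  bl_of <- stats::setNames(as.numeric(dataset$subjects$baseline_total),
                           dataset$subjects$subject_id)
  arms <- dataset$arms[dataset$arms %in% arm_of[used]]
  active <- setdiff(arms, dataset$placebo_arm)
  bl_center <- mean(bl_of[used])

  T_ <- length(visits)
  vrow <- match(cl$visit, visits)
  srow <- match(cl$subject_id, used)
  N <- nrow(cl)

  cols <- list()
  for (v in seq_len(T_)) {
    x <- as.numeric(vrow == v)
    cols[[paste0("visit.", visits[v])]] <- x
  }
  for (a in active) for (v in seq_len(T_))
    cols[[paste0(a, ":", visits[v])]] <-
      as.numeric(cl$arm == a & vrow == v)
  if (spec$baseline_covariate) {
    blc <- cl$baseline - bl_center
    cols[["bl"]] <- blc
    if (T_ > 1) for (v in 2:T_)
      cols[[paste0("bl:", visits[v])]] <- blc * (vrow == v)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)

  structure(list(
    y = cl$change, X = X, subj = srow, visit_idx = vrow,
    subject_id = used, arm = unname(arm_of[used]),
    baseline = unname(bl_of[used]), visits = visits, arms = arms,
    placebo_arm = dataset$placebo_arm, active_arms = active,
    baseline_center = bl_center, n_dropped = n_dropped, n_obs = N
  ), class = "mmrm_design")
}

# --- log-Cholesky machinery -------------------------------------------------

lchol_index <- function(T_) {
  ij <- which(lower.tri(diag(T_), diag = TRUE), arr.ind = TRUE)
  ij <- ij[order(ij[, 2], ij[, 1]), , drop = FALSE]  # column-major
  list(ij = ij, diag = which(ij[, 1] == ij[, 2]), q = nrow(ij))
}

theta_to_L <- function(theta, T_, idx) {
  L <- matrix(0, T_, T_)
  L[idx$ij] <- theta
  diag(L) <- exp(diag(L))
  L
}

sigma_to_theta <- function(Sigma, idx) {
  L <- t(chol(Sigma))
  th <- L[idx$ij]
  th[idx$diag] <- log(diag(L))
  th
}

# Precompute per-missingness-pattern stacked blocks. Rows of X/y must be
# subject-major with visits in schedule order (build_design guarantees it).
mmrm_patterns <- function(design, w) {
  n <- length(design$subject_id)
  sf <- factor(design$subj, levels = seq_len(n))
  vis_by_subj <- split(design$visit_idx, sf)
  key <- vapply(vis_by_subj, paste, character(1), collapse = ",")
  pat <- split(seq_len(n), key)
  lapply(pat, function(subjects) {
    subjects <- sort(subjects)
    obs <- vis_by_subj[[subjects[1]]]
    rows <- which(design$subj %in% subjects)  # subject-major by construction
    t_p <- length(obs)
    swr <- rep(sqrt(w[subjects]), each = t_p)
    list(subjects = subjects, obs = obs, t = t_p, n = length(subjects),
         Xw = design$X[rows, , drop = FALSE] * swr,
         yw = design$y[rows] * swr,
         sumtlogw = sum(t_p * log(w[subjects])))
  })
}

# multiply each t x . subject block of a stacked matrix by S (t x t)
blockmult <- function(S, M, t_p) {
  matrix(S %*% matrix(M, nrow = t_p), nrow = nrow(M))
}

# -2 REML log-likelihood (with constants) and its analytic gradient in the
# log-Cholesky parameters. Returns a closure pair sharing pattern blocks.
mmrm_objective <- function(design, w) {
  T_ <- length(design$visits)
  idx <- lchol_index(T_)
  p <- ncol(design$X)
  pats <- mmrm_patterns(design, w)
  N <- design$n_obs
  wconst <- sum(vapply(pats, `[[`, numeric(1), "sumtlogw"))

  core <- function(theta, want_grad = FALSE, want_fit = FALSE) {
    L <- theta_to_L(theta, T_, idx)
    Sigma <- tcrossprod(L)
    B <- matrix(0, p, p); XVy <- numeric(p); yVy <- 0; logdet <- -wconst
    work <- vector("list", length(pats))
    for (k in seq_along(pats)) {
      pt <- pats[[k]]
      Sg <- Sigma[pt$obs, pt$obs, drop = FALSE]
      ch <- tryCatch(chol(Sg), error = function(e) NULL)
      if (is.null(ch)) return(list(value = 1e10, bad = TRUE))
      S <- chol2inv(ch)
      logdet <- logdet + 2 * pt$n * sum(log(diag(ch)))
      SXw <- blockmult(S, pt$Xw, pt$t)
      Syw <- as.vector(blockmult(S, matrix(pt$yw), pt$t))
      B <- B + crossprod(pt$Xw, SXw)
      XVy <- XVy + crossprod(SXw, pt$yw)
      yVy <- yVy + sum(pt$yw * Syw)
      if (want_grad || want_fit)
        work[[k]] <- list(S = S, SXw = SXw, Syw = Syw)
    }
    Bch <- tryCatch(chol(B), error = function(e) NULL)
    if (is.null(Bch)) return(list(value = 1e10, bad = TRUE))
    beta <- backsolve(Bch, forwardsolve(t(Bch), XVy))
    quad <- yVy - sum(beta * XVy)
    val <- logdet + 2 * sum(log(diag(Bch))) + quad + (N - p) * log(2 * pi)
    out <- list(value = as.numeric(val), beta = as.vector(beta),
                Sigma = Sigma, L = L)
    if (want_fit) out$Binv <- chol2inv(Bch)
    if (want_grad) {
      Binv <- out$Binv %||% chol2inv(Bch)
      grad <- numeric(idx$q)
      # residual blocks v_i = S r_i sqrt(w_i), from Syw - SXw beta
      for (k in seq_along(pats)) {
        pt <- pats[[k]]; wk <- work[[k]]
        wk$Srw <- wk$Syw - as.vector(wk$SXw %*% beta)
        work[[k]] <- wk
      }
      for (g in seq_len(idx$q)) {
        i <- idx$ij[g, 1]; j <- idx$ij[g, 2]
        E <- matrix(0, T_, T_)
        E[i, j] <- if (i == j) L[i, i] else 1
        dS_full <- tcrossprod(E, L)
        dS_full <- dS_full + t(dS_full)
        acc <- 0
        for (k in seq_along(pats)) {
          pt <- pats[[k]]; wk <- work[[k]]
          dS <- dS_full[pt$obs, pt$obs, drop = FALSE]
          if (all(dS == 0)) next
          # tr(V^-1 dV) summed over subjects in the pattern
          acc <- acc + pt$n * sum(wk$S * dS)
          # -tr(B^-1 sum_i w U' dS U)
          dU <- blockmult(dS, wk$SXw, pt$t)
          acc <- acc - sum(Binv * crossprod(wk$SXw, dU))
          # -sum_i w r' S dS S r
          dv <- as.vector(blockmult(dS, matrix(wk$Srw), pt$t))
          acc <- acc - sum(wk$Srw * dv)
        }
        grad[g] <- acc
      }
      out$grad <- grad
    }
    out
  }
  list(core = core, idx = idx, T_ = T_, p = p)
}

#' Fit the weighted mixed model for repeated measures by REML
#'
#' Maximizes the REML log-likelihood of the model in [mmrm_spec()] with
#' subject-level covariance `V_i = Sigma[obs(i), obs(i)] / w_i`. The
#' unstructured `Sigma` is parameterized by its log-Cholesky factor
#' (positive definite at every iterate) and optimized by BFGS with
#' analytic gradients, started from the diagonal of per-visit OLS
#' residual variances.
#'
#' @param design an [build_design()] result, or a [trial_dataset()]
#'   (the design is then built with `spec`).
#' @param weights per-subject positive weights: a named vector (by
#'   subject id), an unnamed vector in design subject order, a
#'   `propensity_table`, or `NULL` for the unweighted analysis.
#' @param spec an [mmrm_spec()] (used both for design building and for
#'   contrast defaults).
#' @return An object of class `pwmmrm_fit`.
#' @export
mmrm_fit <- function(design, weights = NULL, spec = mmrm_spec()) {
  if (inherits(design, "trial_dataset")) design <- build_design(design, spec)
  n <- length(design$subject_id)
  w <- resolve_weights(weights, design$subject_id)
  if (any(!is.finite(w) | w <= 0)) stopf("weights must be positive and finite")
  if (design$n_obs <= ncol(design$X))
    stopf("fewer observations (%d) than fixed-effect columns (%d)",
          design$n_obs, ncol(design$X))

  # Normalize weights by their geometric mean: the GLS solution and all
  # inference are invariant to a common weight scale, and normalizing makes
  # that invariance exact in floating point. Sigma is rescaled on output so
  # that V_i = Sigma / w_i holds in the caller's weight units.
  gmw <- exp(mean(log(w)))
  # rounding to 12 significant digits canonicalizes the normalized weights,
  # so any common rescaling of the input weights is a bit-exact no-op
  wn <- signif(w / gmw, 12)
  obj <- mmrm_objective(design, wn)
  T_ <- obj$T_
  # start: per-visit residual variances around an OLS fit
  b0 <- qr.coef(qr(design$X), design$y)
  b0[is.na(b0)] <- 0
  r0 <- design$y - as.vector(design$X %*% b0)
  v0 <- vapply(seq_len(T_), function(v) {
    rv <- r0[design$visit_idx == v]
    vv <- if (length(rv) > 1) stats::var(rv) else NA_real_
    if (!is.finite(vv) || vv < 1e-4) 1 else vv
  }, numeric(1))
  theta0 <- sigma_to_theta(diag(v0, T_), obj$idx)

  fn <- function(th) obj$core(th)$value
  gr <- function(th) {
    res <- obj$core(th, want_grad = TRUE)
    if (isTRUE(res$bad)) return(rep(0, length(th)))
    res$grad
  }
  opt <- stats::optim(theta0, fn, gr, method = "BFGS",
                      control = list(maxit = 300, reltol = 1e-13))
  final <- obj$core(opt$par, want_grad = TRUE, want_fit = TRUE)
  if (isTRUE(final$bad))
    stopf("covariance estimate singular at the optimum")
  gnorm <- sqrt(sum(final$grad^2))
  converged <- opt$convergence == 0 || gnorm < 1e-4

  Sigma <- final$Sigma * gmw  # back to the caller's weight units
  dimnames(Sigma) <- list(design$visits, design$visits)
  vcov_beta <- final$Binv
  dimnames(vcov_beta) <- list(colnames(design$X), colnames(design$X))
  structure(list(
    beta = stats::setNames(final$beta, colnames(design$X)),
    vcov_beta = vcov_beta, Sigma = Sigma,
    reml_loglik = -final$value / 2, neg2_reml = final$value,
    converged = converged, grad_norm = gnorm,
    theta = opt$par, objective = obj, design = design, weights = w,
    spec = spec, n_subjects_used = n, n_obs_used = design$n_obs,
    n_dropped = design$n_dropped
  ), class = "pwmmrm_fit")
}

resolve_weights <- function(weights, subject_id) {
  n <- length(subject_id)
  if (is.null(weights)) return(rep(1, n))
  if (inherits(weights, "propensity_table") ||
      (is.data.frame(weights) && all(c("subject_id", "weight") %in% names(weights))))
    weights <- stats::setNames(weights$weight, weights$subject_id)
  if (!is.null(names(weights))) {
    if (!all(subject_id %in% names(weights)))
      stopf("weights missing for subject(s): %s",
            paste(utils::head(setdiff(subject_id, names(weights)), 3),
                  collapse = ", "))
    return(unname(weights[subject_id]))
  }
  if (length(weights) != n)
    stopf("unnamed weights must have one entry per analyzed subject (%d)", n)
  as.numeric(weights)
}

#' @export
print.pwmmrm_fit <- function(x, ...) {
  cat(sprintf("Weighted MMRM fit (REML): %d subjects, %d observations, %d visits\n",
              x$n_subjects_used, x$n_obs_used, length(x$design$visits)))
  cat(sprintf("  REML log-likelihood: %.4f%s\n", x$reml_loglik,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat("  arms:", paste(x$design$arms, collapse = ", "),
      sprintf("(placebo: %s)\n", x$design$placebo_arm))
  invisible(x)
}

#' @export
coef.pwmmrm_fit <- function(object, ...) object$beta

#' @export
vcov.pwmmrm_fit <- function(object, ...) object$vcov_beta

#' @export
logLik.pwmmrm_fit <- function(object, ...) {
  structure(object$reml_loglik, df = length(object$beta) +
              length(object$theta), class = "logLik")
}

#' @export
summary.pwmmrm_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov_beta))
  tab <- data.frame(estimate = object$beta, se = se,
                    z = object$beta / se)
  av <- object$design$visits[length(object$design$visits)]
  tes <- lapply(object$design$active_arms, function(a)
    treatment_effect(object, a, visit = av))
  out <- list(coefficients = tab, Sigma = object$Sigma,
              treatment_effects = do.call(rbind, lapply(tes, as.data.frame)),
              reml_loglik = object$reml_loglik, converged = object$converged)
  class(out) <- "summary.pwmmrm_fit"
  out
}

#' @export
print.summary.pwmmrm_fit <- function(x, ...) {
  cat("Fixed effects:\n")
  print(round(x$coefficients, 4))
  cat("\nUnstructured covariance (Sigma):\n")
  print(round(x$Sigma, 3))
  cat("\nTreatment effects at the analysis visit:\n")
  print(x$treatment_effects, row.names = FALSE)
  invisible(x)
}
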