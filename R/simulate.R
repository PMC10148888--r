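#' Configuration for the synthetic-trial generator
#'
#' Emulates a three-arm, 8-week, fixed-dose MDD trial in which a latent
#' per-subject propensity to respond to placebo drives both the
#' pre-randomization item drift and the post-randomization placebo
#' component of the response. Defaults follow the published trial's
#' census (156/154/149) and baseline HAMD-17 means/SDs; the propensity
#' distribution defaults to a right-heavy Beta with most mass above 0.8,
#' the pattern reported for the case study.
#'
#' @param arm_sizes named integer vector; one name must be `placebo_arm`.
#' @param placebo_arm placebo arm label.
#' @param visit_weeks post-baseline visit weeks, strictly increasing.
#' @param item_max per-item maxima (default HAMD-17).
#' @param baseline_mean,baseline_sd named per-arm baseline-total moments.
#' @param propensity_beta `c(a, b)` of the latent Beta propensity.
#' @param kappa item-drift signal strength: expected screening-to-baseline
#'   total drift is `-kappa * pi_i * screening_total`. `kappa = 0` removes
#'   all propensity signal from the pre-randomization items.
#' @param drift_noise_sd SD of the propensity-independent component of the
#'   total drift (points).
#' @param item_jitter expected number of one-point between-item transfers
#'   per subject (item-level noise that leaves the total unchanged).
#' @param placebo_asymptote maximal asymptotic fractional improvement of
#'   the placebo component (reached as `pi -> 1`).
#' @param placebo_tc exponential time constant of the placebo component,
#'   in weeks.
#' @param drug_effect named additive change (points, negative = improved)
#'   at the last visit per active arm; ramps linearly in time.
#' @param drug_attenuation in \[0,1\]: the drug component is scaled by
#'   `1 - drug_attenuation * pi_i` (response ceiling: subjects already
#'   responding non-specifically have less room for a specific effect).
#'   0 gives a purely additive drug effect.
#' @param resid_sd,resid_cor SD and exchangeable correlation of the
#'   compound-symmetric residual trajectory noise; `resid_Sigma` (a full
#'   T x T matrix) overrides both for matched-covariance studies.
#' @param resid_Sigma optional T x T residual covariance.
#' @param dropout_hazard per-visit probability of (monotone) dropout.
#' @param threshold fractional reduction defining response.
#' @return A `sim_config` list.
#' @export
sim_config <- function(arm_sizes = c(active_low = 156L, active_high = 154L,
                                     placebo = 149L),
                       placebo_arm = "placebo",
                       visit_weeks = c(1L, 2L, 3L, 4L, 6L, 8L),
                       item_max = hamd17_item_max(),
                       baseline_mean = c(active_low = 23.13,
                                         active_high = 23.51,
                                         placebo = 23.81),
                       baseline_sd = c(active_low = 2.89,
                                       active_high = 3.28, placebo = 3.23),
                       propensity_beta = c(5, 1.2),
                       kappa = 0.25, drift_noise_sd = 1.2,
                       item_jitter = 2,
                       placebo_asymptote = 0.7, placebo_tc = 3,
                       drug_effect = c(active_low = -5, active_high = -7),
                       drug_attenuation = 1,
                       resid_sd = 3.5, resid_cor = 0.55,
                       resid_Sigma = NULL,
                       dropout_hazard = 0.03, threshold = 0.41) {
  # align per-arm parameters with the declared arms: unnamed scalars are
  # recycled; arms missing from a named vector get the fallback
  arms <- names(arm_sizes)
  align <- function(x, fallback) {
    if (is.null(names(x))) return(stats::setNames(rep_len(x, length(arms)), arms))
    out <- stats::setNames(rep(fallback, length(arms)), arms)
    out[intersect(names(x), arms)] <- x[intersect(names(x), arms)]
    out
  }
  baseline_mean <- align(baseline_mean, 23.5)
  baseline_sd <- align(baseline_sd, 3.2)
  active <- setdiff(arms, placebo_arm)
  drug_effect <- align(drug_effect, 0)[active]
  cfg <- list(arm_sizes = arm_sizes, placebo_arm = placebo_arm,
              visit_weeks = visit_weeks, item_max = as.integer(item_max),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              propensity_beta = propensity_beta, kappa = kappa,
              drift_noise_sd = drift_noise_sd, item_jitter = item_jitter,
              placebo_asymptote = placebo_asymptote, placebo_tc = placebo_tc,
              drug_effect = drug_effect, drug_attenuation = drug_attenuation,
              resid_sd = resid_sd, resid_cor = resid_cor,
              resid_Sigma = resid_Sigma, dropout_hazard = dropout_hazard,
              threshold = threshold)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (any(cfg$arm_sizes < 1)) stopf("arm sizes must be >= 1")
  if (!cfg$placebo_arm %in% names(cfg$arm_sizes))
    stopf("placebo arm '%s' not among the arm sizes", cfg$placebo_arm)
  if (any(cfg$propensity_beta <= 0)) stopf("Beta parameters must be > 0")
  if (cfg$dropout_hazard < 0 || cfg$dropout_hazard >= 1)
    stopf("dropout hazard must be in [0,1)")
  if (any(diff(cfg$visit_weeks) <= 0) || any(cfg$visit_weeks <= 0))
    stopf("visit weeks must be positive and strictly increasing")
  maxtot <- sum(cfg$item_max)
  if (any(cfg$baseline_mean >= maxtot))
    stopf("baseline mean above the scale maximum (%d): infeasible", maxtot)
  active <- setdiff(names(cfg$arm_sizes), cfg$placebo_arm)
  if (!all(active %in% names(cfg$drug_effect) |
             length(cfg$drug_effect) == 0) && length(active))
    stopf("drug_effect must name every active arm")
  invisible(cfg)
}

# allocate `total` points over items with capacities item_max,
# probabilities proportional to capacity; repair any overflow
alloc_items <- function(total, item_max) {
  J <- length(item_max)
  total <- min(max(total, 0L), sum(item_max))
  x <- as.integer(stats::rmultinom(1, total, prob = item_max))
  over <- which(x > item_max)
  while (length(over)) {
    excess <- sum(x[over] - item_max[over])
    x[over] <- item_max[over]
    room <- which(x < item_max)
    for (k in seq_len(excess)) {
      pick <- room[sample.int(length(room), 1)]
      x[pick] <- x[pick] + 1L
      if (x[pick] == item_max[pick]) room <- setdiff(room, pick)
    }
    over <- which(x > item_max)
  }
  x
}

# remove `d` points from items, probability proportional to current score
remove_points <- function(x, d) {
  for (k in seq_len(d)) {
    tot <- sum(x)
    if (tot == 0L) break
    pick <- sample.int(length(x), 1, prob = x)
    x[pick] <- x[pick] - 1L
  }
  x
}

# move one point between random items (total preserved, bounds respected)
jitter_items <- function(x, item_max, m) {
  for (k in seq_len(m)) {
    from <- which(x > 0); to <- which(x < item_max)
    if (!length(from) || !length(to)) break
    i <- from[sample.int(length(from), 1)]
    j <- to[sample.int(length(to), 1)]
    if (i != j) { x[i] <- x[i] - 1L; x[j] <- x[j] + 1L }
  }
  x
}

#' Generate a synthetic randomized trial with latent placebo propensity
#'
#' Draws a latent propensity `pi_i ~ Beta(a, b)` per subject; builds
#' screening items to a normally-drawn target total; applies an integer
#' screening-to-baseline drift whose expectation is
#' `-kappa * pi_i * screening_total` (plus propensity-independent noise
#' and total-preserving item jitter), so the item-change vector is
#' informative about `pi_i`; then simulates post-baseline change
#' trajectories as a propensity-dependent exponential placebo component
#' plus a linearly-ramping drug component (attenuated by the response
#' ceiling `1 - drug_attenuation * pi`) plus correlated Gaussian noise,
#' rounded and clamped to valid totals, with monotone per-visit dropout.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed; identical config + seed gives an identical
#'   trial.
#' @return list(dataset = [trial_dataset()], truth = data.frame with
#'   `subject_id`, `arm`, `pi`, `true_label`, `drug_week_eos`; attribute
#'   `true_te` holds the specific (propensity-free) drug effect per
#'   active arm).
#' @export
generate_trial <- function(cfg = sim_config(), seed = 1L) {
  validate_sim_config(cfg)
  with_seed(seed, {
    arms <- names(cfg$arm_sizes)
    n <- sum(cfg$arm_sizes)
    arm <- rep(arms, times = cfg$arm_sizes)
    ids <- sprintf("S%04d", seq_len(n))
    a <- cfg$propensity_beta[1]; b <- cfg$propensity_beta[2]
    pi_i <- stats::rbeta(n, a, b)
    pi_i <- pmin(pmax(pi_i, 1e-6), 1 - 1e-6)
    e_pi <- a / (a + b)

    maxtot <- sum(cfg$item_max)
    mu_s <- cfg$baseline_mean[arm] / (1 - cfg$kappa * e_pi)
    s_tot <- pmin(pmax(round(stats::rnorm(n, mu_s, cfg$baseline_sd[arm])),
                       1L), maxtot)
    scr <- t(vapply(s_tot, alloc_items, integer(length(cfg$item_max)),
                    item_max = cfg$item_max))
    drift <- round(cfg$kappa * pi_i * s_tot +
                     stats::rnorm(n, 0, cfg$drift_noise_sd))
    bas <- scr
    njit <- stats::rpois(n, cfg$item_jitter)
    for (i in seq_len(n)) {
      x <- scr[i, ]
      d <- drift[i]
      if (d > 0) x <- remove_points(x, d)
      else if (d < 0) {  # worsening: add points where headroom remains
        for (k in seq_len(-d)) {
          room <- which(x < cfg$item_max)
          if (!length(room)) break
          pick <- room[sample.int(length(room), 1)]
          x[pick] <- x[pick] + 1L
        }
      }
      bas[i, ] <- jitter_items(x, cfg$item_max, njit[i])
    }
    b_tot <- rowSums(bas)

    # post-baseline change trajectories
    wk <- cfg$visit_weeks
    T_ <- length(wk)
    eos_wk <- wk[T_]
    f_i <- cfg$placebo_asymptote * pi_i
    placebo_comp <- outer(-f_i * b_tot, 1 - exp(-wk / cfg$placebo_tc))
    drug_full <- ifelse(arm == cfg$placebo_arm, 0,
                        cfg$drug_effect[arm])
    drug_full[is.na(drug_full)] <- 0
    drug_comp <- outer(drug_full * (1 - cfg$drug_attenuation * pi_i),
                       wk / eos_wk)
    Sig <- cfg$resid_Sigma %||%
      (cfg$resid_sd^2 * ((1 - cfg$resid_cor) * diag(T_) +
                           cfg$resid_cor * matrix(1, T_, T_)))
    Lr <- t(chol(Sig))
    noise <- t(Lr %*% matrix(stats::rnorm(n * T_), T_, n))
    totals_mat <- round(b_tot + placebo_comp + drug_comp + noise)
    totals_mat <- pmin(pmax(totals_mat, 0), maxtot)

    # monotone dropout
    miss <- matrix(FALSE, n, T_)
    if (cfg$dropout_hazard > 0) {
      miss <- matrix(stats::runif(n * T_) < cfg$dropout_hazard, n, T_)
      if (T_ > 1)
        for (v in 2:T_) miss[, v] <- miss[, v] | miss[, v - 1]
    }
    vlabs <- paste0("week", wk)
    obs <- which(!miss, arr.ind = TRUE)
    totals <- data.frame(subject_id = ids[obs[, 1]],
                         visit = vlabs[obs[, 2]],
                         total = as.integer(totals_mat[obs]),
                         stringsAsFactors = FALSE)
    totals <- totals[order(match(totals$subject_id, ids),
                           match(totals$visit, vlabs)), ]

    subjects <- data.frame(subject_id = ids, arm = arm,
                           screening_to_baseline_days =
                             4L + stats::rpois(n, 3.5),
                           stringsAsFactors = FALSE)
    ds <- trial_dataset(subjects, scr, bas, totals,
                        visits = data.frame(visit = vlabs, week = wk),
                        arms = arms, placebo_arm = cfg$placebo_arm,
                        item_max = cfg$item_max)
    truth <- data.frame(
      subject_id = ids, arm = arm, pi = pi_i,
      true_label = as.integer(f_i * (1 - exp(-eos_wk / cfg$placebo_tc)) >=
                                cfg$threshold),
      drug_week_eos = drug_full * (1 - cfg$drug_attenuation * pi_i),
      stringsAsFactors = FALSE)
    attr(truth, "true_te") <- cfg$drug_effect
    list(dataset = ds, truth = truth)
  })
}

#' Ceiling AUC of the latent propensity for observed placebo response
#'
#' The AUC of the true latent propensity against the observed
#' end-of-study response labels in the placebo arm: the discrimination an
#' estimated propensity model can at best approach.
#'
#' @param truth truth table from [generate_trial()].
#' @param dataset the matching dataset.
#' @param threshold a [threshold_spec()] used for labeling.
#' @return AUC in \[0,1\].
#' @export
propensity_oracle_auc <- function(truth, dataset,
                                  threshold = threshold_spec("HAMD17")) {
  lab <- label_response(dataset, threshold)
  keep <- lab$arm == dataset$placebo_arm & !is.na(lab$label)
  pi_i <- stats::setNames(truth$pi, truth$subject_id)
  roc_auc(pi_i[lab$subject_id[keep]], lab$label[keep])
}
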