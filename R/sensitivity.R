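#' Distribution of propensity probabilities by arm
#'
#' Half-open binning `[low, high)` with the last bin closed at the top, so
#' a probability exactly on an interior edge falls in the upper bin.
#'
#' @param table a `propensity_table` from [predict_propensity()].
#' @param edges interior bin edges (defaults 0.2, 0.4, 0.6, 0.8, giving
#'   bins <0.2, 0.2-0.4, 0.4-0.6, 0.6-0.8, >0.8).
#' @return data.frame: `arm`, `bin`, `count`, `percent` (per-arm
#'   percentages sum to 100).
#' @export
bin_propensity <- function(table, edges = c(0.2, 0.4, 0.6, 0.8)) {
  if (nrow(table) == 0) stopf("empty propensity table")
  if (is.unsorted(edges, strictly = TRUE)) stopf("bin edges must be strictly increasing")
  brk <- c(0, edges, 1)
  labs <- c(paste0("<", edges[1]),
            if (length(edges) > 1)
              paste0(edges[-length(edges)], "-", edges[-1]),
            paste0(">", edges[length(edges)]))
  bin <- cut(table$probability, brk, labels = labs, right = FALSE,
             include.lowest = TRUE)
  bin[table$probability >= brk[length(brk) - 1]] <- labs[length(labs)]
  out <- do.call(rbind, lapply(unique(table$arm), function(a) {
    ct <- table(factor(bin[table$arm == a], levels = labs))
    data.frame(arm = a, bin = labs, count = as.integer(ct),
               percent = 100 * as.integer(ct) / sum(ct),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Sensitivity of the treatment effect to extreme propensities
#'
#' Refits the MMRM under the 2 x 3 grid \{weighted, unweighted\} x
#' \{all subjects, low-propensity removed, high-propensity removed\}, for
#' every active-vs-placebo comparison at the analysis visit, and records
#' removed-subject counts per cell. Cells whose subset empties an arm are
#' flagged infeasible and the grid continues.
#'
#' @param dataset a [trial_dataset()].
#' @param table a `propensity_table` covering every analyzed subject.
#' @param low_cut drop subjects with probability strictly below this in
#'   the "low-removed" analyses (default 0.2).
#' @param high_cut drop subjects with probability strictly above this in
#'   the "high-removed" analyses (default 0.8).
#' @param spec an [mmrm_spec()].
#' @param visit analysis visit (default: last scheduled).
#' @return A `sensitivity_report`: `$grid` (one row per analysis x
#'   comparison), `$bias` (per weighting scheme, see [bias_metric()]),
#'   `$low_cut`, `$high_cut`.
#' @export
run_sensitivity_grid <- function(dataset, table, low_cut = 0.2,
                                 high_cut = 0.8, spec = mmrm_spec(),
                                 visit = NULL) {
  visit <- visit %||% dataset$visits$visit[nrow(dataset$visits)]
  prob <- stats::setNames(table$probability, table$subject_id)
  subsets <- list(
    all = table$subject_id,
    low_removed = table$subject_id[prob >= low_cut],
    high_removed = table$subject_id[prob <= high_cut]
  )
  schemes <- c("weighted", "unweighted")
  rows <- list()
  for (scheme in schemes) for (sub in names(subsets)) {
    ids <- subsets[[sub]]
    removed <- nrow(table) - length(ids)
    ds_sub <- tryCatch(subset_subjects(dataset, ids), error = function(e) NULL)
    arms_present <- if (is.null(ds_sub)) character(0)
    else unique(ds_sub$subjects$arm)
    feasible <- !is.null(ds_sub) &&
      all(dataset$arms %in% arms_present) && length(ids) > 0
    if (!feasible) {
      for (a in setdiff(dataset$arms, dataset$placebo_arm))
        rows[[length(rows) + 1]] <- data.frame(
          analysis = scheme, subset = sub,
          comparison = paste0(a, "_vs_", dataset$placebo_arm),
          te = NA_real_, se = NA_real_, p = NA_real_,
          effect_size = NA_real_, n_removed = removed, feasible = FALSE,
          stringsAsFactors = FALSE)
      next
    }
    wts <- if (scheme == "weighted") table[table$subject_id %in% ids, ] else NULL
    fit <- mmrm_fit(ds_sub, weights = wts, spec = spec)
    for (a in fit$design$active_arms) {
      te <- treatment_effect(fit, a, visit = visit)
      rows[[length(rows) + 1]] <- data.frame(
        analysis = scheme, subset = sub, comparison = te$comparison,
        te = te$te, se = te$se, p = te$p, effect_size = te$effect_size,
        n_removed = removed, feasible = TRUE, stringsAsFactors = FALSE)
    }
  }
  grid <- do.call(rbind, rows)
  bias <- vapply(schemes, function(scheme) {
    g <- grid[grid$analysis == scheme & grid$feasible, ]
    all_te <- g$te[g$subset == "all"]
    names(all_te) <- g$comparison[g$subset == "all"]
    sub_g <- g[g$subset != "all", ]
    if (!nrow(sub_g) || any(all_te == 0)) return(NA_real_)
    tryCatch(bias_metric(all_te,
                         split(stats::setNames(sub_g$te, sub_g$comparison),
                               sub_g$subset)),
             error = function(e) NA_real_)
  }, numeric(1))
  structure(list(grid = grid, bias = bias, low_cut = low_cut,
                 high_cut = high_cut, visit = visit),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity grid at %s (cuts: p < %s removed / p > %s removed)\n",
              x$visit, x$low_cut, x$high_cut))
  print(x$grid, row.names = FALSE)
  cat(sprintf("\nMean %% absolute TE deviation (bias): weighted %.3f, unweighted %.3f\n",
              x$bias[["weighted"]], x$bias[["unweighted"]]))
  invisible(x)
}

#' Mean relative absolute deviation of subset treatment effects
#'
#' The bias metric B: the mean, over every (comparison, subset) pair, of
#' `|TE_subset - TE_all| / |TE_all|`. Scale-invariant in the TEs.
#'
#' @param te_all named vector of all-data TEs, one per comparison.
#' @param te_subsets list of named vectors (same comparison names), one
#'   per subset analysis.
#' @return Nonnegative scalar B.
#' @export
bias_metric <- function(te_all, te_subsets) {
  if (any(te_all == 0))
    stopf("bias undefined: an all-data TE is zero",
          class = "pwmmrm_undefined_bias_error")
  if (!is.list(te_subsets)) te_subsets <- list(te_subsets)
  devs <- unlist(lapply(te_subsets, function(ts) {
    nm <- names(ts) %||% names(te_all)
    abs(ts - te_all[nm]) / abs(te_all[nm])
  }), use.names = FALSE)
  mean(devs)
}
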