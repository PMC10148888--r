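#' Split labeled placebo-arm subjects into training and validation sets
#'
#' A label-stratified random partition: `fraction` of the responders and
#' `fraction` of the non-responders (rounded) go to training, the rest to
#' validation. Subjects with a missing response label are excluded.
#'
#' @param dataset a [trial_dataset()].
#' @param labels output of [label_response()].
#' @param fraction training fraction in (0,1); default 0.75.
#' @param seed integer seed (same seed, same partition).
#' @return list(train = subject ids, validation = subject ids).
#' @export
split_placebo <- function(dataset, labels, fraction = 0.75, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stopf("fraction must be in (0,1)")
  lab <- labels[labels$arm == dataset$placebo_arm & !is.na(labels$label), ]
  if (nrow(lab) == 0) stopf("no labeled placebo-arm subjects")
  strata <- split(lab$subject_id, lab$label)
  if (length(strata) < 2) {
    warnf("all placebo labels identical; falling back to a plain random split")
    strata <- list(lab$subject_id)
  }
  # per-stratum training counts: floors plus largest-remainder top-up so the
  # overall training size is round(fraction * n)
  ns <- vapply(strata, length, integer(1))
  raw <- fraction * ns
  k <- floor(raw)
  extra <- round(fraction * sum(ns)) - sum(k)
  if (extra > 0) {
    o <- order(-(raw - k))
    k[o[seq_len(extra)]] <- k[o[seq_len(extra)]] + 1
  }
  # keep both labels represented on both sides when counts permit
  if (length(strata) > 1)
    k <- pmin(pmax(k, ifelse(ns >= 2, 1L, 0L)), ifelse(ns >= 2, ns - 1L, ns))
  with_seed(seed, {
    train <- unlist(lapply(seq_along(strata),
                           function(i) sample(strata[[i]], k[i])),
                    use.names = FALSE)
    list(train = sort(train),
         validation = sort(setdiff(lab$subject_id, train)))
  })
}

default_topology_grid <- function(n_items = 17L) {
  g <- lapply(seq_len(n_items), function(k) k)
  two <- list(c(4L, 2L), c(8L, 4L), c(12L, 6L), c(17L, 8L))
  three <- list(c(8L, 4L, 2L), c(12L, 6L, 5L), c(17L, 12L, 6L))
  c(g, two, three)
}

#' Grid search over network topologies
#'
#' Trains one network per candidate hidden-layer configuration on the
#' training split and scores each by validation AUC; the best validation
#' AUC wins, with ties broken by fewer total nodes, then fewer layers.
#' Each candidate trains from a seed derived deterministically from the
#' master seed, so the selection is reproducible.
#'
#' @param X_train,y_train training item changes and labels.
#' @param X_valid,y_valid validation split (both labels present).
#' @param grid list of integer vectors of hidden-layer sizes; the default
#'   covers all single layers of 1 to `ncol(X_train)` nodes plus
#'   representative 2- and 3-layer pyramids.
#' @param cfg a [train_config()]; its seed acts as the master seed.
#' @return list(best = hidden sizes, model = trained best network,
#'   table = per-candidate score data.frame).
#' @export
grid_search_topology <- function(X_train, y_train, X_valid, y_valid,
                                 grid = default_topology_grid(ncol(X_train)),
                                 cfg = train_config()) {
  if (length(grid) == 0) stopf("empty topology grid",
                               class = "pwmmrm_config_error")
  if (length(unique(y_valid)) < 2)
    stopf("validation split needs both labels",
          class = "pwmmrm_single_label_error")
  rows <- lapply(seq_along(grid), function(i) {
    hidden <- as.integer(grid[[i]])
    cfg_i <- cfg
    cfg_i$seed <- spawn_seed(cfg$seed, paste0("topology-", paste(hidden, collapse = "x")))
    m <- train_mlp(X_train, y_train, hidden, cfg_i)
    data.frame(topology = paste(hidden, collapse = "-"),
               n_layers = length(hidden), n_nodes = sum(hidden),
               train_loss = utils::tail(m$trace, 1) %||% NA_real_,
               valid_auc = roc_auc(predict(m, X_valid), y_valid),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  o <- order(-tab$valid_auc, tab$n_nodes, tab$n_layers)
  best_i <- o[1]
  hidden <- as.integer(strsplit(tab$topology[best_i], "-")[[1]])
  cfg_b <- cfg
  cfg_b$seed <- spawn_seed(cfg$seed, paste0("topology-", paste(hidden, collapse = "x")))
  list(best = hidden, model = train_mlp(X_train, y_train, hidden, cfg_b),
       table = tab)
}

#' Predict the placebo-response propensity and analysis weight for every subject
#'
#' Applies the trained network to the pre-randomization item changes of
#' all subjects in all arms; the analysis weight is the inverse of the
#' predicted probability after clipping to `[p_min, p_max]`. Clipping
#' guards against unbounded weights from near-zero probabilities; set
#' `p_min = 0, p_max = 1` to invert raw probabilities.
#'
#' @param model a trained `pwmmrm_mlp`.
#' @param dataset a [trial_dataset()].
#' @param p_min,p_max clipping bounds for the probability before
#'   inversion (defaults 0.05 and 1).
#' @return A `propensity_table` data.frame: `subject_id`, `arm`,
#'   `probability`, `weight`; attribute `n_excluded` counts subjects
#'   dropped for missing pre-randomization items.
#' @export
predict_propensity <- function(model, dataset, p_min = 0.05, p_max = 1) {
  X <- item_changes(dataset)
  ok <- stats::complete.cases(X)
  if (any(!ok))
    warnf("%d subject(s) excluded: missing pre-randomization items", sum(!ok))
  p <- predict(model, X[ok, , drop = FALSE])
  pc <- pmin(pmax(p, p_min), p_max)
  out <- data.frame(subject_id = dataset$subjects$subject_id[ok],
                    arm = dataset$subjects$arm[ok],
                    probability = p, weight = 1 / pc,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "n_excluded") <- sum(!ok)
  class(out) <- c("propensity_table", "data.frame")
  out
}
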