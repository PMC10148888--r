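#' Default column-name schema for long-format trial files
#'
#' @param n_items number of scale items (item columns are `item1..itemJ`).
#' @return Named list mapping logical fields to file column names.
#' @export
trial_schema <- function(n_items = 17L) {
  list(subject = "subject_id", arm = "arm", visit = "visit", days = "days",
       total = "total", items = paste0("item", seq_len(n_items)))
}

delim_for <- function(path) {
  if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
}

#' Read a long-format randomized-trial file
#'
#' One row per subject x visit. Pre-randomization rows carry the visit tags
#' `screening` and `baseline` and fill the item columns; post-baseline rows
#' carry `week<k>` tags and fill the total-score column. The baseline total
#' is recomputed from the items and cross-checked against the total column
#' when present.
#'
#' @param path CSV or TSV file (dialect chosen by extension).
#' @param schema column-name map, see [trial_schema()].
#' @param arms optional arm labels (default: observed arms, placebo first
#'   if present).
#' @param placebo_arm placebo arm label; default `"placebo"` if observed,
#'   else the first arm.
#' @param item_max per-item maxima, recycled/validated downstream.
#' @return A [trial_dataset()].
#' @export
read_trial_long <- function(path, schema = trial_schema(),
                            arms = NULL, placebo_arm = NULL,
                            item_max = hamd17_item_max()) {
  if (!file.exists(path)) stopf("input file not found: %s", path,
                                class = "pwmmrm_io_error")
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(schema$subject, schema$arm, schema$visit, schema$total)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stopf("missing mandatory column(s): %s", paste(miss, collapse = ", "),
          class = "pwmmrm_schema_error")
  pre <- df[[schema$visit]] %in% c("screening", "baseline")
  if (any(pre)) {
    miss_it <- setdiff(schema$items, names(df))
    if (length(miss_it))
      stopf("missing item column(s): %s", paste(miss_it, collapse = ", "),
            class = "pwmmrm_schema_error")
  }
  if (anyDuplicated(df[c(schema$subject, schema$visit)]))
    stopf("duplicate subject x visit row(s)", class = "pwmmrm_integrity_error")

  scr <- df[df[[schema$visit]] == "screening", ]
  bas <- df[df[[schema$visit]] == "baseline", ]
  ids <- unique(df[[schema$subject]])
  if (!all(ids %in% scr[[schema$subject]]) || !all(ids %in% bas[[schema$subject]]))
    stopf("every subject needs both a screening and a baseline row",
          class = "pwmmrm_validation_error")
  scr <- scr[match(ids, scr[[schema$subject]]), ]
  bas <- bas[match(ids, bas[[schema$subject]]), ]

  days <- if (!is.null(schema$days) && schema$days %in% names(df))
    as.integer(scr[[schema$days]]) else rep(NA_integer_, length(ids))
  subjects <- data.frame(subject_id = as.character(ids),
                         arm = as.character(scr[[schema$arm]]),
                         screening_to_baseline_days = days,
                         stringsAsFactors = FALSE)
  screening_items <- as.matrix(scr[, schema$items, drop = FALSE])
  baseline_items <- as.matrix(bas[, schema$items, drop = FALSE])

  # cross-check any stated baseline total against the item sum
  if (any(!is.na(bas[[schema$total]]))) {
    st <- as.integer(bas[[schema$total]])
    calc <- as.integer(rowSums(baseline_items))
    bad <- which(!is.na(st) & st != calc)
    if (length(bad))
      stopf("baseline total (%d) disagrees with item sum (%d) for subject %s",
            st[bad[1]], calc[bad[1]], ids[bad[1]],
            class = "pwmmrm_validation_error")
  }

  post <- df[!(df[[schema$visit]] %in% c("screening", "baseline")), ]
  totals <- data.frame(subject_id = as.character(post[[schema$subject]]),
                       visit = as.character(post[[schema$visit]]),
                       total = as.integer(post[[schema$total]]),
                       stringsAsFactors = FALSE)
  vlabs <- unique(totals$visit)
  wk <- suppressWarnings(as.integer(sub("^week", "", vlabs)))
  if (any(is.na(wk)))
    stopf("unrecognized visit tag(s): %s (expected week<k>)",
          paste(vlabs[is.na(wk)], collapse = ", "),
          class = "pwmmrm_schema_error")
  o <- order(wk)
  visits <- data.frame(visit = vlabs[o], week = wk[o], stringsAsFactors = FALSE)

  obs_arms <- unique(subjects$arm)
  if (is.null(arms))
    arms <- if ("placebo" %in% obs_arms)
      c("placebo", setdiff(obs_arms, "placebo")) else obs_arms
  if (is.null(placebo_arm))
    placebo_arm <- if ("placebo" %in% arms) "placebo" else arms[1]

  trial_dataset(subjects, screening_items, baseline_items, totals, visits,
                arms, placebo_arm, item_max)
}

#' Write a trial dataset in the long sparse format
#'
#' Emits exactly the dialect [read_trial_long()] consumes; a read of the
#' written file reproduces the dataset field-for-field. Missing
#' post-baseline visits produce no row.
#'
#' @param dataset a [trial_dataset()].
#' @param path output CSV/TSV path.
#' @param schema column-name map, see [trial_schema()].
#' @return `path`, invisibly.
#' @export
write_trial_long <- function(dataset, path, schema = trial_schema(length(dataset$item_max))) {
  s <- dataset$subjects
  J <- length(dataset$item_max)
  mk_pre <- function(tag, items) {
    out <- data.frame(s$subject_id, s$arm, tag,
                      s$screening_to_baseline_days,
                      as.integer(rowSums(items)), stringsAsFactors = FALSE)
    names(out) <- c(schema$subject, schema$arm, schema$visit, schema$days,
                    schema$total)
    it <- as.data.frame(items)
    names(it) <- schema$items
    cbind(out, it)
  }
  rows <- rbind(mk_pre("screening", dataset$screening_items),
                mk_pre("baseline", dataset$baseline_items))
  if (nrow(dataset$totals)) {
    arm <- stats::setNames(s$arm, s$subject_id)
    days <- stats::setNames(s$screening_to_baseline_days, s$subject_id)
    post <- data.frame(dataset$totals$subject_id,
                       arm[dataset$totals$subject_id],
                       dataset$totals$visit,
                       days[dataset$totals$subject_id],
                       dataset$totals$total, stringsAsFactors = FALSE)
    names(post) <- c(schema$subject, schema$arm, schema$visit, schema$days,
                     schema$total)
    it <- as.data.frame(matrix(NA_integer_, nrow(post), J))
    names(it) <- schema$items
    rows <- rbind(rows, cbind(post, it))
  }
  # stable order: subject, then screening/baseline/weeks
  vord <- c("screening", "baseline", dataset$visits$visit)
  rows <- rows[order(match(rows[[schema$subject]], s$subject_id),
                     match(rows[[schema$visit]], vord)), ]
  ok <- tryCatch({
    utils::write.table(rows, path, sep = delim_for(path), row.names = FALSE,
                       quote = FALSE, na = "")
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stopf("cannot write to %s", path, class = "pwmmrm_io_error")
  invisible(path)
}
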