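#' Per-item score maxima for the 17-item Hamilton Depression Rating Scale
#'
#' Items 1-3, 7-11 and 15 are scored 0-4; the remaining eight items are
#' scored 0-2 (maximum total 52). Other scales (e.g. the 10-item MADRS,
#' each item 0-6) are supported by passing a different maxima vector to
#' [trial_dataset()].
#'
#' @return Integer vector of length 17.
#' @export
hamd17_item_max <- function() {
  c(4L, 4L, 4L, 2L, 2L, 2L, 4L, 4L, 4L, 4L, 4L, 2L, 2L, 2L, 4L, 2L, 2L)
}

#' Construct a validated randomized-trial rating-scale dataset
#'
#' The container holds, for every subject, the arm label, the 17 (or
#' configurable-J) item scores at the screening and baseline visits, the
#' day offset between those visits, and the total score at each observed
#' post-baseline visit. Post-baseline visits are sparse: a missing visit is
#' simply absent, never imputed.
#'
#' @param subjects data.frame with columns `subject_id`, `arm`,
#'   `screening_to_baseline_days` (nonnegative integer).
#' @param screening_items,baseline_items integer matrices, one row per
#'   subject (in `subjects` order), one column per scale item.
#' @param totals data.frame with columns `subject_id`, `visit`, `total`:
#'   the post-baseline total scores in long sparse form.
#' @param visits data.frame with columns `visit` (label) and `week`
#'   (strictly increasing positive integers; week 0 is reserved for
#'   baseline and must not appear).
#' @param arms character vector of arm labels.
#' @param placebo_arm the reference (placebo) arm label.
#' @param item_max per-item score maxima; defaults to [hamd17_item_max()].
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(subjects, screening_items, baseline_items, totals,
                          visits, arms, placebo_arm,
                          item_max = hamd17_item_max()) {
  screening_items <- as.matrix(screening_items)
  baseline_items <- as.matrix(baseline_items)
  storage.mode(screening_items) <- "integer"
  storage.mode(baseline_items) <- "integer"
  subjects$subject_id <- as.character(subjects$subject_id)
  subjects$arm <- as.character(subjects$arm)
  totals$subject_id <- as.character(totals$subject_id)
  totals$visit <- as.character(totals$visit)
  visits$visit <- as.character(visits$visit)
  rownames(screening_items) <- rownames(baseline_items) <- subjects$subject_id
  colnames(screening_items) <- colnames(baseline_items) <-
    paste0("item", seq_len(ncol(baseline_items)))

  ds <- structure(list(
    subjects = subjects, screening_items = screening_items,
    baseline_items = baseline_items, totals = totals, visits = visits,
    arms = as.character(arms), placebo_arm = as.character(placebo_arm),
    item_max = as.integer(item_max)
  ), class = "trial_dataset")
  ds$subjects$baseline_total <- as.integer(rowSums(baseline_items))
  validate_trial_dataset(ds)
  ds
}

validate_trial_dataset <- function(ds) {
  s <- ds$subjects
  if (anyDuplicated(s$subject_id))
    stopf("duplicate subject identifiers: %s",
          paste(unique(s$subject_id[duplicated(s$subject_id)]), collapse = ", "),
          class = "pwmmrm_integrity_error")
  if (!all(s$arm %in% ds$arms))
    stopf("subject arm label(s) not in declared arm list: %s",
          paste(setdiff(s$arm, ds$arms), collapse = ", "),
          class = "pwmmrm_validation_error")
  if (length(ds$placebo_arm) != 1L || !(ds$placebo_arm %in% ds$arms))
    stopf("exactly one declared arm must be the placebo arm",
          class = "pwmmrm_validation_error")
  if (any(s$screening_to_baseline_days < 0, na.rm = TRUE))
    stopf("screening_to_baseline_days must be nonnegative",
          class = "pwmmrm_validation_error")
  wk <- ds$visits$week
  if (any(wk <= 0) || any(diff(wk) <= 0))
    stopf("post-baseline visit weeks must be strictly increasing and > 0 (week 0 is baseline)",
          class = "pwmmrm_validation_error")
  J <- length(ds$item_max)
  for (fld in c("screening_items", "baseline_items")) {
    m <- ds[[fld]]
    if (ncol(m) != J)
      stopf("%s has %d columns; %d items configured", fld, ncol(m), J,
            class = "pwmmrm_validation_error")
    bad <- which(m < 0 | m > rep(ds$item_max, each = nrow(m)), arr.ind = TRUE)
    if (nrow(bad) > 0)
      stopf("item score out of range: subject %s, item %d (%s)",
            s$subject_id[bad[1, 1]], bad[1, 2], fld,
            class = "pwmmrm_validation_error")
  }
  if (nrow(ds$totals)) {
    if (anyDuplicated(ds$totals[c("subject_id", "visit")]))
      stopf("duplicate subject x visit total-score rows",
            class = "pwmmrm_integrity_error")
    if (!all(ds$totals$visit %in% ds$visits$visit))
      stopf("post-baseline totals at undeclared visit(s): %s",
            paste(setdiff(ds$totals$visit, ds$visits$visit), collapse = ", "),
            class = "pwmmrm_validation_error")
    if (!all(ds$totals$subject_id %in% s$subject_id))
      stopf("total-score rows for unknown subject(s)",
            class = "pwmmrm_integrity_error")
    max_total <- sum(ds$item_max)
    if (any(ds$totals$total < 0 | ds$totals$total > max_total))
      stopf("post-baseline total outside [0, %d]", max_total,
            class = "pwmmrm_validation_error")
  }
  invisible(ds)
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %d subjects, %d arms (placebo: %s), %d post-baseline visits\n",
              nrow(x$subjects), length(x$arms), x$placebo_arm, nrow(x$visits)))
  cat("  arm census: ",
      paste(sprintf("%s=%d", names(table(x$subjects$arm)), table(x$subjects$arm)),
            collapse = ", "), "\n", sep = "")
  cat(sprintf("  %d post-baseline total-score observations\n", nrow(x$totals)))
  invisible(x)
}

#' Screening-to-baseline item change vectors
#'
#' The pre-randomization predictors: for each subject and item j,
#' baseline score minus screening score.
#'
#' @param dataset a [trial_dataset()].
#' @param subject_id optional subject subset (default: all, in dataset order).
#' @return Integer matrix, one row per subject, one column per item.
#' @export
item_changes <- function(dataset, subject_id = NULL) {
  d <- dataset$baseline_items - dataset$screening_items
  if (!is.null(subject_id)) d <- d[as.character(subject_id), , drop = FALSE]
  d
}

#' Change from baseline of the total score at a visit
#'
#' @param dataset a [trial_dataset()].
#' @param visit a declared post-baseline visit label.
#' @return Named numeric vector over all subjects (dataset order); `NA` for
#'   subjects without the visit (missing is explicit, never zero).
#' @export
change_from_baseline <- function(dataset, visit) {
  visit <- as.character(visit)
  if (!visit %in% dataset$visits$visit)
    stopf("visit '%s' is not in the visit schedule", visit)
  tt <- dataset$totals[dataset$totals$visit == visit, ]
  out <- stats::setNames(rep(NA_real_, nrow(dataset$subjects)),
                         dataset$subjects$subject_id)
  out[tt$subject_id] <- tt$total
  out - dataset$subjects$baseline_total
}

# Long-form change-from-baseline table used by the MMRM stage.
changes_long <- function(dataset) {
  t <- dataset$totals
  bl <- stats::setNames(dataset$subjects$baseline_total, dataset$subjects$subject_id)
  arm <- stats::setNames(dataset$subjects$arm, dataset$subjects$subject_id)
  data.frame(subject_id = t$subject_id, arm = arm[t$subject_id],
             visit = t$visit, baseline = as.numeric(bl[t$subject_id]),
             change = t$total - as.numeric(bl[t$subject_id]),
             stringsAsFactors = FALSE, row.names = NULL)
}

# Subset a dataset to a set of subject ids (keeps declared arms/visits).
subset_subjects <- function(dataset, ids) {
  ids <- as.character(ids)
  keep <- dataset$subjects$subject_id %in% ids
  trial_dataset(
    subjects = dataset$subjects[keep, c("subject_id", "arm",
                                        "screening_to_baseline_days")],
    screening_items = dataset$screening_items[keep, , drop = FALSE],
    baseline_items = dataset$baseline_items[keep, , drop = FALSE],
    totals = dataset$totals[dataset$totals$subject_id %in% ids, ],
    visits = dataset$visits, arms = dataset$arms,
    placebo_arm = dataset$placebo_arm, item_max = dataset$item_max
  )
}
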