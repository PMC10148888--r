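# Deterministic tiny-dataset builder: item scores are filled greedily to
# the requested totals (no RNG), so expected values can be stated exactly.

fill_items <- function(total, item_max = hamd17_item_max()) {
  x <- integer(length(item_max))
  for (j in seq_along(item_max)) {
    take <- min(total, item_max[j])
    x[j] <- take
    total <- total - take
    if (total == 0) break
  }
  x
}

make_dataset <- function(baseline_totals, arms_of,
                         totals = NULL, visits = c(week4 = 4L, week8 = 8L),
                         screening_totals = baseline_totals,
                         placebo_arm = "placebo") {
  n <- length(baseline_totals)
  ids <- sprintf("P%02d", seq_len(n))
  scr <- t(vapply(screening_totals, fill_items, integer(17)))
  bas <- t(vapply(baseline_totals, fill_items, integer(17)))
  tot <- if (is.null(totals)) {
    data.frame(subject_id = character(0), visit = character(0),
               total = integer(0))
  } else {
    data.frame(subject_id = ids[totals$subject],
               visit = totals$visit, total = totals$total,
               stringsAsFactors = FALSE)
  }
  trial_dataset(
    subjects = data.frame(subject_id = ids, arm = arms_of,
                          screening_to_baseline_days = 7L,
                          stringsAsFactors = FALSE),
    screening_items = scr, baseline_items = bas, totals = tot,
    visits = data.frame(visit = names(visits), week = as.integer(visits),
                        stringsAsFactors = FALSE),
    arms = unique(c(placebo_arm, arms_of)), placebo_arm = placebo_arm
  )
}

table2_fixture <- function() {
  path <- system.file("extdata", "table2_te.csv", package = "pwmmrm")
  utils::read.csv(path, stringsAsFactors = FALSE)
}
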