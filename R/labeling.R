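#' Response-threshold specification
#'
#' The placebo response is defined as a clinically relevant percent
#' reduction from baseline in the total score. Shipped defaults follow the
#' published anchor-based derivation: 38% on the MADRS and its
#' equipercentile-linked HAMD-17 equivalent of 41%.
#'
#' @param scale `"HAMD17"` or `"MADRS"`.
#' @param percent_reduction fraction strictly in (0,1); default 0.41 for
#'   HAMD-17 and 0.38 for MADRS.
#' @return A `threshold_spec` object.
#' @export
threshold_spec <- function(scale = c("HAMD17", "MADRS"),
                           percent_reduction = NULL) {
  scale <- match.arg(scale)
  if (is.null(percent_reduction))
    percent_reduction <- if (scale == "HAMD17") 0.41 else 0.38
  if (!is.numeric(percent_reduction) || percent_reduction <= 0 ||
      percent_reduction >= 1)
    stopf("percent_reduction must be strictly between 0 and 1")
  structure(list(scale = scale, percent_reduction = percent_reduction),
            class = "threshold_spec")
}

#' CGI-I anchor map for threshold derivation
#'
#' Mean percent reductions from baseline associated with Clinical Global
#' Impression-Improvement levels, from published equipercentile linking of
#' the MADRS to the CGI-I: CGI-I 3 ("minimally improved") 24.5%, CGI-I 2
#' ("much improved") 52.5%, CGI-I 1 ("very much improved") 82%.
#'
#' @param anchors named numeric vector: names are CGI-I levels (1-7),
#'   values are mean fractional reductions.
#' @return An `anchor_map` object (validated: reduction decreases as the
#'   CGI-I score increases).
#' @export
anchor_map <- function(anchors = c(`1` = 0.82, `2` = 0.525, `3` = 0.245)) {
  lev <- as.integer(names(anchors))
  if (any(is.na(lev)) || any(lev < 1 | lev > 7))
    stopf("anchor names must be CGI-I levels 1-7")
  o <- order(lev)
  anchors <- anchors[o]
  if (any(diff(anchors) > 0))
    stopf("percent reduction must decrease as the CGI-I score increases")
  structure(anchors, class = "anchor_map")
}

#' Derive a response threshold from CGI-I anchors
#'
#' The midpoint rule takes the arithmetic mean of the reductions at two
#' CGI-I levels (the published analysis uses the value between "minimally"
#' and "much" improved). An explicit `override` fraction may be supplied
#' instead; the computed midpoint is retained alongside for audit.
#'
#' @param anchors an [anchor_map()].
#' @param lower_cgi,upper_cgi CGI-I levels bracketing the clinically
#'   relevant improvement (defaults 3 and 2).
#' @param rule `"midpoint"` or `"override"`.
#' @param override fraction used when `rule = "override"`.
#' @param scale scale the threshold applies to.
#' @return A `threshold_spec` with attribute `midpoint` (the computed
#'   anchor midpoint).
#' @export
derive_threshold_from_anchors <- function(anchors, lower_cgi = 3L,
                                          upper_cgi = 2L,
                                          rule = c("midpoint", "override"),
                                          override = NULL,
                                          scale = "MADRS") {
  rule <- match.arg(rule)
  lev <- as.integer(names(anchors))
  for (l in c(lower_cgi, upper_cgi))
    if (!l %in% lev)
      stopf("CGI-I level %d has no anchor", l, class = "pwmmrm_config_error")
  mid <- unname((anchors[as.character(lower_cgi)] +
                   anchors[as.character(upper_cgi)]) / 2)
  frac <- if (rule == "override") {
    if (is.null(override)) stopf("override rule requires an override fraction",
                                 class = "pwmmrm_config_error")
    override
  } else mid
  out <- threshold_spec(scale, frac)
  attr(out, "midpoint") <- mid
  out
}

#' Equipercentile linking of two score scales
#'
#' Maps a source-scale score to the target-scale score with the same
#' percentile rank, using the mid-rank (average-rank) convention for
#' discrete scores with linear interpolation between adjacent observed
#' score levels, clamped to the target sample's observed range.
#'
#' @param dist_source,dist_target nonempty numeric samples of observed
#'   scores on the two scales.
#' @param x source-scale score(s) to link.
#' @return Target-equivalent score(s).
#' @export
equipercentile_link <- function(dist_source, dist_target, x) {
  if (!length(dist_source) || !length(dist_target))
    stopf("empty score sample")
  pr <- function(sample, q) {
    # mid-rank percentile at observed levels, linear between levels
    lev <- sort(unique(sample))
    n <- length(sample)
    p_at <- vapply(lev, function(v)
      (sum(sample < v) + 0.5 * sum(sample == v)) / n, numeric(1))
    vapply(q, function(qq) {
      if (qq <= lev[1]) return(p_at[1])
      if (qq >= lev[length(lev)]) return(p_at[length(p_at)])
      stats::approx(lev, p_at, xout = qq, ties = "ordered")$y
    }, numeric(1))
  }
  p <- pr(dist_source, x)
  lev_t <- sort(unique(dist_target))
  p_t <- vapply(lev_t, function(v)
    (sum(dist_target < v) + 0.5 * sum(dist_target == v)) / length(dist_target),
    numeric(1))
  vapply(p, function(pp) {
    if (pp <= p_t[1]) return(lev_t[1])
    if (pp >= p_t[length(p_t)]) return(lev_t[length(lev_t)])
    # invert the piecewise-linear percentile function
    stats::approx(p_t, lev_t, xout = pp, ties = "ordered")$y
  }, numeric(1))
}

#' Label end-of-study placebo response
#'
#' A subject is a responder (label 1) when the fractional reduction from
#' baseline of the total score at the end-of-study visit meets or exceeds
#' the threshold. Subjects missing the end-of-study visit are handled per
#' `missing_rule`: `"observed"` labels them `NA` (excluded from
#' label-dependent steps, flagged), `"locf"` carries the last observed
#' post-baseline total forward.
#'
#' @param dataset a [trial_dataset()].
#' @param threshold a [threshold_spec()].
#' @param eos_visit end-of-study visit label (default: last scheduled).
#' @param missing_rule `"observed"` or `"locf"`.
#' @return data.frame: `subject_id`, `arm`, `observed_percent_change`
#'   (fraction of baseline, NA when unobserved), `label` (0/1/NA).
#' @export
label_response <- function(dataset, threshold = threshold_spec("HAMD17"),
                           eos_visit = NULL,
                           missing_rule = c("observed", "locf")) {
  missing_rule <- match.arg(missing_rule)
  if (is.null(eos_visit)) eos_visit <- dataset$visits$visit[nrow(dataset$visits)]
  if (any(dataset$subjects$baseline_total == 0))
    stopf("baseline total of 0 gives an undefined percent change (subject %s)",
          dataset$subjects$subject_id[dataset$subjects$baseline_total == 0][1])
  eos <- change_from_baseline(dataset, eos_visit)
  if (missing_rule == "locf") {
    vord <- dataset$visits$visit
    for (v in rev(vord[seq_len(match(eos_visit, vord) - 1)])) {
      idx <- is.na(eos)
      if (!any(idx)) break
      eos[idx] <- change_from_baseline(dataset, v)[idx]
    }
  }
  pc <- -eos / dataset$subjects$baseline_total  # fractional reduction
  lab <- ifelse(is.na(pc), NA_integer_,
                as.integer(pc >= threshold$percent_reduction))
  data.frame(subject_id = dataset$subjects$subject_id,
             arm = dataset$subjects$arm,
             observed_percent_change = pc, label = lab,
             stringsAsFactors = FALSE, row.names = NULL)
}
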