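test_that("anchor midpoint rule reproduces the published threshold derivation", {
  am <- anchor_map(c(`3` = 0.245, `2` = 0.525))
  th <- derive_threshold_from_anchors(am, lower_cgi = 3, upper_cgi = 2)
  expect_equal(th$percent_reduction, 0.385)
  expect_equal(attr(th, "midpoint"), 0.385)

  th38 <- derive_threshold_from_anchors(am, 3, 2, rule = "override",
                                        override = 0.38)
  expect_equal(th38$percent_reduction, 0.38)
  expect_equal(th38$scale, "MADRS")
  expect_equal(attr(th38, "midpoint"), 0.385)  # retained for audit

  degen <- derive_threshold_from_anchors(anchor_map(c(`3` = 0.30, `2` = 0.30)),
                                         3, 2)
  expect_equal(degen$percent_reduction, 0.30)

  expect_error(derive_threshold_from_anchors(am, 5, 2), "level 5",
               class = "pwmmrm_config_error")
  expect_error(anchor_map(c(`2` = 0.2, `3` = 0.5)), "decrease")
})

test_that("shipped default thresholds are 41% HAMD-17 and 38% MADRS", {
  expect_equal(threshold_spec("HAMD17")$percent_reduction, 0.41)
  expect_equal(threshold_spec("MADRS")$percent_reduction, 0.38)
  expect_error(threshold_spec("HAMD17", 1.2), "between 0 and 1")
})

test_that("equipercentile linking matches mid-rank percentile arithmetic", {
  # self-linking is the identity at observed scores
  s <- c(0, 3, 3, 7, 10, 12)
  for (x in unique(s))
    expect_equal(equipercentile_link(s, s, x), x)
  # equal percentile ranks across a doubled scale
  expect_equal(equipercentile_link(c(0, 1, 2, 3), c(0, 2, 4, 6), 1), 2)
  # median maps to median for odd-sized samples of distinct scores
  set.seed(42)
  for (k in 1:5) {
    a <- sample(0:30, 11)
    b <- sample(0:60, 9)
    expect_equal(equipercentile_link(a, b, stats::median(a)),
                 stats::median(b))
  }
  # monotone nondecreasing in x
  src <- sample(0:52, 40, replace = TRUE)
  tgt <- sample(0:60, 35, replace = TRUE)
  xs <- seq(0, 52, by = 0.5)
  ys <- equipercentile_link(src, tgt, xs)
  expect_true(all(diff(ys) >= -1e-12))
  expect_true(all(ys >= min(tgt) & ys <= max(tgt)))
  expect_error(equipercentile_link(numeric(0), tgt, 1), "empty")
})

test_that("response labels apply the fractional-reduction rule at end of study", {
  ds <- make_dataset(c(24L, 20L, 24L, 24L),
                     c("placebo", "placebo", "placebo", "placebo"),
                     totals = data.frame(
                       subject = c(1L, 2L, 3L, 4L),
                       visit = c("week8", "week8", "week8", "week4"),
                       total = c(14L, 20L, 15L, 10L)))
  lab <- label_response(ds, threshold_spec("HAMD17", 0.41))
  expect_equal(lab$label[1], 1L)   # 10/24 = 0.4167 >= 0.41
  expect_equal(lab$label[2], 0L)   # no change
  expect_equal(lab$label[3], 0L)   # 9/24 = 0.375 < 0.41
  expect_true(is.na(lab$label[4])) # missing week 8, observed-case rule
  # LOCF carries the week-4 value forward: 14/24 = 0.583 -> responder
  lab2 <- label_response(ds, threshold_spec("HAMD17", 0.41),
                         missing_rule = "locf")
  expect_equal(lab2$label[4], 1L)
})

test_that("lowering the threshold never flips a responder to non-responder", {
  gen <- generate_trial(sim_config(arm_sizes = c(placebo = 40L)), seed = 2)
  ths <- c(0.6, 0.5, 0.41, 0.3, 0.2)
  labs <- lapply(ths, function(t)
    label_response(gen$dataset, threshold_spec("HAMD17", t))$label)
  for (k in seq_len(length(ths) - 1)) {
    both <- !is.na(labs[[k]]) & !is.na(labs[[k + 1]])
    expect_true(all(labs[[k + 1]][both] >= labs[[k]][both]))
  }
})

test_that("a zero baseline total is rejected as an undefined percent change", {
  ds <- make_dataset(c(24L, 20L), c("placebo", "placebo"))
  ds$subjects$baseline_total[2] <- 0L
  expect_error(label_response(ds), "undefined")
})
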