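make_labeled_placebo <- function(n_resp, n_non) {
  n <- n_resp + n_non
  # baseline 24; responders drop to 10 (58%), non-responders to 20 (17%)
  make_dataset(rep(24L, n), rep("placebo", n),
               totals = data.frame(subject = seq_len(n), visit = "week8",
                                   total = c(rep(10L, n_resp),
                                             rep(20L, n_non))))
}

test_that("placebo split is stratified, exhaustive and seed-reproducible", {
  ds <- make_labeled_placebo(40, 60)
  lab <- label_response(ds)
  sp <- split_placebo(ds, lab, fraction = 0.75, seed = 3)
  expect_length(sp$train, 75)
  expect_length(sp$validation, 25)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), ds$subjects$subject_id)
  lab_of <- setNames(lab$label, lab$subject_id)
  expect_equal(sum(lab_of[sp$train] == 1), 30)      # 75% of 40 responders
  expect_equal(sum(lab_of[sp$validation] == 1), 10)
  expect_equal(sum(lab_of[sp$train] == 0), 45)      # 75% of 60 non-responders
  expect_identical(split_placebo(ds, lab, 0.75, seed = 3), sp)
  expect_false(identical(split_placebo(ds, lab, 0.75, seed = 4)$train,
                         sp$train))
})

test_that("single-label placebo data triggers the plain-split fallback with a warning", {
  ds <- make_labeled_placebo(0, 20)
  lab <- label_response(ds)
  expect_warning(sp <- split_placebo(ds, lab, 0.75, seed = 1), "identical")
  expect_length(sp$train, 15)
})

test_that("grid search breaks AUC ties toward the smaller network", {
  set.seed(17)
  X <- rbind(matrix(rnorm(40, -2), 20, 2), matrix(rnorm(40, 2), 20, 2))
  y <- rep(0:1, each = 20)
  res <- grid_search_topology(X[c(TRUE, FALSE), ], y[c(TRUE, FALSE)],
                              X[c(FALSE, TRUE), ], y[c(FALSE, TRUE)],
                              grid = list(2L, 4L),
                              cfg = train_config(max_epochs = 200))
  expect_equal(res$table$valid_auc[1], res$table$valid_auc[2])  # both solve it
  expect_equal(res$best, 2L)
})

test_that("XOR patterns defeat a 1-node network but not a 4-node one", {
  set.seed(23)
  base <- matrix(c(-1, -1, 1, 1, -1, 1, -1, 1), 4, 2)
  X <- base[rep(1:4, each = 20), ] + matrix(rnorm(160, sd = 0.15), 80, 2)
  y <- rep(c(0, 1, 1, 0), each = 20)
  idx <- rep(c(TRUE, FALSE), 40)
  res <- grid_search_topology(X[idx, ], y[idx], X[!idx, ], y[!idx],
                              grid = list(1L, 4L),
                              cfg = train_config(max_epochs = 600, l2 = 1e-5,
                                                 seed = 2))
  tab <- res$table
  expect_gt(tab$valid_auc[tab$topology == "4"],
            tab$valid_auc[tab$topology == "1"])
  expect_equal(res$best, 4L)
  expect_error(grid_search_topology(X[idx, ], y[idx], X[!idx, ], y[!idx],
                                    grid = list()),
               class = "pwmmrm_config_error")
})

test_that("propensity weights follow the clipped inverse-probability rule", {
  ds <- make_dataset(c(24L, 24L, 24L), rep("placebo", 3))
  m <- pwmmrm:::new_mlp(list(matrix(0, 1, 17)), list(0), rep(0, 17),
                        rep(1, 17), c(17L, 1L))
  # bias 0 -> p = 0.5 -> weight 2
  pt <- predict_propensity(m, ds, p_min = 0.05, p_max = 1)
  expect_equal(pt$probability, rep(0.5, 3))
  expect_equal(pt$weight, rep(2, 3))
  # p = 0.999 clipped at 0.99 -> weight 1/0.99
  m$b[[1]] <- qlogis(0.999)
  pt <- predict_propensity(m, ds, p_min = 0.05, p_max = 0.99)
  expect_equal(pt$weight, rep(1 / 0.99, 3), tolerance = 1e-12)
  # p = 0.01 clipped up to 0.05 -> weight 20
  m$b[[1]] <- qlogis(0.01)
  pt <- predict_propensity(m, ds, p_min = 0.05, p_max = 1)
  expect_equal(pt$weight, rep(20, 3), tolerance = 1e-12)
})

test_that("weights stay within the clip-implied bounds on generated data", {
  gen <- generate_trial(sim_config(arm_sizes = c(placebo = 30L, a = 30L)),
                        seed = 19)
  lab <- label_response(gen$dataset)
  sp <- split_placebo(gen$dataset, lab, seed = 1)
  lab_of <- setNames(lab$label, lab$subject_id)
  X <- item_changes(gen$dataset)
  m <- train_mlp(X[sp$train, ], lab_of[sp$train], 3,
                 train_config(max_epochs = 100))
  pt <- predict_propensity(m, gen$dataset, p_min = 0.05, p_max = 0.98)
  expect_true(all(pt$weight >= 1 / 0.98 - 1e-12))
  expect_true(all(pt$weight <= 1 / 0.05 + 1e-12))
  expect_equal(nrow(pt), 60)
})
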