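test_that("design matrix accounting: columns, rows, dropped subjects", {
  # 2 arms x 2 visits, complete data
  ds <- make_dataset(c(24L, 22L, 26L, 23L), c("placebo", "placebo", "a", "a"),
                     totals = expand.grid(subject = 1:4,
                                          visit = c("week4", "week8"),
                                          stringsAsFactors = FALSE) |>
                       transform(total = 18L))
  d <- build_design(ds, mmrm_spec())
  expect_equal(nrow(d$X), 8)  # 4 subjects x 2 visits
  # 2 visit + 2 arm:visit + baseline + baseline:visit = 6
  expect_equal(ncol(d$X), 6)
  expect_equal(qr(d$X)$rank, 6)

  # a subject missing week4 contributes one row; one with no visits is dropped
  ds2 <- make_dataset(c(24L, 22L, 26L), c("placebo", "a", "a"),
                      totals = data.frame(
                        subject = c(1L, 1L, 2L),
                        visit = c("week4", "week8", "week8"),
                        total = c(20L, 16L, 18L)))
  d2 <- build_design(ds2, mmrm_spec())
  expect_equal(d2$n_obs, 3)
  expect_equal(d2$n_dropped, 1)
  expect_equal(sum(d2$subj == 2), 1)
})

test_that("T=1 with unit weights reduces to closed-form ANCOVA with REML variance", {
  set.seed(61)
  n <- 24
  bl <- sample(18:30, n, replace = TRUE)
  arm <- rep(c("placebo", "a"), each = n / 2)
  y <- -3 - 2 * (arm == "a") + 0.4 * (bl - mean(bl)) + rnorm(n, sd = 2)
  ds <- make_dataset(as.integer(bl), arm, visits = c(week8 = 8L),
                     totals = data.frame(subject = seq_len(n), visit = "week8",
                                         total = as.integer(round(bl + y))))
  fit <- mmrm_fit(ds)
  d <- build_design(ds, mmrm_spec())
  ols <- lm(d$y ~ 0 + d$X)
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(unname(fit$Sigma[1, 1]),
               sum(resid(ols)^2) / (n - ncol(d$X)), tolerance = 1e-6)
  expect_equal(unname(sqrt(diag(fit$vcov_beta))),
               unname(sqrt(diag(vcov(ols)))), tolerance = 1e-6)
})

test_that("T=1 weighted fit equals closed-form weighted least squares", {
  set.seed(62)
  n <- 20
  bl <- sample(20:28, n, replace = TRUE)
  arm <- rep(c("placebo", "a"), each = n / 2)
  tot <- as.integer(pmax(round(bl - 5 + rnorm(n, sd = 3)), 0))
  ds <- make_dataset(as.integer(bl), arm, visits = c(week8 = 8L),
                     totals = data.frame(subject = seq_len(n),
                                         visit = "week8", total = tot))
  w <- runif(n, 0.3, 4)
  d <- build_design(ds, mmrm_spec())
  fit <- mmrm_fit(d, weights = w)
  wls <- lm(d$y ~ 0 + d$X, weights = w)
  expect_equal(unname(fit$beta), unname(coef(wls)), tolerance = 1e-8)
})

test_that("common weights reproduce the unweighted analysis exactly", {
  gen <- make_instance(71, n_per_arm = 10, T_ = 3, complete = FALSE)
  d <- build_design(gen$dataset, mmrm_spec())
  f0 <- mmrm_fit(d)
  fc <- mmrm_fit(d, weights = rep(3.7, length(d$subject_id)))
  expect_lt(max(abs(f0$beta - fc$beta)), 1e-10)
  expect_lt(max(abs(f0$vcov_beta - fc$vcov_beta)), 1e-10)
})

test_that("REML solution matches the dense generic-optimizer oracle on small instances", {
  for (seed in c(101, 102, 103)) {
    gen <- make_instance(seed, n_per_arm = 7, T_ = 3,
                         complete = seed %% 2 == 0)
    d <- build_design(gen$dataset, mmrm_spec())
    w <- withr::with_seed(seed, runif(length(d$subject_id), 0.5, 2))
    fit <- mmrm_fit(d, weights = w)
    orc <- oracle_reml(d, w)
    expect_lt(abs(fit$reml_loglik - orc$reml_loglik), 1e-6)
    expect_lt(max(abs(fit$beta - orc$beta)), 1e-6)
    # the dense evaluation at the package's Sigma agrees with the package's
    # own objective value
    dens <- dense_neg2reml(fit$Sigma, d, w)
    expect_equal(dens$value, fit$neg2_reml, tolerance = 1e-8)
    expect_gt(min(eigen(fit$Sigma, symmetric = TRUE)$values), 0)
  }
})

test_that("complete balanced data: final-visit contrast equals per-visit ANCOVA", {
  gen <- make_instance(81, n_per_arm = 15, T_ = 3, complete = TRUE)
  ds <- gen$dataset
  fit <- mmrm_fit(ds)
  te <- treatment_effect(fit, "active", visit = "week8")
  cb <- change_from_baseline(ds, "week8")
  df <- data.frame(y = cb, arm = ds$subjects$arm,
                   bl = ds$subjects$baseline_total)
  anc <- lm(y ~ arm + bl, data = df)
  expect_equal(te$te, unname(coef(anc)["armplacebo"]) * -1, tolerance = 1e-8)
})

test_that("LS means: limiting cases and the GLS prediction oracle", {
  # intercept-only model (one arm, one visit, no baseline covariate):
  # the LS mean is the weighted grand mean
  n <- 10
  tot <- as.integer(c(20, 22, 18, 25, 24, 19, 21, 23, 20, 22))
  ds <- make_dataset(rep(24L, n), rep("placebo", n), visits = c(week8 = 8L),
                     totals = data.frame(subject = 1:n, visit = "week8",
                                         total = tot))
  w <- seq(0.5, 5, length.out = n)
  fit <- mmrm_fit(build_design(ds, mmrm_spec(baseline_covariate = FALSE)),
                  weights = w, spec = mmrm_spec(baseline_covariate = FALSE))
  lsm <- ls_means(fit, "week8")
  expect_equal(lsm$lsmean, weighted.mean(tot - 24, w), tolerance = 1e-8)

  # seeded fit: LS means equal the GLS prediction c'beta with beta from the
  # dense oracle at the fitted covariance
  gen <- make_instance(91, n_per_arm = 8, T_ = 3, complete = FALSE)
  d <- build_design(gen$dataset, mmrm_spec())
  fit2 <- mmrm_fit(d)
  dens <- dense_neg2reml(fit2$Sigma, d, rep(1, length(d$subject_id)))
  lsm2 <- ls_means(fit2, "week8")
  pl <- dens$beta[match("visit.week8", colnames(d$X))]
  ac <- pl + dens$beta[match("active:week8", colnames(d$X))]
  expect_equal(lsm2$lsmean[lsm2$arm == "placebo"], unname(pl), tolerance = 1e-6)
  expect_equal(lsm2$lsmean[lsm2$arm == "active"], unname(ac), tolerance = 1e-6)
  expect_true(all(lsm2$se > 0))
  expect_error(ls_means(fit2, "week99"), "not in the model")
})

test_that("treatment effect of an arm against itself is exactly null", {
  gen <- make_instance(95, n_per_arm = 6)
  fit <- mmrm_fit(gen$dataset)
  te <- treatment_effect(fit, "placebo", "placebo")
  expect_equal(te$te, 0)
  expect_equal(te$p, 1)
  expect_equal(te$effect_size, 0)
  expect_error(treatment_effect(fit, "nonexistent"), "arm")
})

test_that("effect size follows the pooled-SD reconstruction", {
  expect_equal(effect_size(2, 1, 2, 2), 2)
  expect_equal(effect_size(1, 0.5, 50, 50), 0.4)
  expect_equal(effect_size(0, 1, 10, 10), 0)
  expect_equal(effect_size(-3, 1.5, 100, 100), 3 * sqrt(0.02) / 1.5)
  expect_error(effect_size(1, 0, 10, 10), "positive")
  expect_error(effect_size(1, 1, 0, 10), ">= 1")
})

test_that("Satterthwaite df is plausible and the residual switch works", {
  gen <- make_instance(97, n_per_arm = 10, T_ = 2, complete = FALSE)
  fit_s <- mmrm_fit(gen$dataset, spec = mmrm_spec(df_method = "satterthwaite"))
  fit_r <- mmrm_fit(gen$dataset, spec = mmrm_spec(df_method = "residual"))
  te_s <- treatment_effect(fit_s, "active")
  te_r <- treatment_effect(fit_r, "active")
  expect_equal(te_r$df, fit_r$n_obs_used - length(fit_r$beta))
  expect_gt(te_s$df, 1)
  expect_lt(te_s$df, te_r$df + 1e-9)   # Satterthwaite never exceeds residual here
  expect_equal(te_s$te, te_r$te)       # the point estimate is df-free
})

test_that("unweighted REML agrees with nlme::gls under corSymm/varIdent", {
  skip_if_not_installed("nlme")
  gen <- make_instance(121, n_per_arm = 12, T_ = 3, complete = FALSE)
  d <- build_design(gen$dataset, mmrm_spec())
  fit <- mmrm_fit(d)
  gdf <- data.frame(y = d$y, subj = factor(d$subj), v = factor(d$visit_idx),
                    check.names = FALSE)
  X <- d$X; colnames(X) <- make.names(colnames(X))
  gdf <- cbind(gdf, as.data.frame(X))
  fm <- stats::as.formula(paste("y ~ 0 +", paste(colnames(X), collapse = "+")))
  g <- nlme::gls(fm, data = gdf,
                 correlation = nlme::corSymm(form = ~ as.integer(v) | subj),
                 weights = nlme::varIdent(form = ~ 1 | v), method = "REML",
                 control = nlme::glsControl(msMaxIter = 200,
                                            tolerance = 1e-10))
  expect_lt(max(abs(coef(g) - fit$beta)), 1e-4)
  expect_lt(abs(as.numeric(logLik(g)) - fit$reml_loglik), 1e-4)
  expect_lt(max(abs(sqrt(diag(g$varBeta)) - sqrt(diag(fit$vcov_beta)))), 1e-4)
})
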