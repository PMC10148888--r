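# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check.

# Exhaustive Mann-Whitney pair count: (#{pos>neg} + 0.5 #{pos==neg}) / (n1 n0)
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Central finite-difference gradient of the MLP loss in all weights/biases
mlp_fd_gradient <- function(model, X, y, loss, l2, h = 1e-6) {
  f <- function(m) pwmmrm:::mlp_loss_grad(m, X, y, loss, l2,
                                          want_grad = FALSE)$loss
  gW <- lapply(model$W, function(w) array(0, dim(w)))
  gb <- lapply(model$b, function(b) numeric(length(b)))
  for (l in seq_along(model$W)) {
    for (k in seq_along(model$W[[l]])) {
      mp <- model; mm <- model
      mp$W[[l]][k] <- mp$W[[l]][k] + h
      mm$W[[l]][k] <- mm$W[[l]][k] - h
      gW[[l]][k] <- (f(mp) - f(mm)) / (2 * h)
    }
    for (k in seq_along(model$b[[l]])) {
      mp <- model; mm <- model
      mp$b[[l]][k] <- mp$b[[l]][k] + h
      mm$b[[l]][k] <- mm$b[[l]][k] - h
      gb[[l]][k] <- (f(mp) - f(mm)) / (2 * h)
    }
  }
  list(gW = gW, gb = gb)
}

# Dense-matrix -2 REML log-likelihood: builds the full block-diagonal V
# and uses generic determinant()/solve() calls only.
dense_neg2reml <- function(Sigma, design, w) {
  X <- design$X; y <- design$y
  N <- length(y); p <- ncol(X)
  V <- matrix(0, N, N)
  for (i in seq_along(design$subject_id)) {
    rows <- which(design$subj == i)
    obs <- design$visit_idx[rows]
    V[rows, rows] <- Sigma[obs, obs, drop = FALSE] / w[i]
  }
  Vi <- solve(V)
  B <- t(X) %*% Vi %*% X
  beta <- solve(B, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  val <- as.numeric(determinant(V)$modulus) +
    as.numeric(determinant(B)$modulus) +
    as.numeric(t(r) %*% Vi %*% r) + (N - p) * log(2 * pi)
  list(value = val, beta = as.vector(beta))
}

# Generic-optimizer REML oracle: parameterizes Sigma by log-variances and
# atanh-correlations (a different parameterization from the package's
# log-Cholesky) and minimizes the dense objective with derivative-free
# Nelder-Mead followed by finite-difference BFGS polish.
oracle_reml <- function(design, w = rep(1, length(design$subject_id))) {
  T_ <- length(design$visits)
  ncor <- T_ * (T_ - 1) / 2
  par_to_sigma <- function(par) {
    v <- exp(par[seq_len(T_)])
    R <- diag(T_)
    if (ncor > 0) {
      R[lower.tri(R)] <- tanh(par[T_ + seq_len(ncor)])
      R[upper.tri(R)] <- t(R)[upper.tri(R)]
    }
    diag(sqrt(v), T_) %*% R %*% diag(sqrt(v), T_)
  }
  fn <- function(par) {
    S <- par_to_sigma(par)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-10)
      return(1e10)
    tryCatch(dense_neg2reml(S, design, w)$value, error = function(e) 1e10)
  }
  # scale-aware start: per-visit sample variances of the response
  v0 <- vapply(seq_len(T_), function(v) {
    yy <- design$y[design$visit_idx == v]
    max(stats::var(yy), 0.5)
  }, numeric(1))
  par0 <- c(log(v0), rep(0, ncor))
  if (length(par0) > 1)
    par0 <- stats::optim(par0, fn, method = "Nelder-Mead",
                         control = list(maxit = 4000, reltol = 1e-14))$par
  opt <- stats::optim(par0, fn, method = "BFGS",
                      control = list(maxit = 400, reltol = 1e-14,
                                     ndeps = rep(1e-5, length(par0))))
  S <- par_to_sigma(opt$par)
  res <- dense_neg2reml(S, design, w)
  list(Sigma = S, beta = res$beta, neg2 = res$value,
       reml_loglik = -res$value / 2)
}

# Small seeded trial instances for MMRM checks
make_instance <- function(seed, n_per_arm = 8, T_ = 3, complete = TRUE) {
  wk <- switch(T_, `1` = 8L, `2` = c(4L, 8L), c(2L, 4L, 8L))
  cfg <- sim_config(arm_sizes = c(active = n_per_arm, placebo = n_per_arm),
                    visit_weeks = as.integer(wk),
                    drug_effect = c(active = -3),
                    dropout_hazard = if (complete) 0 else 0.12)
  generate_trial(cfg, seed = seed)
}
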