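#' Training configuration for the placebo-response perceptron
#'
#' Training is deterministic full-batch gradient descent with an Armijo
#' backtracking line search, so a seed fixes the whole trajectory. The
#' loss defaults to binary cross-entropy (sum-of-squares is selectable);
#' an L2 penalty on the connection weights regularizes the small-sample
#' fits typical of a single placebo arm.
#'
#' @param loss `"cross-entropy"` or `"sum-of-squares"`.
#' @param max_epochs maximum gradient steps (>= 0; 0 returns the seeded
#'   initial network untouched).
#' @param tol convergence tolerance on the absolute loss change per epoch.
#' @param l2 L2 penalty coefficient on weights (not biases).
#' @param seed integer seed for weight initialization.
#' @return A `train_config` list.
#' @export
train_config <- function(loss = c("cross-entropy", "sum-of-squares"),
                         max_epochs = 500L, tol = 1e-9, l2 = 1e-4,
                         seed = 1L) {
  loss <- match.arg(loss)
  if (tol <= 0) stopf("tol must be > 0")
  if (max_epochs < 0) stopf("max_epochs must be >= 0")
  structure(list(loss = loss, max_epochs = as.integer(max_epochs),
                 tol = tol, l2 = l2, seed = as.integer(seed)),
            class = "train_config")
}

# seeded initial network: logistic hidden + logistic output layers
mlp_init <- function(n_in, hidden, seed) {
  sizes <- c(n_in, hidden, 1L)
  with_seed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      r <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
      W[[l]] <- matrix(stats::runif(sizes[l + 1L] * sizes[l], -r, r),
                       sizes[l + 1L], sizes[l])
      b[[l]] <- rep(0, sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

new_mlp <- function(W, b, center, scale, layer_sizes, trace = numeric(0),
                    converged = NA) {
  structure(list(W = W, b = b, center = center, scale = scale,
                 layer_sizes = layer_sizes, trace = trace,
                 converged = converged),
            class = "pwmmrm_mlp")
}

#' @export
print.pwmmrm_mlp <- function(x, ...) {
  cat(sprintf("<pwmmrm_mlp> layers %s, %d epochs trained%s\n",
              paste(x$layer_sizes, collapse = "-"), length(x$trace),
              if (isTRUE(x$converged)) " (converged)" else ""))
  invisible(x)
}

# forward pass on a raw (unstandardized) feature matrix; returns the
# activations of every layer (needed by backprop)
mlp_forward_full <- function(model, X) {
  X <- as.matrix(X)
  if (ncol(X) != model$layer_sizes[1])
    stopf("input has %d features; network expects %d", ncol(X),
          model$layer_sizes[1])
  A <- list(sweep(sweep(X, 2, model$center), 2, model$scale, "/"))
  for (l in seq_along(model$W))
    A[[l + 1L]] <- logistic(tcrossprod(A[[l]], model$W[[l]]) +
                              rep(model$b[[l]], each = nrow(X)))
  A
}

#' Forward pass: predicted placebo-response probability
#'
#' @param object a trained `pwmmrm_mlp`.
#' @param newdata matrix of item changes (one row per subject) or a
#'   [trial_dataset()] (item changes are computed for all subjects).
#' @param ... unused.
#' @return Numeric vector of probabilities strictly in (0,1).
#' @export
predict.pwmmrm_mlp <- function(object, newdata, ...) {
  if (inherits(newdata, "trial_dataset")) newdata <- item_changes(newdata)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  A <- mlp_forward_full(object, newdata)
  drop(A[[length(A)]])
}

# loss and analytic gradient (backpropagation) at the model's weights.
# Returns list(loss, gW, gb). y in {0,1}; X raw features.
mlp_loss_grad <- function(model, X, y, loss = "cross-entropy", l2 = 0,
                          want_grad = TRUE) {
  n <- nrow(X)
  A <- mlp_forward_full(model, X)
  L <- length(model$W)
  p <- drop(A[[L + 1L]])
  eps <- 1e-12
  data_loss <- if (loss == "cross-entropy") {
    -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
  } else mean((p - y)^2) / 2
  pen <- l2 / 2 * sum(vapply(model$W, function(w) sum(w^2), numeric(1)))
  out <- list(loss = data_loss + pen)
  if (!want_grad) return(out)
  # output-layer delta; logistic derivative cancels for cross-entropy
  delta <- if (loss == "cross-entropy") matrix((p - y) / n, ncol = 1)
  else matrix((p - y) * p * (1 - p) / n, ncol = 1)
  gW <- vector("list", L); gb <- vector("list", L)
  for (l in L:1) {
    gW[[l]] <- crossprod(delta, A[[l]]) + l2 * model$W[[l]]
    gb[[l]] <- colSums(delta)
    if (l > 1)
      delta <- (delta %*% model$W[[l]]) * A[[l]] * (1 - A[[l]])
  }
  out$gW <- gW; out$gb <- gb
  out
}

flatten_par <- function(W, b) c(unlist(W), unlist(b))

#' Train the placebo-response multilayer perceptron
#'
#' Fits a network of 1-3 logistic hidden layers mapping standardized
#' screening-to-baseline item changes to the probability of end-of-study
#' placebo response, by full-batch gradient descent with backtracking line
#' search on the configured loss. Inputs are standardized with
#' training-set statistics stored in the model.
#'
#' @param X matrix of item changes (rows: subjects).
#' @param y binary response labels (0/1), both classes present.
#' @param hidden integer vector of hidden-layer sizes (length 1-3).
#' @param cfg a [train_config()].
#' @return A `pwmmrm_mlp` with the per-epoch loss trace in `$trace`.
#' @export
train_mlp <- function(X, y, hidden, cfg = train_config()) {
  X <- as.matrix(X); y <- as.numeric(y)
  if (nrow(X) < 2) stopf("need at least 2 subjects")
  if (length(unique(y)) < 2)
    stopf("training labels contain a single class; cannot train",
          class = "pwmmrm_single_label_error")
  if (length(hidden) < 1 || length(hidden) > 3 || any(hidden < 1))
    stopf("hidden must give 1-3 positive layer sizes")
  center <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  init <- mlp_init(ncol(X), as.integer(hidden), cfg$seed)
  model <- new_mlp(init$W, init$b, center, scl,
                   c(ncol(X), as.integer(hidden), 1L))
  if (cfg$max_epochs == 0L) { model$converged <- FALSE; return(model) }

  g <- mlp_loss_grad(model, X, y, cfg$loss, cfg$l2)
  f0 <- g$loss
  trace <- numeric(cfg$max_epochs)
  step <- 1
  converged <- FALSE
  for (ep in seq_len(cfg$max_epochs)) {
    if (!is.finite(g$loss))
      stopf("non-finite loss at epoch %d (divergence)", ep,
            class = "pwmmrm_divergence_error")
    gnorm2 <- sum(flatten_par(g$gW, g$gb)^2)
    if (gnorm2 < 1e-20) { trace <- trace[seq_len(ep - 1)]; converged <- TRUE; break }
    # Armijo backtracking from an expanding trial step
    step <- min(step * 2, 1e3)
    accepted <- FALSE
    while (step > 1e-14) {
      cand <- model
      for (l in seq_along(model$W)) {
        cand$W[[l]] <- model$W[[l]] - step * g$gW[[l]]
        cand$b[[l]] <- model$b[[l]] - step * g$gb[[l]]
      }
      fc <- mlp_loss_grad(cand, X, y, cfg$loss, cfg$l2, want_grad = FALSE)$loss
      if (is.finite(fc) && fc <= f0 - 1e-4 * step * gnorm2) {
        accepted <- TRUE; break
      }
      step <- step / 2
    }
    if (!accepted) { trace <- trace[seq_len(ep - 1)]; converged <- TRUE; break }
    model <- cand
    trace[ep] <- fc
    if (abs(f0 - fc) < cfg$tol) {
      trace <- trace[seq_len(ep)]; converged <- TRUE; f0 <- fc; break
    }
    f0 <- fc
    g <- mlp_loss_grad(model, X, y, cfg$loss, cfg$l2)
    if (ep == cfg$max_epochs) trace <- trace[seq_len(ep)]
  }
  model$trace <- trace
  model$converged <- converged
  model
}

#' Serialize a trained network to JSON
#'
#' Stores topology, input-standardization constants and row-major weight
#' matrices; [mlp_from_json()] restores an identical predictor.
#'
#' @param model a `pwmmrm_mlp`.
#' @param path output path; `NULL` returns the JSON string.
#' @export
mlp_to_json <- function(model, path = NULL) {
  doc <- list(layer_sizes = model$layer_sizes, center = model$center,
              scale = model$scale,
              weights = lapply(model$W, function(w)
                list(nrow = nrow(w), ncol = ncol(w),
                     data = as.vector(t(w)))),
              biases = model$b)
  js <- jsonlite::toJSON(doc, auto_unbox = FALSE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' @rdname mlp_to_json
#' @param json JSON string or path produced by [mlp_to_json()].
#' @export
mlp_from_json <- function(json) {
  if (file.exists(json)) json <- paste(readLines(json), collapse = "")
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  Wraw <- doc$weights
  if (is.data.frame(Wraw))
    Wraw <- lapply(seq_len(nrow(Wraw)), function(i)
      list(nrow = Wraw$nrow[i], ncol = Wraw$ncol[i], data = Wraw$data[[i]]))
  W <- lapply(Wraw, function(x)
    matrix(unlist(x$data), unlist(x$nrow), unlist(x$ncol), byrow = TRUE))
  b <- if (is.matrix(doc$biases))
    lapply(seq_len(nrow(doc$biases)), function(i) doc$biases[i, ])
  else if (is.list(doc$biases)) doc$biases else list(doc$biases)
  new_mlp(W, b, doc$center, doc$scale, doc$layer_sizes)
}
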