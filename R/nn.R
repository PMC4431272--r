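# Single-hidden-layer neural network classifier: 6 inputs (one per muscle),
# one hidden layer of 8 tanh units, 9 logistic output units f(s) =
# 1 / (1 + exp(-mu * s)) against one-of-k targets, sum-of-squares loss.
# Training uses full-batch BFGS with analytic gradients and seeded
# initialization, so identical data and seed give identical weights.

nn_unpack <- function(par, d, h, k) {
  i <- 0
  w1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  w2 <- matrix(par[i + seq_len(h * k)], h, k); i <- i + h * k
  b2 <- par[i + seq_len(k)]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

nn_forward <- function(w, x, mu) {
  hpre <- sweep(x %*% w$w1, 2, w$b1, "+")
  hact <- tanh(hpre)
  spre <- sweep(hact %*% w$w2, 2, w$b2, "+")
  list(h = hact, f = 1 / (1 + exp(-mu * spre)))
}

#' Train the neural-network motion classifier
#'
#' @param features numeric matrix, one row per example, one column per
#'   channel (6 for the canonical muscle set).
#' @param labels integer motion codes in 1..9, one per row.
#' @param seed integer seed for weight initialization (training is
#'   deterministic given the seed).
#' @param config list of options: `hidden` (hidden units, default 8),
#'   `mu` (output sigmoid slope, default 1), `epochs` (maximum BFGS
#'   iterations, default 300), `tol` (relative convergence tolerance,
#'   default 1e-10).
#' @return an `nn_model` with layer weights, input standardization
#'   constants, `mu` and `training_meta` (epochs used, final loss, seed,
#'   training accuracy).
#' @export
nn_train <- function(features, labels, seed = 1, config = list()) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  if (nrow(x) != length(labels)) stop("one label per feature row required",
                                      call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("degenerate-training error: need at least two classes",
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop("input error: non-finite feature values",
                               call. = FALSE)
  h <- config$hidden %||% 8L
  mu <- config$mu %||% 1
  epochs <- config$epochs %||% 300L
  tol <- config$tol %||% 1e-10
  k <- 9L
  d <- ncol(x)
  center <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scl, "/")
  y <- matrix(0, nrow(x), k)
  y[cbind(seq_len(nrow(x)), labels)] <- 1

  n <- nrow(xs)
  loss <- function(par) {
    w <- nn_unpack(par, d, h, k)
    f <- nn_forward(w, xs, mu)$f
    sum((y - f)^2) / n
  }
  grad <- function(par) {
    w <- nn_unpack(par, d, h, k)
    fw <- nn_forward(w, xs, mu)
    delta2 <- 2 * (fw$f - y) * mu * fw$f * (1 - fw$f) / n
    gw2 <- crossprod(fw$h, delta2)
    gb2 <- colSums(delta2)
    delta1 <- (delta2 %*% t(w$w2)) * (1 - fw$h^2)
    gw1 <- crossprod(xs, delta1)
    gb1 <- colSums(delta1)
    c(as.numeric(gw1), gb1, as.numeric(gw2), gb2)
  }

  set.seed(seed)
  par0 <- stats::rnorm(d * h + h + h * k + k, sd = 0.5)
  fit <- stats::optim(par0, loss, grad, method = "BFGS",
                      control = list(maxit = epochs, reltol = tol))
  w <- nn_unpack(fit$par, d, h, k)
  model <- structure(
    list(hidden_weights = w$w1, hidden_bias = w$b1,
         output_weights = w$w2, output_bias = w$b2,
         mu = mu, center = center, scale = scl,
         training_meta = list(epochs = fit$counts[["function"]],
                              final_loss = fit$value, seed = seed)),
    class = "nn_model")
  model$training_meta$train_accuracy <-
    accuracy(nn_predict(model, x)$label, labels)$accuracy
  model
}

#' Predict motions with a trained neural network
#'
#' Forward pass (standardize, tanh hidden layer, logistic outputs); the
#' predicted class is the argmax of the 9 output activations, ties broken by
#' the lowest class code.
#'
#' @param model an `nn_model` from [nn_train()].
#' @param x numeric vector (one example) or matrix (one row per example)
#'   with the training dimensionality.
#' @return list with `label` (integer codes) and `scores` (matrix of output
#'   activations, one row per example).
#' @export
nn_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != length(model$center)) {
    stop("input error: expected ", length(model$center),
         "-dimensional input", call. = FALSE)
  }
  if (any(!is.finite(x))) stop("input error: non-finite input", call. = FALSE)
  xs <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  w <- list(w1 = model$hidden_weights, b1 = model$hidden_bias,
            w2 = model$output_weights, b2 = model$output_bias)
  scores <- nn_forward(w, xs, model$mu)$f
  list(label = as.integer(apply(scores, 1, which.max)), scores = scores)
}
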