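# Support vector machine trained by sequential minimal optimization (SMO).
# The binary trainer is a full Platt-style SMO: it repeatedly picks a pair
# of Lagrange multipliers violating the KKT conditions, solves the
# two-variable dual subproblem analytically, and maintains an output cache
# so each step costs O(n). Multiclass reduction is one-vs-one with majority
# voting (36 machines for 9 classes), the LIBSVM convention.

#' Kernel specification
#'
#' @param type `"rbf"` or `"linear"`.
#' @param gamma RBF width; `NULL` (default) means `1 / (d * mean per-feature
#'   variance)` computed from the training data.
#' @return a `kernel_spec` list.
#' @export
kernel_spec <- function(type = c("rbf", "linear"), gamma = NULL) {
  type <- match.arg(type)
  structure(list(type = type, gamma = gamma), class = "kernel_spec")
}

kernel_matrix <- function(kernel, x, y = x) {
  x <- as.matrix(x); y <- as.matrix(y)
  lin <- x %*% t(y)
  if (kernel$type == "linear") return(lin)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * lin
  exp(-kernel$gamma * pmax(d2, 0))
}

resolve_gamma <- function(kernel, x) {
  if (kernel$type == "rbf" && is.null(kernel$gamma)) {
    v <- mean(apply(x, 2, stats::var))
    if (!is.finite(v) || v <= 0) v <- 1
    kernel$gamma <- 1 / (ncol(x) * v)
  }
  kernel
}

# Platt SMO on a precomputed kernel matrix. t in {-1, +1}. Returns alpha, b
# and the number of two-variable steps taken.
smo_solve <- function(kmat, t, c_penalty, tol = 1e-3, max_passes = 200) {
  n <- length(t)
  alpha <- numeric(n)
  b <- 0
  fcache <- numeric(n)  # f_i = sum_j alpha_j t_j K_ij (decision minus b)
  eps <- 1e-12
  steps <- 0L

  take_step <- function(i1, i2) {
    if (i1 == i2) return(FALSE)
    a1 <- alpha[i1]; a2 <- alpha[i2]
    y1 <- t[i1]; y2 <- t[i2]
    e1 <- fcache[i1] + b - y1
    e2 <- fcache[i2] + b - y2
    s <- y1 * y2
    if (s > 0) {
      lo <- max(0, a1 + a2 - c_penalty); hi <- min(c_penalty, a1 + a2)
    } else {
      lo <- max(0, a2 - a1); hi <- min(c_penalty, c_penalty + a2 - a1)
    }
    if (lo >= hi) return(FALSE)
    k11 <- kmat[i1, i1]; k22 <- kmat[i2, i2]; k12 <- kmat[i1, i2]
    eta <- k11 + k22 - 2 * k12
    if (eta > 0) {
      a2new <- a2 + y2 * (e1 - e2) / eta
      a2new <- min(max(a2new, lo), hi)
    } else {
      # degenerate curvature: evaluate the objective at both clip bounds
      f1 <- y1 * (e1 + b) - a1 * k11 - s * a2 * k12
      f2 <- y2 * (e2 + b) - s * a1 * k12 - a2 * k22
      l1 <- a1 + s * (a2 - lo); h1 <- a1 + s * (a2 - hi)
      lobj <- l1 * f1 + lo * f2 + 0.5 * l1^2 * k11 + 0.5 * lo^2 * k22 +
        s * lo * l1 * k12
      hobj <- h1 * f1 + hi * f2 + 0.5 * h1^2 * k11 + 0.5 * hi^2 * k22 +
        s * hi * h1 * k12
      a2new <- if (lobj < hobj - eps) lo else if (lobj > hobj + eps) hi else a2
    }
    if (abs(a2new - a2) < eps * (a2new + a2 + eps)) return(FALSE)
    a1new <- a1 + s * (a2 - a2new)
    d1 <- y1 * (a1new - a1); d2 <- y2 * (a2new - a2)
    b1 <- b - e1 - d1 * k11 - d2 * k12
    b2 <- b - e2 - d1 * k12 - d2 * k22
    bnew <- if (a1new > 0 && a1new < c_penalty) b1
      else if (a2new > 0 && a2new < c_penalty) b2
      else (b1 + b2) / 2
    alpha[i1] <<- a1new
    alpha[i2] <<- a2new
    fcache <<- fcache + d1 * kmat[, i1] + d2 * kmat[, i2]
    b <<- bnew
    steps <<- steps + 1L
    TRUE
  }

  examine <- function(i2) {
    y2 <- t[i2]; a2 <- alpha[i2]
    e2 <- fcache[i2] + b - y2
    r2 <- e2 * y2
    if (!((r2 < -tol && a2 < c_penalty) || (r2 > tol && a2 > 0))) {
      return(FALSE)
    }
    nb <- which(alpha > 0 & alpha < c_penalty)
    if (length(nb) > 1) {
      err <- fcache[nb] + b - t[nb]
      i1 <- nb[which.max(abs(err - e2))]
      if (take_step(i1, i2)) return(TRUE)
    }
    for (i1 in nb) if (take_step(i1, i2)) return(TRUE)
    for (i1 in seq_len(n)) if (take_step(i1, i2)) return(TRUE)
    FALSE
  }

  num_changed <- 0L
  examine_all <- TRUE
  pass <- 0L
  while ((num_changed > 0 || examine_all) && pass < max_passes) {
    pass <- pass + 1L
    num_changed <- 0L
    cand <- if (examine_all) seq_len(n) else
      which(alpha > 0 & alpha < c_penalty)
    for (i in cand) num_changed <- num_changed + examine(i)
    examine_all <- if (examine_all) FALSE else num_changed == 0
  }
  list(alpha = alpha, b = b, steps = steps)
}

#' Dual objective of a binary SVM
#'
#' `L(a) = sum(a) - 0.5 * sum_{n,m} a_n a_m t_n t_m k(x_n, x_m)`, the
#' quantity SMO maximizes subject to `0 <= a <= c` and `sum(a * t) = 0`.
#'
#' @param alpha dual coefficients.
#' @param t labels in `{-1, +1}`.
#' @param kmat kernel matrix.
#' @return scalar objective value.
#' @export
svm_dual_objective <- function(alpha, t, kmat) {
  at <- alpha * t
  sum(alpha) - 0.5 * as.numeric(t(at) %*% kmat %*% at)
}

#' Train a binary SVM by SMO
#'
#' @param features numeric matrix, one row per example.
#' @param t labels in `{-1, +1}`.
#' @param kernel a [kernel_spec()].
#' @param c_penalty box constraint c > 0 (default 1).
#' @param tol KKT violation tolerance (default 1e-3).
#' @return a `svm_binary` list: `sv` (support vectors), `coef`
#'   (`alpha_n * t_n` for support vectors), `bias`, `alpha` (full vector),
#'   `kernel`, `c_penalty`, `dual_objective`, `steps`.
#' @export
svm_train_binary <- function(features, t, kernel = kernel_spec(),
                             c_penalty = 1, tol = 1e-3) {
  x <- as.matrix(features)
  t <- as.numeric(t)
  if (!all(t %in% c(-1, 1)) || length(unique(t)) < 2) {
    stop("degenerate-training error: need both classes in {-1, +1}",
         call. = FALSE)
  }
  if (c_penalty <= 0) stop("c_penalty must be positive", call. = FALSE)
  kernel <- resolve_gamma(kernel, x)
  kmat <- kernel_matrix(kernel, x)
  fit <- smo_solve(kmat, t, c_penalty, tol = tol)
  sv_idx <- which(fit$alpha > 1e-12)
  structure(
    list(sv = x[sv_idx, , drop = FALSE], coef = fit$alpha[sv_idx] * t[sv_idx],
         bias = fit$b, alpha = fit$alpha, sv_index = sv_idx,
         kernel = kernel, c_penalty = c_penalty,
         dual_objective = svm_dual_objective(fit$alpha, t, kmat),
         steps = fit$steps),
    class = "svm_binary")
}

#' Decision values of a binary SVM
#'
#' Evaluates `y(x) = sum_n a_n t_n k(x, x_n) + b` over the support vectors.
#'
#' @param model a `svm_binary`.
#' @param x vector or matrix of inputs.
#' @return numeric decision value per input row.
#' @export
svm_decision <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (nrow(model$sv) == 0) return(rep(model$bias, nrow(x)))
  as.numeric(kernel_matrix(model$kernel, x, model$sv) %*% model$coef +
               model$bias)
}

#' Train the multiclass SVM motion classifier
#'
#' One-vs-one reduction: one binary SMO-trained machine per unordered class
#' pair (36 machines for all 9 motion classes), combined by majority voting.
#'
#' @param features numeric matrix, one row per example.
#' @param labels integer motion codes in 1..9.
#' @param kernel a [kernel_spec()] (default RBF with data-driven gamma).
#' @param c_penalty box constraint (default 1).
#' @param tol SMO KKT tolerance (default 1e-3).
#' @return an `svm_model`: `machines` (per-pair binary models referencing
#'   rows of `sv`), `sv` (unique support vectors across machines),
#'   `classes`, `n_support` (unique support vector count = kernel
#'   evaluations per prediction), `kernel`, `c_penalty`.
#' @export
svm_train <- function(features, labels, kernel = kernel_spec(),
                      c_penalty = 1, tol = 1e-3) {
  x <- as.matrix(features)
  labels <- as.integer(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2) {
    stop("degenerate-training error: need at least two classes",
         call. = FALSE)
  }
  kernel <- resolve_gamma(kernel, x)
  pairs <- utils::combn(classes, 2)
  machines <- vector("list", ncol(pairs))
  sv_rows <- integer(0)
  for (p in seq_len(ncol(pairs))) {
    ci <- pairs[1, p]; cj <- pairs[2, p]
    idx <- which(labels == ci | labels == cj)
    t <- ifelse(labels[idx] == ci, 1, -1)
    fit <- svm_train_binary(x[idx, , drop = FALSE], t, kernel = kernel,
                            c_penalty = c_penalty, tol = tol)
    machines[[p]] <- list(pos = ci, neg = cj, bias = fit$bias,
                          coef = fit$coef, rows = idx[fit$sv_index],
                          dual_objective = fit$dual_objective)
    sv_rows <- union(sv_rows, idx[fit$sv_index])
  }
  sv_rows <- sort(sv_rows)
  for (p in seq_along(machines)) {
    machines[[p]]$sv_pos <- match(machines[[p]]$rows, sv_rows)
    machines[[p]]$rows <- NULL
  }
  structure(
    list(machines = machines, sv = x[sv_rows, , drop = FALSE],
         classes = classes, n_support = length(sv_rows),
         kernel = kernel, c_penalty = c_penalty),
    class = "svm_model")
}

#' Predict motions with a trained SVM
#'
#' Evaluates every one-vs-one machine's decision function over the shared
#' support-vector kernel row (`n_support` kernel evaluations per input) and
#' votes; vote ties are broken by the lowest class code. A positive decision
#' votes for the pair's first (lower-coded) class.
#'
#' @param model an `svm_model` from [svm_train()].
#' @param x numeric vector (one example) or matrix (rows = examples).
#' @return list with `label` (integer codes), `votes` (matrix, one column
#'   per class) and `kernel_evals` (kernel evaluations per prediction loop,
#'   equal to `model$n_support`).
#' @export
svm_predict <- function(model, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != ncol(model$sv)) {
    stop("input error: expected ", ncol(model$sv), "-dimensional input",
         call. = FALSE)
  }
  if (any(!is.finite(x))) stop("input error: non-finite input", call. = FALSE)
  votes <- matrix(0L, nrow(x), 9)
  # chunked so the input-by-support-vector kernel block stays bounded
  chunk <- max(1L, floor(4e6 / max(model$n_support, 1)))
  for (start in seq(1, nrow(x), by = chunk)) {
    rows <- start:min(start + chunk - 1, nrow(x))
    kx <- kernel_matrix(model$kernel, x[rows, , drop = FALSE], model$sv)
    for (m in model$machines) {
      dec <- as.numeric(kx[, m$sv_pos, drop = FALSE] %*% m$coef + m$bias)
      winner <- ifelse(dec > 0, m$pos, m$neg)
      for (cl in unique(winner)) {
        sel <- rows[winner == cl]
        votes[sel, cl] <- votes[sel, cl] + 1L
      }
    }
  }
  list(label = as.integer(apply(votes, 1, which.max)), votes = votes,
       kernel_evals = model$n_support)
}
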