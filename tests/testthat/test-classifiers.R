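# Classifiers: single-hidden-layer NN and SMO-trained SVM.

test_that("nn_train separates well-separated classes deterministically", {
  blobs <- make_blobs(40, c(1, 4, 9), seed = 60)
  m1 <- nn_train(blobs$x, blobs$y, seed = 7)
  expect_gte(m1$training_meta$train_accuracy, 0.99)
  expect_equal(dim(m1$hidden_weights), c(6, 8))
  expect_equal(dim(m1$output_weights), c(8, 9))

  m2 <- nn_train(blobs$x, blobs$y, seed = 7)
  expect_identical(m1$hidden_weights, m2$hidden_weights)
  expect_identical(m1$output_weights, m2$output_weights)

  expect_error(nn_train(blobs$x, rep(3, nrow(blobs$x))),
               "degenerate-training error")
  bad <- blobs$x
  bad[1, 1] <- Inf
  expect_error(nn_train(bad, blobs$y), "input error")
})

test_that("nn_predict computes the documented sigmoid chain", {
  # hand-built 2-input model, identity standardization
  model <- structure(list(
    hidden_weights = matrix(c(1, -1), 2, 1),
    hidden_bias = 0.5,
    output_weights = matrix(c(2, -1, 0, 0, 0, 0, 0, 0, 0), 1, 9),
    output_bias = rep(0.1, 9),
    mu = 2, center = c(0, 0), scale = c(1, 1),
    training_meta = list()), class = "nn_model")
  x <- c(0.3, -0.2)
  h <- tanh(0.3 * 1 + (-0.2) * (-1) + 0.5)
  s <- h * c(2, -1, rep(0, 7)) + 0.1
  expect_equal(as.numeric(nn_predict(model, x)$scores),
               1 / (1 + exp(-2 * s)), tolerance = 1e-12)
  expect_equal(nn_predict(model, x)$label, 1L)

  # f(0) = 0.5 for any mu; all-zero weights -> uniform scores, lowest code
  zero <- model
  zero$hidden_weights[] <- 0
  zero$hidden_bias <- 0
  zero$output_weights[] <- 0
  zero$output_bias <- rep(0, 9)
  for (mu in c(0.5, 1, 4)) {
    zero$mu <- mu
    out <- nn_predict(zero, c(1.7, -0.4))
    expect_true(all(out$scores == 0.5))
    expect_equal(out$label, 1L)
  }

  expect_error(nn_predict(model, c(1, 2, 3)), "input error")
  # pure function: repeated calls agree
  expect_identical(nn_predict(model, x), nn_predict(model, x))
})

test_that("SMO recovers the analytic max-margin solution", {
  x <- rbind(c(0, 0), c(2, 2))
  fit <- svm_train_binary(x, c(-1, 1), kernel_spec("linear"),
                          c_penalty = 1e6, tol = 1e-6)
  # margin boundary x1 + x2 = 2: w = (0.5, 0.5), alpha = 0.25 each, b = -1
  expect_equal(fit$alpha, c(0.25, 0.25), tolerance = 1e-6)
  expect_equal(fit$bias, -1, tolerance = 1e-6)
  expect_equal(nrow(fit$sv), 2)
  expect_equal(svm_decision(fit, c(1, 1)), 0, tolerance = 1e-6)
  expect_equal(svm_decision(fit, c(2, 2)), 1, tolerance = 1e-6)
  expect_error(svm_train_binary(x, c(1, 1)), "degenerate-training error")
})

test_that("SMO matches the projected-gradient QP oracle on small problems", {
  set.seed(61)
  for (trial in 1:6) {
    n <- sample(8:20, 1)
    x <- matrix(rnorm(n * 3), n, 3)
    t <- sign(rnorm(n))
    if (all(t == t[1])) t[1] <- -t[1]
    kern <- if (trial %% 2 == 0) kernel_spec("linear") else
      kernel_spec("rbf", gamma = 0.5)
    c_pen <- sample(c(0.5, 1, 10), 1)
    fit <- svm_train_binary(x, t, kern, c_penalty = c_pen, tol = 1e-5)
    kmat <- emgmotion:::kernel_matrix(emgmotion:::resolve_gamma(kern, x), x)
    oracle <- qp_oracle(kmat, t, c_pen)
    expect_equal(fit$dual_objective, oracle$objective, tolerance = 1e-4)
    # support sets agree on all non-negligible multipliers: membership may
    # only differ where both solvers put (near-)zero weight
    disagree <- xor(fit$alpha > 1e-4, oracle$alpha > 1e-4)
    expect_true(all(pmax(fit$alpha, oracle$alpha)[disagree] < 0.02 * c_pen))
    # dual feasibility
    expect_lt(abs(sum(fit$alpha * t)), 1e-8)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= c_pen + 1e-12))
  }
})

test_that("SMO handles contradictory labels with slack", {
  x <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  t <- c(1, -1, 1, -1)
  fit <- svm_train_binary(x, t, kernel_spec("linear"), c_penalty = 0.5,
                          tol = 1e-5)
  kmat <- emgmotion:::kernel_matrix(kernel_spec("linear"), x)
  oracle <- qp_oracle(kmat, t, 0.5)
  expect_equal(fit$dual_objective, oracle$objective, tolerance = 1e-4)
  expect_true(any(fit$alpha >= 0.5 - 1e-9))  # slack forces bound multipliers
})

test_that("SMO dual objective beats random feasible points", {
  set.seed(62)
  n <- 12
  x <- matrix(rnorm(n * 2), n, 2)
  t <- rep(c(-1, 1), 6)
  c_pen <- 1
  kern <- kernel_spec("rbf", gamma = 1)
  fit <- svm_train_binary(x, t, kern, c_penalty = c_pen, tol = 1e-5)
  kmat <- emgmotion:::kernel_matrix(kern, x)
  objs <- vapply(1:1000, function(i) {
    a <- project_dual_feasible(runif(n, 0, c_pen), t, c_pen)
    svm_dual_objective(a, t, kmat)
  }, numeric(1))
  expect_true(all(objs <= fit$dual_objective + 1e-6))
})

test_that("multiclass SVM: one machine per pair, voting, tie-break", {
  blobs <- make_blobs(25, 1:9, sep = 8, seed = 63)
  model <- svm_train(blobs$x, blobs$y)
  expect_equal(length(model$machines), 36)  # 9 * 8 / 2
  pred <- svm_predict(model, blobs$x)
  expect_gte(accuracy(pred$label, blobs$y)$accuracy, 0.99)
  expect_equal(pred$kernel_evals, model$n_support)
  # pure function
  expect_identical(svm_predict(model, blobs$x[1, ]),
                   svm_predict(model, blobs$x[1, ]))
  expect_error(svm_train(blobs$x, rep(5, nrow(blobs$x))),
               "degenerate-training error")
  expect_error(svm_predict(model, c(1, 2)), "input error")
})

test_that("support-vector count grows with training-set size", {
  counts <- vapply(c(30, 90, 240), function(n) {
    blobs <- make_blobs(n, c(1, 2, 3), sep = 1.2, sd = 1, seed = 64)
    svm_train(blobs$x, blobs$y)$n_support
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("svm decision arithmetic matches hand evaluation", {
  # hand-built 2-SV linear machine
  model <- structure(list(
    sv = rbind(c(1, 0), c(0, 1)), coef = c(0.7, -0.4), bias = 0.2,
    kernel = kernel_spec("linear")), class = "svm_binary")
  x <- c(2, 3)
  expect_equal(svm_decision(model, x),
               0.7 * (2 * 1) - 0.4 * (3 * 1) + 0.2, tolerance = 1e-12)
  # all-zero duals -> decision = bias
  zero <- model
  zero$coef <- c(0, 0)
  expect_equal(svm_decision(zero, x), 0.2)
  # duplicating a support vector with half its coefficient changes nothing
  dup <- model
  dup$sv <- rbind(c(1, 0), c(1, 0), c(0, 1))
  dup$coef <- c(0.35, 0.35, -0.4)
  expect_equal(svm_decision(dup, x), svm_decision(model, x),
               tolerance = 1e-12)
})
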