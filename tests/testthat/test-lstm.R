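zero_params <- function(d, H) {
  p <- lstm_params(d, H, seed = 1)
  for (nm in c("Ui", "Wi", "Uf", "Wf", "Uo", "Wo", "Ug", "Wg")) p[[nm]] <- p[[nm]] * 0
  p
}

test_that("the zero-weight step has its closed form", {
  set.seed(1)
  p <- zero_params(3, 4)
  x <- matrix(stats::rnorm(2 * 3), 2, 3)
  prev <- list(h = matrix(stats::rnorm(8), 2, 4), tout = matrix(stats::rnorm(8), 2, 4))
  st <- lstm_step(x, prev, p)
  expect_equal(st$tout, 0.5 * prev$tout, tolerance = 1e-12)
  expect_equal(st$h, 0.5 * tanh(st$tout), tolerance = 1e-12)
})

test_that("gate outputs and hidden states stay in their ranges", {
  set.seed(2)
  p <- lstm_params(5, 4, seed = 3)
  st <- NULL
  x <- matrix(stats::rnorm(6 * 5), 6, 5)
  for (k in 1:5) st <- lstm_step(x, st, p)
  expect_true(all(abs(st$h) < 1))
})

test_that("a scalar oracle reproduces the step and the error sequence", {
  for (s in 1:5) {
    p <- lstm_params(1, 1, seed = 100 + s)
    set.seed(200 + s)
    x <- stats::rnorm(1)
    res <- run_until_converged(matrix(x, 1, 1), p, tol = 1e-12, max_iter = 40)
    orc <- oracle_lstm_scalar(x, p, res$iterations)
    expect_equal(res$e_trace, orc$e_trace, tolerance = 1e-10)
    expect_equal(res$tout[1, 1], orc$tout, tolerance = 1e-10)
  }
})

test_that("variance-literal gates vanish on constant pre-activations", {
  p <- lstm_params(2, 3, activation = "variance_literal", seed = 1)
  # identical columns make every row's pre-activation vector constant,
  # so the dispersion gate is exactly 0 and the cell output dies
  for (nm in c("Ui", "Uf", "Uo", "Ug")) p[[nm]] <- matrix(0.3, 2, 3)
  for (nm in c("Wi", "Wf", "Wo", "Wg")) p[[nm]] <- matrix(0.1, 3, 3)
  st <- lstm_step(matrix(c(1, -2), 1, 2), NULL, p)
  expect_equal(st$tout, matrix(0, 1, 3))
  expect_equal(st$h, matrix(0, 1, 3))
})

test_that("iteration on zero input from zero state converges immediately", {
  p <- lstm_params(3, 2, seed = 5)
  res <- run_until_converged(matrix(0, 1, 3), p, tol = 0.01)
  expect_true(res$converged)
  expect_identical(res$iterations, 1L)
  expect_equal(res$e, 0)
})

test_that("tolerance-terminated runs end below the convergence threshold", {
  for (s in 1:5) {
    p <- lstm_params(4, 3, seed = 300 + s)
    set.seed(s)
    res <- run_until_converged(matrix(stats::rnorm(4), 1, 4), p, tol = 0.01, max_iter = 200)
    if (res$converged) expect_lt(res$e, 0.01)
  }
  expect_error(run_until_converged(matrix(0, 1, 3), lstm_params(3, 2), tol = -1), "tol")
})

test_that("analytic gradients match finite differences", {
  set.seed(9)
  x <- matrix(stats::rnorm(6 * 3), 6, 3)
  labels <- rep(1:2, 3)
  loss_at <- function(p, head) {
    fw <- behavrec:::.lstm_forward_cache(x, p, 2)
    logits <- fw$h %*% head$w + matrix(head$b, 6, 2, byrow = TRUE)
    post <- behavrec:::softmax_rows(logits)
    -mean(log(post[cbind(1:6, labels)]))
  }
  p <- lstm_params(3, 2, seed = 10)
  head <- list(w = matrix(stats::rnorm(4, sd = 0.2), 2, 2), b = c(0.1, -0.2))
  fw <- behavrec:::.lstm_forward_cache(x, p, 2)
  logits <- fw$h %*% head$w + matrix(head$b, 6, 2, byrow = TRUE)
  post <- behavrec:::softmax_rows(logits)
  y <- matrix(0, 6, 2)
  y[cbind(1:6, labels)] <- 1
  g <- behavrec:::.lstm_backward(x, p, fw, (post - y) / 6, head)
  eps <- 1e-6
  for (nm in c("Ui", "Wf", "Ug", "Wo")) {
    p2 <- p
    p2[[nm]][1, 1] <- p2[[nm]][1, 1] + eps
    num <- (loss_at(p2, head) - loss_at(p, head)) / eps
    expect_equal(g[[nm]][1, 1], num, tolerance = 1e-4)
  }
  h2 <- head
  h2$w[1, 1] <- h2$w[1, 1] + eps
  expect_equal(g$w[1, 1], (loss_at(p, h2) - loss_at(p, head)) / eps, tolerance = 1e-4)
})

test_that("training separates a linearly separable two-class problem", {
  set.seed(42)
  n <- 40
  x <- rbind(
    matrix(stats::rnorm(n * 2, mean = 2, sd = 0.3), n, 2),
    matrix(stats::rnorm(n * 2, mean = -2, sd = 0.3), n, 2)
  )
  labels <- rep(1:2, each = n)
  m <- train_classifier(x, labels, hidden_dim = 4, learning_rate = 0.5, epochs = 200, seed = 1)
  expect_lte(length(m$history), 200L)
  pred <- predict_classes(m, x)
  expect_gte(mean(pred$class == labels), 0.99)
})

test_that("a head-only fit decreases the loss monotonically at a small step size", {
  set.seed(43)
  x <- matrix(stats::rnorm(30 * 3), 30, 3)
  labels <- sample(1:3, 30, replace = TRUE)
  m <- train_classifier(x, labels,
    hidden_dim = 3, learning_rate = 0.01,
    epochs = 80, head_only = TRUE, seed = 2
  )
  expect_true(all(diff(m$history) <= 1e-10))
})

test_that("shuffled labels yield chance-level held-out accuracy", {
  set.seed(44)
  x <- matrix(stats::rnorm(300 * 4), 300, 4)
  labels <- sample(rep(1:3, each = 100))
  m <- train_classifier(x[1:150, ], labels[1:150],
    hidden_dim = 4,
    learning_rate = 0.2, epochs = 150, weight_decay = 0.05, seed = 3
  )
  acc <- mean(predict_classes(m, x[151:300, ])$class == labels[151:300])
  expect_lt(abs(acc - 1 / 3), 0.1)
})

test_that("training rejects degenerate inputs", {
  x <- matrix(stats::rnorm(20), 10, 2)
  expect_error(train_classifier(x, rep(1L, 10)), "2 classes")
  expect_error(predict_classes(
    train_classifier(x, rep(1:2, 5), epochs = 2),
    matrix(0, 2, 5)
  ), "input_dim")
})

test_that("the softmax head is normalised, shift-invariant and ties to the lowest index", {
  model <- structure(
    list(
      params = lstm_params(2, 2, seed = 1), head = list(w = matrix(0, 2, 3), b = rep(0, 3)),
      n_steps = 2L, n_classes = 3L, effect_map = 1:3
    ),
    class = "lstm_model"
  )
  pred <- predict_classes(model, matrix(stats::rnorm(10), 5, 2))
  expect_equal(unname(as.matrix(pred[, 1:3])), matrix(1 / 3, 5, 3), tolerance = 1e-9)
  expect_true(all(pred$class == 1L)) # exact tie -> lowest index
  expect_equal(rowSums(pred[, 1:3]), rep(1, 5), tolerance = 1e-9)

  set.seed(8)
  model$head$w <- matrix(stats::rnorm(6), 2, 3)
  p1 <- predict_classes(model, matrix(stats::rnorm(10), 5, 2))
  model2 <- model
  model2$head$b <- model$head$b + 7.3 # constant logit shift
  set.seed(8)
  x <- matrix(stats::rnorm(10), 5, 2)
  expect_equal(
    as.matrix(predict_classes(model, x)[, 1:3]),
    as.matrix(predict_classes(model2, x)[, 1:3]),
    tolerance = 1e-9
  )
})

test_that("seeded training is bitwise reproducible", {
  set.seed(55)
  x <- matrix(stats::rnorm(60), 20, 3)
  labels <- rep(1:2, 10)
  m1 <- train_classifier(x, labels, epochs = 30, seed = 9)
  m2 <- train_classifier(x, labels, epochs = 30, seed = 9)
  expect_identical(m1, m2)
})
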