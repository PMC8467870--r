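test_that("the logistic response hits its analytic points", {
  expect_equal(logistic_h(c(1, 0, 0), c(0, 0, 0)), 0.5)
  expect_equal(logistic_h(c(1, 0, 0), c(log(3), 0, 0)), 0.75)
  # saturation without overflow
  expect_equal(logistic_h(c(1, 0, 0), c(40, 0, 0)), 1, tolerance = 1e-12)
  expect_lt(logistic_h(c(1, 0, 0), c(30, 0, 0)), 1)
  expect_gt(logistic_h(c(1, 0, 0), c(30, 0, 0)), 1 - 1e-12)
  expect_gt(logistic_h(c(1, 0, 0), c(-700, 0, 0)), 0)
  expect_lte(logistic_h(c(1, 0, 0), c(700, 0, 0)), 1)
  expect_error(logistic_h(c(1, 0), c(0, 0, 0)), "dimension")
})

test_that("the cost is ln 2 at zero and matches a per-row loop", {
  set.seed(1)
  P <- cbind(1, matrix(runif(50 * 4), 50, 4))
  y <- rbinom(50, 1, 0.5)
  beta0 <- numeric(5)
  expect_equal(meta_cost(P, y, beta0), log(2), tolerance = 1e-12)
  beta <- rnorm(5)
  loop <- 0
  for (j in 1:50) {
    h <- logistic_h(P[j, ], beta)
    loop <- loop - (y[j] * log(h) + (1 - y[j]) * log(1 - h)) / 50
  }
  expect_equal(meta_cost(P, y, beta), loop, tolerance = 1e-12)
  # near-perfect predictions drive the cost to zero
  ysep <- c(rep(0, 25), rep(1, 25))
  Psep <- cbind(1, c(rep(-1, 25), rep(1, 25)))
  expect_lt(meta_cost(Psep, ysep, c(0, 50)), 1e-10)
  expect_error(meta_cost(P[0, , drop = FALSE], integer(0), beta0), "empty")
})

test_that("gradient descent recovers known coefficients", {
  set.seed(2)
  beta_true <- c(-0.8, 1.5, -2.0, 0.7)
  M <- 1e5
  X <- cbind(1, matrix(rnorm(M * 3), M, 3))
  y <- rbinom(M, 1, logistic_h(X, beta_true))
  fit <- fit_meta(X, y, tol = 1e-8)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - beta_true) / abs(beta_true)), 0.05)
  # first-order optimality at the solution
  h <- logistic_h(X, fit$beta)
  expect_lt(max(abs(crossprod(X, h - y) / M)), 1e-8)
})

test_that("gradient descent agrees with the IRLS oracle", {
  set.seed(3)
  M <- 4000
  X <- cbind(1, matrix(rnorm(M * 3), M, 3))
  y <- rbinom(M, 1, logistic_h(X, c(0.3, -1, 0.6, 1.2)))
  fit <- fit_meta(X, y, tol = 1e-10)
  or <- glm.fit(X, y, family = binomial())
  expect_lt(max(abs(fit$beta - or$coefficients)), 1e-4)
})

test_that("descent never increases the cost and rejects one-class data", {
  set.seed(4)
  P <- cbind(1, matrix(rnorm(80 * 2), 80, 2))
  y <- as.integer(P[, 2] + 0.3 * rnorm(80) > 0)
  fit <- fit_meta(P, y, max_iter = 500)
  expect_lte(fit$cost, log(2))  # start was beta = 0
  expect_error(fit_meta(P, rep(1, 80)), "both classes")
  # duplicating every row leaves the objective (and optimum) unchanged
  fit2 <- fit_meta(rbind(P, P), c(y, y), max_iter = 500)
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-6)
})

test_that("stacked inputs assemble and decide at the strict 0.5 rule", {
  set.seed(5)
  n <- 10
  mk <- function() { p <- runif(n); cbind(1 - p, p) }
  P <- meta_input(list(mk(), mk(), mk(), mk()))
  expect_equal(dim(P), c(n, 9L))
  expect_true(all(P[, 1] == 1))
  expect_error(meta_input(list(matrix(0.5, 2, 3))), "n x 2")
  bad <- cbind(runif(n), runif(n))
  expect_error(meta_input(list(bad)), "sum to 1")
  # h = 0.5 exactly -> normal (label 0); just above -> arousal
  dec <- predict_meta(rbind(c(1, 0), c(1, 0.08)), c(0, 0.5))
  expect_equal(dec$probability[1], 0.5)
  expect_identical(dec$label, c(0L, 1L))
  # decisions depend on p'beta only
  expect_identical(predict_meta(P, rep(0.1, 9))$label,
                   predict_meta(2 * P, rep(0.05, 9))$label)
})

test_that("rank-deficient stacked designs still converge to a minimum", {
  set.seed(6)
  n <- 400
  truth <- rbinom(n, 1, 0.45)
  noisy <- function(sd) {
    p <- pmin(pmax(truth + rnorm(n, 0, sd), 0.02), 0.98)
    cbind(1 - p, p)
  }
  P <- meta_input(list(noisy(0.3), noisy(0.35), noisy(0.25), noisy(0.4)))
  fit <- fit_meta(P, truth, max_iter = 2e4)
  expect_lt(fit$cost, meta_cost(P, truth, numeric(9)))
  acc <- mean(predict_meta(P, fit$beta)$label == truth)
  expect_gt(acc, 0.8)
})
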