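test_that("the CAR precision matches the hand-computed 3-cell path and rejects bad parameters", {
  path3 <- grid_lattice(c(0, 0, 3, 1), 1)
  W <- adjacency_matrix(path3)
  Q <- as.matrix(car_precision(W, 0.5, 1))
  expect_equal(unname(Q),
               rbind(c(1, -0.5, 0), c(-0.5, 2, -0.5), c(0, -0.5, 1)))
  expect_true(all(eigen(Q, symmetric = TRUE, only.values = TRUE)$values > 0))
  # small lambda approaches the diagonal tau * D
  Q0 <- as.matrix(car_precision(W, 1e-9, 2))
  expect_equal(unname(diag(Q0)), c(2, 4, 2))
  expect_lt(max(abs(Q0[upper.tri(Q0)])), 1e-8)

  expect_error(car_precision(W, 1.2, 1), "lambda")
  expect_error(car_precision(W, 0.5, -1), "tau")
})

test_that("the CAR precision is positive definite across random lattices and parameters", {
  set.seed(402)
  for (rep in seq_len(200)) {
    lat <- random_small_lattice(80)
    W <- adjacency_matrix(lat, sample(c("rook", "queen"), 1))
    Q <- car_precision(W, runif(1, 1e-3, 1 - 1e-3), exp(runif(1, -2, 2)))
    expect_error(Matrix::Cholesky(Q, LDL = FALSE), NA)
  }
})

test_that("the sparse CAR log-density equals the dense multivariate-normal oracle", {
  set.seed(403)
  for (rep in seq_len(25)) {
    lat <- random_small_lattice(100)
    W <- adjacency_matrix(lat)
    lambda <- runif(1, 0.05, 0.95)
    tau <- exp(runif(1, -1, 1))
    g <- rnorm(lat$n_cells)
    expect_equal(car_logpdf(g, W, lambda, tau),
                 dense_car_logpdf(g, W, lambda, tau), tolerance = 1e-8)
  }
})

test_that("the CAR log-density at zero reduces to the normalising constant and scales with tau", {
  lat <- grid_lattice(c(0, 0, 4, 3), 1)
  W <- adjacency_matrix(lat)
  n <- lat$n_cells
  Q <- car_precision(W, 0.7, 1.3)
  ld <- as.numeric(determinant(as.matrix(Q), logarithm = TRUE)$modulus)
  expect_equal(car_logpdf(rep(0, n), W, 0.7, 1.3),
               -n / 2 * log(2 * pi) + ld / 2, tolerance = 1e-10)
  g <- rnorm(n)
  expect_equal(car_logpdf(g, W, 0.7, 4 * 1.3) - car_logpdf(g, W, 0.7, 1.3),
               dense_car_logpdf(g, W, 0.7, 4 * 1.3) -
                 dense_car_logpdf(g, W, 0.7, 1.3), tolerance = 1e-8)
})

test_that("logistic process probabilities behave at the anchors", {
  expect_equal(process_probability(c(1, 0.5), c(1, 2), -2), 0.5)
  expect_equal(process_probability(c(1, 1), c(0, 0), 0), 0.5)
  expect_equal(process_probability(c(1, 1), c(500, 500), 0), 1)
  expect_error(process_probability(c(1, 1, 1), c(1, 2), 0), "columns")
})

test_that("the mixture is convex in its arguments", {
  expect_equal(mixture_probability(0.3, 0.9, 1), 0.3)
  expect_equal(mixture_probability(0.3, 0.9, 0), 0.9)
  expect_equal(mixture_probability(0.2, 0.6, 0.5), 0.4)
  set.seed(404)
  p <- runif(200); s <- runif(200); a <- runif(200)
  q <- mixture_probability(p, s, a)
  expect_true(all(q >= pmin(p, s) - 1e-12 & q <= pmax(p, s) + 1e-12))
  expect_error(mixture_probability(0.5, 0.5, 1.2), "alpha")
})

test_that("the joint log-posterior equals an independently coded sum of terms", {
  set.seed(405)
  lat <- grid_lattice(c(0, 0, 2, 2), 1)
  W <- adjacency_matrix(lat)
  n <- 4
  De <- cbind(1, rnorm(n)); Da <- cbind(1, rnorm(n))
  y <- c(1L, 0L, NA, 1L); yc <- c(0L, 1L, 1L, NA)
  dat <- model_data(list(y), yc, De, Da, W, normalize = FALSE)
  pars <- model_params(list(c(0.3, -0.6)), c(0.1, 0.8), 0.7, 0.4, 1.2,
                       rnorm(n))
  pr <- po_priors(beta_var = 100)

  # oracle: every term written out directly
  p_i <- plogis(De %*% c(0.3, -0.6) + pars$G)[, 1]
  s <- plogis(Da %*% c(0.1, 0.8) + pars$G)[, 1]
  q <- 0.7 * p_i + 0.3 * s
  ll <- sum(dbinom(y[!is.na(y)], 1, q[!is.na(y)], log = TRUE)) +
    sum(dbinom(yc[!is.na(yc)], 1, s[!is.na(yc)], log = TRUE))
  prior <- dense_car_logpdf(pars$G, W, 0.4, 1.2) +
    sum(dnorm(c(0.3, -0.6, 0.1, 0.8), 0, 10, log = TRUE)) +
    dbeta(0.7, 5, 5, log = TRUE) + dbeta(0.4, 5, 5, log = TRUE) +
    dgamma(1.2, 1, rate = 0.01, log = TRUE)
  expect_equal(joint_log_posterior(pars, dat, pr), ll + prior,
               tolerance = 1e-10)
})

test_that("removing one observed cell changes the log-posterior by exactly its Bernoulli term", {
  set.seed(406)
  lat <- grid_lattice(c(0, 0, 3, 1), 1)
  W <- adjacency_matrix(lat)
  De <- cbind(1, rnorm(3)); Da <- cbind(1, rnorm(3))
  pars <- model_params(list(c(0.2, 0.4)), c(-0.1, 0.3), 0.6, 0.5, 1,
                       rnorm(3))
  y_full <- c(1L, 1L, 0L); yc <- c(0L, 1L, 0L)
  d1 <- model_data(list(y_full), yc, De, Da, W, normalize = FALSE)
  y_drop <- y_full; y_drop[2] <- NA
  d2 <- model_data(list(y_drop), yc, De, Da, W, normalize = FALSE)
  p2 <- plogis(sum(De[2, ] * c(0.2, 0.4)) + pars$G[2])
  s2 <- plogis(sum(Da[2, ] * c(-0.1, 0.3)) + pars$G[2])
  q2 <- 0.6 * p2 + 0.4 * s2
  expect_equal(joint_log_posterior(pars, d1) - joint_log_posterior(pars, d2),
               log(q2), tolerance = 1e-12)
})

test_that("the log-posterior is invariant to a consistent permutation of the cells", {
  set.seed(407)
  lat <- grid_lattice(c(0, 0, 3, 3), 1)
  W <- adjacency_matrix(lat)
  n <- 9
  De <- cbind(1, rnorm(n)); Da <- cbind(1, rnorm(n))
  y <- sample(c(0L, 1L, NA), n, replace = TRUE)
  yc <- sample(c(0L, 1L), n, replace = TRUE)
  pars <- model_params(list(c(0.3, -0.2)), c(0, 0.5), 0.5, 0.6, 0.8,
                       rnorm(n))
  d1 <- model_data(list(y), yc, De, Da, W, normalize = FALSE)
  perm <- sample(n)
  d2 <- model_data(list(y[perm]), yc[perm], De[perm, ], Da[perm, ],
                   W[perm, perm], normalize = FALSE)
  p2 <- pars; p2$G <- pars$G[perm]
  expect_equal(joint_log_posterior(pars, d1), joint_log_posterior(p2, d2),
               tolerance = 1e-10)
})

test_that("conflicting degenerate probabilities give -Inf, not an error", {
  lat <- grid_lattice(c(0, 0, 2, 1), 1)
  W <- adjacency_matrix(lat)
  De <- cbind(c(1, 1)); Da <- cbind(c(1, 1))
  dat <- model_data(list(c(1L, 1L)), c(0L, 0L), De, Da, W, normalize = FALSE)
  # alpha = 1 and a hugely negative intercept force Q = 0 against y = 1
  pars <- model_params(list(-2000), 0, 1, 0.5, 1, c(0, 0))
  expect_identical(joint_log_posterior(pars, dat), -Inf)
})
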