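test_that("CAR field draws are zero-centred with the prescribed covariance", {
  lat <- grid_lattice(c(0, 0, 2, 2), 1)
  W <- adjacency_matrix(lat)
  g <- simulate_car_field(W, 0.8, 1, n = 50000, seed = 81)
  emp <- cov(t(g))
  Q <- as.matrix(car_precision(W, 0.8, 1))
  expect_lt(max(abs(rowMeans(g))), 0.02)
  expect_lt(max(abs(emp - solve(Q))), 0.05)

  lat3 <- grid_lattice(c(0, 0, 3, 3), 1)
  g3 <- simulate_car_field(adjacency_matrix(lat3), 0.5, 2, n = 10000,
                           seed = 82)
  expect_lt(max(abs(rowMeans(g3))), 0.03)
})

test_that("field draws are reproducible from the seed", {
  lat <- grid_lattice(c(0, 0, 5, 5), 1)
  W <- adjacency_matrix(lat)
  expect_identical(simulate_car_field(W, 0.9, 1, seed = 7),
                   simulate_car_field(W, 0.9, 1, seed = 7))
})

test_that("simulated covariates have intercepts, reproduce under a seed, and smoothing adds spatial correlation", {
  X <- simulate_covariates(50, r = 2, s = 3, seed = 9)
  expect_equal(ncol(X$D_e), 3L)
  expect_equal(ncol(X$D_a), 4L)
  expect_true(all(X$D_e[, 1] == 1))
  expect_identical(X, simulate_covariates(50, r = 2, s = 3, seed = 9))

  lat <- grid_lattice(c(0, 0, 12, 12), 1)
  W <- adjacency_matrix(lat)
  d <- Matrix::rowSums(W)
  moran <- function(v) {
    v <- v - mean(v)
    (length(v) / sum(d)) * as.numeric(t(v) %*% W %*% v) / sum(v^2)
  }
  raw <- simulate_covariates(lat$n_cells, 1, 1, seed = 10)
  sm <- simulate_covariates(lat$n_cells, 1, 1, seed = 10, W = W,
                            smoothing = 3)
  # permutation null for the unsmoothed column
  set.seed(11)
  null <- replicate(200, moran(sample(raw$D_e[, 2])))
  expect_lt(abs(moran(raw$D_e[, 2])), max(abs(null)) + 0.05)
  expect_gt(moran(sm$D_e[, 2]), quantile(null, 0.999))
})

test_that("dataset generation honours the mixture limits and the missing-fraction contract", {
  lat <- grid_lattice(c(0, 0, 10, 10), 1)
  # alpha = 1 for all taxa and a hugely negative effort intercept:
  # y_c almost surely all zero while y is driven by P alone
  pars <- model_params(beta_p = list(c(0.5, 1, -1)),
                       beta_s = c(-30, 0.5, 0.5),
                       alpha = 1, lambda = 0.5, tau = 1, G = numeric(0))
  sim <- simulate_dataset(lat, pars, seed = 21)
  expect_equal(sum(sim$data$y_c), 0L)
  expect_equal(sim$latent$Q[, 1], sim$latent$P[, 1])

  expect_equal(sum(is.na(sim$data$y_c)), 0L)  # missing_frac = 0 regime
  sim2 <- simulate_dataset(lat, pars, seed = 21, missing_frac_yc = 0.3)
  expect_equal(sum(is.na(sim2$data$y_c)), 30L)
  expect_error(simulate_dataset(lat, pars, seed = 1, missing_frac_yc = 1),
               "missing fractions")
})

test_that("responses are Bernoulli draws at the stated probabilities", {
  lat <- grid_lattice(c(0, 0, 40, 40), 1)
  # constant Q: intercept-only signal, spatial field suppressed by huge tau
  pars <- model_params(beta_p = list(c(qlogis(0.3), 0, 0)),
                       beta_s = c(0, 0, 0),
                       alpha = 1, lambda = 0.5, tau = 1e8, G = numeric(0))
  sim <- simulate_dataset(lat, pars, seed = 31)
  expect_lt(abs(mean(sim$data$y[, 1]) - 0.3), 0.04)
  expect_lt(max(abs(sim$latent$Q[, 1] - 0.3)), 0.01)
})

test_that("latent mixtures always lie between suitability and effort", {
  for (seed in 1:5) {
    sim <- small_sim(seed = 40 + seed, alpha = c(runif(1), runif(1)))
    for (i in 1:2) {
      lo <- pmin(sim$latent$P[, i], sim$latent$S)
      hi <- pmax(sim$latent$P[, i], sim$latent$S)
      expect_true(all(sim$latent$Q[, i] >= lo - 1e-12 &
                        sim$latent$Q[, i] <= hi + 1e-12))
    }
  }
})

test_that("a simulation round-trips through its directory export losslessly", {
  sim <- small_sim(seed = 55, missing_frac_yc = 0.2)
  dir <- tempfile("simdir")
  write_simulation(sim, dir)
  back <- read_simulation(dir)
  expect_identical(back$data$y, sim$data$y)
  expect_identical(back$data$y_c, sim$data$y_c)
  expect_equal(back$data$D_e[[1]], sim$data$D_e[[1]], tolerance = 0)
  expect_equal(back$params$G, sim$params$G, tolerance = 0)
  expect_equal(back$latent$S, sim$latent$S, tolerance = 0,
               ignore_attr = TRUE)
  expect_equal(as.matrix(back$W), as.matrix(sim$W), ignore_attr = TRUE)
  expect_identical(back$seed, sim$seed)
  unlink(dir, recursive = TRUE)
})

test_that("covariate-dependent missingness hits the high-covariate cells", {
  lat <- grid_lattice(c(0, 0, 10, 10), 1)
  pars <- model_params(beta_p = list(c(0, 1, 0)), beta_s = c(0, 1, 0),
                       alpha = 0.5, lambda = 0.5, tau = 1, G = numeric(0))
  sim <- simulate_dataset(lat, pars, seed = 66, missing_frac_yc = 0.2,
                          missing_covariate = 1)
  miss <- is.na(sim$data$y_c)
  expect_gt(mean(sim$data$D_a[miss, 2]), mean(sim$data$D_a[!miss, 2]))
})

test_that("a genuine logistic recovery: regressing simulated effort on its design recovers beta_s", {
  lat <- grid_lattice(c(0, 0, 30, 30), 1)
  pars <- model_params(beta_p = list(c(0, 0.5, 0)), beta_s = c(0.4, 1, -0.7),
                       alpha = 1, lambda = 0.5, tau = 1e8, G = numeric(0))
  sim <- simulate_dataset(lat, pars, seed = 71)
  fitg <- glm(sim$data$y_c ~ sim$data$D_a[, 2] + sim$data$D_a[, 3],
              family = binomial())
  se <- sqrt(diag(vcov(fitg)))
  expect_true(all(abs(coef(fitg) - c(0.4, 1, -0.7)) < 3 * se))
})
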