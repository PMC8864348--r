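# minimal hand-built po_fit used for summary-convention tests
fake_fit <- function(chain_list, names) {
  structure(list(
    draws = lapply(chain_list, function(m) {
      m <- as.matrix(m); colnames(m) <- names; m
    }),
    param_names = names,
    diagnostics = data.frame(parameter = names,
                             rhat = NA_real_, n_eff = NA_real_,
                             stringsAsFactors = FALSE),
    converged = NA),
    class = "po_fit")
}

test_that("split R-hat separates mixed from unmixed chains", {
  expect_equal(rhat(cbind(rep(2, 100), rep(2, 100))), 1)  # constant draws
  set.seed(501)
  mixed <- cbind(rnorm(4000), rnorm(4000), rnorm(4000))
  expect_lt(rhat(mixed), 1.02)
  apart <- cbind(rnorm(200, -5), rnorm(200, 5))
  expect_gt(rhat(apart), 2)
  expect_error(rhat(matrix(rnorm(10), ncol = 1)), "2 chains")
  expect_error(rhat(matrix(rnorm(6), ncol = 2)), "4 draws")
})

test_that("effective sample size is near n for iid draws and collapses for sticky chains", {
  set.seed(502)
  iid <- matrix(rnorm(4000), ncol = 2)
  expect_gt(ess(iid), 2500)
  ar <- matrix(0, 2000, 1)
  for (t in 2:2000) ar[t] <- 0.97 * ar[t - 1] + rnorm(1)
  expect_lt(ess(ar), 400)
  expect_equal(ess(matrix(1, 50, 2)), 100)
})

test_that("posterior summaries use linearly interpolated percentiles and flag signed intervals", {
  f <- fake_fit(list(matrix(1:50, ncol = 1), matrix(51:100, ncol = 1)),
                "theta")
  s <- summarize_posterior(f, params = "theta")
  expect_equal(s$q2.5, 3.475)
  expect_equal(s$q50, 50.5)
  expect_equal(s$q97.5, 97.525)
  expect_true(s$significant)       # interval excludes 0

  f2 <- fake_fit(list(matrix(c(7, 7, 7, 7), ncol = 1),
                      matrix(c(7, 7, 7, 7), ncol = 1)), "c")
  s2 <- summarize_posterior(f2, params = "c")
  expect_equal(s2$mean, 7)
  expect_equal(s2$q2.5, 7)
  expect_equal(s2$q97.5, 7)

  f3 <- fake_fit(list(matrix(seq(-1, 1, length.out = 100), ncol = 1)), "z")
  expect_false(summarize_posterior(f3, params = "z")$significant)
})

test_that("with zero-information data the posterior returns the Beta(5,5) prior for alpha", {
  lat <- grid_lattice(c(0, 0, 4, 4), 1)
  n <- lat$n_cells
  dat <- model_data(list(rep(NA_integer_, n)), rep(NA_integer_, n),
                    matrix(rnorm(n), n, 1), matrix(rnorm(n), n, 1),
                    adjacency_matrix(lat), normalize = FALSE)
  fit <- suppressWarnings(
    fit_pojsdm(dat, po_priors(), quick_config(seed = 30, iterations = 3000,
                                              burn_in = 1000)))
  a <- do.call(rbind, fit$draws)[, "alpha[taxon_1]"]
  expect_equal(mean(a), 0.5, tolerance = 0.05)
  expect_lt(abs(var(a) - 25 / (100 * 11)), 0.005)
})

test_that("fits are bit-reproducible from the sampler seed", {
  sim <- small_sim(seed = 12, nx = 5)
  f1 <- suppressWarnings(fit_pojsdm(sim$data, po_priors(),
                                    quick_config(seed = 9, iterations = 300,
                                                 burn_in = 100)))
  f2 <- suppressWarnings(fit_pojsdm(sim$data, po_priors(),
                                    quick_config(seed = 9, iterations = 300,
                                                 burn_in = 100)))
  expect_identical(f1$draws, f2$draws)
  expect_identical(summarize_posterior(f1), summarize_posterior(f2))
})

test_that("imputation returns probabilities only for missing cells, all within [0, 1]", {
  sim <- small_sim(seed = 13, nx = 6, missing_frac_yc = 0.25)
  fit <- suppressWarnings(fit_pojsdm(sim$data, po_priors(),
                                     quick_config(seed = 14)))
  imp <- impute_missing(fit)
  expect_setequal(imp$cell[imp$response == "y_c"],
                  which(is.na(sim$data$y_c)))
  expect_true(all(imp$prob >= 0 & imp$prob <= 1))

  sim0 <- small_sim(seed = 15, nx = 5)
  fit0 <- suppressWarnings(fit_pojsdm(sim0$data, po_priors(),
                                      quick_config(seed = 16,
                                                   iterations = 300,
                                                   burn_in = 100)))
  expect_equal(nrow(impute_missing(fit0)), 0L)
})

test_that("a non-mixing run is returned flagged with a warning, never silently", {
  sim <- small_sim(seed = 17, nx = 5)
  # 60 iterations cannot mix: expect the flag to trip
  expect_warning(
    fit <- fit_pojsdm(sim$data, po_priors(),
                      fit_config(chains = 3, iterations = 60, burn_in = 20,
                                 thin = 1, seed = 2)),
    "not converged")
  expect_false(fit$converged)
  expect_s3_class(fit, "po_fit")
})

test_that("model data validation enforces shared dimensions and clean designs", {
  lat <- grid_lattice(c(0, 0, 2, 2), 1)
  W <- adjacency_matrix(lat)
  X <- matrix(rnorm(4), 4, 1)
  expect_error(model_data(list(c(0L, 1L)), rep(0L, 4), X, X, W), "n_cells")
  Xna <- X; Xna[1] <- NA
  expect_error(model_data(list(rep(0L, 4)), rep(0L, 4), Xna, X, W),
               "missing values")
  expect_error(model_data(list(rep(0L, 4)), rep(0L, 4), X, X, W[1:3, 1:3]),
               "dimension")
  d <- model_data(list(rep(0L, 4)), rep(1L, 4), X, X, W)
  expect_equal(colnames(d$D_e[[1]])[1], "(Intercept)")
  # normalisation standardises the covariate column
  expect_equal(mean(d$D_e[[1]][, 2]), 0, tolerance = 1e-12)
  expect_equal(sd(d$D_e[[1]][, 2]), 1, tolerance = 1e-12)
})
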