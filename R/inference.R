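#' MCMC sampler configuration
#'
#' Defaults follow the full-scale analysis protocol (4 chains, 35 000
#' iterations, burn-in 17 500, thinning 35); test-scale runs simply pass
#' smaller values.
#'
#' @param chains number of independent chains (>= 1; >= 2 for R-hat).
#' @param iterations iterations per chain.
#' @param burn_in warm-up iterations discarded (also the adaptation window
#'   of the proposal scales); must be < `iterations`.
#' @param thin keep every `thin`-th post-burn-in draw (>= 1).
#' @param seed integer seed controlling every source of randomness in the
#'   fit (initial values and proposals); identical seeds give identical
#'   posteriors.
#' @param field_sweeps number of single-site sweeps of the spatial field
#'   (each followed by the level-shift and amplitude moves) per iteration.
#'   The field is the slowest-mixing block; extra sweeps cost little
#'   relative to the coefficient updates and improve mixing of
#'   `lambda`/`tau`.
#' @param param_sweeps number of coefficient/mixing/CAR-parameter update
#'   sweeps per iteration, reducing the autocorrelation of the
#'   random-walk updates at a modest per-iteration cost.
#' @return an object of class `po_fit_config`.
#' @export
fit_config <- function(chains = 4, iterations = 35000, burn_in = 17500,
                       thin = 35, seed = 1, field_sweeps = 3,
                       param_sweeps = 3) {
  stopifnot(chains >= 1, iterations > 1, burn_in >= 0, burn_in < iterations,
            thin >= 1, field_sweeps >= 1, param_sweeps >= 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 seed = as.integer(seed),
                 field_sweeps = as.integer(field_sweeps),
                 param_sweeps = as.integer(param_sweeps)),
            class = "po_fit_config")
}

# neighbour list (0-based) of a sparse adjacency matrix, by column
.neighbour_list <- function(W) {
  W <- methods::as(methods::as(W, "CsparseMatrix"), "generalMatrix")
  n <- ncol(W)
  counts <- diff(W@p)
  unname(split(W@i, factor(rep(seq_len(n), counts), levels = seq_len(n))))
}

#' Fit the presence-only joint SDM by MCMC
#'
#' Samples the full posterior of all regression coefficients, mixing
#' weights, CAR parameters and the shared spatial field, by adaptive
#' Metropolis-within-Gibbs (single-site updates for the field, Gibbs for
#' `tau`, an exact level-shift move resolving the intercept/field
#' identifiability). Cells with missing responses contribute no likelihood
#' term — the exact marginal form of treating each missing Bernoulli outcome
#' as an augmented parameter — and their posterior presence probabilities
#' are recovered from the latent process draws by [impute_missing()].
#'
#' @param data a [model_data()] object.
#' @param priors a [po_priors()] object.
#' @param config a [fit_config()] object.
#' @param fix_alpha optional numeric vector (length `n_taxa`): fix taxon
#'   `i`'s mixing weight to `fix_alpha[i]`; `NA` entries stay free. Fixing
#'   all alphas at 1 with `y_c` fully missing reduces the model to
#'   independent spatial logistic regressions.
#' @return an object of class `po_fit`: per-chain draw matrices (columns
#'   named `beta_p[taxon,covariate]`, `beta_s[covariate]`, `alpha[taxon]`,
#'   `lambda`, `tau`, `G[cell]`), the configuration, per-parameter R-hat and
#'   effective sample size, and a `converged` flag (R-hat < 1.1 for every
#'   parameter). Non-converged fits are returned flagged, with a warning,
#'   never silently.
#' @export
fit_pojsdm <- function(data, priors = po_priors(), config = fit_config(),
                       fix_alpha = NULL) {
  stopifnot(inherits(data, "po_model_data"), inherits(priors, "po_priors"),
            inherits(config, "po_fit_config"))
  n <- data$n_cells
  W <- data$W
  deg <- Matrix::rowSums(W)
  if (any(deg == 0))
    stop("lattice has isolated cells (degree 0); the proper CAR precision ",
         "is singular there")
  dis <- 1 / sqrt(deg)
  Wn <- Matrix::Diagonal(x = dis) %*% W %*% Matrix::Diagonal(x = dis)
  evals <- eigen(as.matrix(Matrix::forceSymmetric(Wn)), symmetric = TRUE,
                 only.values = TRUE)$values
  nb <- .neighbour_list(W)

  if (is.null(fix_alpha)) fix_alpha <- rep(NA_real_, data$n_taxa)
  if (length(fix_alpha) != data$n_taxa)
    stop("'fix_alpha' must have one entry per taxon")
  alpha_fixed <- !is.na(fix_alpha)

  pe <- vapply(data$D_e, ncol, integer(1))
  pa <- ncol(data$D_a)
  param_names <- c(
    unlist(lapply(seq_len(data$n_taxa), function(i)
      sprintf("beta_p[%s,%s]", data$taxa[i], colnames(data$D_e[[i]])))),
    sprintf("beta_s[%s]", colnames(data$D_a)),
    sprintf("alpha[%s]", data$taxa),
    "lambda", "tau",
    sprintf("G[%d]", seq_len(n))
  )

  prior_list <- list(beta_var = priors$beta_var,
                     alpha_a = priors$alpha_shape[1],
                     alpha_b = priors$alpha_shape[2],
                     lambda_a = priors$lambda_shape[1],
                     lambda_b = priors$lambda_shape[2],
                     tau_shape = priors$tau_shape,
                     tau_rate = priors$tau_rate)

  set.seed(config$seed)
  draws <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    init <- list(
      beta_p = lapply(pe, function(p) rnorm(p, 0, 1)),
      beta_s = rnorm(pa, 0, 1),
      alpha = ifelse(alpha_fixed, fix_alpha, runif(data$n_taxa, 0.25, 0.75)),
      lambda = runif(1, 0.3, 0.7),
      tau = exp(runif(1, -0.7, 0.7)),
      G = rnorm(n, 0, 0.5)
    )
    res <- .run_mcmc_chain(
      y = data$y, yc = data$y_c, De = data$D_e, Da = data$D_a,
      nb_list = nb, deg = deg, evals = evals,
      priors = prior_list, init = init,
      alpha_fixed = alpha_fixed,
      n_iter = config$iterations, burn_in = config$burn_in,
      thin = config$thin, field_sweeps = config$field_sweeps,
      param_sweeps = config$param_sweeps
    )
    m <- res$samples
    colnames(m) <- param_names
    draws[[ch]] <- m
  }

  diag_df <- data.frame(parameter = param_names,
                        rhat = NA_real_, n_eff = NA_real_,
                        stringsAsFactors = FALSE)
  if (config$chains >= 2L && nrow(draws[[1]]) >= 4L) {
    for (j in seq_along(param_names)) {
      x <- vapply(draws, function(m) m[, j], numeric(nrow(draws[[1]])))
      diag_df$rhat[j] <- rhat(x)
      diag_df$n_eff[j] <- ess(x)
    }
  }
  converged <- all(is.na(diag_df$rhat) | diag_df$rhat < 1.1)
  fit <- structure(
    list(draws = draws, param_names = param_names, config = config,
         priors = priors, data = data, diagnostics = diag_df,
         converged = converged, fix_alpha = fix_alpha),
    class = "po_fit"
  )
  if (!is.na(converged) && !converged)
    warning(sprintf("MCMC not converged: %d parameter(s) with R-hat >= 1.1",
                    sum(diag_df$rhat >= 1.1, na.rm = TRUE)))
  fit
}

#' @export
print.po_fit <- function(x, ...) {
  cat(sprintf(paste0("po_fit: %d chains x %d retained draws, %d parameters\n",
                     "  max R-hat: %.3f; converged (all R-hat < 1.1): %s\n"),
              length(x$draws), nrow(x$draws[[1]]), length(x$param_names),
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
              x$converged))
  invisible(x)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale reduction factor computed on split chains: each chain is
#' halved, then `R-hat = sqrt(((n-1)/n * W + B/n) / W)` with `W` the mean
#' within-(half)chain variance and `B` the between-chain variance of the
#' means. Values below 1.1 are taken as converged. Convention: if every
#' retained draw is identical (zero total variance, e.g. a fixed parameter)
#' the statistic is defined as exactly 1.
#'
#' @param x matrix of draws, iterations in rows and chains in columns (or a
#'   list of equal-length numeric vectors, one per chain).
#' @return the split-R-hat value.
#' @export
rhat <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("R-hat needs at least 2 chains")
  if (nrow(x) < 4L) stop("R-hat needs at least 4 draws per chain")
  half <- floor(nrow(x) / 2)
  sp <- cbind(x[seq_len(half), , drop = FALSE],
              x[nrow(x) - half + seq_len(half), , drop = FALSE])
  if (var(as.vector(sp)) == 0) return(1)
  m <- ncol(sp); n_it <- nrow(sp)
  means <- colMeans(sp)
  vars <- apply(sp, 2, var)
  W <- mean(vars)
  B <- n_it * var(means)
  if (W == 0) return(Inf)
  sqrt(((n_it - 1) / n_it * W + B / n_it) / W)
}

#' Effective sample size
#'
#' Per-chain effective sample size from the autocorrelation function with
#' Geyer's initial-positive-sequence truncation, summed over chains. A
#' zero-variance (constant) input returns the total draw count.
#'
#' @inheritParams rhat
#' @return estimated number of effectively independent draws.
#' @export
ess <- function(x) {
  if (is.list(x)) x <- do.call(cbind, x)
  x <- as.matrix(x)
  total <- 0
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    n_it <- length(v)
    if (var(v) == 0) { total <- total + n_it; next }
    rho <- drop(stats::acf(v, lag.max = min(n_it - 2L, 500L),
                           plot = FALSE)$acf)[-1]
    s <- 0; t <- 1
    while (t + 1 <= length(rho)) {
      pair <- rho[t] + rho[t + 1]
      if (pair < 0) break
      s <- s + pair
      t <- t + 2
    }
    total <- total + n_it / (1 + 2 * s)
  }
  total
}

#' Posterior summary table
#'
#' Per-parameter posterior mean, 2.5/50/97.5 percentiles (linear
#' interpolation, R quantile type 7), effective sample size, split-R-hat
#' and a significance flag (the 95% credible interval excludes 0, the usual
#' bold-face convention of posterior tables).
#'
#' @param fit a [fit_pojsdm()] result.
#' @param params optional character vector or regular expression selecting
#'   parameters; by default all parameters except the per-cell field `G`.
#' @param include_G logical; include the `G[k]` cells (default FALSE).
#' @return data frame with columns `parameter`, `mean`, `q2.5`, `q50`,
#'   `q97.5`, `n_eff`, `rhat`, `significant`.
#' @export
summarize_posterior <- function(fit, params = NULL, include_G = FALSE) {
  stopifnot(inherits(fit, "po_fit"))
  sel <- fit$param_names
  if (!include_G && is.null(params)) sel <- sel[!grepl("^G\\[", sel)]
  if (!is.null(params)) {
    sel <- if (all(params %in% fit$param_names)) params
           else fit$param_names[grepl(params, fit$param_names)]
    if (length(sel) == 0L) stop("no parameter matches 'params'")
  }
  pooled <- do.call(rbind, fit$draws)
  out <- do.call(rbind, lapply(sel, function(p) {
    v <- pooled[, p]
    q <- quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = p, mean = mean(v), q2.5 = q[1], q50 = q[2],
               q97.5 = q[3],
               n_eff = fit$diagnostics$n_eff[fit$diagnostics$parameter == p],
               rhat = fit$diagnostics$rhat[fit$diagnostics$parameter == p],
               significant = q[1] > 0 | q[3] < 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# indices of each parameter block in the draw matrices
.param_index <- function(fit) {
  nm <- fit$param_names
  list(
    beta_p = lapply(fit$data$taxa, function(tx)
      which(startsWith(nm, sprintf("beta_p[%s,", tx)))),
    beta_s = which(startsWith(nm, "beta_s[")),
    alpha = vapply(fit$data$taxa, function(tx)
      which(nm == sprintf("alpha[%s]", tx)), integer(1)),
    lambda = which(nm == "lambda"),
    tau = which(nm == "tau"),
    G = which(grepl("^G\\[", nm))
  )
}

# per-draw latent process values at selected cells.
# Returns list(P = list of n_taxa [cells x draws], S = [cells x draws],
# Q = list of [cells x draws]); draws pooled over chains.
.process_draws <- function(fit, cells = NULL) {
  idx <- .param_index(fit)
  data <- fit$data
  if (is.null(cells)) cells <- seq_len(data$n_cells)
  pooled <- do.call(rbind, fit$draws)
  Gd <- t(pooled[, idx$G[cells], drop = FALSE])        # cells x draws
  S <- plogis(data$D_a[cells, , drop = FALSE] %*%
                t(pooled[, idx$beta_s, drop = FALSE]) + Gd)
  P <- Q <- vector("list", data$n_taxa)
  for (i in seq_len(data$n_taxa)) {
    P[[i]] <- plogis(data$D_e[[i]][cells, , drop = FALSE] %*%
                       t(pooled[, idx$beta_p[[i]], drop = FALSE]) + Gd)
    a <- pooled[, idx$alpha[i]]
    Q[[i]] <- sweep(P[[i]], 2, a, "*") + sweep(S, 2, 1 - a, "*")
  }
  list(P = P, S = S, Q = Q, cells = cells)
}

#' Posterior presence probabilities at missing cells
#'
#' For every cell whose response was missing, the posterior mean of its
#' Bernoulli probability under the relevant process — the mixture `Q_i` for
#' a taxon response, the sampling effort `S` for the complementary response
#' — reconstructed from the latent draws. This is the augmented-scheme
#' posterior over missing outcomes: through the shared CAR field, the
#' imputed probability is informed by the data in neighbouring cells.
#'
#' @param fit a [fit_pojsdm()] result.
#' @return data frame with columns `response` (taxon name or `"y_c"`),
#'   `cell` (position), `cell_id` (if cell identifiers are available) and
#'   `prob`; zero rows when nothing is missing.
#' @export
impute_missing <- function(fit) {
  stopifnot(inherits(fit, "po_fit"))
  data <- fit$data
  out <- list()
  ids <- rownames(data$D_e[[1]])
  for (i in seq_len(data$n_taxa)) {
    miss <- which(is.na(data$y[, i]))
    if (length(miss) > 0L) {
      pd <- .process_draws(fit, miss)
      out[[length(out) + 1L]] <- data.frame(
        response = data$taxa[i], cell = miss,
        cell_id = if (is.null(ids)) NA_character_ else ids[miss],
        prob = rowMeans(pd$Q[[i]]), stringsAsFactors = FALSE)
    }
  }
  miss <- which(is.na(data$y_c))
  if (length(miss) > 0L) {
    pd <- .process_draws(fit, miss)
    out[[length(out) + 1L]] <- data.frame(
      response = "y_c", cell = miss,
      cell_id = if (is.null(ids)) NA_character_ else ids[miss],
      prob = rowMeans(pd$S), stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(response = character(0), cell = integer(0),
                      cell_id = character(0), prob = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
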