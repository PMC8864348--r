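#' Draw the CAR spatial field
#'
#' Exact draw(s) from the proper-CAR prior `N(0, Q^{-1})`,
#' `Q = tau * (D - lambda * W)`, via sparse Cholesky factorisation: with
#' `Q = P' L L' P`, a standard-normal vector `z` maps to
#' `g = P' (L')^{-1} z`.
#'
#' @inheritParams car_precision
#' @param n number of independent draws.
#' @param seed optional integer seed (set before drawing).
#' @return numeric vector (one draw) or `n_cells x n` matrix.
#' @export
simulate_car_field <- function(W, lambda, tau, n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  Q <- car_precision(W, lambda, tau)
  nc <- nrow(Q)
  ch <- tryCatch(Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("CAR precision is not positive definite: ",
                        conditionMessage(e)))
  z <- matrix(rnorm(nc * n), nc, n)
  # solve L' w = z, then undo the fill-reducing permutation
  g <- as.matrix(Matrix::solve(ch, Matrix::solve(ch, z, system = "Lt"),
                               system = "Pt"))
  if (n == 1L) drop(g) else g
}

#' Simulate per-cell covariates
#'
#' Standard-normal covariate columns, optionally spatially smoothed by
#' repeated neighbour averaging, plus an intercept column — the ecological
#' design `D_e` and the anthropological design `D_a` of a synthetic study.
#'
#' @param n_cells number of cells.
#' @param r number of ecological covariates.
#' @param s number of anthropological covariates.
#' @param seed optional integer seed.
#' @param W adjacency matrix, required when `smoothing > 0`.
#' @param smoothing integer number of neighbour-averaging sweeps (0 = iid
#'   noise, no spatial autocorrelation); smoothed columns are re-standardised.
#' @return list with matrices `D_e` (`n_cells x (r+1)`) and `D_a`
#'   (`n_cells x (s+1)`), intercept first.
#' @export
simulate_covariates <- function(n_cells, r, s, seed = NULL, W = NULL,
                                smoothing = 0) {
  stopifnot(r >= 1, s >= 1)
  if (!is.null(seed)) set.seed(seed)
  make <- function(k, prefix) {
    X <- matrix(rnorm(n_cells * k), n_cells, k)
    if (smoothing > 0) {
      if (is.null(W)) stop("'W' is required when smoothing > 0")
      d <- pmax(Matrix::rowSums(W), 1)
      for (it in seq_len(smoothing))
        X <- as.matrix((X + W %*% X / d) / 2)
      X <- scale(X)[, , drop = FALSE]
    }
    colnames(X) <- paste0(prefix, seq_len(k))
    cbind(`(Intercept)` = 1, X)
  }
  list(D_e = make(r, "eco"), D_a = make(s, "anthro"))
}

#' Simulate a full dataset from the generative model
#'
#' Draws the shared CAR field, computes the ecological suitabilities `P_i`,
#' the sampling effort `S` and the mixtures `Q_i`, then draws
#' `y_i ~ Bernoulli(Q_i)` and `y_c ~ Bernoulli(S)` and masks a fraction of
#' cells as missing, completely at random. This is the model's own
#' data-generating process, so inference can be validated against known
#' parameters without any external data.
#'
#' @param lattice a [grid_lattice()] (or `nx`/`ny` via `lattice_dim`).
#' @param params a [model_params()] object without `G` (the field is drawn
#'   here), or with `G` to reuse a fixed field. `beta_p` lengths determine
#'   `r + 1`; `beta_s` length determines `s + 1`.
#' @param seed integer seed; the same seed and configuration reproduce the
#'   dataset bit-identically.
#' @param missing_frac_yc fraction of `y_c` cells masked missing, in
#'   `[0, 1)`; 0 reproduces the no-missing-information regime.
#' @param missing_frac_y fraction of taxon cells masked missing (default 0).
#' @param covariate_smoothing passed to [simulate_covariates()].
#' @param adjacency_rule rook or queen, for the lattice graph.
#' @param missing_covariate optional column index of `D_a`; when given,
#'   missingness in `y_c` is concentrated on cells with high values of that
#'   covariate (a covariate-dependent stress-test regime) instead of
#'   completely at random.
#' @return an object of class `po_simulation`: list with `params` (including
#'   the drawn `G`), `data` (a [model_data()]), `latent` (true per-cell `P`
#'   matrix, `S`, `Q` matrix), `lattice`, `W` and `seed`.
#' @export
simulate_dataset <- function(lattice, params, seed,
                             missing_frac_yc = 0, missing_frac_y = 0,
                             covariate_smoothing = 0,
                             adjacency_rule = "rook",
                             missing_covariate = NULL) {
  stopifnot(inherits(lattice, "po_lattice"), inherits(params, "po_params"))
  if (missing_frac_yc < 0 || missing_frac_yc >= 1 ||
      missing_frac_y < 0 || missing_frac_y >= 1)
    stop("missing fractions must lie in [0, 1)")
  set.seed(seed)
  n <- lattice$n_cells
  n_taxa <- length(params$beta_p)
  r <- length(params$beta_p[[1]]) - 1L
  s <- length(params$beta_s) - 1L
  W <- adjacency_matrix(lattice, adjacency_rule)
  X <- simulate_covariates(n, r, s, W = W, smoothing = covariate_smoothing)
  rownames(X$D_e) <- rownames(X$D_a) <- lattice$cells$cell_id
  if (length(params$G) == n) {
    G <- params$G
  } else {
    G <- simulate_car_field(W, params$lambda, params$tau)
  }
  S <- process_probability(X$D_a, params$beta_s, G)
  P <- vapply(seq_len(n_taxa), function(i)
    process_probability(X$D_e, params$beta_p[[i]], G), numeric(n))
  Q <- vapply(seq_len(n_taxa), function(i)
    mixture_probability(P[, i], S, params$alpha[i]), numeric(n))
  y <- apply(Q, 2, function(q) rbinom(n, 1L, q))
  y_c <- rbinom(n, 1L, S)
  if (missing_frac_yc > 0) {
    k <- floor(missing_frac_yc * n)
    if (!is.null(missing_covariate)) {
      v <- X$D_a[, missing_covariate + 1L]
      idx <- order(v, decreasing = TRUE)[seq_len(k)]
    } else {
      idx <- sample.int(n, k)
    }
    y_c[idx] <- NA_integer_
  }
  if (missing_frac_y > 0) {
    for (i in seq_len(n_taxa))
      y[sample.int(n, floor(missing_frac_y * n)), i] <- NA_integer_
  }
  dat <- model_data(
    y = lapply(seq_len(n_taxa), function(i) y[, i]),
    y_c = y_c, D_e = X$D_e, D_a = X$D_a, W = W, normalize = FALSE
  )
  truth <- model_params(params$beta_p, params$beta_s, params$alpha,
                        params$lambda, params$tau, G)
  structure(list(params = truth, data = dat,
                 latent = list(P = P, S = S, Q = Q),
                 lattice = lattice, W = W, seed = as.integer(seed)),
            class = "po_simulation")
}

#' @export
print.po_simulation <- function(x, ...) {
  cat(sprintf("po_simulation: %d cells, %d taxa, seed %d\n",
              x$data$n_cells, x$data$n_taxa, x$seed))
  invisible(x)
}
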