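#' Proper-CAR precision matrix
#'
#' Precision matrix of the proper conditional autoregressive (CAR) prior for
#' the shared spatial field: `Q = tau * (D - lambda * W)`, where `W` is the
#' binary adjacency matrix of the lattice and `D` the diagonal matrix of
#' neighbour counts. `Q` is symmetric positive definite for every
#' `lambda` in (0, 1) on a connected lattice.
#'
#' `tau` multiplies the whole precision, so `1 / tau` plays the role of the
#' overall variance of the field (conditional variances are
#' `1 / (tau * d_k)`).
#'
#' @param W sparse symmetric binary adjacency matrix (zero diagonal), e.g.
#'   from [adjacency_matrix()].
#' @param lambda spatial-dependence parameter, strictly inside (0, 1).
#' @param tau precision multiplier, > 0.
#' @return sparse symmetric matrix `tau * (D - lambda * W)`.
#' @export
car_precision <- function(W, lambda, tau) {
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0 || lambda >= 1)
    stop("'lambda' must lie strictly inside (0, 1)")
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be positive")
  W <- methods::as(W, "CsparseMatrix")
  d <- Matrix::rowSums(W)
  Matrix::forceSymmetric(tau * (Matrix::Diagonal(x = d) - lambda * W))
}

#' Log-density of the proper-CAR field
#'
#' Evaluates `log N(g; 0, Q^{-1})` with `Q = tau * (D - lambda * W)` through
#' a sparse Cholesky factorisation (log-determinant plus quadratic form),
#' identical to the dense multivariate-normal density but scalable to large
#' lattices.
#'
#' @param g numeric vector of field values, one per cell.
#' @param W sparse adjacency matrix.
#' @inheritParams car_precision
#' @return the log-density (a single number).
#' @export
car_logpdf <- function(g, W, lambda, tau) {
  Q <- car_precision(W, lambda, tau)
  n <- nrow(Q)
  if (length(g) != n) stop("'g' must have one value per cell")
  ch <- tryCatch(Matrix::Cholesky(Q, LDL = FALSE, perm = TRUE),
                 error = function(e)
                   stop("CAR precision is not positive definite (disconnected ",
                        "lattice or boundary lambda): ", conditionMessage(e)))
  logdet <- 2 * as.numeric(Matrix::determinant(ch, sqrt = TRUE)$modulus)
  quad <- sum(g * as.numeric(Q %*% g))
  -0.5 * n * log(2 * pi) + 0.5 * logdet - 0.5 * quad
}

#' Logistic process probability
#'
#' The per-cell probability of a logistic ecological or sampling process:
#' `plogis(beta' d + g)`. Used identically for each ecological suitability
#' `P_i` (with the ecological design and coefficients) and the sampling
#' effort `S` (with the anthropological design); the spatial effect `g` is
#' the same shared field in both.
#'
#' @param design design matrix (`n x p`) or a single covariate row.
#' @param beta coefficient vector of length `p`.
#' @param g spatial effect: scalar or vector of length `n`.
#' @return probabilities in (0, 1).
#' @export
process_probability <- function(design, beta, g = 0) {
  if (is.null(dim(design))) design <- matrix(design, nrow = 1L)
  if (ncol(design) != length(beta))
    stop(sprintf("design has %d columns but beta has length %d",
                 ncol(design), length(beta)))
  plogis(drop(design %*% beta) + g)
}

#' Convex mixture of suitability and sampling effort
#'
#' The observation probability for a taxon:
#' `q = alpha * p + (1 - alpha) * s`, a convex combination on the
#' probability scale. `alpha` is the taxon's contribution to ecological
#' suitability; `1 - alpha` is the sampling-bias share.
#'
#' @param p ecological-suitability probability (vectorised).
#' @param s sampling-effort probability.
#' @param alpha mixing weight in `[0, 1]`.
#' @return probabilities, elementwise between `min(p, s)` and `max(p, s)`.
#' @export
mixture_probability <- function(p, s, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("'alpha' must lie in [0, 1]")
  if (any(p < 0 | p > 1, na.rm = TRUE) || any(s < 0 | s > 1, na.rm = TRUE))
    stop("'p' and 's' must be probabilities")
  alpha * p + (1 - alpha) * s
}

#' Prior specification
#'
#' Priors for all model parameters: zero-mean normal on every regression
#' coefficient, Beta on each mixing weight `alpha_i` and on the CAR
#' dependence `lambda`, and inverse-gamma on the CAR variance `1 / tau`
#' (equivalently, gamma with the same shape and rate on the precision
#' multiplier `tau`).
#'
#' @param beta_var variance of the normal prior on regression coefficients.
#'   Default 100 (appropriate for normalised covariates); use 1e4 for
#'   covariates on their raw scale.
#' @param alpha_shape,lambda_shape two positive Beta shape parameters;
#'   default `c(5, 5)`.
#' @param tau_shape,tau_rate shape and rate of the inverse-gamma prior on
#'   the CAR variance; default 1 and 0.01.
#' @return an object of class `po_priors`.
#' @export
po_priors <- function(beta_var = 100, alpha_shape = c(5, 5),
                      lambda_shape = c(5, 5), tau_shape = 1, tau_rate = 0.01) {
  stopifnot(beta_var > 0, all(alpha_shape > 0), all(lambda_shape > 0),
            tau_shape > 0, tau_rate > 0)
  structure(list(beta_var = beta_var, alpha_shape = alpha_shape,
                 lambda_shape = lambda_shape, tau_shape = tau_shape,
                 tau_rate = tau_rate),
            class = "po_priors")
}

#' Model data container
#'
#' Bundles and validates everything the likelihood needs: the per-taxon
#' presence responses, the complementary (sampling-effort) response, the
#' ecological and anthropological design matrices and the lattice adjacency.
#' All objects must share the same number of cells and cell ordering.
#'
#' An intercept column is prepended to each design matrix unless its first
#' column is already constant 1. With `normalize = TRUE` every non-intercept
#' column is z-scored (centring and scaling are stored so new data can be
#' put on the same scale).
#'
#' @param y list of per-taxon responses ([cell_response()] or 0/1/NA
#'   vectors), optionally named by taxon.
#' @param y_c complementary response (same length), 0/1/NA.
#' @param D_e ecological design: one `n_cells x r` matrix shared by all taxa
#'   or a list of per-taxon matrices.
#' @param D_a anthropological design matrix, `n_cells x s`.
#' @param W sparse adjacency matrix of the lattice.
#' @param normalize logical; z-score covariate columns (default TRUE).
#' @return an object of class `po_model_data`.
#' @export
model_data <- function(y, y_c, D_e, D_a, W, normalize = TRUE) {
  if (!is.list(y)) y <- list(y)
  n_taxa <- length(y)
  if (n_taxa < 1L) stop("need at least one taxon response")
  n <- length(y[[1]])
  y_mat <- vapply(y, function(v) {
    v <- as.integer(v)
    if (length(v) != n) stop("all responses must share n_cells")
    if (any(!v %in% c(0L, 1L) & !is.na(v))) stop("responses must be 0/1/NA")
    v
  }, integer(n))
  y_mat <- matrix(y_mat, nrow = n)
  colnames(y_mat) <- if (!is.null(names(y))) names(y) else
    paste0("taxon_", seq_len(n_taxa))
  y_c <- as.integer(y_c)
  if (length(y_c) != n) stop("'y_c' must share n_cells")
  if (any(!y_c %in% c(0L, 1L) & !is.na(y_c))) stop("'y_c' must be 0/1/NA")
  W <- methods::as(W, "CsparseMatrix")
  if (nrow(W) != n || ncol(W) != n) stop("'W' dimension must equal n_cells")
  if (!Matrix::isSymmetric(W)) stop("'W' must be symmetric")
  if (any(Matrix::diag(W) != 0)) stop("'W' must have a zero diagonal")

  prep <- function(X, label) {
    X <- as.matrix(X)
    if (nrow(X) != n) stop(sprintf("'%s' must have n_cells rows", label))
    if (anyNA(X)) stop(sprintf("'%s' contains missing values; impute first",
                               label))
    has_int <- ncol(X) >= 1L && all(X[, 1] == 1)
    covs <- if (has_int) X[, -1, drop = FALSE] else X
    ctr <- rep(0, ncol(covs)); scl <- rep(1, ncol(covs))
    if (normalize && ncol(covs) > 0L) {
      ctr <- colMeans(covs)
      scl <- apply(covs, 2, sd)
      scl[scl == 0 | !is.finite(scl)] <- 1
      covs <- sweep(sweep(covs, 2, ctr), 2, scl, "/")
    }
    out <- cbind(`(Intercept)` = 1, covs)
    cn <- colnames(out)
    fix <- which(is.na(cn) | cn == "")
    if (length(fix) > 0L) cn[fix] <- paste0(label, fix - 1L)
    colnames(out) <- cn
    attr(out, "center") <- ctr; attr(out, "scale") <- scl
    out
  }
  if (!is.list(D_e)) D_e <- rep(list(D_e), n_taxa)
  if (length(D_e) != n_taxa)
    stop("'D_e' must be one matrix or one per taxon")
  D_e <- lapply(seq_len(n_taxa), function(i) prep(D_e[[i]], "eco"))
  D_a <- prep(D_a, "anthro")
  structure(
    list(y = y_mat, y_c = y_c, D_e = D_e, D_a = D_a, W = W,
         n_cells = n, n_taxa = n_taxa, taxa = colnames(y_mat),
         normalize = normalize),
    class = "po_model_data"
  )
}

#' @export
print.po_model_data <- function(x, ...) {
  cat(sprintf(paste0("po_model_data: %d cells, %d taxa (%s)\n",
                     "  eco covariates: %d; anthro covariates: %d\n",
                     "  missing: %d taxon cells, %d effort cells\n"),
              x$n_cells, x$n_taxa, paste(x$taxa, collapse = ", "),
              ncol(x$D_e[[1]]) - 1L, ncol(x$D_a) - 1L,
              sum(is.na(x$y)), sum(is.na(x$y_c))))
  invisible(x)
}

#' Model parameter container
#'
#' @param beta_p per-taxon ecological coefficient vectors (list, or matrix
#'   with one column per taxon), intercept first.
#' @param beta_s sampling-effort coefficient vector, intercept first.
#' @param alpha per-taxon mixing weights in `[0, 1]`.
#' @param lambda CAR spatial dependence in (0, 1).
#' @param tau CAR precision multiplier, > 0.
#' @param G per-cell spatial field.
#' @return an object of class `po_params`.
#' @export
model_params <- function(beta_p, beta_s, alpha, lambda, tau, G) {
  if (is.matrix(beta_p)) beta_p <- lapply(seq_len(ncol(beta_p)),
                                          function(j) beta_p[, j])
  if (!is.list(beta_p)) beta_p <- list(beta_p)
  if (length(alpha) != length(beta_p))
    stop("'alpha' must have one value per taxon")
  if (any(alpha < 0 | alpha > 1)) stop("'alpha' must lie in [0, 1]")
  if (lambda <= 0 || lambda >= 1) stop("'lambda' must lie inside (0, 1)")
  if (tau <= 0) stop("'tau' must be positive")
  structure(list(beta_p = beta_p, beta_s = as.numeric(beta_s),
                 alpha = as.numeric(alpha), lambda = as.numeric(lambda),
                 tau = as.numeric(tau), G = as.numeric(G)),
            class = "po_params")
}

#' Joint log-posterior (up to an additive constant)
#'
#' Sum of the Bernoulli log-likelihood of every observed taxon cell at its
#' mixture probability `Q_i`, the Bernoulli log-likelihood of every observed
#' complementary cell at the sampling-effort probability `S`, the proper-CAR
#' log-density of the shared field, and the log-priors on all coefficients,
#' mixing weights, `lambda` and `tau`. Cells with missing responses
#' contribute no observation term (their augmented Bernoulli outcome is
#' marginalised exactly). A conflicting degenerate probability (e.g. `Q = 0`
#' with `y = 1`) yields `-Inf`, never an exception.
#'
#' @param params a [model_params()] object.
#' @param data a [model_data()] object.
#' @param priors a [po_priors()] object.
#' @return the log-posterior value.
#' @export
joint_log_posterior <- function(params, data, priors = po_priors()) {
  stopifnot(inherits(params, "po_params"), inherits(data, "po_model_data"),
            inherits(priors, "po_priors"))
  if (length(params$G) != data$n_cells) stop("'G' must have n_cells values")
  s_prob <- process_probability(data$D_a, params$beta_s, params$G)
  ll <- 0
  for (i in seq_len(data$n_taxa)) {
    p_prob <- process_probability(data$D_e[[i]], params$beta_p[[i]], params$G)
    q_prob <- mixture_probability(p_prob, s_prob, params$alpha[i])
    obs <- !is.na(data$y[, i])
    ll <- ll + sum(dbinom(data$y[obs, i], 1L, q_prob[obs], log = TRUE))
  }
  obs_c <- !is.na(data$y_c)
  ll <- ll + sum(dbinom(data$y_c[obs_c], 1L, s_prob[obs_c], log = TRUE))
  lp <- car_logpdf(params$G, data$W, params$lambda, params$tau)
  bsd <- sqrt(priors$beta_var)
  lp <- lp + sum(vapply(params$beta_p,
                        function(b) sum(dnorm(b, 0, bsd, log = TRUE)),
                        numeric(1)))
  lp <- lp + sum(dnorm(params$beta_s, 0, bsd, log = TRUE))
  lp <- lp + sum(dbeta(params$alpha, priors$alpha_shape[1],
                       priors$alpha_shape[2], log = TRUE))
  lp <- lp + dbeta(params$lambda, priors$lambda_shape[1],
                   priors$lambda_shape[2], log = TRUE)
  lp <- lp + dgamma(params$tau, shape = priors$tau_shape,
                    rate = priors$tau_rate, log = TRUE)
  ll + lp
}
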