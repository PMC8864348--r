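# Independent oracles and small fixture builders used across the suite.

# Dense multivariate-normal log-density of the proper-CAR field, computed
# entirely with base dense linear algebra (independent of the sparse path).
dense_car_logpdf <- function(g, W, lambda, tau) {
  Wd <- as.matrix(W)
  Q <- tau * (diag(rowSums(Wd)) - lambda * Wd)
  ld <- as.numeric(determinant(Q, logarithm = TRUE)$modulus)
  -0.5 * length(g) * log(2 * pi) + 0.5 * ld - 0.5 * drop(t(g) %*% Q %*% g)
}

# Brute-force complementary-taxa oracle: node sets via per-node ancestor
# scans only (no descendant traversal shared with the implementation).
oracle_complement_nodes <- function(tree, toi) {
  anc <- function(id) {
    out <- id
    while (!is.na(tree$nodes$parent[id])) {
      id <- tree$nodes$parent[id]
      out <- c(out, id)
    }
    out
  }
  common <- Reduce(intersect, lapply(toi, anc))
  lca <- common[which.max(tree$nodes$depth[common])]
  # normative rule: an LCA that is itself a taxon of interest steps up to
  # its parent so that siblings can form the complement
  if (lca %in% toi && !is.na(tree$nodes$parent[lca]))
    lca <- tree$nodes$parent[lca]
  in_subtree <- function(node, root) root %in% anc(node)
  below <- Filter(function(k) in_subtree(k, lca), tree$nodes$id)
  induced <- unique(c(
    unlist(lapply(toi, function(t) Filter(function(k) in_subtree(k, t),
                                          tree$nodes$id))),
    unlist(lapply(toi, function(t) {
      a <- anc(t)
      a[seq_len(which(a == lca))]
    }))
  ))
  sort(setdiff(below, induced))
}

# Random occurrence table over a random taxonomy (<= ~200 nodes).
random_taxa_records <- function(n_records, seed,
                                ranks = c("kingdom", "family", "genus",
                                          "species")) {
  set.seed(seed)
  sizes <- c(2, 4, 5, 6)  # choices per rank
  out <- lapply(seq_along(ranks), function(j)
    sprintf("%s%d", toupper(substr(ranks[j], 1, 1)),
            sample.int(sizes[j], n_records, replace = TRUE)))
  names(out) <- ranks
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  # make names unique within parent implicitly by joining with the parent
  for (j in seq_along(ranks)[-1])
    df[[j]] <- paste(df[[j - 1]], df[[j]], sep = ".")
  df$decimalLongitude <- runif(n_records, 0, 4)
  df$decimalLatitude <- runif(n_records, 0, 4)
  df
}

# Random connected grid lattice with <= max_cells cells.
random_small_lattice <- function(max_cells = 100) {
  repeat {
    nx <- sample(2:10, 1)
    ny <- sample(2:10, 1)
    if (nx * ny <= max_cells) break
  }
  x0 <- runif(1, -50, 50)
  y0 <- runif(1, -50, 50)
  res <- runif(1, 0.1, 5)
  grid_lattice(c(x0, y0, x0 + nx * res, y0 + ny * res), res)
}

# Small two-taxon simulation used by several tests.
small_sim <- function(seed = 11, nx = 8, alpha = c(0.8, 0.3),
                      lambda = 0.9, tau = 1, missing_frac_yc = 0) {
  lat <- grid_lattice(c(0, 0, nx, nx), 1)
  pars <- model_params(
    beta_p = list(c(-0.5, 1, -1), c(0.5, -1, 0.5)),
    beta_s = c(0.5, 1, -0.5),
    alpha = alpha, lambda = lambda, tau = tau, G = numeric(0)
  )
  simulate_dataset(lat, pars, seed = seed, missing_frac_yc = missing_frac_yc)
}

# fast fit settings for module tests
quick_config <- function(seed = 5, chains = 2, iterations = 800,
                         burn_in = 400, thin = 1)
  fit_config(chains = chains, iterations = iterations, burn_in = burn_in,
             thin = thin, seed = seed)
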