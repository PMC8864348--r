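# File interchange: GeoJSON lattices, Matrix Market adjacency, CSV
# responses/covariates, Newick trees, JSON complement specs and simulation
# directories. All formats are plain text; numeric fields are written with
# 17 significant digits so that a write/read cycle reproduces doubles
# exactly.

.fmt <- function(x) sprintf("%.17g", x)

#' Export a lattice as GeoJSON
#'
#' One polygon feature per cell with property `cell_id` (plus the grid
#' indices); grid metadata is stored on the FeatureCollection so the
#' lattice can be reconstructed exactly by [read_lattice_geojson()].
#'
#' @param lattice a [grid_lattice()] object.
#' @param path output file path.
#' @export
write_lattice_geojson <- function(lattice, path) {
  stopifnot(inherits(lattice, "po_lattice"))
  feats <- lapply(seq_len(lattice$n_cells), function(k) {
    c0 <- lattice$cells[k, ]
    ring <- list(c(c0$x0, c0$y0), c(c0$x1, c0$y0), c(c0$x1, c0$y1),
                 c(c0$x0, c0$y1), c(c0$x0, c0$y0))
    list(type = "Feature",
         properties = list(cell_id = c0$cell_id, ix = c0$ix, iy = c0$iy),
         geometry = list(type = "Polygon", coordinates = list(ring)))
  })
  obj <- list(type = "FeatureCollection",
              properties = list(bbox = lattice$bbox,
                                resolution = lattice$resolution,
                                nx = lattice$nx, ny = lattice$ny),
              features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a lattice from GeoJSON written by [write_lattice_geojson()]
#'
#' @param path input file path.
#' @return a `po_lattice` object.
#' @export
read_lattice_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  props <- obj$features$properties
  coords <- obj$features$geometry$coordinates
  corner <- t(vapply(coords, function(cc) {
    ring <- cc[1, , ]
    c(min(ring[, 1]), min(ring[, 2]), max(ring[, 1]), max(ring[, 2]))
  }, numeric(4)))
  cells <- data.frame(cell_id = props$cell_id, ix = props$ix, iy = props$iy,
                      x0 = corner[, 1], y0 = corner[, 2],
                      x1 = corner[, 3], y1 = corner[, 4],
                      stringsAsFactors = FALSE)
  structure(list(cells = cells, n_cells = nrow(cells),
                 nx = obj$properties$nx, ny = obj$properties$ny,
                 bbox = as.numeric(obj$properties$bbox),
                 resolution = as.numeric(obj$properties$resolution)),
            class = "po_lattice")
}

#' Adjacency matrix export/import (Matrix Market)
#'
#' @param W sparse adjacency matrix.
#' @param path `.mtx` file path.
#' @export
write_adjacency_mtx <- function(W, path) {
  Matrix::writeMM(methods::as(methods::as(W, "CsparseMatrix"),
                              "generalMatrix"), path)
  invisible(path)
}

#' @rdname write_adjacency_mtx
#' @return `read_adjacency_mtx`: a sparse binary symmetric matrix.
#' @export
read_adjacency_mtx <- function(path) {
  W <- Matrix::readMM(path)
  # pattern matrices (binary symmetric) have no numeric slot; promote first
  W <- methods::as(methods::as(methods::as(W, "dMatrix"), "generalMatrix"),
                   "CsparseMatrix")
  W@x[] <- 1
  W
}

#' Cell response CSV export/import
#'
#' Two-column CSV (`cell_id`, `value`); missing cells are written as empty
#' fields.
#'
#' @param response a [cell_response()].
#' @param path CSV path.
#' @export
write_response_csv <- function(response, path) {
  ids <- names(response)
  if (is.null(ids)) ids <- as.character(seq_along(response))
  write.csv(data.frame(cell_id = ids, value = unclass(response)),
            path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_response_csv
#' @export
read_response_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  cell_response(df$value, df$cell_id)
}

# children of each node, as a list indexed by node id
.children <- function(tree) {
  split(tree$nodes$id[-1], factor(tree$nodes$parent[-1],
                                  levels = tree$nodes$id))
}

#' Export a taxonomic tree as Newick
#'
#' Topology and node names only (no branch lengths). Names are sanitised:
#' characters with structural meaning in Newick are replaced by `_`.
#'
#' @param tree a [taxonomic_tree()].
#' @param path optional file path; when `NULL` the Newick string is
#'   returned.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "po_taxonomy"))
  kids <- .children(tree)
  safe <- gsub("[(),:;\\[\\] ']", "_", tree$nodes$name)
  rec <- function(id) {
    ch <- kids[[id]]
    if (length(ch) == 0L) return(safe[id])
    paste0("(", paste(vapply(ch, rec, character(1)), collapse = ","), ")",
           safe[id])
  }
  nwk <- paste0(rec(tree$root), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(path)
}

#' Export a complementary-sample specification as JSON
#'
#' @param complement a [complementary_taxa()] result.
#' @param path JSON path.
#' @export
write_complement_json <- function(complement, path) {
  stopifnot(inherits(complement, "po_complement"))
  jsonlite::write_json(
    list(lca = complement$lca_name,
         taxa_of_interest = complement$taxa_of_interest_names,
         complement_taxa = complement$complement_taxa_names),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' Export a simulated dataset to a directory
#'
#' Writes `responses.csv` (per-cell taxa responses and `y_c`),
#' `design_eco.csv`, `design_anthro.csv`, `adjacency.mtx`,
#' `lattice.geojson`, `latent.csv` (true `P_i`, `S`, `Q_i`) and
#' `truth.json` (generating parameters and seed). The companion
#' [read_simulation()] reproduces the `po_simulation` exactly.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "po_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- sim$lattice$cells$cell_id
  resp <- data.frame(cell_id = ids, sim$data$y, y_c = sim$data$y_c)
  write.csv(resp, file.path(dir, "responses.csv"), row.names = FALSE, na = "")
  wr <- function(M, f) {
    df <- data.frame(cell_id = ids,
                     apply(M, 2, .fmt), check.names = FALSE)
    write.csv(df, file.path(dir, f), row.names = FALSE, quote = FALSE)
  }
  wr(sim$data$D_e[[1]], "design_eco.csv")
  wr(sim$data$D_a, "design_anthro.csv")
  lat <- cbind(P = sim$latent$P, S = sim$latent$S, Q = sim$latent$Q)
  colnames(lat) <- c(paste0("P_", seq_len(ncol(sim$latent$P))), "S",
                     paste0("Q_", seq_len(ncol(sim$latent$Q))))
  wr(lat, "latent.csv")
  write_adjacency_mtx(sim$W, file.path(dir, "adjacency.mtx"))
  write_lattice_geojson(sim$lattice, file.path(dir, "lattice.geojson"))
  tr <- sim$params
  jsonlite::write_json(
    list(beta_p = tr$beta_p, beta_s = tr$beta_s, alpha = tr$alpha,
         lambda = tr$lambda, tau = tr$tau, G = tr$G, seed = sim$seed,
         taxa = sim$data$taxa),
    file.path(dir, "truth.json"), digits = I(17))
  invisible(dir)
}

#' @rdname write_simulation
#' @param dir the directory written by `write_simulation`.
#' @return `read_simulation`: a `po_simulation` object.
#' @export
read_simulation <- function(dir) {
  resp <- read.csv(file.path(dir, "responses.csv"), stringsAsFactors = FALSE)
  D_e <- as.matrix(read.csv(file.path(dir, "design_eco.csv"),
                            check.names = FALSE)[, -1, drop = FALSE])
  D_a <- as.matrix(read.csv(file.path(dir, "design_anthro.csv"),
                            check.names = FALSE)[, -1, drop = FALSE])
  rownames(D_e) <- rownames(D_a) <- resp$cell_id
  lat <- as.matrix(read.csv(file.path(dir, "latent.csv"),
                            check.names = FALSE)[, -1, drop = FALSE])
  W <- read_adjacency_mtx(file.path(dir, "adjacency.mtx"))
  lattice <- read_lattice_geojson(file.path(dir, "lattice.geojson"))
  tr <- jsonlite::read_json(file.path(dir, "truth.json"),
                            simplifyVector = TRUE)
  taxa_cols <- setdiff(names(resp), c("cell_id", "y_c"))
  y <- lapply(taxa_cols, function(cn) resp[[cn]])
  names(y) <- tr$taxa
  dat <- model_data(y = y, y_c = resp$y_c, D_e = D_e, D_a = D_a, W = W,
                    normalize = FALSE)
  beta_p <- if (is.matrix(tr$beta_p)) {
    lapply(seq_len(nrow(tr$beta_p)), function(i) tr$beta_p[i, ])
  } else tr$beta_p
  params <- model_params(beta_p, tr$beta_s, tr$alpha, tr$lambda, tr$tau, tr$G)
  nT <- dat$n_taxa
  structure(list(params = params, data = dat,
                 latent = list(P = lat[, seq_len(nT), drop = FALSE],
                               S = lat[, nT + 1L],
                               Q = lat[, nT + 2L - 1L + seq_len(nT),
                                       drop = FALSE]),
                 lattice = lattice, W = W, seed = as.integer(tr$seed)),
            class = "po_simulation")
}

#' Export posterior draws, summary and diagnostics
#'
#' Writes `draws.csv` (columnar: `parameter`, `chain`, `iteration`,
#' `value`), `summary.csv` (the [summarize_posterior()] table) and
#' `diagnostics.json` (per-parameter R-hat / effective sample size and the
#' convergence flag).
#'
#' @param fit a [fit_pojsdm()] result.
#' @param dir output directory.
#' @param include_G include per-cell field draws in `draws.csv` (default
#'   FALSE; the summary always spans the non-field parameters).
#' @export
write_posterior <- function(fit, dir, include_G = FALSE) {
  stopifnot(inherits(fit, "po_fit"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sel <- fit$param_names
  if (!include_G) sel <- sel[!grepl("^G\\[", sel)]
  long <- do.call(rbind, lapply(seq_along(fit$draws), function(ch) {
    m <- fit$draws[[ch]][, sel, drop = FALSE]
    data.frame(parameter = rep(sel, each = nrow(m)), chain = ch,
               iteration = rep(seq_len(nrow(m)), times = length(sel)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  write.csv(long, file.path(dir, "draws.csv"), row.names = FALSE)
  write.csv(summarize_posterior(fit), file.path(dir, "summary.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(converged = fit$converged,
         diagnostics = fit$diagnostics[!grepl("^G\\[", fit$diagnostics$parameter), ]),
    file.path(dir, "diagnostics.json"), dataframe = "rows", digits = NA)
  invisible(dir)
}
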