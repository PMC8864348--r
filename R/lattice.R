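#' Build a regular grid lattice over a bounding box
#'
#' Constructs the areal lattice that supports the CAR spatial field: a
#' regular rectangular grid of axis-aligned cells covering `bbox`, optionally
#' clipped to a polygon mask. Cells are half-open rectangles
#' `[x0, x1) x [y0, y1)` so that a point on a shared border belongs to
#' exactly one cell, and are ordered row-major from the south-west corner.
#'
#' The number of columns/rows is `ceiling(extent / resolution)`; cells in the
#' last column/row may overrun the bounding box so that the grid always
#' covers it.
#'
#' @param bbox numeric vector `c(xmin, ymin, xmax, ymax)`; must be
#'   non-degenerate.
#' @param resolution cell edge length in the units of `bbox` (a single value
#'   or `c(res_x, res_y)`); must be positive.
#' @param mask optional two-column matrix of polygon vertices; only cells
#'   whose centroid falls inside the polygon are kept. An empty intersection
#'   is an error.
#' @return An object of class `po_lattice`: a list with elements `cells`
#'   (data frame with `cell_id`, grid indices `ix`, `iy` and corner
#'   coordinates), `n_cells`, `nx`, `ny`, `bbox` and `resolution`.
#' @examples
#' lat <- grid_lattice(c(0, 0, 2, 2), 1)
#' lat$n_cells # 4
#' @export
grid_lattice <- function(bbox, resolution, mask = NULL) {
  if (length(bbox) != 4L || !is.numeric(bbox))
    stop("'bbox' must be numeric c(xmin, ymin, xmax, ymax)")
  if (bbox[3] <= bbox[1] || bbox[4] <= bbox[2])
    stop("'bbox' is degenerate: xmax must exceed xmin and ymax must exceed ymin")
  resolution <- rep_len(as.numeric(resolution), 2L)
  if (any(!is.finite(resolution)) || any(resolution <= 0))
    stop("'resolution' must be positive")
  nx <- max(1L, as.integer(ceiling((bbox[3] - bbox[1]) / resolution[1] - 1e-9)))
  ny <- max(1L, as.integer(ceiling((bbox[4] - bbox[2]) / resolution[2] - 1e-9)))
  ix <- rep(seq_len(nx), times = ny)
  iy <- rep(seq_len(ny), each = nx)
  x0 <- bbox[1] + (ix - 1L) * resolution[1]
  y0 <- bbox[2] + (iy - 1L) * resolution[2]
  cells <- data.frame(
    cell_id = sprintf("c%d_%d", ix, iy),
    ix = ix, iy = iy,
    x0 = x0, y0 = y0,
    x1 = x0 + resolution[1], y1 = y0 + resolution[2],
    stringsAsFactors = FALSE
  )
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (ncol(mask) != 2L) stop("'mask' must be a two-column matrix of vertices")
    cx <- (cells$x0 + cells$x1) / 2
    cy <- (cells$y0 + cells$y1) / 2
    keep <- mgcv::in.out(mask, cbind(cx, cy))
    if (!any(keep)) stop("mask does not intersect any grid cell")
    cells <- cells[keep, , drop = FALSE]
    rownames(cells) <- NULL
  }
  structure(
    list(cells = cells, n_cells = nrow(cells), nx = nx, ny = ny,
         bbox = as.numeric(bbox), resolution = resolution),
    class = "po_lattice"
  )
}

#' @export
print.po_lattice <- function(x, ...) {
  cat(sprintf("po_lattice: %d cells (%d x %d grid, resolution %g x %g)\n",
              x$n_cells, x$nx, x$ny, x$resolution[1], x$resolution[2]))
  invisible(x)
}

# map points to cell positions (NA when outside every cell); half-open cells
.locate_points <- function(x, y, lattice) {
  res <- lattice$resolution
  ix <- floor((x - lattice$bbox[1]) / res[1] + 1e-12) + 1L
  iy <- floor((y - lattice$bbox[2]) / res[2] + 1e-12) + 1L
  key <- ifelse(ix >= 1L & iy >= 1L & ix <= lattice$nx & iy <= lattice$ny,
                (iy - 1L) * lattice$nx + ix, NA_integer_)
  map <- integer(lattice$nx * lattice$ny)
  map[(lattice$cells$iy - 1L) * lattice$nx + lattice$cells$ix] <-
    seq_len(lattice$n_cells)
  pos <- ifelse(is.na(key), NA_integer_, map[key])
  pos[!is.na(pos) & pos == 0L] <- NA_integer_  # masked-out cell
  pos
}

#' Adjacency matrix of a lattice
#'
#' Derives the sparse symmetric binary adjacency matrix W of the lattice
#' graph. Under the `rook` rule two cells are neighbours when they share an
#' edge; under `queen` also when they share only a vertex.
#'
#' @param lattice a [grid_lattice()] object.
#' @param rule `"rook"` (default) or `"queen"`.
#' @return a sparse symmetric 0/1 `Matrix::sparseMatrix` of dimension
#'   `n_cells x n_cells` with zero diagonal, rows/columns in lattice cell
#'   order and `dimnames` set to the cell identifiers.
#' @examples
#' W <- adjacency_matrix(grid_lattice(c(0, 0, 2, 2), 1), "rook")
#' Matrix::rowSums(W) # each corner cell of a 2x2 grid has 2 rook neighbours
#' @export
adjacency_matrix <- function(lattice, rule = c("rook", "queen")) {
  rule <- match.arg(rule)
  stopifnot(inherits(lattice, "po_lattice"))
  if (lattice$n_cells < 1L) stop("empty lattice")
  offs <- list(c(1L, 0L), c(0L, 1L))
  if (rule == "queen") offs <- c(offs, list(c(1L, 1L), c(1L, -1L)))
  key <- (lattice$cells$iy - 1L) * (lattice$nx + 2L) + lattice$cells$ix
  idx <- seq_len(lattice$n_cells)
  keymap <- integer((lattice$nx + 2L) * (lattice$ny + 2L))
  keymap[key] <- idx
  ii <- jj <- integer(0)
  for (o in offs) {
    nkey <- (lattice$cells$iy - 1L + o[2]) * (lattice$nx + 2L) +
      lattice$cells$ix + o[1]
    ok <- lattice$cells$ix + o[1] >= 1L & lattice$cells$ix + o[1] <= lattice$nx &
      lattice$cells$iy + o[2] >= 1L & lattice$cells$iy + o[2] <= lattice$ny &
      nkey >= 1L & nkey <= length(keymap)
    nb <- ifelse(ok, keymap[pmax(nkey, 1L)], 0L)
    hit <- nb > 0L
    ii <- c(ii, idx[hit])
    jj <- c(jj, nb[hit])
  }
  W <- Matrix::sparseMatrix(
    i = c(ii, jj), j = c(jj, ii), x = 1,
    dims = c(lattice$n_cells, lattice$n_cells),
    dimnames = list(lattice$cells$cell_id, lattice$cells$cell_id)
  )
  W@x[] <- 1  # collapse any duplicate entries to binary
  W
}

#' Per-cell ternary response
#'
#' Container for a per-cell response taking values 1 (present), 0
#' (absent / pseudo-absent) or `NA` (missing).
#'
#' @param values integer-like vector in `{0, 1, NA}`.
#' @param cell_id optional character vector of cell identifiers.
#' @return a `cell_response` object (integer vector with counts attached).
#' @export
cell_response <- function(values, cell_id = NULL) {
  v <- as.integer(values)
  if (any(!v %in% c(0L, 1L) & !is.na(v)))
    stop("response values must be 0, 1 or NA")
  if (!is.null(cell_id)) names(v) <- cell_id
  structure(v, class = "cell_response",
            n_present = sum(v == 1L, na.rm = TRUE),
            n_absent = sum(v == 0L, na.rm = TRUE),
            n_missing = sum(is.na(v)))
}

#' @export
print.cell_response <- function(x, ...) {
  cat(sprintf("cell_response: %d cells (%d present, %d absent, %d missing)\n",
              length(x), attr(x, "n_present"), attr(x, "n_absent"),
              attr(x, "n_missing")))
  invisible(x)
}

#' Aggregate occurrence points to cell presences
#'
#' Point-in-cell test: a cell scores 1 when at least one point falls inside
#' it and 0 otherwise. Points outside every cell are counted and reported
#' via attribute `n_outside` (with a warning), never an error. Missing-state
#' assignment is a separate policy step (see [complementary_response()]).
#'
#' @param points data frame (or two-column matrix) of point coordinates; the
#'   first two columns are taken as x (longitude) and y (latitude).
#' @param lattice a [grid_lattice()] object in the same coordinate system.
#' @return a [cell_response()] of length `n_cells`.
#' @export
aggregate_presence <- function(points, lattice) {
  stopifnot(inherits(lattice, "po_lattice"))
  pts <- as.data.frame(points)
  v <- integer(lattice$n_cells)
  n_outside <- 0L
  if (nrow(pts) > 0L) {
    pos <- .locate_points(as.numeric(pts[[1]]), as.numeric(pts[[2]]), lattice)
    n_outside <- sum(is.na(pos))
    if (n_outside > 0L)
      warning(sprintf("%d point(s) fall outside the lattice and were ignored",
                      n_outside))
    v[unique(pos[!is.na(pos)])] <- 1L
  }
  out <- cell_response(v, lattice$cells$cell_id)
  attr(out, "n_outside") <- n_outside
  out
}

#' Aggregate point-support covariate values to cells by mean
#'
#' Averages per-point (or per-pixel centre) covariate values over the cell
#' containing each point. Cells that receive no value are flagged; with
#' `impute = "nearest"` they take the value of the nearest non-empty cell
#' centroid instead.
#'
#' @param points data frame whose first two columns are x and y coordinates
#'   and whose remaining columns are covariate values.
#' @param lattice a [grid_lattice()] object.
#' @param impute `"flag"` (default: empty cells are `NA`, listed in attribute
#'   `empty_cells`) or `"nearest"`.
#' @return numeric matrix `n_cells x n_covariates` (column names preserved),
#'   rows in lattice cell order.
#' @export
aggregate_covariates <- function(points, lattice,
                                 impute = c("flag", "nearest")) {
  impute <- match.arg(impute)
  stopifnot(inherits(lattice, "po_lattice"))
  pts <- as.data.frame(points)
  if (ncol(pts) < 3L) stop("need coordinate columns plus >= 1 covariate column")
  vals <- as.matrix(pts[, -(1:2), drop = FALSE])
  if (all(!is.finite(vals))) stop("covariate columns contain no finite values")
  pos <- .locate_points(as.numeric(pts[[1]]), as.numeric(pts[[2]]), lattice)
  keep <- !is.na(pos)
  out <- matrix(NA_real_, lattice$n_cells, ncol(vals),
                dimnames = list(lattice$cells$cell_id, colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    ok <- keep & is.finite(vals[, j])
    if (!any(ok)) stop(sprintf("covariate '%s' has no values inside the lattice",
                               colnames(vals)[j]))
    m <- tapply(vals[ok, j], pos[ok], mean)
    out[as.integer(names(m)), j] <- m
  }
  empty <- which(rowSums(is.na(out)) > 0L)
  if (impute == "nearest" && length(empty) > 0L) {
    cx <- (lattice$cells$x0 + lattice$cells$x1) / 2
    cy <- (lattice$cells$y0 + lattice$cells$y1) / 2
    for (j in seq_len(ncol(out))) {
      miss <- which(is.na(out[, j]))
      full <- which(!is.na(out[, j]))
      for (k in miss) {
        d2 <- (cx[full] - cx[k])^2 + (cy[full] - cy[k])^2
        out[k, j] <- out[full[which.min(d2)], j]
      }
    }
    empty <- integer(0)
  }
  attr(out, "empty_cells") <- empty
  out
}

#' Coarsen a cell response to a blocked grid
#'
#' Aggregates a response to `factor x factor` blocks of cells (used to carry
#' the sampling-effort response at a coarser resolution than the ecological
#' responses). Block rule: 1 if any member cell is 1; else 0 if any member is
#' 0; else missing. Partial blocks at the east/north edges are allowed when
#' `factor` does not divide the grid dimensions.
#'
#' @param response a [cell_response()] aligned with `lattice`.
#' @param lattice the [grid_lattice()] the response lives on.
#' @param factor integer block edge length (>= 1); `factor = 1` is the
#'   identity.
#' @return a [cell_response()] on the coarse grid; the coarse `po_lattice` is
#'   attached as attribute `lattice`, and attribute `membership` maps each
#'   fine cell to its coarse cell position.
#' @export
coarsen_response <- function(response, lattice, factor) {
  stopifnot(inherits(lattice, "po_lattice"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("'factor' must be an integer >= 1")
  if (length(response) != lattice$n_cells)
    stop("response length does not match lattice")
  bx <- (lattice$cells$ix - 1L) %/% factor + 1L
  by <- (lattice$cells$iy - 1L) %/% factor + 1L
  coarse <- grid_lattice(lattice$bbox, lattice$resolution * factor)
  # keep only coarse cells that contain at least one fine cell (masked grids)
  ckey <- (by - 1L) * coarse$nx + bx
  keep <- sort(unique(ckey))
  allkey <- (coarse$cells$iy - 1L) * coarse$nx + coarse$cells$ix
  coarse$cells <- coarse$cells[match(keep, allkey), , drop = FALSE]
  rownames(coarse$cells) <- NULL
  coarse$n_cells <- nrow(coarse$cells)
  member <- match(ckey, keep)
  v <- vapply(seq_along(keep), function(b) {
    vals <- unclass(response)[member == b]
    if (any(vals == 1L, na.rm = TRUE)) 1L
    else if (any(vals == 0L, na.rm = TRUE)) 0L
    else NA_integer_
  }, integer(1))
  out <- cell_response(v, coarse$cells$cell_id)
  attr(out, "lattice") <- coarse
  attr(out, "membership") <- member
  out
}
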