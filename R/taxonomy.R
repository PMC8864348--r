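#' Build a taxonomic tree from occurrence classification paths
#'
#' Parses an occurrence table with ordered rank columns (e.g. kingdom ...
#' species) into a single rooted tree. Identical paths merge into one leaf;
#' node names are unique within a parent, so the same name under two
#' different parents yields two distinct nodes. A synthetic root (`"root"`)
#' joins the top-rank taxa, mirroring a unique static tree of life.
#'
#' @param records data frame of occurrence records.
#' @param ranks character vector naming the rank columns of `records`, in
#'   root-to-leaf order. Default: the seven Linnean ranks.
#' @param on_incomplete `"error"` (default): records with a missing or empty
#'   value in any rank column abort with a per-record report; `"drop"`:
#'   they are removed with a warning (the usual occurrence-cleaning rule).
#' @return an object of class `po_taxonomy`: list with `nodes` (data frame
#'   `id`, `name`, `rank`, `parent`, `depth`), `root` (id), and
#'   `record_nodes` (leaf node id per retained record, named by original row
#'   number).
#' @export
taxonomic_tree <- function(records,
                           ranks = c("kingdom", "phylum", "class", "order",
                                     "family", "genus", "species"),
                           on_incomplete = c("error", "drop")) {
  on_incomplete <- match.arg(on_incomplete)
  records <- as.data.frame(records)
  if (!all(ranks %in% names(records)))
    stop("missing rank column(s): ",
         paste(setdiff(ranks, names(records)), collapse = ", "))
  path <- as.matrix(records[, ranks, drop = FALSE])
  path[path == ""] <- NA
  bad <- which(rowSums(is.na(path)) > 0L)
  if (length(bad) > 0L) {
    report <- sprintf("record %d: missing %s", bad,
                      vapply(bad, function(i)
                        paste(ranks[is.na(path[i, ])], collapse = ","),
                        character(1)))
    if (on_incomplete == "error")
      stop("records with incomplete taxonomic information:\n",
           paste(head(report, 20L), collapse = "\n"))
    warning(sprintf("dropped %d record(s) with incomplete taxonomy",
                    length(bad)))
    path <- path[-bad, , drop = FALSE]
  }
  kept <- setdiff(seq_len(nrow(records)), bad)
  name <- "root"; rank <- "root"; parent <- NA_integer_
  env <- new.env(hash = TRUE)  # "parent|name" -> node id
  n_nodes <- 1L
  record_nodes <- integer(length(kept))
  for (r in seq_along(kept)) {
    cur <- 1L
    for (j in seq_along(ranks)) {
      key <- paste0(cur, "|", path[r, j])
      id <- env[[key]]
      if (is.null(id)) {
        n_nodes <- n_nodes + 1L
        id <- n_nodes
        name[id] <- path[r, j]; rank[id] <- ranks[j]; parent[id] <- cur
        env[[key]] <- id
      }
      cur <- id
    }
    record_nodes[r] <- cur
  }
  depth <- integer(n_nodes)
  for (i in seq_len(n_nodes)[-1]) depth[i] <- depth[parent[i]] + 1L
  names(record_nodes) <- as.character(kept)
  structure(
    list(nodes = data.frame(id = seq_len(n_nodes), name = name, rank = rank,
                            parent = parent, depth = depth,
                            stringsAsFactors = FALSE),
         root = 1L, record_nodes = record_nodes),
    class = "po_taxonomy"
  )
}

#' @export
print.po_taxonomy <- function(x, ...) {
  cat(sprintf("po_taxonomy: %d nodes, %d records, ranks: %s\n",
              nrow(x$nodes), length(x$record_nodes),
              paste(unique(x$nodes$rank[-1]), collapse = " > ")))
  invisible(x)
}

# resolve node references (ids or names) to ids; names must be unambiguous
.resolve_nodes <- function(tree, taxa) {
  if (is.numeric(taxa)) {
    ids <- as.integer(taxa)
    if (any(!ids %in% tree$nodes$id)) stop("unknown node id(s)")
    return(ids)
  }
  vapply(as.character(taxa), function(nm) {
    hit <- tree$nodes$id[tree$nodes$name == nm]
    if (length(hit) == 0L) stop(sprintf("taxon '%s' not in tree", nm))
    if (length(hit) > 1L)
      stop(sprintf("taxon name '%s' is ambiguous; use node ids", nm))
    hit
  }, integer(1), USE.NAMES = FALSE)
}

.ancestors <- function(tree, id) {  # self first, root last
  out <- id
  while (!is.na(tree$nodes$parent[id])) {
    id <- tree$nodes$parent[id]
    out <- c(out, id)
  }
  out
}

.descendants <- function(tree, id) {  # including self
  out <- id
  frontier <- id
  repeat {
    kids <- tree$nodes$id[tree$nodes$parent %in% frontier]
    if (length(kids) == 0L) break
    out <- c(out, kids)
    frontier <- kids
  }
  out
}

#' Lowest common ancestor of a set of taxa
#'
#' @param tree a [taxonomic_tree()].
#' @param taxa node ids or (unambiguous) node names; must be non-empty.
#' @return the node id of the deepest node ancestral to (or equal to) every
#'   taxon in the set; its name is attached as attribute `name`.
#' @export
lowest_common_ancestor <- function(tree, taxa) {
  stopifnot(inherits(tree, "po_taxonomy"))
  if (length(taxa) == 0L) stop("'taxa' must be non-empty")
  ids <- .resolve_nodes(tree, taxa)
  common <- .ancestors(tree, ids[1])
  for (id in ids[-1]) common <- intersect(common, .ancestors(tree, id))
  lca <- common[which.max(tree$nodes$depth[common])]
  structure(lca, name = tree$nodes$name[lca])
}

#' Complementary taxa of a set of taxa of interest
#'
#' Computes the complementary sample specification: all taxa that descend
#' from the lowest common ancestor (LCA) of the taxa of interest but belong
#' neither to a taxon of interest's subtree nor to the spine connecting the
#' LCA to the taxa of interest. Their occurrences act as informed background
#' data for the sampling-effort process.
#'
#' @param tree a [taxonomic_tree()].
#' @param taxa_of_interest non-empty set of node ids or names.
#' @return an object of class `po_complement`: list with `taxa_of_interest`,
#'   `lca`, `complement_taxa` (ids of the maximal complement subtree roots),
#'   `complement_nodes` (every node in the complement) and the matching
#'   `*_names`. When the LCA is itself a taxon of interest (a single taxon,
#'   or nested taxa) it is replaced by its parent, so that the taxon's
#'   siblings form the complement. When the taxa of interest cover the whole
#'   LCA subtree the complement is empty and a warning is raised.
#' @export
complementary_taxa <- function(tree, taxa_of_interest) {
  stopifnot(inherits(tree, "po_taxonomy"))
  toi <- .resolve_nodes(tree, taxa_of_interest)
  lca <- as.integer(lowest_common_ancestor(tree, toi))
  # a single taxon (or nested taxa) is its own LCA, which would make the
  # complement empty by construction; step up to the parent so taxonomic
  # siblings become the background sample
  if (lca %in% toi && !is.na(tree$nodes$parent[lca]))
    lca <- tree$nodes$parent[lca]
  below <- .descendants(tree, lca)
  induced <- unique(c(
    unlist(lapply(toi, .descendants, tree = tree)),
    unlist(lapply(toi, function(id) {
      anc <- .ancestors(tree, id)
      anc[seq_len(which(anc == lca))]  # spine from taxon up to the LCA
    }))
  ))
  comp_nodes <- setdiff(below, induced)
  roots <- comp_nodes[!tree$nodes$parent[comp_nodes] %in% comp_nodes]
  if (length(comp_nodes) == 0L)
    warning("taxa of interest cover the whole LCA subtree; complement is empty")
  structure(
    list(taxa_of_interest = toi,
         taxa_of_interest_names = tree$nodes$name[toi],
         lca = lca, lca_name = tree$nodes$name[lca],
         complement_taxa = roots,
         complement_taxa_names = tree$nodes$name[roots],
         complement_nodes = sort(comp_nodes)),
    class = "po_complement"
  )
}

#' @export
print.po_complement <- function(x, ...) {
  cat(sprintf("po_complement: LCA = %s; %d taxa of interest; %d complement subtree(s) (%d nodes)\n",
              x$lca_name, length(x$taxa_of_interest),
              length(x$complement_taxa), length(x$complement_nodes)))
  invisible(x)
}

# record indices whose classification path passes through any of `ids`
.records_under <- function(tree, ids) {
  leaf_set <- unique(unlist(lapply(ids, .descendants, tree = tree)))
  which(tree$record_nodes %in% leaf_set)
}

#' Records belonging to a taxon
#'
#' A record belongs to a taxon when the taxon lies on the record's
#' classification path (so internal nodes such as genera or families collect
#' all their descendant records).
#'
#' @param tree a [taxonomic_tree()].
#' @param taxon a single node id or name.
#' @return integer vector of record positions (in the order records were
#'   retained by [taxonomic_tree()]).
#' @export
taxon_records <- function(tree, taxon) {
  stopifnot(inherits(tree, "po_taxonomy"))
  .records_under(tree, .resolve_nodes(tree, taxon))
}

#' Complementary response over a lattice
#'
#' Builds the sampling-effort response y^c on the lattice cells from the
#' complementary sample: a cell scores 1 when at least one record of any
#' complement taxon falls in it (the cell was demonstrably sampled); else 0
#' when at least one record of a taxon of interest falls in it
#' (pseudo-absence: somebody sampled there but recorded no complement
#' taxon); otherwise the cell is missing under policy
#' `"no-information-missing"` or 0 under policy `"none"` (no missing
#' information on the sampling effort).
#'
#' @param tree a [taxonomic_tree()].
#' @param complement a [complementary_taxa()] result.
#' @param record_cells integer vector of lattice cell positions (1-based, NA
#'   for records outside the lattice), one per retained record, e.g. from
#'   [.locate_points] via [aggregate_presence()]'s machinery or computed by
#'   the caller.
#' @param lattice the [grid_lattice()] defining the cells.
#' @param missing_policy `"none"` or `"no-information-missing"`.
#' @return a [cell_response()] of length `n_cells`.
#' @export
complementary_response <- function(tree, complement, record_cells, lattice,
                                   missing_policy = c("none",
                                                      "no-information-missing")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(tree, "po_taxonomy"), inherits(complement, "po_complement"),
            inherits(lattice, "po_lattice"))
  if (length(record_cells) != length(tree$record_nodes))
    stop("'record_cells' must map every retained record to a cell")
  comp_rec <- .records_under(tree, complement$complement_taxa)
  toi_rec <- .records_under(tree, complement$taxa_of_interest)
  comp_cells <- unique(record_cells[comp_rec])
  toi_cells <- unique(record_cells[toi_rec])
  v <- rep(if (missing_policy == "none") 0L else NA_integer_, lattice$n_cells)
  v[toi_cells[!is.na(toi_cells)]] <- 0L
  v[comp_cells[!is.na(comp_cells)]] <- 1L
  cell_response(v, lattice$cells$cell_id)
}

#' Locate occurrence records on a lattice
#'
#' Convenience mapping from record coordinates to lattice cell positions,
#' aligned with the records retained by [taxonomic_tree()].
#'
#' @param records the occurrence table passed to [taxonomic_tree()].
#' @param tree the resulting [taxonomic_tree()].
#' @param lattice a [grid_lattice()].
#' @param coords names of the coordinate columns (x then y).
#' @return integer vector of cell positions (NA outside the lattice), one
#'   per retained record.
#' @export
locate_records <- function(records, tree, lattice,
                           coords = c("decimalLongitude", "decimalLatitude")) {
  records <- as.data.frame(records)
  if (!all(coords %in% names(records)))
    stop("missing coordinate column(s): ",
         paste(setdiff(coords, names(records)), collapse = ", "))
  kept <- as.integer(names(tree$record_nodes))
  .locate_points(as.numeric(records[kept, coords[1]]),
                 as.numeric(records[kept, coords[2]]), lattice)
}

#' Presence response of one taxon over a lattice
#'
#' @inheritParams complementary_response
#' @param taxon node id or name.
#' @return a [cell_response()]: 1 where the taxon has >= 1 record, else 0.
#' @export
taxon_response <- function(tree, taxon, record_cells, lattice) {
  stopifnot(inherits(lattice, "po_lattice"))
  cells <- record_cells[taxon_records(tree, taxon)]
  v <- integer(lattice$n_cells)
  v[unique(cells[!is.na(cells)])] <- 1L
  cell_response(v, lattice$cells$cell_id)
}
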