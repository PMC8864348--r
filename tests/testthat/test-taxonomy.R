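mini_records <- function(...) {
  paths <- list(...)
  do.call(rbind, lapply(paths, function(p)
    as.data.frame(as.list(setNames(p, c("family", "species"))),
                  stringsAsFactors = FALSE)))
}

test_that("tree construction merges identical paths and keeps name-within-parent identity", {
  tr <- taxonomic_tree(mini_records(c("F", "A"), c("F", "B")),
                       ranks = c("family", "species"))
  expect_equal(nrow(tr$nodes), 4L)  # root, F, A, B
  expect_setequal(tr$nodes$name, c("root", "F", "A", "B"))

  dup <- taxonomic_tree(mini_records(c("F", "A"), c("F", "A")),
                        ranks = c("family", "species"))
  expect_equal(nrow(dup$nodes), 3L)
  expect_equal(unname(table(dup$record_nodes)[1]), 2L)  # 2 records, 1 leaf

  # same species name under two different families -> two distinct nodes
  conf <- taxonomic_tree(mini_records(c("F1", "X"), c("F2", "X")),
                         ranks = c("family", "species"))
  expect_equal(sum(conf$nodes$name == "X"), 2L)
})

test_that("incomplete classification paths are rejected with a report or dropped", {
  bad <- mini_records(c("F", "A"), c("F", NA))
  expect_error(taxonomic_tree(bad, ranks = c("family", "species")),
               "record 2")
  expect_warning(tr <- taxonomic_tree(bad, ranks = c("family", "species"),
                                      on_incomplete = "drop"),
                 "dropped 1")
  expect_length(tr$record_nodes, 1L)
})

test_that("lowest common ancestor matches direct expectations and the ancestor-chain oracle", {
  df <- data.frame(order = c("O", "O", "O"),
                   family = c("F1", "F1", "F2"),
                   species = c("A", "B", "C"), stringsAsFactors = FALSE)
  tr <- taxonomic_tree(df, ranks = c("order", "family", "species"))
  expect_equal(attr(lowest_common_ancestor(tr, "A"), "name"), "A")
  expect_equal(attr(lowest_common_ancestor(tr, c("A", "B")), "name"), "F1")
  expect_equal(attr(lowest_common_ancestor(tr, c("A", "C")), "name"), "O")
  expect_error(lowest_common_ancestor(tr, character(0)), "non-empty")
})

test_that("complementary taxa equal the brute-force oracle on random trees", {
  for (seed in 1:30) {
    recs <- random_taxa_records(60, seed = 700 + seed)
    tr <- taxonomic_tree(recs, ranks = c("kingdom", "family", "genus",
                                         "species"))
    n_toi <- sample(1:3, 1)
    toi <- sample(tr$nodes$id[-1], n_toi)
    cs <- suppressWarnings(complementary_taxa(tr, toi))
    expect_equal(cs$complement_nodes, oracle_complement_nodes(tr, toi))
    # maximal roots: no complement root is an ancestor/descendant of a ToI
    for (rt in cs$complement_taxa) {
      expect_false(rt %in% unlist(lapply(toi, pojsdm:::.descendants,
                                         tree = tr)))
      expect_false(any(toi %in% pojsdm:::.descendants(tr, rt)))
    }
  }
})

test_that("complementary taxa handle the named worked example and the empty complement", {
  df <- data.frame(family = rep("F", 3), species = c("A", "B", "C"),
                   stringsAsFactors = FALSE)
  tr <- taxonomic_tree(df, ranks = c("family", "species"))
  cs <- complementary_taxa(tr, "A")
  expect_equal(cs$lca_name, "F")
  expect_setequal(cs$complement_taxa_names, c("B", "C"))

  expect_warning(empty <- complementary_taxa(tr, c("A", "B", "C")),
                 "empty")
  expect_length(empty$complement_taxa, 0L)
})

test_that("the complementary response follows the presence / pseudo-absence / missing rule", {
  df <- data.frame(family = c("F", "F", "F"),
                   species = c("A", "B", "A"), stringsAsFactors = FALSE)
  tr <- taxonomic_tree(df, ranks = c("family", "species"))
  cs <- complementary_taxa(tr, "A")   # complement = {B}
  lat <- grid_lattice(c(0, 0, 3, 1), 1)
  # record 1 (ToI A) in cell 1; record 2 (complement B) in cell 2;
  # record 3 (ToI A) also in cell 2; cell 3 empty
  rc <- c(1L, 2L, 2L)
  none <- complementary_response(tr, cs, rc, lat, "none")
  expect_equal(as.integer(none), c(0L, 1L, 0L))  # complement dominates
  mis <- complementary_response(tr, cs, rc, lat, "no-information-missing")
  expect_equal(as.integer(mis)[1:2], c(0L, 1L))
  expect_true(is.na(as.integer(mis)[3]))
})

test_that("no cell is missing in the effort response while present for a taxon", {
  for (seed in 1:10) {
    recs <- random_taxa_records(80, seed = 900 + seed)
    tr <- taxonomic_tree(recs, ranks = c("kingdom", "family", "genus",
                                         "species"))
    lat <- grid_lattice(c(0, 0, 4, 4), 1)
    rc <- pojsdm::locate_records(recs, tr, lat)
    toi <- sample(tr$nodes$id[tr$nodes$rank == "genus"], 2)
    cs <- suppressWarnings(complementary_taxa(tr, toi))
    yc <- complementary_response(tr, cs, rc, lat, "no-information-missing")
    for (t in toi) {
      yi <- taxon_response(tr, t, rc, lat)
      expect_false(any(is.na(yc) & as.integer(yi) == 1L))
    }
    cnt <- attr(yc, "n_present") + attr(yc, "n_absent") + attr(yc, "n_missing")
    expect_equal(cnt, lat$n_cells)
  }
})

test_that("records belong to internal taxa along their path", {
  df <- data.frame(family = c("F1", "F1", "F2"),
                   species = c("A", "B", "C"), stringsAsFactors = FALSE)
  tr <- taxonomic_tree(df, ranks = c("family", "species"))
  expect_equal(taxon_records(tr, "F1"), c(1L, 2L))
  expect_equal(taxon_records(tr, "C"), 3L)
})

test_that("Newick export is parseable and preserves the leaf set", {
  recs <- random_taxa_records(40, seed = 77)
  tr <- taxonomic_tree(recs, ranks = c("kingdom", "family", "genus",
                                       "species"))
  ph <- ape::read.tree(text = write_newick(tr))
  leaves <- setdiff(tr$nodes$id, tr$nodes$parent)
  expect_equal(ape::Ntip(ph), length(leaves))
})
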