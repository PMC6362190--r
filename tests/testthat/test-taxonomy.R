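test_that("ancestor_at_rank walks to the requested rank, including identity", {
  tree <- tiny_taxonomy()
  expect_equal(ancestor_at_rank(tree, "genX", "genus"), "genX")
  expect_equal(ancestor_at_rank(tree, "spX1", "genus"), "genX")
  expect_equal(ancestor_at_rank(tree, "gi1", "phylum"), "phyA")
  # viral lineage has no phylum: explicit absent marker, not a drop
  expect_true(is.na(ancestor_at_rank(tree, "gi4", "phylum")))
  expect_equal(ancestor_at_rank(tree, "gi4", "family"), "virroot")
})

test_that("ancestor_at_rank is idempotent and validates its inputs", {
  tree <- tiny_taxonomy()
  for (rk in c("genus", "family", "phylum")) {
    a <- ancestor_at_rank(tree, c("gi1", "gi2", "gi3"), rk)
    ok <- !is.na(a)
    expect_equal(ancestor_at_rank(tree, a[ok], rk), a[ok])
  }
  expect_error(ancestor_at_rank(tree, "nope", "genus"), "nope")
  expect_error(ancestor_at_rank(tree, "gi1", "kingdom"), "valid ranks")
})

test_that("taxonomy construction rejects cycles and ambiguous maps", {
  nodes <- tibble::tibble(
    node_id = c("a", "b"), parent_id = c("b", "a"),
    rank = c("genus", "family")
  )
  expect_error(
    taxonomy_tree(nodes, tibble::tibble(sequence_id = "s", node_id = "a")),
    "cycle"
  )
  tree_nodes <- tibble::tibble(node_id = "a", parent_id = NA, rank = "genus")
  expect_error(
    taxonomy_tree(tree_nodes,
                  tibble::tibble(sequence_id = c("s", "s"), node_id = c("a", "a"))),
    "more than one node"
  )
})

test_that("aggregate_counts conserves mass and matches hand enumeration", {
  tree <- tiny_taxonomy()
  out <- aggregate_counts(
    tibble::tibble(sequence_id = c("gi1", "gi2"), count = c(3, 5)),
    tree, "genus"
  )
  expect_equal(out$count[out$taxon_id == "genX"], 8)

  out <- aggregate_counts(
    tibble::tibble(sequence_id = c("gi1", "gi2", "gi3"), count = c(4, 6, 1)),
    tree, "genus"
  )
  # oracle: walk parents by hand — gi1,gi2 -> genX; gi3 -> genY
  expect_equal(setNames(out$count, out$taxon_id), c(genX = 10, genY = 1))

  empty <- aggregate_counts(
    tibble::tibble(sequence_id = character(), count = numeric()), tree, "genus"
  )
  expect_equal(nrow(empty), 0)

  expect_error(
    aggregate_counts(tibble::tibble(sequence_id = "giZ", count = 1), tree, "genus"),
    "giZ"
  )
})

test_that("unranked sequences go to an explicit bucket, conserving totals", {
  tree <- tiny_taxonomy()
  counts <- tibble::tibble(sequence_id = c("gi1", "gi3", "gi4"),
                           count = c(2, 3, 7))
  out <- aggregate_counts(counts, tree, "phylum")
  expect_equal(sum(out$count), sum(counts$count))
  expect_true(any(out$unranked))
  expect_equal(out$count[out$unranked], 7)
  expect_equal(out$taxon_id[!out$unranked], "phyA")
})

test_that("conservation holds for random count vectors at every rank", {
  tree <- tiny_taxonomy()
  withr::with_seed(7, {
    for (i in 1:20) {
      counts <- tibble::tibble(
        sequence_id = c("gi1", "gi2", "gi3", "gi4"),
        count = rpois(4, 10)
      )
      for (rk in c("species", "genus", "family", "order", "phylum")) {
        out <- aggregate_counts(counts, tree, rk)
        expect_equal(sum(out$count), sum(counts$count))
      }
    }
  })
})

test_that("distinct detected taxa are non-increasing from species to phylum", {
  sim <- generate_counts(simulate_config(seed = 3, n_phyla = 4))
  counts <- sim$counts
  n_detected <- vapply(
    c("species", "genus", "family", "order", "class", "phylum"),
    function(rk) {
      out <- aggregate_counts(counts, sim$taxonomy, rk)
      sum(tapply(out$count, out$taxon_id, sum) > 0)
    },
    numeric(1)
  )
  expect_true(all(diff(n_detected) <= 0))
})

test_that("rank_summary counts taxa with any aligned pair", {
  genus <- tibble::tibble(
    taxon_id = rep(c("g1", "g2", "g3"), each = 2),
    sample_id = rep(c("s1", "s2"), 3),
    count = c(0, 0, 1, 2, 3, 4)
  )
  species <- tibble::tibble(
    taxon_id = rep(paste0("sp", 1:5), each = 2),
    sample_id = rep(c("s1", "s2"), 5),
    count = c(1, 0, 1, 1, 0, 2, 2, 0, 0, 3)
  )
  out <- rank_summary(list(species = species, genus = genus))
  expect_equal(out$n_taxa_detected[out$rank == "genus"], 2)
  expect_equal(out$n_taxa_detected[out$rank == "species"], 5)

  allzero <- dplyr::mutate(genus, count = 0)
  expect_equal(rank_summary(list(genus = allzero))$n_taxa_detected, 0)
})

test_that("taxonomy round-trips through its TSV layout", {
  tree <- tiny_taxonomy()
  d <- withr::local_tempdir()
  readr::write_tsv(tree$nodes[c("node_id", "parent_id", "rank")],
                   file.path(d, "nodes.tsv"))
  readr::write_tsv(tibble::tibble(node_id = tree$nodes$node_id,
                                  name = toupper(tree$nodes$node_id)),
                   file.path(d, "names.tsv"))
  readr::write_tsv(tree$seq_map, file.path(d, "seqmap.tsv"))
  back <- read_taxonomy(file.path(d, "nodes.tsv"), file.path(d, "seqmap.tsv"),
                        file.path(d, "names.tsv"))
  expect_equal(back$nodes$node_id, tree$nodes$node_id)
  expect_equal(back$nodes$name, toupper(tree$nodes$node_id))
  expect_equal(ancestor_at_rank(back, "gi2", "genus"), "genX")
})
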