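#' Taxonomic rank vocabulary
#'
#' The ordered set of rank levels used throughout the package, from most
#' specific (`sequence`, one reference record in the alignment catalog) to
#' most general (`superkingdom`). Ranks outside this vocabulary (e.g.
#' "no rank" nodes in an NCBI-style taxonomy) are tolerated in the input tree
#' but skipped during ancestor walks.
#'
#' @format A character vector of length 8.
#' @export
RANK_LEVELS <- c(
  "sequence", "species", "genus", "family",
  "order", "class", "phylum", "superkingdom"
)

#' Build a taxonomy tree
#'
#' Assembles a rank-labelled parent-pointer tree plus a map from
#' reference-sequence ids to tree nodes. This is the structure every
#' count-aggregation step consults.
#'
#' @param nodes Data frame with columns `node_id`, `parent_id`, `rank`.
#'   Roots have `parent_id` `NA` (or equal to their own `node_id`,
#'   NCBI-style). Ranks outside [RANK_LEVELS] are allowed and are skipped
#'   when walking to an ancestor.
#' @param seq_map Data frame with columns `sequence_id`, `node_id` mapping
#'   every reference sequence to exactly one node.
#' @param names Optional data frame with columns `node_id`, `name`.
#'
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes, seq_map, names = NULL) {
  nodes <- as_tibble(nodes)
  seq_map <- as_tibble(seq_map)
  req <- c("node_id", "parent_id", "rank")
  if (!all(req %in% colnames(nodes))) {
    abort(paste0("`nodes` must have columns: ", paste(req, collapse = ", ")))
  }
  if (!all(c("sequence_id", "node_id") %in% colnames(seq_map))) {
    abort("`seq_map` must have columns: sequence_id, node_id")
  }
  nodes <- mutate(nodes, across(c("node_id", "parent_id", "rank"), as.character))
  seq_map <- mutate(seq_map, across(c("sequence_id", "node_id"), as.character))

  if (anyDuplicated(nodes$node_id)) {
    abort(paste0(
      "duplicated node ids: ",
      paste(unique(nodes$node_id[duplicated(nodes$node_id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(seq_map$sequence_id)) {
    abort(paste0(
      "sequence ids mapped to more than one node: ",
      paste(unique(seq_map$sequence_id[duplicated(seq_map$sequence_id)]), collapse = ", ")
    ))
  }

  # self-parent roots normalized to NA
  nodes$parent_id[!is.na(nodes$parent_id) & nodes$parent_id == nodes$node_id] <- NA_character_

  missing_parents <- setdiff(stats::na.omit(nodes$parent_id), nodes$node_id)
  if (length(missing_parents) > 0) {
    abort(paste0("parent ids absent from node table: ",
                 paste(missing_parents, collapse = ", ")))
  }
  unmapped <- setdiff(seq_map$node_id, nodes$node_id)
  if (length(unmapped) > 0) {
    abort(paste0("seq_map refers to unknown nodes: ",
                 paste(unmapped, collapse = ", ")))
  }

  parent <- setNames(nodes$parent_id, nodes$node_id)
  # cycle check: every chain must reach a root within n_nodes hops
  cur <- parent
  for (i in seq_len(length(parent) + 1L)) {
    live <- !is.na(cur)
    if (!any(live)) break
    cur[live] <- parent[cur[live]]
  }
  if (any(!is.na(cur))) {
    abort(paste0("taxonomy contains a parent-pointer cycle involving: ",
                 paste(head(names(cur)[!is.na(cur)], 5), collapse = ", ")))
  }

  if (!is.null(names)) {
    names <- mutate(as_tibble(names), across(c("node_id", "name"), as.character))
    nodes <- left_join(nodes, select(names, "node_id", "name"), by = "node_id")
  } else if (!"name" %in% colnames(nodes)) {
    nodes$name <- nodes$node_id
  }
  nodes$name <- coalesce(nodes$name, nodes$node_id)

  structure(
    list(
      nodes = select(nodes, "node_id", "parent_id", "rank", "name"),
      seq_map = seq_map,
      parent = parent,
      rank = setNames(nodes$rank, nodes$node_id),
      seq_node = setNames(seq_map$node_id, seq_map$sequence_id)
    ),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, ",
      nrow(x$seq_map), " reference sequences\n", sep = "")
  rk <- table(factor(x$rank, levels = rev(RANK_LEVELS)))
  rk <- rk[rk > 0]
  if (length(rk) > 0) {
    cat(paste0("  ", names(rk), ": ", as.integer(rk), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Read a taxonomy from delimited files
#'
#' Reads the three-table taxonomy layout used by this package: a nodes table
#' (`node_id`, `parent_id`, `rank`), an optional names table (`node_id`,
#' `name`), and a sequence map (`sequence_id`, `node_id`). The column layout
#' is a deliberate subset of the NCBI taxonomy dump; full taxdump parsing is
#' out of scope.
#'
#' @param nodes_file,seq_map_file,names_file Paths to tab-separated files
#'   with header rows. `names_file` may be `NULL`.
#' @return A [taxonomy_tree()].
#' @export
read_taxonomy <- function(nodes_file, seq_map_file, names_file = NULL) {
  rd <- function(p) readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
  nm <- if (!is.null(names_file)) rd(names_file) else NULL
  taxonomy_tree(rd(nodes_file), rd(seq_map_file), names = nm)
}

rank_or_abort <- function(rank) {
  if (length(rank) != 1L || !rank %in% RANK_LEVELS) {
    abort(paste0("unknown rank '", paste(rank, collapse = ","),
                 "'; valid ranks: ", paste(RANK_LEVELS, collapse = ", ")))
  }
  rank
}

#' Ancestor of a node at a requested rank
#'
#' Walks parent pointers from each node until it reaches a node whose rank
#' equals `rank` (the node itself qualifies). Nodes whose rank is outside
#' [RANK_LEVELS] are stepped over. Lineages that never reach the requested
#' rank (e.g. viruses asked for a phylum) yield `NA`, an explicit
#' "unranked at this level" marker, never a silent drop.
#'
#' @param tree A [taxonomy_tree()].
#' @param node_id Character vector of node ids.
#' @param rank One of [RANK_LEVELS].
#' @return Character vector of ancestor node ids, `NA` where the lineage has
#'   no node at that rank.
#' @export
ancestor_at_rank <- function(tree, node_id, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  rank <- rank_or_abort(rank)
  node_id <- as.character(node_id)
  unknown <- setdiff(node_id, names(tree$parent))
  if (length(unknown) > 0) {
    abort(paste0("unknown node id(s): ", paste(unique(unknown), collapse = ", ")))
  }
  out <- setNames(rep(NA_character_, length(node_id)), NULL)
  cur <- node_id
  live <- rep(TRUE, length(node_id))
  for (i in seq_len(length(tree$parent) + 1L)) {
    if (!any(live)) break
    hit <- live & !is.na(cur) & tree$rank[cur] == rank
    out[hit] <- cur[hit]
    live <- live & !hit & !is.na(cur)
    cur[live] <- unname(tree$parent[cur[live]])
    live <- live & !is.na(cur)
  }
  out
}

#' Aggregate per-sequence counts to a taxonomic rank
#'
#' Sums counts over reference sequences sharing the same ancestor at `rank`.
#' Sequences whose lineage has no node at that rank are kept in explicit
#' unranked rows (carrying their own node id, flagged `unranked = TRUE`) so
#' that total mass is conserved exactly.
#'
#' @param counts Data frame with columns `sequence_id`, `count`, and
#'   optionally `sample_id` (aggregation is then per sample).
#' @param tree A [taxonomy_tree()].
#' @param rank Target rank, one of [RANK_LEVELS].
#' @return A tibble with columns `taxon_id`, (`sample_id`,) `count`,
#'   `unranked`. `sum(result$count) == sum(counts$count)` always holds.
#' @export
aggregate_counts <- function(counts, tree, rank) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  rank <- rank_or_abort(rank)
  counts <- as_tibble(counts)
  if (!all(c("sequence_id", "count") %in% colnames(counts))) {
    abort("`counts` must have columns sequence_id, count")
  }
  if (nrow(counts) == 0) {
    out <- tibble(taxon_id = character(), count = numeric(), unranked = logical())
    if ("sample_id" %in% colnames(counts)) out <- mutate(out, sample_id = character(), .after = "taxon_id")
    return(out)
  }
  counts$sequence_id <- as.character(counts$sequence_id)
  missing_seq <- setdiff(unique(counts$sequence_id), names(tree$seq_node))
  if (length(missing_seq) > 0) {
    abort(paste0("sequence id(s) absent from taxonomy: ",
                 paste(missing_seq, collapse = ", ")))
  }
  if (any(counts$count < 0)) abort("counts must be nonnegative")

  node <- unname(tree$seq_node[counts$sequence_id])
  anc <- ancestor_at_rank(tree, node, rank)
  counts$taxon_id <- ifelse(is.na(anc), node, anc)
  counts$unranked <- is.na(anc)

  keys <- intersect(c("taxon_id", "sample_id", "unranked"), colnames(counts))
  out <- counts |>
    group_by(across(all_of(keys))) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    relocate(any_of(c("taxon_id", "sample_id", "count", "unranked")))
  arrange(out, .data$unranked, .data$taxon_id)
}

#' Taxa detected per rank
#'
#' For a set of count tables at different ranks (sharing the same samples),
#' reports how many taxa have at least one aligned pair in at least one
#' sample — the "aligned in any sample" summary of a taxonomic-distribution
#' table.
#'
#' @param count_tables Named list of data frames (names are ranks), each with
#'   columns `taxon_id`, `count` and optionally `sample_id`.
#' @return A tibble with columns `rank`, `n_taxa_detected`.
#' @export
rank_summary <- function(count_tables) {
  if (is.null(names(count_tables)) || any(names(count_tables) == "")) {
    abort("`count_tables` must be a named list (names are ranks)")
  }
  samples <- purrr::map(count_tables, function(tb) {
    if ("sample_id" %in% colnames(tb)) sort(unique(tb$sample_id)) else character()
  })
  if (length(unique(samples)) > 1) {
    abort("count tables do not share the same sample set")
  }
  purrr::imap_dfr(count_tables, function(tb, rk) {
    tb <- as_tibble(tb)
    det <- tb |>
      group_by(.data$taxon_id) |>
      summarise(total = sum(.data$count), .groups = "drop") |>
      filter(.data$total > 0)
    tibble(rank = rk, n_taxa_detected = nrow(det))
  })
}
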