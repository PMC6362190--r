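#' Center matrix rows
#'
#' Subtracts each row's mean from every cell of the row — the display
#' convention for log2 hit-rate heatmaps, where color then shows deviation
#' from the taxon's own average across samples.
#'
#' @param m Numeric matrix with at least one cell.
#' @return Matrix of the same shape; each row sums to 0.
#' @export
center_rows <- function(m) {
  if (!is.matrix(m) || length(m) == 0) abort("`m` must be a non-empty matrix")
  sweep(m, 1, rowMeans(m), "-")
}

#' Pearson correlation distance between matrix rows
#'
#' `d(i, j) = 1 - cor(row_i, row_j)`, ranging over `[0, 2]`. Rows with zero
#' variance have no defined correlation; they are assigned the maximal
#' informative distance 1 to every other row (with a message), so they join
#' the tree last instead of poisoning it with `NA`s.
#'
#' @param m Numeric matrix (items in rows).
#' @return A `dist` object over rows.
#' @export
correlation_distance <- function(m) {
  if (!is.matrix(m) || nrow(m) < 2) abort("need a matrix with >= 2 rows")
  sds <- apply(m, 1, sd)
  flat <- sds == 0 | !is.finite(sds)
  d <- 1 - suppressWarnings(cor(t(m)))
  if (any(flat)) {
    message(sum(flat), " zero-variance row(s) assigned distance 1 to all others")
    d[flat, ] <- 1
    d[, flat] <- 1
  }
  diag(d) <- 0
  as.dist(d)
}

#' Agglomerative hierarchical clustering of matrix rows or columns
#'
#' Average-linkage clustering on Pearson correlation distance (the
#' convention of classic expression-heatmap software), deterministic for a
#' given input ordering. Euclidean distance is available as a variant.
#'
#' @param m Numeric matrix.
#' @param axis `"rows"` (default) or `"columns"`.
#' @param metric `"correlation"` (default) or `"euclidean"`.
#' @param linkage Linkage method for [stats::hclust()] (default
#'   `"average"`).
#' @return A [stats::hclust] tree; `$order` is the leaf order.
#' @export
hierarchical_cluster <- function(m, axis = c("rows", "columns"),
                                 metric = c("correlation", "euclidean"),
                                 linkage = "average") {
  axis <- match.arg(axis)
  metric <- match.arg(metric)
  if (axis == "columns") m <- t(m)
  if (nrow(m) < 2) abort("need >= 2 items on the clustered axis")
  d <- if (metric == "correlation") correlation_distance(m) else stats::dist(m)
  hclust(d, method = linkage)
}

#' Cluster candidate taxa across samples
#'
#' Builds the candidate-taxon submatrix of log2(HR + pseudocount) values
#' over the non-blank samples, centers rows, and clusters both axes. This
#' is the heatmap view in which case samples sharing a set of enriched taxa
#' form a visible sample cluster.
#'
#' @param hr Hit-rate tibble (post artifact filter).
#' @param samples Sample metadata.
#' @param scan Optional [detect_candidates()] result; its candidate taxa
#'   define the rows. Alternatively give `taxa` directly.
#' @param taxa Optional explicit character vector of taxa to cluster.
#' @param pseudocount Pseudocount for the log2 transform (default 1 PPM).
#' @param metric,linkage Passed to [hierarchical_cluster()].
#' @param include_groups Sample groups shown (default all non-blank).
#' @return An object of class `taxon_clustering` with the centered matrix,
#'   row/column trees and leaf orders.
#' @export
cluster_candidates <- function(hr, samples, scan = NULL, taxa = NULL,
                               pseudocount = 1,
                               metric = "correlation", linkage = "average",
                               include_groups = c("MS", "control", "OND")) {
  samples <- validate_samples(samples)
  if (is.null(taxa)) {
    if (is.null(scan)) abort("give either `scan` or `taxa`")
    taxa <- sort(unique(scan$table$taxon_id[scan$table$is_candidate]))
  }
  if (length(taxa) < 2) abort("need >= 2 taxa to cluster")
  keep <- samples$sample_id[samples$group %in% include_groups]
  if (length(keep) < 2) abort("need >= 2 samples to cluster")

  wide <- hr |>
    filter(.data$taxon_id %in% taxa, .data$sample_id %in% keep) |>
    log2_transform(pseudocount = pseudocount) |>
    select("taxon_id", "sample_id", "log2_hr") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "log2_hr",
                       values_fill = log2(pseudocount))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$taxon_id
  centered <- center_rows(m)

  row_tree <- hierarchical_cluster(centered, "rows", metric, linkage)
  col_tree <- hierarchical_cluster(centered, "columns", metric, linkage)

  structure(
    list(
      matrix = centered,
      row_tree = row_tree, col_tree = col_tree,
      row_order = rownames(centered)[row_tree$order],
      col_order = colnames(centered)[col_tree$order],
      samples = filter(samples, .data$sample_id %in% colnames(centered))
    ),
    class = "taxon_clustering"
  )
}

#' @export
print.taxon_clustering <- function(x, ...) {
  cat("<taxon_clustering> ", nrow(x$matrix), " taxa x ", ncol(x$matrix),
      " samples (row-centered log2 HR)\n", sep = "")
  invisible(x)
}

#' @method tidy taxon_clustering
#' @export
tidy.taxon_clustering <- function(x, ...) {
  as_tibble(x$matrix, rownames = "taxon_id") |>
    tidyr::pivot_longer(-"taxon_id", names_to = "sample_id",
                        values_to = "centered_log2_hr")
}

#' @rdname cluster_candidates
#' @param object A `taxon_clustering`.
#' @param ... Ignored.
#' @method autoplot taxon_clustering
#' @export
autoplot.taxon_clustering <- function(object, ...) {
  long <- tidy(object) |>
    mutate(
      taxon_id = factor(.data$taxon_id, levels = object$row_order),
      sample_id = factor(.data$sample_id, levels = object$col_order)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$taxon_id,
                                     fill = .data$centered_log2_hr)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#1f5bd6", mid = "black",
                                  high = "#ffd400", midpoint = 0,
                                  name = "centered\nlog2 HR") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
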