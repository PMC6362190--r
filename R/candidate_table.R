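#' Published candidate-genus table
#'
#' A transcription of a published table of microbial candidate genera from a
#' deep-sequencing study of demyelinating brain lesions: the 29 genera that
#' were significantly overrepresented (q < 0.05) in at least one case
#' specimen and had at least 100 mapped read pairs across the case group.
#' Columns: `phylum` (the label printed in the table; viruses carry the
#' label "Viruses" rather than a phylum), `family`, `genus`,
#' `ms_mapped_reads`, `control_mapped_reads`, `ms_specimens_increased`,
#' `pathogen`, `ecology`, and a curated `kingdom` column ("Bacteria",
#' "Fungi" or "Viruses") derived from the phylum label.
#'
#' @return A tibble with 29 rows.
#' @export
read_candidate_genus_table <- function() {
  path <- system.file("extdata", "candidate_genera.tsv",
                      package = "taxoutlier", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Apply the mapped-read filter to a candidate-genus table
#'
#' Keeps genera with at least `read_min` mapped reads summed over the case
#' group (non-strict, "at least" semantics).
#'
#' @param table Data frame with an `ms_mapped_reads` column.
#' @param read_min Minimum case-group mapped reads (default 100).
#' @return The filtered tibble.
#' @export
filter_candidate_genera <- function(table, read_min = 100) {
  filter(as_tibble(table), .data$ms_mapped_reads >= read_min)
}

#' Composition of a candidate-genus table
#'
#' Counts genera, distinct phylum labels, and genera per kingdom.
#'
#' @param table Data frame with `genus`, `phylum` and `kingdom` columns.
#' @return A one-row tibble: `n_genera`, `n_phylum_labels`, `n_bacterial`,
#'   `n_fungal`, `n_viral`.
#' @export
candidate_composition <- function(table) {
  table <- as_tibble(table)
  tibble(
    n_genera = length(unique(table$genus)),
    n_phylum_labels = length(unique(table$phylum)),
    n_bacterial = sum(table$kingdom == "Bacteria"),
    n_fungal = sum(table$kingdom == "Fungi"),
    n_viral = sum(table$kingdom == "Viruses")
  )
}
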