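#' Validate a sample metadata table
#'
#' @param samples Data frame with columns `sample_id`, `group` (one of
#'   `"MS"`, `"control"`, `"OND"`, `"blank"` by convention, though arbitrary
#'   case labels are allowed), `run`, `hq_pairs`.
#' @return The validated tibble (invisibly usable in pipes).
#' @keywords internal
validate_samples <- function(samples) {
  samples <- as_tibble(samples)
  req <- c("sample_id", "group", "run", "hq_pairs")
  if (!all(req %in% colnames(samples))) {
    abort(paste0("`samples` must have columns: ", paste(req, collapse = ", ")))
  }
  if (anyDuplicated(samples$sample_id)) {
    abort(paste0("duplicated sample ids: ",
                 paste(unique(samples$sample_id[duplicated(samples$sample_id)]), collapse = ", ")))
  }
  bad <- samples$sample_id[is.na(samples$hq_pairs) | samples$hq_pairs <= 0]
  if (length(bad) > 0) {
    abort(paste0("hq_pairs must be positive; offending sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (any(is.na(samples$group)) || any(is.na(samples$run))) {
    abort("group and run must be defined for every sample")
  }
  samples
}

#' Normalize counts to pairs-per-million hit rates
#'
#' The hit rate (HR) of a taxon in a sample is its concordant-pair count
#' divided by the sample's total high-quality read pairs in millions:
#' `hr = count / hq_pairs * 1e6` (pairs per million, PPM). The denominator is
#' the sample's *total* HQ pairs from upstream QC, including human-mapping
#' pairs. The returned table is completed to the full taxa-by-samples grid
#' (absent combinations get count 0), so downstream per-taxon statistics see
#' every sample.
#'
#' @param counts Data frame with columns `taxon_id`, `sample_id`, `count`.
#' @param samples Sample metadata (`sample_id`, `group`, `run`, `hq_pairs`).
#' @return A tibble with columns `taxon_id`, `sample_id`, `count`, `hr`.
#' @export
compute_hr <- function(counts, samples) {
  samples <- validate_samples(samples)
  counts <- as_tibble(counts)
  req <- c("taxon_id", "sample_id", "count")
  if (!all(req %in% colnames(counts))) {
    abort(paste0("`counts` must have columns: ", paste(req, collapse = ", ")))
  }
  orphan <- setdiff(unique(counts$sample_id), samples$sample_id)
  if (length(orphan) > 0) {
    abort(paste0("count table has sample(s) missing from metadata: ",
                 paste(orphan, collapse = ", ")))
  }
  taxa <- sort(unique(counts$taxon_id))
  grid <- tidyr::expand_grid(taxon_id = taxa, sample_id = samples$sample_id)
  grid |>
    left_join(select(counts, all_of(req)), by = c("taxon_id", "sample_id")) |>
    mutate(count = coalesce(.data$count, 0)) |>
    left_join(select(samples, "sample_id", "hq_pairs"), by = "sample_id") |>
    mutate(hr = .data$count / .data$hq_pairs * 1e6) |>
    select("taxon_id", "sample_id", "count", "hr")
}

#' Per-sample microbial fraction
#'
#' Total microbial concordant pairs of a sample divided by its HQ pairs,
#' times 1e6 — the sample-level summary compared between groups.
#'
#' @param counts Data frame with columns `taxon_id`, `sample_id`, `count`.
#' @param samples Sample metadata.
#' @param sample_id Optional subset of samples; default all in `samples`.
#' @return A tibble with columns `sample_id`, `group`, `run`,
#'   `microbial_pairs`, `hq_pairs`, `fraction_ppm`.
#' @export
microbial_fraction <- function(counts, samples, sample_id = NULL) {
  samples <- validate_samples(samples)
  if (!is.null(sample_id)) {
    unknown <- setdiff(sample_id, samples$sample_id)
    if (length(unknown) > 0) {
      abort(paste0("unknown sample(s): ", paste(unknown, collapse = ", ")))
    }
    samples <- filter(samples, .data$sample_id %in% !!sample_id)
  }
  totals <- as_tibble(counts) |>
    group_by(.data$sample_id) |>
    summarise(microbial_pairs = sum(.data$count), .groups = "drop")
  samples |>
    left_join(totals, by = "sample_id") |>
    mutate(
      microbial_pairs = coalesce(.data$microbial_pairs, 0),
      fraction_ppm = .data$microbial_pairs / .data$hq_pairs * 1e6
    ) |>
    select("sample_id", "group", "run", "microbial_pairs", "hq_pairs", "fraction_ppm")
}

#' Read and write wide count matrices
#'
#' The on-disk layout is a wide TSV: first column `taxon_id`, one column per
#' sample. Sample metadata travels in its own TSV (`sample_id`, `group`,
#' `run`, `hq_pairs`).
#'
#' @param path File path.
#' @return `read_count_table()`: a long tibble (`taxon_id`, `sample_id`,
#'   `count`).
#' @export
read_count_table <- function(path) {
  wide <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (colnames(wide)[1] != "taxon_id") {
    abort("count table must have `taxon_id` as its first column")
  }
  tidyr::pivot_longer(wide, -"taxon_id",
                      names_to = "sample_id", values_to = "count")
}

#' @rdname read_count_table
#' @param counts Long count tibble (`taxon_id`, `sample_id`, `count`).
#' @export
write_count_table <- function(counts, path) {
  wide <- as_tibble(counts) |>
    select("taxon_id", "sample_id", "count") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0) |>
    arrange(.data$taxon_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' @rdname read_count_table
#' @export
read_sample_metadata <- function(path) {
  validate_samples(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
}
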