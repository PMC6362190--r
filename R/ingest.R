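#' Build a reference catalog
#'
#' Labels every reference sequence in the alignment database as human, PhiX
#' sequencing control, or microbial. Microbial references carry the taxonomy
#' sequence id used for aggregation and, where known, the reference length
#' (needed for coverage profiles).
#'
#' @param reference_id Character vector of reference names as they appear in
#'   SAM `RNAME`.
#' @param class One of `"human"`, `"phix"`, `"microbial"` per reference.
#' @param sequence_id Taxonomy sequence id per reference; defaults to
#'   `reference_id` for microbial references, `NA` otherwise.
#' @param length Reference length in bp (`NA` if unknown).
#' @return A tibble of class `reference_catalog`.
#' @export
reference_catalog <- function(reference_id, class,
                              sequence_id = NULL, length = NA_integer_) {
  class <- as.character(class)
  bad <- setdiff(unique(class), c("human", "phix", "microbial"))
  if (length(bad) > 0) {
    abort(paste0("unknown reference class(es): ", paste(bad, collapse = ", "),
                 " (expected human, phix, microbial)"))
  }
  reference_id <- as.character(reference_id)
  if (anyDuplicated(reference_id)) {
    abort(paste0("duplicated reference ids: ",
                 paste(unique(reference_id[duplicated(reference_id)]), collapse = ", ")))
  }
  if (is.null(sequence_id)) {
    sequence_id <- ifelse(class == "microbial", reference_id, NA_character_)
  }
  out <- tibble(
    reference_id = reference_id,
    class = class,
    sequence_id = as.character(sequence_id),
    length = as.integer(length)
  )
  class(out) <- c("reference_catalog", class(out))
  out
}

#' Read paired-end alignment records from a SAM/BAM file
#'
#' Parses the fields the concordant-pair counter needs (QNAME, FLAG, RNAME,
#' POS, MAPQ) via Rsamtools. Plain-text SAM input is converted to BAM in a
#' temporary directory first. Secondary and supplementary alignments are
#' flagged so that only primary records enter pair counting.
#'
#' @param path Path to a SAM (`.sam`) or BAM file.
#' @param sample_id Sample label attached to every record; defaults to the
#'   file name without extension.
#' @return A tibble with columns `read_id`, `mate` (1/2), `reference_id`,
#'   `position`, `mapq`, `unmapped`, `secondary`, `sample_id`.
#' @export
read_sam_pairs <- function(path, sample_id = NULL) {
  if (!file.exists(path)) abort(paste0("alignment file not found: ", path))
  if (is.null(sample_id)) {
    sample_id <- sub("\\.(sam|bam)$", "", basename(path), ignore.case = TRUE)
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  flag <- b$flag
  tibble(
    read_id = b$qname,
    mate = ifelse(bitwAnd(flag, 128L) > 0L, 2L, 1L),
    reference_id = as.character(b$rname),
    position = b$pos,
    mapq = b$mapq,
    unmapped = bitwAnd(flag, 4L) > 0L,
    secondary = bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L,
    sample_id = sample_id
  )
}

#' Count concordant microbial read pairs
#'
#' Implements the pair-level filter at the head of the pipeline: a read pair
#' is counted for a reference sequence R iff both mates map to R, R is
#' microbial, and both mates have `mapq >= mapq_min`. Pairs with any human or
#' PhiX mate go to the human/control tally and never to microbial counts;
#' mates on different microbial references are discordant; pairs failing the
#' MAPQ rule are tallied separately. Each read pair contributes at most one
#' count to exactly one bucket, so the tallies partition the input pairs.
#'
#' Only primary alignments are considered ("mapping once" semantics of a
#' best-hit aligner); secondary/supplementary records are dropped up front.
#'
#' @param records Record tibble as returned by [read_sam_pairs()].
#' @param catalog A [reference_catalog()].
#' @param mapq_min Minimum MAPQ required of *both* mates (default 10, i.e. a
#'   >90\% single-mate mapping probability; see [mapq_to_probability()]).
#' @param hq_pairs Total high-quality read pairs for this sample from
#'   upstream QC (the pairs-per-million denominator); carried, not recomputed.
#' @param sample_id Optional sample label; defaults to the one in `records`.
#' @return An object of class `sample_alignment_summary`: a list with
#'   `counts` (tibble `reference_id`, `sequence_id`, `pairs`), `tallies`
#'   (tibble `category`, `pairs`), `n_pairs`, `hq_pairs`, `sample_id`,
#'   `mapq_min`.
#' @export
count_concordant_pairs <- function(records, catalog, mapq_min = 10,
                                   hq_pairs = NA_real_, sample_id = NULL) {
  stopifnot(mapq_min >= 0)
  records <- as_tibble(records)
  if (is.null(sample_id)) {
    sample_id <- if ("sample_id" %in% colnames(records) && nrow(records) > 0) {
      records$sample_id[[1]]
    } else NA_character_
  }
  if (!"secondary" %in% colnames(records)) records$secondary <- FALSE
  if (!"unmapped" %in% colnames(records)) records$unmapped <- FALSE
  records <- filter(records, !.data$secondary)

  dup <- records |>
    count(.data$read_id, .data$mate) |>
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("malformed input: multiple primary records for read/mate: ",
                 paste(head(paste0(dup$read_id, "/", dup$mate), 5), collapse = ", ")))
  }

  mapped <- filter(records, !.data$unmapped)
  unknown_ref <- setdiff(unique(mapped$reference_id), catalog$reference_id)
  if (length(unknown_ref) > 0) {
    abort(paste0("reference id(s) absent from catalog: ",
                 paste(unknown_ref, collapse = ", ")))
  }

  cat_min <- select(catalog, "reference_id", "class", "sequence_id")
  recs <- records |>
    left_join(cat_min, by = "reference_id") |>
    mutate(class = ifelse(.data$unmapped, NA_character_, .data$class))

  pairs <- recs |>
    select("read_id", "mate", "reference_id", "mapq", "unmapped", "class") |>
    tidyr::pivot_wider(
      names_from = "mate",
      values_from = c("reference_id", "mapq", "unmapped", "class"),
      names_sep = "_"
    )
  for (col in c("reference_id_1", "reference_id_2", "class_1", "class_2")) {
    if (!col %in% colnames(pairs)) pairs[[col]] <- NA_character_
  }
  for (col in c("mapq_1", "mapq_2")) {
    if (!col %in% colnames(pairs)) pairs[[col]] <- NA_integer_
  }
  for (col in c("unmapped_1", "unmapped_2")) {
    if (!col %in% colnames(pairs)) pairs[[col]] <- NA
  }

  pairs <- pairs |>
    mutate(
      singleton = is.na(.data$unmapped_1) | is.na(.data$unmapped_2),
      any_unmapped = coalesce(.data$unmapped_1, TRUE) | coalesce(.data$unmapped_2, TRUE),
      any_host = coalesce(.data$class_1 %in% c("human", "phix"), FALSE) |
        coalesce(.data$class_2 %in% c("human", "phix"), FALSE),
      category = case_when(
        singleton | any_unmapped ~ ifelse(any_host, "human_phix", "unmapped_or_singleton"),
        any_host ~ "human_phix",
        .data$reference_id_1 != .data$reference_id_2 ~ "discordant",
        .data$mapq_1 >= mapq_min & .data$mapq_2 >= mapq_min ~ "concordant_retained",
        TRUE ~ "concordant_low_mapq"
      )
    )

  counts <- pairs |>
    filter(.data$category == "concordant_retained") |>
    count(reference_id = .data$reference_id_1, name = "pairs") |>
    left_join(cat_min, by = "reference_id") |>
    select("reference_id", "sequence_id", "pairs") |>
    arrange(.data$reference_id)

  tallies <- pairs |>
    count(.data$category, name = "pairs") |>
    tidyr::complete(
      category = c("human_phix", "concordant_retained", "concordant_low_mapq",
                   "discordant", "unmapped_or_singleton"),
      fill = list(pairs = 0L)
    )

  structure(
    list(
      sample_id = sample_id,
      hq_pairs = hq_pairs,
      mapq_min = mapq_min,
      n_pairs = nrow(pairs),
      counts = counts,
      tallies = tallies
    ),
    class = "sample_alignment_summary"
  )
}

#' @export
print.sample_alignment_summary <- function(x, ...) {
  cat("<sample_alignment_summary> sample ", x$sample_id,
      ": ", x$n_pairs, " read pairs, mapq_min ", x$mapq_min, "\n", sep = "")
  print(x$tallies)
  invisible(x)
}

#' @method tidy sample_alignment_summary
#' @export
tidy.sample_alignment_summary <- function(x, ...) {
  mutate(x$counts, sample_id = x$sample_id, .before = 1)
}

#' @method glance sample_alignment_summary
#' @export
glance.sample_alignment_summary <- function(x, ...) {
  wide <- tidyr::pivot_wider(x$tallies, names_from = "category", values_from = "pairs")
  mutate(wide,
         sample_id = x$sample_id, hq_pairs = x$hq_pairs,
         n_pairs = x$n_pairs, .before = 1)
}

#' Probability that a single alignment is correctly placed
#'
#' MAPQ is a Phred-scaled mapping-error probability, so the probability that
#' a reported alignment is the correct placement is `1 - 10^(-mapq/10)`.
#' A MAPQ 10 filter therefore retains alignments with a >90\% probability of
#' being the single best match.
#'
#' @param mapq Nonnegative integer vector.
#' @return Probabilities in `[0, 1)`.
#' @export
mapq_to_probability <- function(mapq) {
  if (any(!is.finite(mapq)) || any(mapq < 0)) abort("mapq must be finite and >= 0")
  1 - 10^(-mapq / 10)
}

#' Probability that a concordant pair is correctly placed
#'
#' Under independent mate placement, a pair is mismapped only if both mates
#' are, so the correct-mapping probability is
#' `1 - 10^(-mapq1/10) * 10^(-mapq2/10)`. Two mates at the MAPQ 10 threshold
#' give 0.99.
#'
#' @param mapq1,mapq2 Nonnegative integer vectors (recycled).
#' @return Probabilities in `[0, 1)`.
#' @export
pair_probability <- function(mapq1, mapq2) {
  if (any(!is.finite(c(mapq1, mapq2))) || any(c(mapq1, mapq2) < 0)) {
    abort("mapq must be finite and >= 0")
  }
  1 - 10^(-(mapq1 + mapq2) / 10)
}

#' Binned coverage profile of concordant pairs along a reference
#'
#' Counts concordant read pairs in fixed-width bins tiling
#' `[1, reference_length]`; each pair contributes once, at the leftmost
#' mapped position of its two mates. Used to inspect where on a candidate
#' genome the RNA signal comes from (e.g. rRNA operons vs. the rest of a
#' bacterial chromosome).
#'
#' @param records Record tibble as returned by [read_sam_pairs()].
#' @param catalog A [reference_catalog()] with a `length` for the reference.
#' @param reference_id Reference to profile.
#' @param bin_width Bin width in bp (>= 1).
#' @param mapq_min Minimum MAPQ for both mates; default 0 (no filter), the
#'   convention for raw mapping displays.
#' @return A tibble of class `coverage_profile` with columns `bin_start`,
#'   `bin_end`, `pairs`.
#' @export
coverage_profile <- function(records, catalog, reference_id, bin_width,
                             mapq_min = 0) {
  stopifnot(bin_width >= 1)
  row <- filter(catalog, .data$reference_id == !!reference_id)
  if (nrow(row) == 0) abort(paste0("unknown reference: ", reference_id))
  len <- row$length[[1]]
  if (is.na(len)) abort(paste0("no length recorded for reference: ", reference_id))

  recs <- filter(as_tibble(records), !.data$unmapped,
                 !coalesce(.data$secondary, FALSE),
                 .data$reference_id == !!reference_id)
  prs <- if (nrow(recs) == 0) {
    tibble(read_id = character(), position = integer())
  } else {
    recs |>
      group_by(.data$read_id) |>
      filter(n() == 2, all(.data$mapq >= mapq_min)) |>
      summarise(position = min(.data$position), .groups = "drop")
  }

  starts <- seq.int(1L, len, by = bin_width)
  idx <- pmin(((prs$position - 1L) %/% bin_width) + 1L, length(starts))
  out <- tibble(
    bin_start = starts,
    bin_end = pmin(starts + bin_width - 1L, as.integer(len)),
    pairs = as.integer(tabulate(idx, nbins = length(starts)))
  )
  attr(out, "reference_id") <- reference_id
  attr(out, "bin_width") <- bin_width
  class(out) <- c("coverage_profile", class(out))
  out
}

#' @rdname coverage_profile
#' @param object A `coverage_profile`.
#' @param ... Ignored.
#' @method autoplot coverage_profile
#' @export
autoplot.coverage_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_start, y = .data$pairs)) +
    ggplot2::geom_col(width = attr(object, "bin_width"), fill = "grey25") +
    ggplot2::labs(
      x = paste0("position on ", attr(object, "reference_id"), " (bp)"),
      y = "concordant read pairs"
    ) +
    ggplot2::theme_minimal()
}
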