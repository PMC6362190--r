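#' In-memory analysis of a sequence-level count matrix
#'
#' Runs the statistical stages of the pipeline on an already-ingested
#' sequence-level count table: aggregate to `rank`, normalize to PPM hit
#' rates, exclude blank-flagged artifact taxa, scan every case sample for
#' overrepresented taxa, summarize candidates, cluster them, and compare
#' group-level microbial fractions.
#'
#' @param counts Sequence-level count tibble (`sequence_id`, `sample_id`,
#'   `count`).
#' @param taxonomy A [taxonomy_tree()].
#' @param samples Sample metadata.
#' @param rank Analysis rank (default `"genus"`).
#' @param case_groups Group labels scored as cases (default `"MS"`).
#' @param q_threshold,hr_threshold,pseudocount,sd_floor,family Passed to
#'   [detect_candidates()].
#' @param read_min Passed to [summarize_candidates()].
#' @param blank_filter Apply [exclude_artifacts()] (default `TRUE`).
#' @param cluster Build the candidate-taxon clustering when at least two
#'   candidate taxa exist (default `TRUE`).
#' @param compare_groups Two group labels for the microbial-fraction
#'   comparison, or `NULL` to skip (default case vs control).
#' @return A list of class `taxon_outlier_analysis` with elements `counts`
#'   (aggregated), `hr`, `artifact_filter`, `scan`, `candidate_summary`,
#'   `clustering` (or `NULL`), `group_comparison` (or `NULL`), `params`.
#' @export
analyze_counts <- function(counts, taxonomy, samples, rank = "genus",
                           case_groups = "MS",
                           q_threshold = 0.05, hr_threshold = 1.0,
                           pseudocount = 1, sd_floor = 1e-6,
                           family = "per_sample", read_min = 100,
                           blank_filter = TRUE, cluster = TRUE,
                           compare_groups = c("MS", "control")) {
  samples <- validate_samples(samples)

  agg <- aggregate_counts(counts, taxonomy, rank) |>
    filter(!.data$unranked) |>
    select("taxon_id", "sample_id", "count")
  hr <- compute_hr(agg, samples)

  filt <- exclude_artifacts(hr, samples, bypass = !blank_filter)
  scan <- detect_candidates(
    filt$hr, samples, case_groups = case_groups,
    q_threshold = q_threshold, hr_threshold = hr_threshold,
    pseudocount = pseudocount, sd_floor = sd_floor, family = family
  )
  summary <- summarize_candidates(scan, agg, samples, read_min = read_min)

  clustering <- NULL
  if (cluster &&
      length(unique(scan$table$taxon_id[scan$table$is_candidate])) >= 2) {
    clustering <- cluster_candidates(filt$hr, samples, scan = scan,
                                     pseudocount = pseudocount)
  }

  comparison <- NULL
  if (!is.null(compare_groups)) {
    comparison <- group_fraction_comparison(counts |> rename(taxon_id = "sequence_id"),
                                            samples,
                                            group_a = compare_groups[1],
                                            group_b = compare_groups[2])
  }

  structure(
    list(
      counts = agg, hr = hr, artifact_filter = filt, scan = scan,
      candidate_summary = summary, clustering = clustering,
      group_comparison = comparison,
      params = list(rank = rank, case_groups = case_groups,
                    q_threshold = q_threshold, hr_threshold = hr_threshold,
                    pseudocount = pseudocount, sd_floor = sd_floor,
                    family = family, read_min = read_min,
                    blank_filter = blank_filter)
    ),
    class = "taxon_outlier_analysis"
  )
}

#' @export
print.taxon_outlier_analysis <- function(x, ...) {
  cat("<taxon_outlier_analysis> rank = ", x$params$rank, "\n", sep = "")
  print(x$scan)
  cat(sum(x$candidate_summary$passes_read_filter),
      " candidate taxa pass the ", x$params$read_min,
      "-read case-group filter\n", sep = "")
  invisible(x)
}

#' @method glance taxon_outlier_analysis
#' @export
glance.taxon_outlier_analysis <- function(x, ...) {
  g <- glance(x$scan)
  g$n_taxa_analyzed <- length(unique(x$hr$taxon_id))
  g$n_taxa_excluded_blank <- sum(x$artifact_filter$report$excluded)
  g$n_candidates_read_filtered <- sum(x$candidate_summary$passes_read_filter)
  if (!is.null(x$group_comparison)) {
    g$fraction_p_value <- x$group_comparison$test$p.value
  }
  g
}

read_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    if (!file.exists(config)) abort(paste0("config file not found: ", config))
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) abort("config must be a list or a YAML file path")
  config
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  res
}

#' Run the full pipeline from files on disk
#'
#' File-level orchestration of the analysis: read sample metadata, taxonomy
#' and per-sample SAM alignments (or a pre-counted sequence-level table),
#' count concordant microbial pairs, then run [analyze_counts()] and write
#' all stage outputs plus a run manifest under `out_dir`.
#'
#' The config is a list (or YAML file) with elements:
#' \describe{
#'   \item{samples}{path to the sample metadata TSV}
#'   \item{taxonomy_nodes, taxonomy_seq_map, taxonomy_names}{taxonomy TSVs
#'     (`taxonomy_names` optional)}
#'   \item{alignments}{directory containing `<sample_id>.sam`, with
#'     `catalog` a TSV of the reference catalog; or instead}
#'   \item{counts}{path to a wide sequence-level count TSV}
#'   \item{out_dir}{output directory}
#'   \item{params}{optional list of [analyze_counts()] arguments, plus
#'     `mapq_min` for ingestion}
#' }
#'
#' @param config List or YAML path as described above.
#' @return The [analyze_counts()] bundle, invisibly, with the manifest
#'   attached as `$manifest`.
#' @export
run_pipeline <- function(config) {
  config <- read_pipeline_config(config)
  for (key in c("samples", "out_dir")) {
    if (is.null(config[[key]])) abort(paste0("config is missing '", key, "'"))
  }
  params <- config$params %||% list()
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  samples <- pipeline_stage("metadata", read_sample_metadata(config$samples))
  taxonomy <- pipeline_stage("taxonomy", read_taxonomy(
    config$taxonomy_nodes, config$taxonomy_seq_map,
    names_file = config$taxonomy_names
  ))

  inputs <- c(samples = config$samples, nodes = config$taxonomy_nodes,
              seq_map = config$taxonomy_seq_map)

  if (!is.null(config$counts)) {
    counts <- pipeline_stage("counts",
      read_count_table(config$counts) |> rename(sequence_id = "taxon_id"))
    inputs <- c(inputs, counts = config$counts)
  } else if (!is.null(config$alignments)) {
    if (is.null(config$catalog)) abort("config with 'alignments' needs 'catalog'")
    catalog_tbl <- readr::read_tsv(config$catalog, show_col_types = FALSE,
                                   progress = FALSE)
    catalog <- reference_catalog(catalog_tbl$reference_id, catalog_tbl$class,
                                 sequence_id = catalog_tbl$sequence_id,
                                 length = catalog_tbl$length)
    mapq_min <- params$mapq_min %||% 10
    counts <- pipeline_stage("ingest", {
      purrr::map_dfr(samples$sample_id, function(s) {
        f <- file.path(config$alignments, paste0(s, ".sam"))
        if (!file.exists(f)) {
          message("  no alignment file for ", s, "; assuming zero pairs")
          return(tibble(sequence_id = character(), sample_id = character(),
                        count = numeric()))
        }
        sm <- count_concordant_pairs(read_sam_pairs(f, sample_id = s),
                                     catalog, mapq_min = mapq_min)
        message("  ", s, ": ", sm$n_pairs, " pairs, ",
                sum(sm$counts$pairs), " concordant microbial retained")
        transmute(sm$counts, sequence_id = .data$sequence_id,
                  sample_id = s, count = as.numeric(.data$pairs))
      })
    })
    inputs <- c(inputs, catalog = config$catalog)
  } else {
    abort("config needs either 'counts' or 'alignments'")
  }

  keep <- intersect(names(params),
                    setdiff(names(formals(analyze_counts)),
                            c("counts", "taxonomy", "samples")))
  result <- pipeline_stage("analysis", do.call(
    analyze_counts, c(list(counts = counts, taxonomy = taxonomy,
                           samples = samples), params[keep])
  ))

  pipeline_stage("write", {
    write_count_table(result$counts, file.path(out_dir, "counts.tsv"))
    readr::write_tsv(result$hr, file.path(out_dir, "hit_rates.tsv"))
    readr::write_tsv(result$artifact_filter$report,
                     file.path(out_dir, "exclusion_report.tsv"))
    readr::write_tsv(tidy(result$scan),
                     file.path(out_dir, "candidate_table.tsv"))
    readr::write_tsv(result$candidate_summary,
                     file.path(out_dir, "candidate_summary.tsv"))
    if (!is.null(result$clustering)) {
      readr::write_tsv(tidy(result$clustering),
                       file.path(out_dir, "clustered_matrix.tsv"))
      readr::write_lines(
        c(paste("row_order:", paste(result$clustering$row_order, collapse = "\t")),
          paste("col_order:", paste(result$clustering$col_order, collapse = "\t"))),
        file.path(out_dir, "cluster_orders.txt")
      )
    }
    if (!is.null(result$group_comparison)) {
      jsonlite::write_json(glance(result$group_comparison),
                           file.path(out_dir, "group_comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    TRUE
  })

  outputs <- list.files(out_dir, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("taxoutlier")),
    params = result$params,
    inputs = as.list(tools::md5sum(unname(inputs))),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  result$manifest <- manifest
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
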