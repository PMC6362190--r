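#' Exclude run-artifact taxa using blank specimens
#'
#' Sequencing runs can carry reagent/environmental contamination that shows
#' up in blank (paraffin-only, no tissue) specimens. A taxon is excluded from
#' the whole analysis when its hit rate in one or both blanks is strictly
#' greater than the mean hit rate of that taxon across the run-1 control
#' samples. Ties are retained (`0 > 0` is false, so taxa absent everywhere
#' survive). Exclusion removes the taxon from all samples and both runs;
#' `scope = "run2"` restricts removal to run-2 samples as a documented
#' variant.
#'
#' @param hr Hit-rate tibble from [compute_hr()] (`taxon_id`, `sample_id`,
#'   `count`, `hr`).
#' @param samples Sample metadata; must contain at least one `blank` sample
#'   and one run-1 `control` sample unless `bypass = TRUE`.
#' @param scope `"global"` (default) removes excluded taxa everywhere;
#'   `"run2"` removes them from run-2 samples only.
#' @param bypass If `TRUE`, skip the filter (with a warning) and return the
#'   input unchanged alongside an empty report.
#' @return A list of class `artifact_filter` with elements `hr` (filtered
#'   tibble) and `report` (tibble `taxon_id`, `max_blank_hr`,
#'   `run1_control_mean_hr`, `excluded`).
#' @export
exclude_artifacts <- function(hr, samples, scope = c("global", "run2"),
                              bypass = FALSE) {
  scope <- match.arg(scope)
  samples <- validate_samples(samples)
  hr <- as_tibble(hr)

  report0 <- tibble(taxon_id = character(), max_blank_hr = numeric(),
                    run1_control_mean_hr = numeric(), excluded = logical())
  if (bypass) {
    warn("blank-based artifact filter bypassed; no taxa excluded")
    return(structure(list(hr = hr, report = report0), class = "artifact_filter"))
  }

  blanks <- samples$sample_id[samples$group == "blank"]
  run1_controls <- samples$sample_id[samples$group == "control" & samples$run == 1]
  if (length(blanks) == 0 || length(run1_controls) == 0) {
    abort(paste0(
      "artifact filter needs >= 1 blank and >= 1 run-1 control sample (found ",
      length(blanks), " blank(s), ", length(run1_controls),
      " run-1 control(s)); pass bypass = TRUE to skip explicitly"
    ))
  }

  report <- hr |>
    group_by(.data$taxon_id) |>
    summarise(
      max_blank_hr = if (any(.data$sample_id %in% blanks))
        max(.data$hr[.data$sample_id %in% blanks]) else 0,
      run1_control_mean_hr = if (any(.data$sample_id %in% run1_controls))
        mean(.data$hr[.data$sample_id %in% run1_controls]) else 0,
      .groups = "drop"
    ) |>
    mutate(excluded = .data$max_blank_hr > .data$run1_control_mean_hr)

  excluded_taxa <- report$taxon_id[report$excluded]
  filtered <- if (scope == "global") {
    filter(hr, !.data$taxon_id %in% excluded_taxa)
  } else {
    run2 <- samples$sample_id[samples$run == 2]
    filter(hr, !(.data$taxon_id %in% excluded_taxa & .data$sample_id %in% run2))
  }
  structure(list(hr = filtered, report = report), class = "artifact_filter")
}

#' @export
print.artifact_filter <- function(x, ...) {
  cat("<artifact_filter> ", sum(x$report$excluded), " taxa excluded, ",
      length(unique(x$hr$taxon_id)), " retained\n", sep = "")
  invisible(x)
}

#' @method tidy artifact_filter
#' @export
tidy.artifact_filter <- function(x, ...) x$report
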