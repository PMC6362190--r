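#' Log2-transform hit rates
#'
#' Hit rates are log2-transformed with a pseudocount before outlier scoring:
#' `log2(hr + pseudocount)`. The default pseudocount of 1 PPM bounds the
#' transform at 0 for absent taxa and matches the scale of the candidate
#' hit-rate threshold.
#'
#' @param hr Numeric vector of hit rates in PPM, or a data frame with an
#'   `hr` column (a `log2_hr` column is then added).
#' @param pseudocount Positive PPM offset (default 1).
#' @return Transformed vector, or the input data frame with `log2_hr`.
#' @export
log2_transform <- function(hr, pseudocount = 1) {
  if (!is.numeric(pseudocount) || length(pseudocount) != 1 || pseudocount <= 0) {
    abort("pseudocount must be a single positive number")
  }
  if (is.data.frame(hr)) {
    return(mutate(as_tibble(hr), log2_hr = log2(.data$hr + pseudocount)))
  }
  log2(hr + pseudocount)
}

#' Per-taxon Z-scores of one case sample against the controls
#'
#' For each taxon, the case sample's log2 hit rate is standardized against
#' the control samples: `z = (x_case - mean(controls)) / sd(controls)` with
#' the sample (n-1) standard deviation. Taxa whose control standard
#' deviation falls below `sd_floor` are flagged untestable (`z` is `NA`) and
#' are excluded from the multiple-testing family rather than assigned an
#' infinite score.
#'
#' @param transformed Tibble with columns `taxon_id`, `sample_id`,
#'   `log2_hr` (see [log2_transform()]).
#' @param case_sample_id Single case sample id.
#' @param control_sample_ids At least 3 control sample ids, not containing
#'   the case sample.
#' @param sd_floor Smallest control sd (log2 units) considered testable.
#' @return Tibble `taxon_id`, `log2_hr` (case value), `control_mean`,
#'   `control_sd`, `z`, `testable`.
#' @export
sample_zscores <- function(transformed, case_sample_id, control_sample_ids,
                           sd_floor = 1e-6) {
  if (length(control_sample_ids) < 3) {
    abort("need at least 3 control samples for a Z-score")
  }
  if (case_sample_id %in% control_sample_ids) {
    abort(paste0("case sample ", case_sample_id, " is listed among the controls"))
  }
  transformed <- as_tibble(transformed)
  missing <- setdiff(c(case_sample_id, control_sample_ids),
                     unique(transformed$sample_id))
  if (length(missing) > 0) {
    abort(paste0("sample(s) absent from transformed table: ",
                 paste(missing, collapse = ", ")))
  }

  ctrl <- transformed |>
    filter(.data$sample_id %in% control_sample_ids) |>
    group_by(.data$taxon_id) |>
    summarise(
      control_mean = mean(.data$log2_hr),
      control_sd = sd(.data$log2_hr),
      n_controls = n(),
      .groups = "drop"
    )
  if (any(ctrl$n_controls != length(control_sample_ids))) {
    abort("transformed table is not complete over the control samples")
  }

  transformed |>
    filter(.data$sample_id == case_sample_id) |>
    select("taxon_id", "log2_hr") |>
    left_join(select(ctrl, -"n_controls"), by = "taxon_id") |>
    mutate(
      testable = .data$control_sd >= sd_floor,
      z = ifelse(.data$testable,
                 (.data$log2_hr - .data$control_mean) / .data$control_sd,
                 NA_real_)
    )
}

#' One-tailed p-value for overrepresentation
#'
#' Converts Z-scores to upper-tail standard normal probabilities. Only
#' overrepresentation is of interest, so the test is one-tailed:
#' `p = P(Z >= z)`.
#'
#' @param z Numeric vector; `NA` passes through.
#' @return p-values in `[0, 1]`.
#' @export
one_tailed_p <- function(z) {
  if (any(!is.finite(z) & !is.na(z))) abort("z must be finite (or NA)")
  pnorm(z, lower.tail = FALSE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment: with order statistics `p_(1) <= ... <= p_(m)`,
#' `q_(i) = min_{j >= i} (m * p_(j) / j)`, clipped to 1, returned in the
#' input order. Tied p-values share the same q.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order as `p`.
#' @export
bh_qvalues <- function(p) {
  if (length(p) == 0) return(numeric())
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must be in [0, 1] and non-missing")
  }
  m <- length(p)
  o <- order(p)
  q_sorted <- rev(cummin(rev(m * p[o] / seq_len(m))))
  pmin(1, q_sorted)[order(o)]
}

#' Flag candidate (sample, taxon) pairs
#'
#' A taxon is a candidate in a case sample when it is significantly
#' overrepresented (`q < q_threshold`, strict) *and* its raw hit rate in
#' that sample exceeds `hr_threshold` PPM (strict). Untestable taxa are
#' never candidates.
#'
#' @param table Data frame with columns `q`, `hr` and optionally `testable`.
#' @param q_threshold FDR threshold (default 0.05).
#' @param hr_threshold Hit-rate threshold in PPM (default 1.0).
#' @return The table with an `is_candidate` logical column.
#' @export
call_candidates <- function(table, q_threshold = 0.05, hr_threshold = 1.0) {
  table <- as_tibble(table)
  if (!all(c("q", "hr") %in% colnames(table))) {
    abort("`table` must have columns q and hr")
  }
  testable <- if ("testable" %in% colnames(table)) table$testable else !is.na(table$q)
  mutate(table, is_candidate = coalesce(
    testable & .data$q < q_threshold & .data$hr > hr_threshold, FALSE))
}

#' Per-sample outlier scan for overrepresented taxa
#'
#' The core statistic of the package: every case sample is compared, taxon
#' by taxon, to the control cohort. Hit rates are log2-transformed with a
#' pseudocount, standardized against the control distribution
#' ([sample_zscores()]), converted to one-tailed normal p-values and
#' BH-adjusted within a multiple-testing family. By default the family is
#' the set of testable taxa within one case sample (`family =
#' "per_sample"`); `family = "pooled"` adjusts all case samples' tests
#' together as a documented variant. Candidates are called with
#' [call_candidates()].
#'
#' Control samples are those with `group == "control"` (both runs). OND
#' (other-disease) samples are never part of the control distribution; they
#' are scored as case samples only when listed in `case_groups`.
#'
#' @param hr Hit-rate tibble (`taxon_id`, `sample_id`, `count`, `hr`),
#'   typically post [exclude_artifacts()].
#' @param samples Sample metadata.
#' @param case_groups Group labels scored against the controls (default
#'   `"MS"`).
#' @param q_threshold,hr_threshold Candidate thresholds (strict
#'   inequalities; defaults 0.05 and 1.0 PPM).
#' @param pseudocount Pseudocount for [log2_transform()] (default 1 PPM).
#' @param sd_floor Untestability floor for the control sd (default 1e-6).
#' @param family BH family: `"per_sample"` (default) or `"pooled"`.
#' @return An object of class `candidate_scan`; `tidy()` returns the full
#'   per-(sample, taxon) table with `hr`, `log2_hr`, `z`, `p`, `q`,
#'   `testable`, `is_candidate`.
#' @export
detect_candidates <- function(hr, samples, case_groups = "MS",
                              q_threshold = 0.05, hr_threshold = 1.0,
                              pseudocount = 1, sd_floor = 1e-6,
                              family = c("per_sample", "pooled")) {
  family <- match.arg(family)
  samples <- validate_samples(samples)
  hr <- as_tibble(hr)

  controls <- samples$sample_id[samples$group == "control"]
  cases <- samples$sample_id[samples$group %in% case_groups]
  if (length(cases) == 0) {
    abort(paste0("no samples in case group(s): ", paste(case_groups, collapse = ", ")))
  }
  transformed <- log2_transform(hr, pseudocount = pseudocount)

  per_case <- purrr::map(cases, function(s) {
    z <- sample_zscores(transformed, s, controls, sd_floor = sd_floor)
    z$p <- one_tailed_p(z$z)
    mutate(z, sample_id = s, .before = 1)
  })
  table <- bind_rows(per_case)

  if (family == "per_sample") {
    table <- table |>
      group_by(.data$sample_id) |>
      mutate(q = {
        qq <- rep(NA_real_, n())
        qq[.data$testable] <- bh_qvalues(.data$p[.data$testable])
        qq
      }) |>
      ungroup()
  } else {
    q <- rep(NA_real_, nrow(table))
    q[table$testable] <- bh_qvalues(table$p[table$testable])
    table$q <- q
  }

  table <- table |>
    left_join(select(hr, "taxon_id", "sample_id", "hr"),
              by = c("taxon_id", "sample_id")) |>
    call_candidates(q_threshold = q_threshold, hr_threshold = hr_threshold) |>
    select("sample_id", "taxon_id", "hr", "log2_hr", "control_mean",
           "control_sd", "z", "p", "q", "testable", "is_candidate") |>
    arrange(.data$sample_id, .data$q, .data$taxon_id)

  structure(
    list(
      table = table,
      case_samples = cases,
      control_samples = controls,
      params = list(q_threshold = q_threshold, hr_threshold = hr_threshold,
                    pseudocount = pseudocount, sd_floor = sd_floor,
                    family = family)
    ),
    class = "candidate_scan"
  )
}

#' @export
print.candidate_scan <- function(x, ...) {
  g <- glance(x)
  cat("<candidate_scan> ", length(x$case_samples), " case samples vs ",
      length(x$control_samples), " controls; ",
      g$n_candidate_calls, " candidate calls over ",
      g$n_candidate_taxa, " taxa (q < ", x$params$q_threshold,
      ", HR > ", x$params$hr_threshold, " PPM)\n", sep = "")
  invisible(x)
}

#' @method tidy candidate_scan
#' @export
tidy.candidate_scan <- function(x, ...) x$table

#' @method glance candidate_scan
#' @export
glance.candidate_scan <- function(x, ...) {
  cand <- filter(x$table, .data$is_candidate)
  tibble(
    n_case_samples = length(x$case_samples),
    n_control_samples = length(x$control_samples),
    n_tests = sum(x$table$testable),
    n_candidate_calls = nrow(cand),
    n_candidate_taxa = length(unique(cand$taxon_id)),
    n_samples_with_candidates = length(unique(cand$sample_id))
  )
}

#' Candidate lists per case sample
#'
#' @param scan A [detect_candidates()] result.
#' @return Tibble of candidate rows ordered by sample then q.
#' @export
sample_candidates <- function(scan) {
  stopifnot(inherits(scan, "candidate_scan"))
  scan$table |>
    filter(.data$is_candidate) |>
    arrange(.data$sample_id, .data$q, desc(.data$hr))
}

#' Cross-sample summary of candidate taxa
#'
#' Summarizes each candidate taxon over the case and control groups: total
#' raw mapped pairs in each group, the number of case specimens where it is
#' significantly increased (`q < q_threshold` among testable tests), and
#' whether the case-group total reaches `read_min` mapped pairs (non-strict
#' "at least" rule) — the filter used to reduce a long significant-genus
#' list to a tractable candidate table.
#'
#' @param scan A [detect_candidates()] result.
#' @param counts Raw count tibble at the same rank (`taxon_id`, `sample_id`,
#'   `count`).
#' @param samples Sample metadata.
#' @param read_min Minimum case-group total mapped pairs (default 100).
#' @return Tibble `taxon_id`, `case_reads`, `control_reads`,
#'   `n_specimens_increased`, `passes_read_filter`, ordered by descending
#'   `case_reads`.
#' @export
summarize_candidates <- function(scan, counts, samples, read_min = 100) {
  stopifnot(inherits(scan, "candidate_scan"))
  samples <- validate_samples(samples)
  counts <- as_tibble(counts)

  cand_taxa <- unique(scan$table$taxon_id[scan$table$is_candidate])
  if (length(cand_taxa) == 0) {
    return(tibble(taxon_id = character(), case_reads = numeric(),
                  control_reads = numeric(), n_specimens_increased = integer(),
                  passes_read_filter = logical()))
  }
  case_ids <- scan$case_samples
  ctrl_ids <- scan$control_samples

  totals <- counts |>
    filter(.data$taxon_id %in% cand_taxa) |>
    group_by(.data$taxon_id) |>
    summarise(
      case_reads = sum(.data$count[.data$sample_id %in% case_ids]),
      control_reads = sum(.data$count[.data$sample_id %in% ctrl_ids]),
      .groups = "drop"
    )

  increased <- scan$table |>
    filter(.data$taxon_id %in% cand_taxa, .data$testable,
           .data$q < scan$params$q_threshold) |>
    count(.data$taxon_id, name = "n_specimens_increased")

  tibble(taxon_id = cand_taxa) |>
    left_join(totals, by = "taxon_id") |>
    left_join(increased, by = "taxon_id") |>
    mutate(
      case_reads = coalesce(.data$case_reads, 0),
      control_reads = coalesce(.data$control_reads, 0),
      n_specimens_increased = coalesce(.data$n_specimens_increased, 0L),
      passes_read_filter = .data$case_reads >= read_min
    ) |>
    arrange(desc(.data$case_reads), .data$taxon_id)
}
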