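#' Mann-Whitney U test
#'
#' Two-sided rank-sum test of two independent groups. The U statistic is the
#' number of pairs `(x_i, y_j)` with `x_i > y_j` plus half the tied pairs.
#' In `mode = "auto"`, the p-value is exact (full null distribution via
#' [stats::pwilcox()]) when `n1 * n2 <= 400` and there are no ties; with
#' ties and a small enough pooled sample the exact p is obtained by full
#' enumeration over all group assignments with midrank U; otherwise a
#' tie-corrected normal approximation with continuity correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @param mode `"auto"` (default), `"exact"` (force enumeration /
#'   distribution; errors if infeasible), or `"normal"`.
#' @return An object of class `mw_test` with elements `statistic` (U for
#'   `x` over `y`), `p.value`, `n1`, `n2`, `method`.
#' @export
mann_whitney <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) abort("both groups must be non-empty")
  if (any(!is.finite(c(x, y)))) abort("inputs must be finite")
  n1 <- length(x)
  n2 <- length(y)
  u <- sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  ties <- anyDuplicated(c(x, y)) > 0

  exact_feasible <- if (!ties) n1 * n2 <= 400 else choose(n1 + n2, n1) <= 2e5
  use_exact <- switch(mode,
    auto = exact_feasible,
    exact = TRUE,
    normal = FALSE
  )
  if (mode == "exact" && !exact_feasible) {
    abort("exact Mann-Whitney infeasible at this sample size; use mode = 'auto'")
  }

  if (use_exact) {
    if (!ties) {
      # symmetric exact null distribution of U
      p <- if (u == n1 * n2 / 2) 1 else if (u < n1 * n2 / 2) {
        2 * pwilcox(u, n1, n2)
      } else {
        2 * (1 - pwilcox(u - 1, n1, n2))
      }
      method <- "exact (distribution)"
    } else {
      pooled <- c(x, y)
      splits <- utils::combn(n1 + n2, n1)
      u_all <- apply(splits, 2, function(idx) {
        xi <- pooled[idx]
        yi <- pooled[-idx]
        sum(outer(xi, yi, ">")) + 0.5 * sum(outer(xi, yi, "=="))
      })
      dev <- abs(u - n1 * n2 / 2)
      p <- mean(abs(u_all - n1 * n2 / 2) >= dev - 1e-12)
      method <- "exact (enumeration, midranks)"
    }
  } else {
    n <- n1 + n2
    tie_tab <- table(c(x, y))
    tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
    v <- n1 * n2 / 12 * ((n + 1) - tie_term)
    mu <- n1 * n2 / 2
    if (v <= 0) {
      p <- 1
    } else {
      cc <- 0.5 * sign(u - mu)
      z <- (u - mu - cc) / sqrt(v)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie-corrected, continuity-corrected)"
  }
  p <- min(1, max(p, 0))

  structure(
    list(statistic = c(U = u), p.value = p, n1 = n1, n2 = n2, method = method),
    class = "mw_test"
  )
}

#' @export
print.mw_test <- function(x, ...) {
  cat("Mann-Whitney U test (", x$method, ")\n",
      "U = ", unname(x$statistic), ", n1 = ", x$n1, ", n2 = ", x$n2,
      ", two-sided p = ", signif(x$p.value, 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy mw_test
#' @export
tidy.mw_test <- function(x, ...) {
  tibble(statistic = unname(x$statistic), p.value = x$p.value,
         n1 = x$n1, n2 = x$n2, method = x$method)
}

#' @method glance mw_test
#' @export
glance.mw_test <- function(x, ...) tidy(x)

#' Compare microbial fractions between two sample groups
#'
#' Computes per-sample microbial fractions ([microbial_fraction()]), group
#' means with standard errors, and a two-sided Mann-Whitney test between the
#' two groups.
#'
#' @param counts Count tibble (`taxon_id`, `sample_id`, `count`), typically
#'   at the sequence level.
#' @param samples Sample metadata.
#' @param group_a,group_b Group labels to compare (defaults `"MS"` vs
#'   `"control"`).
#' @param mode Passed to [mann_whitney()].
#' @return An object of class `group_comparison`; `tidy()` gives per-group
#'   mean/SEM, `glance()` the test.
#' @export
group_fraction_comparison <- function(counts, samples,
                                      group_a = "MS", group_b = "control",
                                      mode = "auto") {
  samples <- validate_samples(samples)
  for (g in c(group_a, group_b)) {
    if (!g %in% samples$group) abort(paste0("unknown group label: ", g))
  }
  frac <- microbial_fraction(counts, samples) |>
    filter(.data$group %in% c(group_a, group_b))
  a <- frac$fraction_ppm[frac$group == group_a]
  b <- frac$fraction_ppm[frac$group == group_b]
  test <- mann_whitney(a, b, mode = mode)
  summary <- frac |>
    group_by(group = factor(.data$group, levels = c(group_a, group_b))) |>
    summarise(
      n = n(),
      mean_ppm = mean(.data$fraction_ppm),
      sem_ppm = sd(.data$fraction_ppm) / sqrt(n()),
      .groups = "drop"
    )
  structure(
    list(groups = c(group_a, group_b), data = frac,
         summary = summary, test = test),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> microbial fraction, ", x$groups[1], " vs ",
      x$groups[2], "\n", sep = "")
  print(x$summary)
  print(x$test)
  invisible(x)
}

#' @method tidy group_comparison
#' @export
tidy.group_comparison <- function(x, ...) x$summary

#' @method glance group_comparison
#' @export
glance.group_comparison <- function(x, ...) {
  tibble(
    group_a = x$groups[1], group_b = x$groups[2],
    mean_a_ppm = x$summary$mean_ppm[1], mean_b_ppm = x$summary$mean_ppm[2],
    statistic = unname(x$test$statistic), p.value = x$test$p.value
  )
}

#' @rdname group_fraction_comparison
#' @param object A `group_comparison`.
#' @param ... Ignored.
#' @method autoplot group_comparison
#' @export
autoplot.group_comparison <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$group, y = .data$fraction_ppm)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.7) +
    ggplot2::labs(x = NULL, y = "microbial fraction (PPM)",
                  subtitle = paste0("Mann-Whitney two-sided p = ",
                                    signif(object$test$p.value, 3))) +
    ggplot2::theme_minimal()
}
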