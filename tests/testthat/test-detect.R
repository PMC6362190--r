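test_that("log2 transform applies the pseudocount and stays monotone", {
  expect_equal(log2_transform(0, 1), 0)
  expect_equal(log2_transform(1, 1), 1)
  expect_equal(log2_transform(7, 1), 3)
  expect_error(log2_transform(1, 0), "positive")
  tb <- tibble::tibble(hr = c(0, 3))
  expect_equal(log2_transform(tb)$log2_hr, c(0, 2))
})

test_that("Z-scores use the n-1 control sd and flag degenerate rows", {
  tr <- tibble::tibble(
    taxon_id = "t",
    sample_id = c("case", "c1", "c2", "c3"),
    log2_hr = c(8, 2, 4, 6)
  )
  z <- sample_zscores(tr, "case", c("c1", "c2", "c3"))
  expect_equal(z$z, 2)  # mean 4, sd 2 with n-1

  eq <- dplyr::mutate(tr, log2_hr = c(4, 4, 4, 4))
  z <- sample_zscores(eq, "case", c("c1", "c2", "c3"))
  expect_false(z$testable)
  expect_true(is.na(z$z))

  at_mean <- dplyr::mutate(tr, log2_hr = c(4, 2, 4, 6))
  expect_equal(sample_zscores(at_mean, "case", c("c1", "c2", "c3"))$z, 0)

  expect_error(sample_zscores(tr, "case", c("c1", "c2")), "at least 3")
  expect_error(sample_zscores(tr, "c1", c("c1", "c2", "c3")), "among the controls")
})

test_that("one-tailed p is the upper normal tail", {
  expect_equal(one_tailed_p(0), 0.5)
  expect_equal(one_tailed_p(2), 0.02275, tolerance = 1e-4 / 0.02275)
  expect_equal(one_tailed_p(-3), 0.99865, tolerance = 1e-4 / 0.99865)
  expect_error(one_tailed_p(Inf), "finite")
})

test_that("BH step-up matches the hand-worked example and p.adjust", {
  expect_equal(bh_qvalues(c(0.01, 0.04, 0.03, 0.05)),
               c(0.04, 0.05, 0.05, 0.05))
  expect_equal(bh_qvalues(1), 1)
  expect_error(bh_qvalues(c(0.5, 1.5)), "\\[0, 1\\]")

  withr::with_seed(31, {
    for (i in 1:50) {
      p <- runif(sample(1:100, 1))^sample(1:3, 1)
      q <- bh_qvalues(p)
      expect_equal(q, p.adjust(p, method = "BH"), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("candidate calls need both the q and hit-rate arms, strictly", {
  tb <- tibble::tibble(
    q = c(0.04, 0.04, 0.05, 0.04),
    hr = c(1.5, 0.8, 1.5, 1.0),
    testable = TRUE
  )
  out <- call_candidates(tb)
  expect_equal(out$is_candidate, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("candidate summary totals, specimen counts and read filter", {
  samples <- tiny_samples()
  # fabricated scan: taxon tA candidate in MS-1 and MS-2, tB in MS-1 only
  scan <- structure(list(
    table = tibble::tibble(
      sample_id = rep(c("MS-1", "MS-2"), each = 2),
      taxon_id = rep(c("tA", "tB"), 2),
      hr = c(5, 5, 5, 0.5), q = c(0.01, 0.02, 0.03, 0.2),
      testable = TRUE,
      is_candidate = c(TRUE, TRUE, TRUE, FALSE)
    ),
    case_samples = c("MS-1", "MS-2"),
    control_samples = paste0("C-", 1:4),
    params = list(q_threshold = 0.05)
  ), class = "candidate_scan")
  counts <- tibble::tibble(
    taxon_id = rep(c("tA", "tB"), each = 7),
    sample_id = rep(samples$sample_id, 2),
    count = c(60, 50, 10, 10, 0, 0, 0,    # tA: case total 110
              49, 50, 5, 5, 5, 5, 0)      # tB: case total 99
  )
  out <- summarize_candidates(scan, counts, samples, read_min = 100)
  expect_equal(out$case_reads[out$taxon_id == "tA"], 110)
  expect_true(out$passes_read_filter[out$taxon_id == "tA"])
  expect_false(out$passes_read_filter[out$taxon_id == "tB"])
  expect_equal(out$control_reads[out$taxon_id == "tB"], 20)
  expect_equal(out$n_specimens_increased[out$taxon_id == "tA"], 2L)
  # tB has q < 0.05 in MS-1 only
  expect_equal(out$n_specimens_increased[out$taxon_id == "tB"], 1L)
})

test_that("relaxing either threshold never removes a candidate", {
  sim <- generate_counts(simulate_config(seed = 9, n_phyla = 4))
  agg <- aggregate_counts(sim$counts, sim$taxonomy, "genus") |>
    dplyr::filter(!unranked) |>
    dplyr::select(taxon_id, sample_id, count)
  hr <- compute_hr(agg, sim$samples)
  strict <- tidy(detect_candidates(hr, sim$samples,
                                   q_threshold = 0.05, hr_threshold = 1))
  loose_q <- tidy(detect_candidates(hr, sim$samples,
                                    q_threshold = 0.2, hr_threshold = 1))
  loose_hr <- tidy(detect_candidates(hr, sim$samples,
                                     q_threshold = 0.05, hr_threshold = 0.2))
  key <- function(tb) paste(tb$sample_id, tb$taxon_id)[tb$is_candidate]
  expect_true(all(key(strict) %in% key(loose_q)))
  expect_true(all(key(strict) %in% key(loose_hr)))
})

test_that("per-sample and pooled BH families are both available", {
  sim <- generate_counts(simulate_config(seed = 10, n_phyla = 4))
  agg <- aggregate_counts(sim$counts, sim$taxonomy, "genus") |>
    dplyr::filter(!unranked) |>
    dplyr::select(taxon_id, sample_id, count)
  hr <- compute_hr(agg, sim$samples)
  per <- tidy(detect_candidates(hr, sim$samples, family = "per_sample"))
  pooled <- tidy(detect_candidates(hr, sim$samples, family = "pooled"))
  # q within one sample in the per-sample family must equal BH on that
  # sample's own p-values
  s1 <- dplyr::filter(per, sample_id == per$sample_id[1], testable)
  expect_equal(s1$q, bh_qvalues(s1$p))
  # pooled q comes from the combined family, so it differs in general
  expect_false(isTRUE(all.equal(per$q, pooled$q)))
})

test_that("OND samples stay out of the control distribution", {
  sim <- generate_counts(simulate_config(seed = 13, n_phyla = 3))
  agg <- aggregate_counts(sim$counts, sim$taxonomy, "genus") |>
    dplyr::filter(!unranked) |>
    dplyr::select(taxon_id, sample_id, count)
  hr <- compute_hr(agg, sim$samples)
  scan <- detect_candidates(hr, sim$samples, case_groups = c("MS", "OND"))
  expect_true(all(scan$control_samples %in%
                    sim$samples$sample_id[sim$samples$group == "control"]))
  expect_true(any(grepl("^OND", scan$case_samples)))
})
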