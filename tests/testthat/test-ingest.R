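test_that("concordant-pair counting follows the both-mates rule", {
  cat <- tiny_catalog()
  # both mates on the same microbial reference, high MAPQ
  r <- dplyr::bind_rows(rec("p1", 1, "micA", 30), rec("p1", 2, "micA", 30))
  s <- count_concordant_pairs(r, cat, mapq_min = 10)
  expect_equal(setNames(s$counts$pairs, s$counts$reference_id), c(micA = 1L))

  # mates on different microbial references: discordant, counted nowhere
  r <- dplyr::bind_rows(rec("p1", 1, "micA", 30), rec("p1", 2, "micB", 30))
  s <- count_concordant_pairs(r, cat, mapq_min = 10)
  expect_equal(nrow(s$counts), 0)
  expect_equal(s$tallies$pairs[s$tallies$category == "discordant"], 1L)
})

test_that("MAPQ boundary: both mates must reach the threshold", {
  cat <- tiny_catalog()
  r <- dplyr::bind_rows(rec("p1", 1, "micA", 9), rec("p1", 2, "micA", 30))
  s <- count_concordant_pairs(r, cat, mapq_min = 10)
  expect_equal(nrow(s$counts), 0)
  expect_equal(s$tallies$pairs[s$tallies$category == "concordant_low_mapq"], 1L)

  r <- dplyr::bind_rows(rec("p1", 1, "micA", 10), rec("p1", 2, "micA", 10))
  s <- count_concordant_pairs(r, cat, mapq_min = 10)
  expect_equal(sum(s$counts$pairs), 1L)
})

test_that("pairs with a human or PhiX mate are tallied to the host bucket", {
  cat <- tiny_catalog()
  r <- dplyr::bind_rows(
    rec("p1", 1, "hg", 40), rec("p1", 2, "micA", 40),
    rec("p2", 1, "phiX", 40), rec("p2", 2, "phiX", 40),
    rec("p3", 1, "micA", 40), rec("p3", 2, "micA", 40)
  )
  s <- count_concordant_pairs(r, cat, mapq_min = 10)
  expect_equal(s$tallies$pairs[s$tallies$category == "human_phix"], 2L)
  expect_equal(sum(s$counts$pairs), 1L)
})

test_that("every pair lands in exactly one bucket (partition invariant)", {
  cat <- tiny_catalog()
  withr::with_seed(11, {
    for (i in 1:10) {
      n <- 50
      refs <- sample(cat$reference_id, 2 * n, replace = TRUE)
      r <- tibble::tibble(
        read_id = rep(sprintf("p%03d", 1:n), each = 2),
        mate = rep(1:2, n),
        reference_id = refs,
        position = sample(500, 2 * n, replace = TRUE),
        mapq = sample(0:42, 2 * n, replace = TRUE),
        unmapped = runif(2 * n) < 0.1,
        secondary = FALSE, sample_id = "s1"
      )
      s <- count_concordant_pairs(r, cat, mapq_min = 10)
      expect_equal(sum(s$tallies$pairs), n)
      expect_equal(
        sum(s$counts$pairs),
        s$tallies$pairs[s$tallies$category == "concordant_retained"]
      )
    }
  })
})

test_that("raising the MAPQ threshold never increases any count", {
  cat <- tiny_catalog()
  withr::with_seed(12, {
    n <- 80
    r <- tibble::tibble(
      read_id = rep(sprintf("p%03d", 1:n), each = 2),
      mate = rep(1:2, n),
      reference_id = sample(c("micA", "micB"), 2 * n, replace = TRUE),
      position = 1L, mapq = sample(0:42, 2 * n, replace = TRUE),
      unmapped = FALSE, secondary = FALSE, sample_id = "s1"
    )
    prev <- NULL
    for (thr in c(0, 5, 10, 20, 30, 43)) {
      s <- count_concordant_pairs(r, cat, mapq_min = thr)
      cur <- setNames(s$counts$pairs, s$counts$reference_id)
      if (!is.null(prev)) {
        for (ref in names(cur)) {
          expect_lte(cur[[ref]],
                     if (ref %in% names(prev)) prev[[ref]] else Inf)
        }
        expect_true(all(names(cur) %in% names(prev)))
      }
      prev <- cur
    }
  })
})

test_that("malformed and unknown inputs fail loudly", {
  cat <- tiny_catalog()
  dup <- dplyr::bind_rows(rec("p1", 1, "micA", 30), rec("p1", 1, "micA", 30))
  expect_error(count_concordant_pairs(dup, cat), "multiple primary records")
  r <- dplyr::bind_rows(rec("p1", 1, "mystery", 30), rec("p1", 2, "mystery", 30))
  expect_error(count_concordant_pairs(r, cat), "mystery")
})

test_that("MAPQ converts to mapping probability by the Phred rule", {
  expect_equal(mapq_to_probability(10), 0.9)
  expect_equal(mapq_to_probability(0), 0)
  expect_equal(mapq_to_probability(20), 0.99)
  probs <- mapq_to_probability(0:60)
  expect_true(all(diff(probs) > 0))
  expect_true(all(probs < 1))
  expect_error(mapq_to_probability(-1), ">= 0")
})

test_that("pair mapping probability multiplies mate error probabilities", {
  expect_equal(pair_probability(10, 10), 0.99)
  expect_equal(pair_probability(0, 0), 0)
  expect_equal(pair_probability(10, 20), 0.999)
  expect_error(pair_probability(-1, 10), ">= 0")
})

test_that("coverage profile bins pairs by leftmost mate position", {
  cat <- reference_catalog("micA", "microbial", length = 20L)
  r <- dplyr::bind_rows(
    rec("p1", 1, "micA", 30, pos = 5), rec("p1", 2, "micA", 30, pos = 9),
    rec("p2", 1, "micA", 30, pos = 17), rec("p2", 2, "micA", 30, pos = 15)
  )
  prof <- coverage_profile(r, cat, "micA", bin_width = 10)
  expect_equal(prof$bin_start, c(1L, 11L))
  expect_equal(prof$pairs, c(1L, 1L))

  empty <- coverage_profile(r[0, ], cat, "micA", bin_width = 7)
  expect_equal(nrow(empty), ceiling(20 / 7))
  expect_true(all(empty$pairs == 0))

  expect_error(coverage_profile(r, cat, "nope", 10), "unknown reference")
})

test_that("coverage profile agrees with a direct histogram oracle", {
  cat <- reference_catalog("micA", "microbial", length = 1000L)
  withr::with_seed(5, {
    pos <- sample(1:900, 100, replace = TRUE)
    r <- dplyr::bind_rows(purrr::map(seq_along(pos), function(i) {
      dplyr::bind_rows(
        rec(paste0("p", i), 1, "micA", 30, pos = pos[i]),
        rec(paste0("p", i), 2, "micA", 30, pos = pos[i] + 50)
      )
    }))
    prof <- coverage_profile(r, cat, "micA", bin_width = 100)
    oracle <- tabulate((pos - 1) %/% 100 + 1, nbins = 10)
    expect_equal(prof$pairs, as.integer(oracle))
  })
})

test_that("SAM files round-trip through read_sam_pairs", {
  d <- withr::local_tempdir()
  sam <- file.path(d, "s1.sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:micA\tLN:1000",
    "@SQ\tSN:micB\tLN:1000",
    "p1\t65\tmicA\t100\t30\t50M\t=\t200\t0\t*\t*",
    "p1\t129\tmicA\t200\t25\t50M\t=\t100\t0\t*\t*",
    "p2\t321\tmicB\t10\t7\t50M\t=\t10\t0\t*\t*"  # secondary mate-1 record
  ), sam)
  recs <- read_sam_pairs(sam)
  expect_equal(nrow(recs), 3)
  expect_equal(recs$sample_id[1], "s1")
  expect_equal(recs$mate, c(1L, 2L, 1L))
  expect_equal(recs$mapq, c(30L, 25L, 7L))
  expect_equal(sum(recs$secondary), 1)

  cat <- tiny_catalog()
  s <- count_concordant_pairs(recs, cat, mapq_min = 10)
  expect_equal(setNames(s$counts$pairs, s$counts$reference_id), c(micA = 1L))
})
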