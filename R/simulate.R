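#' Configuration for the synthetic metatranscriptome generator
#'
#' Fixes the study design and noise model for [generate_counts()]. The
#' defaults emulate a two-run FFPE brain-tissue study: 12 case, 15 control,
#' 3 other-disease (OND) and 2 blank specimens split over 2 sequencing runs
#' (blanks on run 2); 200 genera across 10 phyla with 2-3 reference
#' sequences each (500 sequences); per-sample library size of 1e6 HQ pairs
#' (a desk-scale stand-in for the ~1e8 of a production run); per-genus
#' background abundance uniform on log2 PPM in `[-4, 1]` with 0.5 log2 units
#' of between-sample noise and negative-binomial count noise; 10 genera
#' spiked +4 log2 PPM in 4 of the case samples; and 10 run-2 contaminant
#' genera present in blanks at 2^4 = 16 PPM.
#'
#' @param n_case,n_control,n_ond,n_blank Group sizes.
#' @param n_phyla,orders_per_class,genera_per_family Branching of the
#'   generated taxonomy (each phylum has one class, each order one family,
#'   each genus one species).
#' @param seqs_per_genus Integer vector recycled over genera: reference
#'   sequences per genus.
#' @param hq_pairs High-quality read pairs per sample (the PPM
#'   denominator); recycled over samples.
#' @param background_log2_ppm Range (min, max) of per-genus background mean
#'   log2 hit rate, PPM.
#' @param background_sd Between-sample sd of log2 hit rate (log2 units).
#' @param dispersion Negative-binomial size parameter for count noise;
#'   `Inf` gives Poisson counts.
#' @param n_spike_taxa,spike_effect,spike_samples_per_taxon,spike_min_background
#'   Spike design: number of spiked genera, their log2-PPM effect in the
#'   designated case samples, how many case samples each spiked genus is
#'   elevated in, and the minimum background mean (log2 PPM) a genus needs
#'   to be eligible for spiking (keeps spiked hit rates above the 1 PPM
#'   candidate threshold).
#' @param n_contaminant_taxa,contaminant_log2_ppm,contaminant_run
#'   Contaminant design: number of run-restricted contaminant genera, the
#'   log2-PPM level they reach in blanks and in samples of the affected
#'   run, and which run is affected.
#' @param seed Integer seed; fully determines [generate_counts()] output.
#' @return A validated list of class `sim_config`.
#' @export
simulate_config <- function(n_case = 12, n_control = 15, n_ond = 3, n_blank = 2,
                            n_phyla = 10, orders_per_class = 2,
                            genera_per_family = 10, seqs_per_genus = c(2, 3),
                            hq_pairs = 1e6,
                            background_log2_ppm = c(-4, 1),
                            background_sd = 0.5,
                            dispersion = 10,
                            n_spike_taxa = 10, spike_effect = 4,
                            spike_samples_per_taxon = 4,
                            spike_min_background = -1,
                            n_contaminant_taxa = 10,
                            contaminant_log2_ppm = 4,
                            contaminant_run = 2,
                            seed = 1) {
  cfg <- as.list(environment())
  if (any(c(n_case, n_control) < 1)) abort("need >= 1 case and control sample")
  if (any(c(n_ond, n_blank) < 0)) abort("n_ond and n_blank must be >= 0")
  if (background_sd < 0) abort("background_sd must be >= 0")
  if (dispersion <= 0) abort("dispersion must be > 0 (Inf for Poisson)")
  if (spike_samples_per_taxon > n_case) {
    abort("spike_samples_per_taxon cannot exceed n_case")
  }
  if (any(hq_pairs <= 0)) abort("hq_pairs must be positive")
  structure(cfg, class = "sim_config")
}

# deterministic taxonomy scaffold for the simulator
build_sim_taxonomy <- function(config) {
  n_cls <- config$n_phyla
  n_ord <- n_cls * config$orders_per_class
  n_fam <- n_ord
  n_gen <- n_fam * config$genera_per_family

  id <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  phyla <- id("phy", config$n_phyla)
  classes <- id("cls", n_cls)
  orders <- id("ord", n_ord)
  families <- id("fam", n_fam)
  genera <- id("gen", n_gen)
  species <- id("sp", n_gen)

  nseq <- rep_len(config$seqs_per_genus, n_gen)
  seq_ids <- sprintf("seq%04d", seq_len(sum(nseq)))
  seq_genus_idx <- rep(seq_len(n_gen), nseq)

  nodes <- bind_rows(
    tibble(node_id = "sk001", parent_id = NA_character_, rank = "superkingdom"),
    tibble(node_id = phyla, parent_id = "sk001", rank = "phylum"),
    tibble(node_id = classes, parent_id = phyla, rank = "class"),
    tibble(node_id = orders,
           parent_id = rep(classes, each = config$orders_per_class),
           rank = "order"),
    tibble(node_id = families, parent_id = orders, rank = "family"),
    tibble(node_id = genera,
           parent_id = rep(families, each = config$genera_per_family),
           rank = "genus"),
    tibble(node_id = species, parent_id = genera, rank = "species"),
    tibble(node_id = seq_ids, parent_id = species[seq_genus_idx],
           rank = "sequence")
  )
  seq_map <- tibble(sequence_id = seq_ids, node_id = seq_ids)
  list(
    tree = taxonomy_tree(nodes, seq_map),
    genera = genera,
    seq_genus = setNames(genera[seq_genus_idx], seq_ids),
    seqs_in_genus = setNames(nseq, genera)
  )
}

#' Generate a ground-truthed synthetic count dataset
#'
#' Draws a sequence-level taxa-by-samples concordant-pair count matrix with
#' the statistical structure the downstream analysis assumes: per-genus
#' log-normal background hit rates (shared equally by the genus' reference
#' sequences), negative-binomial count noise, log2-scale spikes in a subset
#' of case samples, and run-restricted contaminant genera that appear in
#' the blanks. Blank samples contain only contaminant signal plus sampling
#' noise, never background tissue taxa or spikes. Output is fully
#' determined by `config$seed`.
#'
#' @param config A [simulate_config()].
#' @return An object of class `microbe_sim`: list with `counts` (tibble
#'   `sequence_id`, `sample_id`, `count`; zero cells omitted), `samples`
#'   metadata, `taxonomy` ([taxonomy_tree()]), `background` (per-genus mean
#'   log2 PPM), and `truth` (spiked (taxon, sample) pairs, contaminant
#'   taxa, expected per-sample microbial fraction).
#' @export
generate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, generate_counts_impl(config))
}

generate_counts_impl <- function(config) {
  tax <- build_sim_taxonomy(config)
  genera <- tax$genera
  seq_ids <- names(tax$seq_genus)
  n_seq <- length(seq_ids)

  samples <- bind_rows(
    tibble(sample_id = sprintf("MS-%02d", seq_len(config$n_case)),
           group = "MS"),
    tibble(sample_id = sprintf("C-%02d", seq_len(config$n_control)),
           group = "control"),
    if (config$n_ond > 0)
      tibble(sample_id = sprintf("OND-%02d", seq_len(config$n_ond)),
             group = "OND"),
    if (config$n_blank > 0)
      tibble(sample_id = sprintf("BLANK-%02d", seq_len(config$n_blank)),
             group = "blank")
  )
  samples <- samples |>
    group_by(.data$group) |>
    mutate(run = if (.data$group[1] == "blank") config$contaminant_run
           else ((row_number() - 1L) %% 2L) + 1L) |>
    ungroup() |>
    mutate(hq_pairs = rep_len(config$hq_pairs, n()))

  # per-genus background means; spikes drawn from sufficiently abundant genera
  mu_genus <- setNames(
    runif(length(genera), config$background_log2_ppm[1],
          config$background_log2_ppm[2]),
    genera
  )
  eligible <- genera[mu_genus >= config$spike_min_background]
  if (length(eligible) < config$n_spike_taxa) {
    abort("not enough genera above spike_min_background for the spike design")
  }
  spiked <- sort(sample(eligible, config$n_spike_taxa))
  contam_pool <- setdiff(genera, spiked)
  if (length(contam_pool) < config$n_contaminant_taxa) {
    abort("not enough genera left for the contaminant design")
  }
  contaminants <- sort(sample(contam_pool, config$n_contaminant_taxa))

  case_ids <- samples$sample_id[samples$group == "MS"]
  spikes <- tibble(taxon_id = character(), sample_id = character(),
                   effect_log2 = numeric())
  if (length(spiked) > 0) {
    spikes <- purrr::map_dfr(spiked, function(g) {
      tibble(taxon_id = g,
             sample_id = sort(sample(case_ids, config$spike_samples_per_taxon)),
             effect_log2 = config$spike_effect)
    })
  }

  # sequence-level background mean: genus hit rate split equally over its seqs
  seq_genus <- tax$seq_genus
  seq_mu <- mu_genus[seq_genus] - log2(tax$seqs_in_genus[seq_genus])
  contam_seq_hr <- ifelse(
    seq_genus %in% contaminants,
    2^(config$contaminant_log2_ppm - log2(tax$seqs_in_genus[seq_genus])),
    0
  )

  spike_map <- spikes |>
    mutate(key = paste(.data$taxon_id, .data$sample_id))
  draw_counts <- function(mean_hr, hq) {
    live <- mean_hr > 0
    hr <- numeric(length(mean_hr))
    if (config$background_sd > 0) {
      hr[live] <- mean_hr[live] *
        2^rnorm(sum(live), 0, config$background_sd)
    } else {
      hr[live] <- mean_hr[live]
    }
    mu <- hr * hq / 1e6
    cnt <- integer(length(mu))
    if (is.infinite(config$dispersion)) {
      cnt[live] <- rpois(sum(live), mu[live])
    } else {
      cnt[live] <- rnbinom(sum(live), mu = mu[live], size = config$dispersion)
    }
    cnt
  }

  mats <- purrr::pmap(samples, function(sample_id, group, run, hq_pairs) {
    if (group == "blank") {
      mean_hr <- contam_seq_hr
    } else {
      eff <- rep(0, n_seq)
      if (group == "MS") {
        hit <- paste(seq_genus, sample_id) %in% spike_map$key
        eff[hit] <- config$spike_effect
      }
      mean_hr <- 2^(seq_mu + eff)
      if (run == config$contaminant_run) mean_hr <- mean_hr + contam_seq_hr
    }
    cnt <- draw_counts(mean_hr, hq_pairs)
    keep <- cnt > 0
    tibble(sequence_id = seq_ids[keep], sample_id = sample_id,
           count = as.numeric(cnt[keep]))
  })
  counts <- bind_rows(mats)

  # analytic expectation of the per-sample microbial fraction
  lognorm_factor <- exp((config$background_sd * log(2))^2 / 2)
  expected <- purrr::pmap_dfr(samples, function(sample_id, group, run, hq_pairs) {
    if (group == "blank") {
      mean_hr <- contam_seq_hr
      tot <- sum(mean_hr) * lognorm_factor
    } else {
      eff <- rep(0, n_seq)
      if (group == "MS") {
        hit <- paste(seq_genus, sample_id) %in% spike_map$key
        eff[hit] <- config$spike_effect
      }
      mean_hr <- 2^(seq_mu + eff)
      if (run == config$contaminant_run) mean_hr <- mean_hr + contam_seq_hr
      tot <- sum(mean_hr) * lognorm_factor
    }
    tibble(sample_id = sample_id, expected_fraction_ppm = tot)
  })

  structure(
    list(
      counts = counts,
      samples = samples,
      taxonomy = tax$tree,
      background = tibble(taxon_id = genera, mu_log2_ppm = unname(mu_genus)),
      truth = list(
        spikes = spikes,
        contaminants = tibble(taxon_id = contaminants,
                              run = config$contaminant_run,
                              level_log2_ppm = config$contaminant_log2_ppm),
        expected_fraction = expected
      ),
      config = config
    ),
    class = "microbe_sim"
  )
}

#' @export
print.microbe_sim <- function(x, ...) {
  cat("<microbe_sim> ", nrow(x$samples), " samples, ",
      nrow(x$taxonomy$seq_map), " reference sequences, ",
      nrow(x$counts), " nonzero count cells\n",
      "  spiked genera: ", length(unique(x$truth$spikes$taxon_id)),
      "; contaminant genera: ", nrow(x$truth$contaminants), "\n", sep = "")
  invisible(x)
}

#' Emit synthetic SAM alignments for a count matrix
#'
#' Writes one SAM file per sample in which every concordant microbial pair
#' of the count matrix appears as two primary mate records on the same
#' reference with MAPQ at or above the retention threshold, plus decoy
#' human/PhiX pairs, sub-threshold-MAPQ microbial pairs and discordant
#' pairs at configurable rates, so that the ingest filters have work to do.
#' Re-ingesting with [count_concordant_pairs()] at `mapq_min` within
#' `mapq_range` reproduces the input matrix exactly.
#'
#' @param counts Sequence-level count tibble (`sequence_id`, `sample_id`,
#'   `count`) or a `microbe_sim`.
#' @param out_dir Directory for the SAM files (created if needed).
#' @param catalog Optional [reference_catalog()]; built automatically
#'   (microbial references for every sequence id, one human and one PhiX
#'   decoy reference) when `NULL`.
#' @param read_length,ref_length Read and microbial reference lengths (bp).
#' @param mapq_range Inclusive MAPQ range for retained records (min must be
#'   >= the downstream threshold you plan to use).
#' @param lowmapq_range Inclusive MAPQ range for sub-threshold decoys.
#' @param decoy_human_frac,decoy_phix_frac,decoy_lowmapq_frac,decoy_discordant_frac
#'   Fractions of all emitted pairs that are human, PhiX, low-MAPQ
#'   microbial, and discordant microbial decoys.
#' @param seed Optional seed for the decoy/MAPQ/position draws.
#' @return List with `files` (tibble `sample_id`, `path`, `pairs_emitted`)
#'   and `catalog`.
#' @export
emit_alignments <- function(counts, out_dir, catalog = NULL,
                            read_length = 125, ref_length = 10000,
                            mapq_range = c(30, 42), lowmapq_range = c(0, 9),
                            decoy_human_frac = 0.2, decoy_phix_frac = 0.02,
                            decoy_lowmapq_frac = 0.05,
                            decoy_discordant_frac = 0.03,
                            seed = NULL) {
  if (inherits(counts, "microbe_sim")) {
    all_seqs <- counts$taxonomy$seq_map$sequence_id
    counts <- counts$counts
  } else {
    counts <- as_tibble(counts)
    all_seqs <- sort(unique(counts$sequence_id))
  }
  fracs <- c(decoy_human_frac, decoy_phix_frac, decoy_lowmapq_frac,
             decoy_discordant_frac)
  if (any(fracs < 0) || sum(fracs) >= 1) {
    abort("decoy fractions must be >= 0 and sum to < 1")
  }
  if (ref_length < 2 * read_length + 20) {
    abort("ref_length too small for the requested read_length")
  }
  if (is.null(catalog)) {
    catalog <- reference_catalog(
      reference_id = c(all_seqs, "human_decoy", "phiX_decoy"),
      class = c(rep("microbial", length(all_seqs)), "human", "phix"),
      length = c(rep(ref_length, length(all_seqs)), 1000000L, 5386L)
    )
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  run <- function() {
    header <- c(
      "@HD\tVN:1.6\tSO:unsorted",
      sprintf("@SQ\tSN:%s\tLN:%d", catalog$reference_id, catalog$length)
    )
    len_of <- setNames(catalog$length, catalog$reference_id)
    micro_refs <- catalog$reference_id[catalog$class == "microbial"]

    mk_pairs <- function(refs1, refs2, mapq_lo, mapq_hi, ids) {
      n <- length(refs1)
      if (n == 0) return(character())
      span1 <- pmax(1L, len_of[refs1] - 2L * read_length - 12L)
      span2 <- pmax(1L, len_of[refs2] - 2L * read_length - 12L)
      pos1 <- 1L + as.integer(runif(n) * span1)
      pos2 <- if (identical(refs1, refs2)) {
        pos1 + read_length + sample.int(10L, n, replace = TRUE)
      } else {
        1L + as.integer(runif(n) * span2)
      }
      m1 <- sample(seq.int(mapq_lo, mapq_hi), n, replace = TRUE)
      m2 <- sample(seq.int(mapq_lo, mapq_hi), n, replace = TRUE)
      cig <- paste0(read_length, "M")
      rnext1 <- ifelse(refs1 == refs2, "=", refs2)
      rnext2 <- ifelse(refs1 == refs2, "=", refs1)
      c(
        sprintf("%s\t65\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                ids, refs1, pos1, m1, cig, rnext1, pos2),
        sprintf("%s\t129\t%s\t%d\t%d\t%s\t%s\t%d\t0\t*\t*",
                ids, refs2, pos2, m2, cig, rnext2, pos1)
      )
    }

    files <- purrr::map_dfr(unique(sort(c(counts$sample_id))), function(s) {
      sc <- filter(counts, .data$sample_id == s, .data$count > 0)
      refs_real <- rep(sc$sequence_id, sc$count)
      m <- length(refs_real)
      n_total <- if (m > 0) m / (1 - sum(fracs)) else 0
      n_h <- round(n_total * decoy_human_frac)
      n_p <- round(n_total * decoy_phix_frac)
      n_l <- round(n_total * decoy_lowmapq_frac)
      n_d <- round(n_total * decoy_discordant_frac)

      id_ctr <- 0L
      next_ids <- function(n) {
        out <- sprintf("%s_p%07d", s, id_ctr + seq_len(n))
        id_ctr <<- id_ctr + n
        out
      }
      lines <- c(
        mk_pairs(refs_real, refs_real, mapq_range[1], mapq_range[2],
                 next_ids(m)),
        mk_pairs(rep("human_decoy", n_h), rep("human_decoy", n_h),
                 mapq_range[1], mapq_range[2], next_ids(n_h)),
        mk_pairs(rep("phiX_decoy", n_p), rep("phiX_decoy", n_p),
                 mapq_range[1], mapq_range[2], next_ids(n_p)),
        {
          r <- sample(micro_refs, n_l, replace = TRUE)
          mk_pairs(r, r, lowmapq_range[1], lowmapq_range[2], next_ids(n_l))
        },
        if (n_d > 0 && length(micro_refs) >= 2) {
          r1 <- sample(micro_refs, n_d, replace = TRUE)
          shift <- sample.int(length(micro_refs) - 1L, n_d, replace = TRUE)
          r2 <- micro_refs[(match(r1, micro_refs) + shift - 1L) %%
                             length(micro_refs) + 1L]
          mk_pairs(r1, r2, mapq_range[1], mapq_range[2], next_ids(n_d))
        } else character()
      )
      path <- file.path(out_dir, paste0(s, ".sam"))
      readr::write_lines(c(header, lines), path)
      tibble(sample_id = s, path = path,
             pairs_emitted = m + n_h + n_p + n_l + n_d)
    })
    list(files = files, catalog = catalog)
  }

  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
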