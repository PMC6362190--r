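---
title: "Methods: per-sample taxon outlier detection in tissue metatranscriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: per-sample taxon outlier detection in tissue metatranscriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(taxoutlier)
library(dplyr)
```

# The model and its assumptions

The pipeline answers a per-specimen question: *in this case sample, which
microbial taxa carry more RNA than the control cohort leads us to expect?*
The underlying data are paired-end RNA-seq alignments of tissue specimens
against a panmicrobial reference catalog, alongside host (human) and PhiX
references.

The analysis chain is:

1. **Pair filtering.** A read pair is counted for a reference iff both
   mates map to that same microbial reference (a *concordant pair*) and
   both have MAPQ at or above a threshold (default 10). MAPQ is a
   Phred-scaled error probability, so MAPQ 10 retains alignments with a
   > 90% chance of correct placement and concordant pairs with > 99%
   (`mapq_to_probability()`, `pair_probability()`). Pairs with any human or
   PhiX mate are tallied to a host bucket and never reach microbial counts.
   Only primary alignments are considered, matching the single-best-hit
   semantics of the aligner output the pipeline expects.
2. **Aggregation.** Per-reference counts are summed to a taxonomic rank
   (genus by default) over a parent-pointer taxonomy
   (`aggregate_counts()`). Lineages that lack the requested rank — viruses
   asked for a phylum, for instance — go to an explicit unranked bucket so
   total mass is conserved; they are excluded from rank-level analyses but
   never silently dropped.
3. **Normalization.** Counts become hit rates in pairs per million:
   `HR = count / hq_pairs * 1e6`, with `hq_pairs` the sample's *total*
   high-quality read pairs from upstream QC, including host-mapping pairs.
   That denominator choice makes HR a fraction of sequencing effort, not of
   the (tiny, noisy) microbial sub-library.
4. **Blank-based artifact exclusion.** A taxon whose HR in one or both
   blank (paraffin-only) specimens strictly exceeds its mean HR across
   run-1 controls is excluded everywhere (`exclude_artifacts()`). This
   targets run-restricted reagent contamination that blanks, having no
   tissue, display undiluted.
5. **Outlier scoring.** Hit rates are transformed to `log2(HR + 1)`; each
   case sample is scored per taxon as
   `z = (x_case - mean(x_controls)) / sd(x_controls)` with the sample
   (n−1) standard deviation, converted to a one-tailed upper normal
   p-value (only overrepresentation is of interest), and BH-adjusted
   within the sample's own family of testable taxa
   (`detect_candidates()`). A candidate requires `q < 0.05` *and* raw
   `HR > 1 PPM` in that sample, both strict.
6. **Summaries.** Candidates are summarized per taxon (case/control total
   mapped pairs, number of case specimens increased, an "at least 100
   case-group pairs" filter), clustered as a row-centered log2 heatmap
   (Pearson correlation distance, average linkage, both axes), and the
   per-sample microbial fractions are compared between groups with a
   two-sided Mann-Whitney U test.

The statistical assumptions are deliberately those of the simple procedure:
log2 hit rates of each taxon are approximately normal across control
samples; control samples are exchangeable across runs once blank-flagged
taxa are removed; taxa are tested marginally (no compositional coupling);
and OND (other-disease) specimens belong to neither the control
distribution nor, by default, the case set.

# Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mapq_min` | 10 | Phred | both-mate MAPQ floor for counted pairs |
| `pseudocount` | 1 | PPM | offset inside the log2 transform |
| `q_threshold` | 0.05 | — | BH FDR threshold (strict) |
| `hr_threshold` | 1.0 | PPM | case-sample hit-rate floor (strict) |
| `read_min` | 100 | pairs | case-group total for summary tables (non-strict) |
| `sd_floor` | 1e-6 | log2 units | below this control sd a taxon is untestable |
| `family` | `"per_sample"` | — | BH family: per case sample, or pooled |
| `rank` | `"genus"` | — | aggregation level of the analysis |

Choices worth justifying:

* **Pseudocount 1 PPM.** The transform must handle HR = 0; an offset of
  1 PPM bounds the transform at 0 for absent taxa, keeps it monotone, and
  sits on the same scale as the 1 PPM candidate threshold, so the
  transform does not manufacture apparent signal below the region the
  candidate rule cares about. It is configurable.
* **Sample (n−1) standard deviation.** The controls are a sample used to
  estimate a control population; the estimator should be the unbiased one.
* **Both-mates MAPQ rule.** The pair-probability interpretation
  (`1 - 10^(-(m1+m2)/10)`) is only valid if both mates individually passed;
  requiring both also makes the filter monotone in the threshold.
* **Per-sample BH family.** Each specimen is compared to the controls on
  its own, so the natural multiple-comparison family is the testable taxa
  within one sample. A pooled family across all case samples is available
  behind `family = "pooled"` for sensitivity analyses.
* **Blank-filter tie handling.** The exclusion predicate is strictly
  "greater than": a taxon absent from blanks and controls (0 vs 0) is
  retained. Exclusion is global (all samples, both runs) by default, with
  a documented `scope = "run2"` variant.
* **Filter order.** The blank filter runs before outlier scoring, so the
  `HR > 1 PPM` arm is evaluated on post-filter hit rates.

# The synthetic-data generator

`generate_counts()` draws a sequence-level count matrix with known ground
truth; its defaults define the package's reference study design and are
used as-is by the test suite and `scripts/acceptance.R`:

* 12 case, 15 control, 3 OND and 2 blank specimens over two sequencing
  runs (blanks on run 2, groups alternating between runs);
* 200 genera in a fully ranked hierarchy (10 phyla), each genus with 2–3
  reference sequences (500 sequences total) sharing its abundance equally;
* per-genus background mean log2 HR uniform on [−4, 1] PPM, i.e. roughly
  0.06–2 PPM — sparse, as tissue microbial RNA is — with 0.5 log2 units of
  between-sample log-normal noise and negative-binomial count noise of
  size 10 (`dispersion = Inf` gives Poisson);
* library size 1e6 HQ pairs per sample: a desk-scale choice that keeps a
  200-replicate simulation suite in the order of a minute or two while
  preserving the count sparsity regime of the real assay (real libraries
  of ~1e8 pairs would make the same HRs correspond to 100-fold larger
  counts);
* 10 spiked genera, each elevated +4 log2 PPM (16-fold) in 4 of the 12
  case samples, drawn only from genera with background mean ≥ −1 log2 PPM
  so that spiked hit rates clear the 1 PPM candidate threshold;
* 10 contaminant genera at a 16 PPM level in blanks and run-2 samples,
  disjoint from the spiked set; blanks contain contaminant signal only.

The generator emulates the *statistical* structure the analysis assumes —
log-normal backgrounds, overdispersed counts, run-restricted contamination,
depth variation — and nothing of the sequence level it does not need:
no read sequences or error models, no rRNA-depletion chemistry, no
compositional closure, no correlation between taxa, no biopsy-site or
treatment covariates. Passing tests on these data therefore demonstrate
that the machinery recovers planted effects under its own model; they do
not certify behaviour on real FFPE data, where between-taxon correlation
and non-log-normal tails are to be expected. `emit_alignments()` extends
the simulation down to SAM records (two primary mates per counted pair,
plus human/PhiX, low-MAPQ and discordant decoys) so the ingestion filters
are exercised end to end; re-ingesting emitted alignments reproduces the
source matrix exactly for the above-threshold subset.

# Numerical and degenerate-input choices

* Taxa whose control sd falls below `sd_floor` (typically all-zero control
  rows) are *untestable*: they get no z, no p, and leave the BH family,
  rather than producing infinite scores. A consequence worth knowing: a
  taxon absent from every control cannot be called a candidate however
  large its case signal, because no control-relative scale exists for it.
* `bh_qvalues()` is the explicit step-up estimator
  `q_(i) = min_{j>=i} m p_(j) / j`, clipped to 1; ties share a q. It
  matches `stats::p.adjust(method = "BH")` to machine precision (tested).
* The Mann-Whitney U statistic counts `x > y` pairs plus half the ties.
  The exact branch uses the exact null distribution when the groups are
  tie-free and `n1 * n2 <= 400`, full enumeration over group assignments
  with midranks when ties are present and the pooled sample is small, and
  otherwise a tie-corrected normal approximation with continuity
  correction. Swapping group labels maps U to `n1*n2 − U` and leaves the
  two-sided p unchanged.
* Clustering uses `1 − Pearson correlation` distances and average linkage
  on both axes (the convention of the classic expression-heatmap tools,
  whose exact settings the display mimics); zero-variance rows are
  assigned the maximal informative distance 1 to every other row and
  logged, instead of propagating `NA`. Agglomeration is deterministic for
  a fixed input order, with ties resolved by input index.
* Coverage profiles attribute each pair to the bin containing the leftmost
  mapped mate position — the simplest reproducible convention; fragment
  midpoints would shift bins by half an insert length at most.
* All thresholds are strict inequalities except the `read_min` summary
  filter, which is "at least".

# Known limitations

* **Normal tails on an estimated sd.** Z-scores are computed against a
  standard deviation estimated from 15 controls but converted to p-values
  with the *normal* distribution, as the procedure prescribes. The
  statistic actually has t-like tails (14 df), so far-tail p-values are
  understated — at the thresholds BH ends up using, by several-fold — and
  negative-binomial count skew adds more. The per-(sample, taxon)
  false-call rate stays low, but the *union* of false candidate taxa
  across 12 case samples accumulates: on simulated null-plus-spike data
  the suite measures this directly, and the fraction of unspiked taxa
  collecting at least one candidate call across the case cohort runs
  noticeably above the nominal per-test level. Consumers of per-sample
  candidate lists should treat "candidate in exactly one specimen" rows
  with corresponding caution; the cross-sample `read_min` filter exists
  largely to prune them.
* **Blank scarcity.** With two blanks the artifact filter is a coarse
  instrument: it removes whole taxa, globally, on a single strict
  comparison. It is idempotent and conservative for taxa absent from
  blanks, but cannot distinguish a contaminant from a genuine taxon that
  also happens to contaminate reagents.
* **Upstream inputs are trusted.** `hq_pairs` comes from upstream QC and
  is never recomputed; read trimming, alignment, and reference-database
  construction are out of scope, as is any CIGAR-aware per-base depth.
* **One rank at a time.** Analyses at different ranks re-aggregate from
  the sequence level independently; no cross-rank multiplicity adjustment
  is attempted.

# Problem sizes used by the automated checks

The test suite and acceptance script run entirely on generated data at the
reference design above: 200 null replicates for the type-I check, 50
replicates for spike recovery, 20 seeds for the blank filter and for SAM
round-trips, 1000 random vectors for the BH oracle comparison, and
exhaustive enumeration up to pooled n = 8 for the Mann-Whitney exact
branch. These sizes are the package's own choice of desk scale: large
enough that binomial noise on the measured rates is well below the margins
being checked, small enough to rerun casually.
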