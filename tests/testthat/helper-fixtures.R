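# Small hand-built taxonomy: two bacterial genera (X with gi1/gi2, Y with
# gi3) fully ranked to phylum, plus a virus lineage (gi4) that stops at
# family level (no phylum ancestor).
tiny_taxonomy <- function() {
  nodes <- tibble::tribble(
    ~node_id, ~parent_id, ~rank,
    "root",   NA,         "superkingdom",
    "phyA",   "root",     "phylum",
    "clsA",   "phyA",     "class",
    "ordA",   "clsA",     "order",
    "famA",   "ordA",     "family",
    "genX",   "famA",     "genus",
    "genY",   "famA",     "genus",
    "spX1",   "genX",     "species",
    "spY1",   "genY",     "species",
    "gi1",    "spX1",     "sequence",
    "gi2",    "spX1",     "sequence",
    "gi3",    "spY1",     "sequence",
    "virroot", "root",    "family",
    "genV",   "virroot",  "genus",
    "spV1",   "genV",     "species",
    "gi4",    "spV1",     "sequence"
  )
  seq_map <- tibble::tibble(
    sequence_id = c("gi1", "gi2", "gi3", "gi4"),
    node_id = c("gi1", "gi2", "gi3", "gi4")
  )
  taxonomy_tree(nodes, seq_map)
}

tiny_samples <- function() {
  tibble::tibble(
    sample_id = c("MS-1", "MS-2", "C-1", "C-2", "C-3", "C-4", "BL-1"),
    group = c("MS", "MS", "control", "control", "control", "control", "blank"),
    run = c(1, 2, 1, 1, 2, 2, 2),
    hq_pairs = 1e6
  )
}

# one aligned mate record, mapped by default
rec <- function(read_id, mate, ref, mapq, pos = 100, unmapped = FALSE) {
  tibble::tibble(
    read_id = read_id, mate = mate, reference_id = ref,
    position = pos, mapq = mapq, unmapped = unmapped,
    secondary = FALSE, sample_id = "s1"
  )
}

tiny_catalog <- function() {
  reference_catalog(
    reference_id = c("micA", "micB", "hg", "phiX"),
    class = c("microbial", "microbial", "human", "phix"),
    length = c(1000L, 1000L, 10000L, 5386L)
  )
}

# independent brute-force BH step-up (min over j with p_(j) >= p_(i))
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# independent Mann-Whitney by full enumeration of group assignments
mw_enum_oracle <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  u_of <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- u_of(x, y)
  splits <- utils::combn(n1 + n2, n1)
  u_all <- apply(splits, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  dev <- abs(u_obs - n1 * n2 / 2)
  list(u = u_obs, p = mean(abs(u_all - n1 * n2 / 2) >= dev - 1e-12))
}

# independent average-linkage agglomeration: returns the cophenetic
# distance matrix implied by greedy merging (ties broken by first index)
average_linkage_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  cd <- function(ci, cj) {
    mean(d[clusters[[ci]], clusters[[cj]], drop = FALSE])
  }
  while (sum(active) > 1) {
    idx <- which(active)
    best <- NULL; best_d <- Inf
    for (a in seq_along(idx)) {
      for (b in seq_along(idx)) {
        if (b <= a) next
        dd <- cd(idx[a], idx[b])
        if (dd < best_d - 1e-12) {
          best_d <- dd; best <- c(idx[a], idx[b])
        }
      }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- best_d
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- best_d
    clusters[[length(clusters) + 1]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best] <- FALSE
    active <- c(active, TRUE)
  }
  coph
}
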