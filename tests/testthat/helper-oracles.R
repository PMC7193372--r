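# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_peptide <- function(len) paste(sample(AA, len, replace = TRUE),
                                      collapse = "")

# --- exhaustive-DP alignment oracle -------------------------------------
# Overlap-alignment score via explicit decomposition: a free prefix skip on
# one sequence, a fully penalized global core, a free suffix skip on one
# sequence. The core is scored by a plain three-state global DP. An empty
# core (no alignment column at all) is disallowed, matching the aligner's
# contract that at least one column is emitted.

oracle_global_affine <- function(q, r, sub, go, ge) {
  nq <- nchar(q); nr <- nchar(r)
  if (nq == 0 && nr == 0) return(NA_real_)   # empty core: not a valid combo
  if (nq == 0) return(-(go + ge * nr))
  if (nr == 0) return(-(go + ge * nq))
  qc <- strsplit(q, "")[[1]]; rc <- strsplit(r, "")[[1]]
  NEG <- -1e18
  M <- matrix(NEG, nq + 1, nr + 1)
  U <- matrix(NEG, nq + 1, nr + 1)  # gap in reference
  L <- matrix(NEG, nq + 1, nr + 1)  # gap in query
  M[1, 1] <- 0
  for (i in 2:(nq + 1)) U[i, 1] <- -(go + ge * (i - 1))
  for (j in 2:(nr + 1)) L[1, j] <- -(go + ge * (j - 1))
  for (i in 2:(nq + 1)) {
    for (j in 2:(nr + 1)) {
      s <- sub[qc[i - 1], rc[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], U[i - 1, j - 1], L[i - 1, j - 1]) + s
      U[i, j] <- max(M[i - 1, j] - go - ge, U[i - 1, j] - ge,
                     L[i - 1, j] - go - ge)
      L[i, j] <- max(M[i, j - 1] - go - ge, U[i, j - 1] - go - ge,
                     L[i, j - 1] - ge)
    }
  }
  max(M[nq + 1, nr + 1], U[nq + 1, nr + 1], L[nq + 1, nr + 1])
}

one_sided_skips <- function(nq, nr) {
  m <- cbind(0:nq, 0L)
  if (nr >= 1) m <- rbind(m, cbind(0L, 1:nr))
  m
}

oracle_overlap_score <- function(q, r, sub, go = 11, ge = 1) {
  nq <- nchar(q); nr <- nchar(r)
  pre <- one_sided_skips(nq, nr)
  best <- -Inf
  for (k in seq_len(nrow(pre))) {
    a <- pre[k, 1]; b <- pre[k, 2]
    suf <- one_sided_skips(nq - a, nr - b)
    for (l in seq_len(nrow(suf))) {
      cc <- suf[l, 1]; dd <- suf[l, 2]
      qs <- substr(q, a + 1, nq - cc)
      rs <- substr(r, b + 1, nr - dd)
      sc <- oracle_global_affine(qs, rs, sub, go, ge)
      if (!is.na(sc) && sc > best) best <- sc
    }
  }
  best
}

# --- brute-force BH step-up ---------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    ratios <- vapply(i:m, function(j) m * p[o[j]] / j, numeric(1))
    q[o[i]] <- min(1, min(ratios))
  }
  q
}

# --- brute-force read-to-ORF recount ------------------------------------
# Direct scan, no interval machinery: for every read, every ORF on the same
# contig is checked for >= 50% overlap of the read length; smallest start
# (then orf_id) wins.
oracle_assign_reads <- function(reads, orfs) {
  n_assigned <- 0L
  per_orf <- setNames(integer(length(orfs$orf_id)), orfs$orf_id)
  for (i in seq_len(nrow(reads))) {
    cand <- orfs[orfs$contig == reads$contig[i], , drop = FALSE]
    if (nrow(cand) == 0) next
    rl <- reads$end[i] - reads$start[i] + 1L
    ov <- pmin(reads$end[i], cand$end) - pmax(reads$start[i], cand$start) + 1L
    ok <- ov / rl >= 0.5
    if (!any(ok)) next
    cand <- cand[ok, , drop = FALSE]
    cand <- cand[order(cand$start, cand$orf_id), , drop = FALSE]
    per_orf[cand$orf_id[1]] <- per_orf[cand$orf_id[1]] + 1L
    n_assigned <- n_assigned + 1L
  }
  list(per_orf = per_orf, n_assigned = n_assigned)
}

# Small planted mimicry population shared by several tests.
make_test_population <- function(seed = 42) {
  ref <- make_reference(seed = seed, length = 600, motif = "RWGKPV",
                        motif_position = 300)
  pop <- make_orf_population(ref, list(
    family_spec("fam_a", 6, motif_mismatches = 0, flank_identity = 1.0),
    family_spec("fam_b", 4, motif_mismatches = 1, flank_identity = 0.95),
    family_spec("fam_c", 3, motif_mismatches = 2, flank_identity = 0.9)
  ), flank_span = 30, seed = seed + 1)
  list(ref = ref, pop = pop)
}
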