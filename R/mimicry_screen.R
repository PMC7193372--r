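# BLOSUM62 is shipped with Biostrings; cached per session.
.mimicry_env <- new.env(parent = emptyenv())

blosum62 <- function() {
  if (is.null(.mimicry_env$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .mimicry_env$blosum62 <- e$BLOSUM62
  }
  .mimicry_env$blosum62
}

#' Locate an epitope motif in a reference protein
#'
#' Returns the 1-based inclusive span of the first exact occurrence of the
#' motif; multiple occurrences trigger a warning and the first is used. When
#' the motif is absent, `fuzzy = TRUE` returns the best-identity ungapped
#' placement instead of failing.
#'
#' @param sequence Reference amino-acid string.
#' @param motif Motif string (e.g. `"RWGKPV"`).
#' @param fuzzy Allow a best-identity placement when no exact match exists.
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
locate_motif <- function(sequence, motif, fuzzy = FALSE) {
  check_residues(sequence, "reference")
  check_residues(motif, "motif")
  mlen <- nchar(motif)
  if (mlen > nchar(sequence)) stop("motif longer than reference")
  hits <- gregexpr(motif, sequence, fixed = TRUE)[[1]]
  if (hits[1] != -1) {
    if (length(hits) > 1) {
      warning(sprintf("motif occurs %d times; using the first occurrence at %d",
                      length(hits), hits[1]))
    }
    return(c(start = hits[1], end = hits[1] + mlen - 1L))
  }
  if (!fuzzy) stop("motif not found in reference (set fuzzy = TRUE to allow ",
                   "a best-identity placement)")
  schars <- strsplit(sequence, "")[[1]]
  mchars <- strsplit(motif, "")[[1]]
  n_win <- length(schars) - mlen + 1L
  matches <- vapply(seq_len(n_win), function(i) {
    sum(schars[i:(i + mlen - 1L)] == mchars)
  }, integer(1))
  best <- which.max(matches)
  c(start = best, end = best + mlen - 1L)
}

#' Semi-global pairwise protein alignment (BLOSUM62, affine gaps)
#'
#' Aligns a query ORF to a reference window by overlap alignment: terminal
#' gaps on either sequence are free, internal gaps cost
#' `gap_open + L * gap_extend` for a gap of length `L` (defaults 11 and 1),
#' scored with BLOSUM62. Traceback tie-breaking is deterministic (diagonal,
#' then up, then left), so the alignment is a pure function of its inputs.
#'
#' @param query,reference Amino-acid strings (20 standard residues).
#' @param gap_open,gap_extend Affine gap parameters.
#' @param substitution Substitution matrix (default BLOSUM62 from
#'   Biostrings).
#' @return An object of class `pairwise_alignment`: list with `aligned_query`
#'   and `aligned_ref` (equal-length gapped strings whose degapped forms
#'   reproduce the full inputs), `score`, `query_start = 1`, `ref_start = 1`.
#' @export
align_pair <- function(query, reference, gap_open = 11, gap_extend = 1,
                       substitution = blosum62()) {
  check_residues(query, "query")
  check_residues(reference, "reference")
  if (nchar(query) == 0 || nchar(reference) == 0) {
    stop("sequences must be non-empty")
  }
  alpha <- rownames(substitution)
  qi <- match(strsplit(query, "")[[1]], alpha) - 1L
  ri <- match(strsplit(reference, "")[[1]], alpha) - 1L
  res <- gotoh_overlap(qi, ri, substitution, gap_open, gap_extend)
  qchars <- strsplit(query, "")[[1]]
  rchars <- strsplit(reference, "")[[1]]
  aq <- ifelse(res$q_pos == 0, "-", qchars[pmax(res$q_pos, 1L)])
  ar <- ifelse(res$r_pos == 0, "-", rchars[pmax(res$r_pos, 1L)])
  structure(
    list(aligned_query = paste(aq, collapse = ""),
         aligned_ref = paste(ar, collapse = ""),
         score = res$score, query_start = 1L, ref_start = 1L),
    class = "pairwise_alignment"
  )
}

# Alignment columns occupied by reference positions `positions` (1-based in
# the degapped reference).
ref_columns <- function(aligned_ref, positions) {
  rc <- strsplit(aligned_ref, "")[[1]]
  refpos <- cumsum(rc != "-")
  refpos[rc == "-"] <- NA
  which(refpos %in% positions & rc != "-")
}

#' Trim an alignment to the epitope window
#'
#' Cuts both gapped strings to the alignment columns spanning reference
#' positions `[motif_start - flank, motif_end + flank]` (clipped at the
#' reference ends). Returns `NULL` when the query does not cover the epitope:
#' fewer than `min_motif_cols` of the motif columns hold a query residue.
#'
#' @param alignment A `pairwise_alignment`.
#' @param motif_span Integer `c(start, end)` of the motif on the (degapped)
#'   reference used in the alignment.
#' @param flank Flank width in reference residues (default 30).
#' @param min_motif_cols Minimum motif columns that must carry a query
#'   residue for the ORF to count as covering the epitope (default: all).
#' @return `NULL`, or a list with `trimmed_ref`, `trimmed_query`, and
#'   `motif_cols` (positions of the motif columns within the trimmed
#'   strings).
#' @export
epitope_window <- function(alignment, motif_span, flank = 30L,
                           min_motif_cols = motif_span[2] - motif_span[1] + 1L) {
  ar <- strsplit(alignment$aligned_ref, "")[[1]]
  aq <- strsplit(alignment$aligned_query, "")[[1]]
  stopifnot(length(ar) == length(aq))
  ref_len <- sum(ar != "-")
  mcols <- ref_columns(alignment$aligned_ref, motif_span[1]:motif_span[2])
  covered <- sum(aq[mcols] != "-")
  if (covered < min_motif_cols || covered == 0) return(NULL)
  lo <- max(1L, motif_span[1] - as.integer(flank))
  hi <- min(ref_len, motif_span[2] + as.integer(flank))
  wcols <- ref_columns(alignment$aligned_ref, lo:hi)
  # include any gap columns interior to the window
  cols <- min(wcols):max(wcols)
  list(trimmed_ref = paste(ar[cols], collapse = ""),
       trimmed_query = paste(aq[cols], collapse = ""),
       motif_cols = match(mcols, cols))
}

#' Percent identity over alignment columns
#'
#' Identity = 100 x (matching columns) / (columns where the reference has a
#' residue); a gap in either sequence counts as a mismatch, and columns where
#' the reference itself is gapped are excluded from the denominator. When
#' `columns` is given the computation is restricted to that subset (used for
#' the motif-level identity over the six motif columns).
#'
#' @param aligned_ref,aligned_query Equal-length gapped strings.
#' @param columns Optional integer vector of column indices.
#' @return Percent identity in `[0, 100]`.
#' @export
identity_percent <- function(aligned_ref, aligned_query, columns = NULL) {
  rc <- strsplit(aligned_ref, "")[[1]]
  qc <- strsplit(aligned_query, "")[[1]]
  if (length(rc) != length(qc)) stop("aligned strings differ in length")
  if (!is.null(columns)) {
    rc <- rc[columns]
    qc <- qc[columns]
  }
  denom <- rc != "-"
  if (sum(denom) == 0) stop("no reference residue in the evaluated columns")
  100 * sum(denom & rc == qc) / sum(denom)
}

#' Screen ORFs for alpha-MSH-epitope molecular mimicry
#'
#' For every ORF: align to the reference epitope region (motif plus `flank`
#' residues each side), keep ORFs covering the epitope, trim to the window,
#' and compute motif-level identity (over the motif columns) and window-level
#' identity (over the whole trimmed window). ORFs that fail are logged with a
#' reason.
#'
#' @param orfs Named character vector of ORF amino-acid sequences (or an
#'   `AAStringSet`).
#' @param taxonomy Named character vector, orf_id -> family; missing entries
#'   become `"unassigned"`.
#' @param reference A `reference_protein` (motif already located).
#' @param flank Flank width (default 30 residues).
#' @param min_motif_cols Coverage requirement passed to [epitope_window()].
#' @param gap_open,gap_extend Alignment gap parameters.
#' @return data.frame of class `mimicry_hits` with columns `orf_id`,
#'   `family`, `covers_epitope`, `motif_identity`, `window_identity`,
#'   `trimmed_ref`, `trimmed_query`; attribute `discarded` is a data.frame
#'   (`orf_id`, `reason`) of ORFs not covering the epitope.
#' @export
screen_orfs <- function(orfs, taxonomy, reference, flank = 30L,
                        min_motif_cols = NULL, gap_open = 11, gap_extend = 1) {
  if (methods::is(orfs, "AAStringSet")) {
    orfs <- setNames(as.character(orfs), names(orfs))
  }
  if (length(orfs) == 0) stop("empty ORF set")
  stopifnot(inherits(reference, "reference_protein"))
  mlen <- reference$motif_end - reference$motif_start + 1L
  if (is.null(min_motif_cols)) min_motif_cols <- mlen
  win_start <- max(1L, reference$motif_start - as.integer(flank))
  win_end <- min(nchar(reference$sequence),
                 reference$motif_end + as.integer(flank))
  window <- substr(reference$sequence, win_start, win_end)
  motif_span <- c(reference$motif_start - win_start + 1L,
                  reference$motif_end - win_start + 1L)

  rows <- vector("list", length(orfs))
  disc <- list()
  for (i in seq_along(orfs)) {
    oid <- names(orfs)[i]
    fam <- if (oid %in% names(taxonomy)) taxonomy[[oid]] else "unassigned"
    aln <- align_pair(orfs[[i]], window, gap_open, gap_extend)
    win <- epitope_window(aln, motif_span, flank = flank,
                          min_motif_cols = min_motif_cols)
    if (is.null(win)) {
      disc[[length(disc) + 1L]] <- data.frame(
        orf_id = oid, reason = "does_not_cover_epitope",
        stringsAsFactors = FALSE)
      next
    }
    rows[[i]] <- data.frame(
      orf_id = oid, family = fam, covers_epitope = TRUE,
      motif_identity = identity_percent(win$trimmed_ref, win$trimmed_query,
                                        win$motif_cols),
      window_identity = identity_percent(win$trimmed_ref, win$trimmed_query),
      trimmed_ref = win$trimmed_ref, trimmed_query = win$trimmed_query,
      stringsAsFactors = FALSE
    )
  }
  hits <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(orf_id = character(0), family = character(0),
                       covers_epitope = logical(0), motif_identity = numeric(0),
                       window_identity = numeric(0), trimmed_ref = character(0),
                       trimmed_query = character(0))
  }
  rownames(hits) <- NULL
  class(hits) <- c("mimicry_hits", "data.frame")
  attr(hits, "discarded") <- if (length(disc) > 0) {
    do.call(rbind, disc)
  } else {
    data.frame(orf_id = character(0), reason = character(0))
  }
  hits
}

#' Family-level mimicry summary
#'
#' Per family: number of screened sequences, number with a perfect motif
#' match (100\% motif identity), and the mean window identity; sorted by
#' sequence count, largest family first.
#'
#' @param hits A `mimicry_hits` data.frame from [screen_orfs()].
#' @return data.frame `family`, `n_sequences`, `n_full_motif`,
#'   `mean_window_identity`.
#' @export
summarize_families <- function(hits) {
  if (nrow(hits) == 0) {
    return(data.frame(family = character(0), n_sequences = integer(0),
                      n_full_motif = integer(0),
                      mean_window_identity = numeric(0)))
  }
  fams <- split(hits, hits$family)
  out <- do.call(rbind, lapply(fams, function(h) {
    data.frame(family = h$family[1], n_sequences = nrow(h),
               n_full_motif = sum(abs(h$motif_identity - 100) < 1e-9),
               mean_window_identity = mean(h$window_identity),
               stringsAsFactors = FALSE)
  }))
  out <- out[order(-out$n_sequences, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Distribution of families across homology bins
#'
#' Counts mimicry hits per family in half-open identity bins `[a, b)` (the
#' last bin closed on the right), by window identity.
#'
#' @param hits A `mimicry_hits` data.frame.
#' @param bin_edges Strictly increasing percent edges covering `[0, 100]`.
#' @return Matrix, family x bin counts.
#' @export
homology_distribution <- function(hits,
                                  bin_edges = c(0, 50, 60, 70, 80, 90, 100)) {
  stopifnot(all(diff(bin_edges) > 0), bin_edges[1] <= 0,
            bin_edges[length(bin_edges)] >= 100)
  labels <- paste0("[", bin_edges[-length(bin_edges)], ",",
                   bin_edges[-1],
                   c(rep(")", length(bin_edges) - 2), "]"))
  fams <- sort(unique(hits$family))
  out <- matrix(0L, length(fams), length(labels),
                dimnames = list(fams, labels))
  if (nrow(hits) == 0) return(out)
  bin <- findInterval(hits$window_identity, bin_edges,
                      rightmost.closed = TRUE)
  for (i in seq_len(nrow(hits))) {
    out[hits$family[i], bin[i]] <- out[hits$family[i], bin[i]] + 1L
  }
  out
}
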