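#' Read a homology-search hit table
#'
#' Parses a HMMER-tblout-style TSV with header columns `orf_id`, `ko`,
#' `evalue`, `bitscore`. Rows whose numeric fields do not parse are rejected
#' with their row number (header = row 1).
#'
#' @param path Path to a tab-separated file with header.
#' @return data.frame with columns `orf_id`, `ko`, `evalue`, `bitscore`.
#' @export
parse_hits <- function(path) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("orf_id", "ko", "evalue", "bitscore")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("hit table is missing column(s): ", paste(missing, collapse = ", "))
  }
  for (col in c("evalue", "bitscore")) {
    num <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(num) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      stop(sprintf("unparsable %s '%s' at row %d of %s",
                   col, df[[col]][bad[1]], bad[1] + 1L, path))
    }
    df[[col]] <- num
  }
  if (any(df$evalue < 0, na.rm = TRUE)) stop("negative e-value in hit table")
  df[required]
}

#' Best annotation per ORF
#'
#' For each ORF keeps the hit with the smallest e-value; ties on e-value are
#' broken by the larger bitscore, remaining ties by the lexicographically
#' smallest KO, so the result is fully deterministic.
#'
#' @param hits data.frame with columns `orf_id`, `ko`, `evalue`, `bitscore`.
#' @return Named character vector, orf_id -> KO.
#' @export
best_annotation_per_orf <- function(hits) {
  if (nrow(hits) == 0) return(setNames(character(0), character(0)))
  ord <- order(hits$orf_id, hits$evalue, -hits$bitscore, hits$ko)
  hits <- hits[ord, , drop = FALSE]
  keep <- !duplicated(hits$orf_id)
  setNames(hits$ko[keep], hits$orf_id[keep])
}

#' Assign mapped reads to ORFs by majority overlap
#'
#' A read is assigned to the ORF on its contig whose span covers at least
#' 50\% of the read's aligned length (coordinates 1-based inclusive; strand
#' ignored). When two ORFs qualify, the one with the smaller start wins
#' (then the lexicographically smaller orf_id). Reads below the overlap
#' threshold stay unassigned.
#'
#' @param reads data.frame with columns `read_id`, `contig`, `start`, `end`
#'   and optionally `sample` (defaults to a single sample `"S1"`).
#' @param orfs data.frame with columns `contig`, `start`, `end`, `strand`,
#'   `orf_id`.
#' @param min_overlap Minimum overlap fraction of the read length (0.5).
#' @return data.frame `sample`, `orf_id`, `reads` of per-ORF read counts,
#'   with attribute `unassigned` = number of unassigned reads.
#' @export
assign_reads_to_orfs <- function(reads, orfs, min_overlap = 0.5) {
  stopifnot(all(c("read_id", "contig", "start", "end") %in% names(reads)),
            all(c("contig", "start", "end", "orf_id") %in% names(orfs)))
  if (!"sample" %in% names(reads)) reads$sample <- "S1"
  if (nrow(reads) == 0) {
    out <- data.frame(sample = character(0), orf_id = character(0),
                      reads = integer(0))
    attr(out, "unassigned") <- 0L
    return(out)
  }
  rr <- IRanges::IRanges(start = reads$start, end = reads$end)
  oo <- IRanges::IRanges(start = orfs$start, end = orfs$end)
  ov <- IRanges::findOverlaps(rr, oo)
  qh <- S4Vectors::queryHits(ov)
  sh <- S4Vectors::subjectHits(ov)
  same_contig <- reads$contig[qh] == orfs$contig[sh]
  qh <- qh[same_contig]; sh <- sh[same_contig]
  inter <- pmin(reads$end[qh], orfs$end[sh]) -
    pmax(reads$start[qh], orfs$start[sh]) + 1L
  frac <- inter / (reads$end[qh] - reads$start[qh] + 1L)
  keep <- frac >= min_overlap
  qh <- qh[keep]; sh <- sh[keep]
  assigned <- rep(NA_character_, nrow(reads))
  if (length(qh) > 0) {
    # deterministic tie-break: smaller ORF start, then smaller orf_id
    ord <- order(qh, orfs$start[sh], orfs$orf_id[sh])
    qh <- qh[ord]; sh <- sh[ord]
    first <- !duplicated(qh)
    assigned[qh[first]] <- orfs$orf_id[sh[first]]
  }
  ok <- !is.na(assigned)
  if (!any(ok)) {
    out <- data.frame(sample = character(0), orf_id = character(0),
                      reads = integer(0))
    attr(out, "unassigned") <- sum(!ok)
    return(out)
  }
  out <- aggregate(list(reads = rep.int(1L, sum(ok))),
                   by = list(sample = reads$sample[ok], orf_id = assigned[ok]),
                   FUN = sum)
  out <- out[order(out$sample, out$orf_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unassigned") <- sum(!ok)
  out
}

#' Build the sample-by-annotation contingency table
#'
#' Sums per-ORF read counts into per-KO counts per sample, rolls KO counts up
#' into category counts (a KO contributes to every category it belongs to, so
#' category totals can exceed annotation totals), and computes per-sample
#' relative abundances.
#'
#' @param orf2ko Named character vector, orf_id -> KO (from
#'   [best_annotation_per_orf()]). ORFs with read counts but no annotation
#'   are dropped (their count is reported in attribute `dropped_orfs`).
#' @param orf_read_counts data.frame `sample`, `orf_id`, `reads` (from
#'   [assign_reads_to_orfs()]), or a named vector orf_id -> reads for a
#'   single sample.
#' @param ko2categories Named list, KO -> character vector of categories.
#'   KOs absent from the map are rolled up under `"unmapped"`.
#' @param descriptions Optional named character vector, KO -> description.
#' @param total_reads Optional named vector sample -> total mapped reads; if
#'   supplied, relative abundances use it as denominator instead of the
#'   per-sample annotated-read total.
#' @return An object of class `function_table`: list with matrices `counts`
#'   (sample x KO, integer), `category_counts`, `relative`, and
#'   `descriptions`.
#' @export
build_function_table <- function(orf2ko, orf_read_counts,
                                 ko2categories = list(),
                                 descriptions = NULL, total_reads = NULL) {
  if (!is.data.frame(orf_read_counts)) {
    orf_read_counts <- data.frame(sample = "S1",
                                  orf_id = names(orf_read_counts),
                                  reads = as.integer(orf_read_counts),
                                  stringsAsFactors = FALSE)
  }
  known <- orf_read_counts$orf_id %in% names(orf2ko)
  dropped <- sum(orf_read_counts$reads[!known])
  if (dropped > 0) {
    message(dropped, " reads on unannotated ORFs dropped from the table")
  }
  df <- orf_read_counts[known, , drop = FALSE]
  samples <- sort(unique(orf_read_counts$sample))
  kos <- sort(unique(unname(orf2ko)))
  counts <- matrix(0L, length(samples), length(kos),
                   dimnames = list(samples, kos))
  if (nrow(df) > 0) {
    df$ko <- unname(orf2ko[df$orf_id])
    agg <- aggregate(reads ~ sample + ko, data = df, FUN = sum)
    counts[cbind(agg$sample, agg$ko)] <- as.integer(agg$reads)
  }
  cats_per_ko <- lapply(kos, function(k) {
    cc <- ko2categories[[k]]
    if (is.null(cc) || length(cc) == 0) "unmapped" else cc
  })
  all_cats <- sort(unique(unlist(cats_per_ko)))
  category_counts <- matrix(0L, length(samples), length(all_cats),
                            dimnames = list(samples, all_cats))
  for (j in seq_along(kos)) {
    for (cat in cats_per_ko[[j]]) {
      category_counts[, cat] <- category_counts[, cat] + counts[, j]
    }
  }
  denom <- rowSums(counts)
  if (!is.null(total_reads)) denom <- total_reads[samples]
  relative <- counts / ifelse(denom == 0, 1, denom)
  out <- structure(
    list(counts = counts, category_counts = category_counts,
         relative = relative,
         descriptions = descriptions %||% setNames(character(0), character(0))),
    class = "function_table"
  )
  attr(out, "dropped_orfs") <- dropped
  out
}

#' Filter low-abundance taxa
#'
#' Keeps a taxon only if it has strictly more than 10 reads in at least two
#' samples.
#'
#' @param count_matrix Nonnegative integer matrix, taxa (rows) x samples.
#' @param min_reads Read threshold (strict inequality; default 10).
#' @param min_samples Number of samples required to exceed it (default 2).
#' @return The filtered matrix (possibly with zero rows).
#' @export
filter_taxa <- function(count_matrix, min_reads = 10L, min_samples = 2L) {
  stopifnot(is.matrix(count_matrix), all(count_matrix >= 0))
  keep <- rowSums(count_matrix > min_reads) >= min_samples
  count_matrix[keep, , drop = FALSE]
}
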