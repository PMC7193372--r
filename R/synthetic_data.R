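#' Build a synthetic reference protein carrying an epitope motif
#'
#' Constructs a stand-in for a reference chaperone protein (e.g. the
#' \emph{E. coli} ClpB carrying the alpha-MSH-mimetic hexapeptide RWGKPV):
#' a uniformly random amino-acid sequence with the motif planted as an exact
#' substring at a known position.
#'
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param length Total protein length in residues.
#' @param motif Amino-acid motif string (default `"RWGKPV"`).
#' @param motif_position 1-based start position of the motif.
#' @param id,accession Identifier metadata carried on the result.
#' @return An object of class `reference_protein`: a list with `id`,
#'   `accession`, `sequence`, `motif`, `motif_start`, `motif_end`.
#' @export
make_reference <- function(seed, length = 600L, motif = "RWGKPV",
                           motif_position = 300L,
                           id = "ref_clpb_like", accession = "SYNTHETIC") {
  check_residues(motif, "motif")
  mlen <- nchar(motif)
  if (motif_position < 1L || motif_position > length - mlen + 1L) {
    stop("motif_position must satisfy 1 <= pos <= length - nchar(motif) + 1")
  }
  seq <- withr::with_seed(seed, {
    res <- sample(AA20, length, replace = TRUE)
    res[motif_position:(motif_position + mlen - 1L)] <- strsplit(motif, "")[[1]]
    paste(res, collapse = "")
  })
  structure(
    list(id = id, accession = accession, sequence = seq, motif = motif,
         motif_start = as.integer(motif_position),
         motif_end = as.integer(motif_position + mlen - 1L)),
    class = "reference_protein"
  )
}

#' Family specification for the synthetic ORF generator
#'
#' @param family_name Bacterial family label.
#' @param n_orfs Number of ORFs to emit for the family.
#' @param motif_mismatches Number of substitutions planted inside the motif
#'   copy of every ORF (0..motif length).
#' @param flank_identity Per-residue probability that a flank residue matches
#'   the reference (substitutions always change the residue, so this is the
#'   exact expected per-residue identity of the flanks).
#' @param orf_length Optional nominal ORF length (metadata only; the emitted
#'   ORF length is set by the reference window).
#' @return A `family_spec` list.
#' @export
family_spec <- function(family_name, n_orfs, motif_mismatches = 0L,
                        flank_identity = 1.0, orf_length = NULL) {
  stopifnot(n_orfs >= 0, motif_mismatches >= 0,
            flank_identity >= 0, flank_identity <= 1)
  structure(list(family_name = family_name, n_orfs = as.integer(n_orfs),
                 motif_mismatches = as.integer(motif_mismatches),
                 flank_identity = flank_identity, orf_length = orf_length),
            class = "family_spec")
}

#' Generate a synthetic ORF population around the reference epitope window
#'
#' Each ORF is a copy of the reference window
#' `[motif_start - flank_span, motif_end + flank_span]` (clipped at the
#' sequence ends) with exactly `motif_mismatches` substitutions planted at
#' motif positions chosen without replacement, and each flank residue
#' independently retained with probability `flank_identity` (otherwise
#' substituted to a different residue). Ground truth for downstream recovery
#' tests is recorded alongside.
#'
#' @param reference A `reference_protein` from [make_reference()].
#' @param specs List of [family_spec()] objects.
#' @param flank_span Residues of reference flank on each side of the motif.
#' @param seed Integer seed.
#' @return A list with `orfs` (named character vector of amino-acid
#'   sequences), `taxonomy` (named character, orf_id -> family) and `truth`
#'   (list with per-family `full_motif` counts, `expected_flank_identity`,
#'   and `motif_identity` the planted per-ORF motif identity in percent).
#' @export
make_orf_population <- function(reference, specs, flank_span = 30L, seed = 1L) {
  stopifnot(inherits(reference, "reference_protein"), length(specs) > 0,
            flank_span >= 0)
  mlen <- nchar(reference$motif)
  for (sp in specs) {
    if (sp$motif_mismatches > mlen) {
      stop("motif_mismatches exceeds motif length")
    }
  }
  win_start <- max(1L, reference$motif_start - as.integer(flank_span))
  win_end <- min(nchar(reference$sequence),
                 reference$motif_end + as.integer(flank_span))
  window <- substr(reference$sequence, win_start, win_end)
  motif_cols <- (reference$motif_start - win_start + 1L):
    (reference$motif_end - win_start + 1L)
  wchars <- strsplit(window, "")[[1]]
  flank_cols <- setdiff(seq_along(wchars), motif_cols)

  withr::with_seed(seed, {
    orfs <- character(0)
    taxonomy <- character(0)
    full_motif <- integer(0)
    exp_flank <- numeric(0)
    motif_ident <- numeric(0)
    for (sp in specs) {
      fam <- sp$family_name
      n_full <- 0L
      if (sp$n_orfs > 0) {
        for (i in seq_len(sp$n_orfs)) {
          chars <- wchars
          if (sp$motif_mismatches > 0) {
            pos <- sample(motif_cols, sp$motif_mismatches)
            chars[pos] <- other_residue(chars[pos])
          } else {
            n_full <- n_full + 1L
          }
          if (sp$flank_identity < 1 && length(flank_cols) > 0) {
            keep <- runif(length(flank_cols)) < sp$flank_identity
            mut <- flank_cols[!keep]
            if (length(mut) > 0) chars[mut] <- other_residue(chars[mut])
          }
          orf_id <- sprintf("%s_orf%03d", fam, i)
          orfs[[orf_id]] <- paste(chars, collapse = "")
          taxonomy[[orf_id]] <- fam
        }
      }
      full_motif[[fam]] <- n_full
      exp_flank[[fam]] <- sp$flank_identity
      motif_ident[[fam]] <- 100 * (mlen - sp$motif_mismatches) / mlen
    }
    list(orfs = orfs, taxonomy = taxonomy,
         truth = list(full_motif = full_motif,
                      expected_flank_identity = exp_flank,
                      motif_identity = motif_ident,
                      window = window, motif_cols = motif_cols))
  })
}

#' Simulate the inputs of the annotation-counting pipeline
#'
#' Emits HMMER-hit, ORF-location and read-alignment tables for a set of ORFs
#' with known per-sample, per-KO read counts. Every non-decoy ORF receives
#' one hit to `ko_for_hits` and, with probability 0.3, a strictly inferior
#' second hit (larger e-value) to a decoy KO, so that best-hit selection is
#' exercised. Decoy ORFs receive locations and reads but no hits. Read
#' alignments fall entirely inside their ORF spans.
#'
#' The spec'd read-alignment record has no sample field; to generate the
#' sample-by-annotation contingency table a `sample` column is added here and
#' consumed downstream.
#'
#' @param orfs Named character vector of ORF ids (sequences or any values;
#'   only the names are used).
#' @param reads_per_orf Either a single nonnegative count (constant reads per
#'   ORF per sample) or a function `f(n)` returning `n` nonnegative counts.
#' @param n_decoy_orfs Number of unannotated decoy ORFs to add.
#' @param ko_for_hits KEGG ortholog id assigned to the non-decoy ORFs.
#' @param n_samples Number of samples.
#' @param seed Integer seed.
#' @return List with `hits`, `orf_locations`, `read_alignments` data frames
#'   and `truth` (`reads_per_ko`: sample x KO matrix of planted counts).
#' @export
make_metagenome <- function(orfs, reads_per_orf = 5L, n_decoy_orfs = 0L,
                            ko_for_hits = "K03695", n_samples = 3L,
                            seed = 1L) {
  orf_ids <- if (is.null(names(orfs))) as.character(orfs) else names(orfs)
  draw <- if (is.function(reads_per_orf)) {
    reads_per_orf
  } else {
    stopifnot(reads_per_orf >= 0)
    function(n) rep.int(as.integer(reads_per_orf), n)
  }
  decoy_ids <- if (n_decoy_orfs > 0) sprintf("decoy_orf%03d", seq_len(n_decoy_orfs)) else character(0)
  all_ids <- c(orf_ids, decoy_ids)
  samples <- sprintf("S%d", seq_len(n_samples))

  withr::with_seed(seed, {
    orf_len_nt <- 300L
    locs <- data.frame(
      contig = paste0("ctg_", all_ids),
      start = 101L,
      end = 100L + orf_len_nt,
      strand = sample(c("+", "-"), length(all_ids), replace = TRUE),
      orf_id = all_ids,
      stringsAsFactors = FALSE
    )
    hits <- data.frame(orf_id = character(0), ko = character(0),
                       evalue = numeric(0), bitscore = numeric(0))
    if (length(orf_ids) > 0) {
      ev <- 10^(-runif(length(orf_ids), 20, 50))
      hits <- data.frame(orf_id = orf_ids, ko = ko_for_hits, evalue = ev,
                         bitscore = round(runif(length(orf_ids), 200, 400), 1),
                         stringsAsFactors = FALSE)
      second <- runif(length(orf_ids)) < 0.3
      if (any(second)) {
        # strictly worse e-value than the primary hit, never a tie
        hits2 <- data.frame(
          orf_id = orf_ids[second], ko = "K99999",
          evalue = ev[second] * 10^runif(sum(second), 2, 8),
          bitscore = round(runif(sum(second), 50, 150), 1),
          stringsAsFactors = FALSE
        )
        hits <- rbind(hits, hits2)
      }
    }
    read_len <- 100L
    reads <- vector("list", n_samples * length(all_ids))
    truth_counts <- matrix(0L, nrow = n_samples, ncol = 1,
                           dimnames = list(samples, ko_for_hits))
    k <- 0L
    for (s in seq_len(n_samples)) {
      counts <- draw(length(all_ids))
      stopifnot(all(counts >= 0))
      for (o in seq_along(all_ids)) {
        n_r <- counts[[o]]
        if (n_r == 0) next
        st <- sample(101:(100L + orf_len_nt - read_len + 1L), n_r, replace = TRUE)
        k <- k + 1L
        reads[[k]] <- data.frame(
          read_id = sprintf("%s_%s_r%04d", samples[[s]], all_ids[[o]], seq_len(n_r)),
          contig = paste0("ctg_", all_ids[[o]]),
          start = st, end = st + read_len - 1L,
          sample = samples[[s]], stringsAsFactors = FALSE
        )
        if (all_ids[[o]] %in% orf_ids) {
          truth_counts[s, ko_for_hits] <- truth_counts[s, ko_for_hits] + n_r
        }
      }
    }
    read_alignments <- do.call(rbind, reads[seq_len(k)])
    if (is.null(read_alignments)) {
      read_alignments <- data.frame(read_id = character(0), contig = character(0),
                                    start = integer(0), end = integer(0),
                                    sample = character(0))
    }
    list(hits = hits, orf_locations = locs, read_alignments = read_alignments,
         truth = list(reads_per_ko = truth_counts))
  })
}

#' Simulate a metabolite matrix with one predictive and optional orthogonal
#' latent components
#'
#' Builds `X = t p' + sum_o t_o p_o' + E` where the predictive score vector
#' `t` drives the response (`y = t + noise`), each orthogonal score `t_o` is
#' made orthogonal to `t` (and to earlier `t_o`) by projection, and `E` is
#' i.i.d. Gaussian noise.
#'
#' @param n_samples,n_features Matrix dimensions.
#' @param n_ortho Number of response-orthogonal latent components.
#' @param noise_sd SD of the additive noise in `X` and in `y`.
#' @param seed Integer seed.
#' @return List with `X` (sample x feature matrix), `y` (response) and
#'   `truth` (`t`, `p`, `T_o`, `P_o`, `noise_sd`).
#' @export
make_metabolome <- function(n_samples = 60L, n_features = 40L, n_ortho = 1L,
                            noise_sd = 0.1, seed = 1L) {
  stopifnot(n_samples > n_ortho + 1, noise_sd >= 0)
  withr::with_seed(seed, {
    t <- rnorm(n_samples)
    t <- (t - mean(t)) / sd(t)
    p <- rnorm(n_features)
    X <- tcrossprod(t, p)
    basis <- cbind(t)
    T_o <- NULL
    P_o <- NULL
    if (n_ortho > 0) {
      T_o <- matrix(0, n_samples, n_ortho)
      P_o <- matrix(0, n_features, n_ortho)
      for (k in seq_len(n_ortho)) {
        raw <- rnorm(n_samples)
        # orthogonalize against t and earlier orthogonal scores
        res <- raw - basis %*% solve(crossprod(basis), crossprod(basis, raw))
        res <- drop(res)
        res <- (res - mean(res)) / sd(res)
        po <- rnorm(n_features)
        T_o[, k] <- res
        P_o[, k] <- po
        X <- X + tcrossprod(res, po)
        basis <- cbind(basis, res)
      }
    }
    if (noise_sd > 0) {
      X <- X + matrix(rnorm(n_samples * n_features, sd = noise_sd),
                      n_samples, n_features)
    }
    y <- t + if (noise_sd > 0) rnorm(n_samples, sd = noise_sd) else 0
    dimnames(X) <- list(sprintf("S%d", seq_len(n_samples)),
                        sprintf("feat%03d", seq_len(n_features)))
    names(y) <- rownames(X)
    list(X = X, y = y,
         truth = list(t = t, p = p, T_o = T_o, P_o = P_o, noise_sd = noise_sd))
  })
}

#' Simulate a cohort metadata table with a planted function-adiposity effect
#'
#' `function_abundance` (the per-sample relative abundance of the ClpB-like
#' KEGG function) and BMI are drawn from a bivariate normal with correlation
#' `effect_r`; obesity is assigned by the clinical threshold BMI >= 30.
#' Remaining columns (sex, age, energy and macronutrient intakes) are
#' plausible covariates for regression exercises.
#'
#' @param n Number of subjects.
#' @param effect_r Planted Pearson correlation between function abundance and
#'   BMI, in (-1, 1). The cohort effect is negative in the motivating study.
#' @param seed Integer seed.
#' @return A data.frame with columns `subject_id`, `group`, `bmi`, `sex`,
#'   `age`, `energy_intake`, `protein_g`, `carbohydrate_g`, `lipid_g`,
#'   `fiber_g`, `function_abundance`.
#' @export
make_cohort <- function(n = 131L, effect_r = -0.4, seed = 1L) {
  stopifnot(abs(effect_r) < 1, n >= 2)
  withr::with_seed(seed, {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    zb <- effect_r * z1 + sqrt(1 - effect_r^2) * z2
    bmi <- 31 + 8 * zb
    fa <- 0.15 + 0.03 * z1
    energy <- rnorm(n, 2100, 450)
    data.frame(
      subject_id = sprintf("subj%04d", seq_len(n)),
      group = ifelse(bmi >= 30, "obese", "non_obese"),
      bmi = bmi,
      sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.68, 0.32)),
      age = rnorm(n, 51, 14),
      energy_intake = energy,
      protein_g = pmax(10, energy * 0.16 / 4 + rnorm(n, 0, 10)),
      carbohydrate_g = pmax(20, energy * 0.45 / 4 + rnorm(n, 0, 25)),
      lipid_g = pmax(10, energy * 0.35 / 9 + rnorm(n, 0, 12)),
      fiber_g = pmax(2, rnorm(n, 20, 6)),
      function_abundance = fa,
      stringsAsFactors = FALSE
    )
  })
}
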