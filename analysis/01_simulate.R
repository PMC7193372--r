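#!/usr/bin/env Rscript

# Generates the full synthetic study: a ClpB-like reference protein carrying
# the alpha-MSH motif RWGKPV, per-family ORF populations around the epitope,
# the metagenomic pipeline inputs (hits, ORF locations, read alignments), a
# metabolite matrix with one predictive and one orthogonal latent component,
# and a cohort table with a planted negative function-adiposity association.
# Everything downstream (02-05) consumes these files.

suppressPackageStartupMessages({
  library(clpbmimic)
  library(Biostrings)
})

seed <- 20260929L
outdir <- "results/simulated"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

ref <- make_reference(seed = seed, length = 600, motif = "RWGKPV",
                      motif_position = 300)
writeXStringSet(AAStringSet(setNames(ref$sequence, ref$id)),
                file.path(outdir, "reference.faa"))

# Family mix loosely shaped like the study's top contributors: a few large
# families with perfect motif copies, smaller ones with planted divergence.
specs <- list(
  family_spec("Rikenellaceae",    40, motif_mismatches = 0, flank_identity = 0.92),
  family_spec("Clostridiaceae",   30, motif_mismatches = 0, flank_identity = 0.81),
  family_spec("Ruminococcaceae",  25, motif_mismatches = 1, flank_identity = 0.85),
  family_spec("Lachnospiraceae",  20, motif_mismatches = 1, flank_identity = 0.88),
  family_spec("Prevotellaceae",   15, motif_mismatches = 2, flank_identity = 0.96),
  family_spec("Bacteroidaceae",   10, motif_mismatches = 3, flank_identity = 0.94)
)
pop <- make_orf_population(ref, specs, flank_span = 30, seed = seed + 1)
writeXStringSet(AAStringSet(pop$orfs), file.path(outdir, "orfs.faa"))
write.table(data.frame(orf_id = names(pop$taxonomy),
                       family = unname(pop$taxonomy)),
            file.path(outdir, "taxonomy.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
saveRDS_lines <- function(x, path) {   # plain-text truth dump
  writeLines(paste(names(x), unname(x), sep = "\t"), path)
}
saveRDS_lines(pop$truth$full_motif, file.path(outdir, "truth_full_motif.tsv"))

mg <- make_metagenome(pop$orfs, reads_per_orf = function(n) rpois(n, 5),
                      n_decoy_orfs = 10, ko_for_hits = "K03695",
                      n_samples = 6, seed = seed + 2)
write.table(mg$hits, file.path(outdir, "hmmer_hits.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mg$orf_locations, file.path(outdir, "orf_locations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(mg$read_alignments, file.path(outdir, "read_alignments.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(cbind(sample = rownames(mg$truth$reads_per_ko),
                  as.data.frame(mg$truth$reads_per_ko)),
            file.path(outdir, "truth_reads_per_ko.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

met <- make_metabolome(n_samples = 60, n_features = 40, n_ortho = 1,
                       noise_sd = 0.1, seed = seed + 3)
write.table(cbind(sample = rownames(met$X), as.data.frame(met$X)),
            file.path(outdir, "metabolome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(sample = names(met$y), function_abundance = met$y),
            file.path(outdir, "metabolome_response.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cohort <- make_cohort(n = 131, effect_r = -0.4, seed = seed + 4)
write.table(cohort, file.path(outdir, "cohort.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat("Simulated study written to", outdir, "\n")
cat(" -", length(pop$orfs), "ORFs in", length(specs), "families\n")
cat(" -", nrow(mg$read_alignments), "read alignments across 6 samples\n")
cat(" - metabolome 60 x 40 with 1 orthogonal component\n")
cat(" - cohort n = 131, planted r(function, BMI) = -0.4\n")
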