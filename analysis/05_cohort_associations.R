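#!/usr/bin/env Rscript

# Cohort-level statistics on the simulated subjects: obese vs non-obese
# group comparisons with automatic test dispatch, Spearman and
# covariate-adjusted partial Spearman correlations of the ClpB-like function
# with adiposity, and multiple linear regression with standardized betas.

suppressPackageStartupMessages(library(clpbmimic))

indir <- "results/simulated"
outdir <- "results/cohort"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

co <- read.delim(file.path(indir, "cohort.tsv"))
cat("cohort: n =", nrow(co), "|", sum(co$group == "obese"), "obese\n")

vars <- c("bmi", "age", "energy_intake", "function_abundance")
rows <- lapply(vars, function(v) {
  res <- compare_groups(co[[v]], co$group)
  data.frame(variable = v, test = res$test_name,
             statistic = res$statistic, p = res$p)
})
sexres <- compare_groups(co$sex, co$group, "categorical")
rows[[length(rows) + 1]] <- data.frame(variable = "sex", test = "chi2",
                                       statistic = sexres$statistic,
                                       p = sexres$p)
tab <- do.call(rbind, rows)
tab$q <- bh_adjust(tab$p)
write.table(tab, file.path(outdir, "group_comparisons.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(tab)

sp <- spearman(co$function_abundance, co$bmi)
cat(sprintf("Spearman r(function, BMI) = %.3f (p = %.2g)\n", sp$r, sp$p))
ps <- partial_spearman(co$function_abundance, co$bmi,
                       co[, c("energy_intake", "age")])
cat(sprintf("partial r adjusting energy intake + age = %.3f (p = %.2g)\n",
            ps$r, ps$p))

lmres <- linear_model(co$function_abundance,
                      co[, c("bmi", "age", "energy_intake", "protein_g")],
                      standardize = TRUE)
write.table(lmres, file.path(outdir, "regression_betas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
print(lmres)

assoc <- data.frame(
  x = "function_abundance", y = "bmi",
  covariates = c("", "energy_intake+age"),
  r = c(sp$r, ps$r), p = c(sp$p, ps$p), n = c(sp$n, ps$n),
  method = c(sp$method, ps$method)
)
write.table(assoc, file.path(outdir, "associations.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
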