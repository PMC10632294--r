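#!/usr/bin/env Rscript
# Spatial diagnostics on one fitted trial: sample variogram of the
# phenotype residuals against the model-implied shape (sill at the total
# error variance, nugget discontinuity at zero displacement), and the
# imputation call-rate CDF summary on a family with simulated
# missingness and posterior genotype probabilities.
#
# Writes results/diagnostics/.

suppressPackageStartupMessages(library(clonepart))

out <- file.path("results", "diagnostics")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

# variogram of raw minus genetic+block effects on a fresh simulated trial
fx_map <- spruce_map(scale = 0.25)
parents <- simulate_parent_genotypes(fx_map, seed = 61)
fam <- simulate_family(family_config(150, 150, 1, "D", seed = 62), parents)
val <- assign_genetic_values(fam$geno, architecture_config(1, 0.75), seed = 63)
noise <- noise_config()
tr <- simulate_trial(trial_layout(150, 2, 10, 15), val$u, noise, seed = 64)
truth <- attr(tr, "truth")
obs <- !is.na(tr$value)
resid <- tr$value[obs] - truth$genetic[obs] - truth$block_eff[obs]
v <- sample_variogram(resid, tr[obs, c("master_block", "column", "row")])
utils::write.table(v, file.path(out, "variogram.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
sill <- noise$sigma_r2 + noise$sigma_s2
far <- v$dcol + v$drow >= 10
cat(sprintf("variogram: plateau %.3f vs total error variance %.3f; nugget %.3f\n",
            stats::weighted.mean(v$gamma[far], v$n_pairs[far]), sill, noise$sigma_r2))

# call-rate CDFs under missingness + imputation-style probabilities
m <- apply_genotype_missingness(fam$geno, snp_callrate = 0.79,
                                posterior_error = 0.013, gp = TRUE, seed = 65)
for (p in c(0.7, 0.9)) {
  cc <- callrate_cdf(m$gp, p = p)
  utils::write.table(cc$snp, file.path(out, sprintf("snp_callrate_cdf_p%02d.tsv", p * 100)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  # no imputation is simulated, so call rates stay near the masking rate;
  # the CDF location tracks the 0.79 target
  cat(sprintf("p = %.1f: median SNP call rate %.2f; %.0f%% of SNPs above 0.95\n",
              p, stats::median(cc$snp_call_rate),
              100 * mean(cc$snp_call_rate > 0.95)))
}
cat("diagnostics ->", out, "\n")
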