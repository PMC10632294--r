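# One replicate of the scaled-down recovery study: a fully genotyped
# full-sib family of 200 offspring, 4 ramets each in 4 blocks (10 x 20
# grids stacked into one 40 x 20 master block), true additive fraction
# 0.75 of a unit total genetic variance, f_r = 0.7 and rho = 0.8.

recovery_replicate <- function(rep, with_ci = TRUE) {
  map <- spruce_map()
  parents <- simulate_parent_genotypes(map, seed = 10000 + rep)
  fam <- simulate_family(family_config(200, 200, 1, "R", seed = 20000 + rep),
                         parents)
  val <- assign_genetic_values(fam$geno, architecture_config(1, 0.75),
                               seed = 30000 + rep)
  lay <- trial_layout(200, n_blocks = 4, block_ncol = 10, block_nrow = 20)
  noise <- noise_config(sigma_v2 = 0.15, sigma_r2 = 1.26, sigma_s2 = 0.54,
                        rho_c = 0.8, rho_r = 0.8)
  tr <- simulate_trial(lay, val$u, noise, seed = 40000 + rep)
  pf <- parental_allele_frequencies(rowSums(parents$father),
                                    rowSums(parents$mother))
  grm <- vanraden_g(fam$geno[, pf$keep, drop = FALSE], pf$p)
  td <- trial_data(tr, grm)
  fit <- fit_clonal_model(td, model = 2L, n_starts = 1L,
                          control = list(maxit = 120L, bfgs_maxit = 30L,
                                         se = FALSE))
  out <- list(r_a_hat = fit$estimates$r_a, logL = fit$logL)
  if (with_ci) {
    prof <- profile_additive_fraction(td, fit, grid = "adaptive",
                                      control = list(maxit = 40L,
                                                     bfgs_maxit = 12L))
    out$ci <- ci95_from_profile(prof)
  }
  out
}
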