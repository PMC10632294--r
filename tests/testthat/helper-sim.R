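# Shared fixture builders: compact simulated families and trials with
# known truth, generated in code at test time.

make_family <- function(n = 60L, n_geno = n, q = 1, map_scale = 0.06, seed = 1L,
                        seg_class_probs = c(AaxAa = 0.15, Aaxaa = 0.425, AAxAa = 0.425)) {
  map <- spruce_map(scale = map_scale)
  parents <- simulate_parent_genotypes(map, seg_class_probs, seed = seed)
  father_b <- if (q < 1) simulate_parent_genotypes(map, seg_class_probs, seed = seed + 500L) else NULL
  fam <- simulate_family(family_config(n, n_geno, q, "T", seed = seed + 1L),
                         parents, father_b)
  list(map = map, parents = parents, father_b = father_b, fam = fam)
}

make_trial_data <- function(n = 60L, r_a = 0.75, sigma_u2 = 1, seed = 1L,
                            n_blocks = 2L, block_ncol = 6L, block_nrow = 10L,
                            n_master = 1L, map_scale = 0.06,
                            noise = noise_config(sigma_v2 = 0.15, sigma_r2 = 1.26,
                                                 sigma_s2 = 0.54, rho_c = 0.8, rho_r = 0.8)) {
  fx <- make_family(n, n, 1, map_scale, seed)
  arch <- architecture_config(sigma_u2, r_a,
                              n_causal_add = min(40L, nrow(fx$map)),
                              n_causal_dom = 40L)
  val <- assign_genetic_values(fx$fam$geno, arch, seed = seed + 2L)
  lay <- trial_layout(n, n_blocks, block_ncol, block_nrow, n_master)
  tr <- simulate_trial(lay, val$u, noise, seed = seed + 3L)
  pf <- parental_allele_frequencies(rowSums(fx$parents$father),
                                    rowSums(fx$parents$mother))
  grm <- vanraden_g(fx$fam$geno[, pf$keep, drop = FALSE], pf$p)
  list(td = trial_data(tr, grm), trial = tr, grm = grm, values = val,
       noise = noise, family = fx)
}

# reference parameter set used across likelihood tests
ref_params <- function(r_a = 0.6) {
  list(sigma_u2 = 1, r_a = r_a, sigma_v2 = 0.2, sigma_r2 = 1.2,
       sigma_s2 = 0.5, rho_c = 0.7, rho_r = 0.6)
}
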