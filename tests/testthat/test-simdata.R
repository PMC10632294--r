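test_that("parent simulation respects segregation classes and errors on bad input", {
  map <- spruce_map(scale = 0.1)
  # all SNPs both-parents-het: expected offspring frequency 0.5 everywhere
  p1 <- simulate_parent_genotypes(map, c(AaxAa = 1), seed = 1)
  expect_true(all(rowSums(p1$father) == 1 & rowSums(p1$mother) == 1))
  # mixed classes give expected offspring frequencies 0.25 / 0.50 / 0.75
  p2 <- simulate_parent_genotypes(map, c(AaxAa = 0.3, Aaxaa = 0.4, AAxAa = 0.3), seed = 2)
  freqs <- (rowSums(p2$father) + rowSums(p2$mother)) / 4
  expect_true(all(freqs %in% c(0.25, 0.5, 0.75)))
  expect_error(simulate_parent_genotypes(map, c(AAxAA = 1)), "segregating")
  expect_error(simulate_parent_genotypes(map[0, ], c(AaxAa = 1)))
})

test_that("gamete simulation follows the Haldane model", {
  # two loci 100 cM apart: recombination fraction (1 - exp(-2))/2
  map <- linkage_map(c(G1 = 100), positions = list(c(0, 100)))
  parent <- matrix(c(1L, 1L, 0L, 0L), 2, 2)  # phased hap1 = (1,1), hap2 = (0,0)
  g <- simulate_gametes(parent, map, n = 20000, seed = 3)
  rec <- mean(g[1, ] != g[2, ])
  expect_equal(rec, (1 - exp(-2)) / 2, tolerance = 0.03)
  # loci at identical positions are always co-inherited
  map2 <- linkage_map(c(G1 = 50), positions = list(c(25, 25)))
  g2 <- simulate_gametes(parent, map2, n = 2000, seed = 4)
  expect_true(all(g2[1, ] == g2[2, ]))
  # zero-length map: gamete equals one parental haplotype chosen fairly
  map0 <- linkage_map(c(G1 = 1e-9), positions = list(c(0, 0)))
  g0 <- simulate_gametes(parent, map0, n = 4000, seed = 5)
  expect_true(all(g0[1, ] == g0[2, ]))
  expect_equal(mean(g0[1, ]), 0.5, tolerance = 0.05)
})

test_that("family simulation tracks paternity and heterozygosity", {
  fx <- make_family(n = 400, q = 1, seed = 10)
  expect_true(all(fx$fam$father == "A"))
  # offspring heterozygosity at an AaxAa SNP is 0.5 in expectation
  both_het <- rowSums(fx$parents$father) == 1 & rowSums(fx$parents$mother) == 1
  het <- mean(fx$fam$geno[, both_het] == 1)
  expect_equal(het, 0.5, tolerance = 0.05)
  # mean dosage at a segregating SNP is twice the expected frequency
  freqs <- (rowSums(fx$parents$father) + rowSums(fx$parents$mother)) / 4
  md <- colMeans(fx$fam$geno)
  expect_equal(unname(md), unname(2 * freqs), tolerance = 0.25)
  # q = 0.594 mixture: father-A count is binomial around q * n
  fm <- make_family(n = 478, q = 0.594, seed = 11)
  nA <- sum(fm$fam$father == "A")
  expect_lt(abs(nA - 0.594 * 478), 4 * sqrt(478 * 0.594 * 0.406))
  expect_error(family_config(100, 50, q = 0), "q must lie")
  expect_error(simulate_family(family_config(50, 10, 0.7, "X"),
                               fx$parents), "second father")
})

test_that("genetic values realize the requested variance split exactly", {
  fx <- make_family(n = 200, seed = 20)
  arch <- architecture_config(sigma_u2 = 2, r_a = 0.75, n_causal_add = 50,
                              n_causal_dom = 30)
  val <- assign_genetic_values(fx$fam$geno, arch, seed = 21)
  expect_equal(var(val$u_a), 0.75 * 2, tolerance = 1e-10)
  expect_equal(var(val$u_d), 0.25 * 2, tolerance = 1e-10)
  expect_equal(var(val$u), 2, tolerance = 1e-6)
  # r_a = 1: non-additive part identically zero
  v1 <- assign_genetic_values(fx$fam$geno,
                              architecture_config(1, 1, n_causal_add = 50),
                              seed = 22)
  expect_true(all(v1$u_d == 0))
  expect_error(architecture_config(sigma_u2 = -1, r_a = 0.5))
  expect_error(architecture_config(sigma_u2 = 1, r_a = NaN))
  expect_error(architecture_config(1, 0.5, n_causal_add = 0))
})

test_that("trial simulation produces the requested spatial structure", {
  # lag-1 column correlation of the spatial field on a 30x30 grid
  n <- 30 * 30
  u <- stats::setNames(rep(0, n), paste0("o", seq_len(n)))
  lay <- trial_layout(n, n_blocks = 1, block_ncol = 30, block_nrow = 30)
  noise <- noise_config(sigma_v2 = 0, sigma_r2 = 0, sigma_s2 = 1,
                        rho_c = 0.8, rho_r = 0.6)
  # lag-1 sample correlations of a single field carry sizeable Monte-Carlo
  # error; average a few independent trials
  cc <- rr <- numeric(4)
  for (s in 1:4) {
    tr <- simulate_trial(lay, u, noise, seed = 30 + s)
    truth <- attr(tr, "truth")
    fld <- matrix(NA_real_, 30, 30)
    fld[cbind(truth$row, truth$column)] <- truth$spatial
    cc[s] <- cor(as.vector(fld[, -30]), as.vector(fld[, -1]))
    rr[s] <- cor(as.vector(fld[-30, ]), as.vector(fld[-1, ]))
  }
  expect_equal(mean(cc), 0.8, tolerance = 0.05)
  expect_equal(mean(rr), 0.6, tolerance = 0.05)
  # all structure off except nugget: phenotypic variance ~ sigma_r2
  tr2 <- simulate_trial(lay, u, noise_config(0, 1, 0, 0, 0), seed = 31)
  expect_equal(var(tr2$value), 1, tolerance = 0.15)
  # two master blocks: no spatial correlation across them
  lay2 <- trial_layout(40, n_blocks = 2, block_ncol = 5, block_nrow = 8,
                       n_master = 2)
  tr3 <- simulate_trial(lay2, stats::setNames(rnorm(40), paste0("o", 1:40)),
                        noise, seed = 32)
  expect_equal(sort(unique(tr3$master_block)), c(1, 2))
  expect_error(trial_layout(100, 4, 5, 5), "grid too small")
})

test_that("trial randomization differs between blocks but genotypes are complete", {
  fx <- make_trial_data(n = 30, seed = 40, n_blocks = 3, block_ncol = 6,
                        block_nrow = 5)
  tr <- fx$trial
  for (b in unique(tr$block)) {
    ids <- tr$genotype_id[tr$block == b & !is.na(tr$genotype_id)]
    expect_equal(sort(ids), sort(unique(tr$genotype_id[!is.na(tr$genotype_id)])))
  }
})

test_that("genotype missingness hits target call rates and error rates", {
  fx <- make_family(n = 300, map_scale = 0.35, seed = 50)
  g <- fx$fam$geno
  # call rate 1: nothing missing
  m0 <- apply_genotype_missingness(g, snp_callrate = 1, seed = 51)
  expect_false(anyNA(m0$geno))
  # target mean call rate 0.79 within 0.01 over >= 1e5 calls
  m1 <- apply_genotype_missingness(g, snp_callrate = 0.79, seed = 52)
  expect_gt(length(g), 1e5)
  expect_equal(mean(!is.na(m1$geno)), 0.79, tolerance = 0.01)
  # posterior_error: argmax mismatch fraction matches
  m2 <- apply_genotype_missingness(g, snp_callrate = 1, posterior_error = 0.013,
                                   gp = TRUE, seed = 53)
  called <- apply(m2$gp, c(1, 2), which.max) - 1L
  expect_lt(abs(mean(called != g) - 0.013), 0.003)
  expect_error(apply_genotype_missingness(g, snp_callrate = 1.2), "call rates")
})

test_that("simulation is bit-reproducible under a fixed seed", {
  a <- make_trial_data(n = 24, seed = 60, block_ncol = 4, block_nrow = 6)
  b <- make_trial_data(n = 24, seed = 60, block_ncol = 4, block_nrow = 6)
  expect_identical(a$family$fam$geno, b$family$fam$geno)
  expect_identical(a$trial$value, b$trial$value)
  expect_identical(a$grm$G, b$grm$G)
})

test_that("spatial error covariance matches the separable model over replicates", {
  # covariance at displacement (dc, dr) converges to
  # sigma_s2 * rho_c^dc * rho_r^dr
  nrep <- 200
  rho_c <- 0.7; rho_r <- 0.5
  acc11 <- acc01 <- acc21 <- 0
  set.seed(70)
  for (r in seq_len(nrep)) {
    f <- clonepart:::draw_ar1_field(12, 12, rho_c, rho_r, 1)
    acc01 <- acc01 + mean(f[-12, ] * f[-1, ])           # row lag 1
    acc11 <- acc11 + mean(f[-12, -12] * f[-1, -1])      # lag (1,1)
    acc21 <- acc21 + mean(f[, -c(11, 12)] * f[, -c(1, 2)])  # col lag 2
  }
  expect_equal(acc01 / nrep, rho_r, tolerance = 0.05)
  expect_equal(acc11 / nrep, rho_c * rho_r, tolerance = 0.05)
  expect_equal(acc21 / nrep, rho_c^2, tolerance = 0.05)
})
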