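test_that("sequential QC removes individuals first, then SNPs, with strict thresholds", {
  # 10 individuals x 4 SNPs toy: individual 1 at call rate 0.5; SNP 4 at
  # MAF 0.10 among the survivors
  g <- matrix(1L, 10, 4, dimnames = list(paste0("i", 1:10), paste0("s", 1:4)))
  g[1, 1:2] <- NA                       # individual 1: call rate 0.5
  g[, 4] <- 0L
  g[2:3, 4] <- 1L                       # SNP 4 among i2..i10: freq 2/18 = 0.111
  thr <- qc_thresholds(min_ind_callrate = 0.6, min_snp_callrate = 0.8,
                       min_maf = 0.15)
  out <- sequential_qc(g, thr)
  expect_equal(out$removed_individuals$id, "i1")
  expect_equal(out$removed_snps$snp_id, "s4")
  expect_equal(dim(out$geno), c(9L, 3L))
  # threshold equality is retained: "less than" is strict
  g2 <- matrix(1L, 10, 2, dimnames = list(paste0("i", 1:10), c("a", "b")))
  g2[1:2, 1] <- NA                      # SNP a call rate exactly 0.8
  g2[1:5, 2] <- 0L                      # MAF 0.5
  out2 <- sequential_qc(g2, thr)
  expect_equal(ncol(out2$geno), 2L)
  # complete matrix, MAF 0.5: nothing removed
  out3 <- sequential_qc(g2[, 2, drop = FALSE], thr)
  expect_equal(nrow(out3$removed_individuals), 0L)
  expect_equal(nrow(out3$removed_snps), 0L)
  # everything filtered is an explicit error
  expect_error(sequential_qc(matrix(NA_integer_, 3, 3), thr), "removed")
})

test_that("sequential QC is idempotent", {
  fx <- make_family(n = 80, seed = 100)
  m <- apply_genotype_missingness(fx$fam$geno, snp_callrate = runif(nrow(fx$map), 0.6, 1),
                                  ind_callrate = runif(80, 0.5, 1), seed = 101)
  once <- sequential_qc(m$geno)
  twice <- sequential_qc(once$geno)
  expect_identical(once$geno, twice$geno)
  expect_equal(nrow(twice$removed_individuals), 0L)
  expect_equal(nrow(twice$removed_snps), 0L)
})

test_that("expected offspring distributions follow Mendelian segregation", {
  expect_equal(unname(expected_offspring_distribution(1, 1)), c(0.25, 0.5, 0.25))
  expect_equal(unname(expected_offspring_distribution(2, 0)), c(0, 1, 0))
  expect_equal(unname(expected_offspring_distribution(1, 0)), c(0.5, 0.5, 0))
  expect_error(expected_offspring_distribution(NA, 1), "non-missing")
})

test_that("Mendelian chi-square screen flags violating SNPs only", {
  # 100 offspring, 3 SNPs: SNP1 conforming AaxAa, SNP2 all-homozygous
  # under AaxAa (chi2 = 300), SNP3 conforming Aaxaa
  g <- cbind(
    s1 = rep(c(0L, 1L, 2L), c(25, 50, 25)),
    s2 = rep(0L, 100),
    s3 = rep(c(0L, 1L), c(50, 50))
  )
  rep_ <- mendel_chi2_screen(g, father = c(1, 1, 1), mother = c(1, 1, 0))
  expect_equal(rep_$table$chi2[1], 0)
  expect_equal(rep_$table$chi2[2], 300)
  expect_equal(rep_$removed, "s2")
  # observed proportional to expectation: chi2 = 0, retained
  expect_false(rep_$table$removed[1])
  # M = 1 reduces to an uncorrected 0.05 test
  gb <- cbind(s = rep(c(0L, 1L, 2L), c(33, 50, 17)))
  r1 <- mendel_chi2_screen(gb, 1, 1, alpha = 0.05)
  expect_equal(r1$n_tested, 1L)
  expect_equal(r1$table$removed, r1$table$p < 0.05)
  # degenerate cross is skipped and logged
  gd <- cbind(s = rep(1L, 50))
  rd <- mendel_chi2_screen(gd, 2, 0)
  expect_equal(rd$table$status, "degenerate_cross")
  expect_length(rd$removed, 0L)
})

test_that("Mendelian screen removal set is invariant to offspring ordering", {
  fx <- make_family(n = 120, seed = 110)
  g <- fx$fam$geno
  # corrupt two SNPs
  g[, 3] <- 2L
  g[, 7] <- 0L
  fa <- rowSums(fx$parents$father); mo <- rowSums(fx$parents$mother)
  r1 <- mendel_chi2_screen(g, fa, mo)
  set.seed(1)
  perm <- sample(nrow(g))
  r2 <- mendel_chi2_screen(g[perm, ], fa, mo)
  expect_identical(sort(r1$removed), sort(r2$removed))
})

test_that("opposing homozygotes are detected and removed", {
  g <- cbind(a = c(0L, 1L, 2L), b = c(2L, 1L, 0L))
  prof <- opposing_homozygote_profile(g, father = c(2, 0), mother = c(1, 1))
  # offspring 1: aa under AA father at SNP a, AA under aa father at SNP b
  expect_equal(prof$counts, c(2, 0, 0))
  expect_true(is.na(prof$geno[1, "a"]) && is.na(prof$geno[1, "b"]))
  # heterozygous offspring are never incompatible
  expect_equal(prof$counts[2], 0)
  expect_equal(prof$rate[1], 1)
})

test_that("wrong-father offspring show elevated incompatibility rates", {
  fm <- make_family(n = 150, q = 0.6, map_scale = 0.25, seed = 120)
  fa <- rowSums(fm$parents$father); mo <- rowSums(fm$parents$mother)
  prof <- opposing_homozygote_profile(fm$fam$geno, fa, mo)
  rate_A <- prof$rate[fm$fam$father == "A"]
  rate_B <- prof$rate[fm$fam$father == "B"]
  expect_lt(max(rate_A), min(rate_B))
})

test_that("paternity-mixture detection recovers the mixing fraction", {
  # rates built from the printed screen counts: 194 anomalous of 478
  rates <- c(rep(0.005, 284), rep(0.3, 194))
  mc <- detect_paternity_mixture(rates)
  expect_equal(mc$verdict, "mixture")
  expect_equal(mc$fraction_A, 284 / 478, tolerance = 1e-12)
  expect_equal(mc$se, sqrt(mc$fraction_A * (1 - mc$fraction_A) / 478),
               tolerance = 1e-12)
  # zero flagged: fraction 1, no mixture
  mc0 <- detect_paternity_mixture(rep(0.005, 100))
  expect_equal(mc0$verdict, "no_mixture")
  expect_equal(mc0$fraction_A, 1)
  expect_error(detect_paternity_mixture(rep(0, 10)), "20 offspring")
  # simulated q = 0.6 family with clean genotypes: the recovered groups
  # match the hidden paternity labels, and the realized sire fraction is
  # binomial around 0.6
  fm <- make_family(n = 300, q = 0.6, map_scale = 0.25, seed = 130)
  prof <- opposing_homozygote_profile(fm$fam$geno,
                                      rowSums(fm$parents$father),
                                      rowSums(fm$parents$mother))
  mc2 <- detect_paternity_mixture(prof$rate)
  expect_equal(mc2$verdict, "mixture")
  frac_true <- mean(fm$fam$father == "A")
  expect_equal(mc2$fraction_A, frac_true, tolerance = 0.02)
  expect_lt(abs(frac_true - 0.6), 4 * sqrt(0.6 * 0.4 / 300))
  expect_lt(abs(mc2$fraction_A - 0.6), 2 * mc2$se + 4 * sqrt(0.6 * 0.4 / 300))
})

test_that("pure families are not called mixtures", {
  verdicts <- vapply(1:50, function(r) {
    fx <- make_family(n = 60, q = 1, map_scale = 0.15, seed = 200 + r)
    g <- apply_genotype_missingness(fx$fam$geno, snp_callrate = 0.9,
                                    posterior_error = 0, seed = 300 + r)$geno
    # sprinkle genotyping errors at the background rate
    set.seed(400 + r)
    err <- which(!is.na(g) & runif(length(g)) < 0.013)
    g[err] <- (g[err] + sample(1:2, length(err), replace = TRUE)) %% 3L
    prof <- opposing_homozygote_profile(g, rowSums(fx$parents$father),
                                        rowSums(fx$parents$mother))
    detect_paternity_mixture(prof$rate)$verdict
  }, "")
  expect_gte(sum(verdicts == "no_mixture"), 45L)
})

test_that("call-rate CDFs behave at the degenerate corners", {
  n <- 20; L <- 30
  gp <- array(0, c(n, L, 3))
  gp[, , 2] <- 1                    # all triples degenerate at Aa
  cc <- callrate_cdf(gp, p = 0.9)
  expect_true(all(cc$snp_call_rate == 1))
  expect_equal(cc$snp$cdf[cc$snp$call_rate < 1], rep(0, sum(cc$snp$call_rate < 1)))
  expect_equal(tail(cc$snp$cdf, 1), 1)
  # p = 1: nothing called unless a probability equals 1 exactly
  gp2 <- array(1 / 3, c(n, L, 3))
  cc2 <- callrate_cdf(gp2, p = 0.9)
  expect_true(all(cc2$offspring_call_rate == 0))
  expect_error(callrate_cdf(gp, p = 0.4), "0.5")
})
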