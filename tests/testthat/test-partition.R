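test_that("confidence intervals from quadratic profiles match the Wald form", {
  # deviance ((r - 0.75)/0.05)^2: the 3.84 rule gives 0.75 +/- 1.96 * 0.05
  grid <- seq(0.5, 1, by = 0.005)
  prof <- data.frame(r_a = grid, deviance = ((grid - 0.75) / 0.05)^2)
  ci <- ci95_from_profile(prof)
  expect_equal(unname(ci), c(0.75 - 1.96 * 0.05, 0.75 + 1.96 * 0.05),
               tolerance = 1e-3)
  # deviance below threshold everywhere: full interval
  flat <- data.frame(r_a = seq(0, 1, 0.1), deviance = rep(1, 11))
  expect_equal(unname(ci95_from_profile(flat)), c(0, 1))
  # minimum at the upper boundary: upper endpoint 1
  bnd <- data.frame(r_a = seq(0, 1, 0.1),
                    deviance = ((seq(0, 1, 0.1) - 1) / 0.15)^2)
  ci_b <- ci95_from_profile(bnd)
  expect_equal(unname(ci_b["upper"]), 1)
  expect_lt(ci_b["lower"], 1)
  # non-contiguous sub-threshold region warns and returns the widest interval
  bumpy <- data.frame(r_a = seq(0, 1, 0.1),
                      deviance = c(1, 5, 5, 1, 1, 5, 5, 1, 1, 5, 5))
  expect_warning(ci_w <- ci95_from_profile(bumpy), "not contiguous")
  # widest interval: from 0 to the crossing between 0.8 (D=1) and 0.9 (D=5)
  expect_equal(unname(ci_w), c(0, 0.8 + 0.1 * 2.84 / 4), tolerance = 1e-3)
})

test_that("interval always contains the profile argmin", {
  set.seed(710)
  for (i in 1:10) {
    m <- runif(1)
    s <- runif(1, 0.03, 0.2)
    grid <- seq(0, 1, 0.02)
    prof <- data.frame(r_a = grid, deviance = ((grid - m) / s)^2)
    prof$deviance <- prof$deviance - min(prof$deviance)
    ci <- ci95_from_profile(prof)
    amin <- grid[which.min(prof$deviance)]
    expect_gte(amin, ci["lower"])
    expect_lte(amin, ci["upper"])
  }
})

test_that("pooled profiles sharpen the consensus and measure heterogeneity", {
  grid <- seq(0, 1, 0.01)
  mk <- function(m, s) data.frame(r_a = grid, deviance = ((grid - m) / s)^2)
  # identical profiles: consensus at the shared minimum, X2 = 0
  p <- pool_profiles(list(mk(0.6, 0.1), mk(0.6, 0.1), mk(0.6, 0.1)))
  expect_equal(p$estimate, 0.6, tolerance = 0.01)
  expect_equal(p$X2, 0, tolerance = 1e-6)
  expect_equal(p$df, 2L)
  # pooled CI narrower than each individual CI (curvatures add)
  ci_single <- ci95_from_profile(mk(0.6, 0.1))
  expect_lt(diff(p$ci), diff(ci_single))
  # consensus lies within the hull of individual minima
  p2 <- pool_profiles(list(mk(0.5, 0.08), mk(0.7, 0.08)))
  expect_gte(p2$estimate, 0.5)
  expect_lte(p2$estimate, 0.7)
  expect_gt(p2$X2, 0)
  # single profile passes through with df 0
  p1 <- pool_profiles(list(mk(0.4, 0.1)))
  expect_equal(p1$df, 0L)
  expect_equal(p1$estimate, 0.4, tolerance = 0.01)
})

test_that("inverse-variance pooling matches hand computation", {
  expect_equal(unname(pool_by_inverse_variance(c(0.4, 0.8), c(0.1, 0.1))["estimate"]),
               0.6)
  out <- pool_by_inverse_variance(c(0.8, 0.6), c(0.1, 0.3))
  expect_equal(unname(out["estimate"]), 0.78, tolerance = 1e-10)
  expect_equal(unname(out["se"]), 0.09486833, tolerance = 1e-7)
  one <- pool_by_inverse_variance(0.5, 0.2)
  expect_equal(unname(one), c(0.5, 0.2))
  expect_error(pool_by_inverse_variance(c(0.5, 0.6), c(0.1, 0)), "positive")
})

test_that("heritability arithmetic reproduces the published component table", {
  # pilodyn rows: sigma_P2 and sigma_u2 with f_a give H2 and h2 to 3 dp
  h_sf1 <- heritabilities(list(sigma_u2 = 1.046, sigma_v2 = 2.994 - 1.046,
                               sigma_r2 = 0, sigma_s2 = 0), f_a = 0.912)
  expect_equal(round(unname(h_sf1["H2"]), 3), 0.349)
  expect_equal(round(unname(h_sf1["h2"]), 3), 0.319)
  h_sf2 <- heritabilities(list(sigma_u2 = 1.283, sigma_v2 = 4.673 - 1.283,
                               sigma_r2 = 0, sigma_s2 = 0), f_a = 0.751)
  expect_equal(round(unname(h_sf2["H2"]), 3), 0.275)
  expect_equal(round(unname(h_sf2["h2"]), 3), 0.206)
  # f_a = 1 makes the narrow and broad sense coincide
  h1 <- heritabilities(list(sigma_u2 = 1, sigma_v2 = 0.5, sigma_r2 = 0.5,
                            sigma_s2 = 0), f_a = 1)
  expect_equal(unname(h1["H2"]), unname(h1["h2"]))
  expect_error(heritabilities(list(sigma_u2 = 0, sigma_v2 = 0, sigma_r2 = 0,
                                   sigma_s2 = 0), 1), "positive")
})

test_that("mixture-correction coefficients reproduce the published scaling", {
  cc <- mixture_correction_coefficients(0.594)
  expect_equal(unname(cc$a_rounded), c(2.81, 0.19))
  expect_equal(unname(cc$d_rounded), c(2.14, 0.14))
  # q = 1 is the identity map
  c1 <- mixture_correction_coefficients(1)
  r <- seq(0, 1, 0.05)
  fr <- vapply(r, function(x) correct_mixture_fractions(x, c1)["f_a"], 0)
  expect_equal(unname(fr), r, tolerance = 1e-6)
  fd <- vapply(r, function(x) correct_mixture_fractions(x, c1)["f_d"],
               0, USE.NAMES = FALSE)
  expect_equal(fd, 1 - r, tolerance = 1e-6)
  # coefficients continuous and monotone in q on (0.5, 1]
  qs <- seq(0.51, 1, by = 0.01)
  a1s <- vapply(qs, function(q) mixture_correction_coefficients(q)$a["a1"], 0)
  expect_true(all(diff(a1s) > 0))
  expect_true(all(abs(diff(a1s)) < 0.05))
  expect_error(mixture_correction_coefficients(0.5), "q must lie")
})

test_that("mixture-correction coefficients agree with a Monte-Carlo variance oracle", {
  # simulate additive and dominance values in a two-sire maternal
  # half-sib mixture and recover the within- vs mixture-variance shares
  q <- 0.594
  set.seed(720)
  nrep <- 3000; n_off <- 120
  va_mix <- vd_mix <- va_fs <- vd_fs <- numeric(nrep)
  for (r in seq_len(nrep)) {
    a_m <- rnorm(1); a_f <- rnorm(2)           # parental breeding values, var 1
    d_fam <- rnorm(2, 0, sqrt(1 / 4))          # family-mean dominance, FS relationship 1/4
    sire <- ifelse(runif(n_off) < q, 1L, 2L)
    bv <- (a_m + a_f[sire]) / 2 + rnorm(n_off, 0, sqrt(1 / 2))
    dv <- d_fam[sire] + rnorm(n_off, 0, sqrt(3 / 4))
    va_mix[r] <- var(bv); vd_mix[r] <- var(dv)
    va_fs[r] <- var(bv[sire == 1L]); vd_fs[r] <- var(dv[sire == 1L])
  }
  c_A_mc <- mean(va_fs) / mean(va_mix)
  c_D_mc <- mean(vd_fs) / mean(vd_mix)
  cc <- mixture_correction_coefficients(q)
  expect_equal(c_A_mc, cc$c_A, tolerance = 0.02)
  expect_equal(c_D_mc, cc$c_D, tolerance = 0.02)
  # the mapping r_a -> f_a implied by the Monte-Carlo shares matches
  r_a <- 0.7
  f_a_mc <- c_A_mc * r_a / (c_D_mc - (c_D_mc - c_A_mc) * r_a)
  expect_equal(unname(correct_mixture_fractions(r_a, cc)["f_a"]), f_a_mc,
               tolerance = 0.02)
})

test_that("random-mating conversion matches the published worked values", {
  expect_equal(round(random_mating_conversion(0.6), 2), 0.69)
  expect_equal(round(random_mating_conversion(0.8), 2), 0.86)
  expect_equal(random_mating_conversion(0), 0)
  expect_equal(random_mating_conversion(1), 1)
  expect_error(random_mating_conversion(1.2), "0, 1")
})

test_that("profiles locate the unconstrained optimum and drop monotonically", {
  fx <- make_trial_data(n = 120, seed = 730, n_blocks = 3, block_ncol = 8,
                        block_nrow = 15, r_a = 1, map_scale = 0.3)
  fit <- fit_clonal_model(fx$td, 2, n_starts = 1,
                          control = list(maxit = 200, se = FALSE))
  pr <- profile_additive_fraction(fx$td, fit, grid = c(0, 0.5, 1),
                                  control = list(maxit = 80, bfgs_maxit = 15))
  # data generated fully additive: deviance decreasing towards r_a = 1
  expect_true(all(diff(pr$profile$deviance) < 0.5))
  expect_gt(pr$profile$deviance[1], pr$profile$deviance[3])
  expect_equal(min(pr$profile$deviance), 0)
})

test_that("profile deviance approximates the Wald quadratic near the optimum", {
  fx <- make_trial_data(n = 150, seed = 740, n_blocks = 3, block_ncol = 10,
                        block_nrow = 15, map_scale = 0.3)
  fit <- fit_clonal_model(fx$td, 2, n_starts = 1,
                          control = list(maxit = 200, se = TRUE))
  rhat <- fit$estimates$r_a
  se <- unname(fit$se["r_a"])
  expect_false(is.na(se))
  expect_true(rhat - se > 0.02 && rhat + se < 0.98)
  pts <- c(rhat - se, rhat + se)
  pr <- profile_additive_fraction(fx$td, fit, grid = c(pts, rhat),
                                  control = list(maxit = 120, bfgs_maxit = 20))
  dev <- pr$profile$deviance[match(round(pts, 10), round(pr$profile$r_a, 10))]
  # at +/- 1 se a quadratic likelihood gives deviance 1; the curvature
  # s.e. and the profile need only agree to likelihood-approximation order
  expect_equal(mean(dev), 1, tolerance = 0.5)
})
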