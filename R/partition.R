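## Inference on the additive fraction of the within-family total genetic
## variance: likelihood profiles and 95% CIs by the 3.84 deviance rule,
## pooling across families and sites by summing profiles, inverse-variance
## pooling, heritabilities, the half-sib-mixture correction, and the
## within-family to random-mating conversion.

#' Profile the likelihood over the additive fraction
#'
#' For each grid value of `r_a` all other variance parameters are
#' re-maximized; the profile deviance is `D(r_a) = 2 (max logL -
#' logL(r_a))`, normalized so its minimum over the grid (including the
#' unconstrained fit) is zero. The grid is a coarse sweep of `[0, 1]`
#' refined around the unconstrained estimate. Points whose inner fit
#' fails are flagged and interpolated over with a warning.
#'
#' @param data a [trial_data()] with genotyped trees.
#' @param fit optional unconstrained model-2 [fit_clonal_model()] result
#'   used for initialization (fitted here if missing).
#' @param grid either a numeric vector of `r_a` values, a list with
#'   `coarse` (number of coarse points on `[0, 1]`) and `refine` (number
#'   of extra points within two coarse steps of the optimum), or
#'   `"adaptive"` to walk outward from the optimum in steps of
#'   `adaptive_step` until the deviance clears the 95% threshold (enough
#'   to locate the confidence limits at a fraction of the cost of a full
#'   sweep).
#' @param adaptive_step step size for `grid = "adaptive"`.
#' @param label optional label (e.g. family/site/trait).
#' @param control passed to the inner [fit_clonal_model()] calls; the
#'   inner fits warm-start from the neighbouring grid point.
#' @return A `likelihood_profile`: data.frame `profile` with columns
#'   `r_a`, `deviance`, plus `r_a_hat`, `logL_max`, `label`.
#' @export
profile_additive_fraction <- function(data, fit = NULL,
                                      grid = list(coarse = 21L, refine = 10L),
                                      adaptive_step = 0.08,
                                      label = NULL, control = list()) {
  ctl <- utils::modifyList(list(maxit = 300L, se = FALSE), control)
  if (is.null(fit))
    fit <- fit_clonal_model(data, model = 2L, n_starts = 1L, control = ctl)
  rhat <- fit$estimates$r_a
  if (identical(grid, "adaptive"))
    return(.profile_adaptive(data, fit, adaptive_step, label, ctl))
  if (is.numeric(grid)) {
    pts <- sort(unique(pmin(pmax(grid, 0), 1)))
  } else {
    coarse <- seq(0, 1, length.out = grid$coarse)
    step <- 1 / (grid$coarse - 1)
    refine <- seq(max(0, rhat - 2 * step), min(1, rhat + 2 * step),
                  length.out = grid$refine)
    pts <- sort(unique(round(c(coarse, refine, rhat), 10)))
  }
  ll <- rep(NA_real_, length(pts))
  # walk outward from the point nearest the optimum, warm-starting each
  # inner fit from its neighbour's solution
  ord <- order(abs(pts - rhat))
  init_for <- vector("list", length(pts))
  near <- ord[1]
  init_for[[near]] <- fit$estimates
  done <- logical(length(pts))
  for (i in ord) {
    ini <- init_for[[i]]
    if (is.null(ini)) {
      prev <- which(done)
      ini <- if (length(prev)) init_for[[prev[which.min(abs(pts[prev] - pts[i]))]]] else fit$estimates
    }
    f <- tryCatch(
      fit_clonal_model(data, model = 2L, init = ini, fix = list(r_a = pts[i]),
                       n_starts = 1L, control = ctl),
      error = function(e) NULL
    )
    if (!is.null(f) && is.finite(f$logL)) {
      ll[i] <- f$logL
      init_for[[i]] <- f$estimates
    }
    done[i] <- TRUE
  }
  if (anyNA(ll)) {
    warning(sum(is.na(ll)), " profile point(s) failed to converge; interpolated over")
    ok <- !is.na(ll)
    ll[!ok] <- stats::approx(pts[ok], ll[ok], xout = pts[!ok], rule = 2)$y
  }
  # normalize against the best grid point so the deviance attains zero on
  # the grid (the default grid includes the unconstrained estimate)
  lmax <- max(ll)
  prof <- data.frame(r_a = pts, deviance = 2 * (lmax - ll))
  structure(list(profile = prof, r_a_hat = pts[which.min(prof$deviance)],
                 logL_max = lmax, label = label),
            class = "likelihood_profile")
}

# Walk outward from the unconstrained optimum, warm-starting each inner
# fit from its neighbour, until the deviance clears the CI threshold
# (with margin) or a boundary is reached.
.profile_adaptive <- function(data, fit, step, label, ctl,
                              threshold = stats::qchisq(0.95, 1), margin = 1) {
  rhat <- min(max(fit$estimates$r_a, 0), 1)
  inner <- function(r, ini) {
    f <- tryCatch(
      fit_clonal_model(data, model = 2L, init = ini, fix = list(r_a = r),
                       n_starts = 1L, control = ctl),
      error = function(e) NULL
    )
    if (is.null(f) || !is.finite(f$logL)) NULL else f
  }
  pts <- rhat; lls <- fit$logL; inits <- list(fit$estimates)
  for (dir in c(-1, 1)) {
    r <- rhat; ini <- fit$estimates; last_ll <- fit$logL
    repeat {
      r_next <- r + dir * step
      at_bound <- FALSE
      if (r_next <= 0) { r_next <- 0; at_bound <- TRUE }
      if (r_next >= 1) { r_next <- 1; at_bound <- TRUE }
      f <- inner(r_next, ini)
      if (is.null(f)) break
      pts <- c(pts, r_next); lls <- c(lls, f$logL)
      dev <- 2 * (fit$logL - f$logL)
      r <- r_next; ini <- f$estimates
      if (at_bound || dev > threshold + margin) break
    }
  }
  ord <- order(pts)
  lmax <- max(lls)
  prof <- data.frame(r_a = pts[ord], deviance = 2 * (lmax - lls[ord]))
  structure(list(profile = prof, r_a_hat = prof$r_a[which.min(prof$deviance)],
                 logL_max = lmax, label = label),
            class = "likelihood_profile")
}

.prof_df <- function(profile) {
  if (inherits(profile, "likelihood_profile")) profile$profile
  else as.data.frame(profile)
}

#' 95% confidence interval from a likelihood profile
#'
#' The interval is the set of `r_a` with profile deviance below 3.84 (the
#' 95% point of chi-square with 1 df), endpoints located by linear
#' interpolation between bracketing grid points. When the deviance never
#' crosses the threshold on a side, the boundary 0 or 1 is returned on
#' that side. A non-unimodal sub-threshold region returns the widest
#' interval with a warning.
#'
#' @param profile a `likelihood_profile` (or data.frame with `r_a`,
#'   `deviance`).
#' @param threshold deviance cut-off (default `qchisq(0.95, 1)` = 3.84).
#' @return `c(lower, upper)`.
#' @export
ci95_from_profile <- function(profile, threshold = stats::qchisq(0.95, 1)) {
  d <- .prof_df(profile)
  d <- d[order(d$r_a), ]
  below <- d$deviance < threshold
  if (!any(below)) stop("profile nowhere below the threshold; no interval")
  runs <- rle(below)
  if (sum(runs$values) > 1L)
    warning("profile region below threshold is not contiguous; widest interval returned")
  i1 <- which(below)[1]
  i2 <- rev(which(below))[1]
  lower <- if (i1 == 1L) d$r_a[1] else {
    # interpolate the crossing between i1-1 (above) and i1 (below)
    x0 <- d$r_a[i1 - 1L]; x1 <- d$r_a[i1]
    y0 <- d$deviance[i1 - 1L]; y1 <- d$deviance[i1]
    x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  }
  upper <- if (i2 == nrow(d)) d$r_a[nrow(d)] else {
    x0 <- d$r_a[i2]; x1 <- d$r_a[i2 + 1L]
    y0 <- d$deviance[i2]; y1 <- d$deviance[i2 + 1L]
    x0 + (threshold - y0) * (x1 - x0) / (y1 - y0)
  }
  c(lower = lower, upper = upper)
}

#' Pool likelihood profiles across families and sites
#'
#' Profiles are interpolated onto a common grid (monotone cubic, which
#' preserves unimodality), summed, and renormalized to minimum zero. The
#' consensus estimate is the pooled argmin; its 95% CI uses the 3.84
#' rule on the pooled curve. The heterogeneity statistic is
#' `X^2 = sum_i D_i(consensus)` on `(number of profiles - 1)` df.
#'
#' @param profiles list of `likelihood_profile` objects (or data.frames).
#' @param grid_n number of common grid points on `[0, 1]`.
#' @return A `pooled_estimate` list: `estimate`, `ci`, `profile` (pooled
#'   curve), `X2`, `df`, `p_het`, `n_profiles`.
#' @export
pool_profiles <- function(profiles, grid_n = 201L) {
  if (inherits(profiles, "likelihood_profile")) profiles <- list(profiles)
  np <- length(profiles)
  if (np == 0L) stop("no profiles supplied")
  grid <- seq(0, 1, length.out = grid_n)
  devs <- vapply(profiles, function(p) {
    d <- .prof_df(p)
    f <- stats::splinefun(d$r_a, d$deviance, method = "monoH.FC")
    pmax(f(pmin(pmax(grid, min(d$r_a)), max(d$r_a))), 0)
  }, numeric(grid_n))
  pooled <- rowSums(devs)
  pooled <- pooled - min(pooled)
  i0 <- which.min(pooled)
  consensus <- grid[i0]
  prof <- data.frame(r_a = grid, deviance = pooled)
  ci <- ci95_from_profile(prof)
  X2 <- if (np > 1L) sum(devs[i0, ]) else 0
  df <- max(np - 1L, 0L)
  structure(list(estimate = consensus, ci = ci, profile = prof,
                 X2 = X2, df = df,
                 p_het = if (df > 0L) stats::pchisq(X2, df, lower.tail = FALSE) else NA_real_,
                 n_profiles = np),
            class = "pooled_estimate")
}

#' Inverse-variance pooling of estimates
#'
#' Weighted mean with weights `1/se^2`; the pooled s.e. is
#' `sqrt(1/sum(weights))`.
#'
#' @param estimates numeric vector.
#' @param ses matching standard errors (> 0).
#' @return `c(estimate, se)`.
#' @export
pool_by_inverse_variance <- function(estimates, ses) {
  stopifnot(length(estimates) == length(ses))
  if (any(ses <= 0)) stop("standard errors must be positive")
  w <- 1 / ses^2
  c(estimate = sum(w * estimates) / sum(w), se = sqrt(1 / sum(w)))
}

#' Phenotypic variance and heritabilities
#'
#' `sigma_P2 = sigma_u2 + sigma_v2 + sigma_r2 + sigma_s2`,
#' `H2 = sigma_u2 / sigma_P2` (broad sense) and
#' `h2 = f_a * sigma_u2 / sigma_P2` (narrow sense).
#'
#' @param fit a [fit_clonal_model()] result, or any list with elements
#'   `sigma_u2`, `sigma_v2`, `sigma_r2`, `sigma_s2`.
#' @param f_a additive fraction of the within-family genetic variance.
#' @return `c(sigma_P2, H2, h2)`.
#' @export
heritabilities <- function(fit, f_a) {
  est <- if (inherits(fit, "reml_fit")) fit$estimates else fit
  comp <- c(est$sigma_u2, est$sigma_v2, est$sigma_r2, est$sigma_s2)
  if (anyNA(comp)) stop("all variance components are required")
  sp <- sum(comp)
  if (sp <= 0) stop("phenotypic variance must be positive")
  c(sigma_P2 = sp, H2 = est$sigma_u2 / sp, h2 = f_a * est$sigma_u2 / sp)
}

#' Correction of additive/non-additive fractions for a half-sib mixture
#'
#' When a nominal full-sib family is really a mixture of two maternal
#' half-sib families in proportions `q : 1-q` (unrelated sires), the
#' fitted fractions `r_a`, `r_d` refer to the mixture and must be scaled
#' to full-sib fractions. With within-family shares of the population
#' variances of 1/2 (additive) and 3/4 (dominance-type), and
#' between-family mean variance `q(1-q) sigma/2` for each component
#' (maternal half-sibs: additive relationship 1/4, dominance-type 0), the
#' shares of each component retained in the mixture are
#' `c_A = 0.5 / (0.5 + q(1-q)/2)` and `c_D = 0.75 / (0.75 + q(1-q)/2)`,
#' giving `f_a = c_A r_a / (c_D - (c_D - c_A) r_a)` and
#' `f_d = c_D r_d / (c_A + (c_D - c_A) r_d)`. Coefficients are reported
#' rescaled so the denominator constants are 3 and 2 respectively, at
#' full precision and rounded to 2 dp. At `q = 1` the correction is the
#' identity.
#'
#' @param q majority proportion, in `(0.5, 1]`.
#' @return A `mixture_correction` list: `q`, `c_A`, `c_D`, `a` =
#'   `c(a1, a2)` with `f_a = a1 r_a / (3 - a2 r_a)`, `d` = `c(d1, d2)`
#'   with `f_d = d1 r_d / (2 + d2 r_d)`, and their 2-dp roundings.
#' @export
mixture_correction_coefficients <- function(q) {
  if (!(q > 0.5 && q <= 1)) stop("q must lie in (0.5, 1]")
  b <- q * (1 - q) / 2
  c_A <- 0.5 / (0.5 + b)
  c_D <- 0.75 / (0.75 + b)
  a1 <- 3 * c_A / c_D
  a2 <- 3 - a1
  d1 <- 2 * c_D / c_A
  d2 <- d1 - 2
  structure(list(q = q, c_A = c_A, c_D = c_D,
                 a = c(a1 = a1, a2 = a2), d = c(d1 = d1, d2 = d2),
                 a_rounded = round(c(a1 = a1, a2 = a2), 2),
                 d_rounded = round(c(d1 = d1, d2 = d2), 2)),
            class = "mixture_correction")
}

#' Apply the half-sib-mixture correction to fitted fractions
#'
#' @param r_a,r_d fitted mixture-scale fractions (`r_d = 1 - r_a` under
#'   the model-2 constraint).
#' @param coeffs a [mixture_correction_coefficients()] result.
#' @return Named vector `c(f_a, f_d)` on the full-sib scale.
#' @export
correct_mixture_fractions <- function(r_a, coeffs, r_d = 1 - r_a) {
  stopifnot(inherits(coeffs, "mixture_correction"))
  a <- coeffs$a; d <- coeffs$d
  c(f_a = unname(a["a1"] * r_a / (3 - a["a2"] * r_a)),
    f_d = unname(d["d1"] * r_d / (2 + d["d2"] * r_d)))
}

#' Convert a within-full-sib-family additive fraction to the
#' random-mating-population scale
#'
#' Half the additive variance but three quarters of the dominance and
#' additive-by-additive variance lies within full-sib families, so a
#' within-family additive fraction `f` corresponds to `3f / (2 + f)` in a
#' random-mating population (assuming the non-additive variance is
#' dominance-like or additive-by-additive).
#'
#' @param f_a_within within-family additive fraction in `[0, 1]`.
#' @return The population-scale additive fraction.
#' @export
random_mating_conversion <- function(f_a_within) {
  if (any(f_a_within < 0 | f_a_within > 1)) stop("f_a must lie in [0, 1]")
  3 * f_a_within / (2 + f_a_within)
}
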