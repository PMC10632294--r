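## REML engine for clonal spatial mixed models.
##
## Model 1:  y = Xb + Z_u u + Z_v v + e,  u ~ N(0, sigma_u^2 I) over all
## offspring, v ~ N(0, sigma_v^2 I) over blocks, and e with covariance
## R = sigma_r^2 I + sigma_s^2 blockdiag_k( AR1(rho_c) x AR1(rho_r) )
## over the master blocks (same spatial parameters in every master block).
##
## Model 2 splits u into ungenotyped and genotyped trees: u_1 ~
## N(0, sigma_u^2 I), and for genotyped trees u_2 = u_2(a) + u_2(d) with
## var(u_2(a)) = sigma_u^2 r_a G / k and var(u_2(d)) =
## sigma_u^2 (1 - r_a) I. This builds in the constraint
## sigma_u^2 = k sigma_a^2 + sigma_d^2 exactly, with r_a = k sigma_a^2 /
## sigma_u^2 the additive fraction.
##
## The likelihood has a dense path (any layout, explicit V) and a fast
## structured path (Woodbury identity over the low-rank genetic + block
## part, Kronecker eigen-decomposition of the AR1 x AR1 residual) usable
## when every master block is a completely observed rectangular grid.

#' First-order autoregressive correlation matrix
#'
#' @param n dimension (>= 1).
#' @param rho autocorrelation, `|rho| < 1`.
#' @return The n x n matrix with entries `rho^|i-j|`.
#' @export
ar1_matrix <- function(n, rho) {
  if (n < 1L) stop("n must be >= 1")
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  rho^abs(outer(seq_len(n), seq_len(n), "-"))
}

#' Spatial parameter set
#'
#' @param sigma_r2 nugget (random error) variance.
#' @param sigma_s2 spatially structured error variance.
#' @param rho_c,rho_r column/row autocorrelations.
#' @return A `spatial_params` list including the error fractions
#'   `f_r`, `f_s` when the total error variance is positive.
#' @export
spatial_params <- function(sigma_r2, sigma_s2, rho_c, rho_r) {
  if (sigma_r2 < 0 || sigma_s2 < 0) stop("variances must be non-negative")
  if (abs(rho_c) >= 1 || abs(rho_r) >= 1) stop("|rho| must be < 1")
  out <- list(sigma_r2 = sigma_r2, sigma_s2 = sigma_s2,
              rho_c = rho_c, rho_r = rho_r)
  if (sigma_r2 + sigma_s2 > 0) {
    out$f_r <- sigma_r2 / (sigma_r2 + sigma_s2)
    out$f_s <- 1 - out$f_r
  }
  structure(out, class = "spatial_params")
}

#' Fractions of random and spatial error variance
#'
#' @param spatial a [spatial_params()] (or any list with `sigma_r2`,
#'   `sigma_s2`).
#' @return `c(f_r, f_s)` with `f_r = sigma_r2 / (sigma_r2 + sigma_s2)`.
#' @export
error_fractions <- function(spatial) {
  tot <- spatial$sigma_r2 + spatial$sigma_s2
  if (tot <= 0) stop("total error variance must be positive")
  f_r <- spatial$sigma_r2 / tot
  c(f_r = f_r, f_s = 1 - f_r)
}

#' Residual covariance over observed plots
#'
#' `R = sigma_r2 I + sigma_s2 blockdiag_k(AR1_col x AR1_row)` restricted
#' to the observed plots, with the same spatial parameters shared by all
#' master blocks; plots in different master blocks are uncorrelated.
#'
#' @param spatial a [spatial_params()].
#' @param coords data.frame with columns `master_block`, `column`, `row`
#'   (one row per observed plot; coordinates must be unique within a
#'   master block).
#' @return Dense covariance matrix over the observed plots.
#' @export
residual_covariance <- function(spatial, coords) {
  key <- paste(coords$master_block, coords$column, coords$row)
  if (anyDuplicated(key)) stop("duplicate plot coordinates within a master block")
  n <- nrow(coords)
  R <- matrix(0, n, n)
  for (mb in unique(coords$master_block)) {
    sel <- which(coords$master_block == mb)
    dc <- abs(outer(coords$column[sel], coords$column[sel], "-"))
    dr <- abs(outer(coords$row[sel], coords$row[sel], "-"))
    R[sel, sel] <- spatial$sigma_s2 * spatial$rho_c^dc * spatial$rho_r^dr
  }
  R + diag(spatial$sigma_r2, n)
}

#' Assemble trial data for REML fitting
#'
#' Drops plots with missing phenotypes (fillers, controls, dead trees),
#' orders genotype identities with ungenotyped trees first, and
#' pre-computes the eigen-decomposition of `G/k` for the genotyped
#' subset. The structured likelihood path is enabled when every master
#' block's observed plots form a complete rectangular grid.
#'
#' @param trial a `trial_frame` (or any data.frame with columns
#'   `genotype_id`, `block`, `master_block`, `column`, `row`, `value`).
#' @param grm optional [vanraden_g()] result (or list with `G`, `k`) whose
#'   row names identify the genotyped trees; NULL for model 1.
#' @param covariates optional numeric matrix of extra fixed covariates
#'   indexed by genotype id (e.g. mean heterozygosity), mean-centred and
#'   appended to the intercept-only design.
#' @return A `trial_data` list.
#' @export
trial_data <- function(trial, grm = NULL, covariates = NULL) {
  obs <- trial[!is.na(trial$value), , drop = FALSE]
  if (nrow(obs) == 0L) stop("no observed phenotypes")
  ids <- unique(obs$genotype_id)
  gids <- character(0)
  if (!is.null(grm)) {
    gn <- rownames(grm$G)
    if (is.null(gn)) stop("G must carry row names identifying genotyped trees")
    gids <- intersect(gn, ids)
  }
  uids <- setdiff(ids, gids)
  id_levels <- c(uids, gids)
  id_idx <- match(obs$genotype_id, id_levels)
  X <- matrix(1, nrow(obs), 1L, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[obs$genotype_id, , drop = FALSE]
    cv <- scale(cv, scale = FALSE)
    X <- cbind(X, cv)
  }
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  eigenG <- NULL
  if (length(gids) > 0L) {
    Gk <- grm$G[gids, gids, drop = FALSE] / grm$k
    eg <- eigen((Gk + t(Gk)) / 2, symmetric = TRUE)
    eigenG <- list(Q = eg$vectors, lambda = pmax(eg$values, 0))
  }
  blocks <- factor(obs$block)
  coords <- obs[, c("master_block", "column", "row")]
  structured <- .structured_index(coords)
  structure(list(
    y = obs$value, X = X, id_idx = id_idx, id_levels = id_levels,
    n_ungeno = length(uids), n_geno = length(gids),
    block = blocks, coords = coords, eigenG = eigenG,
    k = if (is.null(grm)) NA_real_ else grm$k,
    structured = structured, n = nrow(obs)
  ), class = "trial_data")
}

# Per-master-block complete-grid index for the Kronecker path, or NULL.
.structured_index <- function(coords) {
  out <- list()
  for (mb in unique(coords$master_block)) {
    sel <- which(coords$master_block == mb)
    nc <- max(coords$column[sel]); nr <- max(coords$row[sel])
    if (length(sel) != nc * nr) return(NULL)
    pos <- (coords$column[sel] - 1L) * nr + coords$row[sel]
    if (anyDuplicated(pos)) return(NULL)
    ord <- sel[order(pos)]
    out[[as.character(mb)]] <- list(rows = ord, nc = nc, nr = nr)
  }
  out
}

# sqrt factor of the genetic covariance over id levels (m x m), columns
# ordered ungenotyped then genotyped.
.genetic_sqrt <- function(data, sigma_u2, r_a, model) {
  m <- length(data$id_levels)
  m1 <- data$n_ungeno
  if (model == 1L || data$n_geno == 0L) {
    return(list(diag_sd = rep(sqrt(sigma_u2), m), Q = NULL))
  }
  lam <- r_a * data$eigenG$lambda + (1 - r_a)
  list(diag_sd = rep(sqrt(sigma_u2), m1),
       Q = data$eigenG$Q, geno_sd = sqrt(sigma_u2 * pmax(lam, 0)))
}

# W such that V = R + W W' (random-effect square root mapped to plots).
.build_W <- function(data, params, model) {
  gs <- .genetic_sqrt(data, params$sigma_u2, params$r_a, model)
  m <- length(data$id_levels)
  m1 <- data$n_ungeno
  n <- data$n
  if (is.null(gs$Q)) {
    Wg <- matrix(0, n, m)
    Wg[cbind(seq_len(n), data$id_idx)] <- gs$diag_sd[data$id_idx]
  } else {
    Lu <- matrix(0, m, m)
    if (m1 > 0L) Lu[cbind(seq_len(m1), seq_len(m1))] <- gs$diag_sd
    m2 <- m - m1
    Lu[(m1 + 1L):m, (m1 + 1L):m] <- gs$Q * rep(gs$geno_sd, each = m2)
    Wg <- Lu[data$id_idx, , drop = FALSE]
  }
  nb <- nlevels(data$block)
  Wv <- matrix(0, n, nb)
  Wv[cbind(seq_len(n), as.integer(data$block))] <- sqrt(params$sigma_v2)
  cbind(Wg, Wv)
}

# Apply R^{-1} to columns of M via the Kronecker eigen-decomposition;
# also returns log|R|. `eig` holds per-block eigen systems and D.
.kron_solve <- function(M, blocks, eig) {
  out <- M
  logdet <- 0
  for (b in seq_along(blocks)) {
    bl <- blocks[[b]]
    e <- eig[[b]]
    nr <- bl$nr; nc <- bl$nc; q <- ncol(M)
    Xb <- M[bl$rows, , drop = FALSE]
    A <- crossprod(e$Qr, matrix(Xb, nr, nc * q))          # (nr, nc*q)
    A <- array(A, c(nr, nc, q))
    A <- matrix(aperm(A, c(2L, 1L, 3L)), nc, nr * q)      # (nc, nr*q)
    A <- crossprod(e$Qc, A)
    A <- A / as.vector(e$D)                               # D is (nc, nr)
    A <- e$Qc %*% A
    A <- array(A, c(nc, nr, q))
    A <- matrix(aperm(A, c(2L, 1L, 3L)), nr, nc * q)
    A <- e$Qr %*% A
    out[bl$rows, ] <- matrix(A, nr * nc, q)
    logdet <- logdet + sum(log(e$D)) * 1
  }
  list(M = out, logdet = logdet)
}

.kron_eigen <- function(blocks, spatial) {
  lapply(blocks, function(bl) {
    ec <- eigen(ar1_matrix(bl$nc, spatial$rho_c), symmetric = TRUE)
    er <- eigen(ar1_matrix(bl$nr, spatial$rho_r), symmetric = TRUE)
    D <- spatial$sigma_r2 + spatial$sigma_s2 * outer(ec$values, er$values)
    list(Qc = ec$vectors, Qr = er$vectors, D = D)
  })
}

#' REML log-likelihood of the clonal spatial mixed model
#'
#' Evaluates the restricted log-likelihood (fixed effects profiled out)
#' at the given variance parameters. Returns `-Inf` with a diagnostic
#' attribute, not an error, when the implied covariance is not positive
#' definite.
#'
#' @param params list with `sigma_u2`, `sigma_v2`, `sigma_r2`, `sigma_s2`,
#'   `rho_c`, `rho_r`, and `r_a` for model 2.
#' @param data a [trial_data()].
#' @param model 1 (total genetic only) or 2 (genotyped trees split into
#'   additive and non-additive parts under the variance constraint).
#' @param method "auto", "structured" or "dense". "auto" uses the
#'   structured Kronecker/Woodbury path when every master block is a
#'   complete grid, else the dense path.
#' @return The REML log-likelihood (scalar).
#' @export
reml_loglik <- function(params, data, model = 2L, method = "auto") {
  pc <- .reml_pieces(params, data, model, method)
  if (!is.list(pc)) return(pc)
  unname(-0.5 * ((pc$n - pc$p) * log(2 * pi) + pc$logdetV + pc$logdetXVX + pc$yPy))
}

# Likelihood building blocks; returns -Inf (with a reason attribute) on a
# non-PD covariance instead of erroring.
.reml_pieces <- function(params, data, model = 2L, method = "auto") {
  stopifnot(inherits(data, "trial_data"))
  model <- as.integer(model)
  if (model == 2L && data$n_geno > 0L && is.null(params$r_a))
    stop("model 2 requires r_a")
  if (any(c(params$sigma_u2, params$sigma_v2, params$sigma_r2, params$sigma_s2) < 0) ||
      abs(params$rho_c) >= 1 || abs(params$rho_r) >= 1)
    return(structure(-Inf, reason = "parameters outside domain"))
  if (!is.null(params$r_a) && (params$r_a < 0 || params$r_a > 1))
    return(structure(-Inf, reason = "r_a outside [0, 1]"))
  use_structured <- switch(method,
    auto = !is.null(data$structured),
    structured = TRUE,
    dense = FALSE,
    stop("unknown method")
  )
  if (use_structured && is.null(data$structured))
    stop("structured path requires completely observed master-block grids")
  W <- .build_W(data, params, model)
  n <- data$n
  p <- ncol(data$X)
  M <- cbind(W, data$X, data$y)
  q <- ncol(W)
  if (use_structured) {
    eig <- .kron_eigen(data$structured, params)
    if (any(vapply(eig, function(e) any(e$D <= 0), TRUE)))
      return(structure(-Inf, reason = "residual covariance not positive definite"))
    ks <- .kron_solve(M, data$structured, eig)
    S <- crossprod(M, ks$M)
    logdetR <- ks$logdet
  } else {
    R <- residual_covariance(
      spatial_params(params$sigma_r2, params$sigma_s2, params$rho_c, params$rho_r),
      data$coords
    )
    cR <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(cR)) return(structure(-Inf, reason = "residual covariance not positive definite"))
    RiM <- backsolve(cR, backsolve(cR, M, transpose = TRUE))
    S <- crossprod(M, RiM)
    logdetR <- 2 * sum(log(diag(cR)))
  }
  C <- diag(q) + S[seq_len(q), seq_len(q), drop = FALSE]
  cC <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(cC)) return(structure(-Inf, reason = "capacitance matrix not positive definite"))
  rest <- q + seq_len(p + 1L)
  Tm <- S[seq_len(q), rest, drop = FALSE]
  Quad <- S[rest, rest, drop = FALSE] -
    crossprod(backsolve(cC, Tm, transpose = TRUE))
  XVX <- Quad[seq_len(p), seq_len(p), drop = FALSE]
  XVy <- Quad[seq_len(p), p + 1L]
  yVy <- Quad[p + 1L, p + 1L]
  cX <- tryCatch(chol(XVX), error = function(e) NULL)
  if (is.null(cX)) return(structure(-Inf, reason = "X'V^-1 X not positive definite"))
  yPy <- yVy - sum(backsolve(cX, XVy, transpose = TRUE)^2)
  list(logdetV = logdetR + 2 * sum(log(diag(cC))),
       logdetXVX = 2 * sum(log(diag(cX))),
       yPy = yPy, n = n, p = p)
}

# REML log-likelihood with the overall variance scale profiled out: for
# V(c) = c * V the optimum is c* = y'Py / (n - p), available in closed
# form from one evaluation. Returns the profiled logL and c*.
.reml_profiled <- function(params, data, model = 2L, method = "auto") {
  pc <- .reml_pieces(params, data, model, method)
  if (!is.list(pc)) return(list(ll = -Inf, c_star = NA_real_))
  np <- pc$n - pc$p
  c_star <- pc$yPy / np
  if (!is.finite(c_star) || c_star <= 0) return(list(ll = -Inf, c_star = NA_real_))
  ll <- -0.5 * (np * log(2 * pi) + np * log(c_star) + pc$logdetV +
                  pc$logdetXVX + np)
  list(ll = ll, c_star = c_star)
}

## ---- optimization over transformed parameters -------------------------

.par_names <- function(model) {
  if (model == 2L) c("sigma_u2", "r_a", "sigma_v2", "sigma_r2", "sigma_s2", "rho_c", "rho_r")
  else c("sigma_u2", "sigma_v2", "sigma_r2", "sigma_s2", "rho_c", "rho_r")
}

.to_transformed <- function(params, model) {
  nm <- .par_names(model)
  vapply(nm, function(k) {
    x <- params[[k]]
    switch(k,
      r_a = stats::qlogis(min(max(x, 1e-6), 1 - 1e-6)),
      rho_c = , rho_r = atanh(min(max(x, -0.998), 0.998)),
      log(max(x, 1e-10))
    )
  }, 0)
}

.from_transformed <- function(th, model) {
  nm <- .par_names(model)
  out <- list()
  for (i in seq_along(nm)) {
    k <- nm[i]
    out[[k]] <- unname(switch(k,
      r_a = stats::plogis(th[i]),
      rho_c = , rho_r = max(min(tanh(th[i]), 0.999), -0.999),
      min(exp(th[i]), 1e9)
    ))
  }
  out
}

# Moment-based starting values: the variance of clone (genotype) means
# estimates sigma_u2 + (block+error)/ramets, the mean within-clone
# variance estimates the block+error total.
.default_init <- function(data, model) {
  vy <- stats::var(data$y)
  sp <- split(data$y, data$id_idx)
  nr <- mean(lengths(sp))
  w <- mean(vapply(sp[lengths(sp) > 1L], stats::var, 0), na.rm = TRUE)
  if (!is.finite(w) || w <= 0) w <- 0.7 * vy
  b <- stats::var(vapply(sp, mean, 0))
  su <- max(b - w / max(nr, 1), 0.05 * vy)
  list(sigma_u2 = su, r_a = 0.5, sigma_v2 = 0.1 * w,
       sigma_r2 = 0.6 * w, sigma_s2 = 0.3 * w, rho_c = 0.6, rho_r = 0.6)
}

#' Fit the clonal spatial mixed model by REML
#'
#' Maximizes the REML log-likelihood over log-variances,
#' atanh-autocorrelations and (model 2) logit `r_a`, so the constraint
#' `sigma_u2 = k sigma_a2 + sigma_d2` and all domain restrictions are
#' built into the parameterization. The overall variance scale is
#' profiled out in closed form; the remaining search is Nelder-Mead with
#' a quasi-Newton polish from systematic multi-starts (the additive
#' fraction is the direction prone to local optima, so extra starts
#' displace it). Standard errors come from the observed information
#' (central-difference curvature on the transformed scale, delta-method
#' back-transform).
#'
#' @param data a [trial_data()].
#' @param model 1 or 2.
#' @param init optional named list of starting values (natural scale).
#' @param fix optional named list of parameters held fixed (natural
#'   scale), e.g. `list(r_a = 0.4)` for likelihood profiling.
#' @param n_starts number of jittered multi-starts.
#' @param control list: `maxit` (Nelder-Mead iterations), `reltol`,
#'   `seed` (jitter seed), `se` (compute standard errors), `method`
#'   (likelihood path).
#' @return A `reml_fit` list: `estimates`, `logL`, `se`, `converged`,
#'   `model`, `fixed`, `counts`.
#' @export
fit_clonal_model <- function(data, model = 2L, init = NULL, fix = NULL,
                             n_starts = 3L, control = list()) {
  model <- as.integer(model)
  ctl <- utils::modifyList(list(maxit = 500L, bfgs_maxit = 60L, reltol = 1e-10,
                                seed = 1L, se = TRUE, method = "auto"), control)
  nm <- .par_names(model)
  var_nm <- c("sigma_u2", "sigma_v2", "sigma_r2", "sigma_s2")
  fix_nm <- intersect(names(fix), nm)
  # the overall variance scale has a closed-form REML optimum, so it is
  # profiled out of the numerical search (one variance is pinned) unless
  # the caller fixed a variance at an absolute value
  profile_scale <- !any(var_nm %in% fix_nm)
  drop_nm <- if (profile_scale) c(fix_nm, "sigma_u2") else fix_nm
  free_nm <- setdiff(nm, drop_nm)
  start <- .default_init(data, model)
  if (!is.null(init)) start <- utils::modifyList(start, init[names(init) %in% nm])
  th_full <- .to_transformed(start, model)
  if (length(fix_nm))
    th_full[fix_nm] <- .to_transformed(utils::modifyList(start, fix), model)[fix_nm]
  free_ix <- match(free_nm, nm)
  par_at <- function(th_free) {
    th <- th_full
    th[free_ix] <- th_free
    pr <- .from_transformed(th, model)
    if (length(fix_nm)) pr[fix_nm] <- fix[fix_nm]
    pr
  }
  objective <- function(th_free) {
    pr <- par_at(th_free)
    ll <- if (profile_scale) .reml_profiled(pr, data, model, method = ctl$method)$ll
          else reml_loglik(pr, data, model, method = ctl$method)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  best <- NULL
  # systematic (seed-independent) multi-starts: the additive fraction is
  # the direction prone to local optima, so extra starts displace it (or,
  # without r_a, the autocorrelations); further starts beyond 3 jitter
  # randomly from ctl$seed
  starts <- list(th_full[free_ix])
  sys_shift <- if ("r_a" %in% free_nm) {
    list(stats::setNames(stats::qlogis(0.15) - th_full["r_a"], "r_a"),
         stats::setNames(stats::qlogis(0.85) - th_full["r_a"], "r_a"))
  } else {
    list(stats::setNames(atanh(0.2) - th_full["rho_c"], "rho_c"),
         stats::setNames(atanh(0.85) - th_full["rho_c"], "rho_c"))
  }
  if (n_starts > 1L)
    for (s in seq_len(min(n_starts - 1L, 2L))) {
      st <- th_full[free_ix]
      st[names(sys_shift[[s]])] <- st[names(sys_shift[[s]])] + sys_shift[[s]]
      starts[[s + 1L]] <- st
    }
  if (n_starts > 3L) {
    rng <- local_rng(ctl$seed)
    for (s in seq(4L, n_starts))
      starts[[s]] <- th_full[free_ix] + stats::rnorm(length(free_ix), 0, 0.4)
  }
  for (s in seq_along(starts)) {
    o <- stats::optim(starts[[s]], objective, method = "Nelder-Mead",
                      control = list(maxit = ctl$maxit, reltol = ctl$reltol))
    # quasi-Newton polish on the smooth transformed scale
    o2 <- tryCatch(
      stats::optim(o$par, objective, method = "BFGS",
                   control = list(maxit = ctl$bfgs_maxit, reltol = 1e-12)),
      error = function(e) o
    )
    if (o2$value <= o$value) o <- o2
    if (is.null(best) || o$value < best$value) best <- o
  }
  est <- par_at(best$par)
  if (profile_scale) {
    cs <- .reml_profiled(est, data, model, method = ctl$method)$c_star
    for (v in var_nm) est[[v]] <- est[[v]] * cs
  }
  logL <- -best$value
  se <- rep(NA_real_, length(nm)); names(se) <- nm
  # curvature of the full (unprofiled) objective at the final estimates
  free_se_nm <- setdiff(nm, fix_nm)
  if (isTRUE(ctl$se) && length(free_se_nm)) {
    th_est <- .to_transformed(est, model)
    se_ix <- match(free_se_nm, nm)
    obj_full <- function(th_free) {
      th <- th_est
      th[se_ix] <- th_free
      pr <- .from_transformed(th, model)
      if (length(fix_nm)) pr[fix_nm] <- fix[fix_nm]
      ll <- reml_loglik(pr, data, model, method = ctl$method)
      if (!is.finite(ll)) return(1e10)
      -ll
    }
    free_nm <- free_se_nm
    H <- .num_hessian(obj_full, th_est[se_ix])
    cv <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(cv) && all(diag(cv) > 0)) {
      sd_t <- sqrt(diag(cv))
      for (i in seq_along(free_nm)) {
        k <- free_nm[i]
        x <- est[[k]]
        deriv <- switch(k, r_a = x * (1 - x),
                        rho_c = , rho_r = 1 - x^2, x)  # d natural / d transformed
        se[k] <- abs(deriv) * sd_t[i]
      }
    }
  }
  converged <- best$convergence == 0L || best$value < 1e9
  if (!converged) warning("REML fit did not converge; best point returned")
  structure(list(model = model, estimates = est, logL = logL, se = se,
                 converged = converged, fixed = fix, counts = best$counts,
                 k = data$k, data = data),
            class = "reml_fit")
}

.num_hessian <- function(f, x, h = 1e-3) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in seq((i + 1L), d)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) / (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

#' Sample variogram of residuals on the trial grid
#'
#' `gamma(dc, dr)` is half the mean squared difference of residuals over
#' all pairs of plots in the same master block displaced by `dc` columns
#' and `dr` rows. For an AR1 x AR1 plus nugget error process the
#' variogram rises from the nugget discontinuity at zero displacement to
#' a sill at the total error variance.
#'
#' @param residuals numeric vector aligned with `coords` rows.
#' @param coords data.frame with `master_block`, `column`, `row`.
#' @return Data.frame with columns `dcol`, `drow`, `gamma`, `n_pairs`.
#' @export
sample_variogram <- function(residuals, coords) {
  stopifnot(length(residuals) == nrow(coords))
  res <- split(seq_along(residuals), coords$master_block)
  tab <- NULL
  for (sel in res) {
    n <- length(sel)
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    dc <- abs(coords$column[sel][ij[, 1]] - coords$column[sel][ij[, 2]])
    dr <- abs(coords$row[sel][ij[, 1]] - coords$row[sel][ij[, 2]])
    sq <- 0.5 * (residuals[sel][ij[, 1]] - residuals[sel][ij[, 2]])^2
    key <- paste(dc, dr)
    s <- tapply(sq, key, sum)
    cnt <- tapply(rep(1, length(sq)), key, sum)
    d <- data.frame(key = names(s), s = as.numeric(s), n = as.numeric(cnt))
    tab <- if (is.null(tab)) d else {
      m <- merge(tab, d, by = "key", all = TRUE)
      m[is.na(m)] <- 0
      data.frame(key = m$key, s = m$s.x + m$s.y, n = m$n.x + m$n.y)
    }
  }
  parts <- do.call(rbind, strsplit(tab$key, " "))
  out <- data.frame(dcol = as.integer(parts[, 1]), drow = as.integer(parts[, 2]),
                    gamma = tab$s / tab$n, n_pairs = tab$n)
  out[order(out$dcol, out$drow), ]
}
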