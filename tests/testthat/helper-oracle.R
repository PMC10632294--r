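# Independent brute-force REML oracle: builds V explicitly from the model
# definition and evaluates the restricted likelihood with solve() and
# determinant(), sharing no code path with the package's Woodbury /
# Kronecker evaluation.

oracle_reml <- function(params, td, G = NULL, k = NULL, model = 2L) {
  n <- td$n
  m <- length(td$id_levels)
  m1 <- td$n_ungeno
  Zu <- matrix(0, n, m)
  Zu[cbind(seq_len(n), td$id_idx)] <- 1
  Zv <- matrix(0, n, nlevels(td$block))
  Zv[cbind(seq_len(n), as.integer(td$block))] <- 1
  Su <- diag(params$sigma_u2, m)
  if (model == 2L && td$n_geno > 0L) {
    gids <- td$id_levels[(m1 + 1L):m]
    Gk <- G[gids, gids, drop = FALSE] / k
    idx <- (m1 + 1L):m
    Su[idx, idx] <- params$sigma_u2 *
      (params$r_a * Gk + (1 - params$r_a) * diag(td$n_geno))
  }
  co <- td$coords
  same_mb <- outer(co$master_block, co$master_block, "==")
  R <- params$sigma_s2 * same_mb *
    params$rho_c^abs(outer(co$column, co$column, "-")) *
    params$rho_r^abs(outer(co$row, co$row, "-"))
  diag(R) <- diag(R) + params$sigma_r2
  V <- Zu %*% Su %*% t(Zu) + params$sigma_v2 * tcrossprod(Zv) + R
  Vi <- solve(V)
  X <- td$X
  y <- td$y
  XVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XVX, t(X) %*% Vi)
  as.numeric(
    -0.5 * ((n - ncol(X)) * log(2 * pi) +
              determinant(V, logarithm = TRUE)$modulus +
              determinant(XVX, logarithm = TRUE)$modulus +
              t(y) %*% P %*% y)
  )
}

# Closed-form REML for an intercept-only iid model: the restricted
# likelihood of y ~ N(mu, sigma2 I).
oracle_iid_reml <- function(y, sigma2) {
  n <- length(y)
  rss <- sum((y - mean(y))^2)
  -0.5 * ((n - 1) * log(2 * pi) + n * log(sigma2) + log(n / sigma2) + rss / sigma2)
}
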