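## Clonal field-trial layout and phenotype simulation. A trial is one
## site x family combination laid out as a randomized complete block
## design; each offspring contributes one ramet per replicate block.
## Non-contiguous blocks are grouped into "master blocks": spatially
## continuous grids that carry their own AR1 x AR1 correlated error field,
## with the same spatial parameters shared by all master blocks.

#' Trial layout specification
#'
#' Blocks are rectangular `block_ncol x block_nrow` grids placed side by
#' side (along the column direction) within their master block, so a
#' master block holding `m` blocks is an `(m * block_ncol) x block_nrow`
#' grid. Plot coordinates are 1-based within a master block. Plots beyond
#' the number of offspring are filler plots (no genotype, no phenotype),
#' mirroring the treatment of uncloned control trees.
#'
#' @param n_offspring number of offspring genotypes planted.
#' @param n_blocks number of replicate blocks; each offspring has one
#'   ramet per block, so ramets per site equals `n_blocks`.
#' @param block_ncol,block_nrow block grid dimensions; must satisfy
#'   `block_ncol * block_nrow >= n_offspring`.
#' @param n_master number of master blocks (1 or 2); blocks are split as
#'   evenly as possible across master blocks.
#' @param site site label.
#' @return A `trial_layout` data.frame with one row per plot and columns
#'   `site`, `block`, `master_block`, `column`, `row`, `filler`.
#' @export
trial_layout <- function(n_offspring, n_blocks = 4L, block_ncol, block_nrow,
                         n_master = 1L, site = "S1") {
  if (block_ncol * block_nrow < n_offspring)
    stop("grid too small: each block must hold one ramet of every offspring")
  stopifnot(n_master >= 1L, n_master <= n_blocks)
  mb_of_block <- rep(seq_len(n_master), length.out = n_blocks)
  mb_of_block <- sort(mb_of_block)
  rows <- vector("list", n_blocks)
  for (b in seq_len(n_blocks)) {
    pos_in_mb <- sum(mb_of_block[seq_len(b)] == mb_of_block[b]) - 1L
    cols <- pos_in_mb * block_ncol + seq_len(block_ncol)
    grid <- expand.grid(row = seq_len(block_nrow), column = cols)
    rows[[b]] <- data.frame(
      site = site, block = b, master_block = mb_of_block[b],
      column = grid$column, row = grid$row
    )
  }
  out <- do.call(rbind, rows)
  out$filler <- FALSE
  class(out) <- c("trial_layout", "data.frame")
  attr(out, "n_offspring") <- as.integer(n_offspring)
  out
}

#' Spatial and block noise configuration
#'
#' @param sigma_v2 replicate-block variance.
#' @param sigma_r2 random (nugget) error variance.
#' @param sigma_s2 spatially structured error variance.
#' @param rho_c,rho_r column and row autocorrelations, in (-1, 1).
#' @return A `noise_config` list.
#' @export
noise_config <- function(sigma_v2 = 0.15, sigma_r2 = 1.26, sigma_s2 = 0.54,
                         rho_c = 0.8, rho_r = 0.8) {
  if (any(c(sigma_v2, sigma_r2, sigma_s2) < 0)) stop("variances must be non-negative")
  if (abs(rho_c) >= 1 || abs(rho_r) >= 1) stop("autocorrelations must lie in (-1, 1)")
  structure(list(sigma_v2 = sigma_v2, sigma_r2 = sigma_r2, sigma_s2 = sigma_s2,
                 rho_c = rho_c, rho_r = rho_r),
            class = "noise_config")
}

# Draw one AR1 x AR1 Gaussian field on a full nc x nr grid via the
# eigen square roots of the two correlation matrices (exact, O(nc^3+nr^3)).
draw_ar1_field <- function(nc, nr, rho_c, rho_r, sigma_s2) {
  if (sigma_s2 == 0) return(matrix(0, nr, nc))
  ec <- eigen(ar1_matrix(nc, rho_c), symmetric = TRUE)
  er <- eigen(ar1_matrix(nr, rho_r), symmetric = TRUE)
  Sc <- ec$vectors %*% (sqrt(pmax(ec$values, 0)) * t(ec$vectors))
  Sr <- er$vectors %*% (sqrt(pmax(er$values, 0)) * t(er$vectors))
  sqrt(sigma_s2) * (Sr %*% matrix(stats::rnorm(nr * nc), nr, nc) %*% Sc)
}

#' Simulate a clonally replicated spatial field trial
#'
#' Ramets are assigned to plots by a seeded random permutation within each
#' block. Phenotype = `mu` + total genetic value of the ortet + block
#' effect + spatially structured error (separable AR1 x AR1 field drawn
#' independently per master block) + nugget error. Filler plots carry a
#' missing phenotype.
#'
#' @param layout a [trial_layout()].
#' @param u named vector of total genetic values; names are offspring ids.
#'   The first `attr(layout, "n_offspring")` entries are planted.
#' @param noise a [noise_config()].
#' @param mu trait mean.
#' @param trait trait label.
#' @param seed integer seed.
#' @return A `trial_frame` data.frame with columns `tree_id`,
#'   `genotype_id`, `site`, `block`, `master_block`, `column`, `row`,
#'   `trait`, `value`, plus truth attributes `truth` (per-plot genetic,
#'   block, spatial, nugget components).
#' @export
simulate_trial <- function(layout, u, noise, mu = 0, trait = "trait", seed = 1L) {
  stopifnot(inherits(layout, "trial_layout"), inherits(noise, "noise_config"))
  n_off <- attr(layout, "n_offspring")
  ids <- names(u)[seq_len(n_off)]
  if (anyNA(ids)) stop("every non-filler plot must map to an offspring with a genetic value")
  rng <- local_rng(seed)
  lay <- as.data.frame(layout)
  lay$genotype_id <- NA_character_
  for (b in unique(lay$block)) {
    idx <- which(lay$block == b)
    slots <- sample(idx, n_off)
    lay$genotype_id[slots] <- ids
  }
  lay$filler <- is.na(lay$genotype_id)
  blocks <- sort(unique(lay$block))
  v <- stats::rnorm(length(blocks), 0, sqrt(noise$sigma_v2))
  names(v) <- as.character(blocks)
  lay$spatial <- 0
  for (mb in unique(lay$master_block)) {
    sel <- lay$master_block == mb
    nc <- max(lay$column[sel]); nr <- max(lay$row[sel])
    fld <- draw_ar1_field(nc, nr, noise$rho_c, noise$rho_r, noise$sigma_s2)
    lay$spatial[sel] <- fld[cbind(lay$row[sel], lay$column[sel])]
  }
  lay$nugget <- stats::rnorm(nrow(lay), 0, sqrt(noise$sigma_r2))
  lay$genetic <- ifelse(lay$filler, NA_real_, u[lay$genotype_id])
  lay$block_eff <- v[as.character(lay$block)]
  value <- mu + lay$genetic + lay$block_eff + lay$spatial + lay$nugget
  value[lay$filler] <- NA_real_
  out <- data.frame(
    tree_id = sprintf("%s_B%d_C%d_R%d", lay$site, lay$block, lay$column, lay$row),
    genotype_id = lay$genotype_id,
    site = lay$site, block = lay$block, master_block = lay$master_block,
    column = lay$column, row = lay$row,
    trait = trait, value = value,
    stringsAsFactors = FALSE
  )
  attr(out, "truth") <- lay[, c("genotype_id", "block", "master_block", "column",
                                "row", "genetic", "block_eff", "spatial", "nugget")]
  attr(out, "noise") <- noise
  attr(out, "mu") <- mu
  class(out) <- c("trial_frame", "data.frame")
  out
}
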