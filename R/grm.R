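## Genomic relationship matrix (VanRaden method 1) from allele dosages,
## with family-internal allele frequencies, and the scalar k that rescales
## the G-based additive variance to the family's realized additive
## variance in the constraint sigma_u^2 = k * sigma_a^2 + sigma_d^2.

#' Expected allele dosage from genotype probabilities
#'
#' The dosage is the expected number of alternative alleles:
#' `0*P0 + 1*P1 + 2*P2`. Probability triples are validated (non-negative,
#' summing to 1 within 1e-6) and renormalized.
#'
#' @param gp a probability triple, or a matrix/data.frame with three
#'   columns (P0, P1, P2), or an n x L x 3 array.
#' @return Dosages in `[0, 2]`, shaped as the input without its last
#'   probability dimension.
#' @export
dosage_from_probabilities <- function(gp) {
  if (is.array(gp) && length(dim(gp)) == 3L) {
    stopifnot(dim(gp)[3] == 3L)
    if (any(gp < 0)) stop("genotype probabilities must be non-negative")
    s <- gp[, , 1] + gp[, , 2] + gp[, , 3]
    if (any(abs(s - 1) > 1e-6)) stop("genotype probabilities must sum to 1 (tolerance 1e-6)")
    return((gp[, , 2] + 2 * gp[, , 3]) / s)
  }
  m <- if (is.null(dim(gp))) matrix(gp, ncol = 3L, byrow = TRUE) else as.matrix(gp)
  if (ncol(m) != 3L) stop("expected probability triples over allele counts 0, 1, 2")
  if (any(m < 0)) stop("genotype probabilities must be non-negative")
  s <- rowSums(m)
  if (any(abs(s - 1) > 1e-6)) stop("genotype probabilities must sum to 1 (tolerance 1e-6)")
  d <- (m[, 2] + 2 * m[, 3]) / s
  if (is.null(dim(gp)) && length(gp) == 3L) d[[1]] else d
}

#' Family-internal allele frequencies from the full-sib parents
#'
#' For a full-sib cross the alternative-allele frequency at a segregating
#' SNP is the parental allele count over 4, i.e. 0.25, 0.5 or 0.75.
#' Monomorphic crosses (frequency 0 or 1) are excluded and logged.
#'
#' @param father,mother parental dosage vectors (0..2; dosages allowed).
#' @return List with `p` (frequencies for retained SNPs), `keep` (logical
#'   over input SNPs) and `excluded` (ids or indices of monomorphic SNPs).
#' @export
parental_allele_frequencies <- function(father, mother) {
  stopifnot(length(father) == length(mother))
  if (anyNA(father) || anyNA(mother)) stop("both parents must be genotyped at every SNP")
  p <- (father + mother) / 4
  keep <- p > 0 & p < 1
  ids <- names(father)
  if (is.null(ids)) ids <- as.character(seq_along(father))
  list(p = p[keep], keep = keep, excluded = ids[!keep])
}

#' VanRaden method-1 genomic relationship matrix
#'
#' `G = W W' / sum_i 2 p_i (1 - p_i)` where `W` holds dosages centred at
#' `2 p_i`. SNPs with frequency 0 or 1 are excluded. Missing dosages are
#' mean-imputed at `2 p_i` with a loud warning (dosages produced by
#' probability expectation should have none). Positive semidefiniteness is
#' checked and reported, not enforced.
#'
#' @param dosages individuals x SNP matrix of alternative-allele dosages
#'   in `[0, 2]`.
#' @param p per-SNP allele frequencies (recycled checkable length), e.g.
#'   from [parental_allele_frequencies()] (pure full-sib families) or
#'   observed means `colMeans(dosages)/2` (mixed families).
#' @return A `genomic_relationship` list: `G`, `k` (from [scaling_k()]),
#'   `freqs`, `denom`, `n_snps`, `psd`.
#' @export
vanraden_g <- function(dosages, p) {
  stopifnot(ncol(dosages) == length(p))
  if (nrow(dosages) < 2L) stop("at least two individuals are required")
  keep <- p > 0 & p < 1
  if (!any(keep)) stop("no SNP with frequency strictly between 0 and 1")
  d <- dosages[, keep, drop = FALSE]
  pk <- p[keep]
  if (anyNA(d)) {
    warning("missing dosages mean-imputed at 2p before centring; ",
            sum(is.na(d)), " cells affected")
    imp <- matrix(2 * pk, nrow(d), ncol(d), byrow = TRUE)
    d[is.na(d)] <- imp[is.na(d)]
  }
  W <- sweep(d, 2L, 2 * pk)
  denom <- sum(2 * pk * (1 - pk))
  G <- tcrossprod(W) / denom
  ev_min <- min(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  structure(list(G = G, k = scaling_k(G), freqs = pk, denom = denom,
                 n_snps = sum(keep), psd = ev_min > -1e-8 * max(1, abs(ev_min))),
            class = "genomic_relationship")
}

#' Rescaling scalar k of a genomic relationship matrix
#'
#' `k = mean(diag(G)) - mean(G)`: the gap between the average
#' self-relationship and the average relationship, which converts the
#' G-based additive variance parameter to the family's realized additive
#' variance.
#'
#' @param G square symmetric relationship matrix.
#' @return The scalar k.
#' @export
scaling_k <- function(G) {
  if (is.null(dim(G)) || nrow(G) == 0L) stop("G must be a non-empty square matrix")
  stopifnot(nrow(G) == ncol(G))
  mean(diag(G)) - mean(G)
}

#' Write a genomic relationship matrix as plain text with a JSON sidecar
#'
#' @param grm a [vanraden_g()] result.
#' @param path output path for the square matrix (tab-separated, header
#'   row of ids); the sidecar `<path>.json` carries k, the frequency
#'   source and the SNP count.
#' @param freq_source "parental" or "observed".
#' @return `path`, invisibly.
#' @export
write_grm <- function(grm, path, freq_source = "parental") {
  utils::write.table(round(grm$G, 10), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  jsonlite::write_json(
    list(k = grm$k, freq_source = freq_source, n_snps = grm$n_snps, psd = grm$psd),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
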