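## Within-family genotype quality control: sequential call-rate/MAF
## filters, Mendelian-inconsistency screening against the parental cross,
## opposing-homozygote profiling, detection of hidden paternity mixtures,
## and call-rate summaries of imputed genotype probabilities.

#' Quality-control thresholds
#'
#' Thresholds are strict ("less than"), so a value exactly equal to a
#' threshold is retained. MAF is computed from the non-missing calls of
#' retained offspring; within a full-sib family segregating SNPs have
#' expected frequencies 0.25, 0.5 or 0.75, so an observed MAF below 0.15
#' is highly unusual.
#'
#' @param min_ind_callrate individual call-rate threshold.
#' @param min_snp_callrate SNP call-rate threshold.
#' @param min_maf minor-allele-frequency threshold.
#' @param alpha Mendelian chi-square test size, Bonferroni-corrected over
#'   the number of SNPs tested.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_ind_callrate = 0.6, min_snp_callrate = 0.8,
                          min_maf = 0.15, alpha = 0.05) {
  v <- c(min_ind_callrate, min_snp_callrate, min_maf, alpha)
  if (any(v < 0 | v > 1)) stop("all thresholds must lie in [0, 1]")
  structure(list(min_ind_callrate = min_ind_callrate,
                 min_snp_callrate = min_snp_callrate,
                 min_maf = min_maf, alpha = alpha),
            class = "qc_thresholds")
}

#' Sequential genotype quality control
#'
#' Individuals with call rates below `min_ind_callrate` are removed first;
#' SNPs are then filtered on call rate and MAF computed from the retained
#' individuals' non-missing calls. Because removing SNPs can push a
#' borderline individual's call rate (over the retained SNPs) below
#' threshold, the individuals-then-SNPs pass is repeated until nothing
#' more is removed, which makes the operation idempotent.
#'
#' @param geno offspring x SNP dosage matrix with `NA` for missing calls.
#' @param thresholds a [qc_thresholds()].
#' @return List with the filtered `geno`, and removal logs
#'   `removed_individuals` and `removed_snps` (data.frames with the
#'   offending value, reason and filter pass).
#' @export
sequential_qc <- function(geno, thresholds = qc_thresholds()) {
  g <- geno
  rm_ind <- rm_snp <- NULL
  pass <- 0L
  repeat {
    pass <- pass + 1L
    out <- .qc_pass(g, thresholds)
    out$removed_individuals$pass <- rep(pass, nrow(out$removed_individuals))
    out$removed_snps$pass <- rep(pass, nrow(out$removed_snps))
    rm_ind <- rbind(rm_ind, out$removed_individuals)
    rm_snp <- rbind(rm_snp, out$removed_snps)
    stable <- nrow(out$removed_individuals) == 0L && nrow(out$removed_snps) == 0L
    g <- out$geno
    if (stable) break
  }
  list(geno = g, removed_individuals = rm_ind, removed_snps = rm_snp,
       thresholds = thresholds, passes = pass)
}

.qc_pass <- function(geno, thresholds) {
  if (nrow(geno) == 0L || ncol(geno) == 0L) stop("genotype matrix is empty")
  ind_cr <- rowMeans(!is.na(geno))
  drop_ind <- ind_cr < thresholds$min_ind_callrate
  ids <- if (is.null(rownames(geno))) as.character(seq_len(nrow(geno))) else rownames(geno)
  removed_individuals <- data.frame(
    id = ids[drop_ind], call_rate = unname(ind_cr[drop_ind]),
    reason = rep("call_rate", sum(drop_ind)), stringsAsFactors = FALSE
  )
  g <- geno[!drop_ind, , drop = FALSE]
  if (nrow(g) == 0L) stop("all individuals removed by call-rate filter")
  snp_cr <- colMeans(!is.na(g))
  p <- colMeans(g, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0
  low_cr <- snp_cr < thresholds$min_snp_callrate
  low_maf <- maf < thresholds$min_maf
  drop_snp <- low_cr | low_maf
  snp_ids <- if (is.null(colnames(g))) as.character(seq_len(ncol(g))) else colnames(g)
  removed_snps <- data.frame(
    snp_id = snp_ids[drop_snp],
    call_rate = unname(snp_cr[drop_snp]), maf = unname(maf[drop_snp]),
    reason = ifelse(low_cr[drop_snp],
                    ifelse(low_maf[drop_snp], "call_rate+maf", "call_rate"),
                    "maf"),
    stringsAsFactors = FALSE
  )
  g <- g[, !drop_snp, drop = FALSE]
  if (ncol(g) == 0L) stop("all SNPs removed by call-rate/MAF filter")
  list(geno = g, removed_individuals = removed_individuals,
       removed_snps = removed_snps, thresholds = thresholds)
}

#' Mendelian offspring genotype distribution for a cross
#'
#' @param father,mother parental allele dosages (0, 1 or 2) at one SNP.
#' @return Probabilities over offspring allele counts 0, 1, 2.
#' @export
expected_offspring_distribution <- function(father, mother) {
  if (is.na(father) || is.na(mother)) stop("both parental genotypes must be non-missing")
  pf <- father / 2
  pm <- mother / 2
  c(`0` = (1 - pf) * (1 - pm), `1` = pf * (1 - pm) + (1 - pf) * pm, `2` = pf * pm)
}

#' Mendelian chi-square screen of SNPs against the parental cross
#'
#' Observed offspring genotype counts are compared to the expectation
#' conditional on the parental genotypes. A SNP is removed when its
#' chi-square p-value falls below `alpha / M`, with `M` the number of SNPs
#' tested (Bonferroni). Classes with expected count below 1 are pooled
#' into the nearest expected class before the test; degenerate crosses
#' (all expectation in one class) and SNPs with a missing parent are
#' skipped and logged.
#'
#' @param geno offspring x SNP dosage matrix (NAs allowed).
#' @param father,mother parental dosage vectors over the same SNPs.
#' @param alpha nominal test size before Bonferroni correction.
#' @return A `mendel_report` list: per-SNP `table` (chi2, df, p, status)
#'   and the `removed` SNP ids.
#' @export
mendel_chi2_screen <- function(geno, father, mother, alpha = 0.05) {
  L <- ncol(geno)
  stopifnot(length(father) == L, length(mother) == L)
  chi2 <- p <- rep(NA_real_, L)
  df <- rep(NA_integer_, L)
  status <- rep("tested", L)
  for (j in seq_len(L)) {
    if (is.na(father[j]) || is.na(mother[j])) { status[j] <- "missing_parent"; next }
    e <- expected_offspring_distribution(father[j], mother[j])
    obs <- tabulate(geno[, j] + 1L, nbins = 3L)
    n <- sum(obs)
    if (n == 0L) { status[j] <- "no_data"; next }
    if (sum(e > 0) < 2L) { status[j] <- "degenerate_cross"; next }
    E <- e * n
    O <- obs
    # pool low-expectation classes into the nearest class with E >= 1
    while (any(E < 1 & E >= 0) && sum(E >= 1) >= 1L && length(E) > 1L) {
      k <- which(E < 1)[1]
      tgt <- which(E >= 1)
      near <- tgt[which.min(abs(tgt - k))]
      E[near] <- E[near] + E[k]
      O[near] <- O[near] + O[k]
      E <- E[-k]; O <- O[-k]
    }
    if (length(E) < 2L) { status[j] <- "degenerate_cross"; next }
    chi2[j] <- sum((O - E)^2 / E)
    df[j] <- length(E) - 1L
    p[j] <- stats::pchisq(chi2[j], df[j], lower.tail = FALSE)
  }
  M <- sum(status == "tested")
  removed <- !is.na(p) & p < alpha / max(M, 1L)
  tab <- data.frame(snp_id = colnames(geno), chi2 = chi2, df = df, p = p,
                    status = status, removed = removed, stringsAsFactors = FALSE)
  structure(list(table = tab, removed = colnames(geno)[removed],
                 n_tested = M, alpha = alpha),
            class = "mendel_report")
}

#' Opposing-homozygote profile of offspring against their parents
#'
#' A call is incompatible when offspring and a parent are homozygous for
#' different alleles (impossible without genotyping error or wrong
#' parentage). Incompatible calls are set missing in the returned matrix;
#' per-offspring rates are incompatibilities over non-missing
#' offspring-parent comparisons. Parents are treated as reliable (they
#' are genotyped at much greater coverage than offspring).
#'
#' @param geno offspring x SNP dosage matrix.
#' @param father,mother parental dosage vectors.
#' @return List with per-offspring `counts`, `comparisons`, `rate`, and
#'   the `geno` matrix with incompatible calls removed.
#' @export
opposing_homozygote_profile <- function(geno, father, mother) {
  L <- ncol(geno)
  stopifnot(length(father) == L, length(mother) == L)
  fa <- matrix(father, nrow(geno), L, byrow = TRUE)
  mo <- matrix(mother, nrow(geno), L, byrow = TRUE)
  inc <- (!is.na(geno)) & (
    (geno == 0 & ((!is.na(fa) & fa == 2) | (!is.na(mo) & mo == 2))) |
    (geno == 2 & ((!is.na(fa) & fa == 0) | (!is.na(mo) & mo == 0)))
  )
  comp <- (!is.na(geno)) & (!is.na(fa) | !is.na(mo))
  counts <- rowSums(inc)
  comparisons <- rowSums(comp)
  rate <- ifelse(comparisons > 0, counts / comparisons, 0)
  cleaned <- geno
  cleaned[inc] <- NA
  list(counts = counts, comparisons = comparisons, rate = rate, geno = cleaned)
}

#' Detect a hidden paternity mixture from incompatibility rates
#'
#' Two independent reads of the rate distribution must agree for a
#' "mixture" verdict: (i) a meaningful share (at least 5%) of offspring
#' exceed `inflation` times the background genotype error rate, and
#' (ii) 2-means clustering finds two well-separated groups (centre gap
#' large against the within-group spread). When neither sees structure
#' the verdict is "no_mixture"; when they disagree it is "ambiguous".
#' For a mixture the groups are taken from the clustering and the
#' reported `fraction_A` is the majority group's share with its binomial
#' standard error.
#'
#' @param rate per-offspring incompatibility rates.
#' @param background_rate background genotype error rate (default 0.013).
#' @param inflation multiple of the background rate used as threshold.
#' @return A `mixture_call` list: `verdict`, `fraction_A`, `se`,
#'   `group` ("A" majority / "B" minority per offspring), `threshold`.
#' @export
detect_paternity_mixture <- function(rate, background_rate = 0.013, inflation = 3) {
  n <- length(rate)
  if (n < 20L) stop("at least 20 offspring are required")
  thr <- background_rate * inflation
  flagged <- rate > thr
  p_flag <- mean(flagged)
  thr_mix <- p_flag >= 0.05
  km_mix <- FALSE
  km_flag <- flagged
  if (diff(range(rate)) > 1e-12) {
    km <- stats::kmeans(rate, centers = c(min(rate), max(rate)))
    hi <- which.max(km$centers)
    km_flag <- km$cluster == hi
    gap <- abs(diff(as.vector(km$centers)))
    spread <- sqrt(mean(vapply(split(rate, km$cluster), function(x)
      if (length(x) > 1L) stats::var(x) else 0, 0)))
    km_mix <- gap > 4 * spread && min(table(km$cluster)) >= 2L
  }
  if (!thr_mix && !km_mix) {
    frac <- 1 - p_flag
    return(structure(list(verdict = "no_mixture", fraction_A = frac,
                          se = sqrt(frac * (1 - frac) / n),
                          group = ifelse(flagged, "B", "A"),
                          threshold = thr, n = n),
                     class = "mixture_call"))
  }
  if (thr_mix && km_mix) {
    p_min <- mean(km_flag)
    frac <- max(p_min, 1 - p_min)
    grp <- if (p_min <= 0.5) ifelse(km_flag, "B", "A") else ifelse(km_flag, "A", "B")
    return(structure(list(verdict = "mixture", fraction_A = frac,
                          se = sqrt(frac * (1 - frac) / n), group = grp,
                          threshold = thr, n = n),
                     class = "mixture_call"))
  }
  frac <- max(p_flag, 1 - p_flag)
  structure(list(verdict = "ambiguous", fraction_A = frac,
                 se = sqrt(frac * (1 - frac) / n),
                 group = ifelse(flagged, "B", "A"), threshold = thr, n = n),
            class = "mixture_call")
}

#' Call-rate cumulative distribution functions from probability triples
#'
#' A genotype is "called" when its maximum posterior probability exceeds
#' `p`. Returns the CDF of SNP call rates over offspring and of offspring
#' call rates over SNPs, evaluated on a fixed call-rate grid; used to
#' assess imputation quality.
#'
#' @param gp offspring x SNP x 3 array of genotype probabilities.
#' @param p calling threshold in `[0.5, 1]` (below 0.5 the assignment
#'   would not be unique).
#' @param grid call-rate grid on which the CDFs are evaluated.
#' @return List of data.frames `snp` and `offspring` with columns
#'   `call_rate` and `cdf`, plus the per-unit call rates.
#' @export
callrate_cdf <- function(gp, p, grid = seq(0, 1, by = 0.01)) {
  if (p < 0.5 || p > 1) stop("threshold p must lie in [0.5, 1]")
  stopifnot(length(dim(gp)) == 3L, dim(gp)[3] == 3L)
  maxp <- pmax(gp[, , 1], gp[, , 2], gp[, , 3])
  called <- maxp > p
  snp_rate <- colMeans(called)
  off_rate <- rowMeans(called)
  list(
    snp = data.frame(call_rate = grid,
                     cdf = vapply(grid, function(x) mean(snp_rate <= x), 0)),
    offspring = data.frame(call_rate = grid,
                           cdf = vapply(grid, function(x) mean(off_rate <= x), 0)),
    snp_call_rate = snp_rate, offspring_call_rate = off_rate, p = p
  )
}
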