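## Simulation of full-sib families: parents, gametes, offspring genotypes,
## genetic values and genotype missingness. Within a full-sib cross only
## three segregation classes produce polymorphic offspring with expected
## alternative-allele frequencies 0.25, 0.50 or 0.75.

.seg_classes <- c("AaxAa", "Aaxaa", "AAxAa")

.class_parents <- list(
  AaxAa = list(father = c(0L, 1L), mother = c(0L, 1L)),
  Aaxaa = list(father = c(0L, 1L), mother = c(0L, 0L)),
  AAxAa = list(father = c(1L, 1L), mother = c(0L, 1L))
)

#' Simulate parental phased genotypes over a linkage map
#'
#' Each SNP is assigned a segregation class (a pair of parental genotypes
#' that segregates in the offspring) by sampling from `seg_class_probs`.
#' Heterozygous parents get a random phase. Only segregating classes are
#' allowed: `AaxAa` (expected offspring frequency 0.50), `Aaxaa` (0.25) and
#' `AAxAa` (0.75); reversed crosses are equivalent by relabelling alleles.
#'
#' @param map a [linkage_map()].
#' @param seg_class_probs named numeric vector of probabilities over the
#'   classes `c("AaxAa", "Aaxaa", "AAxAa")`; must sum to 1.
#' @param seed integer seed.
#' @return A `parent_genotypes` list with phased allele matrices `father`
#'   and `mother` (loci x 2 haplotypes, alleles coded 0/1), the per-locus
#'   `class`, and the `map`.
#' @export
simulate_parent_genotypes <- function(map,
                                      seg_class_probs = c(AaxAa = 0.15, Aaxaa = 0.425, AAxAa = 0.425),
                                      seed = 1L) {
  if (!inherits(map, "linkage_map") || nrow(map) == 0L)
    stop("'map' must be a non-empty linkage_map")
  if (is.null(names(seg_class_probs)) || !all(names(seg_class_probs) %in% .seg_classes))
    stop("segregation class probabilities must be named with segregating classes: ",
         paste(.seg_classes, collapse = ", "))
  if (any(seg_class_probs < 0) || abs(sum(seg_class_probs) - 1) > 1e-8)
    stop("segregation class probabilities must be non-negative and sum to 1")
  L <- nrow(map)
  rng <- local_rng(seed)
  cls <- sample(names(seg_class_probs), L, replace = TRUE, prob = seg_class_probs)
  father <- matrix(0L, L, 2L)
  mother <- matrix(0L, L, 2L)
  for (k in seq_len(L)) {
    pg <- .class_parents[[cls[k]]]
    f <- pg$father
    m <- pg$mother
    if (f[1] != f[2] && runif(1) < 0.5) f <- rev(f)
    if (m[1] != m[2] && runif(1) < 0.5) m <- rev(m)
    father[k, ] <- f
    mother[k, ] <- m
  }
  rownames(father) <- rownames(mother) <- map$snp_id
  structure(list(father = father, mother = mother, class = cls, map = map),
            class = "parent_genotypes")
}

# Functions that take a `seed` argument seed the global RNG here (a NULL
# seed continues the current stream, so composite simulators can hand out
# sub-tasks deterministically from one top-level seed).
local_rng <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Simulate gametes from a phased parent
#'
#' Crossovers follow the Haldane model: the recombination fraction between
#' adjacent loci at map distance d cM is (1 - exp(-2 d / 100)) / 2, with
#' independent recombination events across intervals and free recombination
#' across linkage groups. Loci at identical positions are always
#' co-inherited.
#'
#' @param parent phased allele matrix (loci x 2) as in
#'   [simulate_parent_genotypes()].
#' @param map the [linkage_map()] the parent is phased over.
#' @param n number of gametes.
#' @param seed integer seed (or NULL to use the current RNG state).
#' @return An integer matrix (loci x n) of transmitted alleles (0/1).
#' @export
simulate_gametes <- function(parent, map, n = 1L, seed = NULL) {
  stopifnot(nrow(parent) == nrow(map))
  local_rng(seed)
  L <- nrow(map)
  hap <- matrix(0L, L, n)
  for (g in unique(map$group)) {
    idx <- which(map$group == g)
    d <- diff(map$pos_cM[idx])
    r <- 0.5 * (1 - exp(-2 * d / 100))
    # switch indicator between adjacent loci; start haplotype chosen fairly
    start <- matrix(rep(stats::rbinom(n, 1L, 0.5), each = 1L), 1L, n)
    if (length(idx) > 1L) {
      sw <- matrix(stats::rbinom(length(r) * n, 1L, rep(r, n)), length(r), n)
      cur <- (apply(rbind(start, sw), 2L, cumsum)) %% 2L
    } else {
      cur <- start
    }
    hap[idx, ] <- matrix(parent[cbind(rep(idx, n), as.vector(cur) + 1L)], length(idx), n)
  }
  rownames(hap) <- map$snp_id
  hap
}

#' Family configuration
#'
#' @param n_offspring number of offspring genotypes (clonal ortets).
#' @param n_genotyped size of the genotyped subset.
#' @param q proportion of offspring sired by father A; `q = 1` is a pure
#'   full-sib family, `q < 1` a hidden mixture of two maternal half-sib
#'   families (a second father must then be supplied to
#'   [simulate_family()]).
#' @param family_id label.
#' @param seed integer seed.
#' @return A `family_config` list.
#' @export
family_config <- function(n_offspring = 1500L, n_genotyped = 500L, q = 1,
                          family_id = "SF1", seed = 1L) {
  if (!(q > 0 && q <= 1)) stop("mixture proportion q must lie in (0, 1]")
  if (n_genotyped > n_offspring) stop("n_genotyped must not exceed n_offspring")
  structure(list(n_offspring = as.integer(n_offspring),
                 n_genotyped = as.integer(n_genotyped),
                 q = q, family_id = family_id, seed = as.integer(seed)),
            class = "family_config")
}

#' Simulate a (possibly mixed) full-sib family
#'
#' Offspring genotypes are formed from parental gametes. When `fcfg$q < 1`
#' each offspring is sired by father A with probability q and by father B
#' otherwise; the paternity labels are retained as hidden truth. A random
#' subset of offspring is flagged as genotyped.
#'
#' @param fcfg a [family_config()].
#' @param parents a [simulate_parent_genotypes()] result (father A and
#'   mother).
#' @param father_b optional second `parent_genotypes` whose `father` sires
#'   the minority subfamily; required when `q < 1`.
#' @return A `sim_family` list: `geno` (offspring x SNP dosage matrix,
#'   0/1/2), `father` (A/B per offspring), `genotyped` (logical),
#'   `parents`, `father_b`, `config`, `map`.
#' @export
simulate_family <- function(fcfg, parents, father_b = NULL) {
  stopifnot(inherits(fcfg, "family_config"), inherits(parents, "parent_genotypes"))
  if (fcfg$q < 1 && is.null(father_b))
    stop("a second father's genotypes must be supplied when q < 1")
  map <- parents$map
  n <- fcfg$n_offspring
  rng <- local_rng(fcfg$seed)
  pat <- if (fcfg$q < 1) ifelse(runif(n) < fcfg$q, "A", "B") else rep("A", n)
  gm <- simulate_gametes(parents$mother, map, n)
  gf <- matrix(0L, nrow(map), n)
  if (any(pat == "A"))
    gf[, pat == "A"] <- simulate_gametes(parents$father, map, sum(pat == "A"))
  if (any(pat == "B"))
    gf[, pat == "B"] <- simulate_gametes(father_b$father, map, sum(pat == "B"))
  geno <- t(gm + gf)
  ids <- sprintf("%s_%04d", fcfg$family_id, seq_len(n))
  rownames(geno) <- ids
  colnames(geno) <- map$snp_id
  genotyped <- logical(n)
  genotyped[sample.int(n, fcfg$n_genotyped)] <- TRUE
  structure(list(geno = geno, father = pat, genotyped = genotyped,
                 parents = parents, father_b = father_b,
                 config = fcfg, map = map),
            class = "sim_family")
}

#' Genetic architecture configuration
#'
#' Targets for the within-family total genetic variance and its additive
#' fraction among offspring, and the number of causal loci.
#'
#' @param sigma_u2 within-family total genetic variance (> 0).
#' @param r_a additive fraction of `sigma_u2` in `[0, 1]`.
#' @param n_causal_add,n_causal_dom numbers of causal loci for the additive
#'   and dominance components (dominance loci used only when `r_a < 1`).
#' @param effect_sd standard deviation of raw (pre-rescaling) effects.
#' @return An `architecture_config` list.
#' @export
architecture_config <- function(sigma_u2 = 1, r_a = 0.75,
                                n_causal_add = 200L, n_causal_dom = 200L,
                                effect_sd = 1) {
  if (!is.finite(sigma_u2) || sigma_u2 <= 0) stop("sigma_u2 must be positive")
  if (!is.finite(r_a) || r_a < 0 || r_a > 1) stop("r_a must lie in [0, 1]")
  if (n_causal_add < 1L) stop("at least one additive causal locus is required")
  structure(list(sigma_u2 = sigma_u2, r_a = r_a,
                 n_causal_add = as.integer(n_causal_add),
                 n_causal_dom = as.integer(n_causal_dom),
                 effect_sd = effect_sd),
            class = "architecture_config")
}

#' Assign total genetic values with known additive/non-additive truth
#'
#' Additive values are linear in centred allele dosages at sampled causal
#' loci. Non-additive (dominance-type) values are linear in centred
#' heterozygosity indicators at loci segregating in three genotype
#' classes (both parents heterozygous): within a full-sib family these
#' are the only loci carrying dominance variance — with two genotype
#' classes any genotype effect is re-expressible as additive — and there
#' the centred heterozygosity is uncorrelated with the locus dosage. The
#' dominance part is additionally orthogonalized against the realized
#' additive vector, and both parts are rescaled so their variances across
#' offspring equal `r_a * sigma_u2` and `(1 - r_a) * sigma_u2` exactly.
#'
#' @param geno offspring x SNP dosage matrix (0/1/2).
#' @param arch an [architecture_config()].
#' @param seed integer seed.
#' @return List with `u` (total genetic value per offspring), `u_a`, `u_d`,
#'   and the sampled causal locus indices.
#' @export
assign_genetic_values <- function(geno, arch, seed = 1L) {
  stopifnot(inherits(arch, "architecture_config"))
  L <- ncol(geno)
  if (arch$n_causal_add > L || (arch$r_a < 1 && arch$n_causal_dom > L))
    stop("causal loci must be a subset of simulated loci")
  rng <- local_rng(seed)
  seg <- which(apply(geno, 2L, stats::var) > 0)
  if (length(seg) < arch$n_causal_add) stop("not enough segregating loci for the additive component")
  ca <- sample(seg, arch$n_causal_add)
  alpha <- stats::rnorm(length(ca), 0, arch$effect_sd)
  u_a <- drop(scale(geno[, ca, drop = FALSE], scale = FALSE) %*% alpha)
  v_a <- stats::var(u_a)
  if (v_a <= 0) stop("degenerate additive values; increase causal loci")
  u_a <- u_a * sqrt(arch$r_a * arch$sigma_u2 / v_a)
  if (arch$r_a < 1) {
    three_class <- which(apply(geno, 2L, function(g) length(unique(g[!is.na(g)]))) == 3L)
    if (length(three_class) == 0L)
      stop("no three-genotype-class loci available for the dominance component")
    cd <- sample(three_class, min(arch$n_causal_dom, length(three_class)))
    het <- (geno[, cd, drop = FALSE] == 1) * 1
    delta <- stats::rnorm(length(cd), 0, arch$effect_sd)
    u_d <- drop(scale(het, scale = FALSE) %*% delta)
    if (arch$r_a > 0 && stats::var(u_a) > 0)   # orthogonalize so the variance split is exact
      u_d <- u_d - u_a * (stats::cov(u_d, u_a) / stats::var(u_a))
    v_d <- stats::var(u_d)
    if (v_d <= 0) stop("degenerate dominance values; increase causal loci")
    u_d <- u_d * sqrt((1 - arch$r_a) * arch$sigma_u2 / v_d)
  } else {
    cd <- integer(0)
    u_d <- numeric(nrow(geno))
  }
  u <- u_a + u_d
  names(u) <- names(u_a) <- names(u_d) <- rownames(geno)
  list(u = u, u_a = u_a, u_d = u_d, causal_add = ca, causal_dom = cd)
}

#' Apply genotype missingness and optional genotype-probability triples
#'
#' Each call is retained independently with probability
#' `snp_callrate[j] * ind_callrate[i]`; masked calls become `NA`. When
#' `gp = TRUE`, posterior genotype-probability triples are generated that
#' place most mass on the true genotype with probability
#' `1 - posterior_error` and on a wrong genotype otherwise; masked calls
#' get uninformative (1/3, 1/3, 1/3) triples.
#'
#' @param geno offspring x SNP dosage matrix.
#' @param snp_callrate per-SNP call rates (scalar or vector, recycled).
#' @param ind_callrate per-individual call rates (scalar or vector).
#' @param posterior_error probability that the argmax of a generated
#'   probability triple is not the true genotype.
#' @param gp logical; also return probability triples.
#' @param p_max posterior mass placed on the called genotype.
#' @param seed integer seed.
#' @return List with `geno` (with NAs) and, if requested, `gp`
#'   (offspring x SNP x 3 array of probabilities for allele counts 0/1/2).
#' @export
apply_genotype_missingness <- function(geno, snp_callrate = 0.79, ind_callrate = 1,
                                       posterior_error = 0, gp = FALSE,
                                       p_max = 0.97, seed = 1L) {
  if (any(snp_callrate < 0 | snp_callrate > 1) || any(ind_callrate < 0 | ind_callrate > 1))
    stop("call rates must lie in [0, 1]")
  n <- nrow(geno); L <- ncol(geno)
  rng <- local_rng(seed)
  keep_p <- outer(rep_len(ind_callrate, n), rep_len(snp_callrate, L))
  keep <- matrix(runif(n * L) < keep_p, n, L)
  out <- geno
  out[!keep] <- NA
  res <- list(geno = out)
  if (gp) {
    called <- geno
    if (posterior_error > 0) {
      wrong <- matrix(runif(n * L) < posterior_error, n, L)
      shift <- matrix(sample(1:2, n * L, replace = TRUE), n, L)
      called[wrong] <- (geno[wrong] + shift[wrong]) %% 3L
    }
    gp_arr <- array((1 - p_max) / 2, dim = c(n, L, 3L),
                    dimnames = list(rownames(geno), colnames(geno), c("0", "1", "2")))
    for (k in 0:2) {
      sel <- which(called == k)
      if (length(sel))
        gp_arr[cbind(arrayInd(sel, dim(geno)), k + 1L)] <- p_max
    }
    miss <- which(!keep)
    if (length(miss))
      for (k in 1:3) gp_arr[cbind(arrayInd(miss, dim(geno)), k)] <- 1 / 3
    res$gp <- gp_arr
  }
  res
}
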