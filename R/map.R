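#' Linkage map specification
#'
#' Builds a linkage map over one or more linkage groups with loci placed at
#' stated centimorgan positions. Used by the gamete simulator, which drops
#' crossovers as a Poisson process at 1 Morgan per 100 cM (Haldane model,
#' no interference), independently across groups.
#'
#' @param lengths_cM numeric vector of group lengths in centimorgans; names
#'   are used as group identifiers (defaults to `LG1`, `LG2`, ...).
#' @param n_loci integer vector (recycled) giving the number of loci per
#'   group. Loci are placed at evenly spaced interior positions.
#' @param positions optional list of numeric vectors of explicit positions
#'   per group, overriding `n_loci`.
#' @param prefix character prefix for locus identifiers.
#' @return A `linkage_map` object: a data.frame with columns `group`,
#'   `pos_cM`, `snp_id`, and attribute `lengths_cM`.
#' @export
linkage_map <- function(lengths_cM, n_loci, positions = NULL, prefix = "SNP") {
  if (length(lengths_cM) == 0L) stop("linkage map must contain at least one group")
  if (any(!is.finite(lengths_cM)) || any(lengths_cM <= 0))
    stop("group lengths must be positive and finite")
  if (is.null(names(lengths_cM)))
    names(lengths_cM) <- paste0("LG", seq_along(lengths_cM))
  ng <- length(lengths_cM)
  if (is.null(positions)) {
    n_loci <- rep_len(as.integer(n_loci), ng)
    positions <- lapply(seq_len(ng), function(g) {
      n <- n_loci[g]
      if (n < 1L) stop("each group must carry at least one locus")
      seq(0, lengths_cM[g], length.out = n + 2L)[seq(2L, n + 1L)]
    })
  }
  stopifnot(length(positions) == ng)
  for (g in seq_len(ng)) {
    p <- positions[[g]]
    if (is.unsorted(p)) stop("locus positions within a group must be non-decreasing")
    if (any(p < 0) || any(p > lengths_cM[g]))
      stop("locus positions must lie within [0, group length]")
  }
  map <- data.frame(
    group = rep(names(lengths_cM), vapply(positions, length, 1L)),
    pos_cM = unlist(positions, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  map$snp_id <- sprintf("%s_%05d", prefix, seq_len(nrow(map)))
  attr(map, "lengths_cM") <- lengths_cM
  class(map) <- c("linkage_map", "data.frame")
  map
}

#' Default spruce-like linkage map
#'
#' A 12-group map of 1630 mapped biallelic SNPs spanning about 2143 cM,
#' with per-group lengths and SNP counts matching the marker panel the
#' package's simulated study design emulates.
#'
#' @param scale optional fraction in (0, 1] used to thin the number of loci
#'   per group (map length is kept); handy for fast tests.
#' @return A [linkage_map()] object.
#' @export
spruce_map <- function(scale = 1) {
  lengths <- c(218, 194, 201, 194, 165, 174, 203, 199, 164, 157, 128, 146)
  nsnp <- c(159, 163, 153, 146, 109, 139, 149, 129, 125, 129, 108, 121)
  stopifnot(scale > 0, scale <= 1)
  n <- pmax(2L, as.integer(round(nsnp * scale)))
  linkage_map(stats::setNames(lengths, paste0("LG", 1:12)), n)
}

#' Write or read a linkage map as TSV
#' @param map a [linkage_map()] object.
#' @param path file path.
#' @return `write_map_tsv` returns `path` invisibly; `read_map_tsv` returns
#'   a `linkage_map`.
#' @export
write_map_tsv <- function(map, path) {
  utils::write.table(
    data.frame(group = map$group, cM = map$pos_cM, snp_id = map$snp_id),
    path, sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_map_tsv
#' @export
read_map_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  lengths <- tapply(d$cM, d$group, max)
  # group length is not stored in the TSV; take the furthest locus
  m <- data.frame(group = d$group, pos_cM = d$cM, snp_id = d$snp_id,
                  stringsAsFactors = FALSE)
  attr(m, "lengths_cM") <- lengths[unique(d$group)]
  class(m) <- c("linkage_map", "data.frame")
  m
}
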