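## Plain-file interfaces: VCF genotypes (GT, optional DS dosages and GP
## probability triples), TSV phenotype/layout tables, YAML configs.

#' Write genotypes to VCF
#'
#' Loci are placed on their linkage groups with positions derived from
#' map centimorgans (1 cM = 100 units). Genotype calls are written as GT
#' (missing as `./.`), with optional DS (dosage) and GP (probability
#' triple) fields.
#'
#' @param geno individuals x SNP dosage matrix (0/1/2, NA missing).
#' @param map a [linkage_map()] covering the columns of `geno`.
#' @param path output path; vcfR appends nothing, pass e.g. `"x.vcf.gz"`.
#' @param ds optional individuals x SNP numeric dosage matrix.
#' @param gp optional individuals x SNP x 3 probability array.
#' @return `path`, invisibly.
#' @importClassesFrom vcfR vcfR
#' @export
write_genotypes_vcf <- function(geno, map, path, ds = NULL, gp = NULL) {
  stopifnot(ncol(geno) == nrow(map))
  L <- nrow(map); n <- nrow(geno)
  fix <- cbind(
    CHROM = map$group,
    POS = as.character(round(map$pos_cM * 100) + 1L),
    ID = map$snp_id, REF = "A", ALT = "C",
    QUAL = ".", FILTER = "PASS", INFO = "."
  )
  gt_code <- c("0/0", "0/1", "1/1")
  fmt <- "GT"
  cell <- matrix(gt_code[t(geno) + 1L], L, n)
  cell[is.na(cell)] <- "./."
  if (!is.null(ds)) {
    fmt <- paste0(fmt, ":DS")
    cell <- matrix(paste(cell, sprintf("%.4f", t(ds)), sep = ":"), L, n)
  }
  if (!is.null(gp)) {
    fmt <- paste0(fmt, ":GP")
    gpt <- apply(gp, 1L, function(m) sprintf("%.4f,%.4f,%.4f", m[, 1], m[, 2], m[, 3]))
    cell <- matrix(paste(cell, gpt, sep = ":"), L, n)
  }
  gt <- cbind(FORMAT = fmt, cell)
  colnames(gt) <- c("FORMAT", rownames(geno))
  v <- methods::new("vcfR",
           meta = c("##fileformat=VCFv4.2",
                    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
                    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage\">",
                    "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">"),
           fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read genotypes from VCF
#'
#' @param path VCF path (plain or gzipped).
#' @return List with `geno` (individuals x SNP integer dosages from GT),
#'   `ds` (numeric dosages, if present), `gp` (probability array, if
#'   present), `snp_id`, `chrom`, `pos`.
#' @export
read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  code <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0L
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  code[gt %in% c("1/1", "1|1")] <- 2L
  out <- list(geno = t(code), snp_id = vcfR::getID(v),
              chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v))
  fmt <- v@gt[1, "FORMAT"]
  if (grepl("DS", fmt)) {
    ds <- vcfR::extract.gt(v, element = "DS", as.numeric = TRUE)
    out$ds <- t(ds)
  }
  if (grepl("GP", fmt)) {
    gpc <- t(vcfR::extract.gt(v, element = "GP"))
    arr <- array(NA_real_, c(nrow(gpc), ncol(gpc), 3L),
                 dimnames = list(rownames(gpc), colnames(gpc), c("0", "1", "2")))
    sp <- strsplit(gpc, ",")
    vals <- matrix(as.numeric(unlist(sp)), ncol = 3L, byrow = TRUE)
    for (k in 1:3) arr[, , k] <- matrix(vals[, k], nrow(gpc), ncol(gpc))
    out$gp <- arr
  }
  out
}

#' Write or read a trial phenotype/layout table as TSV
#'
#' Columns: `tree_id`, `genotype_id`, `site`, `block`, `master_block`,
#' `column`, `row`, `trait`, `value`.
#'
#' @param trial a `trial_frame`.
#' @param path file path.
#' @return `write_trial_tsv` returns `path` invisibly; `read_trial_tsv`
#'   a `trial_frame`.
#' @export
write_trial_tsv <- function(trial, path) {
  utils::write.table(as.data.frame(trial), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trial_tsv
#' @export
read_trial_tsv <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = c("NA", ""))
  class(d) <- c("trial_frame", "data.frame")
  d
}
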