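## End-to-end orchestration: simulate -> qc -> grm -> fit -> profile ->
## pool -> report, driven by a single serializable config with one seed
## hierarchy (stage seeds are derived deterministically from the run
## seed, so stages are independently reproducible).

#' Default run configuration
#'
#' A compact demonstration study: one pure full-sib family of 200
#' offspring clonally replicated over 4 blocks (one ramet each, as in the
#' emulated trial design) of a 12 x 20 grid at one site, a thinned
#' linkage map, and the default genetic architecture (additive fraction
#' 0.75 of a unit total genetic variance). All fields can be overridden;
#' the config round-trips through YAML.
#'
#' @return A nested configuration list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    map = list(scale = 0.25),
    families = list(
      list(family_id = "F1", n_offspring = 200L, n_genotyped = 200L, q = 1.0)
    ),
    architecture = list(sigma_u2 = 1, r_a = 0.75,
                        n_causal_add = 100L, n_causal_dom = 100L),
    sites = list(
      list(site = "S1", n_blocks = 4L, block_ncol = 12L, block_nrow = 20L,
           n_master = 1L)
    ),
    noise = list(sigma_v2 = 0.15, sigma_r2 = 1.26, sigma_s2 = 0.54,
                 rho_c = 0.8, rho_r = 0.8),
    missingness = list(snp_callrate = 1, posterior_error = 0, gp = FALSE),
    qc = list(min_ind_callrate = 0.6, min_snp_callrate = 0.8,
              min_maf = 0.15, alpha = 0.05),
    fit = list(maxit = 200L, n_starts = 1L),
    profile = list(grid = "adaptive"),
    background_error_rate = 0.013
  )
}

.validate_config <- function(cfg) {
  need <- c("seed", "map", "families", "architecture", "sites", "noise",
            "qc", "fit", "profile")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) stop("config is missing blocks: ", paste(miss, collapse = ", "))
  for (f in cfg$families)
    if (!(f$q > 0 && f$q <= 1)) stop("family mixture proportion q must lie in (0, 1]")
  invisible(TRUE)
}

.stage_seed <- function(seed, stage, index = 0L) {
  # deterministic substream per (stage, index); arithmetic in double to
  # avoid 32-bit overflow, result kept below 2^31
  s <- as.numeric(seed) * 1009 + match(stage, c("parents", "family", "values",
    "trial", "missing", "fit")) * 101 + as.numeric(index)
  as.integer(s %% 2147483647)
}

#' Simulate a study: families, genetic values and trials at every site
#'
#' @param cfg a configuration as from [default_config()].
#' @return List with `map`, per-family `families` (simulated genotypes,
#'   genetic values, parents) and `trials` (one `trial_frame` per
#'   family x site).
#' @export
simulate_study <- function(cfg = default_config()) {
  .validate_config(cfg)
  map <- spruce_map(scale = cfg$map$scale)
  noise <- do.call(noise_config, cfg$noise)
  families <- list()
  trials <- list()
  for (fi in seq_along(cfg$families)) {
    fc <- cfg$families[[fi]]
    parents <- simulate_parent_genotypes(map, seed = .stage_seed(cfg$seed, "parents", fi))
    father_b <- if (fc$q < 1)
      simulate_parent_genotypes(map, seed = .stage_seed(cfg$seed, "parents", fi + 100L))
    else NULL
    fcfg <- family_config(fc$n_offspring, fc$n_genotyped, fc$q, fc$family_id,
                          seed = .stage_seed(cfg$seed, "family", fi))
    fam <- simulate_family(fcfg, parents, father_b)
    arch <- do.call(architecture_config, cfg$architecture)
    vals <- assign_genetic_values(fam$geno, arch,
                                  seed = .stage_seed(cfg$seed, "values", fi))
    families[[fc$family_id]] <- list(family = fam, values = vals, arch = arch)
    for (si in seq_along(cfg$sites)) {
      sc <- cfg$sites[[si]]
      lay <- trial_layout(fc$n_offspring, sc$n_blocks, sc$block_ncol,
                          sc$block_nrow, sc$n_master, sc$site)
      tr <- simulate_trial(lay, vals$u, noise,
                           seed = .stage_seed(cfg$seed, "trial", fi * 100L + si))
      trials[[paste(fc$family_id, sc$site, sep = ".")]] <-
        list(trial = tr, family_id = fc$family_id, site = sc$site)
    }
  }
  list(map = map, families = families, trials = trials, config = cfg)
}

#' Run the full analysis pipeline on a configuration
#'
#' Executes simulate -> genotype QC -> genomic relationship -> REML fits
#' (model 2) -> likelihood profiles -> pooling, writes every intermediate
#' under `out_dir` with checksums, and returns the results with a run
#' manifest. A family configured with `q < 1` exercises the hidden
#' half-sib-mixture branch: observed allele frequencies are used for its
#' G and the fitted fractions are rescaled to the full-sib scale.
#'
#' @param cfg configuration list or path to a YAML file.
#' @param out_dir output directory (created; defaults to a tempdir).
#' @return List with `study`, `qc`, `grm`, `fits`, `profiles`, `pooled`,
#'   per-family `f_a` summaries, and `manifest`.
#' @export
run_pipeline <- function(cfg = default_config(), out_dir = tempfile("clonepart_run")) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  .validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  message("stage simulate: ", length(cfg$families), " family(ies), ",
          length(cfg$sites), " site(s)")
  study <- simulate_study(cfg)
  artifacts <- character(0)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  artifacts <- c(artifacts, cfg_path)

  qc_out <- list(); grm_out <- list()
  for (fid in names(study$families)) {
    fam <- study$families[[fid]]$family
    message("stage qc: family ", fid)
    gsub_ids <- rownames(fam$geno)[fam$genotyped]
    g <- fam$geno[gsub_ids, , drop = FALSE]
    miss <- do.call(apply_genotype_missingness,
                    c(list(geno = g), cfg$missingness,
                      list(seed = .stage_seed(cfg$seed, "missing",
                                              match(fid, names(study$families))))))
    sq <- sequential_qc(miss$geno, do.call(qc_thresholds, cfg$qc))
    father_d <- rowSums(fam$parents$father)
    mother_d <- rowSums(fam$parents$mother)
    keep_snp <- colnames(sq$geno)
    fa_d <- father_d[keep_snp]; mo_d <- mother_d[keep_snp]
    mend <- mendel_chi2_screen(sq$geno, fa_d, mo_d, alpha = cfg$qc$alpha)
    g2 <- sq$geno[, setdiff(colnames(sq$geno), mend$removed), drop = FALSE]
    oh <- opposing_homozygote_profile(g2, fa_d[colnames(g2)], mo_d[colnames(g2)])
    mix <- detect_paternity_mixture(oh$rate,
                                    background_rate = cfg$background_error_rate)
    qc_out[[fid]] <- list(sequential = sq, mendel = mend, opposing = oh, mixture = mix)
    qc_path <- file.path(out_dir, paste0("qc_", fid, ".json"))
    jsonlite::write_json(
      list(removed_individuals = sq$removed_individuals,
           removed_snps = sq$removed_snps$snp_id,
           mendel_removed = mend$removed,
           mixture = list(verdict = mix$verdict, fraction_A = mix$fraction_A,
                          se = mix$se)),
      qc_path, auto_unbox = TRUE, digits = NA)
    artifacts <- c(artifacts, qc_path)

    message("stage grm: family ", fid)
    d <- oh$geno
    is_mixture <- mix$verdict == "mixture"
    if (is_mixture) {
      p <- colMeans(d, na.rm = TRUE) / 2
      keep <- p > 0 & p < 1
      grm <- suppressWarnings(vanraden_g(d[, keep, drop = FALSE], p[keep]))
      freq_source <- "observed"
    } else {
      pf <- parental_allele_frequencies(fa_d[colnames(d)], mo_d[colnames(d)])
      grm <- suppressWarnings(vanraden_g(d[, pf$keep, drop = FALSE], pf$p))
      freq_source <- "parental"
    }
    grm_out[[fid]] <- list(grm = grm, freq_source = freq_source,
                           mixture = is_mixture)
    gpath <- file.path(out_dir, paste0("grm_", fid, ".tsv"))
    write_grm(grm, gpath, freq_source)
    artifacts <- c(artifacts, gpath, paste0(gpath, ".json"))
  }

  fits <- list(); profiles <- list()
  for (tn in names(study$trials)) {
    tr <- study$trials[[tn]]
    message("stage fit: trial ", tn)
    td <- trial_data(tr$trial, grm_out[[tr$family_id]]$grm)
    fit <- fit_clonal_model(td, model = 2L, n_starts = cfg$fit$n_starts,
                            control = list(maxit = cfg$fit$maxit, se = FALSE,
                                           seed = .stage_seed(cfg$seed, "fit",
                                                              match(tn, names(study$trials)))))
    fits[[tn]] <- fit
    message("stage profile: trial ", tn, " (logL ", round(fit$logL, 2), ")")
    prof <- profile_additive_fraction(td, fit, grid = cfg$profile$grid, label = tn,
                                      control = list(maxit = 60L, bfgs_maxit = 20L))
    profiles[[tn]] <- prof
    ppath <- file.path(out_dir, paste0("profile_", tn, ".tsv"))
    utils::write.table(prof$profile, ppath, sep = "\t", quote = FALSE, row.names = FALSE)
    artifacts <- c(artifacts, ppath)
  }

  message("stage pool: ", length(profiles), " profile(s)")
  pooled <- pool_profiles(profiles)
  fa_by_family <- list()
  for (fid in names(study$families)) {
    sel <- vapply(study$trials, function(x) x$family_id == fid, TRUE)
    pf <- pool_profiles(profiles[sel])
    r_a <- pf$estimate
    if (grm_out[[fid]]$mixture) {
      mixfrac <- max(qc_out[[fid]]$mixture$fraction_A, 0.501)
      cc <- mixture_correction_coefficients(mixfrac)
      fa <- unname(correct_mixture_fractions(r_a, cc)["f_a"])
      ci <- vapply(pf$ci, function(x) unname(correct_mixture_fractions(x, cc)["f_a"]), 0)
    } else {
      fa <- r_a
      ci <- pf$ci
    }
    fa_by_family[[fid]] <- list(r_a = r_a, f_a = fa, ci = ci,
                                corrected = grm_out[[fid]]$mixture)
  }
  res_path <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(consensus_r_a = pooled$estimate, ci = pooled$ci,
         heterogeneity = list(X2 = pooled$X2, df = pooled$df),
         f_a_by_family = fa_by_family),
    res_path, auto_unbox = TRUE, digits = NA)
  artifacts <- c(artifacts, res_path)
  manifest <- data.frame(path = artifacts,
                         md5 = unname(tools::md5sum(artifacts)),
                         stringsAsFactors = FALSE)
  mpath <- file.path(out_dir, "manifest.tsv")
  utils::write.table(manifest, mpath, sep = "\t", quote = FALSE, row.names = FALSE)
  message("pipeline complete in ",
          round(as.numeric(difftime(Sys.time(), t0, units = "secs")), 1), " s")
  list(study = study, qc = qc_out, grm = grm_out, fits = fits,
       profiles = profiles, pooled = pooled, f_a_by_family = fa_by_family,
       manifest = manifest, out_dir = out_dir)
}
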