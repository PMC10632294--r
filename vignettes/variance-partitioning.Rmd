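---
title: "Partitioning additive and non-additive genetic variance in clonal trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning additive and non-additive genetic variance in clonal trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonepart)
```

## The problem

Clonal replication separates genetic from environmental variation: ramets of
the same ortet share their entire genotype, so the between-clone variance in
a well-designed field trial estimates the *total* genetic variance
$\sigma_u^2$. Marker data add a second lever. A genomic relationship matrix
$G$ built from SNP dosages describes only what an additive model over loci
can describe, so a variance component attached to $G$ captures additive
variance, while the remainder of the clone-level variance is non-additive
(dominance and epistasis, not separated further here). `clonepart`
implements this partition for large full-sib families of a conifer breeding
programme, where only a subset of each family is genotyped, trials sit on
spatially structured ground, and one family may secretly be a mixture of two
maternal half-sib families.

Within a full-sib family the quantity estimated is the partition of the
Mendelian sampling variance: the additive fraction
$f_a = k\sigma_a^2 / \sigma_u^2$ and its complement $f_d$.

## Models

**Model 1 (no genomics).** For one trial (a site-by-family combination),

$$ y = Xb + Z_u u + Z_v v + e, \qquad u \sim N(0, \sigma_u^2 I),\quad
v \sim N(0, \sigma_v^2 I), $$

with $v$ the replicate-block effects and a residual covariance

$$ R = \sigma_r^2 I + \sigma_s^2 \bigoplus_k \Sigma_c(\rho_c) \otimes
\Sigma_r(\rho_r), $$

a separable first-order autoregressive field over grid columns and rows,
block-diagonal over "master blocks" (spatially contiguous grids), with the
same four spatial parameters shared by all master blocks of a trial. The
fractions $f_r = \sigma_r^2 / (\sigma_r^2 + \sigma_s^2)$ and $f_s = 1 - f_r$
summarize the nugget/spatial split.

**Model 2 (genotyped/ungenotyped split).** The genetic effects are split
into ungenotyped trees $u_1 \sim N(0, \sigma_u^2 I)$ and genotyped trees
$u_2 = u_{2(a)} + u_{2(d)}$ with

$$ \operatorname{var}(u_{2(a)}) = \sigma_u^2\, r_a\, G / k, \qquad
\operatorname{var}(u_{2(d)}) = \sigma_u^2 (1 - r_a) I, $$

where $k = \overline{\operatorname{diag}(G)} - \overline{G}$ rescales the
$G$-based variance to the family's realized additive variance. This
parameterization *builds in* the constraint $\sigma_u^2 = k\sigma_a^2 +
\sigma_d^2$: ungenotyped and genotyped trees are forced to share one total
genetic variance and $r_a \in [0,1]$ is the additive fraction. Phenotypes of
ungenotyped trees still contribute to every variance component, which
matters both for power and for keeping the spatial grid continuous.

$G$ follows VanRaden's method 1, $G = WW' / \sum_i 2p_i(1-p_i)$ with dosages
centred at $2p_i$. For a pure full-sib family the $p_i$ come from the two
parents (so $p_i \in \{0.25, 0.5, 0.75\}$ at segregating loci); for a family
detected as a mixture, observed offspring frequencies are used. A
consequence of family-internal centring worth stating: the single-locus
covariance between sibs' centred dosages is zero (gametes are independent
draws), so the mean off-diagonal of $G$ is near zero and $k$ is essentially
the mean diagonal, around 0.67–0.73 for realistic within-family
segregation-class mixes.

## REML, likelihood evaluation and inference

The restricted likelihood is maximized over transformed parameters: log
variances, $\operatorname{atanh}$ autocorrelations, logit $r_a$. Two
evaluation paths exist and agree to $10^{-8}$ (tested): a dense path valid
for any layout, and a structured path used when every master block is a
completely observed rectangle, which combines the Kronecker
eigen-decomposition of the AR1 correlation matrices (so $R^{-1}$ costs
$O(c^3 + r^3)$ plus cheap grid transforms) with the Woodbury identity over
the low-rank genetic-plus-block term. The overall variance scale has a
closed-form REML optimum and is profiled out of the numerical search.
Optimization is Nelder–Mead followed by a BFGS polish, with systematic
multi-starts that displace $r_a$ (the one direction prone to local optima);
the multi-starts are deterministic, so refits reproduce the same optimum.
Standard errors come from central-difference observed information on the
transformed scale with a delta-method back-transform.

Confidence intervals for $r_a$ use profile likelihood: other parameters are
re-maximized at fixed $r_a$, and the 95% interval is where the deviance
drop stays below 3.84 ($\chi^2_1$). Profiles are pooled across families and
sites by summing deviance curves (after monotone cubic interpolation onto a
common grid); the pooled argmin is the consensus and
$X^2 = \sum_i D_i(\hat r_a^{\text{cons}})$ on (number of profiles − 1) df
tests homogeneity. Spatial parameters and heritabilities are instead pooled
by inverse sampling variance. Broad- and narrow-sense heritabilities are
$H^2 = \sigma_u^2/\sigma_P^2$ and $h^2 = f_a \sigma_u^2/\sigma_P^2$ with
$\sigma_P^2 = \sigma_u^2 + \sigma_v^2 + \sigma_r^2 + \sigma_s^2$.

## The half-sib mixture

QC can reveal that a nominal full-sib family is a mixture of two maternal
half-sib families (proportions $q : 1-q$, unrelated sires). Detection uses
opposing homozygotes — offspring and parent homozygous for different
alleles, impossible without error or wrong parentage: offspring sired by a
different father show strongly elevated per-offspring incompatibility
rates. Two reads of the rate distribution must agree before a mixture is
called: a threshold screen (share of offspring above three times the
background genotype-error rate of 0.013) and 2-means clustering with a
separation requirement (centre gap above four within-group spreads). We
require agreement at the verdict level, not identical partitions: the fixed
absolute threshold can legitimately fall inside the anomalous cluster, and
demanding identical partitions would turn clear mixtures into "ambiguous".

For a mixture, the fitted $r_a$ refers to the mixture variance and must be
rescaled to full-sib fractions. Within families lie $1/2$ of the additive
but $3/4$ of the dominance-type variance; the between-family (sire) terms
add $q(1-q)\sigma/2$ for each component. The retained shares
$c_A = \tfrac{1/2}{1/2 + q(1-q)/2}$ and $c_D = \tfrac{3/4}{3/4 + q(1-q)/2}$
give

$$ f_a = \frac{c_A r_a}{c_D - (c_D - c_A) r_a}, $$

reported with the denominator constant normalized to 3 (and analogously to
2 for $f_d$); at $q = 0.594$ the coefficients round to $(2.81, 0.19)$ and
$(2.14, 0.14)$. A Monte-Carlo oracle in the test suite re-derives $c_A$ and
$c_D$ by simulating the two-sire mixture directly. The assumed non-additive
structure is dominance-like (full-sib relationship $1/4$, half-sib $0$);
additive-by-additive epistasis is not separately modelled. The same
within/between bookkeeping gives the conversion of a within-family additive
fraction to a random-mating population, $3f_a/(2+f_a)$.

## The synthetic-data generator

No data accompany the study design this package emulates, so the generator
is a first-class module with known truth at every level.

* **Map and genotypes.** A 12-linkage-group map (1630 loci, ~2143 cM).
  Parent genotypes are assigned per SNP from the three segregating classes;
  the default class mix (15% both-parents-heterozygous, the rest split
  between single-heterozygote classes) was chosen so the simulated
  $k \approx 0.73$ sits inside the range observed for real full-sib spruce
  families. Gametes follow the Haldane model (crossovers as a Poisson
  process, no interference), which is the standard choice when only map
  distances are known.
* **Genetic values.** Additive values are linear in centred dosages at
  sampled causal loci. Dominance-type values use centred heterozygosity at
  loci where *both* parents are heterozygous — within a full-sib family
  these are the only loci that carry dominance variance (with two genotype
  classes any effect is re-expressible as additive), and there the centred
  heterozygosity is uncorrelated with the locus dosage. Both parts are
  rescaled so the realized split is exactly $r_a : 1 - r_a$.
* **Trials.** Randomized complete blocks, one ramet per offspring per
  block, blocks laid side by side within master blocks, filler plots with
  missing phenotypes where the grid exceeds the family size (mirroring the
  treatment of control trees). Spatial errors are drawn exactly through the
  eigen square roots of the two AR1 correlation matrices. Noise defaults
  ($\sigma_v^2 = 0.15$, $\sigma_r^2 = 1.26$, $\sigma_s^2 = 0.54$, so
  $f_r = 0.7$, plus $\sigma_u^2 = 1$) give $H^2 \approx 0.34$, matching the
  magnitude seen in the real pilodyn analyses. The field randomization is a
  seeded permutation within block; the true trials' randomization is not
  public, so this is a plausible stand-in, not a reconstruction.
* **Missingness.** Calls are masked independently with per-SNP and
  per-individual retention rates (default mean 0.79, the observed
  post-QC call-rate scale); optional posterior-probability triples put mass
  $1 - 0.013$ on the true genotype, emulating imputation output.

What passing tests on these data do **not** show: robustness to genotyping
artefacts that are not independent across loci (shared RAD loci dropout),
to map errors, or to non-Gaussian trait distributions (bud burst is an
ordinal score). The generator also draws causal loci from the typed SNPs
themselves, so it does not probe incomplete linkage between markers and
causal variants; realized $r_a$ recovery under that regime would be
attenuated toward the marker-captured fraction.

## Numerical and design choices

* Problem sizes in the test-suite recovery study: 30 trials of 200
  genotyped offspring with 4 ramets each, blocks of 10 × 20 stacked into
  one 40 × 20 master block (so every plot is observed and the structured
  likelihood path applies). This recovers the true $r_a = 0.75$ in mean to
  within 0.05 with profile-CI coverage at the nominal level.
* QC thresholds default to the field-standard values (individual call rate
  0.6, SNP call rate 0.8, MAF 0.15, Bonferroni-corrected 5% Mendelian
  test); "less than" is strict, so values equal to a threshold are kept.
  MAF is computed from retained offspring only. Because removing SNPs can
  push a borderline individual below the call-rate threshold, the
  individuals-then-SNPs pass is iterated to a fixed point, making the
  filter idempotent.
* Mendelian test cells with expected count below 1 are pooled into the
  nearest class. Crosses with all expectation in one class are skipped
  (opposing-homozygote screening covers them).
* Monomorphic-in-family loci are excluded from $G$ (retention with zero
  weight would be numerically identical in method 1). Missing dosages are
  mean-imputed at $2p_i$ with a loud warning; $G$ is not blended or bent,
  positive semidefiniteness is checked and reported only.
* Autocorrelations are bounded in $(-0.999, 0.999)$, variances in
  $[10^{-10}, 10^9]$ on the log scale; a non-positive-definite covariance
  returns $-\infty$ rather than an error so the optimizer can retreat.
* Profile grids: default 21 coarse points plus 10 refinement points around
  the optimum; an adaptive mode walks outward from the optimum until the
  deviance clears the CI threshold, which is what the coverage study uses.
* Fillers and any missing plots simply drop their rows; the observed-plot
  submatrix of $R$ is used directly (the dense path), since explicit
  coordinates keep the spatial model coherent without phenotype
  placeholders.

## Limitations

The package fits each trait and trial separately (no multi-trait or
multi-site joint models), does not partition the non-additive variance into
dominance and epistatic components, and does not construct pedigree or
single-step relationship matrices. Heterozygosity can be added as a fixed
covariate to probe inbreeding-depression-like signal, but no other fixed
effects are modelled beyond the intercept. The dense likelihood path scales
as $O(n^3)$ and is intended for trials up to a few thousand plots.

## A worked run

```{r, eval = FALSE}
cfg <- default_config()          # 200 offspring, 4 ramets, 12 x 20 blocks
res <- run_pipeline(cfg, out_dir = tempfile())
res$pooled$estimate              # consensus additive fraction
res$pooled$ci                    # 95% profile CI
```

The `analysis/` scripts run the same stages as a narrative workflow over a
three-family, three-site simulated study, including the hidden-mixture
family and its corrected $f_a$.
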