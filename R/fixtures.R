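# Canonical synthetic worlds used by the test-suite and the examples. Each is
# a fixed architecture_spec: the generator's defaults ARE the stated
# conditions, chosen once (effect sizes calibrated by a pilot simulation at
# package-authoring time and frozen; see the methods vignette).

#' Null world: no genetic or shared signal
#'
#' 110 variants (5 per autosome), MAF 0.3, no effects, prevalence 0.2 for all
#' six diseases. Any model's cross-validated AUROC should be ~0.5.
#'
#' @param seed spec seed.
#' @return an [architecture_spec].
#' @export
spec_null <- function(seed = 1L) {
  architecture_spec(n_variants_per_chrom = rep(5L, N_CHROM), maf = 0.3,
                    prevalence = rep(0.2, 6), seed = seed)
}

#' Pure within-chromosome epistasis world
#'
#' 200 variants (9 per autosome, 10 on chromosomes 1 and 2), MAF 0.5. Eight
#' SNP pairs, each pair on one chromosome, contribute products of centred
#' dosages (effect 1.5) to the IS liability; *no* additive effects, so the
#' true-weight linear PRS carries no information while a nonlinear model can
#' recover the interactions. IS prevalence 0.3 (enough cases for a balanced
#' training fold to learn interactions); the other tasks are pure noise at
#' prevalence 0.2.
#'
#' @param seed spec seed.
#' @return an [architecture_spec].
#' @export
spec_epistasis <- function(seed = 1L) {
  nv <- rep(9L, N_CHROM)
  nv[1:2] <- 10L
  offset <- c(0L, cumsum(nv))[seq_len(N_CHROM)]
  pair_chroms <- c(1L, 3L, 5L, 8L, 11L, 14L, 17L, 20L)
  pairs <- data.frame(
    a = offset[pair_chroms] + 2L,
    b = offset[pair_chroms] + 5L,
    effect = 1.5,
    disease = "IS")
  architecture_spec(n_variants_per_chrom = nv, maf = 0.5,
                    epistatic_pairs = pairs,
                    prevalence = c(0.3, rep(0.2, 5)), seed = seed)
}

#' Shared-genetics multi-task world
#'
#' 110 variants; 24 causal SNPs shared by all six diseases with per-disease
#' scaling: the IS signal is weak (scale 0.25) while the five MRFs carry the
#' same directions strongly (scale 1.0), so auxiliary-task supervision helps
#' the shared representation. A shared latent factor (loading 0.8 everywhere)
#' adds comorbidity between labels without being predictable from genotype.
#'
#' @param seed spec seed.
#' @return an [architecture_spec].
#' @export
spec_shared_factor <- function(seed = 1L) {
  nv <- rep(5L, N_CHROM)
  p <- sum(nv)
  causal <- seq(1L, p, by = 5L)[1:22]          # first SNP of each chromosome
  causal <- c(causal, 3L, 58L)                 # 24 causal variants
  set.seed(20260901L)                          # fixed effect directions
  w <- rnorm(length(causal), sd = 1)
  eff <- matrix(0, p, 6)
  scales <- c(IS = 0.25, AF = 1, CAD = 1, T2D = 1, HT = 1, HCL = 1)
  for (d in 1:6) eff[causal, d] <- scales[d] * w
  architecture_spec(n_variants_per_chrom = nv, maf = 0.3,
                    additive_effects = eff,
                    shared_factor_loading = rep(0.8, 6),
                    prevalence = rep(0.2, 6), seed = seed)
}

#' Attention-recovery world: causal SNPs only on chromosomes 2 and 9
#'
#' 110 variants; all five SNPs on chromosome 2 and all five on chromosome 9
#' carry strong additive IS effects (1.0); everything else is noise. A trained
#' chromosome-wise model's attention report should rank chromosomes 2 and 9
#' in the top quartile.
#'
#' @param seed spec seed.
#' @return an [architecture_spec].
#' @export
spec_attention_recovery <- function(seed = 1L) {
  nv <- rep(5L, N_CHROM)
  p <- sum(nv)
  offset <- c(0L, cumsum(nv))[seq_len(N_CHROM)]
  causal <- c(offset[2] + 1:5, offset[9] + 1:5)
  eff <- matrix(0, p, 6)
  eff[causal, "IS" == DISEASES] <- 1.0
  architecture_spec(n_variants_per_chrom = nv, maf = 0.3,
                    additive_effects = eff,
                    prevalence = rep(0.2, 6), seed = seed)
}

#' Purely additive world (linear ceiling)
#'
#' 110 variants with 30 additive IS effects, no epistasis, no shared factor:
#' the Bayes-optimal score is linear, so the true-weight PRS sits at the
#' ceiling any model can at best match.
#'
#' @param seed spec seed.
#' @return an [architecture_spec].
#' @export
spec_additive <- function(seed = 1L) {
  nv <- rep(5L, N_CHROM)
  p <- sum(nv)
  set.seed(20260902L)
  causal <- sort(sample.int(p, 30L))
  eff <- matrix(0, p, 6)
  eff[causal, 1] <- rnorm(30L, sd = 0.5)
  architecture_spec(n_variants_per_chrom = nv, maf = 0.3,
                    additive_effects = eff,
                    prevalence = rep(0.2, 6), seed = seed)
}
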