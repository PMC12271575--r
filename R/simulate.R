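# Synthetic genotype/phenotype generator. The stated world: MAF-parameterised
# diploid genotypes with Gaussian-copula block LD, liability-threshold
# case/control labels for six diseases sharing one latent factor, planted
# within-chromosome epistatic pairs, and age-at-event correlated with
# liability. Everything is seeded and bit-reproducible.

#' Construct a cohort table
#'
#' Per-sample binary labels for the six tasks plus optional survival
#' covariates. The latent liability matrix is retained as an attribute for
#' oracle tests; it is never used by models.
#'
#' @param sample_ids character vector.
#' @param labels n x 6 binary matrix, columns in [DISEASES] order.
#' @param age_end positive age (years) at event or censoring, or NULL.
#' @param event_is 0/1 ischaemic-stroke event flag; `event_is == 1` requires
#'   `labels[, "IS"] == 1`.
#' @param family_history 0/1 flag, or NULL.
#' @param liability optional n x 6 latent liability matrix.
#' @return data.frame of class `cohort_table`.
#' @export
cohort_table <- function(sample_ids, labels, age_end = NULL, event_is = NULL,
                         family_history = NULL, liability = NULL) {
  labels <- as.matrix(labels)
  assert_that(ncol(labels) == 6L, "cohort_table: labels must have 6 columns")
  colnames(labels) <- DISEASES
  assert_that(all(labels %in% 0:1), "cohort_table: labels must be 0/1")
  n <- length(sample_ids)
  assert_that(nrow(labels) == n, "cohort_table: label rows != sample count")
  df <- data.frame(sample_id = as.character(sample_ids), labels,
                   stringsAsFactors = FALSE)
  if (!is.null(age_end)) {
    assert_that(all(age_end > 0), "cohort_table: age_end must be positive")
    df$age_end <- as.numeric(age_end)
  }
  if (!is.null(event_is)) {
    assert_that(all(event_is %in% 0:1), "cohort_table: event_is must be 0/1")
    assert_that(all(labels[, "IS"][event_is == 1] == 1),
                "cohort_table: event_is = 1 requires IS label 1")
    df$event_is <- as.integer(event_is)
  }
  if (!is.null(family_history)) df$family_history <- as.integer(family_history)
  if (!is.null(liability)) {
    liability <- as.matrix(liability)
    colnames(liability) <- DISEASES
    attr(df, "liability") <- liability
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Architecture of a synthetic cohort
#'
#' Describes the generative world: per-chromosome variant counts, minor-allele
#' frequencies, LD blocks, per-disease additive and epistatic genetic effects,
#' the per-disease loading on one shared latent factor, and disease
#' prevalences.
#'
#' @param n_variants_per_chrom integer vector of length 22.
#' @param maf numeric vector (length 1 or total variant count) in (0, 0.5].
#' @param ld_blocks list of blocks, each `list(chrom =, from =, to =, r =)`
#'   where `from`/`to` index variants *within* the chromosome and `r` in
#'   `[0, 1)` is the target pairwise dosage correlation inside the block.
#' @param additive_effects total-variants x 6 matrix of per-dosage liability
#'   effects (default all zero). Dosages enter centred (g - 2 maf).
#' @param epistatic_pairs data.frame with columns `a`, `b` (panel column
#'   indices on the same chromosome), `effect`, `disease`; the product of the
#'   two centred dosages enters the named disease's liability.
#' @param shared_factor_loading length-6 loading of the shared standard-normal
#'   factor.
#' @param prevalence length-6 disease prevalences in (0, 1).
#' @param noise_sd residual liability standard deviation (default 1).
#' @param seed integer RNG seed stored with the spec.
#' @return object of class `architecture_spec`.
#' @export
architecture_spec <- function(n_variants_per_chrom,
                              maf = 0.3,
                              ld_blocks = list(),
                              additive_effects = NULL,
                              epistatic_pairs = NULL,
                              shared_factor_loading = rep(0, 6),
                              prevalence = rep(0.2, 6),
                              noise_sd = 1,
                              seed = 1L) {
  n_variants_per_chrom <- as.integer(n_variants_per_chrom)
  assert_that(length(n_variants_per_chrom) == N_CHROM,
              "architecture_spec: n_variants_per_chrom must have length 22")
  p <- sum(n_variants_per_chrom)
  assert_that(p >= 1L, "architecture_spec: need at least one variant")
  if (length(maf) == 1L) maf <- rep(maf, p)
  assert_that(length(maf) == p, "architecture_spec: maf length != variant count")
  assert_that(all(maf >= 0 & maf <= 0.5), "architecture_spec: maf must lie in [0, 0.5]")
  if (is.null(additive_effects)) additive_effects <- matrix(0, p, 6)
  additive_effects <- as.matrix(additive_effects)
  assert_that(nrow(additive_effects) == p && ncol(additive_effects) == 6L,
              "architecture_spec: additive_effects must be p x 6")
  colnames(additive_effects) <- DISEASES
  chrom_of <- rep(seq_len(N_CHROM), n_variants_per_chrom)
  if (!is.null(epistatic_pairs)) {
    assert_that(all(c("a", "b", "effect", "disease") %in% names(epistatic_pairs)),
                "architecture_spec: epistatic_pairs needs columns a, b, effect, disease")
    assert_that(all(chrom_of[epistatic_pairs$a] == chrom_of[epistatic_pairs$b]),
                "architecture_spec: epistatic pair members must share a chromosome")
    assert_that(all(epistatic_pairs$disease %in% DISEASES),
                "architecture_spec: unknown disease in epistatic_pairs")
  }
  for (blk in ld_blocks) {
    assert_that(all(c("chrom", "from", "to", "r") %in% names(blk)),
                "architecture_spec: LD block needs chrom, from, to, r")
    assert_that(blk$r >= 0 && blk$r < 1,
                "architecture_spec: LD target r must lie in [0, 1)")
    assert_that(blk$to <= n_variants_per_chrom[blk$chrom],
                "architecture_spec: LD block exceeds chromosome variant count")
  }
  assert_that(length(prevalence) == 6L && all(prevalence > 0 & prevalence < 1),
              "architecture_spec: prevalence must be length 6 in (0, 1)")
  assert_that(length(shared_factor_loading) == 6L,
              "architecture_spec: shared_factor_loading must have length 6")
  structure(list(n_variants_per_chrom = n_variants_per_chrom, maf = maf,
                 ld_blocks = ld_blocks, additive_effects = additive_effects,
                 epistatic_pairs = epistatic_pairs,
                 shared_factor_loading = as.numeric(shared_factor_loading),
                 prevalence = as.numeric(prevalence),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 chrom_of = chrom_of, n_variants = p),
            class = "architecture_spec")
}

#' Variant panel implied by an architecture spec
#'
#' Positions are synthetic (10 kb spacing within each chromosome); effect
#' weights are the spec's *true* IS additive effects, so the PRS baseline with
#' this panel is the true-weight linear score. Alleles are synthetic A
#' (other) / G (effect).
#'
#' @param spec an [architecture_spec].
#' @return a [variant_panel].
#' @export
panel_from_spec <- function(spec) {
  p <- spec$n_variants
  within_idx <- unlist(lapply(spec$n_variants_per_chrom, seq_len))
  tags <- lapply(seq_len(p), function(v) {
    t <- DISEASES[spec$additive_effects[v, ] != 0]
    if (length(t) == 0L) "IS" else t
  })
  variant_panel(rsid = sprintf("sim%d_%d", spec$chrom_of, within_idx),
                chrom = spec$chrom_of, pos = within_idx * 10000L,
                effect_allele = rep("G", p), other_allele = rep("A", p),
                effect_weight = spec$additive_effects[, "IS"],
                trait_tags = tags)
}

# latent equicorrelation rho giving binary (allele-indicator) correlation
# `target_r` when two standard normals are thresholded at qnorm(maf1/2).
copula_rho_for_r <- function(target_r, maf1, maf2) {
  if (target_r == 0) return(0)
  t1 <- qnorm(maf1); t2 <- qnorm(maf2)
  p11 <- function(rho) {
    integrate(function(z) pnorm((t2 - rho * z) / sqrt(1 - rho^2)) * dnorm(z),
              lower = -Inf, upper = t1, rel.tol = 1e-9)$value
  }
  corr_of <- function(rho) {
    (p11(rho) - maf1 * maf2) /
      sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
  }
  uniroot(function(rho) corr_of(rho) - target_r, interval = c(0, 0.9999),
          tol = 1e-8)$root
}

#' Simulate diploid genotypes
#'
#' Genotypes are sums of two independent haplotypes. Within an LD block,
#' haplotype alleles are thresholded from an equicorrelated multivariate
#' normal (Gaussian copula) whose latent correlation is calibrated so the
#' pairwise dosage correlation matches the block's target `r`; outside blocks
#' variants are independent Binomial(2, maf).
#'
#' @param n number of samples (>= 1).
#' @param spec an [architecture_spec].
#' @param seed RNG seed; defaults to the spec's seed.
#' @return a [genotype_matrix] whose panel is [panel_from_spec()].
#' @export
simulate_genotypes <- function(n, spec, seed = spec$seed) {
  assert_that(n >= 1, "simulate_genotypes: n must be >= 1")
  set.seed(seed)
  p <- spec$n_variants
  maf <- spec$maf
  dos <- matrix(0L, n, p)
  in_block <- rep(FALSE, p)
  chrom_offset <- c(0L, cumsum(spec$n_variants_per_chrom))[seq_len(N_CHROM)]
  for (blk in spec$ld_blocks) {
    cols <- chrom_offset[blk$chrom] + seq.int(blk$from, blk$to)
    in_block[cols] <- TRUE
    mafs <- maf[cols]
    rho <- copula_rho_for_r(blk$r, mean(mafs), mean(mafs))
    k <- length(cols)
    for (hap in 1:2) {
      u <- rnorm(n)
      z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
      alle <- sweep(z, 2, qnorm(mafs), "<")
      dos[, cols] <- dos[, cols] + alle
    }
  }
  free <- which(!in_block)
  if (length(free) > 0L) {
    dos[, free] <- vapply(free, function(v) rbinom(n, 2L, maf[v]),
                          integer(n))
  }
  genotype_matrix(dos, sprintf("S%05d", seq_len(n)), panel_from_spec(spec))
}

centred_dosages <- function(G, spec) {
  sweep(ifelse(is.na(G$dosages), 0L, G$dosages), 2, 2 * spec$maf)
}

#' Liability matrix implied by genotypes under a spec
#'
#' For disease d: `l_d = sum additive (centred dosages) + sum epistatic
#' (product of centred dosages of each planted pair) + loading_d * u +
#' noise_sd * eps`, with `u` a per-sample shared standard-normal factor and
#' `eps` standard normal.
#' @keywords internal
compute_liability <- function(G, spec, u, eps) {
  gc <- centred_dosages(G, spec)
  liab <- gc %*% spec$additive_effects
  ep <- spec$epistatic_pairs
  if (!is.null(ep)) {
    for (i in seq_len(nrow(ep))) {
      d <- ep$disease[i]
      liab[, d] <- liab[, d] + ep$effect[i] * gc[, ep$a[i]] * gc[, ep$b[i]]
    }
  }
  liab + outer(u, spec$shared_factor_loading) + spec$noise_sd * eps
}

#' Simulate multi-task disease labels by liability thresholding
#'
#' A sample is a case for disease d iff its liability exceeds the empirical
#' `(1 - prevalence_d)` quantile of the cohort's liability distribution
#' (empirical rather than theoretical-normal quantiles: exact prevalence
#' control even under epistatic, non-normal liabilities).
#'
#' @param G a [genotype_matrix] from [simulate_genotypes()].
#' @param spec the [architecture_spec] used to generate `G`.
#' @param seed RNG seed; defaults to `spec$seed + 1`.
#' @return a [cohort_table] with a retained liability attribute.
#' @export
simulate_multitask_phenotypes <- function(G, spec, seed = spec$seed + 1L) {
  set.seed(seed)
  n <- nrow(G$dosages)
  u <- rnorm(n)
  eps <- matrix(rnorm(n * 6), n, 6)
  liab <- compute_liability(G, spec, u, eps)
  labels <- vapply(1:6, function(d) {
    thr <- quantile(liab[, d], 1 - spec$prevalence[d], names = FALSE)
    as.integer(liab[, d] > thr)
  }, integer(n))
  cohort_table(G$sample_ids, labels, liability = liab)
}

#' Attach ages, IS events, censoring and family history to a cohort
#'
#' IS cases receive event ages `base_age + T` with `T ~ Exp(exp(l_IS) /
#' scale)`: higher liability, proportionally higher hazard, earlier events.
#' Controls receive censoring ages from the same exponential clock at zero
#' liability. Family history is Bernoulli with log-odds increasing in the
#' standardised IS liability.
#'
#' @param cohort a [cohort_table] carrying a liability attribute.
#' @param base_age age (years) at which follow-up starts; default 40.
#' @param scale mean years to event at zero liability; default 30.
#' @param fh_base baseline family-history probability; default 0.3.
#' @param fh_slope log-odds slope on standardised IS liability; default 1.
#' @param seed RNG seed.
#' @return the cohort with `age_end`, `event_is`, `family_history` filled in.
#' @export
simulate_ages_and_events <- function(cohort, base_age = 40, scale = 30,
                                     fh_base = 0.3, fh_slope = 1, seed = 1L) {
  liab <- attr(cohort, "liability")
  assert_that(!is.null(liab), "simulate_ages_and_events: cohort lacks liability matrix")
  set.seed(seed)
  n <- nrow(cohort)
  l_is <- liab[, "IS"]
  rate <- exp(l_is) / scale
  t_event <- rexp(n, rate = rate)
  t_censor <- rexp(n, rate = 1 / scale)
  is_case <- cohort$IS == 1L
  age <- base_age + ifelse(is_case, t_event, t_censor)
  z <- (l_is - mean(l_is)) / max(sd(l_is), 1e-12)
  fh <- rbinom(n, 1L, plogis(qlogis(fh_base) + fh_slope * z))
  cohort$age_end <- age
  cohort$event_is <- as.integer(is_case)
  cohort$family_history <- fh
  cohort
}

#' Simulate a full cohort (genotypes, labels, ages) in one call
#'
#' @inheritParams simulate_genotypes
#' @param ... passed to [simulate_ages_and_events()].
#' @return `list(G = genotype_matrix, cohort = cohort_table)`.
#' @export
simulate_cohort <- function(n, spec, seed = spec$seed, ...) {
  G <- simulate_genotypes(n, spec, seed = seed)
  cohort <- simulate_multitask_phenotypes(G, spec, seed = seed + 1L)
  cohort <- simulate_ages_and_events(cohort, seed = seed + 2L, ...)
  list(G = G, cohort = cohort)
}

#' Read / write architecture specs as JSON
#'
#' @param path JSON file mirroring the [architecture_spec()] fields.
#' @return an `architecture_spec`.
#' @export
read_architecture_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  architecture_spec(
    n_variants_per_chrom = x$n_variants_per_chrom,
    maf = x$maf %||% 0.3,
    ld_blocks = if (is.null(x$ld_blocks)) list() else
      lapply(seq_len(nrow(x$ld_blocks)), function(i) as.list(x$ld_blocks[i, ])),
    additive_effects = x$additive_effects,
    epistatic_pairs = x$epistatic_pairs,
    shared_factor_loading = x$shared_factor_loading %||% rep(0, 6),
    prevalence = x$prevalence %||% rep(0.2, 6),
    noise_sd = x$noise_sd %||% 1,
    seed = x$seed %||% 1L)
}

#' @rdname read_architecture_spec
#' @param spec an `architecture_spec` to serialise.
#' @export
write_architecture_spec <- function(spec, path) {
  x <- spec[c("n_variants_per_chrom", "maf", "additive_effects",
              "shared_factor_loading", "prevalence", "noise_sd", "seed")]
  x$ld_blocks <- if (length(spec$ld_blocks))
    do.call(rbind, lapply(spec$ld_blocks, as.data.frame)) else NULL
  x$epistatic_pairs <- spec$epistatic_pairs
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
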