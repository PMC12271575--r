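# Classic weighted-sum polygenic risk score: the linear baseline the
# chromosome-wise model is compared against. Effect re-estimation, LD-aware
# PRS variants and ML baselines are external methods and out of scope;
# comparison hooks accept their score files as plain vectors.

#' Weighted-sum polygenic risk score
#'
#' `score_i = sum_v weight_v * dosage_iv` over the panel's effect-allele
#' dosages. Missing dosages contribute `weight_v * 2 * maf_v` under policy
#' `"mean"` (requires allele frequencies, estimated from the cohort when not
#' supplied) or nothing under policy `"zero"`.
#'
#' @param G a [genotype_matrix].
#' @param panel a [variant_panel] supplying the weights; defaults to the
#'   genotype matrix's own panel.
#' @param missing_policy `"mean"` or `"zero"`.
#' @param maf optional per-variant allele frequencies for the `"mean"` policy.
#' @param reference_scores optional scores defining the standardisation
#'   reference; defaults to the cohort itself.
#' @return object of class `prs_result`: `score`, `standardized` (z-scored
#'   against the reference cohort) and the policy used.
#' @export
prs_score <- function(G, panel = G$panel, missing_policy = c("mean", "zero"),
                      maf = NULL, reference_scores = NULL) {
  missing_policy <- match.arg(missing_policy)
  assert_that(inherits(G, "genotype_matrix"), "prs_score: G must be a genotype_matrix")
  w <- panel$effect_weight %||% panel$variants$effect_weight
  assert_that(length(w) == ncol(G$dosages), "prs_score: weight/column mismatch")
  d <- G$dosages
  all_missing <- rowSums(!is.na(d)) == 0L
  if (any(all_missing))
    warning(sprintf("%d sample(s) have no called genotypes; scored from the non-missing subset (0 variants)",
                    sum(all_missing)), call. = FALSE)
  if (missing_policy == "mean") {
    if (is.null(maf)) maf <- colMeans(d, na.rm = TRUE) / 2
    maf[is.na(maf)] <- 0
    fill <- matrix(2 * maf, nrow(d), ncol(d), byrow = TRUE)
    d <- ifelse(is.na(d), fill, d)
  } else {
    d <- ifelse(is.na(d), 0, d)
  }
  score <- as.numeric(d %*% w)
  ref <- reference_scores %||% score
  s <- if (length(ref) > 1L) sd(ref) else 0
  standardized <- if (is.finite(s) && s > 0) (score - mean(ref)) / s else score * 0
  structure(list(score = score, standardized = standardized,
                 missing_policy = missing_policy), class = "prs_result")
}

#' @export
print.prs_result <- function(x, ...) {
  cat(sprintf("<prs_result> %d samples, score range [%.3f, %.3f]\n",
              length(x$score), min(x$score), max(x$score)))
  invisible(x)
}
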