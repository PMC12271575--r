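# Downstream evaluation: percentile normalisation against the validation
# population, bin-wise Cox hazard ratios on the age timeline, Harrell's
# C-index, Kaplan-Meier cumulative incidence, and the per-chromosome
# attention report.

PERCENTILE_BINS <- list(
  low       = c(0, 45),
  reference = c(45, 55),
  top55     = c(55, 100),
  top20     = c(80, 100),
  top10     = c(90, 100),
  top5      = c(95, 100),
  top1      = c(99, 100))

#' Map risk scores to percentiles of a reference distribution
#'
#' Percentile = 100 x empirical-CDF rank against the reference cohort
#' (mid-rank for ties), the "validation population" normalisation. Also
#' assigns tertile bins (0-33, 33-67, 67-100) and the percentile scheme bins
#' (low 0-45, reference 45-55, and nested top 55/80/90/95/99-100 bins).
#'
#' @param scores scores to stratify.
#' @param reference_scores scores of the reference (validation) cohort.
#' @return object of class `risk_strata`: `percentile`, `tertile` (factor
#'   `T1 < T2 < T3`) and the logical bin membership matrix `bins`.
#' @export
to_percentiles <- function(scores, reference_scores) {
  assert_that(length(reference_scores) > 0, "to_percentiles: empty reference")
  nref <- length(reference_scores)
  pct <- vapply(scores, function(s) {
    100 * (sum(reference_scores < s) + 0.5 * sum(reference_scores == s)) / nref
  }, numeric(1))
  tertile <- cut(pct, breaks = c(-Inf, 100 / 3, 200 / 3, Inf),
                 labels = c("T1", "T2", "T3"), ordered_result = TRUE)
  bins <- vapply(PERCENTILE_BINS, function(b) {
    if (b[2] >= 100) pct >= b[1] & pct <= 100 else pct >= b[1] & pct < b[2]
  }, logical(length(pct)))
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = 1,
                                         dimnames = list(NULL, names(PERCENTILE_BINS)))
  structure(list(percentile = pct, tertile = tertile, bins = bins),
            class = "risk_strata")
}

#' Cox hazard ratios of risk bins against a reference bin
#'
#' One Cox proportional-hazards fit per comparison bin (age as the time axis,
#' the bin indicator as the only covariate, the reference bin as baseline);
#' HR = exp(coefficient) with a Wald 95% CI. Percentile-scheme bins are
#' nested, hence the pairwise fits rather than one factor model.
#'
#' @param strata a [to_percentiles()] result for the cohort being analysed.
#' @param survival_df data.frame with `age` and `event` (0/1) columns, rows
#'   aligned with `strata`.
#' @param scheme `"tertiles"` (T2 and T3 vs T1) or `"percentiles"` (each top
#'   bin vs the 45-55% reference band).
#' @param conf confidence level (default 0.95).
#' @return data.frame: bin, n, events, HR, lower, upper. A bin with no events
#'   gets NA with a warning.
#' @export
bin_hazard_ratios <- function(strata, survival_df, scheme = c("tertiles",
                                                              "percentiles"),
                              conf = 0.95) {
  scheme <- match.arg(scheme)
  assert_that(all(c("age", "event") %in% names(survival_df)),
              "bin_hazard_ratios: survival_df needs 'age' and 'event'")
  if (scheme == "tertiles") {
    ref <- strata$tertile == "T1"
    comps <- list(T2 = strata$tertile == "T2", T3 = strata$tertile == "T3")
  } else {
    ref <- strata$bins[, "reference"]
    comps <- as.list(as.data.frame(
      strata$bins[, c("top55", "top20", "top10", "top5", "top1"), drop = FALSE]))
  }
  assert_that(sum(survival_df$event[ref]) > 0,
              "bin_hazard_ratios: no events in the reference bin")
  z <- qnorm(1 - (1 - conf) / 2)
  out <- lapply(names(comps), function(nm) {
    sel <- ref | comps[[nm]]
    dat <- data.frame(age = survival_df$age[sel],
                      event = survival_df$event[sel],
                      in_bin = as.integer(comps[[nm]][sel]))
    if (sum(dat$event[dat$in_bin == 1]) == 0) {
      warning(sprintf("bin '%s' has no events; HR undefined", nm), call. = FALSE)
      return(data.frame(bin = nm, n = sum(comps[[nm]]), events = 0,
                        HR = NA_real_, lower = NA_real_, upper = NA_real_))
    }
    fit <- survival::coxph(survival::Surv(age, event) ~ in_bin, data = dat)
    beta <- unname(stats::coef(fit)[1])
    se <- sqrt(stats::vcov(fit)[1, 1])
    data.frame(bin = nm, n = sum(comps[[nm]]),
               events = sum(dat$event[dat$in_bin == 1]),
               HR = exp(beta), lower = exp(beta - z * se),
               upper = exp(beta + z * se))
  })
  do.call(rbind, out)
}

#' Harrell's concordance index on an age timeline
#'
#' Permissible pairs: an event sample and any sample with a strictly later
#' age (a later event or a later-censored survivor). The pair is concordant
#' when the earlier-event sample has the higher score; score ties count 1/2.
#'
#' @param scores risk scores.
#' @param age age at event or censoring.
#' @param event 0/1 event flag.
#' @return C-index in `[0, 1]`.
#' @export
c_index <- function(scores, age, event) {
  event <- as.integer(event)
  assert_that(length(scores) == length(age) && length(age) == length(event),
              "c_index: length mismatch")
  conc <- 0; ties <- 0; total <- 0
  for (i in which(event == 1L)) {
    later <- age > age[i]
    total <- total + sum(later)
    conc <- conc + sum(scores[i] > scores[later])
    ties <- ties + sum(scores[i] == scores[later])
  }
  assert_that(total > 0, "c_index: no permissible pairs")
  (conc + 0.5 * ties) / total
}

#' C-index over task combinations
#'
#' Trains one model per task subset (always including IS) and reports the
#' held-out C-index of the IS risk score on the age timeline. Subsets can be
#' realised either as loss masks on the full panel (`panel_scope = "full"`)
#' or by restricting the panel to the subset's tagged variants
#' (`panel_scope = "subset"`).
#'
#' @param G a [genotype_matrix].
#' @param cohort a `cohort_table` with `age_end` and `event_is`.
#' @param combinations list of character vectors of task names (each must
#'   contain "IS"), e.g. `list("IS", c("IS", "HT"), DISEASES)`.
#' @param cfg a [model_config()].
#' @param seed split/train seed.
#' @param train_frac fraction used for training (balanced on IS); the rest is
#'   the evaluation pool.
#' @param panel_scope `"full"` or `"subset"`.
#' @param ... passed to [train_metageno()].
#' @return data.frame with one row per combination: label, tasks, c_index.
#' @export
c_index_by_task_combination <- function(G, cohort, combinations,
                                        cfg = model_config(), seed = 1L,
                                        train_frac = 0.8,
                                        panel_scope = c("full", "subset"),
                                        ...) {
  panel_scope <- match.arg(panel_scope)
  labels <- as.matrix(cohort[, DISEASES])
  states_full <- dosage_states(G, cfg$missing_policy)
  groups_full <- group_by_chromosome(G$panel)
  plan <- make_fold_plan(labels[, "IS"], k = max(2L, round(1 / (1 - train_frac))),
                         seed = seed)
  tr <- plan$train_idx[[1L]]
  ev <- plan$eval_idx[[1L]]
  rows <- lapply(combinations, function(tasks) {
    assert_that("IS" %in% tasks, "every combination must include IS")
    assert_that(all(tasks %in% DISEASES), "unknown task in combination")
    tw <- as.numeric(DISEASES %in% tasks)
    if (panel_scope == "subset") {
      keep <- vapply(G$panel$variants$trait_tags,
                     function(t) any(t %in% tasks), logical(1))
      sub_panel <- with(G$panel$variants[keep, ],
                        variant_panel(rsid, chrom, pos, effect_allele,
                                      other_allele, effect_weight,
                                      G$panel$variants$trait_tags[keep]))
      states <- states_full[, keep, drop = FALSE]
      groups <- group_by_chromosome(sub_panel)
    } else {
      states <- states_full
      groups <- groups_full
    }
    fit <- train_metageno(states[tr, , drop = FALSE],
                          labels[tr, , drop = FALSE], groups = groups,
                          cfg = cfg, task_weights = tw, seed = seed, ...)
    sc <- predict(fit, states[ev, , drop = FALSE])[, "IS"]
    ci <- c_index(sc, cohort$age_end[ev], cohort$event_is[ev])
    label <- if (setequal(tasks, DISEASES)) "All MRFs"
             else paste(tasks, collapse = "+")
    data.frame(combination = label, n_tasks = length(tasks), c_index = ci)
  })
  do.call(rbind, rows)
}

#' Kaplan-Meier cumulative incidence by group on the age axis
#'
#' Cumulative incidence = 1 - KM survival, with Greenwood (log-scale)
#' confidence bands. Empty groups are skipped with a warning.
#'
#' @param survival_df data.frame with `age`, `event`.
#' @param group group assignment (factor/character), one per row.
#' @param conf confidence level.
#' @return named list per group: `times`, `incidence` (non-decreasing, in
#'   `[0, 1]`), `lower`, `upper`, `n`.
#' @export
cumulative_incidence <- function(survival_df, group, conf = 0.95) {
  group <- as.character(group)
  out <- list()
  for (gname in unique(group[!is.na(group)])) {
    sel <- !is.na(group) & group == gname
    if (!any(sel)) {
      warning(sprintf("group '%s' is empty; skipped", gname), call. = FALSE)
      next
    }
    fit <- survival::survfit(
      survival::Surv(age, event) ~ 1,
      data = data.frame(age = survival_df$age[sel],
                        event = survival_df$event[sel]),
      conf.int = conf)
    out[[gname]] <- list(times = fit$time,
                         incidence = 1 - fit$surv,
                         lower = 1 - fit$upper,
                         upper = 1 - fit$lower,
                         n = sum(sel))
  }
  out
}

#' Label risk/covariate subgroups for incidence analysis
#'
#' Crosses top/bottom risk-percentile deciles with binary covariate flags
#' (e.g. hypertension + atrial fibrillation, family history), the subgroup
#' definitions used for age-timeline incidence comparisons.
#'
#' @param strata a [to_percentiles()] result.
#' @param flags logical vector (e.g. `HT == 1 & AF == 1`), or NULL.
#' @param top,bottom percentile width of the extreme-risk groups (default 10).
#' @return character vector of subgroup labels (NA outside the extremes).
#' @export
risk_subgroups <- function(strata, flags = NULL, top = 10, bottom = 10) {
  pct <- strata$percentile
  base <- ifelse(pct >= 100 - top, "top",
                 ifelse(pct < bottom, "bottom", NA_character_))
  if (is.null(flags)) return(base)
  ifelse(is.na(base), NA_character_,
         paste0(base, ifelse(flags, "+flag", "-flag")))
}

#' Per-chromosome attention report
#'
#' For every sample, each SNP's incoming attention mass (column sums of the
#' chromosome-layer attention matrix) is weighted by the norm of the SNP's
#' value vector, summed within each chromosome, averaged over samples, and
#' min-max normalised to `[0, 1]` across the 22 chromosomes.
#'
#' The unweighted raw sum (`weighting = "raw"`) is also available, but note
#' that row-normalised attention makes the per-chromosome raw sum exactly the
#' chromosome's SNP count, so it reflects panel composition, not learned
#' importance; the value-norm weighting is the default for that reason. A
#' degenerate (constant) report is flagged with a warning and returned as
#' zeros with attribute `degenerate = TRUE`.
#'
#' @param model a trained `mg_model` (chromosome-wise or global mode).
#' @param states allele-state matrix or [genotype_matrix].
#' @param weighting `"value_norm"` (default) or `"raw"`.
#' @return data.frame of class `attention_report`: chromosome, m (SNP count),
#'   raw mass and normalized score in `[0, 1]` (min 0, max 1).
#' @export
chromosome_attention_report <- function(model, states,
                                        weighting = c("value_norm", "raw")) {
  weighting <- match.arg(weighting)
  assert_that(model$cfg$mode %in% c("chromosome_wise", "global_snp"),
              "attention report requires an attention-based representation mode (got '%s')",
              model$cfg$mode)
  if (inherits(states, "genotype_matrix"))
    states <- dosage_states(states, model$cfg$missing_policy)
  out <- cpp_predict(states, groups_to_cpp(model$groups), model$params,
                     cfg_to_cpp(model$cfg), return_attention = TRUE)
  per_snp <- if (weighting == "value_norm") out$attn_value else out$attn_raw
  m <- vapply(model$groups, `[[`, integer(1), "m")
  raw <- vapply(model$groups, function(g) {
    if (g$m == 0L) 0 else sum(per_snp[g$cols])
  }, numeric(1))
  rng <- max(raw) - min(raw)
  if (rng < 1e-12) {
    warning("attention report is degenerate (all chromosomes equal)",
            call. = FALSE)
    norm <- rep(0, N_CHROM)
    degenerate <- TRUE
  } else {
    norm <- (raw - min(raw)) / rng
    degenerate <- FALSE
  }
  res <- data.frame(chrom = seq_len(N_CHROM), m = m, raw = raw,
                    normalized = norm)
  attr(res, "degenerate") <- degenerate
  class(res) <- c("attention_report", "data.frame")
  res
}
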