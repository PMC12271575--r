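# Cross-validated training protocol and classification metrics. Folds are
# stratified on the IS label; each training fold is balanced by randomly
# downsampling controls to the case count, and the *entire* validation fold
# (including the controls excluded from training) forms the evaluation pool.

#' Build a stratified, balanced k-fold plan
#'
#' Validation folds are disjoint and partition the cohort; stratification is
#' on the IS label. In every training fold all cases are kept and an equal
#' number of controls is sampled with the fold-specific seed.
#'
#' @param labels_is binary IS label vector.
#' @param k number of folds (default 5).
#' @param seed RNG seed.
#' @return object of class `fold_plan`: `assignments` (per-sample fold index),
#'   `train_idx` (per-fold balanced training indices) and `eval_idx` (per-fold
#'   evaluation pool = the whole validation fold).
#' @export
make_fold_plan <- function(labels_is, k = 5L, seed = 1L) {
  labels_is <- as.integer(labels_is)
  n <- length(labels_is)
  cases <- which(labels_is == 1L)
  controls <- which(labels_is == 0L)
  assert_that(length(cases) >= k && length(controls) >= k,
              "make_fold_plan: need at least k cases and k controls")
  set.seed(seed)
  fold <- integer(n)
  fold[cases] <- sample(rep_len(seq_len(k), length(cases)))
  fold[controls] <- sample(rep_len(seq_len(k), length(controls)))
  train_idx <- vector("list", k)
  eval_idx <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    tr_cases <- tr[labels_is[tr] == 1L]
    tr_controls <- tr[labels_is[tr] == 0L]
    set.seed(seed * 1000L + f)
    kept <- sample(tr_controls, length(tr_cases))
    train_idx[[f]] <- sort(c(tr_cases, kept))
    eval_idx[[f]] <- which(fold == f)
  }
  structure(list(k = k, assignments = fold, train_idx = train_idx,
                 eval_idx = eval_idx, seed = seed), class = "fold_plan")
}

#' Area under the ROC curve (Mann-Whitney statistic)
#'
#' Computed from mid-ranks, so score ties count one half. Optional percentile
#' bootstrap confidence interval from stratified resamples.
#'
#' @param scores numeric scores (higher = more case-like).
#' @param labels binary labels.
#' @param ci compute a bootstrap CI?
#' @param n_boot bootstrap resamples (default 1000).
#' @param conf confidence level.
#' @param seed RNG seed for the bootstrap.
#' @return list with `auroc` and, when `ci`, `lower`/`upper`.
#' @export
auroc <- function(scores, labels, ci = FALSE, n_boot = 1000L, conf = 0.95,
                  seed = 1L) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  assert_that(n1 > 0L && n0 > 0L, "auroc: both classes required")
  a <- (sum(rank(scores, ties.method = "average")[labels == 1L]) -
          n1 * (n1 + 1) / 2) / (n1 * n0)
  if (!ci) return(list(auroc = a))
  set.seed(seed)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  boots <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(i1, n1, replace = TRUE), sample(i0, n0, replace = TRUE))
    y <- labels[idx]
    r <- rank(scores[idx], ties.method = "average")
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
  list(auroc = a, lower = qs[1], upper = qs[2])
}

#' Precision, recall and F1 at a threshold
#'
#' @param scores numeric scores.
#' @param labels binary labels.
#' @param threshold decision threshold (default 0.5).
#' @return list with `precision`, `recall`, `f1`. With no predicted positives,
#'   precision is reported as 0 with a warning.
#' @export
precision_recall_f1 <- function(scores, labels, threshold = 0.5) {
  labels <- as.integer(labels)
  assert_that(any(labels == 1L) && any(labels == 0L),
              "precision_recall_f1: both classes required")
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  if (tp + fp == 0L) {
    warning("no predicted positives; precision undefined, reported as 0",
            call. = FALSE)
    precision <- 0
  } else precision <- tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f1 = f1)
}

#' Run the cross-validated training protocol
#'
#' Trains one model per fold on the balanced training portion and evaluates
#' all six tasks on the fold's evaluation pool. Out-of-fold scores are
#' produced only by models that never saw those samples.
#'
#' @param G a [genotype_matrix] (or an allele-state matrix, with `groups`).
#' @param cohort a `cohort_table` (or n x 6 label matrix).
#' @param cfg a [model_config()].
#' @param k folds (default 5).
#' @param seed seed for the fold plan; fold f trains with seed `seed + f`.
#' @param groups chromosome grouping when `G` is a raw matrix.
#' @param task_weights six loss weights.
#' @param ... passed to [train_metageno()] (epochs, lr, batch_size, ...).
#' @return list with `metrics` (fold x task AUROC table), `oof_scores`
#'   (n x 6 out-of-fold probabilities), `fold_plan` and `models`.
#' @export
run_experiment <- function(G, cohort, cfg = model_config(), k = 5L, seed = 1L,
                           groups = NULL, task_weights = rep(1, 6), ...) {
  if (inherits(G, "genotype_matrix")) {
    groups <- group_by_chromosome(G$panel)
    states <- dosage_states(G, cfg$missing_policy)
  } else {
    states <- as.matrix(G)
    assert_that(!is.null(groups), "run_experiment: groups required")
  }
  labels <- if (inherits(cohort, "cohort_table"))
    as.matrix(cohort[, DISEASES]) else as.matrix(cohort)
  plan <- make_fold_plan(labels[, "IS"], k = k, seed = seed)
  n <- nrow(states)
  oof <- matrix(NA_real_, n, 6, dimnames = list(NULL, DISEASES))
  metrics <- NULL
  models <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- plan$train_idx[[f]]
    ev <- plan$eval_idx[[f]]
    fit <- train_metageno(states[tr, , drop = FALSE],
                          labels[tr, , drop = FALSE], groups = groups,
                          cfg = cfg, task_weights = task_weights,
                          seed = seed + f, ...)
    probs <- predict(fit, states[ev, , drop = FALSE])
    oof[ev, ] <- probs
    models[[f]] <- fit
    for (d in seq_along(DISEASES)) {
      y <- labels[ev, d]
      a <- if (length(unique(y)) == 2L) auroc(probs[, d], y)$auroc else NA_real_
      metrics <- rbind(metrics,
                       data.frame(fold = f, task = DISEASES[d], auroc = a))
    }
  }
  list(metrics = metrics, oof_scores = oof, fold_plan = plan, models = models)
}
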