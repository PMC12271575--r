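# Model configuration, parameter initialisation, Adam training loop and
# prediction. The heavy forward/backward lives in src/; everything random
# (initialisation, minibatch order) is drawn through R's RNG so a seed fixes
# the run bit-for-bit in single-threaded mode.

REPRESENTATION_MODES <- c("chromosome_wise", "global_snp", "independent_snp",
                          "one_hot")
BACKBONE_KINDS <- c("transformer", "lstm", "gru", "cnn", "tcn")

#' Model configuration
#'
#' @param mode SNP representation mode (see [embed_snps()]).
#' @param kind backbone architecture over the 22 chromosome tokens. The
#'   transformer uses multi-head self-attention blocks then a mean over
#'   tokens; `lstm`/`gru` run over tokens in chromosome order and use the
#'   final hidden state; `cnn`/`tcn` apply kernel-3 (dilated, causal for tcn)
#'   convolutions then global mean pooling.
#' @param d embedding dimension (trunk width for the transformer).
#' @param V allele-state count: 4 keeps a dedicated missing state, 3 requires
#'   `missing_policy = "zero"`.
#' @param depth number of backbone blocks/layers (0 allowed for transformer:
#'   pure pooling).
#' @param width hidden width (recurrent state, conv channels, transformer
#'   feed-forward width).
#' @param heads transformer attention heads; must divide `d`.
#' @param dropout reserved; only 0 is supported (desk-scale models here do not
#'   need it and a no-op keeps runs deterministic).
#' @param missing_policy how missing genotypes enter the encoder
#'   (see [dosage_states()]).
#' @return list of class `mg_config`.
#' @export
model_config <- function(mode = "chromosome_wise", kind = "transformer",
                         d = 8L, V = 4L, depth = 1L, width = 16L, heads = 2L,
                         dropout = 0, missing_policy = "state") {
  assert_that(mode %in% REPRESENTATION_MODES, "unknown representation mode '%s'", mode)
  assert_that(kind %in% BACKBONE_KINDS, "unknown backbone kind '%s'", kind)
  assert_that(V %in% c(3L, 4L), "V must be 3 or 4")
  assert_that(missing_policy %in% c("state", "zero"), "unknown missing policy")
  assert_that(V == 4L || missing_policy == "zero",
              "V = 3 requires missing_policy = 'zero'")
  assert_that(dropout == 0, "dropout is reserved; only 0 is supported")
  assert_that(depth >= 0L, "depth must be >= 0")
  assert_that(kind == "transformer" || depth >= 1L,
              "depth 0 is only defined for the transformer backbone")
  if (kind == "transformer" && depth > 0L)
    assert_that(d %% heads == 0L, "heads must divide d")
  structure(list(mode = mode, kind = kind, d = as.integer(d), V = as.integer(V),
                 depth = as.integer(depth), width = as.integer(width),
                 heads = as.integer(heads), dropout = dropout,
                 missing_policy = missing_policy),
            class = "mg_config")
}

cfg_to_cpp <- function(cfg) {
  list(mode = match(cfg$mode, REPRESENTATION_MODES) - 1L,
       kind = match(cfg$kind, BACKBONE_KINDS) - 1L,
       V = cfg$V, d = cfg$d, depth = cfg$depth, width = cfg$width,
       heads = cfg$heads)
}

trunk_dim <- function(cfg) if (cfg$kind == "transformer") cfg$d else cfg$width

#' Initialise all model parameters
#'
#' Embedding-layer parameters (shared state table `E`, per-SNP identity `P`,
#' attention projections, per-chromosome null tokens) plus backbone and head
#' parameters, shaped for the given configuration. Heads start at zero so an
#' untrained model predicts probability 0.5 for every task.
#'
#' @param n_variants panel variant count.
#' @param cfg a [model_config()].
#' @param seed RNG seed.
#' @return named list of parameter matrices (biases are 1-column matrices).
#' @export
init_model_params <- function(n_variants, cfg, seed = 1L) {
  set.seed(seed)
  d <- cfg$d; w <- cfg$width; V <- cfg$V
  rn <- function(r, c, sd) matrix(rnorm(r * c, sd = sd), r, c)
  p <- list()
  if (cfg$mode %in% c("chromosome_wise", "global_snp")) {
    p$E <- rn(V, d, 0.5)
    p$Wq <- rn(d, d, 1 / sqrt(d))
    p$Wk <- rn(d, d, 1 / sqrt(d))
    p$Wv <- rn(d, d, 1 / sqrt(d))
    p$null_tok <- rn(N_CHROM, d, 0.5)
    if (cfg$mode == "chromosome_wise") p$P <- rn(n_variants, d, 0.5)
  } else if (cfg$mode == "independent_snp") {
    p$E_ind <- rn(n_variants * V, d, 0.5)
    p$null_tok <- rn(N_CHROM, d, 0.5)
  }
  if (cfg$kind == "transformer") {
    for (b in seq_len(cfg$depth) - 1L) {
      p[[sprintf("tf%d_Wq", b)]] <- rn(d, d, 1 / sqrt(d))
      p[[sprintf("tf%d_Wk", b)]] <- rn(d, d, 1 / sqrt(d))
      p[[sprintf("tf%d_Wv", b)]] <- rn(d, d, 1 / sqrt(d))
      p[[sprintf("tf%d_Wo", b)]] <- rn(d, d, 1 / sqrt(d))
      p[[sprintf("tf%d_W1", b)]] <- rn(w, d, sqrt(2 / d))
      p[[sprintf("tf%d_b1", b)]] <- matrix(0, w, 1)
      p[[sprintf("tf%d_W2", b)]] <- rn(d, w, 1 / sqrt(w))
      p[[sprintf("tf%d_b2", b)]] <- matrix(0, d, 1)
    }
  } else if (cfg$kind %in% c("lstm", "gru")) {
    gates <- if (cfg$kind == "lstm") 4L else 3L
    for (b in seq_len(cfg$depth) - 1L) {
      din <- if (b == 0L) d else w
      p[[sprintf("rnn%d_Wx", b)]] <- rn(gates * w, din, 1 / sqrt(din))
      p[[sprintf("rnn%d_Wh", b)]] <- rn(gates * w, w, 1 / sqrt(w))
      bvec <- matrix(0, gates * w, 1)
      if (cfg$kind == "lstm") bvec[(w + 1):(2 * w), 1] <- 1  # forget-gate bias
      p[[sprintf("rnn%d_b", b)]] <- bvec
    }
  } else {  # cnn / tcn
    for (b in seq_len(cfg$depth) - 1L) {
      cin <- if (b == 0L) d else w
      p[[sprintf("conv%d_W", b)]] <- rn(w, 3L * cin, sqrt(2 / (3 * cin)))
      p[[sprintf("conv%d_b", b)]] <- matrix(0, w, 1)
    }
  }
  p$Wh <- matrix(0, 6L, trunk_dim(cfg))
  p$bh <- matrix(0, 6L, 1L)
  p
}

groups_to_cpp <- function(groups) lapply(groups, `[[`, "cols")

#' Backbone forward pass over one chromosome-aware representation
#'
#' @param Z 22 x d matrix (see [assemble_representation()]).
#' @param params parameters from [init_model_params()].
#' @param cfg a [model_config()].
#' @return trunk vector (length d for the transformer, `width` otherwise).
#' @export
backbone_forward <- function(Z, params, cfg) {
  assert_that(all(is.finite(Z)), "backbone_forward: non-finite input")
  as.numeric(cpp_backbone_forward(as.matrix(Z), params, cfg_to_cpp(cfg)))
}

#' Six-task predictions from a trunk vector
#'
#' Independent linear heads plus sigmoid, one probability per disease.
#'
#' @param trunk numeric vector (or n x t matrix of trunks).
#' @param heads list with `Wh` (6 x t) and `bh` (6 x 1).
#' @return list with `logits` and `probs` (n x 6, [DISEASES] order).
#' @export
predict_tasks <- function(trunk, heads) {
  Tm <- if (is.matrix(trunk)) trunk else matrix(trunk, nrow = 1)
  assert_that(all(is.finite(Tm)), "predict_tasks: non-finite trunk")
  logits <- Tm %*% t(heads$Wh) + matrix(heads$bh[, 1], nrow(Tm), 6, byrow = TRUE)
  logits <- pmax(pmin(logits, 30), -30)
  colnames(logits) <- DISEASES
  list(logits = logits, probs = 1 / (1 + exp(-logits)))
}

#' Multi-task loss: weighted sum of per-task mean binary cross-entropies
#'
#' @param preds list with `probs` (n x 6) as returned by [predict_tasks()].
#' @param labels n x 6 binary matrix.
#' @param task_weights six non-negative weights, not all zero (default all 1).
#' @return scalar loss.
#' @export
multitask_loss <- function(preds, labels, task_weights = rep(1, 6)) {
  labels <- as.matrix(labels)
  assert_that(all(labels %in% 0:1), "multitask_loss: labels must be 0/1")
  assert_that(all(task_weights >= 0) && any(task_weights > 0),
              "multitask_loss: weights must be >= 0 and not all zero")
  p <- pmin(pmax(preds$probs, 1e-7), 1 - 1e-7)
  bce <- -(labels * log(p) + (1 - labels) * log(1 - p))
  sum(task_weights * colMeans(bce))
}

#' Loss and exact gradients for the full model (compiled path)
#'
#' Mainly for gradient-checking and the training loop.
#'
#' @param states n x p integer allele-state matrix (see [dosage_states()]).
#' @param groups chromosome grouping ([group_by_chromosome()]).
#' @param params parameter list.
#' @param cfg a [model_config()].
#' @param labels n x 6 binary matrix.
#' @param task_weights six weights.
#' @return list with `loss`, `grads` (named like `params`) and `logits`.
#' @export
model_loss_grad <- function(states, groups, params, cfg, labels,
                            task_weights = rep(1, 6)) {
  cpp_loss_grad(states, groups_to_cpp(groups), params, cfg_to_cpp(cfg),
                as.matrix(labels), as.numeric(task_weights))
}

#' Train the chromosome-wise multi-task model
#'
#' Adam with minibatches; optional early stopping on a validation AUROC for
#' the IS task (patience in epochs). Deterministic for a fixed seed.
#'
#' @param states n x p integer allele-state matrix, or a [genotype_matrix]
#'   (converted with the config's missing policy).
#' @param labels n x 6 binary label matrix or a `cohort_table`.
#' @param groups chromosome grouping; computed from the genotype panel when
#'   `states` is a [genotype_matrix].
#' @param cfg a [model_config()].
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size (default 256).
#' @param lr Adam learning rate (default 1e-3).
#' @param task_weights six loss weights (single-task IS mode:
#'   `c(1, 0, 0, 0, 0, 0)`).
#' @param seed RNG seed for initialisation and batch order.
#' @param validation optional `list(states =, labels =)` used for early
#'   stopping on IS AUROC.
#' @param patience early-stopping patience (epochs without improvement).
#' @param verbose print per-epoch loss.
#' @return object of class `mg_model`: parameters, config, groups, history.
#' @export
train_metageno <- function(states, labels, groups = NULL, cfg = model_config(),
                           epochs = 30L, batch_size = 256L, lr = 1e-3,
                           task_weights = rep(1, 6), seed = 1L,
                           validation = NULL, patience = 10L, verbose = FALSE) {
  if (inherits(states, "genotype_matrix")) {
    if (is.null(groups)) groups <- group_by_chromosome(states$panel)
    states <- dosage_states(states, cfg$missing_policy)
  }
  assert_that(!is.null(groups), "train_metageno: groups required for raw state matrices")
  if (inherits(labels, "cohort_table")) labels <- as.matrix(labels[, DISEASES])
  labels <- as.matrix(labels)
  storage.mode(labels) <- "double"
  n <- nrow(states)
  assert_that(nrow(labels) == n, "train_metageno: labels/states row mismatch")

  params <- init_model_params(ncol(states), cfg, seed = seed)
  mstate <- lapply(params, function(x) array(0, dim(x)))
  vstate <- lapply(params, function(x) array(0, dim(x)))
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_auroc = numeric())
  best <- list(auroc = -Inf, params = params, epoch = 0L)
  cgroups <- groups_to_cpp(groups)
  ccfg <- cfg_to_cpp(cfg)
  tw <- as.numeric(task_weights)

  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- ceiling(n / batch_size)
    for (bi in seq_len(n_batches)) {
      idx <- ord[((bi - 1L) * batch_size + 1L):min(bi * batch_size, n)]
      res <- cpp_loss_grad(states[idx, , drop = FALSE], cgroups, params, ccfg,
                           labels[idx, , drop = FALSE], tw)
      ep_loss <- ep_loss + res$loss * length(idx)
      step <- step + 1L
      g <- res$grads
      for (nm in names(g)) {
        mstate[[nm]] <- b1 * mstate[[nm]] + (1 - b1) * g[[nm]]
        vstate[[nm]] <- b2 * vstate[[nm]] + (1 - b2) * g[[nm]]^2
        mhat <- mstate[[nm]] / (1 - b1^step)
        vhat <- vstate[[nm]] / (1 - b2^step)
        params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
      }
    }
    val_auroc <- NA_real_
    if (!is.null(validation)) {
      pv <- cpp_predict(validation$states, cgroups, params, ccfg)
      val_auroc <- auroc(pv$probs[, 1], validation$labels[, 1],
                         ci = FALSE)$auroc
      if (val_auroc > best$auroc) {
        best <- list(auroc = val_auroc, params = params, epoch = ep)
      } else if (ep - best$epoch >= patience) {
        history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                             val_auroc = val_auroc))
        break
      }
    }
    history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n,
                                         val_auroc = val_auroc))
    if (verbose)
      message(sprintf("epoch %d  loss %.4f  val IS AUROC %s", ep, ep_loss / n,
                      ifelse(is.na(val_auroc), "-", sprintf("%.3f", val_auroc))))
  }
  if (!is.null(validation) && is.finite(best$auroc)) params <- best$params

  structure(list(params = params, cfg = cfg, groups = groups,
                 history = history, task_weights = tw, seed = seed),
            class = "mg_model")
}

#' @export
print.mg_model <- function(x, ...) {
  cat(sprintf("<mg_model> %s backbone, %s representation, d = %d, %d epoch(s) trained\n",
              x$cfg$kind, x$cfg$mode, x$cfg$d, nrow(x$history)))
  invisible(x)
}

#' Predict six-task risk probabilities
#'
#' @param object an `mg_model`.
#' @param states n x p allele-state matrix or [genotype_matrix].
#' @param ... unused.
#' @return n x 6 matrix of probabilities ([DISEASES] columns).
#' @export
predict.mg_model <- function(object, states, ...) {
  if (inherits(states, "genotype_matrix"))
    states <- dosage_states(states, object$cfg$missing_policy)
  out <- cpp_predict(states, groups_to_cpp(object$groups), object$params,
                     cfg_to_cpp(object$cfg))
  probs <- out$probs
  colnames(probs) <- DISEASES
  probs
}

#' Embedding-layer output Z for a batch (compiled path)
#'
#' @param model an `mg_model` (or list with `params`, `cfg`, `groups`).
#' @param states allele-state matrix or [genotype_matrix].
#' @return array n x 22 x d.
#' @export
model_representation <- function(model, states) {
  if (inherits(states, "genotype_matrix"))
    states <- dosage_states(states, model$cfg$missing_policy)
  out <- cpp_predict(states, groups_to_cpp(model$groups), model$params,
                     cfg_to_cpp(model$cfg), return_Z = TRUE)
  array(out$Z, c(nrow(states), N_CHROM, model$cfg$d))
}
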