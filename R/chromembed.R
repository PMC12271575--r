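# Chromosome-wise embedding layer: allele-state one-hot encoding, shared
# state-embedding matrix E plus per-SNP identity term P, single-head
# self-attention within each chromosome, mean pooling, and concatenation into
# the 22 x d representation Z. These are the reference (plain R) forward
# implementations used as the layer contract; training uses the compiled path
# in src/, which is checked against these in the tests.

MISSING_STATE <- 3L

#' One-hot encode an allele state
#'
#' States are homozygous-other (0), heterozygous (1), homozygous-effect (2),
#' and optionally a dedicated missing state (index 3) when `V = 4`. Encoding a
#' missing genotype with `V = 3` is an error: three-state mode requires a
#' missing policy that collapses no-calls beforehand (see [dosage_states()]).
#'
#' @param dosage 0, 1, 2 or NA (missing).
#' @param V number of allele states, 3 or 4.
#' @return one-hot numeric vector of length `V`.
#' @export
encode_allele_state <- function(dosage, V = 4L) {
  assert_that(V %in% c(3L, 4L), "encode_allele_state: V must be 3 or 4")
  idx <- if (is.na(dosage)) MISSING_STATE else as.integer(dosage)
  assert_that(idx %in% 0:3, "encode_allele_state: dosage must be 0, 1, 2 or NA")
  if (idx == MISSING_STATE && V == 3L)
    stop_mg("encode_allele_state: missing genotype but V = 3 (no missing state)")
  x <- numeric(V)
  x[idx + 1L] <- 1
  x
}

#' Convert a genotype matrix to integer allele-state codes
#'
#' @param G a [genotype_matrix] or a dosage matrix with NA for missing.
#' @param missing_policy `"state"` keeps no-calls as a dedicated fourth state;
#'   `"zero"` collapses them to the homozygous-other state.
#' @return integer matrix of state codes in 0..3 (0..2 under `"zero"`).
#' @export
dosage_states <- function(G, missing_policy = c("state", "zero")) {
  missing_policy <- match.arg(missing_policy)
  d <- if (inherits(G, "genotype_matrix")) G$dosages else as.matrix(G)
  s <- d
  storage.mode(s) <- "integer"
  if (missing_policy == "state") s[is.na(s)] <- MISSING_STATE
  else s[is.na(s)] <- 0L
  s
}

#' Initialise embedding-layer parameters
#'
#' `E` (V x d) is shared across all SNPs and diseases; `P` (one row per panel
#' variant) is a learned per-SNP identity/positional term added to `E x`;
#' `W_Q`, `W_K`, `W_V` (d x d) are the attention projections, shared across
#' all 22 chromosomes; `null_tok` (22 x d) holds one learned token per
#' chromosome, returned as the pooled summary when a chromosome carries no
#' panel variants.
#'
#' @param n_variants panel variant count.
#' @param d embedding dimension.
#' @param V number of allele states (3 or 4).
#' @param seed RNG seed.
#' @return named list of parameter matrices.
#' @export
init_embedding_params <- function(n_variants, d, V = 4L, seed = 1L) {
  set.seed(seed)
  list(E = matrix(rnorm(V * d, sd = 0.5), V, d),
       P = matrix(rnorm(n_variants * d, sd = 0.5), n_variants, d),
       Wq = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d),
       Wk = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d),
       Wv = matrix(rnorm(d * d, sd = 1 / sqrt(d)), d, d),
       null_tok = matrix(rnorm(N_CHROM * d, sd = 0.5), N_CHROM, d))
}

#' Embed the SNPs of one chromosome
#'
#' Representation modes:
#' \describe{
#'   \item{chromosome_wise}{`e_k = E x_k + P[col_k, ]` (shared state table
#'     plus per-SNP identity); attention runs within the chromosome.}
#'   \item{global_snp}{`e_k = E x_k` only; attention runs over the whole
#'     panel rather than per chromosome.}
#'   \item{independent_snp}{a separate V x d table per SNP, no attention.}
#'   \item{one_hot}{the raw one-hot vector padded (or truncated) to width d;
#'     no learned parameters, no attention.}
#' }
#'
#' @param states integer vector of allele-state codes (0..V-1) for the
#'   chromosome's SNPs, in ascending-position order.
#' @param cols panel column indices of those SNPs (selects rows of `P` or the
#'   per-SNP tables).
#' @param params parameter list from [init_embedding_params()]; for
#'   `independent_snp` a list with `E_ind`, an (n_variants * V) x d matrix of
#'   stacked per-SNP tables.
#' @param mode one of the four representation modes.
#' @param d embedding dimension (needed for `one_hot`).
#' @param V number of allele states.
#' @return m x d matrix of SNP embeddings e_jk.
#' @export
embed_snps <- function(states, cols, params, mode = "chromosome_wise",
                       d = ncol(params$E), V = 4L) {
  assert_that(mode %in% c("chromosome_wise", "global_snp", "independent_snp",
                          "one_hot"),
              "embed_snps: unknown representation mode '%s'", mode)
  m <- length(states)
  if (m == 0L) return(matrix(0, 0L, d))
  assert_that(all(states >= 0L & states < V), "embed_snps: state code outside 0..V-1")
  switch(mode,
    chromosome_wise = params$E[states + 1L, , drop = FALSE] +
      params$P[cols, , drop = FALSE],
    global_snp = params$E[states + 1L, , drop = FALSE],
    independent_snp = params$E_ind[(cols - 1L) * V + states + 1L, , drop = FALSE],
    one_hot = {
      X <- matrix(0, m, d)
      keep <- which(states + 1L <= d)
      X[cbind(keep, states[keep] + 1L)] <- 1
      X
    })
}

row_softmax <- function(L) {
  # max-subtraction for numerical stability
  M <- L - apply(L, 1, max)
  E <- exp(M)
  E / rowSums(E)
}

#' Single-head self-attention over the SNPs of one chromosome
#'
#' `q_k = W_Q e_k`, `k_l = W_K e_l`, `v_l = W_V e_l`;
#' `alpha_kl = softmax_l(q_k . k_l / sqrt(d))`; `h_k = sum_l alpha_kl v_l`.
#' The sqrt(d) divisor is the usual scaling that stabilises training; rows of
#' `alpha` are probability distributions.
#'
#' @param Ej m x d matrix of SNP embeddings (rows e_jk).
#' @param params list with `Wq`, `Wk`, `Wv` (d x d).
#' @return list with `alpha` (m x m attention weights) and `H` (m x d
#'   contextualised embeddings).
#' @export
chromosome_self_attention <- function(Ej, params) {
  Ej <- as.matrix(Ej)
  m <- nrow(Ej); d <- ncol(Ej)
  assert_that(m >= 1L, "chromosome_self_attention: need m >= 1")
  assert_that(all(is.finite(Ej)), "chromosome_self_attention: non-finite input")
  Q <- Ej %*% t(params$Wq)
  K <- Ej %*% t(params$Wk)
  V <- Ej %*% t(params$Wv)
  alpha <- row_softmax(Q %*% t(K) / sqrt(d))
  list(alpha = alpha, H = alpha %*% V)
}

#' Mean-pool contextualised SNP embeddings into a chromosome summary
#'
#' @param H m x d matrix (m may be 0).
#' @param null_token length-d vector returned verbatim when the chromosome is
#'   empty (a learned per-chromosome parameter).
#' @return length-d summary h_j.
#' @export
pool_chromosome <- function(H, null_token) {
  H <- as.matrix(H)
  if (nrow(H) == 0L) return(as.numeric(null_token))
  colMeans(H)
}

#' Stack 22 chromosome summaries into the chromosome-aware representation Z
#'
#' @param h_list list of exactly 22 length-d summaries, in chromosome order.
#' @return 22 x d matrix Z; row j is chromosome j's summary. Z always has 22
#'   rows regardless of panel composition.
#' @export
assemble_representation <- function(h_list) {
  assert_that(length(h_list) == N_CHROM,
              "assemble_representation: need exactly 22 chromosome summaries, got %d",
              length(h_list))
  d <- length(h_list[[1L]])
  assert_that(all(vapply(h_list, length, integer(1)) == d),
              "assemble_representation: summaries differ in length")
  Z <- do.call(rbind, lapply(h_list, as.numeric))
  rownames(Z) <- paste0("chr", seq_len(N_CHROM))
  Z
}

#' Full embedding-layer forward pass for a batch (reference implementation)
#'
#' Computes Z (n x 22 x d) for every sample by composing [embed_snps()],
#' [chromosome_self_attention()], [pool_chromosome()] and
#' [assemble_representation()]. Plain R; used for contract tests and small
#' inputs. Training uses the compiled equivalent.
#'
#' @param states integer n x p matrix of allele-state codes.
#' @param groups chromosome grouping from [group_by_chromosome()].
#' @param params embedding parameters ([init_embedding_params()], plus
#'   `E_ind` for `independent_snp` mode).
#' @param mode representation mode (see [embed_snps()]).
#' @param d embedding dimension.
#' @param V allele-state count.
#' @return array n x 22 x d.
#' @export
chromosome_representation <- function(states, groups, params,
                                      mode = "chromosome_wise",
                                      d = ncol(params$E), V = 4L) {
  states <- as.matrix(states)
  n <- nrow(states)
  Z <- array(0, c(n, N_CHROM, d))
  null_tok <- params$null_tok %||% matrix(0, N_CHROM, d)
  for (i in seq_len(n)) {
    if (mode == "global_snp") {
      cols <- unlist(lapply(groups, `[[`, "cols"))
      Eall <- embed_snps(states[i, cols], cols, params, mode, d, V)
      H <- if (length(cols) > 0L)
        chromosome_self_attention(Eall, params)$H else Eall
      hs <- lapply(seq_len(N_CHROM), function(j) {
        rows <- which(cols %in% groups[[j]]$cols)
        if (length(rows) == 0L) null_tok[j, ] else colMeans(H[rows, , drop = FALSE])
      })
    } else {
      hs <- lapply(seq_len(N_CHROM), function(j) {
        g <- groups[[j]]
        if (g$m == 0L) {
          if (mode == "one_hot") return(numeric(d)) else return(null_tok[j, ])
        }
        Ej <- embed_snps(states[i, g$cols], g$cols, params, mode, d, V)
        H <- if (mode %in% c("chromosome_wise")) {
          chromosome_self_attention(Ej, params)$H
        } else Ej
        pool_chromosome(H, null_tok[j, ])
      })
    }
    Z[i, , ] <- assemble_representation(hs)
  }
  Z
}
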