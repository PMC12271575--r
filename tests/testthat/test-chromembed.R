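test_that("allele states one-hot encode with a dedicated missing state", {
  expect_equal(encode_allele_state(1, 3L), c(0, 1, 0))
  expect_equal(encode_allele_state(0, 4L), c(1, 0, 0, 0))
  expect_equal(encode_allele_state(NA, 4L), c(0, 0, 0, 1))
  expect_error(encode_allele_state(NA, 3L), "V = 3")
  for (v in c(3L, 4L)) for (dose in 0:2) {
    x <- encode_allele_state(dose, v)
    expect_equal(sum(x), 1)
    expect_equal(which(x == 1) - 1L, dose)
  }
})

test_that("dosage_states applies the missing policy", {
  d <- matrix(c(0L, 1L, 2L, NA), 2, 2)
  expect_equal(dosage_states(d, "state")[2, 2], 3L)
  expect_equal(dosage_states(d, "zero")[2, 2], 0L)
})

test_that("embed_snps realises the four representation modes", {
  d <- 6L; V <- 4L
  params <- init_embedding_params(10L, d, V, seed = 1)
  # P = 0: a one-hot state selects a row of E
  p0 <- params; p0$P <- matrix(0, 10, d)
  e <- embed_snps(states = 1L, cols = 4L, p0, "chromosome_wise")
  expect_equal(as.numeric(e), params$E[2, ])
  # positional term breaks ties between identical dosages
  e2 <- embed_snps(c(1L, 1L), c(2L, 3L), params, "chromosome_wise")
  expect_false(isTRUE(all.equal(e2[1, ], e2[2, ])))
  # global mode: identical dosages share one vector
  e3 <- embed_snps(c(1L, 1L), c(2L, 3L), params, "global_snp")
  expect_equal(e3[1, ], e3[2, ])
  # independent mode: separate tables per SNP
  pi <- list(E_ind = matrix(rnorm(10 * V * d), 10 * V, d))
  e4 <- embed_snps(c(2L, 2L), c(1L, 2L), pi, "independent_snp", d = d)
  expect_equal(e4[1, ], pi$E_ind[3, ])
  expect_equal(e4[2, ], pi$E_ind[V + 3, ])
  # one-hot padding to width d
  e5 <- embed_snps(c(0L, 3L), c(1L, 2L), list(), "one_hot", d = d)
  expect_equal(e5[1, ], c(1, rep(0, d - 1)))
  expect_equal(e5[2, ], c(0, 0, 0, 1, 0, 0))
  expect_error(embed_snps(1L, 1L, params, "banana"), "unknown representation")
})

test_that("self-attention matches the displayed equation on edge cases", {
  d <- 5L
  params <- init_embedding_params(4L, d, seed = 2)
  # singleton softmax
  e1 <- matrix(rnorm(d), 1, d)
  out <- chromosome_self_attention(e1, params)
  expect_equal(out$alpha, matrix(1, 1, 1))
  expect_equal(as.numeric(out$H), as.numeric(params$Wv %*% e1[1, ]))
  # equal logits from identical embeddings
  e5 <- matrix(rep(rnorm(d), 5), 5, d, byrow = TRUE)
  out5 <- chromosome_self_attention(e5, params)
  expect_equal(out5$alpha, matrix(0.2, 5, 5))
  expect_error(chromosome_self_attention(matrix(c(1, NaN), 1, 2), params),
               "non-finite")
})

test_that("attention rows are probability distributions and match the oracle", {
  set.seed(3)
  for (rep in 1:10) {
    m <- sample(1:8, 1); d <- sample(2:16, 1)
    params <- list(Wq = matrix(rnorm(d * d), d, d),
                   Wk = matrix(rnorm(d * d), d, d),
                   Wv = matrix(rnorm(d * d), d, d))
    Ej <- matrix(rnorm(m * d), m, d)
    out <- chromosome_self_attention(Ej, params)
    expect_true(all(abs(rowSums(out$alpha) - 1) < 1e-6))
    expect_true(all(out$alpha > 0 & out$alpha < 1 + 1e-12))
    oracle <- attention_oracle(Ej, params$Wq, params$Wk, params$Wv)
    expect_lt(max(abs(out$H - oracle$H)), 1e-10)
    expect_lt(max(abs(out$alpha - oracle$alpha)), 1e-10)
  }
})

test_that("the sqrt(d) divisor reduces to 1 at d = 1", {
  params <- list(Wq = matrix(2), Wk = matrix(3), Wv = matrix(1))
  Ej <- matrix(c(0.5, -1), 2, 1)
  out <- chromosome_self_attention(Ej, params)
  logits <- (2 * Ej[, 1]) %o% (3 * Ej[, 1])   # q k^T / sqrt(1)
  manual <- exp(logits - apply(logits, 1, max))
  manual <- manual / rowSums(manual)
  expect_equal(out$alpha, manual, tolerance = 1e-12)
})

test_that("pooling averages rows and falls back to the null token", {
  v <- rnorm(4)
  H <- rbind(v, v, v)
  expect_equal(pool_chromosome(H, rep(9, 4)), v)
  H2 <- rbind(rep(0, 4), rep(2, 4))
  expect_equal(pool_chromosome(H2, rep(9, 4)), rep(1, 4))
  expect_equal(pool_chromosome(matrix(0, 0, 4), c(7, 8, 9, 10)), c(7, 8, 9, 10))
})

test_that("Z assembles 22 rows in chromosome order", {
  d <- 4L
  hs <- lapply(1:22, function(j) rep(j, d))
  Z <- assemble_representation(hs)
  expect_equal(dim(Z), c(22L, 4L))
  expect_equal(Z[13, ], rep(13, d))
  hs2 <- hs; hs2[[3]] <- hs[[4]]; hs2[[4]] <- hs[[3]]
  Z2 <- assemble_representation(hs2)
  expect_equal(Z2[3, ], Z[4, ]); expect_equal(Z2[4, ], Z[3, ])
  expect_equal(Z2[-(3:4), ], Z[-(3:4), ])
  expect_error(assemble_representation(hs[1:21]), "22")
  expect_true(all(assemble_representation(lapply(1:22, function(j) rep(0, d))) == 0))
})

test_that("permuting states across a chromosome's SNPs is invisible without P", {
  # P = 0 leaves SNPs interchangeable: shuffling which SNP carries which
  # allele state preserves the embedding multiset, hence the pooled h_j.
  # The per-SNP identity term P deliberately breaks that symmetry.
  w <- random_tiny_world(n = 2, seed = 5)
  d <- 6L
  params <- init_embedding_params(ncol(w$states), d, seed = 6)
  params0 <- params; params0$P <- matrix(0, ncol(w$states), d)
  states_perm <- w$states
  set.seed(51)
  for (g in w$groups) {
    if (g$m > 1L) states_perm[, g$cols] <- w$states[, sample(g$cols)]
  }
  expect_false(identical(states_perm, w$states))
  Z1 <- chromosome_representation(w$states, w$groups, params0)
  Z2 <- chromosome_representation(states_perm, w$groups, params0)
  expect_lt(max(abs(Z1 - Z2)), 1e-10)
  # with P enabled the invariance is deliberately broken
  Z3 <- chromosome_representation(w$states, w$groups, params)
  Z4 <- chromosome_representation(states_perm, w$groups, params)
  expect_gt(max(abs(Z3 - Z4)), 1e-4)
})

test_that("compiled representation equals the R reference in every mode", {
  w <- random_tiny_world(n = 3, seed = 7)
  p <- ncol(w$states)
  for (mode in c("chromosome_wise", "global_snp", "independent_snp", "one_hot")) {
    cfg <- model_config(mode = mode, d = 8L)
    params <- init_model_params(p, cfg, seed = 8)
    Zr <- chromosome_representation(w$states, w$groups, params, mode = mode,
                                    d = 8L)
    Zc <- model_representation(list(params = params, cfg = cfg,
                                    groups = w$groups), w$states)
    expect_lt(max(abs(Zr - Zc)), 1e-12)
  }
})

test_that("missing genotypes flow through as the fourth state", {
  panel <- tiny_panel()
  d <- matrix(c(0L, NA, 2L, 1L, NA, 0L, 1L, 2L), 2, 4)
  G <- genotype_matrix(d, c("a", "b"), panel)
  states <- dosage_states(G)
  expect_equal(states[is.na(d)], rep(3L, 2))
  cfg <- model_config(d = 4L)
  params <- init_model_params(4L, cfg, seed = 9)
  groups <- group_by_chromosome(panel)
  Z <- chromosome_representation(states, groups, params)
  expect_true(all(is.finite(Z)))
})
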