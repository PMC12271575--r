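# Shared test utilities: tiny panels, text fixtures written to tempfiles,
# and brute-force oracles kept deliberately independent of the package's
# vectorised implementations.

tiny_panel <- function(chroms = c(1L, 1L, 2L, 7L), pos = c(100L, 500L, 50L, 10L),
                       weights = seq_along(chroms) / 10) {
  variant_panel(rsid = sprintf("rs%d", seq_along(chroms)),
                chrom = chroms, pos = pos,
                effect_allele = rep("G", length(chroms)),
                other_allele = rep("A", length(chroms)),
                effect_weight = weights,
                trait_tags = rep(list("IS"), length(chroms)))
}

write_scoring_file <- function(path, rows, tag_comment = TRUE) {
  # rows: data.frame rsID, chr_name, chr_position, effect_allele,
  #       other_allele, effect_weight
  lines <- c(if (tag_comment) c("# PGS-style scoring file", "# comment"),
             paste(names(rows), collapse = "\t"),
             apply(rows, 1, paste, collapse = "\t"))
  writeLines(lines, path)
  path
}

scoring_rows <- function(n, chrom = 1, start_pos = 1000) {
  data.frame(rsID = sprintf("rs%d_%d", chrom, seq_len(n)),
             chr_name = chrom,
             chr_position = start_pos + seq_len(n) * 10L,
             effect_allele = "G", other_allele = "A",
             effect_weight = round(seq_len(n) / 100, 3))
}

write_vcf_text <- function(path, samples, records) {
  # records: list of list(chrom, pos, id, ref, alt, gts = character vector)
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(records, function(r) {
    paste(c(r$chrom, r$pos, r$id, r$ref, r$alt, ".", "PASS", ".", "GT", r$gts),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# O(m^2 d) double-loop attention oracle, straight from the displayed equation
attention_oracle <- function(Ej, Wq, Wk, Wv) {
  m <- nrow(Ej); d <- ncol(Ej)
  q <- k <- v <- matrix(0, m, d)
  for (t in seq_len(m)) {
    q[t, ] <- Wq %*% Ej[t, ]
    k[t, ] <- Wk %*% Ej[t, ]
    v[t, ] <- Wv %*% Ej[t, ]
  }
  alpha <- matrix(0, m, m)
  for (kk in seq_len(m)) {
    logits <- numeric(m)
    for (l in seq_len(m)) logits[l] <- sum(q[kk, ] * k[l, ]) / sqrt(d)
    e <- exp(logits - max(logits))
    alpha[kk, ] <- e / sum(e)
  }
  H <- matrix(0, m, d)
  for (kk in seq_len(m))
    for (l in seq_len(m)) H[kk, ] <- H[kk, ] + alpha[kk, l] * v[l, ]
  list(alpha = alpha, H = H)
}

# brute-force AUROC: enumerate all case-control pairs
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force Harrell's C: enumerate permissible pairs
c_index_oracle <- function(scores, age, event) {
  n <- length(scores); num <- 0; den <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    for (j in seq_len(n)) {
      if (age[j] > age[i]) {
        den <- den + 1
        if (scores[i] > scores[j]) num <- num + 1
        else if (scores[i] == scores[j]) num <- num + 0.5
      }
    }
  }
  num / den
}

random_tiny_world <- function(n = 12, seed = 99) {
  spec <- spec_null(seed = seed)
  G <- simulate_genotypes(n, spec, seed = seed)
  list(spec = spec, G = G,
       states = dosage_states(G),
       groups = group_by_chromosome(G$panel))
}
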