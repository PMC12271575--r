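test_that("scoring panels merge by variant key with unioned trait tags", {
  f1 <- write_scoring_file(tempfile(fileext = ".txt"),
                           scoring_rows(1, chrom = 3))
  f2 <- write_scoring_file(tempfile(fileext = ".txt"),
                           scoring_rows(1, chrom = 3))
  panel <- read_scoring_panel(c(f1, f2), c("IS", "AF"))
  expect_equal(panel$n_variants, 1L)
  expect_equal(panel$variants$trait_tags[[1]], c("AF", "IS"))

  # six disjoint files -> union is the sum of their counts
  sizes <- c(10, 9, 8, 7, 6, 5)
  files <- mapply(function(n, chrom) {
    write_scoring_file(tempfile(fileext = ".txt"), scoring_rows(n, chrom))
  }, sizes, 1:6)
  panel6 <- read_scoring_panel(files, DISEASES)
  expect_equal(panel6$n_variants, 45L)
})

test_that("non-autosomal scoring rows are dropped with a logged count", {
  rows <- scoring_rows(2, chrom = 1)
  rows$chr_name <- c("1", "X")
  f <- write_scoring_file(tempfile(fileext = ".txt"), rows)
  expect_message(panel <- read_scoring_panel(f, "IS"), "1 non-autosomal")
  expect_equal(panel$n_variants, 1L)
  expect_equal(panel$variants$chrom, 1L)
})

test_that("missing mandatory scoring columns name the file and column", {
  rows <- scoring_rows(2)
  rows$effect_weight <- NULL
  f <- write_scoring_file(tempfile(fileext = ".txt"), rows)
  expect_error(read_scoring_panel(f, "IS"), "effect_weight")
  expect_error(read_scoring_panel(f, "IS"), basename(f))
})

test_that("duplicate-weight conflicts keep the first file's weight", {
  r1 <- scoring_rows(1); r2 <- scoring_rows(1)
  r2$effect_weight <- 0.9
  f1 <- write_scoring_file(tempfile(fileext = ".txt"), r1)
  f2 <- write_scoring_file(tempfile(fileext = ".txt"), r2)
  expect_message(panel <- read_scoring_panel(c(f1, f2), c("IS", "HT")),
                 "conflicting weights")
  expect_equal(panel$variants$effect_weight, r1$effect_weight)
})

test_that("variant_panel rejects sex chromosomes and duplicate keys", {
  expect_error(variant_panel("rs1", 23L, 1L, "G", "A", 0.1, list("IS")),
               "1\\.\\.22")
  expect_error(tiny_panel(chroms = c(1L, 1L), pos = c(5L, 5L)), "duplicate")
})

test_that("VCF genotypes map to effect-allele dosages", {
  panel <- variant_panel(rsid = c("v1", "v2", "v3"),
                         chrom = c(1L, 1L, 2L), pos = c(100L, 200L, 300L),
                         effect_allele = c("G", "A", "G"),
                         other_allele = c("A", "G", "A"),
                         effect_weight = c(0.1, 0.2, 0.3),
                         trait_tags = list("IS", "IS", "IS"))
  # v1: effect == ALT; v2: effect == REF (flip); v3: phase + missing calls
  vcf <- write_vcf_text(tempfile(fileext = ".vcf"), c("s1", "s2", "s3"),
    list(list(chrom = 1, pos = 100, id = "v1", ref = "A", alt = "G",
              gts = c("0/0", "0/1", "1/1")),
         list(chrom = 1, pos = 200, id = "v2", ref = "A", alt = "G",
              gts = c("0/0", "0/1", "1/1")),
         list(chrom = 2, pos = 300, id = "v3", ref = "A", alt = "G",
              gts = c("0|1", "./.", "./1"))))
  G <- read_genotypes_vcf(vcf, panel)
  expect_equal(unname(G$dosages[, 1]), c(0L, 1L, 2L))   # ALT count
  expect_equal(unname(G$dosages[, 2]), c(2L, 1L, 0L))   # flipped: effect = REF
  expect_equal(unname(G$dosages[, 3]), c(1L, NA, NA))   # phased; no-call; half-call
})

test_that("unmatched, mismatched and multi-allelic sites give missing columns", {
  panel <- variant_panel(rsid = c("a", "b", "c"),
                         chrom = c(1L, 1L, 1L), pos = c(10L, 20L, 30L),
                         effect_allele = c("G", "T", "G"),
                         other_allele = c("A", "C", "A"),
                         effect_weight = rep(0.1, 3), trait_tags = list("IS", "IS", "IS"))
  vcf <- write_vcf_text(tempfile(fileext = ".vcf"), "s1",
    list(list(chrom = 1, pos = 20, id = "b", ref = "A", alt = "G", gts = "0/1"),
         list(chrom = 1, pos = 30, id = "c", ref = "A", alt = "G,T", gts = "0/1")))
  expect_warning(expect_warning(expect_warning(
    G <- read_genotypes_vcf(vcf, panel),
    "absent from VCF"), "allele mismatch"), "multi-allelic")
  expect_true(all(is.na(G$dosages)))
})

test_that("align_effect_allele flips and is an involution when effect is REF", {
  expect_equal(align_effect_allele(2L, TRUE), 0L)
  expect_equal(align_effect_allele(1L, TRUE), 1L)
  expect_equal(align_effect_allele(0L, FALSE), 0L)
  for (dose in 0:2)
    expect_equal(align_effect_allele(align_effect_allele(dose, TRUE), TRUE), dose)
})

test_that("chromosome groups partition the panel in position order", {
  panel <- tiny_panel(chroms = c(3L, 3L, 1L, 9L), pos = c(500L, 100L, 7L, 1L))
  groups <- group_by_chromosome(panel)
  expect_length(groups, 22L)
  expect_equal(vapply(groups, `[[`, integer(1), "m")[c(1, 3, 9)], c(1L, 2L, 1L))
  expect_equal(sum(vapply(groups, `[[`, integer(1), "m")), panel$n_variants)
  # every column in exactly one group
  all_cols <- sort(unlist(lapply(groups, `[[`, "cols")))
  expect_equal(all_cols, seq_len(panel$n_variants))
  # within chromosome 3, the pos-100 column precedes pos-500
  g3 <- groups[[3]]
  expect_equal(panel$variants$pos[g3$cols], c(100L, 500L))

  one_chrom <- tiny_panel(chroms = rep(7L, 3), pos = c(3L, 2L, 1L))
  g <- group_by_chromosome(one_chrom)
  expect_equal(vapply(g, `[[`, integer(1), "m"),
               as.integer(seq_len(22) == 7) * 3L)
})

test_that("VCF round trip reproduces dosages exactly", {
  w <- random_tiny_world(n = 8, seed = 4)
  d <- w$G$dosages
  d[1, 3] <- NA  # plant a no-call
  G <- genotype_matrix(d, w$G$sample_ids, w$G$panel)
  path <- tempfile(fileext = ".vcf")
  write_genotypes_vcf(G, path)
  G2 <- read_genotypes_vcf(path, w$G$panel)
  expect_identical(unname(G2$dosages), unname(G$dosages))
  expect_equal(G2$sample_ids, G$sample_ids)
})

test_that("phenotype tables round-trip", {
  spec <- spec_null(seed = 2)
  sim <- simulate_cohort(20, spec)
  path <- tempfile(fileext = ".tsv")
  write_phenotypes(sim$cohort, path)
  back <- read_phenotypes(path)
  expect_equal(back$sample_id, sim$cohort$sample_id)
  expect_equal(as.matrix(back[, DISEASES]), as.matrix(sim$cohort[, DISEASES]))
  expect_equal(back$age_end, sim$cohort$age_end, tolerance = 1e-9)
})

test_that("genotype_matrix validates entries and shapes", {
  panel <- tiny_panel()
  expect_error(genotype_matrix(matrix(3L, 2, 4), c("a", "b"), panel), "0, 1, 2")
  expect_error(genotype_matrix(matrix(0L, 2, 3), c("a", "b"), panel),
               "column count")
})
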