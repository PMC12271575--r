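# Reading scoring panels and VCF genotypes, allele-state encoding, and
# chromosome grouping. External coordinates are 1-based VCF positions;
# internal column indices are the panel order.

#' Construct a variant panel
#'
#' A variant panel is the union of per-disease SNP lists: one row per variant
#' with chromosome, position, effect/other allele, a per-allele log-scale
#' effect weight, and the set of disease tags that contributed the variant.
#'
#' @param rsid character vector of variant identifiers (reporting only;
#'   matching is positional).
#' @param chrom integer chromosome in 1..22; non-autosomal variants are not
#'   admitted.
#' @param pos integer 1-based base-pair position.
#' @param effect_allele,other_allele allele strings; the dosage counts copies
#'   of `effect_allele`.
#' @param effect_weight numeric per-allele weight (used by the PRS baseline
#'   only, not by the network).
#' @param trait_tags list of character vectors, each a subset of [DISEASES].
#' @return An object of class `variant_panel`: a list with a `variants`
#'   data.frame and `n_variants`. Rows are sorted by (chrom, pos); the sorted
#'   order defines genotype-matrix column order.
#' @export
variant_panel <- function(rsid, chrom, pos, effect_allele, other_allele,
                          effect_weight, trait_tags) {
  chrom <- as.integer(chrom)
  pos <- as.integer(pos)
  assert_that(all(chrom >= 1L & chrom <= N_CHROM),
              "variant_panel: chrom must be in 1..22 (sex chromosomes rejected)")
  assert_that(length(rsid) == length(chrom) && length(pos) == length(chrom),
              "variant_panel: field lengths differ")
  if (is.character(trait_tags)) trait_tags <- as.list(trait_tags)
  assert_that(all(unlist(trait_tags) %in% DISEASES),
              "variant_panel: unknown trait tag")
  key <- paste(chrom, pos, effect_allele, other_allele, sep = ":")
  assert_that(!anyDuplicated(key),
              "variant_panel: duplicate (chrom, pos, alleles) record")
  v <- data.frame(rsid = as.character(rsid), chrom = chrom, pos = pos,
                  effect_allele = as.character(effect_allele),
                  other_allele = as.character(other_allele),
                  effect_weight = as.numeric(effect_weight),
                  stringsAsFactors = FALSE)
  v$trait_tags <- trait_tags
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]
  rownames(v) <- NULL
  structure(list(variants = v, n_variants = nrow(v)), class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("<variant_panel> %d variants on %d chromosomes\n",
              x$n_variants, length(unique(x$variants$chrom))))
  invisible(x)
}

read_one_scoring_file <- function(path, tag) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#")]
  assert_that(length(lines) >= 1L, "scoring file '%s' is empty", path)
  dt <- data.table::fread(text = paste(lines, collapse = "\n"), sep = "\t",
                          header = TRUE, colClasses = "character")
  mandatory <- c("chr_name", "chr_position", "effect_allele", "effect_weight")
  for (col in mandatory) {
    if (!col %in% names(dt))
      stop_mg("scoring file '%s' lacks mandatory column '%s'", path, col)
  }
  chrom_raw <- as.character(dt[["chr_name"]])
  autosomal <- grepl("^(chr)?([1-9]|1[0-9]|2[0-2])$", chrom_raw)
  n_dropped <- sum(!autosomal)
  if (n_dropped > 0L)
    message(sprintf("read_scoring_panel: dropped %d non-autosomal variant(s) from '%s'",
                    n_dropped, basename(path)))
  dt <- dt[autosomal, ]
  data.frame(
    rsid = if ("rsID" %in% names(dt)) as.character(dt[["rsID"]]) else NA_character_,
    chrom = as.integer(sub("^chr", "", as.character(dt[["chr_name"]]))),
    pos = as.integer(dt[["chr_position"]]),
    effect_allele = as.character(dt[["effect_allele"]]),
    other_allele = if ("other_allele" %in% names(dt))
      as.character(dt[["other_allele"]]) else NA_character_,
    effect_weight = as.numeric(dt[["effect_weight"]]),
    tag = tag, stringsAsFactors = FALSE)
}

#' Read PGS-Catalog-style scoring files into a deduplicated variant panel
#'
#' Each file is a tab-separated scoring file with a header row (columns
#' `rsID`, `chr_name`, `chr_position`, `effect_allele`, `other_allele`,
#' `effect_weight`; `#`-prefixed metadata lines are ignored) and contributes
#' one disease tag. Variants appearing in several files are merged by the key
#' (chrom, pos, effect allele, other allele): trait tags are unioned and the
#' first file's effect weight is kept (a differing later weight is logged).
#' Non-autosomal records are dropped with a logged count.
#'
#' @param paths character vector of file paths.
#' @param trait_tags character vector, one disease tag per file.
#' @return A [variant_panel].
#' @export
read_scoring_panel <- function(paths, trait_tags) {
  assert_that(length(paths) == length(trait_tags),
              "read_scoring_panel: one trait tag per file required")
  assert_that(all(trait_tags %in% DISEASES), "read_scoring_panel: unknown trait tag")
  parts <- mapply(read_one_scoring_file, paths, trait_tags,
                  SIMPLIFY = FALSE, USE.NAMES = FALSE)
  all <- do.call(rbind, parts)
  assert_that(nrow(all) > 0L, "read_scoring_panel: empty union of scoring files")
  key <- paste(all$chrom, all$pos, all$effect_allele, all$other_allele, sep = ":")
  first <- !duplicated(key)
  tags <- lapply(split(all$tag, key), function(t) sort(unique(t)))
  w_by_key <- split(all$effect_weight, key)
  n_conflict <- sum(vapply(w_by_key, function(w) length(unique(w)) > 1L, logical(1)))
  if (n_conflict > 0L)
    message(sprintf("read_scoring_panel: %d variant(s) had conflicting weights; kept first file's weight",
                    n_conflict))
  u <- all[first, , drop = FALSE]
  variant_panel(rsid = u$rsid, chrom = u$chrom, pos = u$pos,
                effect_allele = u$effect_allele, other_allele = u$other_allele,
                effect_weight = u$effect_weight,
                trait_tags = unname(tags[key[first]]))
}

#' Construct a genotype matrix
#'
#' @param dosages integer matrix, samples x variants, entries 0/1/2 or `NA`
#'   (missing genotype). Column order must equal panel order.
#' @param sample_ids character vector of row identifiers.
#' @param panel a [variant_panel].
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, sample_ids, panel) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  assert_that(inherits(panel, "variant_panel"), "panel must be a variant_panel")
  assert_that(ncol(dosages) == panel$n_variants,
              "genotype_matrix: column count (%d) != panel variant count (%d)",
              ncol(dosages), panel$n_variants)
  assert_that(length(sample_ids) == nrow(dosages),
              "genotype_matrix: sample_ids length mismatch")
  vals <- dosages[!is.na(dosages)]
  assert_that(all(vals %in% 0:2), "genotype_matrix: dosages must be 0, 1, 2 or NA")
  dimnames(dosages) <- list(as.character(sample_ids), panel$variants$rsid)
  structure(list(dosages = dosages, sample_ids = as.character(sample_ids),
                 panel = panel), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d variants (%.2f%% missing)\n",
              nrow(x$dosages), ncol(x$dosages),
              100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' Orient a raw ALT-allele dosage onto the effect allele
#'
#' VCF genotypes count ALT copies; when the panel's effect allele is the REF
#' allele the count must be flipped. An involution when `effect_is_ref`.
#'
#' @param raw_dosage integer vector in 0/1/2 (NA passed through).
#' @param effect_is_ref logical; is the effect allele the VCF REF allele?
#' @return dosage of the effect allele.
#' @export
align_effect_allele <- function(raw_dosage, effect_is_ref) {
  assert_that(all(raw_dosage[!is.na(raw_dosage)] %in% 0:2),
              "align_effect_allele: raw dosage outside 0..2")
  if (isTRUE(effect_is_ref)) 2L - as.integer(raw_dosage) else as.integer(raw_dosage)
}

gt_to_alt_count <- function(gt) {
  # "0/1", "1|0", "./.", ".", "0/." -> ALT copies or NA (half-calls missing)
  alleles <- strsplit(gt, "[/|]", perl = TRUE)
  vapply(alleles, function(a) {
    if (length(a) != 2L || any(a == ".")) return(NA_integer_)
    suppressWarnings(ai <- as.integer(a))
    if (anyNA(ai)) return(NA_integer_)
    sum(ai == 1L)
  }, integer(1))
}

#' Read genotypes from a VCF against a variant panel
#'
#' Variants are matched by (chromosome, position); alleles are then verified:
#' the panel's effect allele must be the site's REF or ALT allele. Dosage is
#' the per-sample count of effect-allele copies taken from the GT field
#' (phase ignored); `./.` and half-calls become missing. When GT is absent the
#' DS field is used, rounded to the nearest value in 0..2. Panel variants
#' absent from the VCF, multi-allelic sites, and allele mismatches yield fully
#' missing columns with a warning.
#'
#' @param path VCF file (plain text or bgzipped).
#' @param panel a [variant_panel].
#' @return A [genotype_matrix] with columns in panel order.
#' @export
read_genotypes_vcf <- function(path, panel) {
  assert_that(file.exists(path), "read_genotypes_vcf: no such file '%s'", path)
  vcf <- tryCatch(
    VariantAnnotation::readVcf(path, genome = "unknown"),
    error = function(e) stop_mg("read_genotypes_vcf: failed to read '%s': %s",
                                path, conditionMessage(e)))
  rr <- SummarizedExperiment::rowRanges(vcf)
  vchrom <- sub("^chr", "", as.character(GenomeInfoDb::seqnames(rr)))
  vpos <- BiocGenerics::start(rr)
  vref <- as.character(rr$REF)
  alt_list <- rr$ALT
  samples <- colnames(vcf)
  n <- length(samples)
  g <- VariantAnnotation::geno(vcf)
  has_gt <- "GT" %in% names(g)
  has_ds <- "DS" %in% names(g)
  assert_that(has_gt || has_ds, "read_genotypes_vcf: VCF has neither GT nor DS")

  pv <- panel$variants
  out <- matrix(NA_integer_, nrow = n, ncol = nrow(pv))
  vcf_key <- paste(vchrom, vpos, sep = ":")
  for (i in seq_len(nrow(pv))) {
    hits <- which(vcf_key == paste(pv$chrom[i], pv$pos[i], sep = ":"))
    if (length(hits) == 0L) {
      warning(sprintf("panel variant %s (%d:%d) absent from VCF; column set missing",
                      pv$rsid[i], pv$chrom[i], pv$pos[i]), call. = FALSE)
      next
    }
    hit <- hits[1L]
    alts <- as.character(alt_list[[hit]])
    if (length(alts) != 1L) {
      warning(sprintf("multi-allelic site at %d:%d skipped", pv$chrom[i], pv$pos[i]),
              call. = FALSE)
      next
    }
    ref <- vref[hit]
    eff <- pv$effect_allele[i]
    if (!(eff %in% c(ref, alts))) {
      warning(sprintf("allele mismatch for %s at %d:%d (panel %s/%s, VCF %s/%s); column set missing",
                      pv$rsid[i], pv$chrom[i], pv$pos[i], eff, pv$other_allele[i],
                      ref, alts), call. = FALSE)
      next
    }
    if (has_gt) {
      raw <- gt_to_alt_count(as.character(g$GT[hit, ]))
    } else {
      ds <- as.numeric(g$DS[hit, ])
      raw <- as.integer(pmin(2, pmax(0, round(ds))))
      raw[is.na(ds)] <- NA_integer_
    }
    out[, i] <- align_effect_allele(raw, effect_is_ref = (eff == ref))
  }
  genotype_matrix(out, samples, panel)
}

#' Write a genotype matrix as a minimal VCF 4.2 file
#'
#' REF is the panel's other allele and ALT the effect allele, so that the
#' written ALT count equals the stored effect-allele dosage and a round trip
#' through [read_genotypes_vcf()] reproduces dosages exactly.
#'
#' @param G a [genotype_matrix].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(G, path) {
  pv <- G$panel$variants
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", G$sample_ids), collapse = "\t")), con)
  for (i in seq_len(nrow(pv))) {
    d <- G$dosages[, i]
    gt <- ifelse(is.na(d), "./.", gt_map[d + 1L])
    id <- if (is.na(pv$rsid[i])) "." else pv$rsid[i]
    writeLines(paste(c(pv$chrom[i], pv$pos[i], id, pv$other_allele[i],
                       pv$effect_allele[i], ".", "PASS", ".", "GT", gt),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Group panel variants by chromosome
#'
#' @param panel a [variant_panel].
#' @return A list of exactly 22 groups (one per autosome, in order). Each
#'   group is a list with `chrom`, `cols` (column indices into the genotype
#'   matrix, sorted by ascending position; possibly empty) and `m` (variant
#'   count, possibly 0).
#' @export
group_by_chromosome <- function(panel) {
  pv <- panel$variants
  lapply(seq_len(N_CHROM), function(j) {
    idx <- which(pv$chrom == j)
    idx <- idx[order(pv$pos[idx])]
    list(chrom = j, cols = as.integer(idx), m = length(idx))
  })
}

#' Read a phenotype/covariate table
#'
#' Tab- or comma-separated with a header. Mandatory columns: `sample_id` and
#' the six binary disease labels `IS, AF, CAD, T2D, HT, HCL`. Optional:
#' `age_end` (years), `event_is` (0/1) and `family_history` (0/1).
#'
#' @param path file path.
#' @return A data.frame of class `cohort_table` (see [cohort_table()]).
#' @export
read_phenotypes <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  assert_that("sample_id" %in% names(dt), "phenotype table lacks 'sample_id'")
  for (d in DISEASES)
    assert_that(d %in% names(dt), "phenotype table lacks label column '%s'", d)
  cohort_table(sample_ids = as.character(dt$sample_id),
               labels = as.matrix(dt[, DISEASES]),
               age_end = dt$age_end %||% NULL,
               event_is = dt$event_is %||% NULL,
               family_history = dt$family_history %||% NULL)
}

#' Write a cohort table to a tab-separated file
#' @param cohort a `cohort_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(cohort, path) {
  df <- as.data.frame(cohort)
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
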