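mk_records <- function(...) data.frame(..., stringsAsFactors = FALSE)

test_that("primary intrachromosomal filter keeps the strongest same-chromosome hit", {
  rec <- mk_records(
    trait = c("P1", "P1", "P1", "P2", "P2"),
    variant_chrom = c("chr1", "chr1", "chr7", "chr2", "chr2"),
    variant_pos = c(100, 5000, 200, 900, 1200),
    gene = c("G1", "G1", "G1", "G2", "G2"),
    gene_chrom = c("chr1", "chr1", "chr1", "chr2", "chr2"),
    gene_tss = c(1500, 1500, 1500, 1000, 1000),
    strength = c(8, 20, 50, 30, 10)
  )
  out <- filter_intrachromosomal_primary(rec)
  expect_equal(nrow(out), 2)
  expect_equal(out$strength, c(20, 30))  # strongest intrachromosomal each
  rej <- attr(out, "rejected")
  expect_equal(nrow(rec), nrow(out) + nrow(rej))
  expect_setequal(unique(rej$reason),
                  c("interchromosomal", "weaker_association"))
})

test_that("a cognate gene is kept only when unambiguous on the variant chromosome", {
  rec <- mk_records(
    trait = c("P1", "P1"),
    variant_chrom = c("chr3", "chr3"),
    variant_pos = c(500, 500),
    gene = c("G_A", "G_B"),
    gene_chrom = c("chr5", "chr3"),   # exactly one cognate gene on chr3
    gene_tss = c(100, 900),
    strength = c(12, 12)
  )
  out <- filter_intrachromosomal_primary(rec)
  expect_equal(out$gene, "G_B")
  # two candidate genes on the same chromosome -> ambiguous, dropped
  rec$gene_chrom <- c("chr3", "chr3")
  out2 <- filter_intrachromosomal_primary(rec)
  expect_equal(nrow(out2), 0)
  expect_true(all(attr(out2, "rejected")$reason == "ambiguous_cognate_gene"))
})

test_that("rank flags override strength and filtering matches a brute-force loop", {
  rec <- mk_records(
    trait = c("P1", "P1"),
    variant_chrom = "chr1", variant_pos = c(10, 20),
    gene = "G1", gene_chrom = "chr1", gene_tss = c(100, 100),
    strength = c(5, 50), rank = c("primary", "secondary")
  )
  out <- filter_intrachromosomal_primary(rec)
  expect_equal(out$strength, 5)  # the flagged primary wins despite weaker

  set.seed(42)
  n <- 60
  rnd <- mk_records(
    trait = sample(paste0("P", 1:12), n, replace = TRUE),
    variant_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    variant_pos = sample.int(1e6, n),
    gene = "G",
    gene_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    gene_tss = sample.int(1e6, n),
    strength = round(runif(n, 1, 100), 3)
  )
  expect_equal(filter_intrachromosomal_primary(rnd)[, names(rnd)],
               brute_primary_filter(rnd),
               ignore_attr = TRUE)
})

test_that("eQTL Z-score threshold is inclusive and keeps the top hit per gene", {
  rec <- mk_records(
    trait = c("E1", "E1", "E2", "E3"),
    strength = c(5.4485, -9.1, 5.4484, -5.4485),
    variant_pos = c(1, 2, 3, 4)
  )
  out <- filter_eqtl_zscore(rec)
  expect_setequal(out$trait, c("E1", "E3"))
  expect_equal(out$strength[out$trait == "E1"], -9.1)  # largest |Z|
  expect_equal(attr(out, "rejected")$reason,
               c("below_zscore_threshold", "weaker_association"))
  # manual check on ten scores
  z <- c(-12, 5.45, 5.44, 0, 8, -5.4485, 3, 20, -4, 6)
  rec10 <- mk_records(trait = paste0("G", 1:10), strength = z,
                      variant_pos = 1:10)
  expect_equal(filter_eqtl_zscore(rec10)$trait,
               paste0("G", which(abs(z) >= 5.4485)))
})

test_that("metabolite filter enforces single-gene chromosomes and strict p", {
  gene_map <- utils::read.delim(extdata("toy_metabolite_gene_map.tsv"),
                                stringsAsFactors = FALSE)
  rec <- mk_records(
    trait = c("M001", "M001", "M001", "M002", "M003"),
    variant_chrom = c("chr1", "chr2", "chr2", "chr3", "chr9"),
    variant_pos = c(100, 500100, 900000, 1500000, 5),
    pvalue = c(1e-20, 1e-12, 1e-9, 5e-8, 1e-30)
  )
  expect_warning(out <- filter_metabolite_single_gene(rec, gene_map),
                 "absent from")
  # M001 has two interacting genes on chr1 -> only its chr2 hits eligible,
  # strongest kept; M002's p = 5e-8 is not strictly below the cutoff
  expect_equal(nrow(out), 1)
  expect_equal(out$variant_pos, 500100)
  expect_equal(out$gene, "GENEZ")
  expect_equal(out$dist, abs(500100 - 750000))
  rej <- attr(out, "rejected")
  expect_equal(nrow(rec), nrow(out) + nrow(rej))
  expect_setequal(rej$reason,
                  c("metabolite_not_in_map", "not_single_interacting_gene",
                    "weaker_association", "p_value_not_below_threshold"))
})

test_that("distance derivation passes precomputed values through unchanged", {
  rec <- mk_records(
    trait = c("A", "B", "C"),
    variant_chrom = "chr1",
    variant_pos = c(1000, NA, NA),
    gene_tss = c(1500, NA, NA),
    dist = c(NA, 77, NA),
    strength = c(1, 2, 3)
  )
  out <- compute_distances(rec)
  expect_equal(out$dist, c(500, 77))
  expect_equal(attr(out, "rejected")$reason, "no_distance_information")
  expect_equal(names(out), c("trait", "chrom", "dist", "strength"))
})

test_that("filters are idempotent", {
  set.seed(7)
  n <- 40
  rec <- mk_records(
    trait = sample(paste0("P", 1:8), n, replace = TRUE),
    variant_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    variant_pos = sample.int(1e6, n),
    gene = "G",
    gene_chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
    gene_tss = sample.int(1e6, n),
    strength = runif(n, 1, 30)
  )
  once <- filter_intrachromosomal_primary(rec)
  twice <- filter_intrachromosomal_primary(once)
  expect_equal(once, twice, ignore_attr = TRUE)
  z_once <- filter_eqtl_zscore(rec)
  expect_equal(z_once, filter_eqtl_zscore(z_once), ignore_attr = TRUE)
})

test_that("study tables load through a YAML column schema", {
  tab <- read_study_table(extdata("toy_study_pqtl.tsv"),
                          extdata("toy_study_schema.yaml"))
  expect_true(all(c("trait", "variant_chrom", "variant_pos", "gene",
                    "gene_chrom", "gene_tss", "strength", "rank") %in%
                    names(tab)))
  expect_equal(nrow(tab), 7)
  bad <- list(columns = list(trait = "NoSuchColumn"))
  expect_error(read_study_table(extdata("toy_study_pqtl.tsv"), bad),
               "absent")
})
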