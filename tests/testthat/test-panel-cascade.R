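mk_sample <- function(id, keys, donor = "D1", treatment = "AAVS1",
                      timepoint = 4L, replicate = 1L, depth = 1000L,
                      alt = 500L, effect = NA_character_, mec = 3000) {
  if (length(keys) == 0L) {
    v <- genotoxscreen:::empty_variant_table()
  } else {
    parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
    v <- variant_table(parts[, 1L], as.integer(parts[, 2L]), parts[, 3L],
                       parts[, 4L], rep_len(alt, length(keys)),
                       rep_len(depth, length(keys)), effect = effect)
  }
  sample_record(id, donor, treatment, timepoint, replicate, v, mec)
}

test_that("reproducible set is the replicate intersection with union-denominator concordance", {
  a <- mk_sample("r1", c("chr1:1:A:G", "chr1:2:C:T"), replicate = 1L)
  b <- mk_sample("r2", c("chr1:1:A:G", "chr1:2:C:T"), replicate = 2L)
  c3 <- mk_sample("r3", c("chr1:1:A:G"), replicate = 3L)

  full <- reproducible_variants(list(a, b, mk_sample("r3b",
                                                     c("chr1:1:A:G", "chr1:2:C:T"),
                                                     replicate = 3L)))
  expect_equal(full$concordance, 1.0)
  expect_equal(nrow(full$variants), 2L)

  part <- reproducible_variants(list(a, b, c3))
  expect_equal(part$concordance, 0.5)
  expect_identical(variant_key(part$variants), "chr1:1:A:G")
  # pooled counts are summed across replicates
  expect_identical(part$variants$depth, 3000L)
  expect_identical(part$variants$alt_reads, 1500L)

  disjoint <- reproducible_variants(list(
    mk_sample("x1", "chr1:1:A:G", replicate = 1L),
    mk_sample("x2", "chr1:2:C:T", replicate = 2L)))
  expect_equal(disjoint$concordance, 0)
  expect_equal(nrow(disjoint$variants), 0L)

  single <- reproducible_variants(list(a))
  expect_equal(single$concordance, 1.0)
  expect_equal(nrow(single$variants), 2L)

  expect_error(reproducible_variants(list(a, mk_sample("y", "chr1:1:A:G",
                                                       donor = "D2"))),
               "mixed")
})

test_that("synonymous filter removes only positively synonymous variants", {
  v <- variant_table(rep("chr1", 3L), 1:3, c("A", "C", "GT"),
                     c("G", "T", "G"), c(1L, 1L, 1L), c(10L, 10L, 10L),
                     effect = c("synonymous", "missense", "frameshift"))
  out <- filter_synonymous(v)
  expect_setequal(out$effect, c("missense", "frameshift"))
  expect_equal(nrow(filter_synonymous(v[v$effect == "synonymous", ])), 0L)
  # unannotated variants pass with a warning (fail-open)
  v$effect[1L] <- NA
  expect_warning(out2 <- filter_synonymous(v), "fail-open")
  expect_equal(nrow(out2), 3L)
})

test_that("germline filter boundary is strict: count 10 retained, 11 removed", {
  v <- variant_table(rep("chr1", 3L), 1:3, rep("A", 3L), rep("G", 3L),
                     rep(1L, 3L), rep(10L, 3L))
  db <- data.frame(chrom = rep("chr1", 2L), pos = 1:2, ref = "A", alt = "G",
                   occurrence_count = c(11L, 10L))
  out <- filter_germline(v, db, 10L)
  expect_setequal(out$pos, c(2L, 3L))  # count 10 and absent key retained
})

test_that("mock subtraction is key-based set difference", {
  treated <- variant_table(rep("chr1", 2L), c(1L, 2L), c("A", "C"),
                           c("G", "T"), c(1L, 1L), c(10L, 10L))
  mock <- variant_table("chr1", 2L, "C", "T", 9L, 10L)
  out <- subtract_mock(treated, mock)
  expect_identical(variant_key(out), "chr1:1:A:G")
  expect_identical(subtract_mock(treated, genotoxscreen:::empty_variant_table()),
                   treated)
  # same position, different ALT is a different key and is retained
  mock2 <- variant_table("chr1", 1L, "A", "T", 9L, 10L)
  expect_equal(nrow(subtract_mock(treated, mock2)), 2L)
})

test_that("synonymous and germline stages commute", {
  set.seed(33)
  v <- variant_table(rep("chr1", 20L), 1:20, rep("A", 20L), rep("G", 20L),
                     rep(1L, 20L), rep(100L, 20L),
                     effect = sample(c("synonymous", "missense"), 20L, TRUE))
  db <- data.frame(chrom = "chr1", pos = 1:10, ref = "A", alt = "G",
                   occurrence_count = sample(c(5L, 50L), 10L, TRUE))
  ab <- filter_germline(filter_synonymous(v), db, 10L)
  ba <- filter_synonymous(filter_germline(v, db, 10L))
  expect_identical(variant_key(ab), variant_key(ba))
})

test_that("strict filter removes SNVs and non-homologous variants only", {
  spacer <- "ACGTACGTACGTACGTACGT"
  guide <- guide_rna("g", spacer, "NGG", "chrH", 60L, "+")
  reference <- Biostrings::DNAStringSet(stats::setNames(
    paste0(strrep("A", 50), spacer, "CGG", strrep("A", 100)), "chrH"))
  v <- variant_table(
    chrom = rep("chrH", 3L),
    pos = c(60L, 60L, 120L),
    ref = c("G", "GT", "AA"),
    alt = c("T", "G", "A"),
    alt_reads = rep(5L, 3L), depth = rep(100L, 3L))
  # row 1: SNV with perfect homology -> removed by the SNV rule
  # row 2: deletion at the site -> homologous, retained
  # row 3: deletion in poly-A context -> no homology, removed
  out <- strict_cas9_filter(v, guide, reference)
  expect_identical(variant_key(out$variants), "chrH:60:GT:G")
  expect_identical(out$removed_snv$pos, 60L)
  expect_identical(out$removed_no_homology$pos, 120L)
})

test_that("CHIP flagging selects by gene list without removing anything", {
  v <- variant_table(rep("chr1", 2L), 1:2, c("A", "C"), c("G", "T"),
                     c(1L, 1L), c(10L, 10L), gene = c("DNMT3A", "GENE1"))
  expect_identical(flag_chip_genes(v, c("DNMT3A", "TET2"))$gene, "DNMT3A")
  expect_equal(nrow(flag_chip_genes(v, character())), 0L)
})

test_that("the cascade conserves counts at every stage and never increases them", {
  co <- generate_cohort(small_cohort_config(seed = 21))
  res <- run_panel_cascade(co$samples, co$germline_db, guides = co$guides,
                           reference = co$reference, strict = TRUE)
  for (cc in res$conditions) {
    lt <- ledger_table(cc$ledger)
    expect_true(all(lt$n_in == lt$n_out + lt$n_removed))
    expect_true(all(diff(c(lt$n_in[1L], lt$n_out)) <= 0))
    for (s in cc$ledger$stages) {
      expect_equal(s$n_in - s$n_out, nrow(s$removed))
    }
  }
})

test_that("a germline-only cohort is fully filtered with exact ledger accounting", {
  cfg <- small_cohort_config(seed = 31, noise_rate = 0,
                             db_holdout_fraction = 0,
                             planted_edits = data.frame(
                               guide = c("AAVS1", "HBB", "ZFPM2"),
                               kind = "on_target", match_count = 23L,
                               vaf_d4 = 0, vaf_d10 = 0))
  co <- generate_cohort(cfg)
  res <- run_panel_cascade(co$samples, co$germline_db)
  for (cc in res$conditions) {
    expect_equal(nrow(cc$final), 0L)
  }
})

test_that("mock subtraction requires a MOCK arm per treated donor", {
  t1 <- mk_sample("t1", "chr1:1:A:G", donor = "D9", treatment = "AAVS1")
  expect_error(run_panel_cascade(list(t1), data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), occurrence_count = integer())), "MOCK")
})

test_that("low-MEC samples are flagged but not excluded", {
  t1 <- mk_sample("t1", "chr1:1:A:G", treatment = "MOCK", mec = 900)
  res <- suppressWarnings(run_panel_cascade(list(t1), data.frame(
    chrom = character(), pos = integer(), ref = character(),
    alt = character(), occurrence_count = integer()),
    panel_thresholds(mock_subtraction = FALSE)))
  expect_true(res$conditions[[1L]]$mec_flagged)
  expect_equal(nrow(res$conditions[[1L]]$final), 1L)
})
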