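test_that("classify_variant agrees with the rule table for all allele pairs up to length 3", {
  alleles <- unlist(lapply(1:3, function(L) {
    apply(do.call(expand.grid, rep(list(c("A", "C", "G", "T")), L)),
          1L, paste, collapse = "")
  }))
  pairs <- expand.grid(ref = alleles, alt = alleles,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- classify_variant(pairs$ref, pairs$alt)
  want <- mapply(oracle_classify, pairs$ref, pairs$alt)
  expect_identical(unname(got), unname(want))
})

test_that("classify_variant rejects invalid alleles", {
  expect_error(classify_variant("A", "A"), "differ")
  expect_error(classify_variant("AN", "A"), "A,C,G,T")
  expect_error(classify_variant("", "A"), "A,C,G,T")
})

test_that("variant_table enforces count invariants and recomputes VAF", {
  v <- variant_table("chr1", 100L, "A", "G", 5L, 100L)
  expect_equal(v$vaf, 0.05, tolerance = 1e-12)
  expect_identical(v$variant_class, "SNV")
  expect_error(variant_table("chr1", 10L, "A", "G", 12L, 10L), "alt_reads")
  expect_error(variant_table("chr1", 10L, "A", "G", 0L, 0L), "depth")
})

test_that("sample_record rejects duplicate variant keys", {
  v <- variant_table(rep("chr1", 2L), c(5L, 5L), c("A", "A"), c("G", "G"),
                     c(1L, 2L), c(10L, 10L))
  expect_error(sample_record("s", "d", "MOCK", 0L, 1L, v), "duplicate")
})

test_that("VCF round trip preserves keys, counts, depths and annotations", {
  set.seed(42)
  v <- variant_table(
    chrom = rep("chr1", 3L), pos = c(100L, 250L, 90L),
    ref = c("A", "AT", "C"), alt = c("G", "A", "CTT"),
    alt_reads = c(5L, 40L, 7L), depth = c(100L, 90L, 55L),
    gene = c("GENE1", NA, "GENE2"),
    effect = c("missense", "frameshift", NA))
  s <- sample_record("s1", "D1", "AAVS1", 4L, 1L, v, 2500)
  path <- withr::local_tempfile(fileext = ".vcf")
  write_variants(s, path, "VCF")
  s2 <- parse_vcf(path, list(sample_id = "s1", donor = "D1",
                             treatment = "AAVS1", timepoint_days = 4L,
                             replicate = 1L, median_exon_coverage = 2500))
  o1 <- order(variant_key(v)); o2 <- order(variant_key(s2$variants))
  expect_identical(variant_key(v)[o1], variant_key(s2$variants)[o2])
  expect_identical(v$alt_reads[o1], s2$variants$alt_reads[o2])
  expect_identical(v$depth[o1], s2$variants$depth[o2])
  expect_identical(v$gene[o1], s2$variants$gene[o2])
  expect_identical(v$effect[o1], s2$variants$effect[o2])
})

test_that("empty samples round-trip as header-only files, TSV export has one row per variant", {
  s <- sample_record("s0", "D1", "MOCK", 0L, 1L)
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_variants(s, vcf, "VCF")
  s2 <- parse_vcf(vcf, list(sample_id = "s0", donor = "D1",
                            treatment = "MOCK", timepoint_days = 0L,
                            replicate = 1L))
  expect_equal(nrow(s2$variants), 0L)

  tsv <- withr::local_tempfile(fileext = ".tsv")
  v <- variant_table(rep("chr1", 2L), c(1L, 2L), c("A", "C"), c("G", "T"),
                     c(1L, 2L), c(10L, 10L))
  write_variants(v, tsv, "TSV")
  lines <- readLines(tsv)
  expect_length(lines, 3L)  # header + 2 rows
})

test_that("multi-allelic records split into one row per alt allele", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    "chr1\t100\t.\tA\tG,T\t.\tPASS\t.\tDP:AD\t100:90,6,4"), path)
  s <- parse_vcf(path, list(sample_id = "x", donor = "d", treatment = "MOCK",
                            timepoint_days = 0L, replicate = 1L))
  expect_equal(nrow(s$variants), 2L)
  expect_setequal(s$variants$alt, c("G", "T"))
  expect_setequal(s$variants$alt_reads, c(6L, 4L))
  expect_true(all(s$variants$depth == 100L))
})

test_that("parse_vcf reports inconsistent or missing count fields", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tDP:AD\t10:0,12"), path)
  md <- list(sample_id = "x", donor = "d", treatment = "MOCK",
             timepoint_days = 0L, replicate = 1L)
  expect_error(parse_vcf(path, md), "exceed depth")

  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS",
    "chr1\t100\t.\tA\tG\t.\tPASS\t.\tGT\t0/1"), path)
  expect_error(parse_vcf(path, md), "DP/AD")
})

test_that("normalization trims to minimal representation and left-aligns indels", {
  # ACC -> GCC is really A -> G after suffix trimming
  v <- variant_table("chr1", 10L, "ACC", "GCC", 1L, 10L)
  n <- normalize_variants(v)
  expect_identical(n$ref, "A")
  expect_identical(n$alt, "G")
  expect_identical(n$pos, 10L)
  expect_identical(n$variant_class, "SNV")

  # shared prefix: CAG -> CAT is G -> T at pos + 2
  v <- variant_table("chr1", 10L, "CAG", "CAT", 1L, 10L)
  n <- normalize_variants(v)
  expect_identical(n$ref, "G")
  expect_identical(n$pos, 12L)

  # deletion in an A-run left-aligns to the run start:
  # ref AAAAT, deletion of one A written at pos 4 shifts to pos 1
  reference <- Biostrings::DNAStringSet(c(chrZ = "AAAATGC"))
  v <- variant_table("chrZ", 4L, "AA", "A", 1L, 10L)
  n <- normalize_variants(v, reference)
  expect_identical(n$pos, 1L)
  expect_identical(n$ref, "AA")
  expect_identical(n$alt, "A")
})

test_that("generated sample records survive a full write/parse round trip", {
  co <- generate_cohort(small_cohort_config(seed = 5))
  s <- co$samples[[8L]]
  dir <- withr::local_tempdir()
  path <- file.path(dir, "s.vcf")
  write_variants(s, path, "VCF")
  s2 <- parse_vcf(path, list(sample_id = s$sample_id, donor = s$donor,
                             treatment = s$treatment,
                             timepoint_days = s$timepoint_days,
                             replicate = s$replicate,
                             median_exon_coverage = s$median_exon_coverage))
  expect_identical(sort(variant_key(s$variants)),
                   sort(variant_key(s2$variants)))
  o1 <- order(variant_key(s$variants)); o2 <- order(variant_key(s2$variants))
  expect_identical(s$variants$alt_reads[o1], s2$variants$alt_reads[o2])
  expect_identical(s$variants$depth[o1], s2$variants$depth[o2])
})
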