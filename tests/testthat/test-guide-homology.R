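test_that("best_homology equals brute-force placement enumeration on random windows", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(23:80, 1L)
    window <- rand_dna(n)
    spacer <- rand_dna(20L)
    got <- best_homology(window, spacer, "NGG")
    expect_identical(got$match_count,
                     oracle_best_homology(window, spacer, "NGG"),
                     info = paste("window", i))
  }
})

test_that("perfect and reverse-complement placements score 23", {
  spacer <- "ACGTACGTACGTACGTACGT"
  hit23 <- paste0(spacer, "TGG")
  win <- paste0(strrep("A", 7), hit23, strrep("A", 5))
  got <- best_homology(win, spacer, "NGG")
  expect_identical(got$match_count, 23L)
  expect_identical(got$offset, 8L)
  expect_identical(got$strand, "+")

  win_rc <- paste0(strrep("A", 7), oracle_revcomp(hit23), strrep("A", 5))
  got_rc <- best_homology(win_rc, spacer, "NGG")
  expect_identical(got_rc$match_count, 23L)
  expect_identical(got_rc$strand, "-")
  expect_identical(got_rc$offset, 8L)
})

test_that("N matches any base; poly-A window vs poly-C spacer scores exactly 1", {
  got <- best_homology(strrep("A", 40), strrep("C", 20), "NGG")
  expect_identical(got$match_count, 1L)  # only the PAM N position
})

test_that("match count is strand-symmetric", {
  set.seed(55)
  for (i in 1:50) {
    window <- rand_dna(sample(25:60, 1L))
    spacer <- rand_dna(20L)
    a <- best_homology(window, spacer, "NGG")$match_count
    b <- best_homology(oracle_revcomp(window), spacer, "NGG")$match_count
    expect_identical(a, b)
  }
})

test_that("mutating a matched position of the best placement cannot increase the score", {
  set.seed(77)
  comp <- function(b) chartr("ACGT", "TGCA", b)
  bases <- c("A", "C", "G", "T")
  tested <- 0L
  for (i in 1:200) {
    n <- 40L
    window <- rand_dna(n)
    spacer <- rand_dna(20L)
    best <- best_homology(window, spacer, "NGG")
    if (best$strand != "+") next
    q <- strsplit(paste0(spacer, "NGG"), "")[[1L]]
    wc <- strsplit(window, "")[[1L]]
    seg <- best$offset:(best$offset + 22L)
    matched <- which(q == wc[seg] & q != "N")
    if (length(matched) == 0L) next
    p <- seg[matched[1L]]
    # pick a replacement base that cannot create a match in any placement
    # overlapping p, on either strand, so the global maximum cannot grow
    forbidden <- wc[p]
    for (o in max(1L, p - 22L):min(n - 22L, p)) {
      j <- p - o + 1L
      if (q[j] != "N") forbidden <- c(forbidden, q[j])
    }
    pr <- n - p + 1L
    for (o in max(1L, pr - 22L):min(n - 22L, pr)) {
      j <- pr - o + 1L
      if (q[j] != "N") forbidden <- c(forbidden, comp(q[j]))
    }
    cand <- setdiff(bases, forbidden)
    if (length(cand) == 0L) next
    wc[p] <- cand[1L]
    mutated <- best_homology(paste(wc, collapse = ""), spacer, "NGG")
    expect_lte(mutated$match_count, best$match_count)
    tested <- tested + 1L
  }
  expect_gte(tested, 10L)
})

test_that("contiguous mode scores the longest run, never more than the total", {
  spacer <- "ACGTACGTACGTACGTACGT"
  win <- paste0(strrep("T", 5), spacer, "AGG", strrep("T", 5))
  tot <- best_homology(win, spacer, "NGG", mode = "total")
  run <- best_homology(win, spacer, "NGG", mode = "contiguous")
  expect_identical(run$match_count, 23L)
  set.seed(3)
  for (i in 1:20) {
    w <- rand_dna(40L); sp <- rand_dna(20L)
    expect_lte(best_homology(w, sp, "NGG", mode = "contiguous")$match_count,
               best_homology(w, sp, "NGG", mode = "total")$match_count)
  }
})

test_that("flag_grna_homology flags engineered placements at the 10-match rule", {
  set.seed(202)
  spacer <- rand_dna(20L)
  guide <- guide_rna("g1", spacer, "NGG", "chrH", 100L, "+")
  plant <- function(k) {
    # embed a 23-mer with exactly k matches in an A/T-poor random context
    site <- strsplit(paste0(spacer, "CGG"), "")[[1L]]
    flip <- sample(setdiff(1:23, 21L), 23L - k)
    for (p in flip) site[p] <- setdiff(c("A", "C", "G", "T"), site[p])[2L]
    paste(site, collapse = "")
  }
  mk_ref <- function(site) {
    Biostrings::DNAStringSet(stats::setNames(
      paste0(strrep("A", 40), site, strrep("A", 60)), "chrH"))
  }
  # variant 5 bp downstream of a perfect protospacer+PAM
  ref <- mk_ref(paste0(spacer, "CGG"))
  v <- list(chrom = "chrH", pos = 68L, ref = "A", alt = "T")
  hit <- flag_grna_homology(v, ref, guide)
  expect_true(hit$flagged)
  expect_identical(hit$best_match_count, 23L)

  # engineered 12-match placement inside the window: flagged
  ref12 <- mk_ref(plant(12L))
  hit12 <- flag_grna_homology(list(chrom = "chrH", pos = 52L, ref = "A",
                                   alt = "T"), ref12, guide)
  expect_identical(hit12$best_match_count,
                   oracle_best_homology(
                     as.character(Biostrings::subseq(ref12[["chrH"]], 10L, 94L)),
                     spacer, "NGG"))
  expect_true(hit12$best_match_count >= 12L)
  expect_true(hit12$flagged)

  # a variant whose window holds no placement above 9 is not flagged
  poly <- Biostrings::DNAStringSet(c(chrH = strrep("A", 120)))
  hitA <- flag_grna_homology(list(chrom = "chrH", pos = 60L, ref = "A",
                                  alt = "T"), poly,
                             guide_rna("g2", strrep("C", 20), "NGG",
                                       "chrH", 60L, "+"))
  expect_identical(hitA$best_match_count, 1L)
  expect_false(hitA$flagged)
})

test_that("windows truncate at contig edges with a warning, erroring below 23 bases", {
  ref <- Biostrings::DNAStringSet(c(chrS = rand_dna(60L)))
  guide <- guide_rna("g", rand_dna(20L), "NGG", "chrS", 30L, "+")
  expect_warning(hit <- flag_grna_homology(list(chrom = "chrS", pos = 5L,
                                                ref = "A", alt = "T"),
                                           ref, guide),
                 "truncated")
  expect_true(hit$best_match_count >= 1L)
  tiny <- Biostrings::DNAStringSet(c(chrS = rand_dna(15L)))
  expect_error(suppressWarnings(
    flag_grna_homology(list(chrom = "chrS", pos = 8L, ref = "A", alt = "T"),
                       tiny, guide)), "23")
})

test_that("on-target assignment uses an inclusive distance window", {
  g <- guide_rna("g", rand_dna(20L), "NGG", "chr1", 1000L, "+")
  at_cut <- list(chrom = "chr1", pos = 1000L, ref = "A")
  expect_true(is_on_target(at_cut, g, 50L))
  expect_true(is_on_target(list(chrom = "chr1", pos = 1050L, ref = "A"), g, 50L))
  expect_false(is_on_target(list(chrom = "chr1", pos = 1051L, ref = "A"), g, 50L))
  # deletion whose REF span reaches back to the window edge counts
  expect_true(is_on_target(list(chrom = "chr1", pos = 940L,
                                ref = strrep("A", 11L)), g, 50L))
  expect_false(is_on_target(list(chrom = "chr2", pos = 1000L, ref = "A"), g, 50L))
})
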