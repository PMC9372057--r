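# Independent brute-force oracles and small fixture builders shared across
# test files. Oracles deliberately avoid the package's code paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")
}

# enumerate every placement on both strands, counting positional matches
oracle_best_homology <- function(window, spacer, pam) {
  q <- strsplit(paste0(spacer, pam), "")[[1L]]
  count_at <- function(wchars, o) {
    sum(q == wchars[o:(o + 22L)] | q == "N")
  }
  best <- -1L
  for (strand in c("+", "-")) {
    w <- if (strand == "+") window else oracle_revcomp(window)
    wc <- strsplit(w, "")[[1L]]
    for (o in seq_len(length(wc) - 22L)) {
      best <- max(best, count_at(wc, o))
    }
  }
  best
}

# one-sided hypergeometric tail P(X >= alt_t) from choose() products
oracle_somatic_p <- function(alt_t, depth_t, alt_n, depth_n) {
  m <- alt_t + alt_n
  total <- depth_t + depth_n
  xs <- max(alt_t, max(0L, depth_t - (total - m))):min(m, depth_t)
  sum(choose(m, xs) * choose(total - m, depth_t - xs)) /
    choose(total, depth_t)
}

# rule-table classifier, written independently of the package's version
oracle_classify <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  if (lr == 1L && la == 1L) "SNV"
  else if (lr == la) "MNV"
  else if (la > lr) "INS"
  else "DEL"
}

# single-chromosome reference with one plus-strand gene
# CDS layout: ATG | codon1 codon2 ... | stop, starting at cds_start
make_toy_gene <- function(codons, cds_start = 11L, flank = 10L,
                          stop_codon = "TAA", gene = "TG1") {
  cds <- paste0("ATG", paste(codons, collapse = ""), stop_codon)
  seq <- paste0(strrep("C", flank), cds, strrep("C", flank))
  reference <- Biostrings::DNAStringSet(stats::setNames(seq, "chrT"))
  gm <- gene_model(gene, "chrT", "+",
                   data.frame(start = cds_start,
                              end = cds_start + nchar(cds) - 1L))
  list(reference = reference, gene = gm, cds_start = cds_start)
}

small_cohort_config <- function(seed = 11L, ...) {
  cohort_config(seed = seed, n_donors = 2L, n_germline_per_donor = 30L,
                gene_count = 5L, ...)
}
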