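# Coding-effect annotation against compact CDS-only gene models, so the
# synonymous filter of the screening cascade is self-contained.

#' Construct a gene model
#'
#' A compact gene model: gene symbol, chromosome, strand and an ordered set of
#' CDS intervals (1-based, inclusive). The concatenated CDS on the coding
#' strand must begin with ATG, end with a stop codon and have length divisible
#' by three.
#'
#' @param gene Gene symbol.
#' @param chrom Sequence name.
#' @param strand `"+"` or `"-"`.
#' @param cds data.frame with columns start, end (genomic, ascending).
#' @param reference Optional `DNAStringSet`; when supplied the start/stop and
#'   frame invariants are checked immediately.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene, chrom, strand, cds, reference = NULL) {
  stopifnot(strand %in% c("+", "-"), nrow(cds) >= 1L)
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  cds$start <- as.integer(cds$start); cds$end <- as.integer(cds$end)
  if (any(cds$end < cds$start)) stop("CDS interval with end < start")
  if (nrow(cds) > 1L && any(cds$start[-1L] <= cds$end[-nrow(cds)])) {
    stop("overlapping CDS intervals in gene ", gene)
  }
  total <- sum(cds$end - cds$start + 1L)
  if (total %% 3L != 0L) {
    stop("total CDS length of ", gene, " is not a multiple of 3")
  }
  gm <- structure(list(gene = gene, chrom = chrom, strand = strand, cds = cds),
                  class = "gene_model")
  if (!is.null(reference)) validate_gene_model(gm, reference)
  gm
}

#' Validate a gene model against the reference
#'
#' Checks the coding-strand CDS starts with ATG and ends with a stop codon.
#'
#' @param gm A [gene_model()].
#' @param reference A `DNAStringSet`.
#' @return `TRUE` invisibly; configuration error otherwise.
#' @export
validate_gene_model <- function(gm, reference) {
  cds <- cds_sequence(gm, reference)
  if (substr(cds, 1L, 3L) != "ATG") {
    stop("gene ", gm$gene, ": CDS does not begin with ATG")
  }
  last <- substr(cds, nchar(cds) - 2L, nchar(cds))
  if (!last %in% c("TAA", "TAG", "TGA")) {
    stop("gene ", gm$gene, ": CDS does not end with a stop codon")
  }
  invisible(TRUE)
}

# Concatenated CDS in transcript (5'->3') orientation.
cds_sequence <- function(gm, reference) {
  chunks <- vapply(seq_len(nrow(gm$cds)), function(i) {
    as.character(Biostrings::subseq(reference[[gm$chrom]],
                                    gm$cds$start[i], gm$cds$end[i]))
  }, character(1))
  s <- paste(chunks, collapse = "")
  if (gm$strand == "-") s <- revcomp(s)
  s
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# Map genomic positions to 1-based CDS coordinates (NA outside CDS).
genome_to_cds <- function(gm, gpos) {
  widths <- gm$cds$end - gm$cds$start + 1L
  offs <- cumsum(c(0L, widths[-length(widths)]))
  plus <- vapply(gpos, function(p) {
    hit <- which(p >= gm$cds$start & p <= gm$cds$end)
    if (length(hit) == 0L) NA_integer_
    else offs[hit] + (p - gm$cds$start[hit] + 1L)
  }, integer(1))
  if (gm$strand == "+") plus else sum(widths) - plus + 1L
}

#' Translate a CDS sequence
#'
#' Standard-table translation with stop codons rendered as `*`.
#'
#' @param seq DNA string, length a multiple of 3, `ACGT` only.
#' @return The protein string (empty input translates to `""`).
#' @examples
#' translate_cds("ATGGAAGAG")  # "MEE"
#' @export
translate_cds <- function(seq) {
  if (nchar(seq) == 0L) return("")
  if (nchar(seq) %% 3L != 0L) stop("CDS length must be a multiple of 3")
  if (!grepl("^[ACGT]+$", seq)) stop("CDS must contain only A,C,G,T")
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     no.init.codon = TRUE))
}

#' Annotate the coding effect of one variant
#'
#' Substitutions (SNV/MNV) fully inside the CDS are re-translated as a block:
#' an identical protein is `synonymous`, any new stop is `nonsense`, any other
#' amino-acid change `missense`. Indels inside the CDS are `frameshift` when
#' the net length change is not a multiple of three, else `inframe_indel`.
#' Variants outside every CDS — or straddling a CDS boundary, which is flagged
#' with a warning — are `noncoding`. Minus-strand genes are evaluated on the
#' reverse complement.
#'
#' @param variant One-row variant table (or list with chrom, pos, ref, alt).
#' @param gene_models List of [gene_model()] objects.
#' @param reference `DNAStringSet` covering the locus.
#' @return Effect string; the matched gene symbol (or `NA`) is attached as
#'   attribute `"gene"`.
#' @export
annotate_effect <- function(variant, gene_models, reference) {
  chrom <- variant$chrom; pos <- as.integer(variant$pos)
  ref <- variant$ref; alt <- variant$alt
  cls <- classify_variant(ref, alt)
  span <- seq.int(pos, pos + nchar(ref) - 1L)

  for (gm in gene_models) {
    if (gm$chrom != chrom) next
    inside <- !is.na(genome_to_cds(gm, span))
    if (!any(inside)) next
    if (!all(inside)) {
      warning(sprintf("variant %s:%d straddles a CDS boundary of %s; noncoding",
                      chrom, pos, gm$gene))
      return(structure("noncoding", gene = gm$gene))
    }
    if (cls %in% c("INS", "DEL")) {
      net <- nchar(alt) - nchar(ref)
      eff <- if (abs(net) %% 3L == 0L) "inframe_indel" else "frameshift"
      return(structure(eff, gene = gm$gene))
    }
    # substitution: rebuild the CDS with alt bases and compare proteins
    cds_ref <- cds_sequence(gm, reference)
    idx <- genome_to_cds(gm, span)
    alt_bases <- strsplit(alt, "")[[1L]]
    if (gm$strand == "-") {
      alt_bases <- strsplit(revcomp(alt), "")[[1L]]
      idx <- rev(idx)
      alt_bases <- alt_bases[order(idx)]
      idx <- sort(idx)
    }
    cds_alt <- strsplit(cds_ref, "")[[1L]]
    cds_alt[idx] <- alt_bases
    cds_alt <- paste(cds_alt, collapse = "")
    p_ref <- translate_cds(cds_ref)
    p_alt <- translate_cds(cds_alt)
    if (p_ref == p_alt) return(structure("synonymous", gene = gm$gene))
    pr <- strsplit(p_ref, "")[[1L]]; pa <- strsplit(p_alt, "")[[1L]]
    changed <- which(pr != pa)
    if (any(pa[changed] == "*")) return(structure("nonsense", gene = gm$gene))
    return(structure("missense", gene = gm$gene))
  }
  structure("noncoding", gene = NA_character_)
}

#' Annotate a whole variant table
#'
#' Fills the `gene` and `effect` columns of a variant table via
#' [annotate_effect()]. Existing annotations are overwritten.
#'
#' @param variants A variant table.
#' @inheritParams annotate_effect
#' @return The annotated variant table.
#' @export
annotate_effects <- function(variants, gene_models, reference) {
  if (nrow(variants) == 0L) return(variants)
  for (i in seq_len(nrow(variants))) {
    eff <- annotate_effect(variants[i, ], gene_models, reference)
    variants$effect[i] <- as.character(eff)
    variants$gene[i] <- attr(eff, "gene")
  }
  variants
}

#' Read gene models from a GFF3 file
#'
#' Expects CDS features carrying a `gene` attribute; all CDS rows sharing a
#' gene symbol form one model.
#'
#' @param path GFF3 file path.
#' @param reference Optional `DNAStringSet` to validate models on load.
#' @return List of [gene_model()] objects, named by gene symbol.
#' @export
read_gene_models <- function(path, reference = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type == "CDS"]
  df <- as.data.frame(gr)
  if (is.null(df$gene)) stop("GFF3 CDS features lack a 'gene' attribute")
  out <- lapply(split(df, df$gene), function(d) {
    gene_model(d$gene[1L], as.character(d$seqnames[1L]),
               as.character(d$strand[1L]),
               data.frame(start = d$start, end = d$end),
               reference = reference)
  })
  out[order(names(out))]
}

#' Write gene models to GFF3
#'
#' @param gene_models List of [gene_model()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(gene_models, path) {
  lines <- c("##gff-version 3")
  for (gm in gene_models) {
    for (i in seq_len(nrow(gm$cds))) {
      lines <- c(lines, paste(gm$chrom, "genotoxscreen", "CDS",
                              gm$cds$start[i], gm$cds$end[i], ".",
                              gm$strand, "0",
                              paste0("ID=cds-", gm$gene, "-", i,
                                     ";gene=", gm$gene),
                              sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
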