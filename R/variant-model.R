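#' @importFrom stats median rbinom rnbinom rpois runif setNames cor complete.cases
#' @importFrom utils read.delim write.table head
NULL

VARIANT_COLUMNS <- c("chrom", "pos", "ref", "alt", "alt_reads", "depth",
                     "vaf", "gene", "effect", "variant_class")

EFFECT_LEVELS <- c("synonymous", "missense", "nonsense", "frameshift",
                   "inframe_indel", "noncoding")

#' Construct a variant table
#'
#' Builds the canonical variant table used throughout the package: one row per
#' called variant with 1-based VCF-style coordinates, alt-read and total depth
#' counts, and the variant allele frequency (VAF) recomputed as
#' `alt_reads / depth`.
#'
#' @param chrom Character vector of sequence names.
#' @param pos Integer vector, 1-based position of the first REF base.
#' @param ref,alt Uppercase DNA allele strings (`A`,`C`,`G`,`T` only).
#' @param alt_reads Integer vector of reads supporting the alternate allele.
#' @param depth Integer vector of total site depth; must satisfy
#'   `0 <= alt_reads <= depth` and `depth >= 1`.
#' @param gene Optional gene symbols (`NA` when unknown).
#' @param effect Optional coding effect, one of
#'   `r paste(EFFECT_LEVELS, collapse = ", ")`, or `NA`.
#' @return A `data.frame` with columns chrom, pos, ref, alt, alt_reads, depth,
#'   vaf, gene, effect, variant_class.
#' @examples
#' variant_table("chr1", 100L, "A", "G", 5L, 100L)
#' @export
variant_table <- function(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          alt_reads = integer(), depth = integer(),
                          gene = NA_character_, effect = NA_character_) {
  n <- length(chrom)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n,
            length(alt_reads) == n, length(depth) == n)
  if (n == 0L) {
    return(empty_variant_table())
  }
  pos <- as.integer(pos)
  alt_reads <- as.integer(alt_reads)
  depth <- as.integer(depth)
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  if (any(is.na(pos)) || any(pos < 1L)) {
    stop("pos must be a positive 1-based coordinate")
  }
  if (any(depth < 1L)) {
    stop("depth must be >= 1 for any called variant")
  }
  if (any(alt_reads < 0L) || any(alt_reads > depth)) {
    bad <- which(alt_reads < 0L | alt_reads > depth)[1L]
    stop(sprintf("alt_reads (%d) outside [0, depth = %d] at %s:%d",
                 alt_reads[bad], depth[bad], chrom[bad], pos[bad]))
  }
  gene <- rep_len(as.character(gene), n)
  effect <- rep_len(as.character(effect), n)
  bad_eff <- !is.na(effect) & !(effect %in% EFFECT_LEVELS)
  if (any(bad_eff)) {
    stop("unknown effect value: ", effect[bad_eff][1L])
  }
  data.frame(
    chrom = as.character(chrom), pos = pos, ref = ref, alt = alt,
    alt_reads = alt_reads, depth = depth,
    vaf = alt_reads / depth,
    gene = gene, effect = effect,
    variant_class = classify_variant(ref, alt),
    stringsAsFactors = FALSE
  )
}

empty_variant_table <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), alt_reads = integer(), depth = integer(),
             vaf = numeric(), gene = character(), effect = character(),
             variant_class = character(), stringsAsFactors = FALSE)
}

#' Classify a variant from its REF and ALT alleles
#'
#' Pure function of the two allele strings: single differing bases are SNVs,
#' equal-length multi-base substitutions are MNVs, and anchored length changes
#' are insertions or deletions.
#'
#' @param ref,alt Character vectors of uppercase DNA alleles.
#' @return Character vector with values `"SNV"`, `"MNV"`, `"INS"` or `"DEL"`.
#' @examples
#' classify_variant(c("A", "AT", "A", "AG"), c("G", "A", "ATT", "CT"))
#' @export
classify_variant <- function(ref, alt) {
  ref <- as.character(ref)
  alt <- as.character(alt)
  if (any(!grepl("^[ACGT]+$", ref)) || any(!grepl("^[ACGT]+$", alt))) {
    stop("alleles must be non-empty strings over {A,C,G,T}")
  }
  if (any(ref == alt)) {
    stop("ref and alt must differ")
  }
  lr <- nchar(ref)
  la <- nchar(alt)
  out <- character(length(ref))
  out[lr == 1L & la == 1L] <- "SNV"
  out[lr == la & lr > 1L] <- "MNV"
  out[la > lr] <- "INS"
  out[lr > la] <- "DEL"
  out
}

#' Variant identity key
#'
#' Variants are compared across samples, the germline database and the mock
#' arm purely by `(chrom, pos, ref, alt)` equality; this helper renders that
#' key as a single string.
#'
#' @param x A variant table (or any data.frame with chrom, pos, ref, alt).
#' @return Character vector of keys, one per row.
#' @export
variant_key <- function(x) {
  if (nrow(x) == 0L) return(character())
  paste(x$chrom, x$pos, x$ref, x$alt, sep = ":")
}

#' Normalize indel representation
#'
#' Reduces each allele pair to its minimal representation (shared suffix then
#' shared prefix trimmed, keeping the 1-base anchor) and, when the reference
#' sequence is supplied, left-aligns pure indels by shifting them through
#' identical upstream sequence. Key-based operations (mock subtraction,
#' germline lookup) assume this canonical form.
#'
#' @param variants A variant table.
#' @param reference Optional `Biostrings::DNAStringSet` covering the loci;
#'   required for left alignment, otherwise only minimal representation is
#'   applied.
#' @return The variant table with pos/ref/alt canonicalized.
#' @export
normalize_variants <- function(variants, reference = NULL) {
  if (nrow(variants) == 0L) return(variants)
  for (i in seq_len(nrow(variants))) {
    ref <- variants$ref[i]; alt <- variants$alt[i]; pos <- variants$pos[i]
    repeat {
      # trim shared suffix while both alleles keep >= 1 base
      while (nchar(ref) > 1L && nchar(alt) > 1L &&
             substr(ref, nchar(ref), nchar(ref)) ==
             substr(alt, nchar(alt), nchar(alt))) {
        ref <- substr(ref, 1L, nchar(ref) - 1L)
        alt <- substr(alt, 1L, nchar(alt) - 1L)
      }
      # left-shift a pure indel whose alleles end in the same base
      if (!is.null(reference) && pos > 1L &&
          (nchar(ref) == 1L || nchar(alt) == 1L) && nchar(ref) != nchar(alt) &&
          substr(ref, nchar(ref), nchar(ref)) ==
          substr(alt, nchar(alt), nchar(alt))) {
        prev <- ref_base(reference, variants$chrom[i], pos - 1L)
        ref <- paste0(prev, substr(ref, 1L, nchar(ref) - 1L))
        alt <- paste0(prev, substr(alt, 1L, nchar(alt) - 1L))
        pos <- pos - 1L
        next
      }
      break
    }
    # trim shared prefix, keeping the final anchor base of each allele
    while (nchar(ref) > 1L && nchar(alt) > 1L &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
    }
    variants$ref[i] <- ref; variants$alt[i] <- alt; variants$pos[i] <- pos
  }
  variants$variant_class <- classify_variant(variants$ref, variants$alt)
  variants
}

ref_base <- function(reference, chrom, pos) {
  as.character(Biostrings::subseq(reference[[chrom]], pos, pos))
}

#' Construct a sample record
#'
#' One sequenced condition: donor, treatment arm (`"MOCK"` or a guide name),
#' timepoint in days, technical replicate number, its variant table and the
#' sample's median exon coverage (MEC), the panel's depth QC metric.
#'
#' @param sample_id Unique sample identifier.
#' @param donor Donor identifier.
#' @param treatment `"MOCK"` or a guide name.
#' @param timepoint_days Integer day of harvest.
#' @param replicate Technical replicate number (>= 1).
#' @param variants A variant table (no duplicate keys).
#' @param median_exon_coverage Positive number; median of per-exon mean depths.
#' @return An object of class `sample_record`.
#' @export
sample_record <- function(sample_id, donor, treatment, timepoint_days,
                          replicate, variants = empty_variant_table(),
                          median_exon_coverage = NA_real_) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L)
  replicate <- as.integer(replicate)
  if (is.na(replicate) || replicate < 1L) stop("replicate must be >= 1")
  if (!is.na(median_exon_coverage) && median_exon_coverage <= 0) {
    stop("median_exon_coverage must be positive")
  }
  if (anyDuplicated(variant_key(variants))) {
    stop("duplicate variant keys within one sample: ",
         variant_key(variants)[duplicated(variant_key(variants))][1L])
  }
  structure(
    list(sample_id = sample_id, donor = as.character(donor),
         treatment = as.character(treatment),
         timepoint_days = as.integer(timepoint_days),
         replicate = replicate, variants = variants,
         median_exon_coverage = as.numeric(median_exon_coverage)),
    class = "sample_record"
  )
}

#' @export
print.sample_record <- function(x, ...) {
  cat(sprintf("<sample_record> %s  donor=%s treatment=%s d%d rep%d\n",
              x$sample_id, x$donor, x$treatment, x$timepoint_days,
              x$replicate))
  cat(sprintf("  %d variants, MEC = %s\n", nrow(x$variants),
              format(x$median_exon_coverage)))
  invisible(x)
}

#' Parse a VCF file into a sample record
#'
#' Reads a VCF (v4.2+) with per-sample `DP` (total depth) and `AD`
#' (ref,alt allelic depths) FORMAT fields. Multi-allelic records are split
#' into one row per alternate allele; VAF is always recomputed as allelic
#' depth over total depth regardless of any AF field. The optional INFO keys
#' `GENE` and `EFF` populate the gene and effect columns.
#'
#' @param path Path to an (uncompressed or gzipped) VCF file.
#' @param sample_metadata A one-row data.frame or named list with sample_id,
#'   donor, treatment, timepoint_days, replicate and optionally
#'   median_exon_coverage.
#' @return A [sample_record()].
#' @export
parse_vcf <- function(path, sample_metadata) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  md <- as.list(sample_metadata)
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(fix) || nrow(vcf@fix) == 0L) {
    return(sample_record(md$sample_id, md$donor, md$treatment,
                         md$timepoint_days, md$replicate,
                         empty_variant_table(),
                         md$median_exon_coverage %||% NA_real_))
  }
  fix <- vcf@fix
  fmt <- vcf@gt[, 1L]
  smp <- vcf@gt[, 2L]
  info_field <- function(info, key) {
    m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]+"), info))
    if (length(m) == 0L) NA_character_ else sub(paste0("^;?", key, "="), "", m)
  }
  rows <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1L]]
    vals <- strsplit(smp[i], ":", fixed = TRUE)[[1L]]
    if (!all(c("DP", "AD") %in% keys)) {
      stop(sprintf("record %s:%s lacks DP/AD FORMAT fields",
                   fix[i, "CHROM"], fix[i, "POS"]))
    }
    dp <- suppressWarnings(as.integer(vals[match("DP", keys)]))
    ad <- suppressWarnings(as.integer(
      strsplit(vals[match("AD", keys)], ",", fixed = TRUE)[[1L]]))
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1L]]
    if (is.na(dp) || anyNA(ad) || length(ad) != length(alts) + 1L) {
      stop(sprintf("unparseable DP/AD at record %s:%s (line %d of data)",
                   fix[i, "CHROM"], fix[i, "POS"], i))
    }
    alt_reads <- ad[-1L]
    if (any(alt_reads > dp)) {
      stop(sprintf("alt reads (%d) exceed depth (%d) at %s:%s",
                   max(alt_reads), dp, fix[i, "CHROM"], fix[i, "POS"]))
    }
    info <- fix[i, "INFO"]
    gene <- info_field(info, "GENE")
    eff <- info_field(info, "EFF")
    k <- length(alts)
    rows[[i]] <- variant_table(
      chrom = rep(fix[i, "CHROM"], k),
      pos = rep(as.integer(fix[i, "POS"]), k),
      ref = rep(fix[i, "REF"], k),
      alt = alts,
      alt_reads = alt_reads,
      depth = rep(dp, k),
      gene = gene, effect = eff
    )
  }
  variants <- do.call(rbind, rows)
  variants <- normalize_variants(variants)
  sample_record(md$sample_id, md$donor, md$treatment, md$timepoint_days,
                md$replicate, variants, md$median_exon_coverage %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1L && is.na(a))) b else a

#' Write variants to VCF or TSV
#'
#' Emits the fixed schema this package also parses: FORMAT `DP:AD` with
#' `AD = depth - alt_reads, alt_reads`, INFO keys `GENE`/`EFF` when set.
#' The round trip `parse(write(x))` preserves keys, counts and depths exactly.
#'
#' @param x A [sample_record()] or a variant table.
#' @param path Output file path.
#' @param format `"VCF"` or `"TSV"`.
#' @return `path`, invisibly.
#' @export
write_variants <- function(x, path, format = c("VCF", "TSV")) {
  format <- match.arg(format)
  variants <- if (inherits(x, "sample_record")) x$variants else x
  sample_name <- if (inherits(x, "sample_record")) x$sample_id else "SAMPLE"
  if (format == "TSV") {
    write.table(variants[, VARIANT_COLUMNS], path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    return(invisible(path))
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=genotoxscreen",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=EFF,Number=1,Type=String,Description=\"Coding effect\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_name, sep = "\t")
  )
  body <- character(0)
  if (nrow(variants) > 0L) {
    info <- vapply(seq_len(nrow(variants)), function(i) {
      parts <- character(0)
      if (!is.na(variants$gene[i])) parts <- c(parts, paste0("GENE=", variants$gene[i]))
      if (!is.na(variants$effect[i])) parts <- c(parts, paste0("EFF=", variants$effect[i]))
      if (length(parts) == 0L) "." else paste(parts, collapse = ";")
    }, character(1))
    ord <- order(variants$chrom, variants$pos, variants$ref, variants$alt)
    v <- variants[ord, ]
    info <- info[ord]
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\tDP:AD\t%d:%d,%d",
                    v$chrom, v$pos, v$ref, v$alt, info,
                    v$depth, v$depth - v$alt_reads, v$alt_reads)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a sample sheet and its per-sample VCFs
#'
#' The sample sheet is a TSV with columns sample_id, donor, treatment,
#' timepoint_days, replicate, vcf_path (relative paths resolved against the
#' sheet's directory) and optionally median_exon_coverage.
#'
#' @param sheet_path Path to the sample sheet TSV.
#' @return A list of [sample_record()] objects, named by sample_id.
#' @export
read_sample_sheet <- function(sheet_path) {
  sheet <- read.delim(sheet_path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "donor", "treatment", "timepoint_days",
              "replicate", "vcf_path")
  if (!all(needed %in% names(sheet))) {
    stop("sample sheet lacks columns: ",
         paste(setdiff(needed, names(sheet)), collapse = ", "))
  }
  base <- dirname(sheet_path)
  records <- lapply(seq_len(nrow(sheet)), function(i) {
    p <- sheet$vcf_path[i]
    if (!file.exists(p)) p <- file.path(base, p)
    parse_vcf(p, sheet[i, setdiff(names(sheet), "vcf_path")])
  })
  names(records) <- sheet$sample_id
  records
}
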