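# Spacer+PAM homology scoring around called variants. The screening rule
# flags a variant as guide-homologous when the best ungapped placement of the
# 23-mer (20-nt spacer + 3-nt PAM) within a +/-20 bp window around the
# variant matches at >= 10 positions, on either strand, with N matching any
# base.

#' Construct a guide RNA record
#'
#' @param name Guide name (also used as treatment label).
#' @param spacer 20-nt protospacer-matching DNA string.
#' @param pam 3-nt PAM pattern over `{A,C,G,T,N}` (e.g. `"NGG"`).
#' @param target_chrom Chromosome of the intended target site.
#' @param cut_pos 1-based position of the blunt cut (between protospacer
#'   positions 17 and 18, i.e. 3 bp 5' of the PAM).
#' @param strand Strand carrying the protospacer (`"+"` or `"-"`).
#' @return An object of class `guide_rna`.
#' @export
guide_rna <- function(name, spacer, pam = "NGG", target_chrom = NA_character_,
                      cut_pos = NA_integer_, strand = "+") {
  spacer <- toupper(spacer); pam <- toupper(pam)
  if (nchar(spacer) != 20L || !grepl("^[ACGT]+$", spacer)) {
    stop("spacer must be a 20-nt ACGT string")
  }
  if (nchar(pam) != 3L || !grepl("^[ACGTN]+$", pam)) {
    stop("pam must be a 3-character pattern over {A,C,G,T,N}")
  }
  stopifnot(strand %in% c("+", "-"))
  structure(list(name = name, spacer = spacer, pam = pam,
                 target_chrom = as.character(target_chrom),
                 cut_pos = as.integer(cut_pos), strand = strand),
            class = "guide_rna")
}

#' Read a guide table
#'
#' TSV with columns name, spacer, pam, chrom, cut_pos, strand.
#'
#' @param path Guide table path.
#' @return Named list of [guide_rna()] objects.
#' @export
read_guides <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    guide_rna(tab$name[i], tab$spacer[i], tab$pam[i], tab$chrom[i],
              tab$cut_pos[i], tab$strand[i])
  })
  names(out) <- tab$name
  out
}

#' Write a guide table
#' @param guides Named list of [guide_rna()] objects.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path) {
  tab <- do.call(rbind, lapply(guides, function(g) {
    data.frame(name = g$name, spacer = g$spacer, pam = g$pam,
               chrom = g$target_chrom, cut_pos = g$cut_pos,
               strand = g$strand, stringsAsFactors = FALSE)
  }))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Best spacer+PAM placement in a window
#'
#' Slides the 23-mer `spacer + pam` across every offset of `window_seq` on
#' both strands (the minus strand scans the reverse complement of the window)
#' and counts positional matches; `N` in the query matches any base. Ties
#' break toward the smallest offset, plus strand first.
#'
#' @param window_seq DNA string of length >= 23.
#' @param spacer 20-nt spacer.
#' @param pam 3-nt PAM pattern.
#' @param mode `"total"` (default) scores the number of matching positions of
#'   a placement; `"contiguous"` scores its longest run of consecutive
#'   matches.
#' @return List with `match_count`, `offset` (1-based start of the placement
#'   in `window_seq` coordinates) and `strand`.
#' @export
best_homology <- function(window_seq, spacer, pam = "NGG",
                          mode = c("total", "contiguous")) {
  mode <- match.arg(mode)
  window_seq <- toupper(window_seq)
  n <- nchar(window_seq)
  if (n < 23L) stop("window must be at least 23 bases, got ", n)
  query <- strsplit(paste0(toupper(spacer), toupper(pam)), "")[[1L]]
  if (length(query) != 23L) stop("spacer+pam must total 23 bases")
  wild <- query == "N"

  score_strand <- function(seq_chars) {
    m <- length(seq_chars) - 22L
    vapply(seq_len(m), function(o) {
      hits <- (query == seq_chars[o:(o + 22L)]) | wild
      if (mode == "total") sum(hits) else longest_run(hits)
    }, numeric(1))
  }
  w_fwd <- strsplit(window_seq, "")[[1L]]
  w_rev <- strsplit(revcomp(window_seq), "")[[1L]]
  s_fwd <- score_strand(w_fwd)
  s_rev <- score_strand(w_rev)
  # minus-strand placement starting at offset o of the revcomp covers
  # original window positions (n - o - 21) .. (n - o + 1)
  cand <- rbind(
    data.frame(count = s_fwd, offset = seq_along(s_fwd), strand = "+"),
    data.frame(count = s_rev, offset = n - seq_along(s_rev) - 21L,
               strand = "-")
  )
  cand <- cand[order(-cand$count, cand$offset,
                     match(cand$strand, c("+", "-"))), ]
  list(match_count = as.integer(cand$count[1L]),
       offset = as.integer(cand$offset[1L]),
       strand = cand$strand[1L])
}

longest_run <- function(hits) {
  r <- rle(hits)
  if (!any(r$values)) 0L else max(r$lengths[r$values])
}

#' Score guide homology around a variant
#'
#' Extracts the reference window spanning `flank` bases upstream of the
#' variant position through `flank` bases downstream of the REF allele end,
#' extended by 22 bases on each side so every 23-mer placement overlapping
#' the window is scored, then applies [best_homology()]. The variant is
#' flagged when the best placement matches at `min_match` or more positions.
#'
#' @param variant One-row variant table (or list with chrom, pos, ref, alt).
#' @param reference `DNAStringSet`.
#' @param guide A [guide_rna()].
#' @param flank Window half-width in bp (default 20).
#' @param min_match Match-count threshold for flagging (default 10).
#' @param mode Passed to [best_homology()].
#' @return One-row data.frame: chrom, pos, ref, alt, best_match_count,
#'   best_offset (placement start minus variant pos, signed), best_strand,
#'   flagged.
#' @export
flag_grna_homology <- function(variant, reference, guide, flank = 20L,
                               min_match = 10L, mode = "total") {
  chrom <- variant$chrom
  pos <- as.integer(variant$pos)
  ref_len <- nchar(variant$ref)
  contig_len <- length(reference[[chrom]])
  start <- pos - flank - 22L
  end <- pos + ref_len - 1L + flank + 22L
  if (start < 1L || end > contig_len) {
    warning(sprintf("window for %s:%d truncated at contig edge", chrom, pos))
    start <- max(1L, start); end <- min(contig_len, end)
  }
  if (end - start + 1L < 23L) {
    stop(sprintf("window for %s:%d shorter than 23 bases after truncation",
                 chrom, pos))
  }
  win <- as.character(Biostrings::subseq(reference[[chrom]], start, end))
  best <- best_homology(win, guide$spacer, guide$pam, mode = mode)
  data.frame(chrom = chrom, pos = pos, ref = variant$ref, alt = variant$alt,
             best_match_count = best$match_count,
             best_offset = as.integer(start + best$offset - 1L - pos),
             best_strand = best$strand,
             flagged = best$match_count >= min_match,
             stringsAsFactors = FALSE)
}

#' Is a variant at the guide's on-target site?
#'
#' True iff the variant lies on the guide's target chromosome and the minimum
#' distance from any REF-allele base to the cut position is at most
#' `window_bp` (inclusive).
#'
#' @param variant One-row variant table (or list with chrom, pos, ref).
#' @param guide A [guide_rna()] with target_chrom and cut_pos set.
#' @param window_bp Non-negative window half-width (default 50).
#' @return Logical scalar.
#' @export
is_on_target <- function(variant, guide, window_bp = 50L) {
  stopifnot(window_bp >= 0L)
  if (is.na(guide$cut_pos)) stop("guide has no cut_pos")
  if (variant$chrom != guide$target_chrom) return(FALSE)
  lo <- as.integer(variant$pos)
  hi <- lo + nchar(variant$ref) - 1L
  d <- if (guide$cut_pos < lo) lo - guide$cut_pos
       else if (guide$cut_pos > hi) guide$cut_pos - hi
       else 0L
  d <= window_bp
}
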