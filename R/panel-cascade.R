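# The deep-panel screening cascade: replicate concordance, synonymous
# filter, germline-database occurrence filter, mock subtraction and the
# optional strict nuclease filter (indels with guide homology only), each
# stage recorded in a conservation-checked ledger.

#' Panel cascade thresholds
#'
#' Defaults are the published operating values: germline variants reported
#' more than 10 times in the occurrence database are removed, homology is
#' scored over a +/-20 bp flank with a 10-match threshold, and samples below
#' 1300 median exon coverage are flagged (not excluded).
#'
#' @param germline_max_occurrences Retain variants with database occurrence
#'   count `<=` this value; remove strictly above it (default 10).
#' @param mock_subtraction Remove variants present in the donor's mock arm
#'   (default `TRUE`).
#' @param strict_flank Homology window half-width for the strict filter.
#' @param strict_min_match Match threshold for the strict filter.
#' @param mec_lower_spec Lower specification limit on median exon coverage.
#' @param chip_gene_list Character vector of clonal-hematopoiesis (CHIP)
#'   gene symbols used for flagging.
#' @return A list of class `panel_thresholds`.
#' @export
panel_thresholds <- function(germline_max_occurrences = 10L,
                             mock_subtraction = TRUE,
                             strict_flank = 20L,
                             strict_min_match = 10L,
                             mec_lower_spec = 1300,
                             chip_gene_list = character()) {
  stopifnot(germline_max_occurrences > 0, strict_flank > 0,
            strict_min_match > 0, mec_lower_spec > 0)
  structure(list(germline_max_occurrences = as.integer(germline_max_occurrences),
                 mock_subtraction = isTRUE(mock_subtraction),
                 strict_flank = as.integer(strict_flank),
                 strict_min_match = as.integer(strict_min_match),
                 mec_lower_spec = mec_lower_spec,
                 chip_gene_list = as.character(chip_gene_list)),
            class = "panel_thresholds")
}

# --- filter ledger ---------------------------------------------------------

new_ledger <- function() {
  structure(list(stages = list()), class = "filter_ledger")
}

add_stage <- function(ledger, name, before, after, reason) {
  removed_keys <- setdiff(variant_key(before), variant_key(after))
  removed <- before[variant_key(before) %in% removed_keys,
                    c("chrom", "pos", "ref", "alt"), drop = FALSE]
  if (nrow(removed) > 0L) removed$reason <- reason
  else removed$reason <- character(0)
  stopifnot(nrow(before) == nrow(after) + nrow(removed))  # conservation
  ledger$stages[[name]] <- list(stage = name, n_in = nrow(before),
                                n_out = nrow(after), removed = removed)
  ledger
}

#' Ledger summary table
#'
#' @param ledger A `filter_ledger`.
#' @return data.frame with one row per stage: stage, n_in, n_out, n_removed.
#' @export
ledger_table <- function(ledger) {
  stopifnot(inherits(ledger, "filter_ledger"))
  do.call(rbind, lapply(ledger$stages, function(s) {
    data.frame(stage = s$stage, n_in = s$n_in, n_out = s$n_out,
               n_removed = nrow(s$removed), stringsAsFactors = FALSE)
  }))
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("<filter_ledger>\n")
  print(ledger_table(x))
  invisible(x)
}

# --- stages ----------------------------------------------------------------

#' Replicate-reproducible variants
#'
#' The reproducible set is the intersection of the replicates' variant-key
#' sets; concordance is `|intersection| / |union|`. Alt reads and depth of
#' each reproducible variant are summed across replicates, so pooled depth
#' drives the pooled limit of detection. A single replicate returns its own
#' set with concordance 1.
#'
#' @param replicate_samples List of [sample_record()]s from the same donor,
#'   treatment and timepoint.
#' @return List with `variants` (pooled variant table) and `concordance`.
#' @export
reproducible_variants <- function(replicate_samples) {
  stopifnot(length(replicate_samples) >= 1L)
  meta <- unique(t(vapply(replicate_samples, function(s) {
    c(s$donor, s$treatment, as.character(s$timepoint_days))
  }, character(3))))
  if (nrow(meta) != 1L) {
    stop("replicates from mixed donor/treatment/timepoint conditions")
  }
  key_sets <- lapply(replicate_samples, function(s) variant_key(s$variants))
  inter <- Reduce(intersect, key_sets)
  uni <- Reduce(union, key_sets)
  concordance <- if (length(uni) == 0L) 1.0 else length(inter) / length(uni)

  all_v <- do.call(rbind, lapply(replicate_samples, function(s) s$variants))
  keep <- all_v[variant_key(all_v) %in% inter, , drop = FALSE]
  if (nrow(keep) > 0L) {
    k <- variant_key(keep)
    agg_alt <- tapply(keep$alt_reads, k, sum)
    agg_dp <- tapply(keep$depth, k, sum)
    first <- keep[!duplicated(k), , drop = FALSE]
    fk <- variant_key(first)
    first$alt_reads <- as.integer(agg_alt[fk])
    first$depth <- as.integer(agg_dp[fk])
    first$vaf <- first$alt_reads / first$depth
    pooled <- first[order(first$chrom, first$pos, first$ref, first$alt), ,
                    drop = FALSE]
    rownames(pooled) <- NULL
  } else {
    pooled <- empty_variant_table()
  }
  list(variants = pooled, concordance = concordance)
}

#' Remove synonymous variants
#'
#' Variants positively annotated `synonymous` are removed; every other
#' effect, including `noncoding` and unannotated (`NA`, retained with a
#' warning), passes.
#'
#' @param variants A variant table with the effect column populated.
#' @return The filtered variant table.
#' @export
filter_synonymous <- function(variants) {
  if (nrow(variants) == 0L) return(variants)
  if (anyNA(variants$effect)) {
    warning(sum(is.na(variants$effect)),
            " variant(s) without effect annotation retained (fail-open)")
  }
  variants[is.na(variants$effect) | variants$effect != "synonymous", ,
           drop = FALSE]
}

#' Read a germline occurrence database
#'
#' TSV with columns chrom, pos, ref, alt, occurrence_count.
#'
#' @param path Database path.
#' @return data.frame keyed by (chrom, pos, ref, alt).
#' @export
read_germline_db <- function(path) {
  db <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("chrom", "pos", "ref", "alt", "occurrence_count")
  if (!all(needed %in% names(db))) {
    stop("germline db lacks columns: ",
         paste(setdiff(needed, names(db)), collapse = ", "))
  }
  bad <- which(is.na(suppressWarnings(as.integer(db$occurrence_count))))
  if (length(bad) > 0L) {
    stop("malformed occurrence_count in germline db row ", bad[1L])
  }
  db$occurrence_count <- as.integer(db$occurrence_count)
  db
}

#' Remove database-reported germline variants
#'
#' Removes variants whose occurrence count in the germline database is
#' strictly greater than `max_occurrences` (the published rule removes
#' variants "reported to occur more than 10 times"; a count of exactly 10 is
#' retained). Keys absent from the database are retained.
#'
#' @param variants A variant table.
#' @param germline_db data.frame from [read_germline_db()].
#' @param max_occurrences Strict removal threshold (default 10).
#' @return The filtered variant table.
#' @export
filter_germline <- function(variants, germline_db, max_occurrences = 10L) {
  if (nrow(variants) == 0L) return(variants)
  counts <- germline_db$occurrence_count[
    match(variant_key(variants), variant_key(germline_db))]
  keep <- is.na(counts) | counts <= max_occurrences
  variants[keep, , drop = FALSE]
}

#' Subtract mock-arm variants
#'
#' Removes every treated variant whose key appears in the donor's mock
#' reproducible set (any timepoint), regardless of VAF: a variant present
#' without nuclease cannot have been introduced by it.
#'
#' @param treated_variants Variant table from a nuclease arm.
#' @param mock_variants Variant table of the same donor's mock arm(s).
#' @return The filtered variant table.
#' @export
subtract_mock <- function(treated_variants, mock_variants) {
  if (nrow(treated_variants) == 0L) return(treated_variants)
  treated_variants[!(variant_key(treated_variants) %in%
                       variant_key(mock_variants)), , drop = FALSE]
}

#' Strict nuclease filter
#'
#' The secondary, maximally specific view: removes all SNVs, then removes
#' remaining variants whose best spacer+PAM placement within the homology
#' window does not reach the match threshold. Only guide-homologous indels
#' and MNVs survive.
#'
#' @param variants A variant table.
#' @param guide A [guide_rna()].
#' @param reference `DNAStringSet`.
#' @param thresholds A [panel_thresholds()].
#' @return List with `variants` (survivors) and `removed_snv` /
#'   `removed_no_homology` key tables.
#' @export
strict_cas9_filter <- function(variants, guide, reference,
                               thresholds = panel_thresholds()) {
  non_snv <- variants[variants$variant_class != "SNV", , drop = FALSE]
  if (nrow(non_snv) > 0L) {
    flagged <- vapply(seq_len(nrow(non_snv)), function(i) {
      flag_grna_homology(non_snv[i, ], reference, guide,
                         flank = thresholds$strict_flank,
                         min_match = thresholds$strict_min_match)$flagged
    }, logical(1))
    kept <- non_snv[flagged, , drop = FALSE]
  } else {
    kept <- non_snv
  }
  list(variants = kept,
       removed_snv = variants[variants$variant_class == "SNV",
                              c("chrom", "pos", "ref", "alt"), drop = FALSE],
       removed_no_homology = non_snv[!(variant_key(non_snv) %in%
                                         variant_key(kept)),
                                     c("chrom", "pos", "ref", "alt"),
                                     drop = FALSE])
}

#' Flag variants in CHIP-associated genes
#'
#' Annotation only — never a removal stage. Returns the subset of variants
#' whose gene symbol belongs to the clonal-hematopoiesis gene list.
#'
#' @param variants A variant table with gene symbols.
#' @param chip_gene_list Character vector of gene symbols.
#' @return The flagged subset of the variant table.
#' @export
flag_chip_genes <- function(variants, chip_gene_list) {
  variants[!is.na(variants$gene) & variants$gene %in% chip_gene_list, ,
           drop = FALSE]
}

# --- end-to-end cascade ----------------------------------------------------

#' Run the full screening cascade over a cohort
#'
#' Groups samples by donor x treatment x timepoint, forms the replicate-
#' reproducible set, then applies the synonymous, germline-database and mock
#' subtraction filters (and optionally the strict nuclease filter to
#' non-mock arms). Every stage is recorded in a per-condition ledger with
#' exact count conservation. Mock subtraction uses the union of the donor's
#' mock reproducible sets across all timepoints. Samples whose median exon
#' coverage falls below the lower specification limit are flagged in the
#' condition summary but not excluded.
#'
#' @param samples List of [sample_record()]s (a whole cohort including mock
#'   arms).
#' @param germline_db data.frame from [read_germline_db()].
#' @param thresholds A [panel_thresholds()].
#' @param guides Named list of [guide_rna()]s (needed when `strict = TRUE`).
#' @param reference `DNAStringSet` (needed when `strict = TRUE`).
#' @param strict Apply the strict nuclease filter to nuclease arms
#'   (default `FALSE`, the permissive primary view).
#' @return Object of class `panel_cascade_result`: per-condition list with
#'   final variants, ledger, concordance, MEC flags and CHIP flags.
#' @export
run_panel_cascade <- function(samples, germline_db,
                              thresholds = panel_thresholds(),
                              guides = NULL, reference = NULL,
                              strict = FALSE) {
  stopifnot(length(samples) >= 1L)
  if (strict && (is.null(guides) || is.null(reference))) {
    stop("strict mode requires guides and reference")
  }
  cond_key <- vapply(samples, function(s) {
    paste(s$donor, s$treatment, s$timepoint_days, sep = "|")
  }, character(1))
  groups <- split(samples, cond_key)

  donors <- unique(vapply(samples, function(s) s$donor, character(1)))
  if (thresholds$mock_subtraction) {
    has_mock <- vapply(donors, function(d) {
      any(vapply(samples, function(s) s$donor == d && s$treatment == "MOCK",
                 logical(1)))
    }, logical(1))
    treated_donors <- unique(vapply(
      Filter(function(s) s$treatment != "MOCK", samples),
      function(s) s$donor, character(1)))
    missing <- setdiff(treated_donors, donors[has_mock])
    if (length(missing) > 0L) {
      stop("mock subtraction enabled but donor(s) lack a MOCK arm: ",
           paste(missing, collapse = ", "))
    }
  }

  # mock reproducible union per donor, across timepoints
  mock_union <- lapply(setNames(donors, donors), function(d) {
    mocks <- Filter(function(s) s$donor == d && s$treatment == "MOCK", samples)
    if (length(mocks) == 0L) return(empty_variant_table())
    tps <- split(mocks, vapply(mocks, function(s) s$timepoint_days, integer(1)))
    do.call(rbind, lapply(tps, function(g) reproducible_variants(g)$variants))
  })

  conditions <- lapply(groups, function(g) {
    s1 <- g[[1L]]
    rep_out <- reproducible_variants(g)
    union_v <- do.call(rbind, lapply(g, function(s) s$variants))
    union_v <- union_v[!duplicated(variant_key(union_v)), , drop = FALSE]

    ledger <- new_ledger()
    ledger <- add_stage(ledger, "replicate_concordance", union_v,
                        rep_out$variants, "not_reproducible")
    v <- rep_out$variants
    v2 <- filter_synonymous(v)
    ledger <- add_stage(ledger, "synonymous_filter", v, v2, "synonymous")
    v3 <- filter_germline(v2, germline_db, thresholds$germline_max_occurrences)
    ledger <- add_stage(ledger, "germline_filter", v2, v3,
                        "germline_db_occurrence")
    v4 <- v3
    if (thresholds$mock_subtraction && s1$treatment != "MOCK") {
      v4 <- subtract_mock(v3, mock_union[[s1$donor]])
      ledger <- add_stage(ledger, "mock_subtraction", v3, v4, "present_in_mock")
    }
    v5 <- v4
    if (strict && s1$treatment != "MOCK") {
      guide <- guides[[s1$treatment]]
      if (is.null(guide)) stop("no guide named ", s1$treatment)
      out <- strict_cas9_filter(v4, guide, reference, thresholds)
      v5 <- out$variants
      ledger <- add_stage(ledger, "strict_cas9_filter", v4, v5,
                          "snv_or_no_gRNA_homology")
    }
    mecs <- vapply(g, function(s) s$median_exon_coverage, numeric(1))
    list(donor = s1$donor, treatment = s1$treatment,
         timepoint_days = s1$timepoint_days,
         n_replicates = length(g),
         concordance = rep_out$concordance,
         reproducible = rep_out$variants,
         final = v5,
         ledger = ledger,
         mec = mecs,
         mec_flagged = any(!is.na(mecs) & mecs < thresholds$mec_lower_spec),
         chip_flagged = flag_chip_genes(v5, thresholds$chip_gene_list))
  })
  structure(list(conditions = conditions, thresholds = thresholds,
                 strict = strict),
            class = "panel_cascade_result")
}

#' Per-condition summary of a cascade run
#'
#' @param result A `panel_cascade_result`.
#' @return data.frame: donor, treatment, timepoint_days, n_replicates,
#'   concordance, n_reproducible, n_final, mec_flagged, n_chip_flagged.
#' @export
cascade_summary <- function(result) {
  stopifnot(inherits(result, "panel_cascade_result"))
  out <- do.call(rbind, lapply(result$conditions, function(cc) {
    data.frame(donor = cc$donor, treatment = cc$treatment,
               timepoint_days = cc$timepoint_days,
               n_replicates = cc$n_replicates,
               concordance = cc$concordance,
               n_reproducible = nrow(cc$reproducible),
               n_final = nrow(cc$final),
               mec_flagged = cc$mec_flagged,
               n_chip_flagged = nrow(cc$chip_flagged),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$donor, out$treatment, out$timepoint_days), , drop = FALSE]
}

#' @export
print.panel_cascade_result <- function(x, ...) {
  cat(sprintf("<panel_cascade_result> %d conditions (strict = %s)\n",
              length(x$conditions), x$strict))
  print(cascade_summary(x))
  invisible(x)
}

#' Write cascade ledgers as JSON
#'
#' @param result A `panel_cascade_result`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_ledgers <- function(result, path) {
  obj <- lapply(result$conditions, function(cc) {
    list(donor = cc$donor, treatment = cc$treatment,
         timepoint_days = cc$timepoint_days,
         concordance = cc$concordance,
         stages = lapply(cc$ledger$stages, function(s) {
           list(stage = s$stage, n_in = s$n_in, n_out = s$n_out,
                removed = s$removed)
         }))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
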