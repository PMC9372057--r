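# Summary tables behind the screening report: gene burden per condition,
# VAF x MEC with per-variant filter fate, and indel length spectra.

#' Gene burden per condition
#'
#' Long-format count of final variants per donor x treatment x timepoint x
#' gene; counts sum to the total number of input variants carrying a gene
#' symbol (variants without one are tallied under `NA`).
#'
#' @param result A `panel_cascade_result` from [run_panel_cascade()].
#' @return data.frame: donor, treatment, timepoint_days, gene, count.
#' @export
summarize_gene_burden <- function(result) {
  stopifnot(inherits(result, "panel_cascade_result"))
  rows <- list()
  for (cc in result$conditions) {
    v <- cc$final
    if (nrow(v) == 0L) next
    tab <- table(ifelse(is.na(v$gene), NA_character_, v$gene), useNA = "ifany")
    rows[[length(rows) + 1L]] <- data.frame(
      donor = cc$donor, treatment = cc$treatment,
      timepoint_days = cc$timepoint_days,
      gene = names(tab), count = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = character(), treatment = character(),
                      timepoint_days = integer(), gene = character(),
                      count = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$donor, out$treatment, out$timepoint_days, out$gene), ,
      drop = FALSE]
}

#' VAF x MEC table with filter fate
#'
#' One row per replicate-reproducible variant of every condition, carrying
#' its pooled VAF, the condition's mean replicate MEC and the variant's fate
#' through the cascade: which stage removed it, or `retained`.
#'
#' @param result A `panel_cascade_result`.
#' @return data.frame: donor, treatment, timepoint_days, chrom, pos, ref,
#'   alt, vaf, depth, mec, fate.
#' @export
vaf_mec_table <- function(result) {
  stopifnot(inherits(result, "panel_cascade_result"))
  rows <- list()
  for (cc in result$conditions) {
    v <- cc$reproducible
    if (nrow(v) == 0L) next
    fate <- rep("retained", nrow(v))
    keys <- variant_key(v)
    for (s in cc$ledger$stages) {
      if (s$stage == "replicate_concordance") next
      hit <- keys %in% variant_key(s$removed)
      fate[hit & fate == "retained"] <- s$stage
    }
    rows[[length(rows) + 1L]] <- data.frame(
      donor = cc$donor, treatment = cc$treatment,
      timepoint_days = cc$timepoint_days,
      chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      vaf = v$vaf, depth = v$depth, mec = mean(cc$mec), fate = fate,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(donor = character(), treatment = character(),
                      timepoint_days = integer(), chrom = character(),
                      pos = integer(), ref = character(), alt = character(),
                      vaf = numeric(), depth = integer(), mec = numeric(),
                      fate = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$donor, out$treatment, out$timepoint_days, out$chrom,
            out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Indel length spectrum at a locus
#'
#' Distribution of net indel length (alt length minus ref length; SNVs and
#' MNVs are excluded) over the variants of one locus window, weighted by VAF
#' and normalized to sum to 1.
#'
#' @param variants A variant table whose rows share a locus window.
#' @return data.frame: net_length, vaf_fraction (empty for no indels).
#' @export
summarize_indel_spectrum <- function(variants) {
  ind <- variants[variants$variant_class %in% c("INS", "DEL"), , drop = FALSE]
  if (nrow(ind) == 0L) {
    return(data.frame(net_length = integer(), vaf_fraction = numeric()))
  }
  net <- nchar(ind$alt) - nchar(ind$ref)
  agg <- tapply(ind$vaf, net, sum)
  out <- data.frame(net_length = as.integer(names(agg)),
                    vaf_fraction = as.numeric(agg) / sum(agg))
  out[order(out$net_length), , drop = FALSE]
}

#' Per-sample and pooled limits of detection
#'
#' Evaluates a detection model at each sample's median exon coverage and at
#' the pooled depth (sum of replicate MECs) of every donor x treatment x
#' timepoint group.
#'
#' @param samples List of [sample_record()]s.
#' @param model A [calibrate_detection()] model.
#' @return List with `per_sample` and `per_condition` data.frames.
#' @export
lod_report <- function(samples, model = calibrate_detection()) {
  per_sample <- do.call(rbind, lapply(samples, function(s) {
    data.frame(sample_id = s$sample_id, donor = s$donor,
               treatment = s$treatment, timepoint_days = s$timepoint_days,
               replicate = s$replicate, mec = s$median_exon_coverage,
               lod = lod_at_depth(model, s$median_exon_coverage),
               stringsAsFactors = FALSE)
  }))
  rownames(per_sample) <- NULL
  key <- paste(per_sample$donor, per_sample$treatment,
               per_sample$timepoint_days, sep = "|")
  per_condition <- do.call(rbind, lapply(split(per_sample, key), function(g) {
    pooled <- sum(g$mec)
    data.frame(donor = g$donor[1L], treatment = g$treatment[1L],
               timepoint_days = g$timepoint_days[1L],
               n_replicates = nrow(g), pooled_depth = pooled,
               pooled_lod = lod_at_depth(model, pooled),
               stringsAsFactors = FALSE)
  }))
  rownames(per_condition) <- NULL
  list(per_sample = per_sample,
       per_condition = per_condition[order(per_condition$donor,
                                           per_condition$treatment,
                                           per_condition$timepoint_days), ,
                                     drop = FALSE])
}

#' Write somatic calls to TSV
#'
#' @param calls A `somatic_calls` data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_somatic_calls <- function(calls, path) {
  write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an inversion-control report as JSON
#'
#' @param inv Output of [inversion_control()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_inversion_report <- function(inv, path) {
  jsonlite::write_json(
    list(n_forward = inv$n_forward, n_reverse = inv$n_reverse,
         ratio = inv$ratio,
         forward = as.data.frame(inv$forward),
         reverse = as.data.frame(inv$reverse)),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
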