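# Simplified tumor-normal somatic comparison: the edited arm plays "tumor",
# the mock arm "normal". A one-sided exact (hypergeometric) test on the
# (alt, ref) x (tumor, normal) table calls candidate somatic variants, the
# published VAF filters then prune them, and a label-inversion control
# estimates the pipeline's background call rate.

#' Somatic comparison thresholds
#'
#' Defaults are the published filters: exome-style analysis removes calls at
#' mock VAF strictly above 0.01; genome-style analysis removes calls below
#' 0.001 tumor VAF or above 0.01 mock VAF.
#'
#' @param alpha One-sided exact-test significance level (default 0.01).
#' @param wes_max_normal_vaf Exome-mode maximum normal (mock) VAF retained.
#' @param wgs_min_tumor_vaf Genome-mode minimum tumor VAF retained.
#' @param wgs_max_normal_vaf Genome-mode maximum normal VAF retained.
#' @return A list of class `somatic_thresholds`.
#' @export
somatic_thresholds <- function(alpha = 0.01, wes_max_normal_vaf = 0.01,
                               wgs_min_tumor_vaf = 0.001,
                               wgs_max_normal_vaf = 0.01) {
  stopifnot(alpha > 0, alpha < 1)
  structure(list(alpha = alpha, wes_max_normal_vaf = wes_max_normal_vaf,
                 wgs_min_tumor_vaf = wgs_min_tumor_vaf,
                 wgs_max_normal_vaf = wgs_max_normal_vaf),
            class = "somatic_thresholds")
}

# One-sided exact p-value for tumor alt enrichment: with X hypergeometric
# over (alt_total, ref_total) drawn tumor_depth times, p = P(X >= alt_t).
somatic_p_value <- function(alt_t, depth_t, alt_n, depth_n) {
  stats::phyper(alt_t - 1, m = alt_t + alt_n,
                n = (depth_t - alt_t) + (depth_n - alt_n),
                k = depth_t, lower.tail = FALSE)
}

#' Call somatic variants between a tumor and a normal sample
#'
#' For each variant called in the tumor sample, the matching normal counts
#' are looked up by variant key; a site absent from the normal call set
#' contributes zero alt reads at the normal sample's local depth (from a
#' depth track when supplied, else its median exon coverage). The call is
#' somatic iff the one-sided exact test rejects at `alpha` and the tumor VAF
#' exceeds the normal VAF. Sites with zero depth in both samples are skipped
#' with a warning.
#'
#' @param tumor_sample,normal_sample [sample_record()] objects.
#' @param thresholds A [somatic_thresholds()].
#' @param normal_depth_track Optional data.frame (pos, depth) giving normal
#'   depth at sites absent from the normal call set.
#' @return data.frame of class `somatic_calls`: one row per tumor variant
#'   with tumor/normal VAF and depth, p_value, adjusted_vaf and `somatic`.
#' @export
call_somatic <- function(tumor_sample, normal_sample,
                         thresholds = somatic_thresholds(),
                         normal_depth_track = NULL) {
  tv <- tumor_sample$variants
  nv <- normal_sample$variants
  if (nrow(tv) == 0L) {
    out <- data.frame(chrom = character(), pos = integer(), ref = character(),
                      alt = character(), variant_class = character(),
                      gene = character(),
                      tumor_vaf = numeric(), tumor_depth = integer(),
                      normal_vaf = numeric(), normal_depth = integer(),
                      p_value = numeric(), adjusted_vaf = numeric(),
                      somatic = logical(), stringsAsFactors = FALSE)
    class(out) <- c("somatic_calls", "data.frame")
    return(out)
  }
  idx <- match(variant_key(tv), variant_key(nv))
  default_depth <- function(pos) {
    if (!is.null(normal_depth_track)) {
      d <- normal_depth_track$depth[match(pos, normal_depth_track$pos)]
      ifelse(is.na(d), round(normal_sample$median_exon_coverage), d)
    } else {
      rep(round(normal_sample$median_exon_coverage), length(pos))
    }
  }
  normal_alt <- ifelse(is.na(idx), 0L, nv$alt_reads[idx])
  normal_depth <- ifelse(is.na(idx), default_depth(tv$pos), nv$depth[idx])
  skip <- tv$depth == 0L & normal_depth == 0L
  if (any(skip)) {
    warning(sum(skip), " site(s) with zero depth in both samples skipped")
  }
  keep <- !skip & normal_depth > 0L
  tv <- tv[keep, , drop = FALSE]
  normal_alt <- normal_alt[keep]
  normal_depth <- as.integer(normal_depth[keep])

  p <- vapply(seq_len(nrow(tv)), function(i) {
    somatic_p_value(tv$alt_reads[i], tv$depth[i], normal_alt[i],
                    normal_depth[i])
  }, numeric(1))
  normal_vaf <- ifelse(normal_depth > 0L, normal_alt / normal_depth, 0)
  out <- data.frame(
    chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
    variant_class = tv$variant_class, gene = tv$gene,
    tumor_vaf = tv$vaf, tumor_depth = tv$depth,
    normal_vaf = normal_vaf, normal_depth = normal_depth,
    p_value = p,
    adjusted_vaf = pmax(0, tv$vaf - normal_vaf),
    somatic = p <= thresholds$alpha & tv$vaf > normal_vaf,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("somatic_calls", "data.frame")
  out
}

#' Exome-style normal-VAF filter
#'
#' Retains calls whose normal (mock) VAF is at most `max_normal_vaf`; calls
#' strictly above the threshold are removed, exactly as published (a call at
#' precisely the threshold is retained).
#'
#' @param calls A `somatic_calls` data.frame.
#' @param max_normal_vaf Threshold (default 0.01).
#' @return Filtered calls.
#' @export
filter_normal_vaf <- function(calls, max_normal_vaf = 0.01) {
  calls[calls$normal_vaf <= max_normal_vaf, , drop = FALSE]
}

#' Genome-style VAF filters
#'
#' Retains calls with tumor VAF at least `wgs_min_tumor_vaf` (calls below
#' 0.1% VAF removed) and normal VAF at most `wgs_max_normal_vaf` (calls
#' above 1% mock VAF removed).
#'
#' @param calls A `somatic_calls` data.frame.
#' @param thresholds A [somatic_thresholds()].
#' @return Filtered calls.
#' @export
wgs_filter <- function(calls, thresholds = somatic_thresholds()) {
  calls[calls$tumor_vaf >= thresholds$wgs_min_tumor_vaf &
          calls$normal_vaf <= thresholds$wgs_max_normal_vaf, , drop = FALSE]
}

#' Background-VAF subtraction
#'
#' Sets `adjusted_vaf = max(0, tumor_vaf - normal_vaf)` on every call,
#' leaving all other fields (and membership) unchanged.
#'
#' @param calls A `somatic_calls` data.frame.
#' @return The calls with adjusted_vaf recomputed.
#' @export
subtract_background_vaf <- function(calls) {
  calls$adjusted_vaf <- pmax(0, calls$tumor_vaf - calls$normal_vaf)
  calls
}

#' Label-inversion control
#'
#' Runs the somatic comparison in both label orders — A as tumor vs B as
#' normal, then B as tumor vs A as normal — applying the mode's filters to
#' each, and reports both call counts and their ratio as the empirical
#' false-positive context.
#'
#' @param sample_a,sample_b [sample_record()] objects.
#' @param thresholds A [somatic_thresholds()].
#' @param mode `"wes"` (normal-VAF filter) or `"wgs"` (tumor+normal VAF
#'   filters).
#' @return List with `forward` and `reverse` filtered calls, `n_forward`,
#'   `n_reverse` and `ratio` (forward / reverse; `NA` when both are 0,
#'   `Inf` when only reverse is 0).
#' @export
inversion_control <- function(sample_a, sample_b,
                              thresholds = somatic_thresholds(),
                              mode = c("wes", "wgs")) {
  mode <- match.arg(mode)
  run_dir <- function(tum, nor) {
    calls <- call_somatic(tum, nor, thresholds)
    calls <- calls[calls$somatic, , drop = FALSE]
    calls <- subtract_background_vaf(calls)
    if (mode == "wes") filter_normal_vaf(calls, thresholds$wes_max_normal_vaf)
    else wgs_filter(calls, thresholds)
  }
  fwd <- run_dir(sample_a, sample_b)
  rev <- run_dir(sample_b, sample_a)
  ratio <- if (nrow(fwd) == 0L && nrow(rev) == 0L) NA_real_
           else if (nrow(rev) == 0L) Inf
           else nrow(fwd) / nrow(rev)
  list(forward = fwd, reverse = rev,
       n_forward = nrow(fwd), n_reverse = nrow(rev), ratio = ratio)
}

#' Coverage concordance between two depth tracks
#'
#' Pearson correlation of per-site depths, the check behind the observation
#' that low-coverage sites in one arm are low-coverage in the other.
#'
#' @param depth_track_a,depth_track_b Equal-length numeric depth vectors.
#' @return Correlation coefficient; `NA` with attribute `flagged = TRUE`
#'   when either track has zero variance.
#' @export
coverage_concordance <- function(depth_track_a, depth_track_b) {
  stopifnot(length(depth_track_a) == length(depth_track_b))
  if (stats::sd(depth_track_a) == 0 || stats::sd(depth_track_b) == 0) {
    return(structure(NA_real_, flagged = TRUE))
  }
  stats::cor(depth_track_a, depth_track_b)
}

#' Read-depth dropout check near the cut site
#'
#' Ratio of mean depth within `cut_pos +/- window_bp` to the median depth of
#' the remainder of the track; flagged when the ratio falls below
#' `flag_below` (a large on-target deletion or chromothriptic loss would
#' depress coverage here).
#'
#' @param depth_track Numeric vector of per-position depths (position i =
#'   coordinate i).
#' @param cut_pos Cut coordinate within the track.
#' @param window_bp Window half-width.
#' @param flag_below Flagging threshold on the ratio (default 0.5).
#' @return List with `ratio` and `flagged`.
#' @export
coverage_dropout_check <- function(depth_track, cut_pos, window_bp = 50L,
                                   flag_below = 0.5) {
  n <- length(depth_track)
  lo <- cut_pos - window_bp; hi <- cut_pos + window_bp
  if (lo < 1L || hi > n) stop("window extends outside the depth track")
  inside <- seq.int(lo, hi)
  bg <- stats::median(depth_track[-inside])
  ratio <- if (bg == 0) NA_real_ else mean(depth_track[inside]) / bg
  list(ratio = ratio, flagged = !is.na(ratio) && ratio < flag_below)
}
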