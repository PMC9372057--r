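# Depth -> limit-of-detection model. The default is a constant-expected-
# alt-reads law LoD(d) = lambda_star / d calibrated at the panel's published
# operating point (LoD 0.205% VAF at median exon coverage 3550, 95%
# sensitivity); a binomial k-threshold mode is available for sensitivity
# analyses.

#' Calibrate a detection model at a depth/LoD anchor
#'
#' The calibrated model carries `lambda_star = depth_anchor * lod_anchor`,
#' the expected number of alt reads at the limit of detection, and maps any
#' depth to the minimum detectable VAF via `LoD(d) = lambda_star / d`.
#'
#' @param depth_anchor Depth at the operating point (e.g. a panel's median
#'   exon coverage, 3550 by default).
#' @param lod_anchor Limit of detection as a VAF fraction at `depth_anchor`
#'   (0.00205 by default).
#' @param sensitivity_target Detection probability the LoD refers to
#'   (default 0.95).
#' @param k_min Optional integer: minimum alt reads for a call. When set,
#'   [lod_at_depth()] switches to the binomial-sensitivity definition.
#' @return An object of class `detection_model`.
#' @examples
#' m <- calibrate_detection(3550, 0.00205)
#' lod_at_depth(m, 3 * 3550)  # pooled triplicate depth
#' @export
calibrate_detection <- function(depth_anchor = 3550, lod_anchor = 0.00205,
                                sensitivity_target = 0.95, k_min = NULL) {
  if (depth_anchor <= 0) stop("depth_anchor must be positive")
  if (lod_anchor <= 0 || lod_anchor >= 1) stop("lod_anchor must be in (0,1)")
  if (sensitivity_target <= 0 || sensitivity_target >= 1) {
    stop("sensitivity_target must be in (0,1)")
  }
  if (!is.null(k_min)) {
    k_min <- as.integer(k_min)
    if (is.na(k_min) || k_min < 0L) stop("k_min must be a non-negative integer")
  }
  structure(
    list(sensitivity_target = sensitivity_target,
         lambda_star = depth_anchor * lod_anchor,
         k_min = k_min,
         anchor = c(depth_anchor = depth_anchor, lod_anchor = lod_anchor)),
    class = "detection_model"
  )
}

#' @export
print.detection_model <- function(x, ...) {
  cat(sprintf(paste0("<detection_model> lambda* = %.4f alt reads ",
                     "(anchor: LoD %.4g at depth %g, sensitivity %g)\n"),
              x$lambda_star, x$anchor["lod_anchor"], x$anchor["depth_anchor"],
              x$sensitivity_target))
  if (!is.null(x$k_min)) cat(sprintf("  binomial mode, k_min = %d\n", x$k_min))
  invisible(x)
}

#' Limit of detection at a given depth
#'
#' Constant-lambda mode returns `lambda_star / depth`. When the model carries
#' `k_min`, returns the smallest VAF whose binomial detection sensitivity at
#' that depth reaches the model's sensitivity target (bisection to 1e-9).
#'
#' @param model A [calibrate_detection()] model.
#' @param depth Positive depth (scalar or vector in constant-lambda mode).
#' @return Minimum detectable VAF (fraction).
#' @export
lod_at_depth <- function(model, depth) {
  stopifnot(inherits(model, "detection_model"))
  if (any(depth <= 0)) stop("depth must be positive")
  if (is.null(model$k_min)) {
    return(model$lambda_star / depth)
  }
  vapply(depth, function(d) {
    lo <- 0; hi <- 1
    while (hi - lo > 1e-9) {
      mid <- (lo + hi) / 2
      if (detection_sensitivity(mid, d, model$k_min) >=
          model$sensitivity_target) hi <- mid else lo <- mid
    }
    hi
  }, numeric(1))
}

#' Binomial detection sensitivity
#'
#' Probability of observing at least `k_min` alt reads when the true VAF is
#' `vaf` at the given depth: `P(X >= k_min)`, `X ~ Binomial(depth, vaf)`,
#' computed with the stable upper-tail of `pbinom`.
#'
#' @param vaf True variant allele fraction in `[0, 1]`.
#' @param depth Integer depth (>= 1).
#' @param k_min Minimum alt reads for a call (>= 0).
#' @return Detection probability.
#' @examples
#' detection_sensitivity(0.5, 10, 2)  # 1 - 11/1024
#' @export
detection_sensitivity <- function(vaf, depth, k_min) {
  if (any(vaf < 0) || any(vaf > 1)) stop("vaf must be in [0,1]")
  if (any(depth < 1)) stop("depth must be >= 1")
  if (any(k_min < 0)) stop("k_min must be >= 0")
  ifelse(k_min == 0, 1,
         stats::pbinom(k_min - 1, size = depth, prob = vaf,
                       lower.tail = FALSE))
}
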