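# COBRA (combined bisulfite restriction analysis) methylation index and
# standard-curve correction.  Band intensities are length-normalized to
# molar amounts before forming the index.

#' COBRA methylation index from band intensities
#'
#' `index = (cut/cut_len) / ((cut/cut_len) + (uncut/uncut_len)) * 100`,
#' i.e. the molar fraction of the restriction-cut (methylated) fragment,
#' in percent.  With the LINE1 amplicon the cut band is 246 bp and the
#' uncut band 413 bp.  The index is invariant to rescaling both
#' intensities by a common positive factor.
#'
#' @param cut_intensity,uncut_intensity band intensities (>= 0,
#'   vectorized; a pair with both zero is an error).
#' @param cut_len,uncut_len fragment lengths in bp (defaults 246, 413).
#' @return raw methylation index in percent, in \[0, 100\].
#' @export
methylation_index <- function(cut_intensity, uncut_intensity,
                              cut_len = 246, uncut_len = 413) {
  stopifnot(cut_len > 0, uncut_len > 0)
  if (any(cut_intensity < 0) || any(uncut_intensity < 0))
    stop_invalid("band intensities must be non-negative")
  if (any(cut_intensity == 0 & uncut_intensity == 0))
    stop_invalid("both band intensities are zero")
  cutm <- cut_intensity / cut_len
  uncutm <- uncut_intensity / uncut_len
  100 * cutm / (cutm + uncutm)
}

#' Fit a linear standard curve from control samples
#'
#' Ordinary least squares of raw index on true % methylation of the
#' methylated/unmethylated control mixtures: `raw = slope * true +
#' intercept`.
#'
#' @param true_pct true % methylation of the controls (>= 2 distinct
#'   values).
#' @param raw_pct measured raw indices (%).
#' @return a `standard_curve` list: slope, intercept, r2, points.
#' @export
fit_standard_curve <- function(true_pct, raw_pct) {
  stopifnot(length(true_pct) == length(raw_pct))
  if (length(true_pct) < 2L || length(unique(true_pct)) < 2L)
    stop_invalid("need >= 2 control points with distinct true values")
  fit <- stats::lm(raw_pct ~ true_pct)
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope <= 0)
    stop_invalid("standard curve slope must be > 0")
  ss_tot <- sum((raw_pct - mean(raw_pct))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  out <- list(slope = slope, intercept = unname(stats::coef(fit)[1L]),
              r2 = r2,
              points = data.frame(true_pct = true_pct, raw_pct = raw_pct))
  class(out) <- "standard_curve"
  out
}

#' Correct a raw methylation index with a standard curve
#'
#' Inverts the fitted line, `corrected = (raw - intercept) / slope`, and
#' clamps the result to \[0, 100\].
#'
#' @param raw_pct raw index (%) (vectorized).
#' @param curve a [fit_standard_curve()] result.
#' @return corrected methylation level in percent.
#' @export
correct_index <- function(raw_pct, curve) {
  stopifnot(inherits(curve, "standard_curve"))
  clamp((raw_pct - curve$intercept) / curve$slope, 0, 100)
}

#' COBRA quantification table: raw and corrected indices per sample
#'
#' @param bands data.frame(sample_id, cut_intensity, uncut_intensity).
#' @param curve optional standard curve; without one, corrected equals
#'   raw.
#' @param cut_len,uncut_len fragment lengths in bp.
#' @return data.frame: sample_id, raw_index, corrected_index.
#' @export
cobra_quantify <- function(bands, curve = NULL, cut_len = 246,
                           uncut_len = 413) {
  raw <- methylation_index(bands$cut_intensity, bands$uncut_intensity,
                           cut_len, uncut_len)
  corrected <- if (is.null(curve)) raw else correct_index(raw, curve)
  data.frame(sample_id = bands$sample_id, raw_index = raw,
             corrected_index = corrected, stringsAsFactors = FALSE)
}
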