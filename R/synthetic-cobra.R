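# Synthetic COBRA band intensities with a known distortion curve.

#' Generate synthetic COBRA band measurements and a control ladder
#'
#' The observed ("raw") methylation index of each sample follows a linear
#' distortion of its true methylated fraction,
#' `raw% = intercept + slope * true% + noise`, and band intensities are
#' reconstructed so that [methylation_index()] of the bands returns exactly
#' that raw index (cut intensity proportional to `raw_frac * cut_len`,
#' uncut to `(1 - raw_frac) * uncut_len`).  A control ladder spanning
#' 0-100% true methylation is distorted by the same curve, so fitting it
#' with [fit_standard_curve()] and applying [correct_index()] recovers the
#' true fractions.
#'
#' @param true_fraction named numeric vector (by sample_id) of true
#'   methylated fractions in \[0, 1\].
#' @param distortion c(slope, intercept) of the linear distortion on the
#'   percent scale; slope must be > 0.
#' @param band_noise Gaussian sd (percent points) added to raw indices.
#' @param control_points true % methylation of the control ladder.
#' @param cut_len,uncut_len fragment lengths (bp) of the cut (methylated)
#'   and uncut (unmethylated) bands; defaults 246 and 413.
#' @param molarity arbitrary common molarity scale of the bands.
#' @param seed integer seed.
#' @return list: `bands` (sample_id, cut_intensity, uncut_intensity),
#'   `controls` (true_pct, raw_pct), and `truth` (true fractions and the
#'   distortion used).
#' @export
generate_cobra <- function(true_fraction,
                           distortion = c(slope = 1, intercept = 0),
                           band_noise = 0,
                           control_points = c(0, 25, 50, 75, 100),
                           cut_len = 246, uncut_len = 413,
                           molarity = 10,
                           seed = 1L) {
  stopifnot(is.numeric(true_fraction), length(true_fraction) >= 1,
            all(true_fraction >= 0 & true_fraction <= 1),
            band_noise >= 0, cut_len > 0, uncut_len > 0, molarity > 0)
  slope <- unname(distortion[["slope"]] %||% distortion[[1L]])
  intercept <- unname(distortion[["intercept"]] %||% distortion[[2L]])
  if (slope <= 0) stop_invalid("distortion slope must be > 0")
  if (is.null(names(true_fraction)))
    names(true_fraction) <- sprintf("S%02d", seq_along(true_fraction))

  set.seed(derive_seed(seed, 51L))
  raw_pct <- intercept + slope * (true_fraction * 100) +
    stats::rnorm(length(true_fraction), 0, band_noise)
  raw_pct <- clamp(raw_pct, 0, 100)
  raw_frac <- raw_pct / 100
  bands <- data.frame(sample_id = names(true_fraction),
                      cut_intensity = raw_frac * cut_len * molarity,
                      uncut_intensity = (1 - raw_frac) * uncut_len * molarity,
                      stringsAsFactors = FALSE)

  ctrl_raw <- intercept + slope * control_points +
    stats::rnorm(length(control_points), 0, band_noise)
  controls <- data.frame(true_pct = control_points,
                         raw_pct = clamp(ctrl_raw, 0, 100))

  list(bands = bands, controls = controls,
       truth = list(true_fraction = true_fraction,
                    slope = slope, intercept = intercept))
}
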