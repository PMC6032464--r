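#' Hematocrit value
#'
#' Fraction of blood volume occupied by red cells, used to convert arterial
#' blood concentration to plasma concentration. The default 0.45 is the fixed
#' value assumed for all patients.
#'
#' @param value fraction in (0, 1).
#' @return An object of class `hematocrit`.
#' @export
hematocrit <- function(value = 0.45) {
  value <- as.numeric(value)
  if (!is.finite(value) || value < 0 || value >= 1)
    dce_validation_error("hematocrit must be a fraction in [0, 1)")
  structure(list(value = value), class = "hematocrit")
}

#' Convert a signal curve to a relative-enhancement concentration curve
#'
#' Computes C(t) = S(t)/S0 - 1, where S0 is the arithmetic mean of the
#' pre-contrast (baseline) frames. Relative enhancement is used directly as
#' the tracer-concentration proxy (no relaxivity calibration); the implied
#' linearity between enhancement and concentration is an assumption of the
#' analysis. The result is scale-invariant: multiplying the signal by any
#' k > 0 leaves C(t) unchanged.
#'
#' @param curve a [signal_curve()].
#' @param kind what the region represents (`"tissue"` default, or
#'   `"arterial_blood"` for aortic ROIs).
#' @param s0_floor minimum admissible S0 relative to the curve's maximum
#'   signal; baselines below `s0_floor * max(signal)` (or non-positive) raise
#'   a conversion error rather than producing exploding enhancement values.
#' @return A [conc_curve()] on the same time grid.
#' @export
signal_to_concentration <- function(curve, kind = "tissue", s0_floor = 1e-6) {
  stopifnot(inherits(curve, "signal_curve"))
  s0 <- mean(curve$values[seq_len(curve$n_baseline)])
  if (!is.finite(s0) || s0 <= 0 || s0 < s0_floor * max(curve$values))
    dce_conversion_error(sprintf(
      "ROI '%s': baseline signal S0 = %g is non-positive or below the floor",
      curve$roi_id, s0))
  conc_curve(curve$roi_id, curve$times, curve$values / s0 - 1, kind = kind)
}

#' Convert arterial blood concentration to plasma concentration
#'
#' Scales a whole-blood concentration curve by 1/(1 - Hct): the tracer is
#' confined to plasma, so the plasma concentration exceeds the blood
#' concentration by the plasma fraction.
#'
#' @param curve a [conc_curve()] of kind `"arterial_blood"`.
#' @param hct a [hematocrit()] (default 0.45).
#' @return A [conc_curve()] of kind `"arterial_plasma"`.
#' @export
blood_to_plasma <- function(curve, hct = hematocrit()) {
  stopifnot(inherits(curve, "conc_curve"))
  if (is.numeric(hct)) hct <- hematocrit(hct)
  if (curve$kind != "arterial_blood")
    dce_stop(sprintf("expected an arterial_blood curve, got '%s'", curve$kind),
             "dce_type_error")
  conc_curve(curve$roi_id, curve$times, curve$values / (1 - hct$value),
             kind = "arterial_plasma")
}

#' Semi-automatic arterial input function from candidate curves
#'
#' Emulates semi-automatic AIF selection over several aortic slices: candidate
#' curves whose peak enhancement falls below `peak_fraction` of the largest
#' peak among candidates are excluded (flat or partial-volume curves), and the
#' remaining curves are averaged pointwise.
#'
#' @param candidates list of [conc_curve()] objects of kind
#'   `"arterial_blood"`, all on the same time grid.
#' @param peak_fraction exclusion threshold as a fraction of the maximum peak
#'   (default 0.5).
#' @return The mean [conc_curve()] (kind `"arterial_blood"`, roi_id `"aif"`).
#' @export
semi_auto_aif <- function(candidates, peak_fraction = 0.5) {
  if (inherits(candidates, "conc_curve")) candidates <- list(candidates)
  if (!length(candidates)) dce_validation_error("no candidate curves supplied")
  tt <- candidates[[1]]$times
  for (cv in candidates) {
    if (!isTRUE(all.equal(cv$times, tt)))
      dce_validation_error("candidate curves must share a common time grid")
  }
  peaks <- vapply(candidates, function(cv) max(cv$values), numeric(1))
  keep <- peaks >= peak_fraction * max(peaks)
  if (!any(keep)) dce_stop("all AIF candidates excluded", "dce_aif_error")
  vals <- rowMeans(vapply(candidates[keep], `[[`, numeric(length(tt)), "values"))
  conc_curve("aif", tt, vals, kind = "arterial_blood")
}
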