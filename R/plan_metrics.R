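#' Homogeneity index of the target dose distribution
#'
#' HI = (D2% - D98%) / prescription dose. Zero means a perfectly uniform
#' target dose; values below about 0.1 are generally considered acceptable
#' for whole-breast plans. The percentile pair is configurable.
#'
#' @param ptv PTV [dvh].
#' @param plan A [plan_context()] supplying the prescription dose.
#' @param upper_percent Hot percentile (default 2, i.e. D2%).
#' @param lower_percent Cold percentile (default 98, i.e. D98%).
#' @return Dimensionless HI (>= 0 for any realistic DVH).
#' @export
homogeneity_index <- function(ptv, plan, upper_percent = 2, lower_percent = 98) {
  if (!inherits(plan, "plan_context")) stop("plan must be a plan_context")
  (dose_at_volume(ptv, upper_percent) - dose_at_volume(ptv, lower_percent)) /
    plan$total_dose
}

#' Conformity index at a reference isodose
#'
#' CI = (V_RI of the PTV)^2 / (100 * sum over structures of V_RI), with
#' every V expressed as a percentage of the structure's own volume. The sum
#' includes the PTV itself, which makes the ideal case (full PTV coverage,
#' nothing else at the isodose) normalize exactly to 1; CI always lies in
#' \[0, 1\].
#'
#' By default the chest wall is excluded from the denominator: it largely
#' overlaps the irradiated breast and is deliberately carried to (near)
#' prescription dose, so counting it would saturate the index at ~0.5 for
#' any clinically conformal plan. Structures receiving nothing at the
#' isodose contribute V_RI = 0 rather than being dropped.
#'
#' @param patient A [patient_record()].
#' @param reference_isodose Isodose level in Gy; default
#'   `ri_fraction * prescription` (95% of prescription: 47.5 Gy CF,
#'   40.43 Gy HF).
#' @param ri_fraction Fraction of prescription used when
#'   `reference_isodose` is `NULL`.
#' @param exclude Structure roles excluded from the denominator sum.
#' @return Dimensionless CI in \[0, 1\].
#' @export
conformity_index <- function(patient, reference_isodose = NULL,
                             ri_fraction = 0.95, exclude = "chest_wall") {
  if (!inherits(patient, "patient_record")) stop("patient must be a patient_record")
  ri <- if (is.null(reference_isodose))
    ri_fraction * patient$plan$total_dose else as.numeric(reference_isodose)[1]
  if (!is.finite(ri) || ri < 0) stop("reference isodose must be >= 0")
  keep <- setdiff(names(patient$structures), exclude)
  keep <- union("ptv", keep)  # PTV always counted
  v <- vapply(patient$structures[keep], volume_at_dose, numeric(1), dose = ri)
  total <- sum(v)
  if (total <= 0)
    stop("degenerate plan: no structure receives any volume at the reference isodose")
  v[["ptv"]]^2 / (100 * total)
}
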