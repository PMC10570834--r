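#' Treatment-plan context
#'
#' Prescription total dose and fraction number of an arm. The two study
#' arms supported out of the box are conventional fractionation
#' (CF, 50 Gy / 25 fractions) and hypofractionation (HF, 42.56 Gy / 16
#' fractions); see [cf_plan()] and [hf_plan()].
#'
#' @param total_dose Prescription dose in Gy (> 0).
#' @param n_fractions Number of treatment fractions (integer >= 1).
#' @return An object of class `"plan_context"`.
#' @export
plan_context <- function(total_dose, n_fractions) {
  total_dose <- as.numeric(total_dose)[1]
  n_fractions <- as.integer(n_fractions)[1]
  if (!is.finite(total_dose) || total_dose <= 0) stop("total_dose must be > 0")
  if (is.na(n_fractions) || n_fractions < 1L) stop("n_fractions must be >= 1")
  structure(list(total_dose = total_dose, n_fractions = n_fractions),
            class = "plan_context")
}

#' @rdname plan_context
#' @export
cf_plan <- function() plan_context(50, 25L)

#' @rdname plan_context
#' @export
hf_plan <- function() plan_context(42.56, 16L)

#' @export
print.plan_context <- function(x, ...) {
  cat(sprintf("<plan> %.4g Gy in %d fractions (%.3g Gy/fx)\n",
              x$total_dose, x$n_fractions, x$total_dose / x$n_fractions))
  invisible(x)
}

#' Canonical structure roles
#'
#' Role labels used throughout the package for the contoured structures of
#' a whole-breast plan. `ptv` is mandatory in every [patient_record()].
#'
#' @return Character vector of role names.
#' @export
structure_roles <- function() {
  c("ptv", "heart", "ipsilateral_lung", "contralateral_lung",
    "chest_wall", "contralateral_breast", "spinal_cord")
}

#' Per-patient structure set
#'
#' Bundles a patient's plan context with the named DVHs of the contoured
#' structures. The PTV must be present; role names must be unique.
#'
#' @param patient_id Identifier string.
#' @param arm Treatment arm label, `"CF"` or `"HF"`.
#' @param plan A [plan_context()].
#' @param structures Named list of [dvh] objects; names are structure roles
#'   (see [structure_roles()]; extra roles are allowed).
#' @return An object of class `"patient_record"`.
#' @export
patient_record <- function(patient_id, arm = c("CF", "HF"), plan, structures) {
  arm <- match.arg(arm)
  if (!inherits(plan, "plan_context")) stop("plan must be a plan_context")
  if (!is.list(structures) || is.null(names(structures)) ||
      any(!nzchar(names(structures))))
    stop("structures must be a fully named list of dvh objects")
  if (anyDuplicated(names(structures))) stop("structure roles must be unique")
  if (!"ptv" %in% names(structures)) stop("a 'ptv' structure is required")
  for (s in structures) validate_dvh(s)
  structure(list(patient_id = as.character(patient_id)[1], arm = arm,
                 plan = plan, structures = structures),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("<patient_record> %s [%s], %.4g Gy / %d fx, %d structures: %s\n",
              x$patient_id, x$arm, x$plan$total_dose, x$plan$n_fractions,
              length(x$structures), paste(names(x$structures), collapse = ", ")))
  invisible(x)
}
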