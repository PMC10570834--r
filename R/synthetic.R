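#' Per-structure dose/volume model for the synthetic generator
#'
#' The synthetic cohort generator draws, for every structure of every
#' patient, (i) an absolute structure volume from a truncated Gaussian,
#' (ii) a patient-level mean dose from a truncated Gaussian centered at
#' `mean_dose_fraction * prescription` with between-patient SD
#' `mean_between_sd`, (iii) a patient-level dose heterogeneity SD as
#' `dose_sd` with lognormal between-patient jitter `sd_rel_between`, and
#' then lays down a differential DVH as the bin masses of a Gaussian
#' truncated at 0 Gy (or a two-component "cold spot" mixture).
#'
#' @param mean_dose_fraction Structure mean dose as a fraction of the
#'   prescription dose.
#' @param dose_sd Within-structure dose heterogeneity SD in Gy; 0 gives an
#'   exactly uniform (delta) DVH.
#' @param mean_between_sd Between-patient SD of the structure mean dose,
#'   Gy.
#' @param sd_rel_between Lognormal sigma of the between-patient jitter on
#'   `dose_sd`.
#' @param shape `"gaussian_truncated"` or `"bimodal_cold_spot"`.
#' @param cold_fraction,cold_dose_fraction Mixture weight and relative
#'   dose of the cold component (bimodal shape only).
#' @param volume_mean,volume_sd Absolute structure volume distribution,
#'   cm^3.
#' @return A list of class `"structure_model"`.
#' @export
structure_model <- function(mean_dose_fraction, dose_sd,
                            mean_between_sd = 0, sd_rel_between = 0,
                            shape = c("gaussian_truncated", "bimodal_cold_spot"),
                            cold_fraction = 0.1, cold_dose_fraction = 0.7,
                            volume_mean = 100, volume_sd = 0) {
  shape <- match.arg(shape)
  if (dose_sd < 0 || mean_between_sd < 0 || sd_rel_between < 0)
    stop("spread parameters must be >= 0")
  if (volume_mean <= 0) stop("volume_mean must be > 0")
  structure(list(mean_dose_fraction = mean_dose_fraction, dose_sd = dose_sd,
                 mean_between_sd = mean_between_sd,
                 sd_rel_between = sd_rel_between, shape = shape,
                 cold_fraction = cold_fraction,
                 cold_dose_fraction = cold_dose_fraction,
                 volume_mean = volume_mean, volume_sd = volume_sd),
            class = "structure_model")
}

#' Default structure models for a whole-breast arm
#'
#' Structure volumes follow the observed per-arm cohort means and SDs of
#' whole-breast IMRT patients (heart ~490/569 cm^3, lungs ~0.9-1.1 L, PTV
#' ~0.7 L for the CF/HF arms); contralateral-breast and spinal-cord
#' volumes are generic anatomical values. Mean dose fractions are tuning
#' constants of the generator, not measured values: the PTV and chest wall
#' sit a few percent above prescription with ~1-1.5 Gy heterogeneity, the
#' ipsilateral lung receives a substantially higher fraction (0.35) than
#' the heart (0.05) and contralateral lung (0.03), reproducing the
#' standard tangent-field dose ordering.
#'
#' @param arm `"CF"` or `"HF"` (selects the volume column).
#' @return Named list of [structure_model()] objects.
#' @export
default_structure_models <- function(arm = c("CF", "HF")) {
  arm <- match.arg(arm)
  vols <- if (arm == "CF") {
    list(ptv = c(673, 206), heart = c(490, 79),
         ipsilateral_lung = c(928, 192), contralateral_lung = c(1000, 268),
         chest_wall = c(515, 187), contralateral_breast = c(600, 180),
         spinal_cord = c(45, 12))
  } else {
    list(ptv = c(706, 184), heart = c(569, 129),
         ipsilateral_lung = c(931, 234), contralateral_lung = c(1080, 220),
         chest_wall = c(541, 164), contralateral_breast = c(620, 170),
         spinal_cord = c(45, 12))
  }
  dose <- list(  # mean fraction, within sd (Gy), between sd (Gy), sd jitter
    ptv = c(1.03, 1.0, 0.25, 0.15),
    heart = c(0.05, 1.5, 0.40, 0.15),
    ipsilateral_lung = c(0.35, 4.0, 1.50, 0.15),
    contralateral_lung = c(0.03, 1.0, 0.30, 0.15),
    chest_wall = c(1.03, 1.5, 0.40, 0.15),
    contralateral_breast = c(0.03, 1.0, 0.30, 0.15),
    spinal_cord = c(0.02, 0.5, 0.15, 0.15))
  out <- lapply(names(dose), function(role) {
    d <- dose[[role]]; v <- vols[[role]]
    structure_model(mean_dose_fraction = d[1], dose_sd = d[2],
                    mean_between_sd = d[3], sd_rel_between = d[4],
                    volume_mean = v[1], volume_sd = v[2])
  })
  names(out) <- names(dose)
  out
}

#' Synthetic cohort specification
#'
#' Default arm sizes mirror the study design the generator emulates: 19
#' patients under conventional fractionation (50 Gy / 25 fx) and 9 under
#' hypofractionation (42.56 Gy / 16 fx).
#'
#' @param arm `"CF"` or `"HF"`.
#' @param n_patients Number of patients (default 19 for CF, 9 for HF).
#' @param plan A [plan_context()] (default [cf_plan()] / [hf_plan()]).
#' @param structures Named list of [structure_model()] objects.
#' @param bin_width DVH bin width in Gy (default 0.1).
#' @param seed Integer seed; patients use per-index substreams, so a
#'   cohort is reproducible and each patient is independent of cohort
#'   order and size.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(arm = c("CF", "HF"), n_patients = NULL, plan = NULL,
                        structures = NULL, bin_width = 0.1, seed = 1L) {
  arm <- match.arg(arm)
  if (is.null(n_patients)) n_patients <- if (arm == "CF") 19L else 9L
  n_patients <- as.integer(n_patients)
  if (is.na(n_patients) || n_patients < 1L) stop("n_patients must be >= 1")
  if (is.null(plan)) plan <- if (arm == "CF") cf_plan() else hf_plan()
  if (!inherits(plan, "plan_context")) stop("plan must be a plan_context")
  if (is.null(structures)) structures <- default_structure_models(arm)
  if (!length(structures) || is.null(names(structures)))
    stop("structures must be a named list of structure_model objects")
  if (!"ptv" %in% names(structures)) stop("a 'ptv' structure model is required")
  for (m in structures)
    if (!inherits(m, "structure_model")) stop("invalid structure model")
  if (bin_width <= 0) stop("bin_width must be > 0")
  structure(list(arm = arm, n_patients = n_patients, plan = plan,
                 structures = structures, bin_width = bin_width,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# one-draw truncated normal (truncation below at `lower`); exact inverse-CDF
rtrunc1 <- function(mean, sd, lower = 0) {
  if (sd <= 0) return(max(mean, lower))
  plo <- stats::pnorm(lower, mean, sd)
  stats::qnorm(stats::runif(1, plo, 1), mean, sd)
}

synth_dvh <- function(role, model, plan, bin_width) {
  td <- plan$total_dose
  vol <- rtrunc1(model$volume_mean, model$volume_sd, lower = 1e-3)
  mu <- rtrunc1(model$mean_dose_fraction * td, model$mean_between_sd)
  sdw <- if (model$dose_sd > 0 && model$sd_rel_between > 0)
    model$dose_sd * exp(stats::rnorm(1, 0, model$sd_rel_between))
  else model$dose_sd
  if (sdw == 0)
    return(dvh(role, c(mu, mu), 1, vol))
  top <- max(td * 1.3, mu + 6 * sdw)
  edges <- seq(0, top, by = bin_width)
  if (edges[length(edges)] < top) edges <- c(edges, top)
  p <- diff(stats::pnorm(edges, mu, sdw))
  if (model$shape == "bimodal_cold_spot") {
    cf <- model$cold_fraction
    p <- (1 - cf) * p +
      cf * diff(stats::pnorm(edges, mu * model$cold_dose_fraction, sdw))
  }
  s <- sum(p)
  if (s <= 0) stop("degenerate synthetic dose model for ", role)
  dvh(role, edges, p / s, vol)
}

#' Generate one synthetic patient
#'
#' Deterministic given `(spec$seed, patient_index)`: the generator seeds a
#' per-patient substream, so the same patient is reproduced regardless of
#' how many other patients are drawn. The caller's RNG state is preserved.
#'
#' @param spec A [cohort_spec()].
#' @param patient_index Positive integer index within the cohort.
#' @return A [patient_record()].
#' @export
generate_patient <- function(spec, patient_index) {
  if (!inherits(spec, "cohort_spec")) stop("spec must be a cohort_spec")
  patient_index <- as.integer(patient_index)
  if (is.na(patient_index) || patient_index < 1L)
    stop("patient_index must be >= 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed((abs(spec$seed) %% 1000003L) * 2011L + 7919L * patient_index)
  sts <- lapply(names(spec$structures), function(role)
    synth_dvh(role, spec$structures[[role]], spec$plan, spec$bin_width))
  names(sts) <- names(spec$structures)
  patient_record(sprintf("%s-%03d", spec$arm, patient_index), spec$arm,
                 spec$plan, sts)
}

#' Generate a synthetic cohort
#'
#' @param spec A [cohort_spec()].
#' @return List of `spec$n_patients` [patient_record()] objects.
#' @export
generate_cohort <- function(spec) {
  lapply(seq_len(spec$n_patients), function(i) generate_patient(spec, i))
}
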