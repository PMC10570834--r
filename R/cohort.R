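#' Arm summary: mean, sample SD, n
#'
#' @param values Numeric vector, length >= 2 (NAs dropped).
#' @return List with `mean`, `sd` (n-1 denominator), `n`.
#' @export
summarize_arm <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2L)
    stop("at least 2 observations are required to summarize an arm")
  list(mean = mean(values), sd = stats::sd(values), n = length(values))
}

#' Independent two-sample t-test
#'
#' Two-sided test of equal means with the classical pooled-variance
#' (Student) statistic by default; set `welch = TRUE` for the Welch
#' unequal-variance form. The sign convention is
#' `t = (mean(group_a) - mean(group_b)) / SE`, so passing (CF, HF) matches
#' the reporting convention of CF-vs-HF comparison tables. Degenerate
#' zero-variance input is resolved explicitly: equal means give `t = 0,
#' p = 1`; unequal means give `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch test instead of pooled variance.
#' @return List with `t_value`, `p_value`, `df`.
#' @export
independent_t_test <- function(group_a, group_b, welch = FALSE) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 observations")
  pooled_var <- ((na - 1) * stats::var(group_a) +
                 (nb - 1) * stats::var(group_b)) / (na + nb - 2)
  if (pooled_var == 0) {
    delta <- mean(group_a) - mean(group_b)
    if (delta == 0) return(list(t_value = 0, p_value = 1, df = na + nb - 2))
    return(list(t_value = sign(delta) * Inf, p_value = 0, df = na + nb - 2))
  }
  tt <- stats::t.test(group_a, group_b, var.equal = !welch)
  list(t_value = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

params_for_role <- function(role, tissue) {
  key <- switch(role,
                ptv = "ptv",
                heart = "heart",
                ipsilateral_lung = "lung",
                contralateral_lung = "lung",
                NA_character_)
  if (is.na(key) || is.null(tissue[[key]])) NULL else tissue[[key]]
}

#' Per-patient plan-evaluation metrics
#'
#' Computes the full evaluation row for one patient: structure volumes,
#' conformity and homogeneity indices, PTV Dmin/Dmax/Dmean, EUD and TCP of
#' the PTV, LKB NTCP of the heart and each lung, and V at the requested
#' percent-of-prescription levels for the PTV and chest wall. TCP and NTCP
#' are reported in percent; EUD and D-statistics in Gy; volumes in cm^3.
#' Quantities whose structure is missing are set to `NA` with a warning.
#'
#' @param patient A [patient_record()].
#' @param tissue Tissue-parameter registry
#'   (default [default_tissue_parameters()]).
#' @param ri_fraction Reference-isodose fraction of prescription for the
#'   conformity index (default 0.95).
#' @param v_levels Percent-of-prescription levels for V metrics
#'   (default 95, 100, 107).
#' @param eud_dose_floor Cold-spot clamp forwarded to [eud()].
#' @return One-row `data.frame`.
#' @export
patient_metrics <- function(patient, tissue = default_tissue_parameters(),
                            ri_fraction = 0.95, v_levels = c(95, 100, 107),
                            eud_dose_floor = 0) {
  if (!inherits(patient, "patient_record")) stop("patient must be a patient_record")
  st <- patient$structures
  plan <- patient$plan
  miss <- function(role) {
    warning(sprintf("patient %s: structure '%s' missing, quantity set to NA",
                    patient$patient_id, role), call. = FALSE)
    NA_real_
  }
  row <- list(patient_id = patient$patient_id, arm = patient$arm)
  for (role in structure_roles())
    row[[paste0("vol_", role)]] <-
      if (role %in% names(st)) st[[role]]$volume_cm3 else miss(role)
  row$ci <- conformity_index(patient, ri_fraction = ri_fraction)
  row$hi <- homogeneity_index(st$ptv, plan)
  ss <- dvh_summary(st$ptv)
  row$d_min_ptv <- ss$d_min
  row$d_max_ptv <- ss$d_max
  row$d_mean_ptv <- ss$d_mean
  tp <- params_for_role("ptv", tissue)
  row$eud_ptv <- eud(st$ptv, plan, tp, dose_floor = eud_dose_floor)
  row$tcp_ptv <- 100 * tcp_poisson_lq(st$ptv, plan, tp)
  for (role in c("heart", "ipsilateral_lung", "contralateral_lung")) {
    col <- paste0("ntcp_", role)
    row[[col]] <- if (role %in% names(st))
      100 * ntcp_lkb(st[[role]], plan, params_for_role(role, tissue))
    else miss(role)
  }
  for (role in c("ptv", "chest_wall")) {
    for (lev in v_levels) {
      col <- sprintf("v%g_%s", lev, role)
      row[[col]] <- if (role %in% names(st))
        volume_at_dose(st[[role]], lev / 100 * plan$total_dose)
      else miss(role)
    }
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Per-cohort metrics table
#'
#' Applies [patient_metrics()] to every patient of a cohort and binds the
#' rows.
#'
#' @param patients List of [patient_record()] objects.
#' @param ... Passed on to [patient_metrics()].
#' @return A `data.frame`, one row per patient.
#' @export
cohort_metrics <- function(patients, ...) {
  do.call(rbind, lapply(patients, patient_metrics, ...))
}

#' Compare two treatment arms quantity by quantity
#'
#' Summarizes every evaluation quantity (mean +/- sample SD per arm) and
#' tests the CF-vs-HF difference with an independent two-sample t-test at
#' alpha = 0.05. Row order follows the fixed column order of
#' [patient_metrics()]: volumes, CI, HI, PTV dose statistics,
#' radiobiological endpoints, then V-level coverages. No multiple-testing
#' correction is applied. Patients with a quantity `NA` (missing
#' structure) are excluded from that quantity only.
#'
#' @param cf_patients,hf_patients Lists of [patient_record()] (>= 2 each).
#' @param tissue Tissue-parameter registry.
#' @param quantities Optional character vector restricting/ordering the
#'   compared quantities (default: all metric columns).
#' @param welch Use Welch's t-test instead of pooled variance.
#' @param alpha Significance level (default 0.05).
#' @param ... Passed on to [patient_metrics()].
#' @return A `data.frame` of class `"cohort_comparison"` with columns
#'   `quantity`, `cf_mean`, `cf_sd`, `cf_n`, `hf_mean`, `hf_sd`, `hf_n`,
#'   `t_value`, `p_value`, `significant`.
#' @export
compare_cohorts <- function(cf_patients, hf_patients,
                            tissue = default_tissue_parameters(),
                            quantities = NULL, welch = FALSE, alpha = 0.05,
                            ...) {
  if (length(cf_patients) < 2L || length(hf_patients) < 2L)
    stop("each arm needs at least 2 patients")
  cf <- cohort_metrics(cf_patients, tissue = tissue, ...)
  hf <- cohort_metrics(hf_patients, tissue = tissue, ...)
  all_q <- setdiff(names(cf), c("patient_id", "arm"))
  if (is.null(quantities)) quantities <- all_q
  bad <- setdiff(quantities, all_q)
  if (length(bad)) stop("unknown quantities: ", paste(bad, collapse = ", "))
  rows <- lapply(quantities, function(q) {
    a <- cf[[q]][!is.na(cf[[q]])]
    b <- hf[[q]][!is.na(hf[[q]])]
    if (length(a) < 2L || length(b) < 2L) {
      warning(sprintf("quantity '%s': fewer than 2 usable patients in an arm; skipped", q),
              call. = FALSE)
      return(NULL)
    }
    sa <- summarize_arm(a); sb <- summarize_arm(b)
    tt <- independent_t_test(a, b, welch = welch)
    data.frame(quantity = q, cf_mean = sa$mean, cf_sd = sa$sd, cf_n = sa$n,
               hf_mean = sb$mean, hf_sd = sb$sd, hf_n = sb$n,
               t_value = tt$t_value, p_value = tt$p_value,
               significant = tt$p_value < alpha, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("cohort_comparison", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' Format a cohort comparison as a fixed-width report table
#'
#' @param x A `cohort_comparison` from [compare_cohorts()].
#' @return Character vector of report lines (mean +/- SD per arm, t, p).
#' @export
format_comparison <- function(x) {
  fmt <- function(m, s) sprintf("%.3f ± %.3f", m, s)
  lines <- sprintf("%-26s %-20s %-20s %8.2f %8.4f%s",
                   x$quantity, fmt(x$cf_mean, x$cf_sd),
                   fmt(x$hf_mean, x$hf_sd), x$t_value, x$p_value,
                   ifelse(x$significant, " *", ""))
  header <- sprintf("%-26s %-20s %-20s %8s %8s", "quantity",
                    sprintf("CF (n=%d)", max(x$cf_n)),
                    sprintf("HF (n=%d)", max(x$hf_n)), "t", "p")
  c(header, strrep("-", nchar(header)), lines,
    sprintf("* p < %.2f, independent two-sample t-test (no multiplicity correction)",
            attr(x, "alpha")))
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}
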