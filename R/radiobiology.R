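#' Tissue-specific radiobiological parameters
#'
#' Container for the constants driving the dose-response models: the
#' linear-quadratic fractionation ratio `alpha_beta` (Gy), the Niemierko
#' EUD exponent `a` (negative for tumor targets, where cold spots
#' dominate), the Poisson-LQ slope `gamma` and 50%-response dose `d50`
#' (Gy), and the LKB slope `m` and volume-effect exponent `n` for organs
#' at risk.
#'
#' @param organ Organ/role label.
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @param a EUD exponent (targets; must be nonzero when given).
#' @param gamma Normalized maximum slope of the dose-response curve
#'   (targets).
#' @param d50 Dose giving 50% response probability, Gy (> 0).
#' @param m LKB slope parameter (> 0; organs at risk).
#' @param n LKB volume-effect parameter in (0, 1\] (organs at risk).
#' @return An object of class `"tissue_parameters"`.
#' @export
tissue_parameters <- function(organ, alpha_beta, a = NULL, gamma = NULL,
                              d50 = NULL, m = NULL, n = NULL) {
  num1 <- function(x) if (is.null(x)) NULL else as.numeric(x)[1]
  alpha_beta <- num1(alpha_beta)
  if (!is.finite(alpha_beta) || alpha_beta <= 0) stop("alpha_beta must be > 0")
  a <- num1(a); gamma <- num1(gamma); d50 <- num1(d50)
  m <- num1(m); n <- num1(n)
  if (!is.null(a) && (!is.finite(a) || a == 0)) stop("a must be nonzero")
  if (!is.null(d50) && (!is.finite(d50) || d50 <= 0)) stop("d50 must be > 0")
  if (!is.null(m) && (!is.finite(m) || m <= 0)) stop("m must be > 0")
  if (!is.null(n) && (!is.finite(n) || n <= 0 || n > 1))
    stop("n must lie in (0, 1]")
  structure(list(organ = as.character(organ)[1], alpha_beta = alpha_beta,
                 a = a, gamma = gamma, d50 = d50, m = m, n = n),
            class = "tissue_parameters")
}

#' Default tissue-parameter registry
#'
#' Reads the packaged whole-breast parameter set: alpha/beta = 4 Gy for
#' breast PTV, heart and lung; breast PTV a = -7.2, gamma = 1.3,
#' D50 = 30.89 Gy; heart D50 = 48 Gy, m = 0.1, n = 0.35; lung
#' D50 = 37.6 Gy, m = 0.35, n = 0.87. Both lungs share the `lung` entry.
#' Every value can be overridden by supplying your own YAML file to
#' [read_tissue_parameters()].
#'
#' @return Named list of [tissue_parameters()] keyed by organ
#'   (`ptv`, `heart`, `lung`).
#' @export
default_tissue_parameters <- function() {
  read_tissue_parameters(
    system.file("extdata", "tissue_parameters.yaml", package = "radcomp",
                mustWork = TRUE))
}

#' Read a tissue-parameter registry from YAML
#'
#' The file maps organ names to keys `alpha_beta`, and optionally `a`,
#' `gamma`, `d50`, `m`, `n` (see the packaged
#' `extdata/tissue_parameters.yaml` for the expected layout).
#'
#' @param path Path to a YAML file.
#' @return Named list of [tissue_parameters()].
#' @export
read_tissue_parameters <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(org) {
    p <- raw[[org]]
    tissue_parameters(org, alpha_beta = p[["alpha_beta"]], a = p[["a"]],
                      gamma = p[["gamma"]], d50 = p[["d50"]], m = p[["m"]], n = p[["n"]])
  })
  names(out) <- names(raw)
  out
}

#' Fractionation-corrected dose (EQD, 2 Gy-equivalent)
#'
#' Linear-quadratic conversion of a total dose `D` delivered in
#' `n_fractions` equal fractions into the biologically equivalent dose
#' delivered at 2 Gy per fraction:
#' `EQD = D * (alpha_beta + D / n_fractions) / (alpha_beta + 2)`.
#' When the per-fraction dose is exactly 2 Gy, EQD equals D. Every voxel is
#' assumed to be treated in all fractions, so a voxel's per-fraction dose
#' is its total dose divided by `n_fractions`.
#'
#' @param dose Total physical dose(s) in Gy (vectorized, >= 0).
#' @param n_fractions Number of fractions (>= 1).
#' @param alpha_beta Alpha/beta ratio in Gy (> 0).
#' @return EQD in Gy, same length as `dose`.
#' @examples
#' eqd(50, 25, 4)      # 50
#' eqd(42.56, 16, 4)   # 47.2416
#' @export
eqd <- function(dose, n_fractions, alpha_beta) {
  if (any(!is.finite(dose)) || any(dose < 0)) stop("dose must be >= 0")
  if (n_fractions < 1) stop("n_fractions must be >= 1")
  if (alpha_beta <= 0) stop("alpha_beta must be > 0")
  dose * (alpha_beta + dose / n_fractions) / (alpha_beta + 2)
}

## -- EQD-space kernels ------------------------------------------------------
## These operate on a vector of per-bin (or per-voxel) EQD values and the
## associated volumes; volumes are normalized internally, so absolute or
## fractional volumes are both accepted.

#' Generalized-mean equivalent uniform dose from EQD values
#'
#' Niemierko gEUD: `EUD = (sum_i v_i * EQD_i^a)^(1/a)` over normalized
#' volumes `v_i`. Evaluated in log space for numerical stability at large
#' `|a|`. For negative `a` a zero-dose component drives the generalized
#' mean to 0; the mathematical limit is returned with a warning. Supply
#' `dose_floor > 0` to clamp cold bins instead.
#'
#' @param eqd_gy EQD per bin/voxel, Gy.
#' @param volume Nonnegative volumes (any scale; normalized internally).
#' @param a Nonzero exponent; `a = 1` is the plain mean, large negative `a`
#'   approaches the minimum.
#' @param dose_floor Lower clamp in Gy applied to `eqd_gy` before
#'   evaluation (default 0 = no clamp).
#' @return EUD in Gy.
#' @export
eud_gmean <- function(eqd_gy, volume, a, dose_floor = 0) {
  if (!is.finite(a) || a == 0) stop("a must be nonzero and finite")
  w <- normalize_volumes(volume)
  keep <- w > 0
  w <- w[keep]
  x <- pmax(eqd_gy[keep], dose_floor)
  if (a < 0 && any(x <= 0)) {
    warning("zero-dose component with negative exponent: EUD -> 0 ",
            "(set dose_floor > 0 for a cold-spot-robust value)")
    return(0)
  }
  if (any(x <= 0)) return(0)  # a > 0 with all mass at 0
  lx <- a * log(x)
  mmax <- max(lx)
  exp((mmax + log(sum(w * exp(lx - mmax)))) / a)
}

#' Poisson linear-quadratic TCP from EQD values
#'
#' Voxel-wise Poisson-LQ response aggregated over the target:
#' `TCP = prod_i [exp(-exp(e*gamma - (EQD_i/D50) * (e*gamma - ln ln 2)))]^{v_i}`
#' with `e` Euler's number and `v_i` normalized volumes. At a uniform EQD
#' equal to `d50` the model returns exactly 0.5.
#'
#' @inheritParams eud_gmean
#' @param gamma Normalized maximum slope of the dose-response curve.
#' @param d50 50%-control dose, Gy.
#' @return Probability in \[0, 1\].
#' @export
tcp_from_eqd <- function(eqd_gy, volume, gamma, d50) {
  if (d50 <= 0) stop("d50 must be > 0")
  w <- normalize_volumes(volume)
  eg <- exp(1) * gamma
  lnln2 <- log(log(2))
  log_tcp <- sum(w * -exp(eg - (eqd_gy / d50) * (eg - lnln2)))
  exp(log_tcp)
}

#' LKB effective dose from EQD values
#'
#' Kutcher-Burman volume reduction of a heterogeneous distribution to the
#' uniform dose with equal complication effect:
#' `Deff = (sum_i v_i * EQD_i^(1/n))^n`. `n = 1` gives the mean EQD
#' (parallel organ); small `n` approaches the maximum (serial organ).
#' Uniform dose returns that dose for any `n`.
#'
#' @inheritParams eud_gmean
#' @param n Volume-effect parameter in (0, 1].
#' @return Effective dose in Gy.
#' @export
deff_gmean <- function(eqd_gy, volume, n) {
  if (!is.finite(n) || n <= 0 || n > 1) stop("n must lie in (0, 1]")
  w <- normalize_volumes(volume)
  sum(w * eqd_gy^(1 / n))^n
}

normalize_volumes <- function(volume) {
  if (any(volume < 0)) stop("volumes must be >= 0")
  s <- sum(volume)
  if (s <= 0) stop("total volume must be > 0")
  volume / s
}

## -- DVH-level endpoints ----------------------------------------------------

dvh_eqd <- function(x, plan, params) {
  d <- dvh_differential(x)
  keep <- d$values > 0
  list(eqd = eqd(bin_centers(d)[keep], plan$n_fractions, params$alpha_beta),
       vol = d$values[keep])
}

#' Equivalent uniform dose of a structure
#'
#' Converts each DVH bin to its fractionation-corrected dose ([eqd()]) and
#' reduces with the Niemierko generalized mean ([eud_gmean()]). For a
#' uniform distribution the result is the EQD of that dose regardless of
#' the exponent.
#'
#' @param x A [dvh] (any form; converted to differential).
#' @param plan A [plan_context()].
#' @param params [tissue_parameters()] providing `alpha_beta` and `a`.
#' @param dose_floor Optional cold-spot clamp in Gy, see [eud_gmean()].
#' @return EUD in Gy.
#' @export
eud <- function(x, plan, params, dose_floor = 0) {
  if (is.null(params$a)) stop("EUD requires the exponent 'a'")
  pe <- dvh_eqd(x, plan, params)
  eud_gmean(pe$eqd, pe$vol, params$a, dose_floor = dose_floor)
}

#' Tumor control probability of a target structure
#'
#' Poisson linear-quadratic TCP over the target DVH (see [tcp_from_eqd()]).
#'
#' @inheritParams eud
#' @param params [tissue_parameters()] providing `alpha_beta`, `gamma`,
#'   `d50`.
#' @return Probability in \[0, 1\].
#' @export
tcp_poisson_lq <- function(x, plan, params) {
  if (is.null(params$gamma) || is.null(params$d50))
    stop("TCP requires 'gamma' and 'd50'")
  pe <- dvh_eqd(x, plan, params)
  tcp_from_eqd(pe$eqd, pe$vol, params$gamma, params$d50)
}

#' LKB effective dose of an organ at risk
#'
#' @inheritParams eud
#' @param params [tissue_parameters()] providing `alpha_beta` and `n`.
#' @return Effective dose in Gy.
#' @export
effective_dose <- function(x, plan, params) {
  if (is.null(params$n)) stop("effective dose requires 'n'")
  pe <- dvh_eqd(x, plan, params)
  deff_gmean(pe$eqd, pe$vol, params$n)
}

#' Lyman-Kutcher-Burman NTCP of an organ at risk
#'
#' Reduces the DVH to the effective dose `Deff` ([effective_dose()]), forms
#' `t = (Deff - D50) / (m * D50)` and returns `NTCP = Phi(t)`, the standard
#' normal CDF. `Deff = D50` gives exactly 0.5; NTCP is strictly increasing
#' in `Deff`.
#'
#' @inheritParams eud
#' @param params [tissue_parameters()] providing `alpha_beta`, `d50`, `m`,
#'   `n`.
#' @return Probability in (0, 1).
#' @export
ntcp_lkb <- function(x, plan, params) {
  if (is.null(params$d50) || is.null(params$m) || is.null(params$n))
    stop("LKB NTCP requires 'd50', 'm' and 'n'")
  deff <- effective_dose(x, plan, params)
  stats::pnorm((deff - params$d50) / (params$m * params$d50))
}
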