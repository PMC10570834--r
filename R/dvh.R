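#' Dose-volume histogram objects
#'
#' A `dvh` stores one structure's dose distribution as a histogram over
#' contiguous dose bins. Two forms exist:
#'
#' * `"differential"`: `values` has one entry per bin (length `B` for
#'   `B + 1` bin edges) giving the fraction of the structure volume whose
#'   dose falls in that bin; fractions sum to 1.
#' * `"cumulative"`: `values` has one entry per bin *edge* (length `B + 1`)
#'   giving the fraction of the volume receiving at least that dose; the
#'   curve is non-increasing and starts at 1.
#'
#' Bin edges must be non-decreasing and non-negative. A zero-width bin
#' (`lo == hi`) is permitted and represents a point mass ("delta" bin): the
#' whole bin fraction is received at exactly that dose. This is how exactly
#' uniform distributions are represented.
#'
#' Within a positive-width bin, dose is attributed to the bin center for
#' moment-type quantities (Dmean, EUD, TCP, NTCP inputs), while Dx% and
#' V_RI interpolate linearly on the cumulative curve between bin edges.
#' Under this convention splitting a bin into two equal halves leaves Dx%,
#' V_RI and Dmean unchanged.
#'
#' @param structure Structure label (e.g. `"ptv"`, `"heart"`).
#' @param bin_edges Numeric vector of dose bin edges in Gy, non-decreasing,
#'   first edge >= 0, length `B + 1`.
#' @param values Numeric vector of volume fractions: length `B`
#'   (differential) or `B + 1` (cumulative).
#' @param volume_cm3 Absolute structure volume in cm^3 (> 0).
#' @param form `"differential"` or `"cumulative"`.
#' @return An object of class `"dvh"`.
#' @examples
#' d <- dvh("ptv", c(0, 10, 20), c(0.4, 0.6), volume_cm3 = 650)
#' dvh_cumulative(d)$values  # 1.0 0.6 0.0
#' @export
dvh <- function(structure, bin_edges, values, volume_cm3,
                form = c("differential", "cumulative")) {
  form <- match.arg(form)
  obj <- structure(
    list(structure = as.character(structure)[1],
         bin_edges = as.numeric(bin_edges),
         values = as.numeric(values),
         volume_cm3 = as.numeric(volume_cm3)[1],
         form = form),
    class = "dvh")
  validate_dvh(obj)
  obj
}

#' Validate a dvh object
#'
#' Checks the structural invariants of a [dvh] and stops with an
#' informative message on violation.
#'
#' @param x A `dvh`.
#' @return `x`, invisibly.
#' @export
validate_dvh <- function(x) {
  if (!inherits(x, "dvh")) stop("not a 'dvh' object")
  e <- x$bin_edges
  v <- x$values
  if (length(e) < 2L || anyNA(e) || any(!is.finite(e)))
    stop("bin_edges must be a finite numeric vector of length >= 2")
  if (any(diff(e) < 0)) stop("bin_edges must be non-decreasing")
  if (e[1] < 0) stop("dose values must be >= 0")
  if (anyNA(v) || any(!is.finite(v))) stop("volume values must be finite")
  if (!is.finite(x$volume_cm3) || x$volume_cm3 <= 0)
    stop("absolute volume must be > 0")
  if (x$form == "differential") {
    if (length(v) != length(e) - 1L)
      stop("differential form needs one value per bin (length(bin_edges) - 1)")
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      stop("volume fractions must lie in [0, 1]")
    if (abs(sum(v) - 1) > 1e-9)
      stop("differential volume fractions must sum to 1 (tolerance 1e-9)")
  } else {
    if (length(v) != length(e))
      stop("cumulative form needs one value per bin edge")
    if (abs(v[1] - 1) > 1e-9)
      stop("cumulative curve must start at 1 (100% of volume at >= 0 Gy)")
    if (any(diff(v) > 1e-12))
      stop("cumulative curve must be non-increasing")
    if (any(v < -1e-12) || any(v > 1 + 1e-12))
      stop("cumulative values must lie in [0, 1]")
  }
  invisible(x)
}

#' @export
print.dvh <- function(x, ...) {
  b <- length(x$bin_edges) - 1L
  cat(sprintf("<dvh> %s: %d bins over [%.4g, %.4g] Gy, %s form, %.1f cm^3\n",
              x$structure, b, x$bin_edges[1], x$bin_edges[length(x$bin_edges)],
              x$form, x$volume_cm3))
  invisible(x)
}

#' Single-bin (uniform-dose) DVH
#'
#' Convenience constructor for a structure receiving exactly `dose` Gy in
#' its whole volume, represented as one zero-width delta bin.
#'
#' @param structure Structure label.
#' @param dose Dose in Gy (>= 0).
#' @param volume_cm3 Absolute volume in cm^3.
#' @return A differential [dvh] with all volume at `dose`.
#' @export
uniform_dvh <- function(structure, dose, volume_cm3 = 100) {
  dvh(structure, c(dose, dose), 1, volume_cm3, form = "differential")
}

#' Convert a DVH to cumulative form
#'
#' The cumulative value at bin edge `e` is the total volume fraction
#' receiving dose >= `e`. Differential input is required (the operation on
#' already-cumulative input is the identity).
#'
#' @param x A [dvh].
#' @return A `dvh` in cumulative form.
#' @seealso [dvh_differential()] for the inverse.
#' @export
dvh_cumulative <- function(x) {
  validate_dvh(x)
  if (x$form == "cumulative") return(x)
  cum <- c(1, 1 - cumsum(x$values))
  # clamp accumulated rounding
  cum[length(cum)] <- max(cum[length(cum)], 0)
  out <- x
  out$values <- cum
  out$form <- "cumulative"
  out
}

#' Convert a DVH to differential form
#'
#' Inverse of [dvh_cumulative()]: bin fractions are the negative discrete
#' differences of the cumulative curve. Round-tripping reproduces the input
#' to within 1e-12.
#'
#' @param x A [dvh].
#' @return A `dvh` in differential form.
#' @export
dvh_differential <- function(x) {
  validate_dvh(x)
  if (x$form == "differential") return(x)
  out <- x
  out$values <- pmax(-diff(x$values), 0)
  out$form <- "differential"
  out
}

bin_centers <- function(x) {
  e <- x$bin_edges
  (e[-length(e)] + e[-1]) / 2
}

#' Minimum dose received by the hottest x% of a structure (Dx%)
#'
#' Returns the dose `d` such that `x_percent` of the structure volume
#' receives at least `d`, by linear interpolation on the cumulative DVH.
#' On a plateau of the cumulative curve the highest dose attaining the
#' requested fraction is returned (the "minimum dose received by x% of the
#' volume" reading). Monotone non-increasing in `x_percent`.
#'
#' @param x A [dvh].
#' @param x_percent Volume percentage in (0, 100].
#' @return Dose in Gy.
#' @examples
#' d <- uniform_dvh("ptv", 50)
#' dose_at_volume(d, 98)  # 50
#' @export
dose_at_volume <- function(x, x_percent) {
  if (!is.numeric(x_percent) || length(x_percent) != 1L ||
      is.na(x_percent) || x_percent <= 0 || x_percent > 100)
    stop("x_percent must be a single value in (0, 100]")
  cd <- dvh_cumulative(x)
  e <- cd$bin_edges
  cum <- cd$values
  y <- x_percent / 100
  idx <- which(cum >= y - 1e-12)
  if (!length(idx)) return(e[1])
  i <- max(idx)
  if (i == length(cum)) return(e[i])
  denom <- cum[i] - cum[i + 1]
  if (denom <= 0) return(e[i])
  e[i] + (e[i + 1] - e[i]) * (cum[i] - y) / denom
}

#' Percent of structure volume receiving at least a given dose (V_RI)
#'
#' Linear interpolation of the cumulative DVH between bin edges. A query
#' exactly at a delta bin's dose counts the whole point mass (dose >= RI is
#' inclusive).
#'
#' @param x A [dvh].
#' @param dose Reference dose (isodose) in Gy, >= 0.
#' @return Percentage of volume in \[0, 100\].
#' @examples
#' d <- uniform_dvh("ptv", 50)
#' volume_at_dose(d, 47.5)  # 100
#' volume_at_dose(d, 53.5)  # 0
#' @export
volume_at_dose <- function(x, dose) {
  if (!is.numeric(dose) || length(dose) != 1L || is.na(dose) || dose < 0)
    stop("dose must be a single value >= 0")
  cd <- dvh_cumulative(x)
  e <- cd$bin_edges
  cum <- cd$values
  if (dose <= e[1]) return(100)
  if (dose > e[length(e)]) return(0)
  hit <- e == dose
  if (any(hit)) return(100 * max(cum[hit]))
  j <- findInterval(dose, e)
  frac <- (dose - e[j]) / (e[j + 1] - e[j])
  100 * (cum[j] + frac * (cum[j + 1] - cum[j]))
}

#' Summary dose statistics of a DVH
#'
#' Dmin and Dmax are the bin-center doses of the lowest and highest bin with
#' nonzero volume fraction; Dmean is the volume-weighted mean of bin-center
#' doses.
#'
#' @param x A [dvh].
#' @return A list with elements `d_min`, `d_max`, `d_mean` (Gy).
#' @export
dvh_summary <- function(x) {
  d <- dvh_differential(x)
  v <- d$values
  if (sum(v) <= 0) stop("DVH carries no volume")
  ctr <- bin_centers(d)
  nz <- which(v > 0)
  list(d_min = ctr[min(nz)],
       d_max = ctr[max(nz)],
       d_mean = sum(v * ctr) / sum(v))
}
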