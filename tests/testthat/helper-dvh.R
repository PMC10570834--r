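# shared fixture builders (all programmatic; no stored data)

# random valid differential DVH
rand_dvh <- function(n_bins = 5, max_dose = 60, structure = "s", vol = 100) {
  edges <- sort(stats::runif(n_bins + 1, 0, max_dose))
  v <- stats::runif(n_bins)
  dvh(structure, edges, v / sum(v), vol)
}

# mixture of point masses ("delta" bins) at given doses
delta_mix_dvh <- function(structure, doses, fractions, vol = 100) {
  o <- order(doses)
  doses <- doses[o]
  fractions <- fractions[o]
  k <- length(doses)
  edges <- rep(doses, each = 2)
  vals <- numeric(2 * k - 1)
  vals[seq(1, 2 * k - 1, by = 2)] <- fractions
  dvh(structure, edges, vals, vol)
}

# physical total dose whose EQD equals `eqd_target` (closed-form inverse
# of the linear-quadratic conversion; independent of the package path)
dose_for_eqd <- function(eqd_target, n_fractions, alpha_beta) {
  nf <- n_fractions
  ab <- alpha_beta
  nf / 2 * (-ab + sqrt(ab^2 + 4 * eqd_target * (ab + 2) / nf))
}

# histogram a voxel-dose list into a contiguous DVH of given bin width
bin_voxels <- function(doses, width, structure = "s", vol = 100) {
  edges <- seq(0, max(doses) + width, by = width)
  h <- graphics::hist(doses, breaks = edges, plot = FALSE)
  dvh(structure, edges, h$counts / length(doses), vol)
}

# bin-center doses of a differential DVH (test-local copy)
bin_centers <- function(d) {
  e <- d$bin_edges
  (e[-length(e)] + e[-1]) / 2
}

# patient with uniformly irradiated structures
make_uniform_patient <- function(doses, plan = cf_plan(), arm = "CF",
                                 id = "p1") {
  sts <- lapply(names(doses), function(r) uniform_dvh(r, doses[[r]]))
  names(sts) <- names(doses)
  patient_record(id, arm, plan, sts)
}
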