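tis <- default_tissue_parameters()

test_that("the packaged tissue registry carries the whole-breast constants", {
  expect_equal(tis$ptv$alpha_beta, 4)
  expect_equal(tis$ptv$a, -7.2)
  expect_equal(tis$ptv$gamma, 1.3)
  expect_equal(tis$ptv$d50, 30.89)
  expect_equal(tis$heart[c("d50", "m", "n")], list(d50 = 48, m = 0.1, n = 0.35))
  expect_equal(tis$lung[c("d50", "m", "n")], list(d50 = 37.6, m = 0.35, n = 0.87))
})

test_that("EQD conversion matches hand arithmetic and is monotone", {
  expect_equal(eqd(50, 25, 4), 50)                     # 2 Gy/fx fixed point
  expect_equal(eqd(42.56, 16, 4), 47.2416, tolerance = 1e-9)
  expect_equal(eqd(0, 25, 4), 0)
  d <- seq(0, 80, by = 0.5)
  expect_true(all(diff(eqd(d, 16, 4)) > 0))
  expect_error(eqd(-1, 25, 4), "dose")
})

test_that("EUD is the Niemierko generalized mean over EQD", {
  p <- cf_plan()
  # uniform distribution: EUD equals the EQD of that dose for any a
  for (a in c(-100, -7.2, -1, 1, 3)) {
    prm <- tissue_parameters("t", 4, a = a)
    expect_equal(eud(uniform_dvh("ptv", 50), p, prm), 50, tolerance = 1e-9)
    expect_equal(eud(uniform_dvh("ptv", 30), p, prm), eqd(30, 25, 4),
                 tolerance = 1e-9)
  }
  # two equal-volume components: brute-force formula oracle
  expect_equal(eud_gmean(c(40, 50), c(0.5, 0.5), -7.2),
               (0.5 * 40^-7.2 + 0.5 * 50^-7.2)^(-1 / 7.2))
  expect_equal(eud_gmean(c(40, 50), c(0.5, 0.5), -7.2), 42.938225486128772,
               tolerance = 1e-9)
  expect_lt(eud_gmean(c(40, 50), c(0.5, 0.5), -7.2), 45)  # cold spot dominates
  expect_equal(eud_gmean(c(40, 50), c(0.5, 0.5), 1), 45)
})

test_that("zero-dose cold spots drive negative-exponent EUD to 0 unless floored", {
  d <- delta_mix_dvh("ptv", c(0, 50), c(0.1, 0.9))
  prm <- tis$ptv
  expect_warning(e0 <- eud(d, cf_plan(), prm), "dose_floor")
  expect_equal(e0, 0)
  ef <- eud(d, cf_plan(), prm, dose_floor = 1e-6)
  expect_gt(ef, 0)
})

test_that("Poisson-LQ TCP hits its analytic fixed points", {
  # uniform EQD at D50 gives exactly 1/2
  expect_equal(tcp_from_eqd(30.89, 1, gamma = 1.3, d50 = 30.89), 0.5,
               tolerance = 1e-12)
  # brute-force evaluation at uniform EQD = 50
  eg <- exp(1) * 1.3
  oracle <- exp(-exp(eg - (50 / 30.89) * (eg - log(log(2)))))
  expect_equal(tcp_from_eqd(50, 1, 1.3, 30.89), oracle)
  expect_equal(oracle, 0.93981218373398312, tolerance = 1e-12)
  # zero dose: control probability vanishes
  expect_equal(tcp_from_eqd(0, 1, 1.3, 30.89), exp(-exp(eg)))
  expect_lt(tcp_from_eqd(0, 1, 1.3, 30.89), 1e-14)
})

test_that("LKB effective dose is the Kutcher-Burman generalized mean", {
  for (n in c(0.1, 0.35, 0.87, 1))
    expect_equal(deff_gmean(30, 1, n), 30, tolerance = 1e-12)
  expect_equal(deff_gmean(c(0, 40), c(0.5, 0.5), 1), 20)
  expect_equal(deff_gmean(c(20, 40), c(0.5, 0.5), 0.5),
               (0.5 * 20^2 + 0.5 * 40^2)^0.5)
  expect_equal(deff_gmean(c(20, 40), c(0.5, 0.5), 0.5), sqrt(1000))
  expect_error(deff_gmean(10, 1, 0), "n must")
  expect_error(deff_gmean(10, 1, 1.5), "n must")
})

test_that("LKB NTCP is the normal CDF of the reduced dose deficit", {
  p16 <- plan_context(42.56, 16)
  # Deff = D50 gives exactly 1/2 for any organ
  d_lung <- dose_for_eqd(37.6, 16, 4)
  expect_equal(ntcp_lkb(uniform_dvh("lung", d_lung), p16, tis$lung), 0.5,
               tolerance = 1e-12)
  # lung at Deff = 20 Gy: normal-CDF oracle
  d20 <- dose_for_eqd(20, 16, 4)
  expect_equal(ntcp_lkb(uniform_dvh("lung", d20), p16, tis$lung),
               pnorm((20 - 37.6) / (0.35 * 37.6)), tolerance = 1e-12)
  expect_equal(pnorm((20 - 37.6) / (0.35 * 37.6)), 0.0905483329828672,
               tolerance = 1e-10)
  # zero dose to a serial organ: deep normal tail
  expect_lt(ntcp_lkb(uniform_dvh("heart", 0), cf_plan(), tis$heart), 1e-12)
})

test_that("endpoints are invariant to bin merging and permutation", {
  p <- cf_plan()
  a <- delta_mix_dvh("s", c(20, 20, 40), c(0.25, 0.25, 0.5))
  b <- delta_mix_dvh("s", c(20, 40), c(0.5, 0.5))
  for (f in list(function(d) eud(d, p, tis$ptv),
                 function(d) tcp_poisson_lq(d, p, tis$ptv),
                 function(d) ntcp_lkb(d, p, tis$lung)))
    expect_equal(f(a), f(b), tolerance = 1e-12)

  # permutation: masses entered in a different order describe the same DVH
  e1 <- delta_mix_dvh("s", c(10, 30, 50), c(0.2, 0.3, 0.5))
  e2 <- delta_mix_dvh("s", c(50, 10, 30), c(0.5, 0.2, 0.3))
  expect_equal(eud(e1, p, tis$ptv), eud(e2, p, tis$ptv))
  expect_equal(ntcp_lkb(e1, p, tis$lung), ntcp_lkb(e2, p, tis$lung))
})

test_that("scaling every bin dose up strictly increases all endpoints", {
  set.seed(5)
  p <- cf_plan()
  d <- rand_dvh(10, max_dose = 55, structure = "s")
  scale_dvh <- function(d, f) dvh(d$structure, d$bin_edges * f, d$values,
                                  d$volume_cm3)
  d2 <- scale_dvh(d, 1.15)
  expect_gt(eud(d2, p, tis$ptv), eud(d, p, tis$ptv))
  expect_gt(tcp_poisson_lq(d2, p, tis$ptv), tcp_poisson_lq(d, p, tis$ptv))
  expect_gt(effective_dose(d2, p, tis$lung), effective_dose(d, p, tis$lung))
  expect_gt(ntcp_lkb(d2, p, tis$lung), ntcp_lkb(d, p, tis$lung))
})

test_that("limit exponents recover mean and minimum EQD", {
  p <- cf_plan()
  set.seed(9)
  d <- bin_voxels(rnorm(2000, 45, 3), width = 0.5)
  eqds <- eqd(bin_centers(dvh_differential(d))[d$values > 0], 25, 4)
  w <- d$values[d$values > 0]
  prm1 <- tissue_parameters("t", 4, a = 1)
  expect_equal(eud(d, p, prm1), sum(w * eqds), tolerance = 1e-9)
  expect_equal(effective_dose(d, p, tissue_parameters("t", 4, n = 1)),
               sum(w * eqds), tolerance = 1e-9)
  # the a -> -Inf limit approaches the minimum EQD; checked on a discrete
  # mixture whose coldest component carries substantial volume
  mix <- delta_mix_dvh("s", c(40, 45, 50), c(0.4, 0.3, 0.3))
  prm100 <- tissue_parameters("t", 4, a = -100)
  expect_lt(abs(eud(mix, p, prm100) - min(eqd(c(40, 45, 50), 25, 4))), 0.5)
})
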