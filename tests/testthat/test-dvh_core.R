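test_that("differential/cumulative conversion does the finite-sum bookkeeping", {
  d <- dvh("ptv", c(0, 10, 20), c(0.4, 0.6), 100)
  expect_equal(dvh_cumulative(d)$values, c(1, 0.6, 0))

  single <- dvh("ptv", c(0, 5), 1, 100)
  expect_equal(dvh_cumulative(single)$values, c(1, 0))
})

test_that("differential <-> cumulative is a bijection up to 1e-12", {
  set.seed(42)
  for (i in 1:20) {
    d <- rand_dvh(n_bins = sample(1:40, 1))
    back <- dvh_differential(dvh_cumulative(d))
    expect_equal(back$values, d$values, tolerance = 1e-12)
    expect_identical(back$bin_edges, d$bin_edges)
    # cumulative differences recover the fractions directly
    expect_equal(-diff(dvh_cumulative(d)$values), d$values, tolerance = 1e-12)
  }
})

test_that("Dx% interpolates linearly on the cumulative curve", {
  u <- uniform_dvh("ptv", 50)
  expect_equal(dose_at_volume(u, 98), 50)
  expect_equal(dose_at_volume(u, 2), 50)

  # cumulative points (40,100%) (50,50%) (60,0%); x=75 brackets 40-50:
  # d = 40 + (1 - 0.75) / (1 - 0.5) * 10 = 45
  cd <- dvh("ptv", c(40, 50, 60), c(1, 0.5, 0), 100, form = "cumulative")
  expect_equal(dose_at_volume(cd, 75), 45)
  expect_equal(dose_at_volume(cd, 50), 50)
  expect_equal(dose_at_volume(cd, 25), 55)

  # hot percentile exceeds cold percentile
  two <- delta_mix_dvh("ptv", c(40, 50), c(0.5, 0.5))
  expect_gt(dose_at_volume(two, 2), dose_at_volume(two, 98))

  # monotone non-increasing in x on random DVHs
  set.seed(7)
  for (i in 1:10) {
    d <- rand_dvh(12)
    xs <- seq(1, 100, by = 7)
    ds <- vapply(xs, function(x) dose_at_volume(d, x), numeric(1))
    expect_true(all(diff(ds) <= 1e-12))
  }

  expect_error(dose_at_volume(u, 0), "x_percent")
  expect_error(dose_at_volume(u, 101), "x_percent")
})

test_that("V at dose counts the volume receiving at least that dose", {
  u <- uniform_dvh("ptv", 50)
  expect_equal(volume_at_dose(u, 47.5), 100)
  expect_equal(volume_at_dose(u, 53.5), 0)
  expect_equal(volume_at_dose(u, 50), 100)   # >= is inclusive

  two <- delta_mix_dvh("ptv", c(40, 50), c(0.5, 0.5))
  expect_equal(volume_at_dose(two, 45), 50)
  expect_equal(volume_at_dose(two, 40), 100)
  expect_equal(volume_at_dose(two, 50), 50)

  expect_error(volume_at_dose(u, -1), "dose")
})

test_that("Dx% and V_RI are mutual quasi-inverses on strictly decreasing curves", {
  set.seed(11)
  for (i in 1:10) {
    edges <- c(0, sort(stats::runif(6, 1, 60)))
    v <- stats::runif(6, 0.05, 1)
    d <- dvh("s", edges, v / sum(v), 100)
    for (x in c(10, 25, 50, 75, 90)) {
      dd <- dose_at_volume(d, x)
      expect_equal(volume_at_dose(d, dd), x, tolerance = 1e-8)
    }
  }
})

test_that("summary statistics match the explicit volume-weighted sums", {
  u <- uniform_dvh("ptv", 50)
  expect_equal(dvh_summary(u), list(d_min = 50, d_max = 50, d_mean = 50))

  two <- delta_mix_dvh("ptv", c(40, 50), c(0.5, 0.5))
  expect_equal(dvh_summary(two)$d_mean, 45)

  d <- dvh("s", c(0, 10, 20, 40, 60), c(0.1, 0.2, 0.3, 0.4), 100)
  ctr <- c(5, 15, 30, 50)
  s <- dvh_summary(d)
  expect_equal(s$d_mean, sum(c(0.1, 0.2, 0.3, 0.4) * ctr))
  expect_equal(s$d_min, 5)
  expect_equal(s$d_max, 50)
  expect_true(s$d_min <= s$d_mean && s$d_mean <= s$d_max)
})

test_that("Dx%, V_RI and Dmean are invariant under bin refinement", {
  split_bins <- function(d) {
    e <- d$bin_edges
    v <- d$values
    ne <- numeric(0); nv <- numeric(0)
    for (i in seq_along(v)) {
      mid <- (e[i] + e[i + 1]) / 2
      ne <- c(ne, e[i], mid)
      nv <- c(nv, v[i] / 2, v[i] / 2)
    }
    dvh(d$structure, c(ne, e[length(e)]), nv, d$volume_cm3)
  }
  set.seed(3)
  for (i in 1:5) {
    d <- rand_dvh(8)
    r <- split_bins(d)
    for (x in c(2, 50, 98))
      expect_equal(dose_at_volume(r, x), dose_at_volume(d, x), tolerance = 1e-9)
    for (ri in c(5, 20, 45))
      expect_equal(volume_at_dose(r, ri), volume_at_dose(d, ri), tolerance = 1e-9)
    expect_equal(dvh_summary(r)$d_mean, dvh_summary(d)$d_mean, tolerance = 1e-9)
  }
})

test_that("DVH validation rejects malformed input", {
  expect_error(dvh("s", c(10, 0), 1, 100), "non-decreasing")
  expect_error(dvh("s", c(-1, 5), 1, 100), ">= 0")
  expect_error(dvh("s", c(0, 5, 10), c(0.4, 0.4), 100), "sum to 1")
  expect_error(dvh("s", c(0, 5), 1, -3), "volume")
  expect_error(dvh("s", c(0, 5, 10), c(0.5, 1, 0), 100, form = "cumulative"),
               "start at 1")
  expect_error(dvh("s", c(0, 5, 10), c(1, 0.2, 0.4), 100, form = "cumulative"),
               "non-increasing")
})
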