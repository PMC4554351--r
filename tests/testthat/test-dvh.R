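test_that("uniform dose yields a single occupied bin and a step cumulative curve", {
  g <- make_uniform_grid(10)
  d <- compute_dvh(g, full_mask(g), bin_width = 1)
  expect_equal(sum(d$volume > 0), 1)                  # one occupied bin, [10, 11)
  expect_equal(metric_Vx(d, 0), 100)
  expect_equal(metric_Vx(d, 5), 100)
  expect_equal(metric_Vx(d, 10), 100)
  expect_equal(metric_Vx(d, 11), 0)                   # nothing a full bin above
  expect_lt(abs(metric_mean(d) - 10), 0.5 + 1e-12)    # half-bin quantisation
  expect_equal(metric_max(d), 11)                     # upper edge of top bin
  expect_equal(d$total_volume_cc, 125 * 8 / 1000)
})

test_that("8-voxel histogram agrees with the voxel-level brute-force oracle", {
  doses <- c(0, 10, 20, 30, 40, 50, 60, 70)
  g <- dose_grid(array(doses, c(2, 2, 2)), spacing = c(2, 2, 2))
  d <- compute_dvh(g, full_mask(g), bin_width = 10)
  expect_equal(sort(d$volume[d$volume > 0]), rep(0.125, 8))  # 12.5% per bin

  # oracle: direct count over the 8 voxels
  v35_oracle <- 100 * mean(doses >= 35)                      # 50%
  mean_oracle <- mean(doses)                                 # 35 Gy
  expect_lte(abs(metric_Vx(d, 35) - v35_oracle), 100 * 0.125)  # one bin mass
  expect_lte(abs(metric_mean(d) - mean_oracle), 10 / 2)        # half a bin

  # the exact point representation reproduces the oracle values exactly
  dp <- dvh_from_points(doses)
  expect_equal(metric_Vx(dp, 35), v35_oracle)
  expect_equal(metric_mean(dp), mean_oracle)
  expect_equal(metric_max(dp), 70)
})

test_that("point DVHs reproduce hand-derived conversions and metrics", {
  # two volumes: 25% at 20 Gy, 75% at 60 Gy
  d <- dvh_from_points(c(20, 60), c(0.25, 0.75))
  cc <- to_cumulative(d)
  expect_equal(cc$volume[cc$dose == 0], 1)
  expect_equal(cc$volume[cc$dose == 20], 1)      # everything receives >= 20
  expect_equal(cc$volume[cc$dose == 60], 0.75)
  expect_equal(metric_Dx(d, 90), 20)             # read off the cumulative curve
  expect_equal(metric_Vx(d, 35), 75)
  expect_equal(metric_mean(d), 50)

  # single bin at 10 Gy: cumulative 1 up to 10 Gy
  u <- dvh_from_points(10)
  expect_equal(metric_Vx(u, 10), 100)
  expect_equal(metric_Vx(u, 10.01), 0)
  expect_equal(metric_mean(u), 10)
  expect_equal(metric_max(u), 10)

  # uniform 36.5 Gy: mean = max = D90, V20 = 100, V40 = 0
  w <- dvh_from_points(36.5)
  expect_equal(metric_mean(w), 36.5)
  expect_equal(metric_max(w), 36.5)
  expect_equal(metric_Dx(w, 90), 36.5)
  expect_equal(metric_Vx(w, 20), 100)
  expect_equal(metric_Vx(w, 40), 0)
})

test_that("differential/cumulative conversion round-trips losslessly", {
  set.seed(42)
  for (i in 1:20) {
    d <- rand_point_dvh(sample(2:12, 1))
    cc <- to_cumulative(d)
    expect_equal(cc$volume[1], 1)
    expect_true(all(diff(cc$volume) <= 1e-12))
    back <- to_differential(cc)
    expect_equal(back$dose, d$dose, tolerance = 1e-12)
    expect_equal(back$volume, d$volume, tolerance = 1e-12)
  }
  # converting to the form already held is the identity
  d <- rand_point_dvh()
  expect_identical(to_differential(d), d)
})

test_that("invalid DVHs and inputs are rejected", {
  g <- make_uniform_grid(10)
  empty <- structure_mask("none", array(FALSE, dim(g$values)))
  expect_error(compute_dvh(g, empty), "structure-empty")
  small <- structure_mask("off", array(TRUE, c(2, 2, 2)))
  expect_error(compute_dvh(g, small), "geometry error")
  expect_error(compute_dvh(g, full_mask(g), bin_width = 0), "positive")

  # non-monotone cumulative curve
  expect_error(incidose:::new_dvh("s", "cumulative", c(0, 10, 20), c(1, 0.4, 0.6)),
               "monotone")
  # differential mass not summing to 1
  expect_error(incidose:::new_dvh("s", "differential", c(0, 10), c(0, 0.5)),
               "sum to 1")

  d <- rand_point_dvh()
  expect_error(metric_Dx(d, 0), "domain error")
  expect_error(metric_Dx(d, 101), "domain error")
  expect_error(metric_Vx(d, -1), "domain error")
})

test_that("Dx/Vx are quasi-inverse and all metrics scale linearly with dose", {
  set.seed(7)
  for (i in 1:10) {
    d <- rand_point_dvh(10)
    for (p in c(5, 25, 50, 90, 99)) {
      dx <- metric_Dx(d, p)
      expect_gte(metric_Vx(d, dx), p - 1e-9)
    }
    s <- stats::runif(1, 0.3, 2.5)
    ds <- scale_dvh(d, s)
    expect_equal(metric_mean(ds), s * metric_mean(d), tolerance = 1e-12)
    expect_equal(metric_max(ds), s * metric_max(d), tolerance = 1e-12)
    expect_equal(metric_Dx(ds, 60), s * metric_Dx(d, 60), tolerance = 1e-12)
    expect_equal(metric_Vx(ds, s * 30), metric_Vx(d, 30), tolerance = 1e-9)
  }
})

test_that("fine-binned DVH mean converges to the voxel-wise mean", {
  set.seed(11)
  for (i in 1:5) {
    g <- rand_grid()
    d <- compute_dvh(g, full_mask(g), bin_width = 0.1)
    expect_lte(abs(metric_mean(d) - mean(g$values)), 0.05)
  }
})

test_that("conformation number behaves like van't Riet/Paddick CN", {
  dims <- c(8, 8, 8)
  vals <- array(0, dims)
  ptv_arr <- array(FALSE, dims)
  ptv_arr[3:4, 3:4, 3:4] <- TRUE          # 8 voxels
  # reference isodose exactly the PTV
  vals[ptv_arr] <- 60
  g <- dose_grid(vals, spacing = c(2, 2, 2))
  ptv <- structure_mask("ptv", ptv_arr)
  expect_equal(conformity_index(g, ptv, 60), 1)

  # PTV fully covered, PIV twice the PTV volume -> CN = 0.5, RTOG ratio = 2
  vals2 <- array(0, dims)
  vals2[3:4, 3:4, 3:6] <- 60              # 16 voxels including the PTV
  g2 <- dose_grid(vals2, spacing = c(2, 2, 2))
  expect_equal(conformity_index(g2, ptv, 60), 0.5)
  expect_equal(conformity_ratio_rtog(g2, ptv, 60), 2)

  # PIV disjoint from the PTV -> 0; empty PIV -> 0
  vals3 <- array(0, dims)
  vals3[7:8, 7:8, 7:8] <- 60
  g3 <- dose_grid(vals3, spacing = c(2, 2, 2))
  expect_equal(conformity_index(g3, ptv, 60), 0)
  expect_equal(conformity_index(g, ptv, 80), 0)

  empty <- structure_mask("ptv", array(FALSE, dims))
  expect_error(conformity_index(g, empty, 60), "structure-empty")
})
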