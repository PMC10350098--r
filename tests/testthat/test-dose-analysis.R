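# Depth-dose curves, 3D gamma, plan indices.

test_that("idd sums transverse planes and conserves the dose-volume integral", {
  g <- vpmc_grid(array(1, c(10, 10, 10)), c(0, 0, 0), c(1, 1, 1))
  cur <- idd(g)
  expect_true(all(cur$idd == 100))
  expect_equal(sum(cur$idd), sum(g$values) * prod(g$spacing))
  set.seed(41)
  g$values[] <- runif(1000)
  expect_equal(sum(idd(g)$idd), sum(g$values) * prod(g$spacing))
})

test_that("pdd normalizes to 100% and is scale invariant", {
  g <- vpmc_grid(array(runif(27e3, 0.1, 2), c(30, 30, 30)), c(-15, -15, 0),
                 c(1, 1, 1))
  p1 <- pdd(g)
  expect_equal(max(p1$pdd), 100)
  g7 <- g; g7$values <- 7 * g$values
  expect_equal(pdd(g7)$pdd, p1$pdd)
  g0 <- g; g0$values[] <- 0
  expect_error(pdd(g0), "undefined")
})

test_that("gamma of a grid against itself passes everywhere with gamma 0", {
  g <- vpmc_grid(smooth_field(c(15, 15, 15), 42), c(0, 0, 0), c(1, 1, 1))
  out <- gamma3d(g, g)
  expect_equal(out$pass_rate, 100)
  expect_true(all(out$gamma[!is.na(out$gamma)] == 0))
  ge <- g; ge$values <- 1.019 * g$values
  expect_equal(gamma3d(g, ge)$pass_rate, 100)  # within the 2% criterion
  g0 <- g; g0$values[] <- 0
  expect_error(gamma3d(g, g0, gamma_criteria(2, 2, 1000)), "threshold")
})

test_that("gamma pass rate matches the brute-force oracle on 20^3 grids", {
  for (seed in c(1, 2, 3)) {
    ref <- smooth_field(c(20, 20, 20), seed)
    # evaluated grid: slightly shifted and rescaled copy -> a mix of clear
    # passes and clear failures
    ev <- 1.03 * ref[c(2:20, 20), , ] + 0.015 * max(ref)
    gr <- vpmc_grid(ref, c(0, 0, 0), c(1, 1, 1))
    gv <- vpmc_grid(ev, c(0, 0, 0), c(1, 1, 1))
    fast <- gamma3d(gr, gv)$pass_rate
    slow <- gamma_pass_oracle(ref, ev, c(1, 1, 1))
    expect_lt(abs(fast - slow), 0.5)
  }
})

test_that("gamma normalization is asymmetric and monotone in the criteria", {
  ref <- smooth_field(c(18, 18, 18), 7)
  ev <- 0.5 * ref
  gr <- vpmc_grid(ref, c(0, 0, 0), c(1, 1, 1))
  gv <- vpmc_grid(ev, c(0, 0, 0), c(1, 1, 1))
  ab <- gamma3d(gr, gv)$pass_rate
  ba <- gamma3d(gv, gr)$pass_rate
  expect_false(isTRUE(all.equal(ab, ba)))

  set.seed(44)
  ev2 <- ref * (1 + rnorm(length(ref), 0, 0.03))
  gv2 <- vpmc_grid(array(ev2, dim = dim(ref)), c(0, 0, 0), c(1, 1, 1))
  p22 <- gamma3d(gr, gv2, gamma_criteria(2, 2, 10))$pass_rate
  p32 <- gamma3d(gr, gv2, gamma_criteria(3, 2, 10))$pass_rate
  p23 <- gamma3d(gr, gv2, gamma_criteria(2, 3, 10))$pass_rate
  expect_gte(p32, p22)
  expect_gte(p23, p22)
})

test_that("resampling preserves grids on identical frames and interpolates others", {
  g <- vpmc_grid(smooth_field(c(12, 12, 12), 9), c(0, 0, 0), c(2, 2, 2))
  same <- resample_grid(g, g)
  expect_equal(same$values, g$values)
  fine <- vpmc_grid(array(0, c(23, 23, 23)), c(0, 0, 0), c(1, 1, 1))
  r <- resample_grid(g, fine)
  expect_equal(r$values[seq(1, 23, 2), seq(1, 23, 2), seq(1, 23, 2)], g$values)
})

test_that("plan indices match their definitions and a direct voxel loop", {
  dims <- c(21, 21, 21)
  g <- vpmc_grid(array(0, dims), c(-10, -10, -10), c(1, 1, 1))
  soi <- sphere_mask(g, c(0, 0, 0), 5)
  g$values[soi] <- 2
  pi1 <- plan_indices(g, soi, 2)
  expect_equal(pi1$V100, 100)
  expect_equal(pi1$Dmin, 100)
  expect_equal(pi1$CI100, 1)
  expect_equal(pi1$RHI100, 1)

  # iso-dose sphere with twice the SOI radius -> CI = 8 up to discretization
  g2 <- vpmc_grid(array(0, dims), c(-10, -10, -10), c(1, 1, 1))
  g2$values[sphere_mask(g2, c(0, 0, 0), 10)] <- 1
  expect_lt(abs(plan_indices(g2, soi, 1)$CI100 - 8), 0.5)

  set.seed(46)
  g3 <- vpmc_grid(array(runif(prod(dims)), dims), c(-10, -10, -10), c(1, 1, 1))
  p <- 0.6
  pi3 <- plan_indices(g3, soi, p)
  v <- as.numeric(g3$values); m <- as.logical(soi)
  nin <- 0; nsoi <- 0; dmin <- Inf; dmax <- -Inf; niso <- 0
  for (i in seq_along(v)) {
    if (v[i] >= p) niso <- niso + 1
    if (m[i]) {
      nsoi <- nsoi + 1
      if (v[i] >= p) nin <- nin + 1
      dmin <- min(dmin, v[i]); dmax <- max(dmax, v[i])
    }
  }
  expect_identical(pi3$V100, 100 * nin / nsoi)
  expect_identical(pi3$Dmin, 100 * dmin / p)
  expect_identical(pi3$CI100, niso / nsoi)
  expect_identical(pi3$RHI100, dmax / p)
  expect_error(plan_indices(g3, soi & FALSE, 1), "empty")
})
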