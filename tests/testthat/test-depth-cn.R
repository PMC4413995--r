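test_that("bin building enforces the unmasked-base threshold", {
  g <- flat_genome(1e4)
  expect_equal(nrow(build_bins(g)), 10)  # 10-kb unmasked chrom -> 10 bins

  # bin 1 fully masked -> dropped; bin 2 with 299 unmasked -> dropped;
  # bin 3 with exactly 300 unmasked -> retained
  g$mask <- data.frame(chrom = "chr1",
                       start = c(0, 1000, 2000),
                       end = c(1000, 1000 + 701, 2000 + 700))
  grid <- build_bins(g)
  expect_false(0 %in% grid$start)
  expect_false(1000 %in% grid$start)
  expect_true(2000 %in% grid$start)
  expect_equal(grid$unmasked[grid$start == 2000], 300)

  # overlapping mask intervals are unioned, not an error
  g$mask <- data.frame(chrom = "chr1", start = c(0, 500), end = c(800, 1000))
  expect_false(0 %in% build_bins(g)$start)
  expect_error(build_bins(g, bin_size = 0), "bin_size")
  # blacklisted chromosomes are dropped
  expect_error(build_bins(g, blacklist = "chr1"), "blacklist")
})

test_that("population pooling sums depths and is symmetric", {
  expect_equal(pool_population(cbind(c(5, 1), c(7, 2))), c(12, 3))
  expect_equal(pool_population(matrix(c(5, 1), ncol = 1)), c(5, 1))
  expect_equal(pool_population(cbind(c(5, 1), c(7, 2))),
               pool_population(cbind(c(7, 2), c(5, 1))))
  expect_error(pool_population(list(1:3, 1:4)), "mismatched")
})

test_that("GC factors are reference-mean over stratum-mean", {
  # two populated strata with means 8 and 10; global mean 9
  g <- flat_genome(4e5)
  g$gc$gc <- rep(c(0.405, 0.505), each = 200)
  grid <- build_bins(g)
  depth <- rep(c(8, 10), each = 200)
  res <- correct_gc(depth, grid, min_bins = 100)
  f40 <- res$model$factor[res$model$gc_lo == 0.40]
  f50 <- res$model$factor[res$model$gc_lo == 0.50]
  expect_equal(f40, 9 / 8)    # 1.125
  expect_equal(f50, 9 / 10)   # 0.9
  # sparse strata inherit the nearest populated factor
  expect_equal(res$model$factor[res$model$gc_lo == 0.00], 9 / 8)
  expect_equal(res$model$factor[res$model$gc_lo == 0.99], 9 / 10)

  # flat depth: all factors 1, track unchanged
  flat <- correct_gc(rep(4, nrow(grid)), grid)
  expect_true(all(flat$model$factor == 1))
  expect_equal(flat$depth, rep(4, nrow(grid)))
  expect_error(correct_gc(depth, grid, reference_bins = integer(0)),
               "empty")
})

test_that("GC correction flattens a known simulated bias", {
  g <- simulate_genome(c(chr1 = 2e6), mask_density = 0, seed = 5)
  grid <- build_bins(g)
  depth <- simulate_depth_track(grid, coverage = 20, dispersion = 50,
                                seed = 6)  # default unimodal GC bias
  res <- correct_gc(depth, grid)
  stratum <- floor(grid$gc / 0.01)
  ok <- names(which(table(stratum) >= 100))
  means <- tapply(res$depth, stratum, mean)[ok]
  expect_lt(max(means) / min(means) - 1, 0.02)
  # correction preserves the reference-set global mean (within 0.1%)
  expect_lt(abs(mean(res$depth) / mean(depth) - 1), 0.001)
})

test_that("two-stage diploid calibration matches its contract", {
  grid <- flat_grid(1e5)
  seed_reg <- data.frame(chrom = "chr1", start = 0, end = 60000)
  # homogeneous diploid genome: d2 = 10 at both stages
  cal <- calibrate_diploid(rep(10, 100), grid, seed_reg)
  expect_equal(cal$d2, 10)
  expect_equal(cal$d2_stage1, 10)
  expect_equal(cal$n_stages, 2L)

  # seed regions polluted by a CN=4 segment: stage 2 gets closer to truth
  depth <- rep(10, 100)
  depth[41:60] <- 20  # CN 4 inside the seed interval
  cal2 <- calibrate_diploid(depth, grid, seed_reg)
  expect_lt(abs(cal2$d2 - 10), abs(cal2$d2_stage1 - 10))

  # scale equivariance: CN track unchanged under depth rescaling
  cal_a <- calibrate_diploid(depth, grid, seed_reg)
  cal_b <- calibrate_diploid(depth * 3.7, grid, seed_reg)
  expect_equal(estimate_cn(depth, cal_a),
               estimate_cn(depth * 3.7, cal_b))
  expect_error(calibrate_diploid(depth, grid,
    data.frame(chrom = "chr1", start = 0, end = 3000)), "seed regions")
})

test_that("CN estimation is depth over diploid depth times two", {
  expect_equal(estimate_cn(15, 10), 3)
  expect_equal(estimate_cn(0, 10), 0)
  expect_error(estimate_cn(5, -1), "diploid depth")

  # simulated CN=6 locus at 10x: estimated locus mean CN in [5.5, 6.5]
  grid <- flat_grid(2e5)
  cn_bins <- rep(2, nrow(grid)); cn_bins[100:120] <- 6
  depth <- simulate_depth_track(grid, cn_bins, coverage = 10,
                                gc_bias = NULL, seed = 8)
  cal <- calibrate_diploid(depth, grid,
    data.frame(chrom = "chr1", start = 0, end = 9e4))
  cn <- estimate_cn(depth, cal)
  expect_gt(mean(cn[100:120]), 5.5)
  expect_lt(mean(cn[100:120]), 6.5)
  # diploid-region RMSE stays small at this coverage
  expect_lt(sqrt(mean((cn[-(100:120)] - 2)^2)), 0.5)
})
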