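test_that("simulate_genome is deterministic and hits the mask density", {
  g1 <- simulate_genome(c(chr1 = 1e6), mask_density = 0, seed = 7)
  expect_equal(nrow(g1$gc), 1000)  # 1000 candidate 1-kb bins
  expect_equal(mask_fraction(g1), 0)

  g2 <- simulate_genome(c(chr1 = 1e6), mask_density = 0.3, seed = 7)
  g3 <- simulate_genome(c(chr1 = 1e6), mask_density = 0.3, seed = 7)
  expect_identical(g2, g3)

  g4 <- simulate_genome(c(chr1 = 1e7), mask_density = 0.40, seed = 1)
  expect_gte(mask_fraction(g4), 0.38)
  expect_lte(mask_fraction(g4), 0.42)
  # mask intervals within bounds, GC defined for every candidate bin
  expect_true(all(g4$mask$start >= 0 & g4$mask$end <= 1e7))
  expect_false(anyNA(g4$gc$gc))
  expect_true(all(g4$gc$gc >= 0 & g4$gc$gc <= 1))
  expect_error(simulate_genome(c(chr1 = -5)), "positive")
})

test_that("copy-number evolution follows the step process on the tree", {
  star <- species_tree(ape::read.tree(text =
    "(A:1,B:1,C:1,D:1,E:1,F:1,G:1);"))
  # rate 0: every population carries the root CN
  tv0 <- evolve_cn_on_tree(star, n_loci = 200, rate = 0, seed = 1)
  expect_true(all(tv0$cn == tv0$root_cn))
  expect_true(all(tv0$cn >= 0))

  # Monte-Carlo oracle: per-branch expected events 1, root CN high enough
  # that the 0-floor never binds, so tip displacement is Skellam(1/2, 1/2)
  # with E|D| = exp(-1) (I0(1) + I1(1)) = 0.6737; 1e5 loci x 7 tips keeps
  # the MC error well inside +/- 0.02
  tv <- evolve_cn_on_tree(star, n_loci = 1e5, rate = 1,
                          root_states = 10, seed = 2)
  disp <- abs(tv$cn - tv$root_cn)
  expect_equal(mean(disp), exp(-1) * (besselI(1, 0) + besselI(1, 1)),
               tolerance = 0.03)

  # determinism
  expect_identical(evolve_cn_on_tree(star, 500, seed = 3),
                   evolve_cn_on_tree(star, 500, seed = 3))
})

test_that("admixture with proportion 1 copies the donor at non-OR loci", {
  phy <- ape::read.tree(text = "((A:0.5,B:0.5):0.2,(C:0.5,D:0.5):0.2);")
  tr <- species_tree(phy, admixture = data.frame(
    donor = "A", recipient = "C", prop = 1))
  tv <- evolve_cn_on_tree(tr, n_loci = 400, rate = 1, seed = 4)
  non <- tv$class == "nonOR"
  expect_true(all(tv$cn[non, "C"] == tv$cn[non, "A"]))
  # OR loci are untouched by admixture: they still differ sometimes
  expect_gt(sum(tv$cn[!non, "C"] != tv$cn[!non, "A"]), 0)
})

test_that("depth track matches the negative-binomial moment contract", {
  grid <- flat_grid(1e5)
  # CN=2, no bias, coverage 10: long-run mean depth within 10 +/- 0.1
  reps <- do.call(c, lapply(1:1000, function(s)
    simulate_depth_track(grid[1:100, ], coverage = 10, gc_bias = NULL,
                         seed = s)))
  expect_gt(mean(reps), 9.9)
  expect_lt(mean(reps), 10.1)

  # CN=0 locus: depth identically zero without a noise floor
  d0 <- simulate_depth_track(grid, cn_bins = 0, coverage = 10, seed = 1)
  expect_true(all(d0 == 0))
  dnf <- simulate_depth_track(grid, cn_bins = 0, coverage = 10,
                              noise_floor = 0.1, seed = 1)
  expect_lt(mean(dnf), 0.5)

  # CN=6 locus at coverage 10: mean depth about 30 (3x diploid)
  d6 <- simulate_depth_track(grid, cn_bins = 6, coverage = 10,
                             gc_bias = NULL, seed = 2)
  expect_gt(mean(d6), 28.5)
  expect_lt(mean(d6), 31.5)

  expect_identical(simulate_depth_track(grid, seed = 9),
                   simulate_depth_track(grid, seed = 9))
})

test_that("genotype simulation matches the binomial path-length contract", {
  phy <- ape::read.tree(text = "(A:0.05,B:0.05);")
  g <- simulate_genotypes(phy, n_sites = 1e5, snp_rate = 1,
                          n_individuals = 1, stub_length = 0, seed = 1)
  # path length 0.1, rate 1: diff fraction in 0.1 +/- 3 sqrt(0.1/n)
  obs <- mean(g[1, ] != g[2, ])
  expect_lt(abs(obs - 0.1), 3 * sqrt(0.1 / 1e5) + 0.1^2)  # + parity bias

  g0 <- simulate_genotypes(phy, n_sites = 1000, snp_rate = 0, seed = 2)
  expect_true(all(g0[1, ] == g0[2, ]))

  expect_identical(simulate_genotypes(phy, 500, seed = 3),
                   simulate_genotypes(phy, 500, seed = 3))
})

test_that("simulated cohorts are deterministic and internally consistent", {
  co <- simulate_cohort(chrom_sizes = c(chr1 = 3e6), n_regions = 8,
                        n_sites = 5000, seed = 21)
  co2 <- simulate_cohort(chrom_sizes = c(chr1 = 3e6), n_regions = 8,
                         n_sites = 5000, seed = 21)
  expect_identical(co$depth, co2$depth)
  expect_identical(co$regions, co2$regions)
  # planted regions are variable by construction
  expect_true(all(apply(co$truth_cn, 1, sd) >= 1))
  expect_true(all(apply(co$truth_cn, 1, max) >= 4))
  # regions do not overlap each other
  gr <- GenomicRanges::GRanges(co$regions$chrom,
    IRanges::IRanges(co$regions$start + 1, co$regions$end))
  expect_true(all(GenomicRanges::countOverlaps(gr, gr) == 1))
})
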