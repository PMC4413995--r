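test_that("MCR chaining applies the run-length and threshold rules", {
  grid <- flat_grid(2e4)  # 20 bins
  cn <- rep(2, 20)

  cn[1:6] <- 2.6  # exactly 6 consecutive bins at 2.6
  m <- call_mcrs(cn, grid, "A")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 0); expect_equal(m$end, 6000)
  expect_equal(m$mean_cn, 2.6)

  cn <- rep(2, 20); cn[1:5] <- 2.6  # 5 bins: below the minimum
  expect_equal(nrow(call_mcrs(cn, grid, "A")), 0)

  # [2.6 2.6 2.4 2.6 x6]: only the last 6-bin run survives
  cn <- rep(2, 20); cn[1:9] <- c(2.6, 2.6, 2.4, rep(2.6, 6))
  m <- call_mcrs(cn, grid, "A")
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 3000); expect_equal(m$end, 9000)

  # a dropped (masked) bin breaks a run even when CN stays high
  g <- flat_genome(2e4)
  g$mask <- data.frame(chrom = "chr1", start = 5000, end = 5800)
  grid2 <- build_bins(g)  # bin 6 dropped
  cn2 <- rep(2.8, nrow(grid2))
  # the dropped bin splits one 19-bin stretch into runs of 5 and 14
  expect_equal(nrow(call_mcrs(cn2, grid2, "A", min_bins = 5)), 2)
  expect_equal(nrow(call_mcrs(cn2, grid2, "A", min_bins = 6)), 1)
})

test_that("MCR merging is a transitive single-linkage union", {
  a <- data.frame(chrom = "chr1", start = 10000, end = 20000,
                  population = "A", n_bins = 10, mean_cn = 3)
  b <- data.frame(chrom = "chr1", start = 18000, end = 30000,
                  population = "B", n_bins = 12, mean_cn = 4)
  m <- merge_mcrs(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$start, 10000); expect_equal(m$end, 30000)
  expect_equal(m$populations, "A,B")

  # disjoint MCRs unchanged
  c2 <- data.frame(chrom = "chr1", start = 50000, end = 56000,
                   population = "C", n_bins = 6, mean_cn = 3)
  expect_equal(nrow(merge_mcrs(list(a, c2))), 2)

  # chain A-B, B-C where A and C do not touch: one region spans all three
  c3 <- data.frame(chrom = "chr1", start = 29000, end = 40000,
                   population = "C", n_bins = 11, mean_cn = 3)
  m3 <- merge_mcrs(list(a, b, c3))
  expect_equal(nrow(m3), 1)
  expect_equal(m3$start, 10000); expect_equal(m3$end, 40000)
  expect_equal(m3$populations, "A,B,C")
})

test_that("region scoring averages retained-bin CN per population", {
  grid <- flat_grid(1e4)
  cnm <- cbind(A = rep(4.2, 10), B = c(rep(3, 5), rep(5, 5)))
  one_bin <- data.frame(chrom = "chr1", start = 0, end = 1000)
  sc <- score_regions(one_bin, cnm, grid)
  expect_equal(unname(sc$cn[1, "A"]), 4.2)
  two_bins <- data.frame(chrom = "chr1", start = 4000, end = 6000)
  sc2 <- score_regions(two_bins, cnm, grid)
  expect_equal(unname(sc2$cn[1, "B"]), 4)  # mean of bins at 3 and 5
  expect_false(any(sc2$missing))
})

test_that("CNVR ascertainment uses the sample sd across populations", {
  grid <- flat_grid(1e4)
  regions <- data.frame(chrom = "chr1", start = c(0, 2000, 4000),
                        end = c(1000, 3000, 5000))
  cnm <- matrix(2, 10, 7, dimnames = list(NULL, paste0("p", 1:7)))
  cnm[1, ] <- 3                       # sd 0 -> rejected
  cnm[3, ] <- c(2, 2, 2, 2, 2, 2, 4)  # sd 0.756 -> accepted
  cnm[5, ] <- c(2, 2, 2, 2, 2, 2, 3)  # sd 0.378 -> rejected
  sc <- score_regions(regions, cnm, grid)
  cv <- ascertain_cnvrs(sc, sd_threshold = 0.7)
  expect_equal(nrow(cv$regions), 1)
  expect_equal(cv$regions$start, 2000)
  expect_equal(cv$regions$sd, sd(c(2, 2, 2, 2, 2, 2, 4)))
  # monotonicity: raising the threshold never adds CNVRs
  for (thr in c(0.2, 0.5, 0.756, 0.9)) {
    expect_lte(nrow(ascertain_cnvrs(sc, thr + 0.1)$regions),
               nrow(ascertain_cnvrs(sc, thr)$regions))
  }
  # permutation invariance in population order
  perm <- sample(7)
  cv_p <- ascertain_cnvrs(score_regions(regions, cnm[, perm], grid), 0.7)
  expect_equal(cv_p$regions$sd, cv$regions$sd)
})

test_that("population-specific flagging needs exactly one high population", {
  cnvrs <- list(cn = rbind(c(2, 2, 2, 2, 2, 2, 6),
                           c(2, 2, 2, 2, 2, 4, 6),
                           c(2.4, 2.4, 2.4, 2.4, 2.4, 2.4, 2.6)))
  expect_equal(population_specific(cnvrs), c(TRUE, FALSE, TRUE))
})

test_that("group ascertainment, comparison and resampling behave", {
  co <- simulate_cohort(chrom_sizes = c(chr1 = 4e6), n_regions = 12,
                        n_sites = 2000, seed = 31)
  cn <- sapply(co$populations, function(p)
    population_cn(co$depth[, co$ind_pop == p], co$grid,
                  co$seed_regions)$cn)
  isea <- c("Sbar", "Sver", "Sceb", "Scel")
  ga <- group_ascertain(cn, co$grid, isea)
  gb <- group_ascertain(cn, co$grid, c("Europe", "China", "Sumatra"))
  cmp <- compare_groups(ga, gb)
  expect_equal(cmp$n_shared_a, sum(cmp$shared_a))
  expect_equal(nrow(cmp$unique_a), nrow(ga$regions) - cmp$n_shared_a)

  # identical CN tracks in both groups: no unique regions
  cn_dup <- cn[, c(1, 2, 3, 1, 2, 3)]
  colnames(cn_dup) <- c("a1", "a2", "a3", "b1", "b2", "b3")
  g1 <- group_ascertain(cn_dup, co$grid, c("a1", "a2", "a3"))
  g2 <- group_ascertain(cn_dup, co$grid, c("b1", "b2", "b3"))
  cmp2 <- compare_groups(g1, g2)
  expect_equal(nrow(cmp2$unique_a), 0)
  expect_equal(nrow(cmp2$unique_b), 0)

  # 3-of-4 resampling returns one set per combination
  rs <- group_resample(cn, co$grid, isea, 3)
  expect_length(rs, 4)
  expect_error(group_ascertain(cn, co$grid, "Sbar"), "two populations")
})

test_that("every CNVR interval is covered by an MCR of some population", {
  co <- simulate_cohort(chrom_sizes = c(chr1 = 3e6), n_regions = 8,
                        n_sites = 2000, seed = 32)
  cn <- sapply(co$populations, function(p)
    population_cn(co$depth[, co$ind_pop == p], co$grid,
                  co$seed_regions)$cn)
  cv <- call_cnvrs(cn, co$grid)
  mcrs <- do.call(rbind, attr(cv, "mcrs"))
  ov <- GenomicRanges::countOverlaps(
    GenomicRanges::GRanges(cv$regions$chrom,
      IRanges::IRanges(cv$regions$start + 1, cv$regions$end)),
    GenomicRanges::GRanges(mcrs$chrom,
      IRanges::IRanges(mcrs$start + 1, mcrs$end)))
  expect_true(all(ov >= 1))
})
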