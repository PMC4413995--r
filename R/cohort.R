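## sample non-overlapping planted windows (in bins) from runs of
## consecutive retained bins, leaving >= gap_bins retained bins between
## windows so regions cannot merge into each other downstream.
place_regions <- function(grid, n_regions, region_bins = c(8, 20),
                          gap_bins = 4) {
  bs <- attr(grid, "bin_size")
  run_id <- cumsum(c(TRUE, !(grid$chrom[-1] == grid$chrom[-nrow(grid)] &
                             grid$start[-1] == grid$end[-nrow(grid)])))
  runs <- split(seq_len(nrow(grid)), run_id)
  runs <- runs[vapply(runs, length, 1L) >= region_bins[1]]
  placed <- list()
  ## greedy left-to-right placement with random lengths and random skips
  for (r in runs) {
    i <- 1
    while (i + region_bins[1] - 1 <= length(r)) {
      len <- sample(seq(region_bins[1], region_bins[2]), 1)
      if (i + len - 1 > length(r)) break
      idx <- r[i:(i + len - 1)]
      placed[[length(placed) + 1]] <- idx
      i <- i + len + gap_bins + sample(0:10, 1)
    }
  }
  if (length(placed) < n_regions)
    stop("genome too small to place ", n_regions, " regions")
  placed <- placed[sort(sample(seq_along(placed), n_regions))]
  data.frame(
    chrom = vapply(placed, function(i) grid$chrom[i[1]], ""),
    start = vapply(placed, function(i) grid$start[i[1]], 0),
    end = vapply(placed, function(i) grid$end[i[length(i)]], 0))
}

## draw truth CN profiles for planted regions until n qualify as truly
## variable: cross-population sd >= min_sd and at least one population
## clearly multi-copy (max >= min_max). Returns a cn_truth-like subset.
draw_variable_truth <- function(tree, n, step_size, rate, root_states,
                                class_mix, min_sd, min_max, seed) {
  got_cn <- NULL; got_cls <- NULL
  batch_seed <- seed
  while (is.null(got_cn) || nrow(got_cn) < n) {
    tv <- evolve_cn_on_tree(tree, n_loci = 4 * n, rate = rate,
                            class_mix = class_mix,
                            root_states = root_states,
                            step_size = step_size, seed = batch_seed)
    keep <- apply(tv$cn, 1, sd) >= min_sd & apply(tv$cn, 1, max) >= min_max
    got_cn <- rbind(got_cn, tv$cn[keep, , drop = FALSE])
    got_cls <- c(got_cls, as.character(tv$class[keep]))
    batch_seed <- batch_seed + 1000L
  }
  list(cn = got_cn[seq_len(n), , drop = FALSE],
       class = factor(got_cls[seq_len(n)], levels = c("OR", "nonOR")))
}

#' Simulate a full synthetic cohort: genome, truth, depth and genotypes
#'
#' Emulates the study design end to end: a repeat-masked genome, a set of
#' planted copy-number variable regions whose per-population integer CN
#' evolved on a species tree (OR loci strictly on the tree, non-OR loci
#' additionally perturbed by admixture), two individuals per population
#' with GC-biased negative-binomial depth tracks, diploid background
#' elsewhere, seed "assumed diploid" regions, and diploid-region SNP
#' genotypes. Planted regions are genuinely variable by construction
#' (cross-population CN sd at least `min_truth_sd` and at least one clearly
#' multi-copy population): regions whose true dispersion sits at the
#' ascertainment boundary (sd barely 0.7) are unrecoverable in principle —
#' any scoring attenuation drops them below threshold — so the generator
#' plants unambiguous variable regions (default truth sd >= 1, i.e. at
#' least two event-steps of cross-population dispersion).
#'
#' @param chrom_sizes named vector of chromosome sizes (default one 20-Mb
#'   chromosome).
#' @param mask_density masked genome fraction.
#' @param tree a [species_tree()]; default [default_sus_tree()].
#' @param n_regions number of planted variable regions.
#' @param region_bins length-2 integer range of region lengths in bins.
#' @param coverage_range per-individual coverage is drawn uniformly from
#'   this range (x-fold at CN = 2).
#' @param n_individuals individuals per population.
#' @param dispersion negative-binomial size for read counts.
#' @param step_size CN change per event; the cohort default 2 models fixed
#'   inter-population differences (one copy per haplotype).
#' @param rate event-rate multiplier on tree branch lengths.
#' @param root_states root CN states for planted regions.
#' @param min_truth_sd,min_truth_max variability conditions planted regions
#'   must meet.
#' @param stub_length private per-individual branch length (CN and SNP).
#' @param n_seed_regions,seed_region_bins number and length (bins) of seed
#'   "assumed diploid" calibration regions sampled outside planted regions.
#' @param n_sites,snp_rate diploid-region SNP simulation parameters.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `sim_cohort` with elements `genome`, `grid`,
#'   `regions` (planted intervals + class), `truth_cn` (regions x
#'   populations), `ind_cn` (regions x individuals), `depth` (bins x
#'   individuals matrix), `populations`, `ind_pop`, `seed_regions`,
#'   `genotypes`, `tree`, `params`.
#' @export
simulate_cohort <- function(chrom_sizes = c(chr1 = 2e7),
                            mask_density = 0.4,
                            tree = default_sus_tree(),
                            n_regions = 60,
                            region_bins = c(8, 20),
                            coverage_range = c(7, 18),
                            n_individuals = 2,
                            dispersion = 30,
                            step_size = 2L,
                            rate = 1,
                            root_states = 2:5,
                            min_truth_sd = 1.0,
                            min_truth_max = 4,
                            stub_length = 0.02,
                            n_seed_regions = 200,
                            seed_region_bins = 5,
                            n_sites = 2e5,
                            snp_rate = 0.05,
                            seed = 1L) {
  set.seed(seed)
  genome <- simulate_genome(chrom_sizes, mask_density = mask_density,
                            seed = seed)
  grid <- build_bins(genome)
  set.seed(seed + 1L)
  regions <- place_regions(grid, n_regions, region_bins)
  truth <- draw_variable_truth(tree, n_regions, step_size, rate,
                               root_states,
                               class_mix = c(OR = 0.5, nonOR = 0.5),
                               min_sd = min_truth_sd,
                               min_max = min_truth_max,
                               seed = seed + 2L)
  regions$class <- truth$class
  pops <- tree$phylo$tip.label

  ## individual CN: population CN evolved further along a private stub
  inds <- as.vector(t(outer(pops, seq_len(n_individuals), paste, sep = "_")))
  ind_pop <- setNames(rep(pops, each = n_individuals), inds)
  ind_cn <- matrix(NA_integer_, n_regions, length(inds),
                   dimnames = list(NULL, inds))
  set.seed(seed + 3L)
  for (i in seq_along(inds))
    ind_cn[, i] <- evolve_cn_branch(truth$cn[, ind_pop[[i]]],
                                    rate * stub_length, step_size)

  ## seed diploid regions: retained bins outside planted regions
  set.seed(seed + 4L)
  free <- setdiff(seq_len(nrow(grid)), bins_in_regions(grid, regions))
  anchors <- sort(sample(free, min(n_seed_regions, length(free))))
  seed_regions <- data.frame(
    chrom = grid$chrom[anchors],
    start = grid$start[anchors],
    end = pmin(grid$start[anchors] + seed_region_bins * attr(grid, "bin_size"),
               chrom_sizes[grid$chrom[anchors]]))

  set.seed(seed + 5L)
  coverages <- setNames(runif(length(inds), coverage_range[1],
                              coverage_range[2]), inds)
  depth <- matrix(0, nrow(grid), length(inds),
                  dimnames = list(NULL, inds))
  for (i in seq_along(inds)) {
    cnb <- cn_profile_bins(grid, regions, ind_cn[, i])
    depth[, i] <- simulate_depth_track(grid, cnb,
                                       coverage = coverages[[i]],
                                       dispersion = dispersion,
                                       seed = seed + 10L + i)
  }

  geno <- simulate_genotypes(tree, n_sites = n_sites, snp_rate = snp_rate,
                             n_individuals = n_individuals,
                             stub_length = stub_length, seed = seed + 6L)

  structure(list(genome = genome, grid = grid, regions = regions,
                 truth_cn = truth$cn, ind_cn = ind_cn, depth = depth,
                 populations = pops, ind_pop = ind_pop,
                 coverages = coverages,
                 seed_regions = seed_regions, genotypes = geno,
                 tree = tree,
                 params = list(step_size = step_size, rate = rate,
                               snp_rate = snp_rate, seed = seed)),
            class = "sim_cohort")
}

#' Simulate a truth-level cohort for the rate-ratio comparison
#'
#' Generates per-individual integer copy numbers at `n_loci` variable-region
#' loci (event rate `cnv_rate`, events of `step_size` copies) and
#' diploid-region genotypes at `n_sites` sites (flip rate `snp_rate`) on the
#' same species tree, with individuals on private stub branches for both
#' processes. This is the study condition for comparing how fast binary
#' copy-number differences and SNPs accumulate: by default copy-number
#' events arrive 2.5 times faster than SNP substitutions.
#'
#' @param tree a [species_tree()].
#' @param n_loci number of copy-number loci (the CNVR count denominator).
#' @param n_sites number of diploid SNP sites.
#' @param snp_rate SNP flip rate per unit branch length.
#' @param cnv_rate copy-number event rate per unit branch length.
#' @param step_size copies per event (default 2, fixed per-haplotype events).
#' @param n_individuals individuals per population.
#' @param stub_length private branch length per individual.
#' @param seed integer seed.
#' @return list with `cn` (loci x individuals), `genotypes`
#'   (individuals x sites), `ind_pop`, `tree`.
#' @export
simulate_rate_cohort <- function(tree = default_sus_tree(admixture = FALSE),
                                 n_loci = 1408, n_sites = 1e6,
                                 snp_rate = 0.05,
                                 cnv_rate = 2.5 * snp_rate,
                                 step_size = 2L, n_individuals = 2,
                                 stub_length = 0.02, seed = 1L) {
  truth <- evolve_cn_on_tree(tree, n_loci = n_loci, rate = cnv_rate,
                             class_mix = c(OR = 0.5, nonOR = 0.5),
                             root_states = 2:5, step_size = step_size,
                             seed = seed)
  pops <- tree$phylo$tip.label
  inds <- as.vector(t(outer(pops, seq_len(n_individuals), paste, sep = "_")))
  ind_pop <- setNames(rep(pops, each = n_individuals), inds)
  cn <- matrix(NA_integer_, n_loci, length(inds),
               dimnames = list(NULL, inds))
  set.seed(seed + 1L)
  for (i in seq_along(inds))
    cn[, i] <- evolve_cn_branch(truth$cn[, ind_pop[[i]]],
                                cnv_rate * stub_length, step_size)
  geno <- simulate_genotypes(tree, n_sites = n_sites, snp_rate = snp_rate,
                             n_individuals = n_individuals,
                             stub_length = stub_length, seed = seed + 2L)
  list(cn = cn, genotypes = geno, ind_pop = ind_pop, tree = tree,
       class = truth$class)
}
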