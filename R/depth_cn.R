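#' Pool per-individual depth tracks into one population track
#'
#' Individuals of the same population are merged by summing their per-bin
#' depths before any correction or calibration, increasing sensitivity for
#' copy-number inference. All tracks must live on the same bin grid.
#'
#' @param depths numeric matrix bins x individuals (or a list of equal
#'   length vectors).
#' @return numeric vector of per-bin pooled depth.
#' @export
pool_population <- function(depths) {
  if (is.list(depths)) {
    if (length(unique(vapply(depths, length, 1L))) != 1)
      stop("depth tracks are on mismatched grids")
    depths <- do.call(cbind, depths)
  }
  if (is.null(dim(depths))) depths <- matrix(depths, ncol = 1)
  if (ncol(depths) < 1) stop("need at least one individual")
  rowSums(depths)
}

#' Fit and apply GC-stratum depth correction factors
#'
#' Bins are stratified by GC fraction into fixed-width strata. For each
#' stratum the multiplicative factor is (mean depth of reference bins) /
#' (mean depth of reference bins in the stratum); corrected depth is raw
#' depth times the factor of the bin's stratum. Strata holding fewer than
#' `min_bins` reference bins inherit the factor of the nearest populated
#' stratum, so sparse GC extremes are never corrected by noisy factors.
#' By construction the correction leaves the reference-set mean essentially
#' unchanged.
#'
#' @param depth numeric per-bin depth aligned to `grid`.
#' @param grid a [build_bins()] grid.
#' @param reference_bins integer indices of reference bins (default: all).
#' @param stratum_width GC stratum width (default 0.01).
#' @param min_bins minimum reference bins for a stratum to get its own
#'   factor.
#' @return list with `model` (data.frame `gc_lo`, `gc_hi`, `n_ref`,
#'   `factor`) and `depth` (corrected track).
#' @export
correct_gc <- function(depth, grid, reference_bins = seq_along(depth),
                       stratum_width = 0.01, min_bins = 100) {
  if (length(reference_bins) == 0) stop("empty GC reference set")
  if (length(depth) != nrow(grid)) stop("depth not aligned to grid")
  nstrat <- ceiling(1 / stratum_width)
  stratum <- pmin(nstrat, floor(grid$gc / stratum_width) + 1L)
  ref_str <- stratum[reference_bins]
  ref_depth <- depth[reference_bins]
  global_mean <- mean(ref_depth)
  n_ref <- tabulate(ref_str, nbins = nstrat)
  sums <- vapply(seq_len(nstrat), function(s)
    sum(ref_depth[ref_str == s]), 0)
  means <- ifelse(n_ref > 0, sums / pmax(n_ref, 1), NA_real_)
  fac <- ifelse(n_ref >= min_bins & means > 0, global_mean / means,
                NA_real_)
  populated <- which(!is.na(fac))
  if (!length(populated)) stop("no GC stratum has enough reference bins")
  ## nearest populated stratum inherits
  for (s in seq_len(nstrat)) {
    if (is.na(fac[s]))
      fac[s] <- fac[populated[which.min(abs(populated - s))]]
  }
  ## renormalize so the reference-set mean is preserved exactly (sparse
  ## strata inherit factors and would otherwise shift it slightly)
  corrected_ref_mean <- mean(depth[reference_bins] * fac[ref_str])
  if (corrected_ref_mean > 0) fac <- fac * global_mean / corrected_ref_mean
  model <- data.frame(gc_lo = (seq_len(nstrat) - 1) * stratum_width,
                      gc_hi = pmin(1, seq_len(nstrat) * stratum_width),
                      n_ref = n_ref, factor = fac)
  list(model = model, depth = depth * fac[stratum])
}

#' Two-stage diploid depth calibration
#'
#' Stage 1 takes the mean corrected depth over bins overlapping the seed
#' "assumed diploid" regions (orthology-derived genic regions in the real
#' workflow) as a provisional diploid depth and computes provisional CN.
#' Stage 2 reclassifies as diploid every genome-wide bin whose provisional
#' CN lies in `[1.5, 2.5)` and recomputes the diploid depth as the mean
#' over that set; exactly one recalculation is performed. The second stage
#' shields the calibration from non-diploid or GC-atypical seed regions.
#'
#' @param depth corrected per-bin depth.
#' @param grid a [build_bins()] grid.
#' @param seed_regions data.frame `chrom`/`start`/`end` of assumed diploid
#'   regions; must overlap at least `min_seed_bins` retained bins.
#' @param window provisional-CN window classified as diploid in stage 2.
#' @param min_seed_bins minimum retained bins the seed regions must hit.
#' @return list of class `diploid_cal` with `d2` (final diploid depth),
#'   `d2_stage1`, `diploid_bins` (stage-2 indices), `n_stages = 2`.
#' @export
calibrate_diploid <- function(depth, grid, seed_regions,
                              window = c(1.5, 2.5), min_seed_bins = 50) {
  idx <- bins_in_regions(grid, seed_regions)
  if (length(idx) < min_seed_bins)
    stop("seed regions overlap only ", length(idx), " retained bins")
  d2_1 <- mean(depth[idx])
  if (d2_1 <= 0) stop("stage-1 diploid depth is not positive")
  prov_cn <- 2 * depth / d2_1
  dip <- which(prov_cn >= window[1] & prov_cn < window[2])
  if (!length(dip)) stop("stage-2 diploid bin set is empty")
  structure(list(d2 = mean(depth[dip]), d2_stage1 = d2_1,
                 diploid_bins = dip, n_stages = 2L),
            class = "diploid_cal")
}

#' Estimate per-bin copy number
#'
#' `CN = 2 * depth / d2`, the diploid-calibrated read-depth estimator.
#'
#' @param depth corrected per-bin depth.
#' @param cal a [calibrate_diploid()] result (or a positive scalar `d2`).
#' @return numeric per-bin CN (>= 0).
#' @export
estimate_cn <- function(depth, cal) {
  d2 <- if (inherits(cal, "diploid_cal")) cal$d2 else cal
  if (!is.numeric(d2) || d2 <= 0) stop("diploid depth must be > 0")
  2 * depth / d2
}

#' Full depth-to-CN inference for one population
#'
#' Convenience wrapper running the inference in the pipeline order: pool
#' individuals, (optionally) pre-calibrate on the seed regions to predict
#' a diploid GC-reference set, GC-correct, run the two-stage diploid
#' calibration, and convert to CN.
#'
#' @param depths bins x individuals depth matrix (raw).
#' @param grid a [build_bins()] grid.
#' @param seed_regions assumed-diploid seed intervals.
#' @param gc_reference `"diploid"` (default; GC factors fit on bins
#'   provisionally classified diploid from the seed calibration), `"all"`,
#'   or `"seed"` (the seed-region bins themselves).
#' @param ... passed to [correct_gc()].
#' @return list with `cn`, `depth` (corrected pooled), `gc_model`, `cal`.
#' @export
population_cn <- function(depths, grid, seed_regions,
                          gc_reference = c("diploid", "all", "seed"), ...) {
  gc_reference <- match.arg(gc_reference)
  pooled <- pool_population(depths)
  ref <- switch(gc_reference,
    all = seq_along(pooled),
    seed = bins_in_regions(grid, seed_regions),
    diploid = {
      idx <- bins_in_regions(grid, seed_regions)
      prov <- 2 * pooled / mean(pooled[idx])
      which(prov >= 1.5 & prov < 2.5)
    })
  gc <- correct_gc(pooled, grid, reference_bins = ref, ...)
  cal <- calibrate_diploid(gc$depth, grid, seed_regions)
  list(cn = estimate_cn(gc$depth, cal), depth = gc$depth,
       gc_model = gc$model, cal = cal)
}
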