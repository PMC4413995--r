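#' Simulate a per-bin read-depth track for one individual
#'
#' Read counts per retained bin are negative binomial with mean
#' `coverage * (CN/2) * g(GC) * unmasked / read_length` (plus an optional
#' noise floor) and dispersion `size = dispersion`; the reported per-bin
#' depth is `reads * read_length / unmasked`, i.e. mean per-base depth over
#' the unmasked part of the bin. The GC bias curve `g` is rescaled to unit
#' mean over the grid so that `coverage` stays interpretable as genome-wide
#' haploid-pair coverage at CN = 2.
#'
#' @param grid a [build_bins()] grid.
#' @param cn_bins per-bin true copy number (numeric, recycled scalar ok);
#'   default diploid everywhere.
#' @param coverage expected depth at CN = 2 (x-fold, > 0).
#' @param dispersion negative-binomial size parameter of read counts.
#' @param read_length read length in bp used to convert counts to depth.
#' @param gc_bias function of GC fraction giving relative coverage
#'   (normalized internally), or `NULL` for no bias.
#' @param noise_floor additive expected depth independent of CN (mapping
#'   noise); default 0.
#' @param seed integer seed.
#' @return numeric vector of per-bin mean depth, aligned to `grid` rows.
#' @export
simulate_depth_track <- function(grid, cn_bins = 2, coverage = 10,
                                 dispersion = 30, read_length = 100,
                                 gc_bias = gc_bias_default,
                                 noise_floor = 0, seed = 1L) {
  if (coverage <= 0) stop("coverage must be > 0")
  if (any(grid$unmasked <= 0)) stop("bin with zero unmasked bases requested")
  set.seed(seed)
  n <- nrow(grid)
  cn <- rep_len(cn_bins, n)
  g <- if (is.null(gc_bias)) rep(1, n) else {
    gv <- gc_bias(grid$gc)
    if (any(gv <= 0)) stop("GC bias curve must be positive")
    gv / mean(gv)
  }
  mu_depth <- coverage * (cn / 2) * g + noise_floor
  mu_reads <- mu_depth * grid$unmasked / read_length
  reads <- rnbinom(n, mu = mu_reads, size = dispersion)
  reads * read_length / grid$unmasked
}

#' Map truth loci to per-bin copy numbers
#'
#' @param grid a [build_bins()] grid.
#' @param loci data.frame with `chrom`, `start`, `end`.
#' @param cn numeric vector of CN per locus (one population/individual).
#' @param background CN outside any locus (default diploid).
#' @return numeric per-bin CN vector aligned to `grid`.
#' @export
cn_profile_bins <- function(grid, loci, cn, background = 2) {
  out <- rep(background, nrow(grid))
  if (is.null(loci) || nrow(loci) == 0) return(out)
  ov <- GenomicRanges::findOverlaps(as_granges(grid), as_granges(loci))
  out[S4Vectors::queryHits(ov)] <- cn[S4Vectors::subjectHits(ov)]
  out
}
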