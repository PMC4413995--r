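#' Simulate a repeat-masked reference genome skeleton
#'
#' Generates chromosome sizes, a repeat-mask interval set and a smooth
#' per-bin GC landscape. The object stands in for a repeat-masked reference
#' assembly: downstream code only needs the mask (which bins survive the
#' unmasked-base filter) and per-bin GC (which drives the simulated
#' coverage bias), never the sequence itself.
#'
#' Mask intervals are placed uniformly with geometric lengths until the
#' requested masked fraction is reached (the union is measured, so
#' overlapping placements do not overshoot); the achieved fraction is within
#' about two percent of the request. GC follows an AR(1) process along each
#' chromosome, clamped to `gc_range`, giving the long-range GC
#' autocorrelation real genomes show so that GC strata are well populated.
#'
#' @param chrom_sizes named integer vector of chromosome lengths in bp.
#' @param mask_density target masked fraction of the genome in `[0, 1)`.
#' @param mask_mean_len mean repeat interval length in bp.
#' @param gc_mean,gc_sd,gc_phi mean, marginal sd and lag-1 autocorrelation of
#'   the per-bin GC process.
#' @param gc_range length-2 numeric, GC values are clamped into this range.
#' @param bin_size bin width in bp used for the GC landscape.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return an object of class `sim_genome`: list with `chrom_sizes`, `mask`
#'   (data.frame chrom/start/end, 0-based half-open), `gc` (data.frame
#'   chrom/start/gc, one row per candidate bin) and `bin_size`.
#' @examples
#' g <- simulate_genome(c(chr1 = 1e6), mask_density = 0, seed = 1)
#' nrow(g$gc)  # 1000 candidate 1-kb bins
#' @export
simulate_genome <- function(chrom_sizes,
                            mask_density = 0.4,
                            mask_mean_len = 600,
                            gc_mean = 0.45, gc_sd = 0.07, gc_phi = 0.98,
                            gc_range = c(0.2, 0.7),
                            bin_size = 1000,
                            seed = 1L) {
  if (any(chrom_sizes <= 0)) stop("chromosome sizes must be positive")
  if (is.null(names(chrom_sizes)))
    names(chrom_sizes) <- paste0("chr", seq_along(chrom_sizes))
  if (mask_density < 0 || mask_density >= 1)
    stop("mask_density must be in [0, 1)")
  set.seed(seed)

  mask <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    L <- chrom_sizes[[chr]]
    if (mask_density == 0) return(NULL)
    ## expected union coverage of n intervals of mean length l is
    ## 1 - exp(-n l / L); solve for n, then top up until within tolerance
    n0 <- ceiling(-L * log(1 - mask_density) / mask_mean_len)
    starts <- integer(0); ends <- integer(0)
    draw <- function(n) {
      len <- pmax(50L, stats::rgeom(n, 1 / mask_mean_len) + 1L)
      s <- sample.int(L, n, replace = TRUE) - 1L
      list(start = s, end = pmin(s + len, L))
    }
    d <- draw(n0)
    starts <- d$start; ends <- d$end
    covered <- function() {
      ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
      sum(IRanges::width(ir))
    }
    while (covered() < (mask_density - 0.005) * L) {
      d <- draw(max(50L, ceiling(n0 / 20)))
      starts <- c(starts, d$start); ends <- c(ends, d$end)
    }
    ir <- IRanges::reduce(IRanges::IRanges(starts + 1L, ends))
    data.frame(chrom = chr,
               start = IRanges::start(ir) - 1L,
               end = IRanges::end(ir))
  }))
  if (is.null(mask))
    mask <- data.frame(chrom = character(0), start = integer(0),
                       end = integer(0))

  gc <- do.call(rbind, lapply(names(chrom_sizes), function(chr) {
    nb <- floor(chrom_sizes[[chr]] / bin_size)
    innov_sd <- gc_sd * sqrt(1 - gc_phi^2)
    z <- numeric(nb)
    z[1] <- stats::rnorm(1, 0, gc_sd)
    eps <- stats::rnorm(nb, 0, innov_sd)
    for (i in seq_len(nb - 1)) z[i + 1] <- gc_phi * z[i] + eps[i + 1]
    data.frame(chrom = chr,
               start = (seq_len(nb) - 1L) * bin_size,
               gc = pmin(gc_range[2], pmax(gc_range[1], gc_mean + z)))
  }))

  structure(list(chrom_sizes = chrom_sizes, mask = mask, gc = gc,
                 bin_size = bin_size, seed = seed),
            class = "sim_genome")
}

#' Masked fraction of a simulated genome
#' @param genome a `sim_genome`.
#' @return masked fraction of total genome length.
#' @export
mask_fraction <- function(genome) {
  if (nrow(genome$mask) == 0) return(0)
  sum(genome$mask$end - genome$mask$start) / sum(genome$chrom_sizes)
}

#' Default GC bias curve
#'
#' Smooth unimodal coverage bias, `exp(-4 (gc - 0.45)^2)`, rescaled by the
#' caller to unit mean over the bins it is applied to. Matches the
#' qualitative shape reported for Illumina coverage: depressed coverage at
#' both GC extremes.
#'
#' @param gc numeric vector of GC fractions.
#' @return positive bias multipliers (unnormalized).
#' @export
gc_bias_default <- function(gc) exp(-4 * (gc - 0.45)^2)
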