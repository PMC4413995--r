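#' Build the retained 1-kb bin grid from a mask
#'
#' Tiles each chromosome into non-overlapping `bin_size` windows, counts
#' unmasked bases per window (mask intervals are unioned first, so
#' overlapping mask records are not an error) and keeps only bins with at
#' least `min_unmasked` unmasked bases. GC is carried per bin and refers to
#' the unmasked portion of the bin. Trailing partial windows are dropped.
#'
#' @param genome a [simulate_genome()] object, or a list with elements
#'   `chrom_sizes` (named vector), `mask` (data.frame chrom/start/end,
#'   0-based half-open) and `gc` (data.frame chrom/start/gc, one row per
#'   candidate bin).
#' @param bin_size bin width in bp (> 0).
#' @param min_unmasked minimum unmasked bases for a bin to be retained.
#' @param blacklist character vector of chromosomes to exclude (e.g. sex
#'   chromosomes, which the analysis excludes by design).
#' @return `bin_grid`: data.frame with `chrom`, `start`, `end`, `unmasked`,
#'   `gc`, sorted, non-overlapping; attributes `bin_size`, `min_unmasked`.
#' @examples
#' g <- simulate_genome(c(chr1 = 1e5), mask_density = 0, seed = 1)
#' grid <- build_bins(g)
#' nrow(grid)
#' @export
build_bins <- function(genome, bin_size = 1000, min_unmasked = 300,
                       blacklist = NULL) {
  if (bin_size <= 0) stop("bin_size must be > 0")
  chrom_sizes <- genome$chrom_sizes
  mask <- genome$mask
  gc <- genome$gc
  chroms <- setdiff(names(chrom_sizes), blacklist)
  if (!length(chroms)) stop("no chromosomes left after blacklist")
  if (nrow(mask) > 0 &&
      any(mask$start < 0 |
          mask$end > chrom_sizes[match(mask$chrom, names(chrom_sizes))],
          na.rm = TRUE))
    stop("mask intervals outside chromosome bounds")

  grids <- lapply(chroms, function(chr) {
    nb <- floor(chrom_sizes[[chr]] / bin_size)
    if (nb == 0) return(NULL)
    start <- (seq_len(nb) - 1L) * bin_size
    unmasked <- rep(bin_size, nb)
    mk <- mask[mask$chrom == chr, , drop = FALSE]
    if (nrow(mk) > 0) {
      mir <- IRanges::reduce(IRanges::IRanges(mk$start + 1L, mk$end))
      bir <- IRanges::IRanges(start + 1L, start + bin_size)
      ov <- IRanges::findOverlaps(bir, mir)
      if (length(ov) > 0) {
        w <- IRanges::width(IRanges::pintersect(
          bir[S4Vectors::queryHits(ov)], mir[S4Vectors::subjectHits(ov)]))
        masked <- tapply(w, S4Vectors::queryHits(ov), sum)
        unmasked[as.integer(names(masked))] <-
          bin_size - as.integer(masked)
      }
    }
    gcc <- gc[gc$chrom == chr, , drop = FALSE]
    gcv <- gcc$gc[match(start, gcc$start)]
    data.frame(chrom = chr, start = start, end = start + bin_size,
               unmasked = unmasked, gc = gcv)
  })
  out <- do.call(rbind, grids)
  out <- out[out$unmasked >= min_unmasked, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "bin_size") <- bin_size
  attr(out, "min_unmasked") <- min_unmasked
  class(out) <- c("bin_grid", "data.frame")
  out
}

## GRanges view of a bin grid (or any chrom/start/end data.frame);
## 0-based half-open on disk, 1-based closed inside GRanges.
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

## indices of grid bins overlapping a set of intervals (>= 1 bp)
bins_in_regions <- function(grid, regions) {
  ov <- GenomicRanges::findOverlaps(as_granges(grid), as_granges(regions))
  sort(unique(S4Vectors::queryHits(ov)))
}
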