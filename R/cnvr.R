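#' Chain multi-copy regions (MCRs) in one population
#'
#' Maximal runs of genomically consecutive retained bins whose CN meets the
#' seed threshold are chained; runs shorter than `min_bins` are discarded.
#' A dropped (masked) bin breaks a run, mirroring how repetitive sequence
#' breaks region contiguity in the real genome.
#'
#' @param cn per-bin CN aligned to `grid`.
#' @param grid a [build_bins()] grid.
#' @param population population label recorded in the output.
#' @param seed_threshold per-bin CN threshold for chaining (default 2.5).
#' @param min_bins minimum run length in bins (default 6).
#' @return data.frame `chrom`, `start`, `end`, `population`, `n_bins`,
#'   `mean_cn`.
#' @export
call_mcrs <- function(cn, grid, population = "pop",
                      seed_threshold = 2.5, min_bins = 6) {
  stopifnot(length(cn) == nrow(grid))
  bs <- attr(grid, "bin_size") %||% (grid$end[1] - grid$start[1])
  hot <- cn >= seed_threshold
  n <- length(cn)
  consec <- c(FALSE, grid$chrom[-1] == grid$chrom[-n] &
                     grid$start[-1] == grid$end[-n])
  ## a new run starts at every hot bin that is not a hot continuation
  run_start <- hot & !(c(FALSE, hot[-n]) & consec)
  run_id <- ifelse(hot, cumsum(run_start), NA_integer_)
  if (!any(hot))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), population = character(0),
                      n_bins = integer(0), mean_cn = numeric(0)))
  idx <- split(which(hot), run_id[hot])
  keep <- idx[vapply(idx, length, 1L) >= min_bins]
  if (!length(keep))
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), population = character(0),
                      n_bins = integer(0), mean_cn = numeric(0)))
  data.frame(
    chrom = vapply(keep, function(i) grid$chrom[i[1]], ""),
    start = vapply(keep, function(i) grid$start[i[1]], 0),
    end = vapply(keep, function(i) grid$end[i[length(i)]], 0),
    population = population,
    n_bins = vapply(keep, length, 1L),
    mean_cn = vapply(keep, function(i) mean(cn[i]), 0),
    row.names = NULL)
}

#' Merge MCRs across populations into candidate regions
#'
#' Single-linkage union: intervals sharing at least one base merge, and
#' merging is transitive across populations. Each merged region records the
#' populations that contributed an MCR to it.
#'
#' @param mcr_list list (or single data.frame) of [call_mcrs()] outputs.
#' @return data.frame `chrom`, `start`, `end`, `populations`
#'   (comma-separated contributors).
#' @export
merge_mcrs <- function(mcr_list) {
  if (is.data.frame(mcr_list)) mcr_list <- list(mcr_list)
  all_mcr <- do.call(rbind, mcr_list)
  if (is.null(all_mcr) || nrow(all_mcr) == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), populations = character(0)))
  gr <- as_granges(all_mcr)
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(red, gr)
  pops <- vapply(split(all_mcr$population[S4Vectors::subjectHits(ov)],
                       S4Vectors::queryHits(ov)),
                 function(p) paste(sort(unique(p)), collapse = ","), "")
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             populations = pops, row.names = NULL)
}

#' Score merged regions: per-population mean CN
#'
#' For each region and population, the mean CN over the region's retained
#' bins. A population with no retained bin in a region (possible when
#' grids are filtered differently) is recorded as CN 0 and flagged missing,
#' keeping the CN matrix rectangular for downstream trees.
#'
#' @param regions data.frame `chrom`/`start`/`end`.
#' @param cn_matrix bins x populations CN matrix aligned to `grid`.
#' @param grid a [build_bins()] grid.
#' @return list with `regions`, `cn` (regions x populations), `missing`
#'   (logical matrix of the same shape).
#' @export
score_regions <- function(regions, cn_matrix, grid) {
  stopifnot(nrow(cn_matrix) == nrow(grid))
  ov <- GenomicRanges::findOverlaps(as_granges(grid), as_granges(regions))
  bins_by_region <- split(S4Vectors::queryHits(ov),
                          S4Vectors::subjectHits(ov))
  if (nrow(regions) > 0 && !length(bins_by_region))
    stop("no region overlaps any retained bin")
  cn <- matrix(0, nrow(regions), ncol(cn_matrix),
               dimnames = list(NULL, colnames(cn_matrix)))
  miss <- matrix(TRUE, nrow(regions), ncol(cn_matrix),
                 dimnames = list(NULL, colnames(cn_matrix)))
  for (r in names(bins_by_region)) {
    i <- as.integer(r)
    b <- bins_by_region[[r]]
    cn[i, ] <- colMeans(cn_matrix[b, , drop = FALSE])
    miss[i, ] <- FALSE
  }
  list(regions = regions, cn = cn, missing = miss)
}

#' Ascertain CNVRs by cross-population CN dispersion
#'
#' Keeps scored regions whose sample standard deviation (n - 1 denominator)
#' of per-population CN meets the threshold.
#'
#' @param scored a [score_regions()] result.
#' @param sd_threshold minimum cross-population sd (default 0.7).
#' @return list of class `cnvr_set`: `regions` (with `sd` column), `cn`,
#'   `missing`, restricted to ascertained regions.
#' @export
ascertain_cnvrs <- function(scored, sd_threshold = 0.7) {
  if (ncol(scored$cn) < 2) stop("need at least two populations")
  sds <- apply(scored$cn, 1, sd)
  keep <- which(sds >= sd_threshold)
  regions <- scored$regions[keep, , drop = FALSE]
  regions$sd <- sds[keep]
  rownames(regions) <- NULL
  structure(list(regions = regions,
                 cn = scored$cn[keep, , drop = FALSE],
                 missing = scored$missing[keep, , drop = FALSE],
                 sd_threshold = sd_threshold),
            class = "cnvr_set")
}

#' Flag population-specific CNVRs
#'
#' A CNVR is population specific when its CN is at least `cn_threshold` in
#' exactly one population and below it in all others.
#'
#' @param cnvrs a `cnvr_set`.
#' @param cn_threshold multi-copy threshold (default 2.5, the MCR seed).
#' @return logical vector over the CNVRs.
#' @export
population_specific <- function(cnvrs, cn_threshold = 2.5) {
  rowSums(cnvrs$cn >= cn_threshold) == 1
}

#' Run the full per-population CNVR ascertainment
#'
#' Chains MCRs in every population, merges them, scores the merged regions
#' and ascertains by cross-population sd — the complete region-calling
#' stage on an existing CN matrix.
#'
#' @param cn_matrix bins x populations CN matrix.
#' @param grid a [build_bins()] grid.
#' @param seed_threshold,min_bins,sd_threshold see [call_mcrs()] and
#'   [ascertain_cnvrs()].
#' @return a `cnvr_set` (with `mcrs` attached as attribute).
#' @export
call_cnvrs <- function(cn_matrix, grid, seed_threshold = 2.5,
                       min_bins = 6, sd_threshold = 0.7) {
  mcrs <- lapply(colnames(cn_matrix), function(p)
    call_mcrs(cn_matrix[, p], grid, p, seed_threshold, min_bins))
  merged <- merge_mcrs(mcrs)
  scored <- score_regions(merged, cn_matrix, grid)
  out <- ascertain_cnvrs(scored, sd_threshold)
  attr(out, "mcrs") <- mcrs
  out
}

#' Group-wise CNVR ascertainment
#'
#' Re-runs the whole pipeline using only the populations of one group
#' (e.g. the *Sus scrofa* populations vs the island clade).
#'
#' @param cn_matrix bins x populations CN matrix.
#' @param grid a [build_bins()] grid.
#' @param group character vector of >= 2 population names.
#' @param ... passed to [call_cnvrs()].
#' @return a `cnvr_set` for the group.
#' @export
group_ascertain <- function(cn_matrix, grid, group, ...) {
  if (length(group) < 2) stop("a group needs at least two populations")
  if (!all(group %in% colnames(cn_matrix))) stop("unknown group populations")
  call_cnvrs(cn_matrix[, group, drop = FALSE], grid, ...)
}

#' Compare two group CNVR sets
#'
#' Partitions the two sets into shared (overlapping by >= 1 bp in the other
#' group's set) and group-unique regions.
#'
#' @param setA,setB `cnvr_set` objects.
#' @return list with `shared_a`, `shared_b` (logical vectors), `n_shared_a`,
#'   `n_shared_b`, `unique_a`, `unique_b` (region data.frames).
#' @export
compare_groups <- function(setA, setB) {
  if (nrow(setA$regions) == 0 || nrow(setB$regions) == 0) {
    sa <- logical(nrow(setA$regions)); sb <- logical(nrow(setB$regions))
  } else {
    ov <- GenomicRanges::findOverlaps(as_granges(setA$regions),
                                      as_granges(setB$regions))
    sa <- seq_len(nrow(setA$regions)) %in% S4Vectors::queryHits(ov)
    sb <- seq_len(nrow(setB$regions)) %in% S4Vectors::subjectHits(ov)
  }
  list(shared_a = sa, shared_b = sb,
       n_shared_a = sum(sa), n_shared_b = sum(sb),
       unique_a = setA$regions[!sa, , drop = FALSE],
       unique_b = setB$regions[!sb, , drop = FALSE])
}

#' Leave-populations-out group resampling
#'
#' Re-ascertains group CNVRs for every `k`-subset of the group's
#' populations, the taxon-sampling robustness check.
#'
#' @param cn_matrix bins x populations CN matrix.
#' @param grid a [build_bins()] grid.
#' @param group population names of the group.
#' @param k subset size.
#' @param ... passed to [call_cnvrs()].
#' @return named list of `cnvr_set`, one per combination.
#' @export
group_resample <- function(cn_matrix, grid, group, k, ...) {
  combos <- combn(group, k, simplify = FALSE)
  out <- lapply(combos, function(g)
    group_ascertain(cn_matrix, grid, g, ...))
  names(out) <- vapply(combos, paste, "", collapse = ",")
  out
}
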