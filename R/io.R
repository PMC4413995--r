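#' Read a BED-style interval file
#'
#' Tab-separated, 0-based half-open, no header. Extra columns are kept
#' under the supplied names. Input need not be sorted; rows are sorted by
#' chromosome and start.
#'
#' @param path file path.
#' @param extra_cols names for columns beyond chrom/start/end (e.g.
#'   `c("name", "class")` for gene BED).
#' @return sorted data.frame.
#' @export
read_bed <- function(path, extra_cols = character(0)) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  cols <- c("chrom", "start", "end", extra_cols)
  if (ncol(df) < length(cols))
    stop("expected at least ", length(cols), " columns in ", path)
  df <- df[, seq_along(cols), drop = FALSE]
  names(df) <- cols
  df[order(df$chrom, df$start), , drop = FALSE]
}

#' Write intervals as BED
#'
#' @param df data.frame whose first three columns are chrom/start/end
#'   (0-based half-open); remaining columns are written as-is.
#' @param path output path.
#' @export
write_bed <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a 3-column depth TSV onto a bin grid
#'
#' Accepts either per-bin rows (`chrom`, `bin_start`, `mean_depth`) or
#' per-base rows in the `samtools depth` dialect (`chrom`, `pos` 1-based,
#' `depth`), binned on the fly: per-base depths are summed within each bin
#' and divided by the bin's unmasked base count (positions absent from the
#' file count as zero depth).
#'
#' @param path file path (no header).
#' @param grid a [build_bins()] grid the track is aligned to.
#' @param per_base `TRUE` for the per-base dialect.
#' @return numeric per-bin depth aligned to `grid` (0 where no data).
#' @export
read_depth_tsv <- function(path, grid, per_base = FALSE) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "pos", "depth"),
                   stringsAsFactors = FALSE)
  bs <- attr(grid, "bin_size") %||% (grid$end[1] - grid$start[1])
  key <- paste(grid$chrom, grid$start)
  out <- numeric(nrow(grid))
  if (per_base) {
    bin_start <- (ceiling(df$pos / bs) - 1) * bs
    agg <- tapply(df$depth, paste(df$chrom, bin_start), sum)
    hit <- match(key, names(agg))
    out[!is.na(hit)] <- as.numeric(agg[hit[!is.na(hit)]]) /
      grid$unmasked[!is.na(hit)]
  } else {
    hit <- match(key, paste(df$chrom, df$pos))
    out[!is.na(hit)] <- df$depth[hit[!is.na(hit)]]
  }
  out
}

#' Write a per-population CN (or depth) track TSV
#'
#' Columns chrom, start, end, value; 0-based half-open bins, no header.
#'
#' @param grid a [build_bins()] grid.
#' @param values per-bin numeric vector.
#' @param path output path.
#' @export
write_track_tsv <- function(grid, values, path) {
  write.table(data.frame(grid$chrom, grid$start, grid$end, values),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a track TSV back onto a grid
#' @param path file path.
#' @param grid the grid the track was written from.
#' @return numeric per-bin vector.
#' @export
read_track_tsv <- function(path, grid) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "start", "end", "value"))
  hit <- match(paste(grid$chrom, grid$start), paste(df$chrom, df$start))
  df$value[hit]
}

#' Write a PHYLIP square distance matrix (relaxed labels)
#'
#' Relaxed format: labels of any length, whitespace-separated, one taxon
#' per line, taxon count on the first line.
#'
#' @param d symmetric labelled matrix.
#' @param path output path.
#' @export
write_phylip_dist <- function(d, path) {
  d <- as.matrix(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(d)), con)
  for (i in seq_len(nrow(d)))
    writeLines(paste(c(rownames(d)[i],
                       sprintf("%.6f", d[i, ])), collapse = "  "), con)
  invisible(path)
}

#' Read a relaxed PHYLIP square distance matrix
#' @param path file path.
#' @return labelled symmetric matrix.
#' @export
read_phylip_dist <- function(path) {
  ln <- readLines(path)
  n <- as.integer(trimws(ln[1]))
  rows <- strsplit(trimws(ln[1 + seq_len(n)]), "\\s+")
  labs <- vapply(rows, `[`, "", 1)
  m <- t(vapply(rows, function(r) as.numeric(r[-1]), numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}

#' Write a discrete character matrix as NEXUS (standard datatype)
#'
#' @param states loci x taxa integer matrix (0..9) or `discrete_cn`.
#' @param path output path.
#' @export
write_nexus_standard <- function(states, path) {
  if (inherits(states, "discrete_cn")) states <- states$states
  mat <- apply(states, 2, paste, collapse = "")
  dat <- lapply(seq_len(ncol(states)), function(i)
    strsplit(mat[i], "")[[1]])
  names(dat) <- colnames(states)
  ape::write.nexus.data(dat, path, format = "standard",
                        interleaved = FALSE)
  invisible(path)
}
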