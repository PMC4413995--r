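#' Binary copy-number difference counts
#'
#' For every pair of samples, counts loci where the absolute copy-number
#' difference is at least `threshold` (default 2). Binarization makes the
#' rate deliberately conservative: a jump from two to ten copies needs at
#' least three duplication events but counts once.
#'
#' @param cn_matrix loci x samples numeric matrix.
#' @param threshold minimum |CN difference| to count (default 2).
#' @return symmetric integer matrix of pairwise difference counts.
#' @export
binary_cnd <- function(cn_matrix, threshold = 2) {
  m <- as.matrix(cn_matrix)
  ns <- ncol(m)
  out <- matrix(0L, ns, ns, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    cnt <- sum(abs(m[, i] - m[, j]) >= threshold)
    out[i, j] <- out[j, i] <- cnt
  }
  out
}

#' Pairwise rate matrix from difference counts
#'
#' @param counts symmetric pairwise count matrix.
#' @param n_loci denominator: number of loci (or callable sites).
#' @return object of class `rate_matrix`: the rate matrix with attribute
#'   `denominator`.
#' @export
cnd_rate <- function(counts, n_loci) {
  if (n_loci <= 0) stop("denominator must be > 0")
  structure(counts / n_loci, denominator = n_loci, class = "rate_matrix")
}

#' Pairwise SNP difference rate
#'
#' Fraction of callable diploid sites at which two individuals differ.
#'
#' @param genotypes individuals x sites matrix (e.g. 0/1 states).
#' @return a `rate_matrix` with the site count as denominator.
#' @export
snp_rate <- function(genotypes) {
  g <- as.matrix(genotypes)
  ns <- nrow(g)
  n_sites <- ncol(g)
  out <- matrix(0, ns, ns, dimnames = list(rownames(g), rownames(g)))
  for (i in seq_len(ns - 1)) for (j in (i + 1):ns) {
    d <- mean(g[i, ] != g[j, ])
    out[i, j] <- out[j, i] <- d
  }
  structure(out, denominator = n_sites, class = "rate_matrix")
}

#' Ratio of CND rate to SNP rate
#'
#' Mean (and range) over sample pairs of the ratio of the binary
#' copy-number difference rate to the SNP rate.
#'
#' @param cnd a `rate_matrix` of CND rates.
#' @param snp a `rate_matrix` of SNP rates over the same samples.
#' @return list `mean`, `min`, `max`, `per_pair` (named vector).
#' @export
rate_ratio <- function(cnd, snp) {
  stopifnot(identical(dim(cnd), dim(snp)))
  ut <- upper.tri(cnd)
  if (any(snp[ut] == 0))
    stop("SNP rate is zero for some pair; ratio undefined")
  r <- cnd[ut] / snp[ut]
  labs <- outer(rownames(cnd), colnames(cnd), paste, sep = "-")[ut]
  names(r) <- labs
  list(mean = mean(r), min = min(r), max = max(r), per_pair = r)
}

#' Hierarchical clustering tree on copy-number profiles
#'
#' Agglomerative clustering of samples on Euclidean distances between
#' their CNVR copy-number vectors (complete linkage by default), returned
#' as a rooted `phylo` dendrogram.
#'
#' @param cn_matrix loci x samples matrix.
#' @param method linkage method passed to [stats::hclust()].
#' @return an `ape::phylo` tree.
#' @export
cn_cluster <- function(cn_matrix, method = "complete") {
  if (ncol(cn_matrix) < 2) stop("need at least two samples")
  hc <- hclust(dist(t(cn_matrix)), method = method)
  ape::as.phylo(hc)
}
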