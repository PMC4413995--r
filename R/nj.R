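#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion
#' `Q(i,j) = (n-2) d(i,j) - r(i) - r(j)`. At each step the pair minimizing
#' Q is joined; ties (within 1e-12 relative tolerance) are broken by the
#' lexicographically lowest pair of cluster labels, where a cluster is
#' labelled by the smallest original taxon label it contains, making the
#' algorithm fully deterministic. Negative branch-length estimates are
#' clamped to zero with the deficit moved to the sibling branch, preserving
#' the joined pair's path length. Recovers any additive (tree-metric)
#' matrix exactly.
#'
#' @param d symmetric distance matrix with labelled rows/columns (or
#'   `dist`), at least 3 taxa, zero diagonal.
#' @return unrooted `ape::phylo` tree with branch lengths.
#' @examples
#' d <- matrix(c(0,3,5,6, 3,0,6,7, 5,6,0,7, 6,7,7,0), 4, 4,
#'             dimnames = list(LETTERS[1:4], LETTERS[1:4]))
#' nj_tree(d)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3) stop("need at least 3 taxa")
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <-
      paste0("t", seq_len(n))
  if (max(abs(d - t(d))) > 1e-8 || any(abs(diag(d)) > 1e-12))
    stop("distance matrix must be symmetric with zero diagonal")

  ## clusters carry a growing newick fragment and a representative label
  newick <- rownames(d)
  replab <- rownames(d)
  D <- d
  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    tol <- 1e-12 * max(1, abs(qmin))
    cand <- which(Q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_lab <- t(apply(cand, 1, function(ij)
      sort(c(replab[ij[1]], replab[ij[2]]))))
    best <- order(pair_lab[, 1], pair_lab[, 2])[1]
    i <- cand[best, 1]; j <- cand[best, 2]

    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }

    new_nwk <- sprintf("(%s:%.12g,%s:%.12g)", newick[i], bi, newick[j], bj)
    new_lab <- min(replab[i], replab[j])
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    newick <- c(newick[keep], new_nwk)
    replab <- c(replab[keep], new_lab)
    rownames(D) <- colnames(D) <- replab
  }
  ## final three clusters join at an unresolved internal node
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  bl <- c(b1, b2, b3)
  for (k in which(bl < 0)) bl[k] <- 0
  txt <- sprintf("(%s:%.12g,%s:%.12g,%s:%.12g);",
                 newick[1], bl[1], newick[2], bl[2], newick[3], bl[3])
  ape::read.tree(text = txt)
}

#' Robinson-Foulds distance between two unrooted topologies
#'
#' Thin wrapper over the symmetric-difference (PH85) topological distance;
#' 0 means identical unrooted topologies.
#'
#' @param t1,t2 `phylo` trees over the same tip set.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2),
                            method = "PH85"))
}
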