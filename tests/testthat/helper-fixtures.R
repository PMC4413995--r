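# shared fixtures, all built in code

# minimal unmasked single-chromosome genome with flat GC
flat_genome <- function(size = 1e5, gc = 0.45, bin_size = 1000) {
  nb <- floor(size / bin_size)
  structure(list(
    chrom_sizes = c(chr1 = size),
    mask = data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)),
    gc = data.frame(chrom = "chr1", start = (seq_len(nb) - 1) * bin_size,
                    gc = gc),
    bin_size = bin_size, seed = 0L), class = "sim_genome")
}

flat_grid <- function(size = 1e5, ...) build_bins(flat_genome(size, ...))

# the worked 4-taxon additive matrix from tree ((A:1,B:2):1,(C:3,D:4))
additive4 <- function() {
  d <- matrix(0, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  d["A", "B"] <- 3; d["A", "C"] <- 5; d["A", "D"] <- 6
  d["B", "C"] <- 6; d["B", "D"] <- 7; d["C", "D"] <- 7
  d + t(d)
}

# random additive distance matrix from a random tree; returns both
random_additive <- function(n, seed) {
  set.seed(seed)
  phy <- ape::rtopology(n, rooted = FALSE,
                        tip.label = paste0("t", seq_len(n)))
  phy$edge.length <- runif(nrow(phy$edge), 0.5, 3)
  list(tree = phy, d = ape::cophenetic.phylo(phy))
}

# brute-force ML/least-squares topology oracle: best-fit topology by
# residual over all unrooted topologies (phangorn::allTrees)
brute_force_topology <- function(d) {
  labs <- rownames(d)
  trees <- phangorn::allTrees(length(labs), rooted = FALSE,
                              tip.label = labs)
  resid <- vapply(trees, function(tr) {
    # least-squares branch fit: path incidence matrix
    ne <- nrow(tr$edge)
    pairs <- t(combn(length(labs), 2))
    X <- matrix(0, nrow(pairs), ne)
    masks <- suscape:::node_tip_masks(tr)
    for (r in seq_len(nrow(pairs))) {
      # edges on path i..j: those whose removal separates i from j
      for (e in seq_len(ne)) {
        below <- as.integer(masks[tr$edge[e, 2]])
        i_in <- bitwAnd(below, bitwShiftL(1L, pairs[r, 1] - 1L)) != 0
        j_in <- bitwAnd(below, bitwShiftL(1L, pairs[r, 2] - 1L)) != 0
        if (i_in != j_in) X[r, e] <- 1
      }
    }
    y <- d[pairs]
    fit <- stats::lm.fit(X, y)
    sum(fit$residuals^2)
  }, 0)
  trees[[which.min(resid)]]
}

# tiny k-state enumeration oracle for the Mk likelihood on an unrooted
# 4-taxon tree ((A,B)X, C, D)R, independent of the pruning implementation
mk_enum_4tax <- function(pat, bl, k) {
  # bl: named c(A=, B=, X=, C=, D=); pat: states 1..k for A,B,C,D
  psame <- function(t) 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
  P <- function(t) {
    m <- matrix((1 - exp(-k * t / (k - 1))) / k, k, k)
    diag(m) <- psame(t)
    m
  }
  tot <- 0
  for (r in seq_len(k)) for (x in seq_len(k))
    tot <- tot + (1 / k) * P(bl["X"])[r, x] *
      P(bl["A"])[x, pat[1]] * P(bl["B"])[x, pat[2]] *
      P(bl["C"])[r, pat[3]] * P(bl["D"])[r, pat[4]]
  tot
}
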