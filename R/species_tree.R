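#' Construct a species tree with optional admixture edges
#'
#' Wraps a rooted binary `ape::phylo` tree (branch lengths in expected
#' events per locus) together with a table of admixture edges. An admixture
#' edge `(donor, recipient, prop)` makes the recipient tip copy the donor
#' tip's state at a locus with probability `prop`, after the tree process
#' has run; by default this perturbation is applied to non-OR loci only.
#'
#' @param newick Newick string or an `ape::phylo` object with branch lengths.
#' @param admixture `NULL` or data.frame with columns `donor`, `recipient`
#'   (tip labels) and `prop` in `[0, 1]`.
#' @return object of class `species_tree`: list with `phylo` and `admixture`.
#' @examples
#' tr <- species_tree("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);")
#' @export
species_tree <- function(newick, admixture = NULL) {
  phy <- if (inherits(newick, "phylo")) newick else ape::read.tree(text = newick)
  if (is.null(phy$edge.length)) stop("species tree needs branch lengths")
  if (any(phy$edge.length < 0)) stop("branch lengths must be >= 0")
  if (!is.null(admixture)) {
    stopifnot(all(c("donor", "recipient", "prop") %in% names(admixture)))
    bad <- !(c(admixture$donor, admixture$recipient) %in% phy$tip.label)
    if (any(bad)) stop("admixture edge names must be tip labels")
    if (any(admixture$prop < 0 | admixture$prop > 1))
      stop("admixture proportions must be in [0, 1]")
  }
  structure(list(phylo = phy, admixture = admixture), class = "species_tree")
}

#' Default seven-population suid species tree
#'
#' Mirrors the accepted genus topology for the seven populations analyzed:
#' a *Sus scrofa* clade (Europe, (China, Sumatra)) sister to an island
#' Southeast Asia clade ((Sbar, Sver), (Sceb, Scel)). Branch lengths are
#' expected copy-number events per locus; admixture edges carry the
#' documented inter-specific hybridization pulls of Sumatra towards the
#' island clade and of China towards *Sus cebifrons*.
#'
#' @param scale multiplier applied to all branch lengths.
#' @param admixture logical; include the default admixture edges.
#' @return a [species_tree()].
#' @export
default_sus_tree <- function(scale = 1, admixture = TRUE) {
  nw <- paste0(
    "((Europe:0.22,(China:0.12,Sumatra:0.12):0.10):0.16,",
    "((Sbar:0.14,Sver:0.14):0.08,(Sceb:0.14,Scel:0.14):0.08):0.16);")
  phy <- ape::read.tree(text = nw)
  phy$edge.length <- phy$edge.length * scale
  adm <- if (admixture) data.frame(
    donor = c("Sbar", "Sver", "Sceb"),
    recipient = c("Sumatra", "Sumatra", "China"),
    prop = c(0.20, 0.20, 0.15)) else NULL
  species_tree(phy, adm)
}

## edge indices in postorder (every child's subtree before its own edge),
## computed directly from the edge matrix; much cheaper than
## ape::reorder.phylo for the small trees hit millions of times in MCMC.
postorder_idx <- function(edge, ntip) {
  nnode <- max(edge)
  depth <- rep(NA_integer_, nnode)
  depth[ntip + 1L] <- 0L
  repeat {
    d <- depth[edge[, 1]] + 1L
    changed <- !is.na(d) & (is.na(depth[edge[, 2]]))
    if (!any(changed)) break
    depth[edge[changed, 2]] <- d[changed]
  }
  order(depth[edge[, 1]], decreasing = TRUE)
}

## tip-set bitmask per node; used for constraint checks and clade queries.
## Returns numeric vector over all nodes; bit i-1 set iff tip i below node
## (tree viewed as rooted at ape's root node).
node_tip_masks <- function(phy) {
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  ord <- postorder_idx(phy$edge, ntip)
  mask <- numeric(nnode)
  mask[seq_len(ntip)] <- 2^(seq_len(ntip) - 1)
  for (e in ord) {
    p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
    mask[p] <- mask[p] + mask[ch]
  }
  mask
}

#' Does an unrooted tree contain a given split?
#'
#' Checks whether the taxa in `taxa` form one side of a bipartition of the
#' (unrooted) tree, i.e. are "monophyletic" in the unrooted sense used by
#' constrained topology models.
#'
#' @param phy `ape::phylo`.
#' @param taxa character vector of tip labels.
#' @return logical.
#' @export
has_split <- function(phy, taxa) {
  ntip <- length(phy$tip.label)
  idx <- match(taxa, phy$tip.label)
  if (anyNA(idx)) stop("unknown taxa: ", paste(taxa[is.na(idx)], collapse = ", "))
  target <- sum(2^(idx - 1))
  full <- sum(2^(seq_len(ntip) - 1))
  masks <- node_tip_masks(phy)
  any(masks == target | masks == full - target)
}
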