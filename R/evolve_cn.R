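## ±step birth-death evolution of integer copy number along one branch.
## m = expected number of events; each event moves CN by +step or -step
## with equal probability, never below 0. Loci that cannot possibly reach 0
## are vectorized; the few that can are walked event by event.
evolve_cn_branch <- function(cn, m, step = 1L) {
  n <- length(cn)
  if (m <= 0) return(cn)
  nev <- rpois(n, m)
  out <- cn
  active <- nev > 0
  safe <- active & (cn - step * nev >= 0)
  if (any(safe)) {
    ups <- rbinom(sum(safe), nev[safe], 0.5)
    out[safe] <- cn[safe] + step * (2 * ups - nev[safe])
  }
  risky <- which(active & !safe)
  for (i in risky) {
    x <- cn[i]
    dirs <- sample(c(-1L, 1L), nev[i], replace = TRUE)
    for (d in dirs) x <- max(0L, x + step * d)
    out[i] <- x
  }
  out
}

#' Evolve integer copy numbers on a species tree
#'
#' Copy number starts at a root value drawn uniformly from `root_states`
#' and evolves along each branch by a birth-death step process: events
#' arrive as Poisson with mean `rate * branch length`, each event changing
#' CN by `± step_size` (floored at zero). Loci are split into `OR` and
#' `nonOR` classes; after the tree process, admixture edges of the tree
#' overwrite the recipient population's state with the donor's state with
#' probability `prop`, at loci of the classes in `admixture_classes`
#' (non-OR only by default, modelling OR loci as resistant to admixture).
#'
#' @param tree a [species_tree()] (or `phylo`, taken as admixture-free).
#' @param n_loci number of loci.
#' @param rate event-rate multiplier applied to all branch lengths.
#' @param class_mix named numeric of class proportions for `OR` and `nonOR`.
#' @param root_states integer vector the root CN is drawn from.
#' @param step_size integer CN change per event. The default 1 gives the
#'   classical single-copy step walk; cohort-level simulation uses 2 (a
#'   fixed one-copy-per-haplotype gain or loss shifts diploid CN by two).
#' @param admixture_classes classes subject to admixture overwriting.
#' @param seed integer seed.
#' @return object of class `cn_truth`: list with `cn` (loci x populations
#'   integer matrix), `class` (factor `OR`/`nonOR`), `root_cn`, `tree`.
#' @examples
#' tr <- default_sus_tree()
#' tv <- evolve_cn_on_tree(tr, n_loci = 100, seed = 1)
#' table(tv$class)
#' @export
evolve_cn_on_tree <- function(tree, n_loci, rate = 1,
                              class_mix = c(OR = 0.5, nonOR = 0.5),
                              root_states = 2:6,
                              step_size = 1L,
                              admixture_classes = "nonOR",
                              seed = 1L) {
  if (inherits(tree, "phylo")) tree <- species_tree(tree)
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  if (ntip < 1 || n_loci < 1) stop("empty tree or no loci")
  if (rate < 0) stop("rate must be >= 0")
  set.seed(seed)

  cls <- factor(sample(names(class_mix), n_loci, replace = TRUE,
                       prob = class_mix / sum(class_mix)),
                levels = c("OR", "nonOR"))
  root_cn <- sample(root_states, n_loci, replace = TRUE)

  nnode <- ntip + phy$Nnode
  cn_node <- matrix(NA_integer_, n_loci, nnode)
  root <- ntip + 1L
  cn_node[, root] <- root_cn
  ## preorder = reverse postorder edge order
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    cn_node[, ch] <- evolve_cn_branch(cn_node[, p],
                                      rate * po$edge.length[e], step_size)
  }
  cn <- cn_node[, seq_len(ntip), drop = FALSE]
  colnames(cn) <- phy$tip.label

  if (!is.null(tree$admixture) && nrow(tree$admixture) > 0) {
    tgt <- cls %in% admixture_classes
    for (i in seq_len(nrow(tree$admixture))) {
      a <- tree$admixture[i, ]
      hit <- tgt & (runif(n_loci) < a$prop)
      cn[hit, a$recipient] <- cn[hit, a$donor]
    }
  }

  structure(list(cn = cn, class = cls, root_cn = root_cn, tree = tree),
            class = "cn_truth")
}

#' Simulate biallelic genotypes on a species tree
#'
#' Sites evolve under a symmetric two-state flip process: along a branch of
#' length `l`, a site flips state with probability `(1 - exp(-2 r l)) / 2`
#' (the two-state Markov chain flip probability at rate `r = snp_rate`).
#' Each population contributes `n_individuals` individuals attached to the
#' population tip by private stub branches of length `stub_length`, so
#' within-population pairs also accumulate differences. The expected
#' pairwise difference fraction is approximately `snp_rate * path length`
#' for small rates.
#'
#' @param tree a [species_tree()] or `phylo` (admixture ignored: these are
#'   diploid-region SNPs used as the neutral yardstick).
#' @param n_sites number of sites.
#' @param snp_rate flip rate per unit branch length.
#' @param n_individuals individuals per population.
#' @param stub_length length of each individual's private branch.
#' @param seed integer seed.
#' @return integer matrix individuals x sites (0/1), with attributes
#'   `population` (named character) mapping individuals to populations.
#' @export
simulate_genotypes <- function(tree, n_sites, snp_rate = 1,
                               n_individuals = 2, stub_length = 0.02,
                               seed = 1L) {
  if (inherits(tree, "phylo")) tree <- species_tree(tree)
  phy <- tree$phylo
  if (n_sites <= 0) stop("n_sites must be > 0")
  set.seed(seed)
  ntip <- length(phy$tip.label)
  nnode <- ntip + phy$Nnode
  root <- ntip + 1L
  flip_p <- function(l) (1 - exp(-2 * snp_rate * l)) / 2

  state <- matrix(0L, nnode, n_sites)
  po <- ape::reorder.phylo(phy, "postorder")
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    flips <- runif(n_sites) < flip_p(po$edge.length[e])
    state[ch, ] <- ifelse(flips, 1L - state[p, ], state[p, ])
  }

  inds <- as.vector(t(outer(phy$tip.label, seq_len(n_individuals),
                            paste, sep = "_")))
  geno <- matrix(0L, length(inds), n_sites,
                 dimnames = list(inds, NULL))
  popmap <- setNames(rep(phy$tip.label, each = n_individuals), inds)
  for (i in seq_along(inds)) {
    tipstate <- state[match(popmap[[i]], phy$tip.label), ]
    flips <- runif(n_sites) < flip_p(stub_length)
    geno[i, ] <- ifelse(flips, 1L - tipstate, tipstate)
  }
  attr(geno, "population") <- popmap
  geno
}
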