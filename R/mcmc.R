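## validate that constraint clades are nested or disjoint (hence jointly
## satisfiable on some binary tree)
validate_constraints <- function(constraints, taxa) {
  for (cl in constraints) {
    if (!all(cl %in% taxa)) stop("constraint names unknown taxa")
    if (length(cl) < 2 || length(cl) > length(taxa) - 2)
      stop("a constraint must name 2..(n-2) taxa")
  }
  if (length(constraints) > 1) {
    for (i in seq_along(constraints)) for (j in seq_along(constraints)) {
      if (i >= j) next
      a <- constraints[[i]]; b <- constraints[[j]]
      inter <- intersect(a, b)
      if (length(inter) && !(all(a %in% b) || all(b %in% a)))
        stop("constraints must be nested or disjoint")
    }
  }
  invisible(TRUE)
}

satisfies_constraints <- function(phy, constraints) {
  for (cl in constraints) if (!has_split(phy, cl)) return(FALSE)
  TRUE
}

## one random nearest-neighbor interchange, O(1) on the edge matrix.
## Picks an internal edge (u,v) uniformly, then swaps one of v's child
## subtrees (uniform of 2) with a fixed sibling subtree attached at u.
## Both NNI neighbors of the edge are reachable and the proposal is
## symmetric: 1 / (2 * number of internal edges) in either direction.
nni_propose <- function(phy) {
  ntip <- length(phy$tip.label)
  E <- phy$edge
  int_edges <- which(E[, 2] > ntip)
  if (!length(int_edges)) return(phy)
  e <- int_edges[sample.int(length(int_edges), 1)]
  u <- E[e, 1]; v <- E[e, 2]
  ch <- which(E[, 1] == v)
  sib <- setdiff(which(E[, 1] == u), e)[1]
  ce <- ch[sample.int(length(ch), 1)]
  tmp <- E[ce, 2]
  E[ce, 2] <- E[sib, 2]
  E[sib, 2] <- tmp
  phy$edge <- E
  phy
}

## random unrooted binary topology satisfying the constraints, by rejection
random_constrained_topology <- function(taxa, constraints, bl_rate = 10,
                                        max_tries = 20000) {
  for (i in seq_len(max_tries)) {
    phy <- ape::rtopology(length(taxa), rooted = FALSE, tip.label = taxa)
    if (satisfies_constraints(phy, constraints)) {
      phy$edge.length <- rexp(nrow(phy$edge), bl_rate)
      return(phy)
    }
  }
  stop("could not find a topology satisfying the constraints")
}

#' Metropolis-Hastings MCMC over constrained tree space under Mkv
#'
#' Samples tree topologies and branch lengths from the (power) posterior
#' `prior x likelihood^beta`. Topology moves are random NNI rearrangements
#' rejected outright when they break a constrained clade (a hard uniform
#' prior over constraint-compatible topologies); branch-length moves are
#' multiplier proposals on a random branch. Priors: uniform over compatible
#' topologies, iid Exponential(`bl_rate`) branch lengths. Passing
#' `states = NULL` runs the chain data-free (likelihood identically 1),
#' which samples the prior — useful for validation.
#'
#' @param states loci x taxa integer matrix (0..k-1) or `discrete_cn`, or
#'   `NULL` for a prior-only run.
#' @param taxa taxon names (required when `states` is `NULL`).
#' @param k number of states.
#' @param constraints list of character vectors, each a clade that must be
#'   monophyletic (in the unrooted, split sense).
#' @param n_iter total iterations.
#' @param burnin fraction of iterations discarded (default 0.25).
#' @param thin keep every `thin`-th post-burnin sample.
#' @param beta power on the likelihood (1 = posterior, 0 = prior).
#' @param bl_rate exponential prior rate on branch lengths (mean 1/rate).
#' @param p_topo probability of proposing a topology move.
#' @param tuning log-scale width of the branch multiplier proposal.
#' @param init_tree optional starting `phylo` (must satisfy constraints).
#' @param seed integer seed.
#' @return list of class `mkv_mcmc`: `trees` (list of sampled `phylo`),
#'   `loglik`, `mean_bl` (per-sample mean branch length), `acceptance`
#'   (topology and branch rates), `final_tree`.
#' @export
mkv_mcmc <- function(states = NULL, taxa = NULL, k = 10,
                     constraints = list(), n_iter = 10000,
                     burnin = 0.25, thin = 10, beta = 1,
                     bl_rate = 10, p_topo = 0.3, tuning = 1,
                     init_tree = NULL, seed = 1L) {
  set.seed(seed)
  if (inherits(states, "discrete_cn")) { k <- states$k; states <- states$states }
  if (is.null(taxa)) {
    if (is.null(states)) stop("need taxa when running data-free")
    taxa <- colnames(states)
  }
  validate_constraints(constraints, taxa)
  if (!is.null(states)) {
    if (any(states < 0 | states >= k)) stop("states must lie in 0..k-1")
    if (any(apply(states, 1, function(x) length(unique(x))) < 2))
      stop("constant character present; Mkv needs variable characters")
  }
  loglik_fun <- if (is.null(states)) function(phy) 0 else
    function(phy) as.numeric(mkv_ll_impl(phy, states, k, correct = TRUE))

  phy <- init_tree %||% random_constrained_topology(taxa, constraints,
                                                    bl_rate)
  if (!satisfies_constraints(phy, constraints))
    stop("init_tree violates the constraints")
  ll <- loglik_fun(phy)
  lp <- sum(stats::dexp(phy$edge.length, bl_rate, log = TRUE))

  keep_from <- floor(burnin * n_iter)
  trees <- list(); lls <- numeric(0); mbl <- numeric(0)
  acc <- c(topo = 0, topo_try = 0, bl = 0, bl_try = 0)
  for (it in seq_len(n_iter)) {
    if (runif(1) < p_topo && length(taxa) > 3) {
      acc["topo_try"] <- acc["topo_try"] + 1
      prop <- nni_propose(phy)
      if (satisfies_constraints(prop, constraints)) {
        ll2 <- loglik_fun(prop)
        lp2 <- sum(stats::dexp(prop$edge.length, bl_rate, log = TRUE))
        if (log(runif(1)) < beta * (ll2 - ll) + (lp2 - lp)) {
          phy <- prop; ll <- ll2; lp <- lp2
          acc["topo"] <- acc["topo"] + 1
        }
      }
    } else {
      acc["bl_try"] <- acc["bl_try"] + 1
      e <- sample.int(nrow(phy$edge), 1)
      mult <- exp(tuning * (runif(1) - 0.5))
      prop <- phy
      prop$edge.length[e] <- phy$edge.length[e] * mult
      ll2 <- loglik_fun(prop)
      lp2 <- sum(stats::dexp(prop$edge.length, bl_rate, log = TRUE))
      if (log(runif(1)) < beta * (ll2 - ll) + (lp2 - lp) + log(mult)) {
        phy <- prop; ll <- ll2; lp <- lp2
        acc["bl"] <- acc["bl"] + 1
      }
    }
    if (it > keep_from && (it - keep_from) %% thin == 0) {
      trees[[length(trees) + 1]] <- phy
      lls <- c(lls, ll)
      mbl <- c(mbl, mean(phy$edge.length))
    }
  }
  structure(list(trees = trees, loglik = lls, mean_bl = mbl,
                 acceptance = c(topo = unname(acc["topo"] / max(1, acc["topo_try"])),
                                bl = unname(acc["bl"] / max(1, acc["bl_try"]))),
                 final_tree = phy),
            class = "mkv_mcmc")
}

#' Posterior probability of a clade in an MCMC sample
#'
#' @param fit an [mkv_mcmc()] result.
#' @param taxa character vector of tip labels.
#' @return fraction of sampled trees containing the split.
#' @export
clade_posterior <- function(fit, taxa) {
  mean(vapply(fit$trees, has_split, TRUE, taxa = taxa))
}
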