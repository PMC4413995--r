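#' Discretize copy numbers to ten states per locus
#'
#' Each locus is range-normalized across taxa and mapped to integer states
#' 0-9: `state = round(((CN - CN_min) / (CN_max - CN_min)) * 9)` with
#' halves rounded away from zero, so the per-locus minimum always maps to
#' state 0 and the maximum to state 9. Loci with `CN_max == CN_min`
#' (invariant loci) cannot be transformed and are skipped with a warning —
#' the downstream Mkv model conditions on variability anyway.
#'
#' @param cn_matrix loci x taxa numeric matrix of copy numbers.
#' @param k number of states (default 10, i.e. states 0..9).
#' @return list of class `discrete_cn`: `states` (loci x taxa integer
#'   matrix), `kept` (row indices of transformable loci), `range`
#'   (data.frame `cn_min`, `cn_max` per kept locus), `k`.
#' @examples
#' m <- rbind(c(2, 7, 12), c(0, 1, 4))
#' discretize_cn(m)$states
#' @export
discretize_cn <- function(cn_matrix, k = 10) {
  m <- as.matrix(cn_matrix)
  lo <- apply(m, 1, min)
  hi <- apply(m, 1, max)
  keep <- which(hi > lo)
  if (length(keep) < nrow(m))
    warning(nrow(m) - length(keep),
            " invariant locus/loci skipped (CN_max == CN_min)")
  if (!length(keep)) stop("no variable loci to discretize")
  mm <- m[keep, , drop = FALSE]
  states <- round_half_away((mm - lo[keep]) / (hi[keep] - lo[keep]) *
                            (k - 1))
  storage.mode(states) <- "integer"
  structure(list(states = states, kept = keep,
                 range = data.frame(cn_min = lo[keep], cn_max = hi[keep]),
                 k = as.integer(k)),
            class = "discrete_cn")
}

#' Mkv log-likelihood of a discrete character matrix on a tree
#'
#' Likelihood under the symmetric k-state Mk substitution model with
#' branch lengths in expected substitutions per character, computed by
#' Felsenstein pruning with uniform root frequencies, conditioned on
#' characters being variable (the Mkv ascertainment correction): each
#' site's likelihood is divided by one minus the summed probability of the
#' k all-taxa-constant patterns.
#'
#' @param tree `phylo` over the matrix taxa, with branch lengths.
#' @param states loci x taxa integer matrix with values in `0..k-1`
#'   (columns named by taxa), or a `discrete_cn`.
#' @param k number of states.
#' @param correct apply the variable-characters ascertainment correction
#'   (default `TRUE`); `FALSE` gives the plain Mk likelihood.
#' @return total log-likelihood (scalar) with attribute `site_loglik`.
#' @export
mkv_log_likelihood <- function(tree, states, k = 10, correct = TRUE) {
  if (inherits(states, "discrete_cn")) {
    k <- states$k
    states <- states$states
  }
  if (is.null(colnames(states)))
    stop("state matrix needs taxon column names")
  if (any(states < 0 | states >= k)) stop("states must lie in 0..k-1")
  if (correct && any(apply(states, 1, function(x) length(unique(x))) < 2))
    stop("constant character present; Mkv is defined on variable characters")
  mkv_ll_impl(tree, states, k, correct)
}

## hot path without input validation; used by the MCMC inner loop
mkv_ll_impl <- function(tree, states, k, correct) {
  ord <- match(tree$tip.label, colnames(states))
  if (anyNA(ord)) stop("tree tips and matrix taxa differ")
  eord <- postorder_idx(tree$edge, length(tree$tip.label))
  res <- mkv_loglik_cpp(tree$edge[eord, , drop = FALSE],
                        tree$edge.length[eord],
                        length(tree$tip.label),
                        states[, ord, drop = FALSE], as.integer(k))
  site <- res$site_loglik
  if (correct) {
    log_pconst <- log(k) + res$const_loglik  # k symmetric constant patterns
    site <- site - log1p(-exp(log_pconst))
  }
  structure(sum(site), site_loglik = site)
}

#' Simulate a variable discrete character matrix under Mk
#'
#' Evolves k-state characters on a tree under the symmetric Mk model
#' (uniform root) and discards constant characters, topping up until
#' `n_loci` variable characters are obtained — the generating process the
#' Mkv likelihood assumes.
#'
#' @param tree `phylo` with branch lengths.
#' @param n_loci number of variable characters wanted.
#' @param k number of states (default 10).
#' @param seed integer seed.
#' @return loci x taxa integer matrix (values 0..k-1), columns named.
#' @export
simulate_mk_matrix <- function(tree, n_loci, k = 10, seed = 1L) {
  set.seed(seed)
  ntip <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  nnode <- ntip + tree$Nnode
  draw <- function(n) {
    st <- matrix(NA_integer_, n, nnode)
    st[, ntip + 1L] <- sample.int(k, n, replace = TRUE) - 1L
    for (e in rev(seq_len(nrow(po$edge)))) {
      p <- po$edge[e, 1]; ch <- po$edge[e, 2]
      t <- po$edge.length[e]
      ek <- exp(-k * t / (k - 1))
      psame <- 1 / k + (k - 1) / k * ek
      change <- runif(n) >= psame
      newst <- st[, p]
      if (any(change)) {
        ## conditional on change, the new state is uniform on the others
        shift <- sample.int(k - 1, sum(change), replace = TRUE)
        newst[change] <- (st[change, p] + shift) %% k
      }
      st[, ch] <- newst
    }
    st[, seq_len(ntip), drop = FALSE]
  }
  out <- NULL
  while (is.null(out) || nrow(out) < n_loci) {
    st <- draw(2 * n_loci)
    var <- apply(st, 1, function(x) length(unique(x)) > 1)
    out <- rbind(out, st[var, , drop = FALSE])
  }
  out <- out[seq_len(n_loci), , drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}
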