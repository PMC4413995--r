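#' Stepping-stone beta ladder
#'
#' Power-posterior inverse temperatures placed at quantiles of a
#' Beta(`alpha`, 1) distribution, `beta_j = (j / steps)^(1/alpha)`,
#' concentrating rungs near the prior where the integrand changes fastest.
#' Endpoints are exactly 0 and 1.
#'
#' @param steps number of stepping-stone steps (>= 2).
#' @param alpha Beta shape (default 0.3, the standard recommendation).
#' @return numeric vector of `steps + 1` betas from 0 to 1.
#' @export
ss_ladder <- function(steps = 50, alpha = 0.3) {
  if (steps < 2) stop("need at least 2 steps")
  ((0:steps) / steps)^(1 / alpha)
}

#' Generic stepping-stone marginal-likelihood estimator
#'
#' Estimates `ln` marginal likelihood from a ladder of power posteriors
#' `prior x L^beta`. For each rung `j` the chain samples the power
#' posterior at `beta_j` (continuing from the previous rung's state), and
#' the rung contribution is
#' `ln (1/n) sum_i L(theta_i)^(beta_{j+1} - beta_j)`, accumulated over
#' rungs with a log-sum-exp; a per-rung delta-method Monte Carlo standard
#' error is reported. The model is supplied abstractly as an initial
#' state and a transition kernel, so the same estimator drives both toy
#' conjugate models and the Mkv tree model.
#'
#' The ladder is traversed from the posterior (`beta = 1`) down to the
#' prior: after an initial burn-in at the posterior, each rung's sampler
#' continues from the previous (hotter) rung's state, the usual annealed
#' schedule that lets the chain find the high-likelihood region before the
#' rungs that matter most are sampled.
#'
#' @param init initial state (any R object).
#' @param step_fun function `(state, beta)` performing one MCMC update of
#'   the power posterior at `beta` and returning the new state; the state
#'   must carry its current log-likelihood retrievable by `loglik_fun`.
#' @param loglik_fun function `(state)` returning the log-likelihood.
#' @param steps,alpha ladder parameters, see [ss_ladder()].
#' @param n_per_step samples per rung (after burnin).
#' @param burnin fraction of each rung's iterations discarded.
#' @param init_burn iterations of initial posterior burn-in (default: one
#'   rung's worth).
#' @return list of class `ss_estimate`: `log_ml`, `steps` (data.frame with
#'   `beta`, `dbeta`, `log_ratio`, `mc_se`), `mc_se` (total), `final`.
#' @export
stepping_stone <- function(init, step_fun, loglik_fun, steps = 50,
                           alpha = 0.3, n_per_step = 100, burnin = 0.25,
                           init_burn = NULL) {
  betas <- ss_ladder(steps, alpha)
  state <- init
  nburn <- ceiling(burnin * n_per_step / (1 - burnin))
  init_burn <- init_burn %||% (nburn + n_per_step)
  for (i in seq_len(init_burn)) state <- step_fun(state, 1)
  log_ratios <- numeric(steps)
  ses <- numeric(steps)
  for (j in rev(seq_len(steps))) {
    b <- betas[j]
    dbeta <- betas[j + 1] - betas[j]
    for (i in seq_len(nburn)) state <- step_fun(state, b)
    ll <- numeric(n_per_step)
    for (i in seq_len(n_per_step)) {
      state <- step_fun(state, b)
      ll[i] <- loglik_fun(state)
    }
    x <- dbeta * ll
    m <- max(x)
    w <- exp(x - m)
    log_ratios[j] <- m + log(mean(w))
    ses[j] <- stats::sd(w) / (sqrt(n_per_step) * mean(w))
  }
  structure(list(log_ml = sum(log_ratios),
                 steps = data.frame(beta = betas[-length(betas)],
                                    dbeta = diff(betas),
                                    log_ratio = log_ratios, mc_se = ses),
                 mc_se = sqrt(sum(ses^2)), final = state),
            class = "ss_estimate")
}

#' Stepping-stone marginal likelihood for the Mkv tree model
#'
#' Runs the stepping-stone estimator over constrained tree space: the
#' state is a (topology, branch lengths) pair, the kernel is the
#' [mkv_mcmc()] move mix (constraint-rejecting NNI plus branch
#' multipliers) targeting `prior x L^beta`, and the ladder follows
#' Beta(0.3, 1) quantiles.
#'
#' @param states loci x taxa integer matrix (0..k-1) or `discrete_cn`.
#' @param k number of states.
#' @param constraints list of clades constrained monophyletic.
#' @param steps number of rungs (default 50).
#' @param n_per_step post-burnin samples per rung.
#' @param burnin per-rung burnin fraction (default 0.25).
#' Before the ladder is run, several independent short posterior chains
#' are launched from random constrained topologies and the best end state
#' (by unnormalized posterior density) seeds the ladder, which guards the
#' high-beta rungs against starting in a poor topology mode.
#'
#' @param bl_rate,p_topo,tuning see [mkv_mcmc()].
#' @param n_starts,start_iter mode-finding phase: number of independent
#'   posterior starts and iterations each.
#' @param seed integer seed.
#' @param model optional model id stored in the result.
#' @return an `ss_estimate` with `model` attached.
#' @export
stepping_stone_mkv <- function(states, k = 10, constraints = list(),
                               steps = 50, n_per_step = 200,
                               burnin = 0.25, bl_rate = 10, p_topo = 0.3,
                               tuning = 1, n_starts = 3, start_iter = 500,
                               seed = 1L, model = NULL) {
  set.seed(seed)
  if (inherits(states, "discrete_cn")) { k <- states$k; states <- states$states }
  taxa <- colnames(states)
  validate_constraints(constraints, taxa)
  step_fun <- function(state, beta) {
    if (runif(1) < p_topo && length(taxa) > 3) {
      prop <- nni_propose(state$phy)
      if (satisfies_constraints(prop, constraints)) {
        ll2 <- as.numeric(mkv_ll_impl(prop, states, k, TRUE))
        lp2 <- sum(stats::dexp(prop$edge.length, bl_rate, log = TRUE))
        if (log(runif(1)) < beta * (ll2 - state$ll) + (lp2 - state$lp))
          state <- list(phy = prop, ll = ll2, lp = lp2)
      }
    } else {
      e <- sample.int(nrow(state$phy$edge), 1)
      mult <- exp(tuning * (runif(1) - 0.5))
      prop <- state$phy
      prop$edge.length[e] <- prop$edge.length[e] * mult
      ll2 <- as.numeric(mkv_ll_impl(prop, states, k, TRUE))
      lp2 <- sum(stats::dexp(prop$edge.length, bl_rate, log = TRUE))
      if (log(runif(1)) <
          beta * (ll2 - state$ll) + (lp2 - state$lp) + log(mult))
        state <- list(phy = prop, ll = ll2, lp = lp2)
    }
    state
  }
  ## mode finding: independent posterior chains, keep the densest state.
  ## One start is the NJ topology on pairwise Hamming distances (when it
  ## satisfies the constraints) -- a cheap deterministic point near the
  ## high-likelihood region; the rest are random constrained topologies.
  starts <- list()
  ham <- matrix(0, length(taxa), length(taxa),
                dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) for (j in seq_along(taxa))
    if (i < j) ham[i, j] <- ham[j, i] <-
      mean(states[, i] != states[, j])
  njp <- tryCatch(nj_tree(ham), error = function(e) NULL)
  if (!is.null(njp) && satisfies_constraints(njp, constraints)) {
    njp$edge.length <- pmax(njp$edge.length, 0.01)
    starts[[1]] <- njp
  }
  st <- NULL
  for (i in seq_len(max(1, n_starts))) {
    phy <- if (i <= length(starts)) starts[[i]] else
      random_constrained_topology(taxa, constraints, bl_rate)
    cand <- list(phy = phy,
                 ll = as.numeric(mkv_ll_impl(phy, states, k, TRUE)),
                 lp = sum(stats::dexp(phy$edge.length, bl_rate,
                                      log = TRUE)))
    best <- cand
    for (j in seq_len(start_iter)) {
      cand <- step_fun(cand, 1)
      if (cand$ll + cand$lp > best$ll + best$lp) best <- cand
    }
    if (is.null(st) || best$ll + best$lp > st$ll + st$lp) st <- best
  }

  out <- stepping_stone(st, step_fun, function(s) s$ll, steps = steps,
                        alpha = 0.3, n_per_step = n_per_step,
                        burnin = burnin)
  out$model <- model
  out
}

#' Compare models by marginal likelihood
#'
#' Tabulates delta-lnL = (best marginal likelihood) - (model's marginal
#' likelihood); the best model scores 0 and worse models score positive
#' values. Deltas are invariant to adding a constant to all scores.
#'
#' @param estimates named numeric vector of ln marginal likelihoods, or a
#'   named list of `ss_estimate` objects.
#' @return data.frame `model`, `log_ml`, `delta`, in the given order.
#' @export
compare_models <- function(estimates) {
  if (is.list(estimates))
    estimates <- vapply(estimates, function(e)
      if (inherits(e, "ss_estimate")) e$log_ml else as.numeric(e), 0)
  if (!length(estimates)) stop("no estimates")
  data.frame(model = names(estimates) %||% seq_along(estimates),
             log_ml = as.numeric(estimates),
             delta = max(estimates) - as.numeric(estimates),
             row.names = NULL)
}

#' Predefined constrained topology models for the seven-population cohort
#'
#' The null model constrains the two major clades (the three *Sus scrofa*
#' populations vs the four island species — one split, so one constraint);
#' models m1-m4 each force a cross-clade pair reflecting a documented or
#' hypothesized admixture/translocation scenario: m1 Sver+Sumatra, m2
#' Scel+Sumatra, m3 Sbar+Sumatra, m4 Sceb+China.
#'
#' @return named list of constraint lists, usable with
#'   [stepping_stone_mkv()] and [mkv_mcmc()].
#' @export
sus_constraint_models <- function() {
  list(
    null = list(c("Europe", "China", "Sumatra")),
    m1 = list(c("Sver", "Sumatra")),
    m2 = list(c("Scel", "Sumatra")),
    m3 = list(c("Sbar", "Sumatra")),
    m4 = list(c("Sceb", "China")))
}
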