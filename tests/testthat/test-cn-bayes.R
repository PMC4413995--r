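test_that("discretization maps locus range onto states 0..9", {
  m <- rbind(c(2, 12, 7), c(1, 3, 2))
  colnames(m) <- c("x", "y", "z")
  d <- discretize_cn(m)
  expect_equal(d$states[1, ], c(x = 0L, y = 9L, z = 5L))  # 4.5 -> 5
  expect_equal(d$states[2, ], c(x = 0L, y = 9L, z = 5L))  # 4.5 again
  expect_true(all(apply(d$states, 1, min) == 0))
  expect_true(all(apply(d$states, 1, max) == 9))
  # affine rescaling of a locus leaves its states unchanged
  d2 <- discretize_cn(3 * m + 11)
  expect_equal(unname(d$states), unname(d2$states))
  # invariant loci are skipped with a warning
  expect_warning(d3 <- discretize_cn(rbind(m, c(4, 4, 4))), "invariant")
  expect_equal(d3$kept, 1:2)
  expect_equal(round_half_away(c(4.5, -4.5, 2.4)), c(5, -5, 2))
})

test_that("pruning equals brute-force enumeration (4 taxa, small k)", {
  for (k in c(2, 4, 5)) {
    bl <- c(A = 0.3, B = 0.5, X = 0.2, C = 0.7, D = 0.4)
    tr <- ape::read.tree(text = sprintf(
      "((A:%g,B:%g):%g,C:%g,D:%g);", bl["A"], bl["B"], bl["X"],
      bl["C"], bl["D"]))
    pats <- as.matrix(expand.grid(rep(list(seq_len(k)), 4)))
    Lbf <- apply(pats, 1, mk_enum_4tax, bl = bl, k = k)
    st <- pats - 1L
    colnames(st) <- c("A", "B", "C", "D")
    ll <- vapply(seq_len(nrow(st)), function(i)
      as.numeric(mkv_log_likelihood(tr, st[i, , drop = FALSE], k = k,
                                    correct = FALSE)), 0)
    expect_lt(max(abs(exp(ll) - Lbf)), 1e-10)
    # all-pattern likelihoods sum to one
    expect_equal(sum(Lbf), 1, tolerance = 1e-10)
    expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
    # corrected likelihoods over variable patterns sum to one
    varp <- apply(st, 1, function(x) length(unique(x)) > 1)
    llv <- vapply(which(varp), function(i)
      as.numeric(mkv_log_likelihood(tr, st[i, , drop = FALSE], k = k,
                                    correct = TRUE)), 0)
    expect_equal(sum(exp(llv)), 1, tolerance = 1e-10)
  }
})

test_that("two-taxon likelihood matches the closed form", {
  k <- 10
  t <- 0.37
  tr <- ape::read.tree(text = sprintf("(A:%g,B:%g);", t / 2, t / 2))
  psame <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
  pdiff <- (1 - exp(-k * t / (k - 1))) / k
  same <- matrix(c(3L, 3L), 1, 2, dimnames = list(NULL, c("A", "B")))
  diffp <- matrix(c(3L, 7L), 1, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(as.numeric(mkv_log_likelihood(tr, same, k = k,
                                             correct = FALSE)),
               log(psame / k), tolerance = 1e-12)
  expect_equal(as.numeric(mkv_log_likelihood(tr, diffp, k = k,
                                             correct = FALSE)),
               log(pdiff / k), tolerance = 1e-12)
})

test_that("degenerate branch lengths give -Inf for variable sites", {
  tr <- ape::read.tree(text = "((A:0,B:0):0,C:0,D:0);")
  st <- matrix(c(0L, 1L, 0L, 0L), 1, 4,
               dimnames = list(NULL, c("A", "B", "C", "D")))
  expect_equal(as.numeric(mkv_log_likelihood(tr, st, k = 4,
                                             correct = FALSE)), -Inf)
  # constant input is rejected under the variable-characters model
  cst <- matrix(0L, 1, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  expect_error(mkv_log_likelihood(tr, cst, k = 4), "variable")
})

test_that("transition probabilities are stochastic and mix to uniform", {
  k <- 10
  for (t in c(0.01, 0.5, 5)) {
    psame <- 1 / k + (k - 1) / k * exp(-k * t / (k - 1))
    pdiff <- (1 - exp(-k * t / (k - 1))) / k
    expect_equal(psame + (k - 1) * pdiff, 1, tolerance = 1e-12)
  }
  t <- 1e4
  expect_equal(1 / k + (k - 1) / k * exp(-k * t / (k - 1)), 1 / k,
               tolerance = 1e-12)
})

test_that("data-free MCMC recovers the branch-length prior", {
  fit <- mkv_mcmc(states = NULL, taxa = letters[1:5], n_iter = 20000,
                  thin = 5, p_topo = 0.2, bl_rate = 10, seed = 3)
  m <- mean(fit$mean_bl)
  # prior mean 0.1; allow 3 MC s.e. with a crude autocorrelation guard
  se <- sd(fit$mean_bl) / sqrt(length(fit$mean_bl) / 10)
  expect_lt(abs(m - 0.1), 3 * se + 0.005)
})

test_that("hard constraints hold in every sampled tree", {
  tr <- ape::read.tree(text = "((A:0.4,B:0.4):0.2,(C:0.4,D:0.4):0.2);")
  st <- simulate_mk_matrix(tr, n_loci = 60, k = 6, seed = 5)
  fit <- mkv_mcmc(st, k = 6, constraints = list(c("A", "B")),
                  n_iter = 4000, seed = 6)
  expect_true(all(vapply(fit$trees, has_split, TRUE, taxa = c("A", "B"))))
  # nested/disjoint validation
  expect_error(suscape:::validate_constraints(list(c("A", "B"),
                                                   c("B", "C")),
                                              LETTERS[1:5]),
               "nested or disjoint")
})

test_that("strong signal for a clade yields high posterior support", {
  tr <- ape::read.tree(text =
    "((A:0.3,B:0.3):0.3,(C:0.3,D:0.3):0.3,(E:0.3,F:0.3):0.3);")
  st <- simulate_mk_matrix(tr, n_loci = 200, k = 10, seed = 7)
  fit <- mkv_mcmc(st, k = 10, n_iter = 8000, seed = 8)
  expect_gt(clade_posterior(fit, c("A", "B")), 0.9)
})

test_that("stepping-stone ladder and toy marginal likelihood", {
  b <- ss_ladder(50)
  expect_equal(b[1], 0)
  expect_equal(b[51], 1)
  expect_equal(length(b), 51)
  expect_true(all(diff(b) > 0))

  # conjugate toy: theta ~ U(0,1), L = theta (1 - theta);
  # marginal = Beta(2, 2) integral = 1/6
  set.seed(11)
  step_fun <- function(state, beta) {
    prop <- state$theta + runif(1, -0.3, 0.3)
    prop <- abs(prop)
    if (prop > 1) prop <- 2 - prop
    ll2 <- log(prop) + log(1 - prop)
    if (log(runif(1)) < beta * (ll2 - state$ll))
      state <- list(theta = prop, ll = ll2)
    state
  }
  est <- stepping_stone(list(theta = 0.5, ll = log(0.25)), step_fun,
                        function(s) s$ll, steps = 50, n_per_step = 300)
  expect_lt(abs(est$log_ml - log(1 / 6)), 0.05)
  expect_equal(nrow(est$steps), 50)
  expect_true(all(is.finite(est$steps$log_ratio)))
})

test_that("stepping-stone is stable across seeds on a fixed matrix", {
  tr <- default_sus_tree(scale = 2)$phylo
  st <- simulate_mk_matrix(tr, n_loci = 80, k = 10, seed = 13)
  ests <- vapply(1:3, function(s)
    stepping_stone_mkv(st, k = 10, steps = 10, n_per_step = 400,
                       seed = 20 + s)$log_ml, 0)
  # seed-to-seed spread stays small relative to the ~ -1000 lnL scale at
  # this reduced sampling effort (tighter agreement needs the full-length
  # 50-rung ladder)
  expect_lt(max(ests) - min(ests), 5)
})

test_that("model comparison tables delta-lnL against the best model", {
  expect_equal(compare_models(c(only = -50))$delta, 0)
  tab <- compare_models(c(a = -100, b = -107.46))
  expect_equal(tab$delta, c(0, 7.46))
  shifted <- compare_models(c(a = -100, b = -107.46) + 1234)
  expect_equal(tab$delta, shifted$delta)
})

test_that("branch lengths are recovered within 25 percent", {
  tr <- default_sus_tree(admixture = FALSE)$phylo
  tr$edge.length <- rep(0.25, nrow(tr$edge))
  st <- simulate_mk_matrix(ape::unroot(tr), n_loci = 500, k = 10,
                           seed = 17)
  fit <- mkv_mcmc(st, k = 10, n_iter = 15000, seed = 18,
                  constraints = list(c("Europe", "China", "Sumatra")))
  # compare total tree length, the stable summary across topologies
  true_total <- sum(ape::unroot(tr)$edge.length)
  post_total <- mean(vapply(fit$trees,
                            function(t) sum(t$edge.length), 0))
  expect_lt(abs(post_total - true_total) / true_total, 0.25)
})
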