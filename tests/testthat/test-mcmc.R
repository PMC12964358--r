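mcmc_fixture <- function(n = 3, S = 1, depth = 100, seed = 50, G = 51) {
  set.seed(seed)
  gt <- simulate_fscrp(n, num_samples = S)
  tab <- emit_reads(gt, depth = depth)
  cfg <- model_config(grid_size = G, density = "binomial")
  gl <- compute_grid_likelihood(tab, G, "binomial")
  list(tab = tab, gl = gl, cfg = cfg, bl = make_blocks(gl), gt = gt)
}

test_that("single-mutation data always yield the single-node tree", {
  fx <- mcmc_fixture(1)
  st <- clonetree:::state_new(0L, list(1L))
  set.seed(1)
  for (i in 1:5) {
    st <- particle_gibbs_update(st, fx$bl, fx$cfg, n_particles = 5)
    expect_equal(length(st$parent), 1L)
    expect_equal(st$clusters[[1]], 1L)
  }
})

test_that("the sampler visits the whole enumerable state space", {
  # weak data so no state has negligible posterior mass
  set.seed(2)
  tab <- table_from_prev(matrix(0.5, 3, 1), depth = 2)
  cfg <- model_config(grid_size = 31, density = "binomial")
  gl <- compute_grid_likelihood(tab, 31, "binomial")
  bl <- make_blocks(gl)
  post <- exact_posterior(bl, cfg)
  st <- clonetree:::state_new(0L, list(1:3))
  seen <- character(0)
  set.seed(3)
  for (i in 1:1200) {
    st <- particle_gibbs_update(st, bl, cfg, n_particles = 5)
    st <- prune_regraft_move(st, bl, cfg)
    st <- node_reassignment_move(st, bl, cfg)
    seen <- union(seen, tree_key(clonetree:::state_to_tree(st, bl)))
    if (length(seen) == length(post$keys)) break
  }
  expect_setequal(seen, post$keys)
})

test_that("prune-regraft preserves structure and handles small trees", {
  fx <- mcmc_fixture(5, seed = 51)
  # single-node tree returned unchanged
  st1 <- clonetree:::state_new(0L, list(1:5))
  expect_identical(prune_regraft_move(st1, fx$bl, fx$cfg), st1)
  # node count and cluster contents preserved
  st <- clonetree:::state_new(c(0L, 1L, 1L), list(1:2, 3:4, 5L))
  set.seed(4)
  for (i in 1:10) {
    st2 <- prune_regraft_move(st, fx$bl, fx$cfg)
    expect_equal(length(st2$parent), length(st$parent))
    expect_identical(lapply(st2$clusters, sort), lapply(st$clusters, sort))
    validate_clone_tree(clonetree:::state_to_tree(st2, fx$bl))
    st <- st2
  }
})

test_that("two-node prune-regraft samples attachments by exact joint ratios", {
  fx <- mcmc_fixture(2, seed = 52)
  st <- clonetree:::state_new(c(0L, 0L), list(1L, 2L))
  # candidate targets computed independently per topology
  t_sib <- clonetree:::state_log_target(clonetree:::state_new(c(0L, 0L), list(1L, 2L)), fx$bl, fx$cfg)
  t_chain21 <- clonetree:::state_log_target(clonetree:::state_new(c(0L, 1L), list(1L, 2L)), fx$bl, fx$cfg)
  t_chain12 <- clonetree:::state_log_target(clonetree:::state_new(c(2L, 0L), list(1L, 2L)), fx$bl, fx$cfg)
  set.seed(5)
  n <- 3000
  keys <- replicate(n, tree_key(clonetree:::state_to_tree(
    prune_regraft_move(st, fx$bl, fx$cfg), fx$bl)))
  counts <- table(keys)
  # the move picks one of the two nodes uniformly, then Gibbs over 2 hosts
  p_sib_given1 <- exp(t_sib - logsumexp(c(t_sib, t_chain12)))
  p_sib_given2 <- exp(t_sib - logsumexp(c(t_sib, t_chain21)))
  expected <- c(
    sib = (p_sib_given1 + p_sib_given2) / 2,
    c12 = (1 - p_sib_given1) / 2,
    c21 = (1 - p_sib_given2) / 2
  )
  key_of <- function(pv) tree_key(clonetree:::state_to_tree(
    clonetree:::state_new(pv, list(1L, 2L)), fx$bl))
  lev <- c(key_of(c(0L, 0L)), key_of(c(2L, 0L)), key_of(c(0L, 1L)))
  obs <- as.numeric(table(factor(keys, levels = lev)))
  expect_gt(chisq_gof_p(obs, unname(expected)), 0.001)
})

test_that("node reassignment respects the emptying guard and topology", {
  fx <- mcmc_fixture(4, seed = 53)
  # all singleton nodes: nothing can move
  st <- clonetree:::state_new(c(0L, 1L, 1L, 0L), list(1L, 2L, 3L, 4L))
  set.seed(6)
  st2 <- node_reassignment_move(st, fx$bl, fx$cfg)
  expect_identical(st2$parent, st$parent)
  expect_identical(lapply(st2$clusters, sort), lapply(st$clusters, sort))
  # two fat nodes: contents may change, edges do not
  st <- clonetree:::state_new(c(0L, 1L), list(1:2, 3:4))
  moved <- FALSE
  for (i in 1:30) {
    st2 <- node_reassignment_move(st, fx$bl, fx$cfg)
    expect_identical(st2$parent, st$parent)
    if (!identical(lapply(st2$clusters, sort), lapply(st$clusters, sort)))
      moved <- TRUE
    st <- st2
  }
  expect_true(moved)
})

test_that("trace joints match fresh evaluations; runs are deterministic", {
  fx <- mcmc_fixture(4, S = 2, seed = 54)
  fit <- run_sampler(fx$tab, config = fx$cfg, chains = 2, burnin = 2,
                     iters = 8, particles = 5, seed = 77)
  for (e in fit$trace[seq(1, length(fit$trace), by = 4)]) {
    tr <- clonetree:::state_to_tree(e$state, fx$bl)
    expect_equal(e$joint, joint_log_prob(tr, fx$gl, fx$cfg), tolerance = 1e-9)
  }
  fit2 <- run_sampler(fx$tab, config = fx$cfg, chains = 2, burnin = 2,
                      iters = 8, particles = 5, seed = 77)
  expect_equal(vapply(fit$trace, `[[`, numeric(1), "joint"),
               vapply(fit2$trace, `[[`, numeric(1), "joint"))
  expect_equal(tree_key(fit$map_tree), tree_key(fit2$map_tree))
})

test_that("pre-clustered blocks move together but may share nodes", {
  set.seed(7)
  gt <- simulate_fscrp(8, num_samples = 2, clusters = list(1:4, 5:8))
  tab <- emit_reads(gt, depth = 100)
  cfg <- model_config(grid_size = 31, density = "binomial")
  fit <- run_sampler(tab, preclustering = rep(1:2, each = 4L), config = cfg,
                     chains = 1, burnin = 2, iters = 10, particles = 5,
                     seed = 8)
  for (e in fit$trace) {
    for (cl in e$state$clusters) expect_true(all(cl %in% 1:2))
    tr <- clonetree:::state_to_tree(e$state, fit$blocks)
    for (nodemuts in tr$clusters) {
      # block members never split across nodes
      expect_true(all(table(rep(1:2, each = 4L)[nodemuts]) %in% c(0L, 4L)))
    }
  }
})

test_that("wall-clock budget yields a partial trace with a warning", {
  fx <- mcmc_fixture(6, S = 2, seed = 55)
  expect_warning(
    fit <- run_sampler(fx$tab, config = fx$cfg, chains = 4, burnin = 0,
                       iters = 5000, particles = 10, seed = 9, max_time = 2),
    "budget"
  )
  expect_true(fit$timed_out)
  expect_lt(length(fit$trace), 20000)
})

test_that("moves remain invariant when outlier states are in play", {
  # 2 blocks, outlier modelling on: 7 enumerable states (4 forests, 2
  # single-outlier, 1 all-outlier); PG and reassignment must preserve the
  # exact posterior including the outlier terms
  set.seed(60)
  gt <- simulate_fscrp(6, num_samples = 2, clusters = list(1:3, 4:6))
  tab <- emit_reads(gt, depth = 100)
  cfg <- model_config(grid_size = 31, density = "binomial",
                      outlier_modelling = TRUE, outlier_prob_low = 0.05)
  gl <- compute_grid_likelihood(tab, 31, "binomial")
  nu <- clonetree:::outlier_prior(cfg, 6)
  bl <- make_blocks(gl, rep(1:2, each = 3L), nu)
  states <- list(
    clonetree:::state_new(c(0L, 0L), list(1L, 2L)),
    clonetree:::state_new(c(0L, 1L), list(1L, 2L)),
    clonetree:::state_new(c(2L, 0L), list(1L, 2L)),
    clonetree:::state_new(0L, list(c(1L, 2L))),
    clonetree:::state_new(0L, list(2L), outliers = 1L),
    clonetree:::state_new(0L, list(1L), outliers = 2L),
    clonetree:::state_new(integer(0), list(), outliers = 1:2)
  )
  lps <- vapply(states, clonetree:::state_log_target, numeric(1),
                bl = bl, config = cfg)
  keys <- vapply(states, function(st)
    tree_key(clonetree:::state_to_tree(st, bl)), character(1))
  probs <- exp(lps - logsumexp(lps))
  M <- 3000
  set.seed(61)
  for (mv in list(
    function(st) particle_gibbs_update(st, bl, cfg, n_particles = 8),
    function(st) node_reassignment_move(st, bl, cfg)
  )) {
    idx <- sample.int(length(states), M, replace = TRUE, prob = probs)
    tally <- stats::setNames(numeric(length(keys)), keys)
    for (i in idx) {
      k <- tree_key(clonetree:::state_to_tree(mv(states[[i]]), bl))
      expect_true(k %in% keys)
      tally[k] <- tally[k] + 1
    }
    expect_gt(chisq_gof_p(tally, probs), 0.01)
  }
})
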