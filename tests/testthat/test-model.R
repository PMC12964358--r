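test_that("CRP prior matches closed forms and the seating-sequence oracle", {
  expect_equal(crp_log_prior(list(1L, 2L, 3L), 1), log(1 / 6))
  expect_equal(crp_log_prior(list(1:3), 1), log(1 / 3))
  expect_equal(crp_log_prior(list(1L), 2.7), 0)
  expect_error(crp_log_prior(c(2L, 0L), 1), "empty cluster")

  # oracle: enumerate all 27 seating sequences of 3 customers, alpha = 1.5
  alpha <- 1.5
  seat_prob <- function(seats) {
    # seats: vector of table index chosen by each customer (1-based, new = max+1)
    p <- 1
    counts <- integer(0)
    for (i in seq_along(seats)) {
      k <- seats[i]
      denom <- alpha + i - 1
      if (k > length(counts)) {
        p <- p * alpha / denom
        counts <- c(counts, 1L)
      } else {
        p <- p * counts[k] / denom
        counts[k] <- counts[k] + 1L
      }
    }
    list(p = p, key = paste(sort(table(seats)), collapse = ","))
  }
  seqs <- expand.grid(1, 1:2, 1:3)
  tot <- list()
  for (r in seq_len(nrow(seqs))) {
    s <- as.integer(seqs[r, ])
    if (s[3] > max(s[1:2]) + 1) next
    res <- seat_prob(s)
    prev <- if (is.null(tot[[res$key]])) 0 else tot[[res$key]]
    tot[[res$key]] <- prev + res$p
  }
  # partition {1,2,3} all together has size key "3"
  expect_equal(crp_log_prior(list(1:3), alpha), log(tot[["3"]]),
               tolerance = 1e-12)
  expect_equal(crp_log_prior(list(1L, 2L, 3L), alpha), log(tot[["1,1,1"]]),
               tolerance = 1e-12)
})

test_that("CRP prior is normalized over all partitions (n <= 6)", {
  for (alpha in c(0.5, 1, 2)) {
    for (n in c(3L, 6L)) {
      parts <- all_partitions(n)
      total <- sum(vapply(parts, function(p) exp(crp_log_prior(p, alpha)),
                          numeric(1)))
      expect_equal(total, 1, tolerance = 1e-10)
    }
  }
})

test_that("forest prior matches exhaustive enumeration for K <= 4", {
  for (K in 1:4) {
    n_forests <- length(all_forest_parents(K))
    expect_equal(n_forests, (K + 1)^(K - 1))
    expect_equal(forest_log_prior(K), -log(n_forests))
  }
  expect_error(forest_log_prior(0), "at least one")
})

test_that("DP marginal equals brute-force simplex quadrature", {
  set.seed(5)
  gt <- simulate_fscrp(3, num_samples = 2)
  tab <- emit_reads(gt, depth = 100)
  gl <- compute_grid_likelihood(tab, 31, "binomial")
  for (kappa in c(1, 2)) {
    cfg <- model_config(grid_size = 31, density = "binomial", kappa = kappa)
    for (cl in list(list(1:3), list(1:2, 3L), list(1L, 2L, 3L))) {
      for (pv in all_forest_parents(length(cl))) {
        tr <- clone_tree(pv, cl)
        expect_equal(marginal_loglik(tr, gl, cfg), brute_marginal(tr, gl, kappa),
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("one-node marginal reduces to the uniform outlier marginal", {
  set.seed(6)
  tab <- table_from_prev(matrix(c(0.4, 0.9), 1, 2), depth = 80)
  gl <- compute_grid_likelihood(tab, 101, "binomial")
  cfg <- model_config(grid_size = 101, density = "binomial")
  m <- marginal_loglik(clone_tree(0L, list(1L)), gl, cfg)
  o <- sum(vapply(1:2, function(s)
    outlier_marginal_loglik(gl$loglik[1, s, ], gl$grid), numeric(1)))
  expect_equal(m, o, tolerance = 1e-9)
})

test_that("data-free trees have zero marginal and invariant relabelling", {
  set.seed(7)
  tab <- table_from_prev(matrix(0.5, 4, 2), depth = 10)
  gl <- compute_grid_likelihood(tab, 41, "binomial")
  gl$loglik[] <- 0
  cfg <- model_config(grid_size = 41, density = "binomial")
  for (pv in list(c(0L, 0L), c(0L, 1L))) {
    expect_equal(marginal_loglik(clone_tree(pv, list(1:2, 3:4)), gl, cfg), 0,
                 tolerance = 1e-10)
  }
})

test_that("marginal is invariant to node relabelling and mutation order", {
  set.seed(8)
  gt <- simulate_fscrp(4, num_samples = 2)
  tab <- emit_reads(gt, depth = 100)
  gl <- compute_grid_likelihood(tab, 51, "binomial")
  cfg <- model_config(grid_size = 51, density = "binomial")
  a <- marginal_loglik(clone_tree(c(0L, 1L), list(1:2, 3:4)), gl, cfg)
  b <- marginal_loglik(clone_tree(c(2L, 0L), list(3:4, 1:2)), gl, cfg)
  c_ <- marginal_loglik(clone_tree(c(0L, 1L), list(2:1, c(4L, 3L))), gl, cfg)
  expect_equal(a, b, tolerance = 1e-12)
  expect_equal(a, c_, tolerance = 1e-12)
})

test_that("joint log probability composes its terms", {
  set.seed(9)
  gt <- simulate_fscrp(3, num_samples = 1)
  tab <- emit_reads(gt, depth = 100)
  gl <- compute_grid_likelihood(tab, 31, "binomial")
  cfg <- model_config(grid_size = 31, density = "binomial")
  tr <- clone_tree(c(0L, 1L), list(1:2, 3L))
  # no outliers, nu = 0: reduces to prior + marginal (independent recomputation)
  expect_equal(joint_log_prob(tr, gl, cfg),
               crp_log_prior(list(1:2, 3L), 1) + forest_log_prior(2) +
                 brute_marginal(tr, gl, 1),
               tolerance = 1e-9)
  # all mutations outliers: only nu terms and uniform marginals remain
  cfg2 <- model_config(grid_size = 31, density = "binomial",
                       outlier_modelling = TRUE)
  tro <- clone_tree(integer(0), list(), outliers = 1:3)
  nu <- rep(cfg2$outlier_prob_low, 3)
  om <- vapply(1:3, function(n)
    outlier_marginal_loglik(gl$loglik[n, 1, ], gl$grid), numeric(1))
  expect_equal(joint_log_prob(tro, gl, cfg2), sum(log(nu)) + sum(om),
               tolerance = 1e-9)
  # nu = 0 with outliers present gives -Inf
  expect_equal(joint_log_prob(tro, gl, cfg), -Inf)
})

test_that("prevalence reinstatement: MAP accuracy, determinism, invariants", {
  set.seed(10)
  # single node, VAF 0.25 at depth 1000 -> cellular prevalence near 0.5
  tab <- as_snv_table(data.frame(
    mutation_id = "m1", sample_id = "S1", ref_counts = 750L, alt_counts = 250L,
    major_cn = 1L, minor_cn = 1L, normal_cn = 2L, tumour_content = 1,
    error_rate = 0.001
  ))
  gl <- compute_grid_likelihood(tab, 101, "binomial")
  cfg <- model_config(grid_size = 101, density = "binomial")
  tr <- clone_tree(0L, list(1L))
  pm <- reinstate_prevalences(tr, gl, cfg, mode = "map")
  # grid argmax oracle
  oracle <- gl$grid[which.max(gl$loglik[1, 1, ])]
  expect_equal(pm$cellular["1", 1], oracle)
  expect_lt(abs(pm$cellular["1", 1] - 0.5), 1.5 / 100)
  # deterministic
  expect_identical(pm, reinstate_prevalences(tr, gl, cfg, mode = "map"))

  # invariants on a deeper tree
  set.seed(11)
  gt <- simulate_fscrp(6, num_samples = 3)
  tab <- emit_reads(gt, depth = 300)
  gl <- compute_grid_likelihood(tab, 51, "binomial")
  cfg <- model_config(grid_size = 51, density = "binomial")
  pm <- reinstate_prevalences(gt$tree, gl, cfg, mode = "sample", seed = 4)
  expect_equal(colSums(pm$clonal), rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(pm$cellular["root", ], rep(1, 3), tolerance = 1e-12,
               ignore_attr = TRUE)
  ch <- clonetree:::tree_children(gt$tree$parent)
  for (v in 0:length(gt$tree$parent)) {
    kids <- ch[[v + 1L]]
    expect_equal(pm$cellular[v + 1L, ],
                 pm$clonal[v + 1L, ] + colSums(pm$cellular[kids + 1L, , drop = FALSE]),
                 tolerance = 1e-12)
  }
})

test_that("data-free sampling of prevalences is Dirichlet-uniform", {
  tab <- table_from_prev(matrix(0.5, 2, 1), depth = 10)
  gl <- compute_grid_likelihood(tab, 51, "binomial")
  gl$loglik[] <- 0
  cfg <- model_config(grid_size = 51, density = "binomial")
  tr <- clone_tree(c(0L, 0L), list(1L, 2L))
  set.seed(12)
  draws <- suppressMessages(replicate(3000, {
    pm <- reinstate_prevalences(tr, gl, cfg, mode = "sample", seed = NULL)
    pm$clonal[, 1]
  }))
  # flat Dirichlet over |V| = 3 coordinates: mean 1/3 each, up to grid
  # discretization bias O(1/G) and Monte Carlo noise
  expect_equal(rowMeans(draws), rep(1 / 3, 3), tolerance = 0.05,
               ignore_attr = TRUE)
})

test_that("kappa below one is rejected for grid marginalization", {
  expect_error(model_config(kappa = 0.5), "kappa")
})
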