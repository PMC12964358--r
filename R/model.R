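# Collapsed tree model: CRP + uniform-forest prior, and the grid
# dynamic-programming marginalization of clonal prevalences over the tree.

#' Model configuration
#'
#' @param alpha CRP concentration (> 0); controls the prior number of
#'   clusters.
#' @param kappa symmetric Dirichlet parameter on clonal prevalences (>= 1 on
#'   the grid; 1 is uniform on the simplex).
#' @param outlier_prob_low,outlier_prob_high prior outlier probability tiers:
#'   mutations flagged as residing in deletable regions get the high tier.
#' @param outlier_modelling enable the outlier state (off: all nu = 0).
#' @param grid_size prevalence grid size G.
#' @param density emission density kind.
#' @param precision beta-binomial precision.
#' @param prop_new_node SMC proposal probability of the "create new node"
#'   branch.
#' @return object of class `model_config`.
#' @export
model_config <- function(alpha = 1.0, kappa = 1.0,
                         outlier_prob_low = 1e-4, outlier_prob_high = 0.4,
                         outlier_modelling = FALSE,
                         grid_size = 101L,
                         density = c("beta-binomial", "binomial"),
                         precision = 400,
                         prop_new_node = 0.5) {
  density <- match.arg(density)
  if (alpha <= 0) stop_validation("alpha must be > 0")
  if (kappa < 1) stop_validation("grid marginalization requires kappa >= 1")
  structure(
    list(alpha = alpha, kappa = kappa,
         outlier_prob_low = outlier_prob_low,
         outlier_prob_high = outlier_prob_high,
         outlier_modelling = outlier_modelling,
         grid_size = as.integer(grid_size), density = density,
         precision = precision, prop_new_node = prop_new_node),
    class = "model_config"
  )
}

# per-mutation prior outlier probabilities nu_n
outlier_prior <- function(config, n_mutations, loss_flags = NULL) {
  if (!config$outlier_modelling) return(rep(0, n_mutations))
  flags <- loss_flags %||% rep(FALSE, n_mutations)
  ifelse(flags, config$outlier_prob_high, config$outlier_prob_low)
}

#' CRP log prior of a partition
#'
#' Exchangeable partition probability of the Chinese restaurant process:
#' `alpha^K * prod_b (|b|-1)! / prod_{i=0}^{n-1} (alpha + i)`.
#'
#' @param clusters partition as a list of item vectors, or an integer vector
#'   of cluster sizes.
#' @param alpha concentration parameter (> 0).
#' @return log prior probability.
#' @export
crp_log_prior <- function(clusters, alpha) {
  if (alpha <= 0) stop_validation("alpha must be > 0")
  sizes <- if (is.list(clusters)) vapply(clusters, length, 1L) else as.integer(clusters)
  n <- sum(sizes)
  if (n == 0L) return(0)
  if (any(sizes == 0L)) stop_validation("empty cluster in partition")
  K <- length(sizes)
  K * log(alpha) + sum(lgamma(sizes)) - (lgamma(alpha + n) - lgamma(alpha))
}

#' Uniform rooted-forest log prior
#'
#' The number of rooted labelled forests on K nodes is (K+1)^(K-1) (they
#' biject with labelled trees on K+1 vertices rooted at the extra vertex), so
#' the uniform prior contributes -(K-1) log(K+1).
#'
#' @param num_nodes number of non-root nodes K (>= 1).
#' @return log prior probability.
#' @export
forest_log_prior <- function(num_nodes) {
  K <- as.integer(num_nodes)
  if (K < 1) stop_validation("forest prior needs at least one node")
  -(K - 1) * log(K + 1)
}

# log prior weight vector of one clonal-mass coordinate on the grid. The
# simplex integral is iterated over the K free node coordinates (the dummy
# root's mass is the dependent one): free coordinates carry a trapezoid
# quadrature weight (half at the boundary cells) times the Dirichlet factor
# rho_i^(kappa-1); the root coordinate carries the Dirichlet factor only.
# The composition sum is self-normalized by its data-free value, so a
# one-node marginal reduces exactly to the trapezoidal uniform marginal and a
# data-free tree scores exactly 0.
prior_wlog <- function(grid_size, kappa, root = FALSE) {
  h <- 1 / (grid_size - 1)
  w <- if (root) rep(0, grid_size)
    else log(h) + c(log(0.5), rep(0, grid_size - 2L), log(0.5))
  if (kappa > 1) {
    w <- w + (kappa - 1) * log(prevalence_grid(grid_size))
    w[1L] <- -Inf  # zero clonal mass carries no Dirichlet weight for kappa > 1
  }
  w
}

.ct_cache <- new.env(parent = emptyenv())

# log normalizing constant of the discrete prior over grid compositions of
# total mass 1 into d parts: log sum over compositions of prod rho_v^(kappa-1)
log_norm_const <- function(d, grid_size, kappa) {
  key <- sprintf("Z_%d_%g", grid_size, kappa)
  zs <- .ct_cache[[key]] %||% numeric(0)
  if (length(zs) < d) {
    w <- matrix(prior_wlog(grid_size, kappa), ncol = 1L)
    acc <- if (length(zs) == 0L) NULL else .ct_cache[[paste0(key, "_acc")]]
    if (is.null(acc)) {
      acc <- matrix(prior_wlog(grid_size, kappa, root = TRUE), ncol = 1L)
      zs <- acc[grid_size, 1L]
    }
    while (length(zs) < d) {
      acc <- conv_log(acc, w)
      zs <- c(zs, acc[grid_size, 1L])
    }
    .ct_cache[[key]] <- zs
    .ct_cache[[paste0(key, "_acc")]] <- acc
  }
  zs[d]
}

# G x S matrix of per-node data log-likelihood: sum of member mutations' grid
# rows. items indexes mutations (or blocks, when gl rows are block-level).
node_data_matrix <- function(gl, items, grid_size) {
  S <- length(gl$samples)
  D <- matrix(0, grid_size, S)
  for (n in items)
    D <- D + t(array(gl$loglik[n, , , drop = FALSE], c(S, grid_size)))
  D
}

# Bottom-up message passing over a parent vector. D: list of G x S data
# matrices per node. Returns messages M (subtree mass distributions), the
# children lists and per-node prefix convolution chains (for backtracking).
dp_messages <- function(parent, D, wm, wm_root, max_mode = FALSE,
                        keep_prefix = FALSE) {
  K <- length(parent)
  ch <- tree_children(parent)
  M <- vector("list", K)
  prefix <- if (keep_prefix) vector("list", K + 1L) else NULL
  for (v in tree_postorder(parent)) {
    kids <- ch[[v + 1L]]
    if (keep_prefix) {
      pf <- vector("list", length(kids) + 1L)
      pf[[1L]] <- wm
      for (j in seq_along(kids))
        pf[[j + 1L]] <- conv_log(pf[[j]], M[[kids[j]]], max_mode)
      prefix[[v + 1L]] <- pf
      cw <- pf[[length(pf)]]
    } else {
      cw <- fold_conv_log(c(list(wm), M[kids]), max_mode)
    }
    M[[v]] <- D[[v]] + cw
  }
  root_kids <- ch[[1L]]
  if (keep_prefix) {
    pf <- vector("list", length(root_kids) + 1L)
    pf[[1L]] <- wm_root
    for (j in seq_along(root_kids))
      pf[[j + 1L]] <- conv_log(pf[[j]], M[[root_kids[j]]], max_mode)
    prefix[[1L]] <- pf
    total <- pf[[length(pf)]]
  } else {
    total <- fold_conv_log(c(list(wm_root), M[root_kids]), max_mode)
  }
  list(M = M, total = total, children = ch, prefix = prefix)
}

# core collapsed marginal for a parent vector + data matrices (per sample sum)
dp_marginal <- function(parent, D, config) {
  K <- length(parent)
  if (K == 0L) return(0)
  G <- config$grid_size
  S <- ncol(D[[1L]])
  wm <- matrix(prior_wlog(G, config$kappa), G, S)
  wm_root <- matrix(prior_wlog(G, config$kappa, root = TRUE), G, S)
  res <- dp_messages(parent, D, wm, wm_root)
  sum(res$total[G, ]) - S * log_norm_const(K + 1L, G, config$kappa)
}

#' Collapsed marginal log-likelihood of a clone tree
#'
#' Grid approximation to the integral over the clonal-prevalence simplex of
#' the emission likelihood weighted by the symmetric Dirichlet prior, computed
#' per sample by bottom-up dynamic programming over the tree and summed over
#' samples. Messages over total subtree (cellular) mass are combined by
#' truncated grid convolution; the dummy root carries clonal mass but no data;
#' the discrete prior over grid compositions is self-normalized, so a data-free
#' tree yields exactly 0.
#'
#' @param tree a `clone_tree` (outlier mutations are ignored here; see
#'   [joint_log_prob()]).
#' @param gl a `grid_likelihood` covering all non-outlier mutations.
#' @param config a `model_config`.
#' @return scalar log marginal likelihood.
#' @export
marginal_loglik <- function(tree, gl, config = model_config()) {
  G <- length(gl$grid)
  D <- lapply(tree$clusters, function(it) node_data_matrix(gl, it, G))
  cfg <- config
  cfg$grid_size <- G
  dp_marginal(tree$parent, D, cfg)
}

#' Collapsed joint log probability of a clone tree with outliers
#'
#' Sum of the CRP prior over the non-outlier partition, the uniform rooted
#' forest prior, the marginalized tree likelihood, and the outlier terms: each
#' outlier mutation contributes `log(nu_n)` plus its uniform-prevalence
#' emission marginal, each non-outlier contributes `log(1 - nu_n)`.
#'
#' @inheritParams marginal_loglik
#' @param loss_flags optional logical vector marking mutations in deletable
#'   regions (receive the high outlier-prior tier).
#' @param nu optional explicit per-mutation outlier prior (overrides flags).
#' @return scalar log joint probability (may be -Inf).
#' @export
joint_log_prob <- function(tree, gl, config = model_config(),
                           loss_flags = NULL, nu = NULL) {
  n <- tree$n_mutations
  nu <- nu %||% outlier_prior(config, n, loss_flags)
  out <- tree$outliers
  K <- length(tree$parent)
  lp <- 0
  if (length(out) > 0) {
    om <- outlier_marginals(gl)
    lp <- lp + sum(log(nu[out])) + sum(om[out])
  }
  non_out <- setdiff(seq_len(n), out)
  lp <- lp + sum(log1p(-nu[non_out]))
  if (K > 0) {
    lp <- lp + crp_log_prior(tree$clusters, config$alpha) +
      forest_log_prior(K) + marginal_loglik(tree, gl, config)
  }
  lp
}

#' Reinstate clonal and cellular prevalences for a fixed tree
#'
#' Clonal prevalences are marginalized during tree inference; this recovers
#' them afterwards by a backward pass through the stored dynamic-programming
#' messages: either the exact grid MAP configuration (max-product messages and
#' argmax backtracking) or a draw from the conditional distribution
#' (sum-product messages and stochastic backtracking). Runs per sample.
#'
#' @inheritParams marginal_loglik
#' @param mode `"map"` or `"sample"`.
#' @param seed RNG seed for `mode = "sample"`; if omitted the global RNG
#'   stream is used (a message notes this).
#' @return object of class `prevalence_matrix`: list with `clonal` and
#'   `cellular`, (K+1) x S matrices with the dummy root in row "root". Per
#'   sample, clonal entries sum to 1 (root included) and
#'   `cellular[v] = clonal[v] + sum(cellular[children])`, exactly on the grid.
#' @export
reinstate_prevalences <- function(tree, gl, config = model_config(),
                                  mode = c("map", "sample"), seed = NULL) {
  mode <- match.arg(mode)
  K <- length(tree$parent)
  if (K < 1) stop_validation("tree must have at least one non-root node")
  if (mode == "sample") {
    if (!is.null(seed)) set.seed(seed)
    else message("reinstate_prevalences: sampling with the global RNG stream")
  }
  G <- length(gl$grid)
  S <- length(gl$samples)
  max_mode <- mode == "map"
  D <- lapply(tree$clusters, function(it) node_data_matrix(gl, it, G))
  wm <- matrix(prior_wlog(G, config$kappa), G, S)
  wm_root <- matrix(prior_wlog(G, config$kappa, root = TRUE), G, S)
  res <- dp_messages(tree$parent, D, wm, wm_root, max_mode = max_mode,
                     keep_prefix = TRUE)
  clonal <- matrix(0, K + 1L, S,
                   dimnames = list(c("root", seq_len(K)), gl$samples))
  cellular <- clonal
  pick <- function(lw) {
    if (max_mode) which.max(lw) else {
      p <- exp(lw - logsumexp(lw))
      sample.int(length(lw), 1L, prob = p)
    }
  }
  for (s in seq_len(S)) {
    alloc <- function(v, kidx) {
      # kidx: 1-based grid index of the subtree's total (cellular) mass
      cellular[v + 1L, s] <<- gl$grid[kidx]
      kids <- res$children[[v + 1L]]
      pf <- res$prefix[[v + 1L]]
      rem <- kidx
      for (j in rev(seq_along(kids))) {
        Mj <- res$M[[kids[j]]][, s]
        lw <- pf[[j]][seq_len(rem), s] + Mj[rem - seq_len(rem) + 1L]
        i <- pick(lw)
        alloc(kids[j], rem - i + 1L)
        rem <- i
      }
      clonal[v + 1L, s] <<- gl$grid[rem]
    }
    alloc(0L, G)
  }
  structure(list(clonal = clonal, cellular = cellular, grid = gl$grid),
            class = "prevalence_matrix")
}
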