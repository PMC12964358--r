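# Particle Gibbs and auxiliary MCMC moves over (T, b, o), and the top-level
# sampler loop.

#' One particle Gibbs update of the tree state
#'
#' Samples a data ordering sigma uniformly among orderings consistent with the
#' current state, rebuilds the current state as the retained reference
#' trajectory of a conditional SMC sweep under sigma, and draws the new state
#' from the final particle weights. With a single particle the update returns
#' the reference state unchanged.
#'
#' @param st block-level state.
#' @param bl block data from [make_blocks()].
#' @param config a `model_config`.
#' @param n_particles particles in the conditional sweep.
#' @return new block-level state.
#' @export
particle_gibbs_update <- function(st, bl, config, n_particles = 20L) {
  sigma <- sample_permutation(st)
  choices <- reference_choices(st, sigma)
  sw <- smc_sweep(sigma, bl, config, n_particles = n_particles,
                  ref_choices = choices)
  W <- softmax_log(sw$logw)
  i <- sample.int(length(W), 1L, prob = W)
  particle_to_state(sw$particles[[i]], bl)
}

# all-candidate Gibbs helper: returns index sampled proportionally to
# exp(log target) over candidate states
gibbs_pick <- function(targets) {
  sample.int(length(targets), 1L, prob = softmax_log(targets))
}

#' Subtree prune-regraft move
#'
#' Uniformly selects a non-root node, detaches its subtree, and Gibbs-samples
#' the reattachment point among all remaining nodes (including the dummy
#' root) proportionally to the collapsed joint. Node count and cluster
#' contents are preserved; single-node trees are returned unchanged.
#'
#' @inheritParams particle_gibbs_update
#' @return new block-level state.
#' @export
prune_regraft_move <- function(st, bl, config) {
  K <- length(st$parent)
  if (K < 2L) return(st)
  v <- sample.int(K, 1L)
  sub <- tree_subtree(st$parent, v)
  hosts <- c(0L, setdiff(seq_len(K), sub))
  cand <- lapply(hosts, function(h) {
    st2 <- st
    st2$parent[v] <- h
    st2
  })
  targets <- vapply(cand, state_log_target, numeric(1), bl = bl, config = config)
  cand[[gibbs_pick(targets)]]
}

#' Node reassignment move
#'
#' Visits blocks in a freshly shuffled order; each block whose removal would
#' not empty its node (outlier blocks always qualify) is Gibbs-reassigned
#' among all nodes of the fixed topology, plus the outlier state when outlier
#' modelling is enabled. Edges never change; cluster contents may.
#'
#' @inheritParams particle_gibbs_update
#' @return new block-level state.
#' @export
node_reassignment_move <- function(st, bl, config) {
  K <- length(st$parent)
  if (K == 0L) return(st)
  node_of <- integer(bl$B)
  for (v in seq_len(K)) node_of[st$clusters[[v]]] <- v
  for (b in safe_sample(seq_len(bl$B))) {
    v0 <- node_of[b]
    if (v0 != 0L && length(st$clusters[[v0]]) == 1L) next  # emptying guard
    cand_nodes <- seq_len(K)
    cand <- lapply(cand_nodes, function(v) {
      st2 <- st
      if (v0 != 0L) st2$clusters[[v0]] <- setdiff(st2$clusters[[v0]], b)
      else st2$outliers <- setdiff(st2$outliers, b)
      st2$clusters[[v]] <- c(st2$clusters[[v]], b)
      st2
    })
    if (config$outlier_modelling) {
      st2 <- st
      if (v0 != 0L) st2$clusters[[v0]] <- setdiff(st2$clusters[[v0]], b)
      st2$outliers <- sort(unique(c(st2$outliers, b)))
      cand <- c(cand, list(st2))
    }
    targets <- vapply(cand, state_log_target, numeric(1), bl = bl, config = config)
    k <- gibbs_pick(targets)
    st <- cand[[k]]
    node_of[b] <- if (k <= K) cand_nodes[k] else 0L
  }
  st
}

#' Run the full posterior sampler
#'
#' Per chain: starts from the single-node tree holding every block, then each
#' iteration interleaves one particle Gibbs update, one subtree prune-regraft
#' and one node-reassignment scan. Pre-clustered mutations move as blocks but
#' blocks may co-occupy a node. Returns the pooled post-burn-in trace and the
#' tree maximizing the joint log probability.
#'
#' @param table an `snv_table`.
#' @param preclustering optional named cluster assignment (mutation_id ->
#'   cluster index) from [read_preclustering()], or an integer vector in table
#'   mutation order.
#' @param config a `model_config`.
#' @param chains,burnin,iters,particles run parameters (defaults follow the
#'   reference protocol: 4 chains, 100 burn-in, 5000 iterations, 100
#'   particles).
#' @param seed integer seed; chain c uses seed + c - 1.
#' @param loss_flags logical per mutation: TRUE marks deletable-region
#'   mutations (high outlier-prior tier).
#' @param max_time wall-clock budget in seconds; exceeded -> partial trace
#'   with a warning.
#' @param thin keep every `thin`-th iteration in the trace.
#' @return object of class `clonetree_fit`: list with `trace` (entries:
#'   chain, iter, joint, state), `map_tree`, `map_joint`, `config`, `seed`,
#'   `mutations`, `blocks`.
#' @export
run_sampler <- function(table, preclustering = NULL, config = model_config(),
                        chains = 4L, burnin = 100L, iters = 5000L,
                        particles = 100L, seed = 1L, loss_flags = NULL,
                        max_time = Inf, thin = 1L) {
  gl <- compute_grid_likelihood(table, config$grid_size, config$density,
                                config$precision)
  muts <- attr(table, "mutations")
  assignment <- if (is.null(preclustering)) NULL
    else if (!is.null(names(preclustering))) unname(preclustering[muts])
    else preclustering
  nu <- outlier_prior(config, length(muts), loss_flags)
  bl <- make_blocks(gl, assignment, nu)
  t0 <- Sys.time()
  trace <- list()
  map_joint <- -Inf
  map_state <- NULL
  timed_out <- FALSE
  for (chain in seq_len(chains)) {
    set.seed(seed + chain - 1L)
    st <- state_new(0L, list(seq_len(bl$B)))
    for (iter in seq_len(burnin + iters)) {
      st <- particle_gibbs_update(st, bl, config, n_particles = particles)
      st <- prune_regraft_move(st, bl, config)
      st <- node_reassignment_move(st, bl, config)
      if (iter > burnin && (iter - burnin) %% thin == 0L) {
        j <- state_log_target(st, bl, config)
        trace[[length(trace) + 1L]] <-
          list(chain = chain, iter = iter - burnin, joint = j, state = st)
        if (j > map_joint) {
          map_joint <- j
          map_state <- st
        }
      }
      if (difftime(Sys.time(), t0, units = "secs") > max_time) {
        warning("wall-clock budget exceeded; returning partial trace")
        timed_out <- TRUE
        break
      }
    }
    if (timed_out) break
  }
  structure(
    list(trace = trace, map_tree = state_to_tree(map_state, bl),
         map_state = map_state, map_joint = map_joint, config = config,
         seed = seed, mutations = muts, blocks = bl, gl = gl,
         timed_out = timed_out),
    class = "clonetree_fit"
  )
}

#' @export
print.clonetree_fit <- function(x, ...) {
  cat(sprintf("clonetree_fit: %d trace samples, MAP joint log prob %.3f\n",
              length(x$trace), x$map_joint))
  print(x$map_tree)
  invisible(x)
}
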