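# Independent oracles used across test files: exhaustive enumeration of
# partitions, rooted forests and tree states, and brute-force simplex
# quadrature for the collapsed marginal. These deliberately avoid the
# package's DP/SMC code paths.

all_partitions <- function(n) {
  if (n == 1L) return(list(list(1L)))
  out <- list()
  for (p in all_partitions(n - 1L)) {
    for (k in seq_along(p)) {
      q <- p
      q[[k]] <- c(q[[k]], n)
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(n))
  }
  out
}

# all acyclic parent vectors over K labelled nodes (0 = dummy root)
all_forest_parents <- function(K) {
  if (K == 0L) return(list(integer(0)))
  grids <- do.call(expand.grid, rep(list(0:K), K))
  res <- list()
  for (r in seq_len(nrow(grids))) {
    pv <- as.integer(grids[r, ])
    ok <- TRUE
    for (v in seq_len(K)) {
      u <- v
      steps <- 0L
      while (u != 0L && ok) {
        u <- pv[u]
        steps <- steps + 1L
        if (steps > K) ok <- FALSE
      }
    }
    if (ok) res[[length(res) + 1L]] <- pv
  }
  res
}

# all block-level states (partition x forest, no outliers) over B blocks
enumerate_states <- function(B) {
  out <- list()
  for (part in all_partitions(B)) {
    for (pv in all_forest_parents(length(part))) {
      out[[length(out) + 1L]] <- clonetree:::state_new(pv, part)
    }
  }
  out
}

# brute-force simplex quadrature for the collapsed marginal: enumerate all
# grid compositions of total mass one, apply the same coordinate weights the
# package defines, and sum directly (no message passing)
brute_marginal <- function(tree, gl, kappa = 1) {
  G <- length(gl$grid)
  K <- length(tree$parent)
  idx <- as.matrix(do.call(expand.grid, rep(list(0:(G - 1L)), K)))
  last <- (G - 1L) - rowSums(idx)
  keep <- last >= 0L
  comp <- cbind(idx[keep, , drop = FALSE], last[keep])
  wnode <- clonetree:::prior_wlog(G, kappa)
  wroot <- clonetree:::prior_wlog(G, kappa, root = TRUE)
  w <- rowSums(matrix(wnode[comp[, seq_len(K), drop = FALSE] + 1L],
                      nrow(comp), K)) + wroot[comp[, K + 1L] + 1L]
  out <- 0
  for (s in seq_along(gl$samples)) {
    tot <- w
    for (v in seq_len(K)) {
      sub <- clonetree:::tree_subtree(tree$parent, v)
      cell_idx <- rowSums(comp[, sub, drop = FALSE]) + 1L
      D <- numeric(G)
      for (n in tree$clusters[[v]]) D <- D + gl$loglik[n, s, ]
      tot <- tot + D[cell_idx]
    }
    out <- out + logsumexp(tot) - logsumexp(w)
  }
  out
}

# quick synthetic table: n mutations at given per-mutation-per-sample
# cellular prevalences (matrix n x S), diploid het, depth d
table_from_prev <- function(prev, depth = 100L, tumour_content = 1) {
  n <- nrow(prev)
  S <- ncol(prev)
  rows <- expand.grid(s = seq_len(S), n = seq_len(n))
  xi <- expected_vaf(prev[cbind(rows$n, rows$s)], tumour_content, 2L, 1L)
  alt <- rbinom(nrow(rows), depth, xi)
  as_snv_table(data.frame(
    mutation_id = paste0("m", rows$n), sample_id = paste0("S", rows$s),
    ref_counts = depth - alt, alt_counts = alt,
    major_cn = 1L, minor_cn = 1L, normal_cn = 2L,
    tumour_content = tumour_content, error_rate = 0.001
  ))
}

# exact posterior over enumerable states for a block structure
exact_posterior <- function(bl, cfg) {
  states <- enumerate_states(bl$B)
  lps <- vapply(states, clonetree:::state_log_target, numeric(1),
                bl = bl, config = cfg)
  keys <- vapply(states, function(st)
    tree_key(clonetree:::state_to_tree(st, bl)), character(1))
  probs <- exp(lps - logsumexp(lps))
  list(states = states, lps = lps, keys = keys, probs = probs)
}

# chi-square goodness-of-fit with low-count lumping
chisq_gof_p <- function(counts, probs, min_exp = 5) {
  n <- sum(counts)
  exp_counts <- probs * n
  ord <- order(-exp_counts)
  counts <- counts[ord]
  exp_counts <- exp_counts[ord]
  keep <- exp_counts >= min_exp
  if (sum(!keep) > 0) {
    counts <- c(counts[keep], sum(counts[!keep]))
    exp_counts <- c(exp_counts[keep], sum(exp_counts[!keep]))
  }
  stat <- sum((counts - exp_counts)^2 / exp_counts)
  stats::pchisq(stat, df = length(counts) - 1L, lower.tail = FALSE)
}
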