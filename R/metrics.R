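# Evaluation of inferred trees against ground truth: V-measure,
# ancestor-descendant F-score, log perplexity ratio (VAF reconstruction
# loss), and small-scale relationship reconstruction error.

entropy_counts <- function(n) {
  n <- n[n > 0]
  p <- n / sum(n)
  -sum(p * log(p))
}

#' V-measure clustering accuracy
#'
#' Harmonic mean of homogeneity (1 - H(true|pred)/H(true)) and completeness
#' (1 - H(pred|true)/H(pred)), from the contingency table of the two
#' labelings. Invariant to label permutation on either side.
#'
#' @param true_labels,pred_labels equal-length label vectors.
#' @return value in [0, 1].
#' @export
v_measure <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels))
    stop_validation("label vectors differ in length")
  if (length(true_labels) == 0L) stop_validation("empty labelings")
  tab <- table(true = true_labels, pred = pred_labels)
  n <- sum(tab)
  h_true <- entropy_counts(rowSums(tab))
  h_pred <- entropy_counts(colSums(tab))
  # conditional entropies from the joint
  h_true_given_pred <- sum(vapply(seq_len(ncol(tab)), function(j) {
    cj <- tab[, j]
    if (sum(cj) == 0) 0 else sum(cj) / n * entropy_counts(cj)
  }, numeric(1)))
  h_pred_given_true <- sum(vapply(seq_len(nrow(tab)), function(i) {
    ri <- tab[i, ]
    if (sum(ri) == 0) 0 else sum(ri) / n * entropy_counts(ri)
  }, numeric(1)))
  hom <- if (h_true == 0) 1 else 1 - h_true_given_pred / h_true
  com <- if (h_pred == 0) 1 else 1 - h_pred_given_true / h_pred
  if (hom + com == 0) 0 else 2 * hom * com / (hom + com)
}

# set of ordered (ancestor mutation, descendant mutation) pairs of a tree,
# excluding the given mutations; encoded as a*(N+1)+d integers
ad_pairs <- function(tree, exclude = integer()) {
  N <- tree$n_mutations
  K <- length(tree$parent)
  pairs <- integer(0)
  for (v in seq_len(K)) {
    d_muts <- setdiff(tree$clusters[[v]], exclude)
    if (length(d_muts) == 0L) next
    u <- tree$parent[v]
    anc_muts <- integer(0)
    while (u != 0L) {
      anc_muts <- c(anc_muts, tree$clusters[[u]])
      u <- tree$parent[u]
    }
    anc_muts <- setdiff(anc_muts, exclude)
    if (length(anc_muts) > 0L)
      pairs <- c(pairs, rep(anc_muts, each = length(d_muts)) * (N + 1L) +
                   d_muts)
  }
  pairs
}

#' Ancestor-descendant F-score of a reconstruction
#'
#' Builds the set of ordered mutation pairs (a, d) with a assigned to a proper
#' ancestor node of d's node, in both trees, and reports the F1 of predicted
#' against true pairs. Mutations marked outlier in either tree are dropped
#' from both pair sets before scoring. Empty-set conventions: precision or
#' recall with an empty denominator is 0; if both pair sets are empty the
#' F-score is 1.
#'
#' @param true_tree,pred_tree `clone_tree`s over the same mutations.
#' @return list with `f_score`, `precision`, `recall` and `counts`
#'   (tp/fp/fn/tn over ordered pairs).
#' @export
ad_f_score <- function(true_tree, pred_tree) {
  if (true_tree$n_mutations != pred_tree$n_mutations)
    stop_validation("trees cover different mutation sets")
  N <- true_tree$n_mutations
  exclude <- union(true_tree$outliers, pred_tree$outliers)
  tset <- ad_pairs(true_tree, exclude)
  pset <- ad_pairs(pred_tree, exclude)
  tp <- length(intersect(pset, tset))
  fp <- length(setdiff(pset, tset))
  fn <- length(setdiff(tset, pset))
  m <- N - length(exclude)
  tn <- m * (m - 1L) - tp - fp - fn
  precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
  f <- if (length(tset) == 0L && length(pset) == 0L) 1
    else if (precision + recall == 0) 0
    else 2 * precision * recall / (precision + recall)
  list(f_score = f, precision = precision, recall = recall,
       counts = c(tp = tp, fp = fp, fn = fn, tn = tn))
}

# emission log-likelihood of every table row at a given per-mutation
# per-sample cellular prevalence matrix (N x S, table order)
loglik_at_prevalence <- function(table, prev, density = "binomial",
                                 precision = 400) {
  muts <- attr(table, "mutations")
  samp <- attr(table, "samples")
  mi <- match(table$mutation_id, muts)
  si <- match(table$sample_id, samp)
  out <- numeric(nrow(table))
  for (r in seq_len(nrow(table))) {
    depth <- table$ref_counts[r] + table$alt_counts[r]
    if (depth == 0) next
    st <- genotype_states(table$major_cn[r], table$minor_cn[r], table$normal_cn[r])
    lls <- vapply(seq_len(nrow(st)), function(k) {
      xi <- expected_vaf(prev[mi[r], si[r]], table$tumour_content[r],
                         st$total_cn[k], st$variant_alleles[k], st$normal_cn[k],
                         table$error_rate[r])
      log(st$prior_weight[k]) +
        loglik_counts(table$alt_counts[r], depth, xi, density, precision)
    }, numeric(1))
    out[r] <- logsumexp(lls)
  }
  out
}

#' Log perplexity ratio (VAF reconstruction loss)
#'
#' Difference of the per-mutation-per-sample average negative log emission
#' likelihood under the predicted versus the true cellular prevalences, in
#' nats. Zero when the prediction matches the truth; lower (more negative) is
#' better.
#'
#' @param pred_prev,true_prev N x S per-mutation cellular prevalence matrices
#'   (mutation order of the table).
#' @param table the `snv_table` the likelihood is evaluated on.
#' @param density,precision emission density settings.
#' @return scalar LPR in nats.
#' @export
lpr <- function(pred_prev, table, true_prev, density = "binomial",
                precision = 400) {
  ll_pred <- loglik_at_prevalence(table, pred_prev, density, precision)
  ll_true <- loglik_at_prevalence(table, true_prev, density, precision)
  mean(-ll_pred) - mean(-ll_true)
}

# relation codes between nodes of a parent vector: for ordered node pair
# (i, j): 1 = i ancestor of j, 2 = i descendant of j, 3 = neither, 4 = same
relation_matrix <- function(parent) {
  K <- length(parent)
  anc <- matrix(FALSE, K, K)
  for (v in seq_len(K)) {
    u <- parent[v]
    while (u != 0L) {
      anc[u, v] <- TRUE
      u <- parent[u]
    }
  }
  rel <- matrix(3L, K, K)
  rel[anc] <- 1L
  rel[t(anc)] <- 2L
  diag(rel) <- 4L
  rel
}

# enumerate parent vectors over K clones consistent with the cellular
# prevalence matrix (per sample: parent cellular >= sum of children cellular,
# root children sum <= 1), within tolerance
enumerate_valid_topologies <- function(cellular, tol = 0.01) {
  K <- nrow(cellular)
  ord <- order(-rowMeans(cellular))
  dominates <- function(a, b) all(cellular[a, ] >= cellular[b, ] - tol)
  results <- list()
  parent <- integer(K)
  # child_sum[v+1, s]: accumulated children cellular mass under v (0 = root)
  child_sum <- matrix(0, K + 1L, ncol(cellular))
  budget <- rbind(rep(1, ncol(cellular)), cellular)  # root budget is 1
  recurse <- function(i) {
    if (i > K) {
      results[[length(results) + 1L]] <<- parent
      return(invisible())
    }
    v <- ord[i]
    cands <- c(0L, ord[seq_len(i - 1L)])
    for (p in cands) {
      if (p != 0L && !dominates(p, v)) next
      new_sum <- child_sum[p + 1L, ] + cellular[v, ]
      if (any(new_sum > budget[p + 1L, ] + tol)) next
      old <- child_sum[p + 1L, ]
      child_sum[p + 1L, ] <<- new_sum
      parent[v] <<- p
      recurse(i + 1L)
      child_sum[p + 1L, ] <<- old
    }
  }
  recurse(1L)
  results
}

#' Relationship reconstruction error on small clone sets
#'
#' Exhaustively enumerates all topologies over the true clones whose
#' ancestor-additivity constraints are consistent with the true cellular
#' prevalence matrix, then scores the predicted pairwise mutation relations
#' (ancestor / descendant / branched / same node) against their frequencies
#' over the valid set: the error is the mean over ordered mutation pairs of
#' the fraction of valid topologies whose relation disagrees with the
#' prediction. Restricted to at most `max_nodes` clones; a prevalence matrix
#' violating additivity has an empty valid set and raises an error (the
#' documented failure mode of the metric).
#'
#' @param pred_tree predicted `clone_tree` (its outliers are dropped from the
#'   pair universe).
#' @param true_cellular K x S cellular prevalence matrix of the true clones.
#' @param true_assignment true clone index (1..K) per mutation.
#' @param max_nodes enumeration cap (default 8).
#' @param tol additivity tolerance.
#' @return error in [0, 1].
#' @export
rre_small <- function(pred_tree, true_cellular, true_assignment,
                      max_nodes = 8L, tol = 0.01) {
  K <- nrow(true_cellular)
  if (K > max_nodes)
    stop_validation("RRE enumeration supports at most %d clones (got %d)",
                    max_nodes, K)
  topos <- enumerate_valid_topologies(true_cellular, tol = tol)
  if (length(topos) == 0L)
    stop_validation("no valid topology fits the prevalence matrix (additivity violated)")
  N <- pred_tree$n_mutations
  keep <- setdiff(seq_len(N), pred_tree$outliers)
  pred_node <- integer(N)
  for (v in seq_along(pred_tree$clusters))
    pred_node[pred_tree$clusters[[v]]] <- v
  pred_rel_nodes <- relation_matrix(pred_tree$parent)
  true_rels <- lapply(topos, relation_matrix)
  total <- 0
  npairs <- 0L
  for (a in keep) for (d in keep) {
    if (a == d) next
    pr <- pred_rel_nodes[pred_node[a], pred_node[d]]
    ca <- true_assignment[a]; cd <- true_assignment[d]
    dis <- vapply(true_rels, function(R) R[ca, cd] != pr, logical(1))
    total <- total + mean(dis)
    npairs <- npairs + 1L
  }
  if (npairs == 0L) return(0)
  total / npairs
}

#' Evaluate a reconstruction against ground truth
#'
#' Convenience wrapper computing V-measure (outliers labelled as their own
#' cluster on each side), ancestor-descendant F-score, and optionally LPR
#' (when a table and prevalence matrices are supplied).
#'
#' @param true_tree,pred_tree `clone_tree`s over the same mutations.
#' @param table optional `snv_table` for LPR.
#' @param pred_prev,true_prev optional N x S cellular prevalence matrices for
#'   LPR.
#' @return list with `v_measure`, `ad_f_score`, `counts`, and `lpr` (NA when
#'   not computable).
#' @export
evaluate_reconstruction <- function(true_tree, pred_tree, table = NULL,
                                    pred_prev = NULL, true_prev = NULL) {
  lab_of <- function(tree) {
    lab <- integer(tree$n_mutations)
    for (v in seq_along(tree$clusters)) lab[tree$clusters[[v]]] <- v
    lab[tree$outliers] <- -1L
    lab
  }
  vm <- v_measure(lab_of(true_tree), lab_of(pred_tree))
  ad <- ad_f_score(true_tree, pred_tree)
  lp <- if (!is.null(table) && !is.null(pred_prev) && !is.null(true_prev))
    lpr(pred_prev, table, true_prev) else NA_real_
  list(v_measure = vm, ad_f_score = ad$f_score, counts = ad$counts, lpr = lp)
}
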