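# Synthetic data: clone trees from the forest-CRP or tree-structured
# stick-breaking priors, mutation-loss injection, and multi-sample binomial
# read-count emission with full ground truth.

# cellular prevalence by the bottom-up recursion; clonal is (K+1) x S with the
# dummy root in row 1
cellular_from_clonal <- function(parent, clonal) {
  cellular <- clonal
  for (v in tree_postorder(parent))
    cellular[parent[v] + 1L, ] <- cellular[parent[v] + 1L, ] + cellular[v + 1L, ]
  cellular
}

rdirichlet1 <- function(d, kappa) {
  g <- stats::rgamma(d, shape = kappa)
  g / sum(g)
}

# uniform labelled tree on n vertices via a random Pruefer sequence
random_prufer_parent <- function(n) {
  if (n == 1L) return(integer(0))
  if (n == 2L) return(1L)  # parent of vertex 2 is vertex 1 (the root)
  pr <- sample.int(n, n - 2L, replace = TRUE)
  deg <- tabulate(pr, n) + 1L
  edges <- matrix(0L, n - 1L, 2L)
  used <- logical(n)
  for (i in seq_len(n - 2L)) {
    leaf <- which(deg == 1L & !used)[1L]
    edges[i, ] <- c(leaf, pr[i])
    used[leaf] <- TRUE
    deg[leaf] <- 0L
    deg[pr[i]] <- deg[pr[i]] - 1L
  }
  edges[n - 1L, ] <- which(deg == 1L & !used)
  # orient away from vertex 1 (the dummy root)
  adj <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    a <- edges[i, 1L]; b <- edges[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- integer(n)
  queue <- 1L
  seen <- c(TRUE, rep(FALSE, n - 1L))
  while (length(queue) > 0L) {
    u <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[u]]) if (!seen[w]) {
      seen[w] <- TRUE
      parent[w] <- u
      queue <- c(queue, w)
    }
  }
  parent[-1L]  # parent of vertices 2..n in 1-based vertex labels
}

new_truth <- function(parent, clusters, clonal, samples, chrom) {
  cellular <- cellular_from_clonal(parent, clonal)
  N <- length(unlist(clusters))
  node_of <- integer(N)
  for (v in seq_along(clusters)) node_of[clusters[[v]]] <- v
  mutation_prev <- cellular[node_of + 1L, , drop = FALSE]
  rownames(mutation_prev) <- NULL
  structure(
    list(tree = clone_tree(parent, clusters, n_mutations = N),
         clonal = clonal, cellular = cellular, node_of = node_of,
         mutation_prev = mutation_prev, samples = samples, chrom = chrom,
         lost = integer(0), loss_node = NA_integer_,
         loss_chrom = NA_character_),
    class = "clone_truth"
  )
}

#' Simulate ground truth from the forest-CRP prior
#'
#' Partitions mutations by a Chinese restaurant process, draws a uniformly
#' random rooted forest over the clusters (attached under an empty dummy
#' root), and samples per-sample clonal prevalences from a symmetric Dirichlet
#' over all nodes including the root; cellular prevalences follow by summing
#' up the tree.
#'
#' @param num_snvs number of mutations.
#' @param alpha CRP concentration.
#' @param num_samples number of samples.
#' @param kappa Dirichlet parameter.
#' @param clusters optional fixed partition (list of mutation index vectors)
#'   overriding the CRP draw, e.g. equal-size pre-clusters.
#' @return object of class `clone_truth` with the tree, clonal/cellular
#'   prevalence matrices, per-mutation effective prevalences, and chromosome
#'   labels.
#' @export
simulate_fscrp <- function(num_snvs, alpha = 1.0, num_samples = 1L,
                           kappa = 1.0, clusters = NULL) {
  if (num_snvs < 1) stop_validation("num_snvs must be >= 1")
  if (is.null(clusters)) {
    lab <- integer(num_snvs)
    lab[1L] <- 1L
    K <- 1L
    sizes <- 1L
    for (n in seq_len(num_snvs)[-1L]) {
      p <- c(sizes, alpha)
      k <- sample.int(K + 1L, 1L, prob = p)
      if (k > K) {
        K <- K + 1L
        sizes <- c(sizes, 1L)
      } else sizes[k] <- sizes[k] + 1L
      lab[n] <- k
    }
    clusters <- split(seq_len(num_snvs), lab)
  }
  K <- length(clusters)
  parent <- random_prufer_parent(K + 1L)  # vertices: 1 = dummy root, 2..K+1
  parent <- ifelse(parent == 1L, 0L, parent - 1L)
  clonal <- t(vapply(seq_len(num_samples),
                     function(s) rdirichlet1(K + 1L, kappa),
                     numeric(K + 1L)))
  clonal <- t(clonal)  # (K+1) x S
  if (num_samples == 1L) clonal <- matrix(clonal, K + 1L, 1L)
  chrom <- sample(paste0("chr", 1:22), num_snvs, replace = TRUE)
  new_truth(parent, clusters, clonal, paste0("S", seq_len(num_samples)), chrom)
}

#' Inject mutation loss into a ground truth
#'
#' Picks an origin node with enough mutations and at least one proper
#' descendant, selects the loss node uniformly among the origin's proper
#' descendants, marks `round(loss_proportion * N)` of the origin's mutations
#' as lost, places them on one shared chromosome (genomic locality of the
#' deleted region), and subtracts the loss node's cellular prevalence from the
#' lost mutations' effective prevalence: cells at and below the loss node no
#' longer carry them.
#'
#' @param gt a `clone_truth`.
#' @param loss_proportion fraction of all mutations to lose, in [0, 1).
#' @return modified `clone_truth` with `lost`, `loss_node`, `loss_chrom` set
#'   and `mutation_prev` adjusted.
#' @export
inject_loss <- function(gt, loss_proportion) {
  if (loss_proportion < 0 || loss_proportion >= 1)
    stop_validation("loss_proportion must be in [0, 1)")
  N <- gt$tree$n_mutations
  L <- round(loss_proportion * N)
  if (L == 0L) return(gt)
  parent <- gt$tree$parent
  K <- length(parent)
  if (K == 1L) stop_validation("cannot inject loss into a single-node tree")
  n_desc <- vapply(seq_len(K), function(v) length(tree_subtree(parent, v)) - 1L, 1L)
  sizes <- vapply(gt$tree$clusters, length, 1L)
  eligible <- which(n_desc >= 1L & sizes >= L)
  if (length(eligible) == 0L)
    stop_validation("no eligible origin/descendant pair for loss of %d mutations", L)
  origin <- eligible[sample.int(length(eligible), 1L)]
  desc <- setdiff(tree_subtree(parent, origin), origin)
  loss_node <- desc[sample.int(length(desc), 1L)]
  lost <- sort(safe_sample(gt$tree$clusters[[origin]])[seq_len(L)])
  loss_chrom <- sample(paste0("chr", 1:22), 1L)
  gt$chrom[lost] <- loss_chrom
  eff <- gt$cellular[origin + 1L, ] - gt$cellular[loss_node + 1L, ]
  gt$mutation_prev[lost, ] <- matrix(eff, L, length(eff), byrow = TRUE)
  gt$lost <- lost
  gt$loss_node <- loss_node
  gt$loss_chrom <- loss_chrom
  gt
}

#' Simulate ground truth from a tree-structured stick-breaking prior
#'
#' Draws node assignments by lazily expanding a tree of sticks: at a node of
#' depth d a mutation stops with probability from Beta(1, lambda *
#' depth_decay^d), otherwise descends into a child chosen by a GEM(gamma)
#' stick-breaking over children. Unoccupied nodes are collapsed; per-sample
#' clonal prevalences are then drawn from a uniform Dirichlet over occupied
#' nodes plus the dummy root.
#'
#' @param num_snvs number of mutations.
#' @param num_samples number of samples.
#' @param gamma GEM branching parameter.
#' @param lambda stopping stick parameter at depth 0.
#' @param depth_decay multiplicative decay of lambda per depth level.
#' @return a `clone_truth`.
#' @export
simulate_tssb <- function(num_snvs, num_samples = 1L, gamma = 1.0,
                          lambda = 0.5, depth_decay = 1.0) {
  nu <- numeric(0)      # stopping stick per node
  psi <- list()         # child sticks per node
  kids <- list()        # child node ids per node
  par <- integer(0)     # parent node id (0 for the TSSB root's parent)
  depth <- integer(0)
  add_node <- function(p, d) {
    id <- length(nu) + 1L
    nu[id] <<- stats::rbeta(1, 1, lambda * depth_decay^d)
    psi[[id]] <<- numeric(0)
    kids[[id]] <<- integer(0)
    par[id] <<- p
    depth[id] <<- d
    id
  }
  root <- add_node(0L, 0L)
  assign_node <- function() {
    v <- root
    repeat {
      if (stats::runif(1) < nu[v]) return(v)
      j <- 0L
      repeat {
        j <- j + 1L
        if (j > length(psi[[v]])) {
          psi[[v]][j] <<- stats::rbeta(1, 1, gamma)
          kids[[v]][j] <<- add_node(v, depth[v] + 1L)
        }
        if (stats::runif(1) < psi[[v]][j]) break
      }
      v <- kids[[v]][j]
    }
  }
  assigned <- vapply(seq_len(num_snvs), function(i) assign_node(), 1L)
  occupied <- sort(unique(assigned))
  # collapse unoccupied nodes: parent = nearest occupied proper ancestor
  newid <- stats::setNames(seq_along(occupied), occupied)
  parent <- integer(length(occupied))
  for (i in seq_along(occupied)) {
    u <- par[occupied[i]]
    while (u != 0L && !(u %in% occupied)) u <- par[u]
    parent[i] <- if (u == 0L) 0L else newid[[as.character(u)]]
  }
  clusters <- split(seq_len(num_snvs), newid[as.character(assigned)])
  K <- length(occupied)
  clonal <- matrix(0, K + 1L, num_samples)
  for (s in seq_len(num_samples)) clonal[, s] <- rdirichlet1(K + 1L, 1)
  chrom <- sample(paste0("chr", 1:22), num_snvs, replace = TRUE)
  new_truth(parent, clusters, clonal, paste0("S", seq_len(num_samples)), chrom)
}

#' Emit binomial read counts from a ground truth
#'
#' Mutations are diploid heterozygous (major = minor = 1, normal copy number
#' 2); per mutation and sample, alt counts are Binomial(depth, xi) with xi the
#' copy-number and tumour-content corrected expected VAF at the mutation's
#' effective cellular prevalence.
#'
#' @param gt a `clone_truth`.
#' @param depth total read depth per mutation per sample.
#' @param tumour_content fraction of malignant cells (default 1).
#' @param error_rate sequencing error rate.
#' @return an `snv_table` (includes the `chrom` column).
#' @export
emit_reads <- function(gt, depth, tumour_content = 1.0, error_rate = 0.001) {
  if (depth < 1) stop_validation("depth must be >= 1")
  N <- gt$tree$n_mutations
  S <- length(gt$samples)
  rows <- expand.grid(s = seq_len(S), n = seq_len(N))
  xi <- expected_vaf(gt$mutation_prev[cbind(rows$n, rows$s)], tumour_content,
                     total_cn = 2L, variant_alleles = 1L, normal_cn = 2L,
                     error_rate = error_rate)
  alt <- stats::rbinom(nrow(rows), depth, xi)
  df <- data.frame(
    mutation_id = paste0("m", rows$n),
    sample_id = gt$samples[rows$s],
    ref_counts = depth - alt,
    alt_counts = alt,
    major_cn = 1L, minor_cn = 1L, normal_cn = 2L,
    tumour_content = tumour_content,
    error_rate = error_rate,
    chrom = gt$chrom[rows$n]
  )
  as_snv_table(df)
}

#' Deletable-region flags implied by a ground truth
#'
#' TRUE for mutations on the chromosome where loss occurred (the flag a copy
#' number caller would raise for the deleted region), FALSE elsewhere or when
#' no loss was injected.
#'
#' @param gt a `clone_truth`.
#' @return logical vector of length N.
#' @export
loss_flags_from_truth <- function(gt) {
  if (is.na(gt$loss_chrom)) rep(FALSE, gt$tree$n_mutations)
  else gt$chrom == gt$loss_chrom
}

#' Emulate prevalence-based pre-clustering from a ground truth
#'
#' Groups mutations by their effective prevalence profile: true node, refined
#' by lost status. This is what an accurate non-phylogenetic pre-clustering of
#' the observed VAFs would return, since lost mutations sit at a shifted
#' prevalence and separate from their origin siblings.
#'
#' @param gt a `clone_truth`.
#' @return integer cluster assignment per mutation (dense 1..B).
#' @export
oracle_preclustering <- function(gt) {
  key <- paste0(gt$node_of, "_", seq_len(gt$tree$n_mutations) %in% gt$lost)
  match(key, unique(key))
}
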