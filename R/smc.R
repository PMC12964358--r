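# Bottom-up sequential Monte Carlo over rooted forests, and the auxiliary
# data-ordering permutation machinery. Internally the sampler works at the
# level of "blocks": pre-clustered groups of mutations that move as one
# super-datum whose grid log-likelihood is the sum over members.

# ---- blocks ----------------------------------------------------------------

#' Build block-level data from a grid likelihood
#'
#' Pre-clustered mutations are kept together and move through the sampler as
#' blocks; without pre-clustering every mutation is its own block.
#'
#' @param gl a `grid_likelihood`.
#' @param assignment integer cluster index per mutation (1..B), or NULL for
#'   singleton blocks.
#' @param nu per-mutation prior outlier probabilities.
#' @return internal block structure (list).
#' @export
make_blocks <- function(gl, assignment = NULL, nu = NULL) {
  N <- dim(gl$loglik)[1L]
  G <- length(gl$grid); S <- length(gl$samples)
  assignment <- assignment %||% seq_len(N)
  nu <- nu %||% rep(0, N)
  B <- max(assignment)
  members <- split(seq_len(N), assignment)
  om <- outlier_marginals(gl)
  list(
    B = B,
    members = members,
    sizes = vapply(members, length, 1L),
    D = lapply(members, function(m) node_data_matrix(gl, m, G)),
    out_marg = vapply(members, function(m) sum(om[m]), numeric(1)),
    log_nu_out = vapply(members, function(m) sum(log(nu[m])), numeric(1)),
    log_nu_in = vapply(members, function(m) sum(log1p(-nu[m])), numeric(1)),
    n_mutations = N, G = G, S = S, grid = gl$grid
  )
}

# block-level state: parent vector over nodes, clusters of block ids, outliers
state_new <- function(parent, clusters, outliers = integer()) {
  list(parent = as.integer(parent), clusters = lapply(clusters, as.integer),
       outliers = as.integer(outliers))
}

# expand a block-level state to a mutation-level clone_tree
state_to_tree <- function(st, bl) {
  clone_tree(
    st$parent,
    lapply(st$clusters, function(bs) sort(unlist(bl$members[bs]))),
    outliers = sort(unlist(bl$members[st$outliers])),
    n_mutations = bl$n_mutations
  )
}

# collapsed joint log probability of a block-level state (possibly partial:
# only the blocks present contribute, CRP denominator uses included mutations)
state_log_target <- function(st, bl, config) {
  K <- length(st$parent)
  in_blocks <- unlist(st$clusters)
  lp <- sum(bl$log_nu_in[in_blocks]) +
    sum(bl$log_nu_out[st$outliers]) + sum(bl$out_marg[st$outliers])
  if (K == 0L) return(lp)
  node_sizes <- vapply(st$clusters, function(bs) sum(bl$sizes[bs]), numeric(1))
  D <- lapply(st$clusters, function(bs) Reduce(`+`, bl$D[bs]))
  cfg <- config; cfg$grid_size <- bl$G
  lp + crp_log_prior(node_sizes, config$alpha) + forest_log_prior(K) +
    dp_marginal(st$parent, D, cfg)
}

# ---- particles -------------------------------------------------------------

# a subtree node: blocks at the root of the subtree, data term D, children
# convolution cache cw (w (*) children messages), message M = D + cw,
# recursive children, node/mutation counts
subtree_new <- function(blocks, D, cw, children, K, size_mut) {
  list(blocks = blocks, D = D, cw = cw, M = D + cw, children = children,
       K = K, size_mut = size_mut)
}

delta_log_mat <- function(G, S) {
  m <- matrix(-Inf, G, S); m[1L, ] <- 0; m
}

conv_top <- function(a, b) {
  # top row (total mass 1) of the truncated log convolution, O(G) per sample
  G <- nrow(a)
  vapply(seq_len(ncol(a)), function(s) logsumexp(a[, s] + b[G:1, s]), numeric(1))
}

particle_init <- function(bl, config) {
  list(roots = list(), K = 0L, n_mut = 0L,
       crp_num = 0, out_terms = 0, in_terms = 0, gamma = 0,
       root_L = numeric(0),     # blocks per root subtree
       root_loge = numeric(0),  # log #linear extensions per root subtree
       n_out_blocks = 0L,       # outlier blocks processed so far
       wm = matrix(prior_wlog(bl$G, config$kappa), bl$G, bl$S),
       wm_root = matrix(prior_wlog(bl$G, config$kappa, root = TRUE),
                        bl$G, bl$S))
}

# log number of orderings the bottom-up construction accepts for a forest
# with root subtree block counts Ls / extension counts loges and q free
# (outlier) blocks: shuffle product of the subtrees, times the free merges.
# The sigma-conditional target divides by this count, because sigma given the
# state is uniform over exactly these orderings.
log_lin_ext <- function(Ls, loges, q) {
  Lt <- sum(Ls)
  sum(loges) + lfactorial(Lt) - sum(lfactorial(Ls)) +
    lfactorial(Lt + q) - lfactorial(Lt)
}

# same count for a block-level state (recursive form; tests compare this
# against the particle-side bookkeeping)
state_log_ext <- function(st) {
  ch <- tree_children(st$parent)
  rec <- function(v) {
    kid <- lapply(ch[[v + 1L]], rec)
    Ls <- vapply(kid, `[[`, numeric(1), 1L)
    les <- vapply(kid, `[[`, numeric(1), 2L)
    m <- if (v == 0L) 0L else length(st$clusters[[v]])
    le <- sum(les) + lfactorial(sum(Ls)) - sum(lfactorial(Ls)) + lfactorial(m)
    c(m + sum(Ls), le)
  }
  r <- rec(0L)
  q <- length(st$outliers)
  r[2L] + lfactorial(r[1L] + q) - lfactorial(r[1L])
}

# target value of a particle from its caches; marg recomputed from root
# messages (R truncated convolutions)
particle_gamma <- function(p, bl, config) {
  lp <- p$out_terms + p$in_terms -
    log_lin_ext(p$root_L, p$root_loge, p$n_out_blocks)
  if (p$K == 0L) return(lp)
  total <- fold_conv_log(c(list(p$wm_root), lapply(p$roots, `[[`, "M")))
  marg <- sum(total[bl$G, ]) - bl$S * log_norm_const(p$K + 1L, bl$G, config$kappa)
  lp + p$crp_num - (lgamma(config$alpha + p$n_mut) - lgamma(config$alpha)) +
    forest_log_prior(p$K) + marg
}

# Gamma values for every "attach" outcome of block b: outlier, and joining
# each existing root. Returns list(gammas, aux) with aux caching what
# particle_apply needs.
attach_menu <- function(p, b, bl, config) {
  R <- length(p$roots)
  G <- bl$G; S <- bl$S
  nms <- character(0); gammas <- numeric(0)
  const_in <- p$crp_num + p$out_terms + p$in_terms
  loge0 <- log_lin_ext(p$root_L, p$root_loge, p$n_out_blocks)
  # outlier outcome: extension count gains one free block
  d_ext_out <- log_lin_ext(p$root_L, p$root_loge, p$n_out_blocks + 1L) - loge0
  gammas <- c(gammas, p$gamma + bl$log_nu_out[b] + bl$out_marg[b] - d_ext_out)
  nms <- c(nms, "outlier")
  join_tops <- NULL
  allbut <- NULL
  if (R > 0L) {
    Ms <- lapply(p$roots, `[[`, "M")
    pre <- vector("list", R + 1L); pre[[1L]] <- p$wm_root
    for (i in seq_len(R)) pre[[i + 1L]] <- conv_log(pre[[i]], Ms[[i]])
    suf <- vector("list", R + 1L); suf[[R + 1L]] <- delta_log_mat(G, S)
    for (i in rev(seq_len(R))) suf[[i]] <- conv_log(Ms[[i]], suf[[i + 1L]])
    allbut <- lapply(seq_len(R), function(r) conv_log(pre[[r]], suf[[r + 1L]]))
    n_new <- p$n_mut + bl$sizes[b]
    crp_den <- lgamma(config$alpha + n_new) - lgamma(config$alpha)
    zc <- bl$S * log_norm_const(p$K + 1L, G, config$kappa)
    for (r in seq_len(R)) {
      rt <- p$roots[[r]]
      M_new <- rt$M + bl$D[[b]]
      marg <- sum(conv_top(allbut[[r]], M_new)) - zc
      d_crp <- lgamma(rt$size_mut + bl$sizes[b]) - lgamma(rt$size_mut)
      Ls <- p$root_L; loges <- p$root_loge
      loges[r] <- loges[r] + log(length(rt$blocks) + 1)
      Ls[r] <- Ls[r] + 1
      g <- const_in + d_crp + bl$log_nu_in[b] - crp_den +
        forest_log_prior(p$K) + marg -
        log_lin_ext(Ls, loges, p$n_out_blocks)
      gammas <- c(gammas, g)
      nms <- c(nms, paste0("join", r))
    }
  } else {
    # empty particle: creating a singleton node is the only tree outcome
    g <- new_node_gamma(p, b, integer(0), bl, config)
    gammas <- c(gammas, g)
    nms <- c(nms, "new_empty")
  }
  list(gammas = stats::setNames(gammas, nms), allbut = allbut)
}

# gamma of the "create new node with children at root positions `ch_pos`"
# outcome (also returns nothing cached; applying recomputes messages)
new_node_gamma <- function(p, b, ch_pos, bl, config) {
  kids <- p$roots[ch_pos]
  rest <- p$roots[setdiff(seq_along(p$roots), ch_pos)]
  cw <- fold_conv_log(c(list(p$wm), lapply(kids, `[[`, "M")))
  M_new <- bl$D[[b]] + cw
  K_new <- p$K + 1L
  n_new <- p$n_mut + bl$sizes[b]
  if (length(rest) > 0L) {
    allrest <- fold_conv_log(c(list(p$wm_root), lapply(rest, `[[`, "M")))
    tot <- conv_top(allrest, M_new)
  } else {
    tot <- conv_top(p$wm_root, M_new)
  }
  marg <- sum(tot) - bl$S * log_norm_const(K_new + 1L, bl$G, config$kappa)
  keep <- setdiff(seq_along(p$roots), ch_pos)
  L_kids <- p$root_L[ch_pos]
  loge_new <- sum(p$root_loge[ch_pos]) + lfactorial(sum(L_kids)) -
    sum(lfactorial(L_kids))
  Ls <- c(p$root_L[keep], 1 + sum(L_kids))
  loges <- c(p$root_loge[keep], loge_new)
  p$crp_num + log(config$alpha) + lgamma(bl$sizes[b]) -
    (lgamma(config$alpha + n_new) - lgamma(config$alpha)) +
    p$out_terms + p$in_terms + bl$log_nu_in[b] +
    forest_log_prior(K_new) + marg -
    log_lin_ext(Ls, loges, p$n_out_blocks)
}

# apply a choice to a particle; gamma_new precomputed by the caller
particle_apply <- function(p, choice, b, bl, config, gamma_new) {
  if (choice$type == "outlier") {
    p$out_terms <- p$out_terms + bl$log_nu_out[b] + bl$out_marg[b]
    p$n_out_blocks <- p$n_out_blocks + 1L
  } else if (choice$type == "join") {
    r <- choice$root
    rt <- p$roots[[r]]
    p$crp_num <- p$crp_num +
      lgamma(rt$size_mut + bl$sizes[b]) - lgamma(rt$size_mut)
    p$root_loge[r] <- p$root_loge[r] + log(length(rt$blocks) + 1)
    p$root_L[r] <- p$root_L[r] + 1
    rt$blocks <- c(rt$blocks, b)
    rt$D <- rt$D + bl$D[[b]]
    rt$M <- rt$D + rt$cw
    rt$size_mut <- rt$size_mut + bl$sizes[b]
    p$roots[[r]] <- rt
    p$n_mut <- p$n_mut + bl$sizes[b]
    p$in_terms <- p$in_terms + bl$log_nu_in[b]
  } else {  # new node
    ch_pos <- choice$children
    kids <- p$roots[ch_pos]
    cw <- fold_conv_log(c(list(p$wm), lapply(kids, `[[`, "M")))
    K_sub <- 1L + sum(vapply(kids, `[[`, 0L, "K"))
    node <- subtree_new(b, bl$D[[b]], cw, kids, K_sub, bl$sizes[b])
    keep <- setdiff(seq_along(p$roots), ch_pos)
    L_kids <- p$root_L[ch_pos]
    loge_new <- sum(p$root_loge[ch_pos]) + lfactorial(sum(L_kids)) -
      sum(lfactorial(L_kids))
    p$root_L <- c(p$root_L[keep], 1 + sum(L_kids))
    p$root_loge <- c(p$root_loge[keep], loge_new)
    p$roots <- c(p$roots[keep], list(node))
    p$K <- p$K + 1L
    p$n_mut <- p$n_mut + bl$sizes[b]
    p$crp_num <- p$crp_num + log(config$alpha) + lgamma(bl$sizes[b])
    p$in_terms <- p$in_terms + bl$log_nu_in[b]
  }
  p$gamma <- unname(gamma_new)
  p
}

# ---- proposal --------------------------------------------------------------

softmax_log <- function(lg) {
  m <- max(lg)
  if (m == -Inf) return(rep(1 / length(lg), length(lg)))
  p <- exp(lg - m)
  p / sum(p)
}

#' One semi-adapted SMC proposal step
#'
#' Extends a particle with the next block: with probability
#' `config$prop_new_node` a new node is created whose children are a uniform
#' random subset of the current roots (unadapted); otherwise the block joins
#' an existing root or the outlier state, Gibbs-chosen proportionally to the
#' resulting partial target (adapted). The incremental weight is the
#' partial-target ratio over the proposal probability of the realized choice.
#'
#' @param p particle (internal structure from `particle_init`).
#' @param b block index of the next datum.
#' @param bl block data from [make_blocks()].
#' @param config a `model_config`.
#' @param forced optional forced choice (conditional SMC reference path).
#' @return list(particle, log_inc_weight, choice).
#' @export
smc_propose_extension <- function(p, b, bl, config, forced = NULL) {
  R <- length(p$roots)
  menu <- attach_menu(p, b, bl, config)
  gibbs_p <- softmax_log(menu$gammas)
  p_new_branch <- config$prop_new_node
  if (is.null(forced)) {
    if (stats::runif(1) < p_new_branch) {
      ch_pos <- which(stats::runif(R) < 0.5)
      choice <- list(type = "new", children = ch_pos)
    } else {
      k <- sample.int(length(gibbs_p), 1L, prob = gibbs_p)
      nm <- names(menu$gammas)[k]
      choice <-
        if (nm == "outlier") list(type = "outlier")
        else if (nm == "new_empty") list(type = "new", children = integer(0))
        else list(type = "join", root = as.integer(sub("join", "", nm)))
    }
  } else choice <- forced
  # proposal log probability and target of the realized choice (log space:
  # the Gibbs probability of a forced reference choice may underflow)
  lse_menu <- logsumexp(menu$gammas)
  log_gibbs <- function(nm) log(1 - p_new_branch) + menu$gammas[[nm]] - lse_menu
  if (choice$type == "new") {
    gamma_new <- if (R == 0L) menu$gammas[["new_empty"]]
      else new_node_gamma(p, b, choice$children, bl, config)
    log_q <- log(p_new_branch) - R * log(2)
    if (R == 0L) log_q <- logsumexp(c(log_q, log_gibbs("new_empty")))
  } else if (choice$type == "outlier") {
    gamma_new <- menu$gammas[["outlier"]]
    log_q <- log_gibbs("outlier")
  } else {
    nm <- paste0("join", choice$root)
    gamma_new <- menu$gammas[[nm]]
    log_q <- log_gibbs(nm)
  }
  logw <- gamma_new - p$gamma - log_q
  # a dead particle (zero-probability trajectory) keeps zero weight; NaN can
  # only arise from -Inf arithmetic on such trajectories
  if (is.na(logw)) logw <- -Inf
  p2 <- particle_apply(p, choice, b, bl, config, gamma_new)
  list(particle = p2, logw = logw, choice = choice)
}

systematic_resample <- function(w, n) {
  u <- (stats::runif(1) + 0:(n - 1)) / n
  findInterval(u, cumsum(w)) + 1L
}

#' Bottom-up SMC sweep over a data ordering
#'
#' Grows rooted forests over the blocks in the order `sigma`, reweighing and
#' resampling (systematic, at effective sample size below half the particle
#' count). When `ref_choices` is given, particle 1 is forced along that
#' trajectory and survives every resampling (conditional SMC; the non-reference
#' particles are then resampled multinomially, which keeps the conditional
#' kernel exact).
#'
#' @param sigma block order (all non-outlier and outlier blocks).
#' @param bl block data.
#' @param config a `model_config`.
#' @param n_particles number of particles.
#' @param ref_choices optional list of forced choices (from
#'   `reference_choices`).
#' @return list with `particles`, `logw` (unnormalized final log weights) and
#'   `logZ` (marginal-likelihood estimate of the sigma-constrained target).
#' @export
smc_sweep <- function(sigma, bl, config, n_particles = 20L,
                      ref_choices = NULL) {
  P <- n_particles
  conditional <- !is.null(ref_choices)
  parts <- replicate(P, particle_init(bl, config), simplify = FALSE)
  logw <- rep(0, P)
  logZ <- 0
  for (t in seq_along(sigma)) {
    b <- sigma[t]
    for (i in seq_len(P)) {
      forced <- if (conditional && i == 1L) ref_choices[[t]] else NULL
      res <- smc_propose_extension(parts[[i]], b, bl, config, forced = forced)
      parts[[i]] <- res$particle
      logw[i] <- logw[i] + res$logw
    }
    if (all(logw == -Inf))
      stop(sprintf("SMC failure: all particle weights are zero at generation %d", t))
    lse <- logsumexp(logw)
    W <- exp(logw - lse)
    ess <- 1 / sum(W^2)
    if (ess < P / 2 && t < length(sigma)) {
      logZ <- logZ + lse - log(P)
      idx <- if (conditional) {
        c(1L, sample.int(P, P - 1L, replace = TRUE, prob = W))
      } else {
        systematic_resample(W, P)
      }
      parts <- parts[idx]
      logw <- rep(0, P)
    }
  }
  logZ <- logZ + logsumexp(logw) - log(P)
  list(particles = parts, logw = logw, logZ = logZ)
}

# convert a finished particle to a block-level state
particle_to_state <- function(p, bl) {
  parent <- integer(0)
  clusters <- list()
  add_node <- function(node, parent_id) {
    parent[[length(parent) + 1L]] <<- parent_id
    clusters[[length(clusters) + 1L]] <<- node$blocks
    my_id <- length(parent)
    for (c in node$children) add_node(c, my_id)
    my_id
  }
  for (r in p$roots) add_node(r, 0L)
  in_blocks <- unlist(clusters) %||% integer(0)
  outliers <- setdiff(seq_len(bl$B), in_blocks)
  state_new(parent, clusters, outliers)
}

# ---- permutations ----------------------------------------------------------

safe_sample <- function(x) x[sample.int(length(x))]

# uniform interleaving of a list of sequences (probability proportional to
# remaining length at every slot gives the uniform shuffle product)
shuffle_merge <- function(seqs) {
  seqs <- seqs[vapply(seqs, length, 1L) > 0L]
  if (length(seqs) == 0L) return(integer(0))
  lens <- vapply(seqs, length, 1L)
  pos <- rep(1L, length(seqs))
  out <- integer(sum(lens))
  for (k in seq_along(out)) {
    rem <- lens - pos + 1L
    i <- sample.int(length(seqs), 1L, prob = rem)
    out[k] <- seqs[[i]][pos[i]]
    pos[i] <- pos[i] + 1L
  }
  out
}

#' Sample a data ordering consistent with a tree
#'
#' Draws uniformly among the orderings the bottom-up SMC construction could
#' have used to build the given state: every block of a strict descendant node
#' must precede every block of its ancestor. Uniformity follows from the exact
#' interleaving counts: child subtree orders are merged by a uniform shuffle
#' product and each node's own blocks are appended in random order; outlier
#' blocks are unconstrained and merged uniformly at the top.
#'
#' @param st block-level state (or a `clone_tree` with `bl = NULL`, in which
#'   case clusters hold mutation indices).
#' @param bl unused; kept for signature symmetry.
#' @return integer vector: block order.
#' @export
sample_permutation <- function(st, bl = NULL) {
  ch <- tree_children(st$parent)
  seq_of <- function(v) {
    kid_seqs <- lapply(ch[[v + 1L]], seq_of)
    merged <- shuffle_merge(kid_seqs)
    own <- if (v == 0L) integer(0) else safe_sample(st$clusters[[v]])
    c(merged, own)
  }
  tree_seq <- seq_of(0L)
  shuffle_merge(list(tree_seq, safe_sample(st$outliers)))
}

#' Check that an ordering can rebuild a state bottom-up
#'
#' Independent replay oracle: simulates the SMC construction (create node when
#' its first block arrives, requiring all children subtrees to be complete
#' current roots; join otherwise, requiring the node to still be a root) and
#' reports whether the given state is reachable under `sigma`.
#'
#' @param st block-level state.
#' @param sigma block ordering.
#' @return TRUE/FALSE.
#' @export
is_valid_permutation <- function(st, sigma) {
  K <- length(st$parent)
  node_of <- integer(max(c(unlist(st$clusters), st$outliers, 0L)))
  for (v in seq_len(K)) node_of[st$clusters[[v]]] <- v
  ch <- tree_children(st$parent)
  created <- logical(K)
  remaining <- vapply(st$clusters, length, 1L)
  roots <- integer(0)
  for (b in sigma) {
    if (b %in% st$outliers) next
    v <- node_of[b]
    if (v == 0L) return(FALSE)
    if (!created[v]) {
      kids <- ch[[v + 1L]]
      if (!all(created[kids]) || any(remaining[kids] > 0L) ||
          !all(kids %in% roots)) return(FALSE)
      roots <- c(setdiff(roots, kids), v)
      created[v] <- TRUE
    } else {
      if (!(v %in% roots)) return(FALSE)
    }
    remaining[v] <- remaining[v] - 1L
  }
  all(created) && all(remaining == 0L)
}

# forced choices replaying the construction of `st` under `sigma`, mirroring
# the particle root-list bookkeeping (new nodes appended, children removed)
reference_choices <- function(st, sigma) {
  K <- length(st$parent)
  node_of <- integer(bl_max <- max(c(unlist(st$clusters), st$outliers, 0L)))
  for (v in seq_len(K)) node_of[st$clusters[[v]]] <- v
  ch <- tree_children(st$parent)
  created <- logical(K)
  roots <- integer(0)
  choices <- vector("list", length(sigma))
  for (t in seq_along(sigma)) {
    b <- sigma[t]
    if (b %in% st$outliers) {
      choices[[t]] <- list(type = "outlier")
      next
    }
    v <- node_of[b]
    if (!created[v]) {
      kids <- ch[[v + 1L]]
      pos <- match(kids, roots)
      if (anyNA(pos))
        stop("internal error: reference path not reproducible under sigma")
      choices[[t]] <- list(type = "new", children = pos)
      roots <- c(roots[setdiff(seq_along(roots), pos)], v)
      created[v] <- TRUE
    } else {
      r <- match(v, roots)
      if (is.na(r))
        stop("internal error: reference path not reproducible under sigma")
      choices[[t]] <- list(type = "join", root = r)
    }
  }
  choices
}
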