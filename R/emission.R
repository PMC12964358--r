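# Emission model: probability of a mutation's allele counts given its cellular
# prevalence, corrected for copy number and tumour content (PyClone-style
# three-population mixture), evaluated on the discrete prevalence grid.

#' Enumerate candidate mutational genotype states
#'
#' The bulk sample is modelled as a mixture of three cell populations: normal
#' cells (copy number `normal_cn`, no variant allele), cancer cells not
#' carrying the mutation (copy number `major_cn + minor_cn`, no variant
#' allele), and cancer cells carrying the mutation. The number of variant
#' allele copies in the mutated population is unknown; under the
#' major-copy-number parsimony prior it ranges over 1..`major_cn` with equal
#' weight. One row per candidate variant-allele count is returned; the fixed
#' normal/reference populations are implied by the columns.
#'
#' @param major_cn,minor_cn major/minor copy number of the tumour genotype.
#' @param normal_cn copy number of the normal population (default 2).
#' @return data.frame with columns `variant_alleles`, `total_cn`, `normal_cn`,
#'   `prior_weight` (weights sum to 1).
#' @export
genotype_states <- function(major_cn, minor_cn, normal_cn = 2L) {
  if (minor_cn > major_cn)
    stop_validation("minor_cn (%d) must not exceed major_cn (%d)", minor_cn, major_cn)
  if (major_cn < 1) stop_validation("major_cn must be >= 1")
  v <- seq_len(major_cn)
  data.frame(
    variant_alleles = v,
    total_cn = major_cn + minor_cn,
    normal_cn = normal_cn,
    prior_weight = rep(1 / major_cn, major_cn)
  )
}

#' Expected variant allele frequency under the population mixture
#'
#' Computes xi, the expected fraction of reads supporting the variant allele
#' when a fraction `cellular_prevalence` of malignant cells carry the mutation
#' with `variant_alleles` of `total_cn` copies mutated. Populations contribute
#' alleles proportionally to (1-t) c_N : t (1 - rho) c_R : t rho c_V. Allele
#' fractions at the genotype boundaries are folded with the sequencing error
#' rate (0 variant copies reads at rate `error_rate`, all copies at
#' 1 - `error_rate`).
#'
#' @param cellular_prevalence fraction of malignant cells carrying the
#'   mutation; vectorized.
#' @param tumour_content fraction of cells in the sample that are malignant.
#' @param total_cn total copy number of the cancer genotype.
#' @param variant_alleles copies carrying the variant in mutated cells.
#' @param normal_cn copy number in normal cells (default 2).
#' @param error_rate sequencing error rate in (0, 0.5).
#' @return expected VAF, same length as `cellular_prevalence`.
#' @export
expected_vaf <- function(cellular_prevalence, tumour_content, total_cn,
                         variant_alleles, normal_cn = 2L, error_rate = 0.001) {
  p <- cellular_prevalence
  t <- tumour_content
  mu_of <- function(b, c) {
    if (b == 0) error_rate else if (b == c) 1 - error_rate else b / c
  }
  w_n <- (1 - t) * normal_cn
  w_r <- t * (1 - p) * total_cn
  w_v <- t * p * total_cn
  num <- w_n * mu_of(0, normal_cn) + w_r * mu_of(0, total_cn) +
    w_v * mu_of(variant_alleles, total_cn)
  num / (w_n + w_r + w_v)
}

# log pmf of alt counts given expected VAF; vectorized over xi
loglik_counts <- function(alt, depth, xi, density = "beta-binomial",
                          precision = 400) {
  if (density == "binomial") {
    stats::dbinom(alt, depth, xi, log = TRUE)
  } else {
    a <- xi * precision
    b <- (1 - xi) * precision
    out <- lchoose(depth, alt) + lbeta(alt + a, depth - alt + b) - lbeta(a, b)
    # degenerate means (possible when error_rate = 0): point mass
    out[xi <= 0] <- ifelse(alt == 0, 0, -Inf)
    out[xi >= 1] <- ifelse(alt == depth, 0, -Inf)
    out
  }
}

#' Grid-evaluated emission log-likelihood for an SNV table
#'
#' For every mutation, sample, and grid point g, computes
#' `log f(alt | depth, xi(g))` where the genotype-state mixture is marginalized
#' inside the density (log-sum-exp over candidate variant-allele counts). Rows
#' with zero depth carry no information and get a log-likelihood of 0 across
#' the grid (with a warning).
#'
#' @param table an `snv_table` (see [read_snv_table()]).
#' @param grid_size number of grid points (default 101).
#' @param density `"beta-binomial"` (default) or `"binomial"`.
#' @param precision beta-binomial precision (default 400).
#' @return object of class `grid_likelihood`: list with `loglik`
#'   (array mutation x sample x grid), `mutations`, `samples`, `grid`,
#'   `density`, `precision`.
#' @export
compute_grid_likelihood <- function(table, grid_size = 101L,
                                    density = c("beta-binomial", "binomial"),
                                    precision = 400) {
  density <- match.arg(density)
  stopifnot(inherits(table, "snv_table"))
  muts <- attr(table, "mutations")
  samp <- attr(table, "samples")
  grid <- prevalence_grid(grid_size)
  N <- length(muts); S <- length(samp); G <- length(grid)
  ll <- array(0, dim = c(N, S, G), dimnames = list(muts, samp, NULL))
  zero_depth <- 0L
  mi <- match(table$mutation_id, muts)
  si <- match(table$sample_id, samp)
  for (r in seq_len(nrow(table))) {
    depth <- table$ref_counts[r] + table$alt_counts[r]
    if (depth == 0) {
      zero_depth <- zero_depth + 1L
      next
    }
    st <- genotype_states(table$major_cn[r], table$minor_cn[r], table$normal_cn[r])
    per_state <- vapply(seq_len(nrow(st)), function(k) {
      xi <- expected_vaf(grid, table$tumour_content[r], st$total_cn[k],
                         st$variant_alleles[k], st$normal_cn[k],
                         table$error_rate[r])
      log(st$prior_weight[k]) +
        loglik_counts(table$alt_counts[r], depth, xi, density, precision)
    }, numeric(G))
    row <- if (nrow(st) == 1L) per_state[, 1L] else {
      m <- apply(per_state, 1L, max)
      m + log(rowSums(exp(per_state - m)))
    }
    ll[mi[r], si[r], ] <- row
  }
  if (zero_depth > 0)
    warning(sprintf("%d rows with zero depth carry no information", zero_depth))
  structure(
    list(loglik = ll, mutations = muts, samples = samp, grid = grid,
         density = density, precision = precision),
    class = "grid_likelihood"
  )
}

#' Log marginal likelihood of one grid row under a uniform prevalence prior
#'
#' Approximates `log integral_0^1 f(x | rho) d rho` by the trapezoidal rule on
#' the grid, in log space. This is the per-sample emission marginal used for
#' outlier (lost) mutations, whose cellular prevalence is unconstrained by the
#' tree.
#'
#' @param loglik_row per-grid-point log densities for one mutation in one
#'   sample.
#' @param grid the grid values the row was evaluated on.
#' @return scalar log marginal (-Inf for an all--Inf row).
#' @export
outlier_marginal_loglik <- function(loglik_row, grid = prevalence_grid(length(loglik_row))) {
  G <- length(loglik_row)
  h <- grid[2L] - grid[1L]
  w <- rep(h, G)
  w[c(1L, G)] <- h / 2
  logsumexp(loglik_row + log(w))
}

# N-vector of multi-sample outlier marginals (summed over samples)
outlier_marginals <- function(gl) {
  N <- dim(gl$loglik)[1L]; S <- dim(gl$loglik)[2L]
  vapply(seq_len(N), function(n) {
    sum(vapply(seq_len(S), function(s)
      outlier_marginal_loglik(gl$loglik[n, s, ], gl$grid), numeric(1)))
  }, numeric(1))
}
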