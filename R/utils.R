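#' @useDynLib clonetree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rbinom runif rgamma setNames
#' @importFrom utils head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Numerically stable log-sum-exp
#'
#' @param x numeric vector of log values (may contain -Inf).
#' @return log(sum(exp(x))) computed without underflow.
#' @export
logsumexp <- function(x) {
  m <- max(x)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log-space convolution of two G x S log-mass matrices (see src/conv.cpp)
conv_log <- function(a, b, max_mode = FALSE) .conv_log_cpp(a, b, max_mode)

fold_conv_log <- function(mats, max_mode = FALSE) .fold_conv_log_cpp(mats, max_mode)

#' Equally spaced cellular-prevalence grid on [0, 1]
#'
#' The discretization on which emission densities are evaluated and over which
#' clonal prevalences are marginalized.
#'
#' @param grid_size number of grid points G (>= 2); spacing is 1/(G-1).
#' @return numeric vector of G values from 0 to 1.
#' @export
prevalence_grid <- function(grid_size = 101L) {
  if (grid_size < 2) stop("grid_size must be >= 2")
  seq(0, 1, length.out = grid_size)
}

stop_validation <- function(...) stop(sprintf(...), call. = FALSE)
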