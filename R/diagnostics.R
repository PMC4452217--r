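#' @include AllClasses.R
NULL

#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain variance form: with m chains of length n,
#' `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the pooled variance estimate is `(n-1)/n W + B/n` and R-hat is the
#' square root of its ratio to `W`. Values near 1 indicate the chains are
#' sampling the same distribution; the fit flags parameters at or above the
#' configured threshold (default 1.1).
#'
#' Degenerate chains (all draws identical, e.g. a parameter held fixed)
#' return 1 by convention.
#'
#' @param chains matrix with one column per chain (equal lengths), or a
#'   list of equal-length numeric vectors.
#' @return scalar R-hat estimate.
#' @export
gelmanRhat <- function(chains) {
  if (is.list(chains)) {
    len <- lengths(chains)
    if (length(unique(len)) != 1L) stop("chains must have equal length")
    chains <- do.call(cbind, chains)
  }
  chains <- as.matrix(chains)
  m <- ncol(chains)
  if (m < 2L) stop("at least 2 chains are required")
  n <- nrow(chains)
  if (n < 2L) stop("chains must contain at least 2 draws")
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W < .Machine$double.eps) {
    ## degenerate: no within-chain variation
    return(if (B_over_n < .Machine$double.eps) 1 else Inf)
  }
  varPlus <- (n - 1) / n * W + B_over_n
  sqrt(varPlus / W)
}
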