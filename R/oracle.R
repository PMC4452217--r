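#' @include AllClasses.R likelihood.R
NULL

#' Exact marginal posterior of occupancy by enumeration (verification oracle)
#'
#' With the detection probabilities and lambda held fixed, sums the data
#' likelihood over all `2^n` latent occupancy configurations to obtain the
#' marginal posterior of pooled occupancy `psi` on a grid, exactly up to
#' grid resolution. Intended as an independent cross-check of the MCMC
#' sampler on tiny fixtures; refuses more than 12 locations.
#'
#' @param data a [DetectionSummary-class] with at most 12 locations.
#' @param fixed list with `p_trap`, `p_pellet`, `lambda` (scalars).
#' @param grid numeric vector of psi values (default 401 equally spaced
#'   points on `[0, 1]`).
#' @param config a [ModelConfig-class]; its likelihood mode, methods and
#'   psi prior are honoured (strata must be pooled).
#' @return data.frame with `psi` (grid points) and `mass` (posterior cell
#'   masses summing to 1, trapezoid-weighted).
#' @export
bruteForcePosterior <- function(data, fixed, grid = seq(0, 1, length.out = 401),
                                config = modelConfig()) {
  stopifnot(is(data, "DetectionSummary"))
  n <- nLocations(data)
  if (n > 12L) stop("enumeration oracle limited to 12 locations (2^n terms)")
  if (config@strata != "pooled")
    stop("the enumeration oracle supports pooled occupancy only")
  stopifnot(all(c("p_trap", "p_pellet", "lambda") %in% names(fixed)))

  ## per-location likelihood under z = 0 and z = 1 (psi-independent)
  logL <- matrix(NA_real_, n, 2L)
  for (i in seq_len(n)) {
    di <- new(Class = "DetectionSummary",
              X = data@X[i, , drop = FALSE], Y = data@Y[i, , drop = FALSE],
              E = data@E[i, , drop = FALSE], C = data@C[i, , drop = FALSE],
              habitat = data@habitat[i], nights = data@nights)
    for (zi in 0:1) {
      logL[i, zi + 1L] <- logLikelihood(
        list(z = zi, p_trap = fixed$p_trap, p_pellet = fixed$p_pellet,
             lambda = fixed$lambda), di, config)
    }
  }

  ## impossible states (-Inf) would give 0 * -Inf = NaN in the matrix
  ## product below; a large negative stand-in underflows to 0 on exp()
  logL[!is.finite(logL)] <- -1e12

  ## enumerate z in {0,1}^n; for each configuration the psi-dependence is
  ## psi^S (1-psi)^(n-S) with S = sum(z)
  configs <- as.matrix(expand.grid(rep(list(0:1), n)))
  S <- rowSums(configs)
  logLz <- configs %*% logL[, 2L] + (1 - configs) %*% logL[, 1L]
  ## collapse to weights by occupied count
  w <- vapply(0:n, function(s) {
    lz <- logLz[S == s]
    if (!length(lz)) return(-Inf)
    mx <- max(lz)
    if (!is.finite(mx)) return(-Inf)
    mx + log(sum(exp(lz - mx)))
  }, numeric(1))

  lpost <- vapply(grid, function(psi) {
    terms <- w + (0:n) * log(psi) + (n - (0:n)) * log1p(-psi)
    ## log(0)*0 at the boundary: define psi^0 = 1
    if (psi == 0) terms <- ifelse(0:n == 0, w, -Inf)
    if (psi == 1) terms <- ifelse(0:n == n, w, -Inf)
    mx <- max(terms)
    base <- if (is.finite(mx)) mx + log(sum(exp(terms - mx))) else -Inf
    base + stats::dbeta(psi, config@priorPsi[1], config@priorPsi[2],
                        log = TRUE)
  }, numeric(1))

  dens <- exp(lpost - max(lpost[is.finite(lpost)]))
  mass <- trapezoidMass(grid, dens)
  data.frame(psi = grid, mass = mass)
}

## Convert density values on a grid to normalised cell masses via the
## trapezoid rule (each point owns half of each adjacent interval).
trapezoidMass <- function(x, f) {
  k <- length(x)
  dx <- diff(x)
  w <- c(dx / 2, 0) + c(0, dx / 2)
  m <- f * w
  m / sum(m)
}
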