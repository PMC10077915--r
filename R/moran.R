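#' Moran's I spatial autocorrelation
#'
#' Global Moran's I,
#' `I = (n / W) * sum_ij(w_ij z_i z_j) / sum_i(z_i^2)` with `z` the centered
#' values and `W` the sum of all weights. Under no autocorrelation its
#' expectation is `-1/(n-1)`; the analytic p-value uses the normal
#' approximation with the randomization-assumption variance (which is what
#' a permutation test targets), and a Monte-Carlo permutation p-value is
#' available on request.
#'
#' @param values Numeric vector (non-constant).
#' @param coords Two-column matrix/data frame of coordinates (meters), used
#'   to build inverse-Euclidean-distance weights with zero self-weight;
#'   ignored when `W` is supplied.
#' @param scheme `"inverse_distance_row"` (inverse distance, rows
#'   standardized to sum 1; the default) or `"inverse_distance"` (raw
#'   inverse distance).
#' @param W Optional explicit weight matrix (diagonal ignored); overrides
#'   `coords`/`scheme`, and `scheme` is then reported as `"custom"`.
#' @param nperm Number of random permutations for a Monte-Carlo p-value
#'   (0 = none).
#' @param alternative `"two.sided"`, `"greater"` or `"less"`.
#' @return A list: `observed`, `expected`, `variance`, `sd`, `p_value`
#'   (analytic), `p_perm` (or `NA`), `scheme`.
#' @export
morans_i <- function(values, coords = NULL,
                     scheme = c("inverse_distance_row", "inverse_distance"),
                     W = NULL, nperm = 0,
                     alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  n <- length(values)
  if (n < 4) stop_beeniche("Moran's I needs at least 4 observations")
  if (stats::sd(values) == 0) stop_beeniche("constant values: Moran's I undefined")
  if (is.null(W)) {
    scheme <- match.arg(scheme)
    coords <- as.matrix(coords)
    if (nrow(coords) != n) stop_beeniche("coords must have one row per value")
    d <- as.matrix(stats::dist(coords))
    if (any(d[upper.tri(d)] == 0)) {
      stop_beeniche("duplicate coordinates: inverse-distance weights undefined")
    }
    W <- 1 / d
    diag(W) <- 0
    if (scheme == "inverse_distance_row") W <- W / rowSums(W)
  } else {
    scheme <- "custom"
    W <- as.matrix(W)
    diag(W) <- 0
  }
  z <- values - mean(values)
  s0 <- sum(W)
  obs <- (n / s0) * as.numeric(t(z) %*% W %*% z) / sum(z^2)
  expected <- -1 / (n - 1)
  s1 <- 0.5 * sum((W + t(W))^2)
  s2 <- sum((rowSums(W) + colSums(W))^2)
  b2 <- n * sum(z^4) / sum(z^2)^2 # sample kurtosis
  variance <- (n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
                 b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)) /
    ((n - 1) * (n - 2) * (n - 3) * s0^2) - expected^2
  zscore <- (obs - expected) / sqrt(variance)
  p_value <- switch(alternative,
    two.sided = 2 * stats::pnorm(abs(zscore), lower.tail = FALSE),
    greater = stats::pnorm(zscore, lower.tail = FALSE),
    less = stats::pnorm(zscore)
  )
  p_perm <- NA_real_
  if (nperm > 0) {
    denom_const <- n / s0
    perm_i <- vapply(seq_len(nperm), function(i) {
      zp <- z[sample.int(n)]
      denom_const * as.numeric(t(zp) %*% W %*% zp) / sum(zp^2)
    }, numeric(1))
    exceed <- switch(alternative,
      two.sided = sum(abs(perm_i - expected) >= abs(obs - expected)),
      greater = sum(perm_i >= obs),
      less = sum(perm_i <= obs)
    )
    p_perm <- (exceed + 1) / (nperm + 1)
  }
  list(observed = obs, expected = expected, variance = variance,
       sd = sqrt(variance), p_value = p_value, p_perm = p_perm,
       scheme = scheme)
}
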