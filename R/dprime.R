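#' Projection-based d-prime between two response clusters
#'
#' Measures how separable two clusters of d-dimensional responses are.
#' Both clouds are projected onto the line joining the cluster means; with
#' the higher projected mean labelled cluster 1, the index is
#' \deqn{d' = (\mu_1 - \mu_2) / \sqrt{(\sigma_1^2 + \sigma_2^2)/2}}
#' with sample (n-1) variances of the projected points, so d' >= 0 by
#' construction. In one dimension this reduces to the classic sensitivity
#' index |m_a - m_b| / sqrt((s_a^2 + s_b^2)/2).
#'
#' Identical cluster means give a degenerate projection direction and return
#' 0 (the information-free limit, which permutation nulls do hit). Distinct
#' means with both projected variances zero are an error: separability is
#' infinite and upstream data are degenerate.
#'
#' @param a,b Numeric matrices (observations x dimensions) or plain vectors
#'   for 1-D data; each cluster needs at least 2 points.
#' @return Non-negative scalar d'.
#' @examples
#' dprime(c(0, 2), c(4, 6))               # 4 / sqrt(2)
#' dprime(rbind(c(0, 0), c(0, 2)), rbind(c(3, 1), c(5, 1)))  # 4
#' @export
dprime <- function(a, b) {
  if (!is.matrix(a)) a <- matrix(a, ncol = 1L)
  if (!is.matrix(b)) b <- matrix(b, ncol = 1L)
  if (ncol(a) != ncol(b)) stop("clusters live in different dimensions")
  if (nrow(a) < 2L || nrow(b) < 2L) stop("each cluster needs >= 2 points")
  ma <- colMeans(a); mb <- colMeans(b)
  u <- ma - mb
  nu <- sqrt(sum(u * u))
  if (nu == 0) return(0)
  u <- u / nu
  pa <- as.vector(a %*% u)
  pb <- as.vector(b %*% u)
  # mean(pa) - mean(pb) = ||ma - mb|| > 0, so cluster a is cluster 1
  v1 <- stats::var(pa); v2 <- stats::var(pb)
  s2 <- (v1 + v2) / 2
  if (s2 == 0) stop("zero-variance clusters with distinct means")
  nu / sqrt(s2)
}

# Univariate d' for many (channel x bin) cells at once; means/vars are
# moments over the trial axis. Returns |dm| / sqrt((va + vb)/2) with NA
# where both variances vanish.
dprime_univariate_grid <- function(W, idx_a, idx_b) {
  na <- length(idx_a); nb <- length(idx_b)
  ma <- rowMeans(W[, idx_a, drop = FALSE])
  mb <- rowMeans(W[, idx_b, drop = FALSE])
  va <- (rowSums(W[, idx_a, drop = FALSE]^2) - na * ma^2) / (na - 1)
  vb <- (rowSums(W[, idx_b, drop = FALSE]^2) - nb * mb^2) / (nb - 1)
  s2 <- (pmax(va, 0) + pmax(vb, 0)) / 2
  out <- abs(ma - mb) / sqrt(s2)
  out[ma == mb] <- 0
  out
}
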