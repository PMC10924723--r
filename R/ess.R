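#' Effective sample size of an MCMC trace
#'
#' Autocorrelation-based ESS using Geyer's initial monotone positive
#' sequence estimator: autocovariances are summed in adjacent-lag pairs,
#' truncated at the first negative pair, and forced to be non-increasing.
#' A constant trace is reported as ESS 1.
#'
#' @param x Numeric trace (length >= 10).
#' @return Estimated effective sample size.
#' @export
#' @examples
#' effective_sample_size(rnorm(1000))
effective_sample_size <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 10) stop("trace must have length >= 10")
  if (!all(is.finite(x))) stop("trace contains non-finite values")
  if (stats::var(x) == 0) return(1)
  lag_max <- min(n - 2L, 10000L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  # pair sums Gamma_m = rho_{2m} + rho_{2m+1}
  n_pairs <- floor(length(rho) / 2)
  G <- rho[2 * seq_len(n_pairs) - 1] + rho[2 * seq_len(n_pairs)]
  neg <- which(G < 0)
  if (length(neg)) G <- G[seq_len(neg[1] - 1L)]
  if (length(G) > 1) G <- cummin(G)
  tau <- -1 + 2 * sum(G)
  tau <- max(tau, 1e-12)
  max(1, n / tau)
}
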