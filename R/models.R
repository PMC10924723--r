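#' GTR+G+I nucleotide substitution model parameters
#'
#' The rate matrix is built from the six exchangeabilities (order AC, AG, AT,
#' CG, CT, GT) and the stationary base frequencies, and is rescaled so that
#' the mean substitution rate at stationarity equals 1. Among-site rate
#' variation combines a proportion of invariant sites with gamma-distributed
#' rate multipliers (continuous on the simulation side, `n_categories`
#' discrete categories on the inference side).
#'
#' @param exchangeabilities Six positive GTR exchangeabilities.
#' @param base_freqs Four frequencies summing to 1.
#' @param gamma_shape Gamma shape `alpha` (> 0).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param n_categories Number of discrete gamma categories used in
#'   likelihood computations.
#' @return A `nuc_model` object.
#' @export
nuc_model <- function(exchangeabilities = c(1, 2, 1, 1, 4, 1),
                      base_freqs = c(0.30, 0.20, 0.25, 0.25),
                      gamma_shape = 0.5, p_inv = 0.2, n_categories = 4L) {
  stopifnot(length(exchangeabilities) == 6, all(exchangeabilities > 0),
            length(base_freqs) == 4, all(base_freqs > 0),
            abs(sum(base_freqs) - 1) < 1e-12,
            gamma_shape > 0, p_inv >= 0, p_inv < 1, n_categories >= 1)
  structure(list(exchangeabilities = exchangeabilities,
                 base_freqs = base_freqs, gamma_shape = gamma_shape,
                 p_inv = p_inv, n_categories = as.integer(n_categories),
                 k = 4L, states = c("A", "C", "G", "T")),
            class = c("nuc_model", "subst_model"))
}

#' Mk morphological substitution model parameters
#'
#' Symmetric k-state Markov model with equal off-diagonal rates, rescaled to
#' mean rate 1, with gamma-distributed among-character rate multipliers
#' (shape `char_rate_shape`, mean 1).
#'
#' @param k_states Number of states (>= 2).
#' @param char_rate_shape Gamma shape of among-character rate multipliers.
#' @param n_categories Discrete gamma categories on the inference side.
#' @return A `morph_model` object.
#' @export
morph_model <- function(k_states = 2L, char_rate_shape = 1.39,
                        n_categories = 4L) {
  stopifnot(k_states >= 2, char_rate_shape > 0, n_categories >= 1)
  k <- as.integer(k_states)
  structure(list(k = k, char_rate_shape = char_rate_shape,
                 p_inv = 0, gamma_shape = char_rate_shape,
                 n_categories = as.integer(n_categories),
                 states = as.character(seq_len(k) - 1L)),
            class = c("morph_model", "subst_model"))
}

# Eigendecomposition of a reversible rate matrix via symmetrization.
# Returns U, Uinv, lambda with Q = U diag(lambda) Uinv and P(t) = U e^{L t} Uinv.
# The matrix is normalized so -sum(pi_i Q_ii) = 1.
rev_eigen <- function(exch, freqs) {
  k <- length(freqs)
  Q <- matrix(0, k, k)
  Q[lower.tri(Q)] <- exch
  Q <- Q + t(Q)
  Q <- Q * rep(freqs, each = k)   # Q_ij = s_ij * pi_j
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  d <- sqrt(freqs)
  B <- Q * (d %o% (1 / d))        # D^1/2 Q D^-1/2, symmetric
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, Uinv = t(e$vectors) * rep(d, each = k),
       lambda = e$values, pi = freqs, Q = Q)
}

model_eigen <- function(model) {
  if (inherits(model, "nuc_model")) {
    rev_eigen(model$exchangeabilities, model$base_freqs)
  } else {
    k <- model$k
    rev_eigen(rep(1, k * (k - 1) / 2), rep(1 / k, k))
  }
}

# Discrete gamma rate categories (mean of each quantile section; Yang 1994),
# with mean exactly renormalized to 1.
discrete_gamma <- function(shape, k) {
  if (k == 1L) return(1)
  q <- stats::qgamma(seq_len(k - 1) / k, shape = shape, rate = shape)
  bounds <- c(0, q, Inf)
  p_up <- stats::pgamma(bounds, shape = shape + 1, rate = shape)
  r <- k * diff(p_up)
  r / mean(r)
}
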