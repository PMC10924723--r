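# Simulate discrete states down a phylogram given a reversible model.
# `site_rates` is one non-negative multiplier per column; states are evolved
# with transition probabilities P(b * r) computed from the eigendecomposition.
# Returns an n_tip x L integer matrix of states in 1..k, rownames = tip labels.
evolve_states <- function(phy, eig, site_rates, root_probs) {
  k <- length(eig$pi)
  L <- length(site_rates)
  n_tip <- ape::Ntip(phy)
  n_node <- n_tip + phy$Nnode
  ord <- ape::reorder.phylo(phy, "postorder")
  edges <- ord$edge[rev(seq_len(nrow(ord$edge))), , drop = FALSE]  # preorder
  elen <- ord$edge.length[rev(seq_len(nrow(ord$edge)))]
  root <- edges[1L, 1L]
  states <- matrix(NA_integer_, n_node, L)
  states[root, ] <- sample.int(k, L, replace = TRUE, prob = root_probs)
  cum_mat <- upper.tri(matrix(0, k, k), diag = TRUE) * 1
  for (e in seq_len(nrow(edges))) {
    par <- edges[e, 1L]; ch <- edges[e, 2L]
    ps <- states[par, ]
    cs <- integer(L)
    Eb <- exp(outer(site_rates * elen[e], eig$lambda))  # L x k
    for (x in unique(ps)) {
      idx <- which(ps == x)
      P <- (Eb[idx, , drop = FALSE] *
              matrix(eig$U[x, ], length(idx), k, byrow = TRUE)) %*% eig$Uinv
      P[P < 0] <- 0
      P <- P / rowSums(P)
      u <- stats::runif(length(idx))
      cum <- P %*% cum_mat
      cs[idx] <- 1L + as.integer(rowSums(cum < u))
    }
    states[ch, ] <- cs
  }
  out <- states[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Simulate a nucleotide alignment on a phylogram
#'
#' Root states are drawn from the stationary base frequencies. Each site gets
#' a rate multiplier that is 0 with probability `p_inv` and otherwise drawn
#' from a continuous gamma distribution with shape `gamma_shape` and mean 1.
#' States evolve down each branch with GTR transition probabilities computed
#' by matrix exponentiation; columns are independent.
#'
#' @param phy A `phylo` phylogram (branch lengths in substitutions/site).
#' @param model A [nuc_model()].
#' @param L Number of sites (default 1000).
#' @param seed Integer seed or `NULL`.
#' @return Character matrix (`n_taxa` x `L`) of states `A`/`C`/`G`/`T` with
#'   tip labels as rownames (plain matrix).
#' @export
simulate_alignment <- function(phy, model = nuc_model(), L = 1000L,
                               seed = NULL) {
  stopifnot(inherits(model, "nuc_model"), L >= 1)
  eig <- model_eigen(model)
  with_seed(seed, {
    inv <- stats::runif(L) < model$p_inv
    rates <- ifelse(inv, 0,
                    stats::rgamma(L, shape = model$gamma_shape,
                                  rate = model$gamma_shape))
    idx <- evolve_states(phy, eig, rates, model$base_freqs)
    out <- matrix(model$states[idx], nrow(idx), ncol(idx),
                  dimnames = list(rownames(idx), NULL))

    out
  })
}

#' Simulate a morphological character matrix on a phylogram
#'
#' Each character receives an i.i.d. gamma(shape = `char_rate_shape`,
#' mean 1) rate multiplier; the root state is uniform over the k states and
#' evolution follows the symmetric Mk model. Invariant characters are kept
#' (no ascertainment filtering).
#'
#' @param phy A `phylo` phylogram (branch lengths in changes/character).
#' @param model A [morph_model()].
#' @param n_chars Number of characters.
#' @param seed Integer seed or `NULL`.
#' @return Integer matrix (`n_taxa` x `n_chars`) of states in `0..k-1` with
#'   tip labels as rownames (plain matrix).
#' @export
simulate_characters <- function(phy, model = morph_model(), n_chars = 100L,
                                seed = NULL) {
  stopifnot(inherits(model, "morph_model"), n_chars >= 1)
  eig <- model_eigen(model)
  with_seed(seed, {
    rates <- stats::rgamma(n_chars, shape = model$char_rate_shape,
                           rate = model$char_rate_shape)
    idx <- evolve_states(phy, eig, rates, rep(1 / model$k, model$k))
    out <- idx - 1L

    out
  })
}

#' Mask cells of a character matrix as missing
#'
#' Replaces `round(fraction * n_cells)` uniformly chosen cells with `NA`
#' (missing-completely-at-random), emulating the missing-data burden typical
#' of empirical morphological matrices (about 33%).
#'
#' @param m A character matrix from [simulate_characters()].
#' @param fraction Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed or `NULL`.
#' @return The masked matrix.
#' @export
mask_missing <- function(m, fraction = 0.33, seed = NULL) {
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1)
    stop("`fraction` must be in [0, 1)")
  n_mask <- round(fraction * length(m))
  if (n_mask == 0) return(m)
  with_seed(seed, {
    m[sample.int(length(m), n_mask)] <- NA
    m
  })
}
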