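# Independent oracles used across the suite. These deliberately avoid the
# package's pruning/optimization code paths: likelihoods are computed by
# exhaustive enumeration over internal-node states, distances by closed
# forms, and null distributions by explicit enumeration.

# Exhaustive-enumeration log-likelihood (any <=5-taxon tree, few sites).
# Shares only the eigendecomposition/discrete-gamma helpers with the
# package; the sum over histories is naive.
oracle_loglik <- function(tree, el, data, model) {
  eig <- ratelink:::model_eigen(model)
  crates <- ratelink:::discrete_gamma(model$gamma_shape, model$n_categories)
  k <- model$k
  n <- ape::Ntip(tree)
  edge <- tree$edge
  nnode <- max(edge)
  internals <- setdiff(unique(as.vector(edge)), seq_len(n))
  root <- setdiff(edge[, 1], edge[, 2])[1]
  Pm <- function(t) {
    P <- eig$U %*% diag(exp(eig$lambda * t)) %*% eig$Uinv
    pmax(P, 0)
  }
  states_int <- ratelink:::data_to_int(data, model)[tree$tip.label, ,
                                                   drop = FALSE]
  combs <- as.matrix(expand.grid(rep(list(seq_len(k)), length(internals))))
  ll <- 0
  for (site in seq_len(ncol(states_int))) {
    tipst <- states_int[, site]
    cat_lik <- numeric(length(crates))
    for (ci in seq_along(crates)) {
      Ps <- lapply(seq_len(nrow(edge)), function(e) Pm(el[e] * crates[ci]))
      total <- 0
      for (r in seq_len(nrow(combs))) {
        st <- integer(nnode)
        st[internals] <- combs[r, ]
        prob <- eig$pi[st[root]]
        for (e in seq_len(nrow(edge))) {
          par <- st[edge[e, 1]]
          ch <- edge[e, 2]
          if (ch <= n) {
            s <- tipst[ch]
            if (s >= 0) prob <- prob * Ps[[e]][par, s + 1]
            # missing tip: sum over states of a stochastic row = 1
          } else {
            prob <- prob * Ps[[e]][par, st[ch]]
          }
        }
        total <- total + prob
      }
      cat_lik[ci] <- total
    }
    site_lik <- mean(cat_lik)
    if (model$p_inv > 0) {
      ok <- vapply(seq_len(k), function(s) all(tipst < 0 | tipst == s - 1),
                   logical(1))
      site_lik <- (1 - model$p_inv) * site_lik +
        model$p_inv * sum(eig$pi[ok])
    }
    ll <- ll + log(site_lik)
  }
  ll
}

# Closed-form Jukes-Cantor expected mismatch proportion for distance d
jc_mismatch <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Closed-form JC distance estimator from a mismatch proportion
jc_distance <- function(p) -0.75 * log(1 - 4 * p / 3)

# Closed-form 2-state Mk expected mismatch for branch-length sum d
mk2_mismatch <- function(d) (1 - exp(-2 * d)) / 2

# Quick fixtures -------------------------------------------------------

fixture_pair <- function(n_taxa = 8, sigma = 0.75, coupled = TRUE,
                         seed = 1, n_chars = 20, L = 200, k = 2) {
  spec <- scenario_spec(n_taxa, n_chars, k, sigma, coupled,
                        seq_length = L, master_seed = seed)
  pair <- generate_scenario_pair(spec)
  pair$aln <- simulate_alignment(pair$mol_phylogram, nuc_model(), L,
                                 seed = seed + 1000)
  pair$chars <- simulate_characters(pair$morph_phylogram, morph_model(k),
                                    n_chars, seed = seed + 2000)
  pair
}
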