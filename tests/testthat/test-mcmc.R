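test_that("ESS estimator matches closed-form oracles", {
  set.seed(91)
  # i.i.d. draws: ESS ~ n
  x <- stats::rnorm(1e4)
  expect_lt(abs(effective_sample_size(x) - 1e4) / 1e4, 0.15)
  # constant trace
  expect_equal(effective_sample_size(rep(3.3, 100)), 1)
  # AR(1), phi = 0.5: ESS ~ n (1 - phi) / (1 + phi)
  n <- 1e5; phi <- 0.5
  ar <- stats::filter(stats::rnorm(n), phi, method = "recursive")
  ess <- effective_sample_size(as.numeric(ar))
  expect_lt(abs(ess - n * (1 - phi) / (1 + phi)) /
              (n * (1 - phi) / (1 + phi)), 0.15)
  expect_error(effective_sample_size(1:5), "length")
})

test_that("prior-only MCMC recovers the prior moments", {
  tr <- simulate_chronogram(6, seed = 1)
  st <- mcmc_settings(chain_length = 4e4, n_chains = 2, thin = 10, seed = 7)
  post <- run_mcmc(tr, NULL, NULL, clock_model_spec("lognormal", "unlinked"),
                   st, likelihood_on = FALSE)
  pooled <- do.call(rbind, lapply(post$chains, function(m)
    m[-seq_len(floor(nrow(m) * 0.1)), , drop = FALSE]))
  mcse <- function(x) stats::sd(x) / sqrt(effective_sample_size(x))
  # log mu ~ N(log 1e-3, 3)
  lm <- log(pooled[, "mu.mol"])
  expect_lt(abs(mean(lm) - log(1e-3)), 3 * mcse(lm))
  # sigma ~ Exp(1): mean 1
  s <- pooled[, "sigma.morph"]
  expect_lt(abs(mean(s) - 1), 3 * mcse(s))
  # log multiplier: E[log m] = E[-sigma^2/2] = -1 under sigma ~ Exp(1)
  # (the raw multiplier mean is too heavy-tailed for a stable CLT check)
  m1 <- log(pooled[, paste0("rate.mol.", post$branch_ids[1])] /
              pooled[, "mu.mol"])
  expect_lt(abs(mean(m1) - (-1)), 3 * mcse(m1))
  # fixed-sigma run: log multipliers ~ N(-sigma^2/2, sigma)
  st2 <- mcmc_settings(chain_length = 2e4, n_chains = 1, thin = 5, seed = 8)
  post2 <- run_mcmc(tr, NULL, NULL,
                    clock_model_spec("lognormal", "unlinked"), st2,
                    likelihood_on = FALSE,
                    fixed = list(sigma = c(mol = 0.75)))
  ch <- post2$chains[[1]]
  ch <- ch[-seq_len(floor(nrow(ch) * 0.1)), ]
  lmul <- log(ch[, paste0("rate.mol.", post2$branch_ids[2])] /
                ch[, "mu.mol"])
  expect_lt(abs(mean(lmul) - (-0.75^2 / 2)), 3 * mcse(lmul))
  expect_lt(abs(stats::sd(lmul) - 0.75), 3 * mcse(lmul))
})

test_that("MCMC posterior matches fine-grid quadrature on a 3-taxon toy", {
  # one free branch-rate multiplier, all other parameters pinned
  tr <- load_chronogram("((A:50,B:50):50,C:100);")
  nm <- nuc_model(p_inv = 0.1)
  phy <- tr; phy$edge.length <- tr$edge.length * 1e-3
  aln <- simulate_alignment(phy, nm, 300, seed = 5)
  po <- ratelink:::postorder_tree(tr)
  ne <- nrow(tr$edge)
  free_edge <- which(po$tree$edge[, 2] == which(tr$tip.label == "A"))
  fx <- rep(1, ne); fx[free_edge] <- NA
  sig0 <- 0.8
  st <- mcmc_settings(chain_length = 1.2e5, n_chains = 2, thin = 20,
                      seed = 3)
  post <- run_mcmc(tr, aln, NULL, clock_model_spec("lognormal", "unlinked"),
                   st, nuc_mod = nm,
                   fixed = list(mu = c(mol = 1e-3), sigma = c(mol = sig0),
                                mult = list(mol = fx)))
  id <- post$branch_ids[free_edge]
  pooled <- do.call(rbind, lapply(post$chains, function(m)
    m[-seq_len(floor(nrow(m) * 0.1)), , drop = FALSE]))
  msamp <- pooled[, paste0("rate.mol.", id)] / 1e-3
  dur <- post$durations[id]
  grid <- seq(1e-4, 8, length.out = 2000)
  ll_g <- vapply(grid, function(m) {
    el <- tr$edge.length * 1e-3
    el[po$perm[free_edge]] <- dur * 1e-3 * m
    nucleotide_loglik(tr, el, aln, nm)
  }, numeric(1))
  lp <- ll_g + stats::dnorm(log(grid), -sig0^2 / 2, sig0, log = TRUE) -
    log(grid)
  w <- exp(lp - max(lp))
  cdf <- cumsum(w) / sum(w)
  sup <- max(abs(stats::ecdf(msamp)(grid) - cdf))
  expect_lt(sup, 0.02)
})

test_that("branch-rate summaries equal naive pooled recomputation", {
  tr <- simulate_chronogram(5, seed = 2)
  st <- mcmc_settings(chain_length = 2000, n_chains = 2, thin = 10,
                      seed = 11)
  post <- run_mcmc(tr, NULL, NULL, clock_model_spec("lognormal", "unlinked"),
                   st, likelihood_on = FALSE)
  summ <- summarize_branch_rates(post, burnin_fraction = 0.1)
  id <- post$branch_ids[3]
  naive <- unlist(lapply(post$chains, function(m) {
    m[-seq_len(floor(nrow(m) * 0.1)), paste0("rate.mol.", id)]
  }))
  row <- summ$mol[summ$mol$branch == id, ]
  expect_equal(row$mean, mean(naive))
  expect_equal(row$median, stats::median(naive))
  # trivial trace arithmetic
  x <- c(1, 2, 3, 4)
  expect_equal(mean(x), 2.5)
  expect_equal(stats::median(x), 2.5)
})

test_that("exponential clock has unit-mean multipliers and no sigma", {
  tr <- simulate_chronogram(5, seed = 6)
  st <- mcmc_settings(chain_length = 2e4, n_chains = 1, thin = 5, seed = 9)
  post <- run_mcmc(tr, NULL, NULL,
                   clock_model_spec("exponential", "unlinked"), st,
                   likelihood_on = FALSE)
  ch <- post$chains[[1]]
  expect_false(any(grepl("^sigma", colnames(ch))))
  m <- ch[-seq_len(2e2), paste0("rate.mol.", post$branch_ids[1])] /
    ch[-seq_len(2e2), "mu.mol"]
  mcse <- stats::sd(m) / sqrt(effective_sample_size(m))
  expect_lt(abs(mean(m) - 1), 3 * mcse)   # Exp(1): mean 1, cv 1
  expect_lt(abs(stats::sd(m) - 1), 4 * mcse)
})

test_that("trace files round-trip through the TSV writer", {
  tr <- simulate_chronogram(4, seed = 8)
  st <- mcmc_settings(chain_length = 1000, n_chains = 2, thin = 10,
                      seed = 10)
  post <- run_mcmc(tr, NULL, NULL, settings = st, likelihood_on = FALSE)
  tmp <- withr::local_tempdir()
  files <- write_traces(post, file.path(tmp, "run"))
  expect_length(files, 2 + 2)   # two chains + two partitions
  back <- utils::read.table(files[1], header = TRUE, sep = "\t",
                            check.names = FALSE)
  expect_equal(nrow(back), nrow(post$chains[[1]]))
  expect_equal(back[["mu.mol"]], unname(post$chains[[1]][, "mu.mol"]))
})

test_that("MCMC is deterministic given the seed and flags low ESS", {
  tr <- simulate_chronogram(4, seed = 3)
  phy <- build_phylogram(tr, rep(1e-3, nrow(tr$edge)))
  aln <- simulate_alignment(phy, nuc_model(), 100, seed = 4)
  st <- mcmc_settings(chain_length = 2000, n_chains = 1, thin = 10,
                      seed = 5)
  p1 <- run_mcmc(tr, aln, NULL, settings = st)
  p2 <- run_mcmc(tr, aln, NULL, settings = st)
  expect_identical(p1$chains[[1]], p2$chains[[1]])
  # a 2000-step chain cannot reach ESS 200 on everything: flag, not fail
  expect_true(length(p1$flagged) >= 0)
  expect_true(all(p1$chains[[1]][, grep("^rate", colnames(p1$chains[[1]]))]
                  > 0))
})
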