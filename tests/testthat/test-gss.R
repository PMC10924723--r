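test_that("a flat likelihood gives log-ML zero for any ladder", {
  res <- gss_ml_generic(function(th) 0,
                        function(th) stats::dnorm(th[1], log = TRUE),
                        ref_mean = 0, ref_sd = 1,
                        n_steps = 5, chain_length = 1500, seed = 3)
  expect_equal(res$log_ml, 0, tolerance = 1e-9)
  expect_equal(res$log_ml, sum(res$contributions))
})

test_that("GSS matches the conjugate normal-normal marginal likelihood", {
  set.seed(4)
  m0 <- 0; s0 <- 2; s <- 1; n <- 20
  x <- stats::rnorm(n, 1.3, s)
  loglik <- function(th) sum(stats::dnorm(x, th[1], s, log = TRUE))
  logprior <- function(th) stats::dnorm(th[1], m0, s0, log = TRUE)
  Sig <- diag(s^2, n) + s0^2
  exact <- as.numeric(-0.5 * (n * log(2 * pi) +
                                determinant(Sig)$modulus +
                                t(x - m0) %*% solve(Sig) %*% (x - m0)))
  v_post <- 1 / (1 / s0^2 + n / s^2)
  post_mean <- v_post * (m0 / s0^2 + sum(x) / s^2)
  # deliberately imperfect reference (inflated sd) so every rung works
  res <- gss_ml_generic(loglik, logprior, ref_mean = post_mean + 0.2,
                        ref_sd = sqrt(v_post) * 1.6,
                        n_steps = 8, chain_length = 5000, seed = 2)
  expect_lt(abs(res$log_ml - exact), max(3 * res$se, 0.05))
  # doubling the chain length must not shift the estimate materially
  res2 <- gss_ml_generic(loglik, logprior, ref_mean = post_mean + 0.2,
                         ref_sd = sqrt(v_post) * 1.6,
                         n_steps = 8, chain_length = 10000, seed = 5)
  expect_lt(abs(res2$log_ml - res$log_ml),
            max(3 * sqrt(res$se^2 + res2$se^2), 0.05))
})

test_that("GSS matches quadrature on a one-parameter Mk toy", {
  # single branch, binary characters; parameter = log branch length with
  # lognormal prior; oracle = trapezoid quadrature over the length
  tr <- load_chronogram("(A:1,B:1);")
  mm <- morph_model(2, char_rate_shape = 1e9)
  truephy <- tr; truephy$edge.length <- c(0.15, 0.15)
  ch <- simulate_characters(truephy, mm, 150, seed = 6)
  loglik <- function(th) {
    d <- exp(th[1])
    morphology_loglik(tr, c(d / 2, d / 2), ch, mm)
  }
  logprior <- function(th) stats::dnorm(th[1], log(0.3), 1, log = TRUE)
  grid <- seq(-8, 3, length.out = 3000)
  lg <- vapply(grid, function(g) loglik(g) + logprior(g), numeric(1))
  h <- diff(grid)[1]
  exact <- log(sum(exp(lg - max(lg))) * h) + max(lg)
  res <- gss_ml_generic(loglik, logprior, ref_mean = log(0.3), ref_sd = 0.8,
                        n_steps = 8, chain_length = 4000, seed = 7)
  expect_lt(abs(res$log_ml - exact), max(3 * res$se, 0.05))
})

test_that("a degenerate reference is rejected with advice", {
  expect_error(gss_ml_generic(function(th) 0, function(th) 0,
                              ref_mean = 0, ref_sd = 0),
               "pilot")
})

test_that("bayes_factor applies the threshold rule and antisymmetry", {
  bf <- bayes_factor(-100, -103)
  expect_equal(bf$log_bf, 3)
  expect_equal(bf$decision, "linked")
  expect_equal(bayes_factor(-103, -100)$log_bf, -3)
  expect_equal(bayes_factor(-103, -100)$decision, "unlinked")
  expect_equal(bayes_factor(-5, -5)$decision, "indeterminate")
  # boundary is strict
  expect_false(bayes_modelsel_test(1.0)$detected)
  expect_true(bayes_modelsel_test(41.1)$detected)
  expect_false(bayes_modelsel_test(-5)$detected)
})

test_that("phylogenetic GSS prefers the generating linkage on toy data", {
  # tiny smoke check of the full pipeline; scaled far below desk defaults
  pair <- fixture_pair(n_taxa = 5, sigma = 0.75, coupled = TRUE, seed = 9,
                       n_chars = 40, L = 120)
  ps <- mcmc_settings(chain_length = 6000, n_chains = 1, thin = 10,
                      seed = 21)
  ml_l <- gss_logml(pair$chronogram, pair$aln, pair$chars,
                    clock_model_spec("lognormal", "linked"),
                    n_steps = 4, chain_length = 2500, seed = 31,
                    pilot_settings = ps)
  ml_u <- gss_logml(pair$chronogram, pair$aln, pair$chars,
                    clock_model_spec("lognormal", "unlinked"),
                    n_steps = 4, chain_length = 2500, seed = 32,
                    pilot_settings = ps)
  expect_true(is.finite(ml_l$log_ml) && is.finite(ml_u$log_ml))
  bf <- bayes_factor(ml_l, ml_u)
  expect_true(is.finite(bf$log_bf))
})
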