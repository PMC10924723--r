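test_that("sigma = 0 gives every branch exactly the mean rate", {
  tr <- simulate_chronogram(10, seed = 1)
  ra <- draw_branch_rates(tr, clock_spec("lognormal", 9.65e-4, 0), seed = 1)
  expect_equal(unname(ra$rates), rep(9.65e-4, nrow(tr$edge)))
})

test_that("lognormal rate draws have expectation mu and log-sd sigma", {
  # Monte-Carlo oracle: 1e5 draws, within 3 SE of stated moments
  mu <- 9.65e-4; sigma <- 1.25
  tr <- simulate_chronogram(3, seed = 2)
  n_draw <- ceiling(1e5 / nrow(tr$edge))
  draws <- unlist(lapply(seq_len(n_draw), function(i)
    draw_branch_rates(tr, clock_spec("lognormal", mu, sigma),
                      seed = 1000 + i)$rates))
  se_mean <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - mu), 3 * se_mean)
  lsd <- stats::sd(log(draws))
  se_lsd <- lsd / sqrt(2 * (length(draws) - 1))
  expect_lt(abs(lsd - sigma), 3 * se_lsd)
})

test_that("phylogram branch lengths are duration times rate", {
  tr <- simulate_chronogram(8, seed = 3)
  ones <- rep(1, nrow(tr$edge))
  expect_equal(build_phylogram(tr, ones)$edge.length, tr$edge.length)
  tr2 <- load_chronogram("(A:10,B:10);")
  phy <- build_phylogram(tr2, c(2e-3, 2e-3))
  expect_equal(phy$edge.length, c(0.02, 0.02))
  expect_error(build_phylogram(tr, ones[-1]), "every branch")
})

test_that("mean total phylogram length matches mu x total duration", {
  # Monte-Carlo oracle over replicate rate draws
  tr <- simulate_chronogram(8, seed = 4)
  mu <- 9.65e-4
  cl <- clock_spec("lognormal", mu, 0.75)
  tot <- vapply(1:2000, function(i)
    sum(build_phylogram(tr, draw_branch_rates(tr, cl,
                                              seed = i))$edge.length),
    numeric(1))
  expected <- mu * sum(tr$edge.length)
  se <- stats::sd(tot) / sqrt(length(tot))
  expect_lt(abs(mean(tot) - expected), 3 * se)
})

test_that("coupling scales every branch by the same factor", {
  tr <- simulate_chronogram(10, seed = 5)
  phy <- build_phylogram(tr, draw_branch_rates(
    tr, clock_spec("lognormal", 9.65e-4, 0.75), seed = 6))
  morph <- couple_morph_phylogram(phy, 1.90)
  ratio <- morph$edge.length / phy$edge.length
  expect_equal(ratio, rep(1.90, length(ratio)), tolerance = 1e-12)
  expect_equal(couple_morph_phylogram(phy, 1)$edge.length, phy$edge.length)
  expect_equal(stats::cor(morph$edge.length, phy$edge.length,
                          method = "spearman"), 1)
  # default factor equals the rounded ratio of the two default mean rates
  expect_equal(formals(couple_morph_phylogram)$scale_factor,
               round(1.83e-3 / 9.65e-4, 2))
})

test_that("scenario pairs honour the coupling contract", {
  sp_c <- scenario_spec(8, 20, 2, 0.75, coupled = TRUE, master_seed = 9)
  pc <- generate_scenario_pair(sp_c)
  ratio <- pc$morph_phylogram$edge.length / pc$mol_phylogram$edge.length
  expect_equal(ratio, rep(1.90, length(ratio)), tolerance = 1e-12)

  sp_u <- scenario_spec(8, 20, 2, 0.75, coupled = FALSE, master_seed = 9)
  pu <- generate_scenario_pair(sp_u)
  expect_false(isTRUE(all.equal(
    pu$morph_phylogram$edge.length / pu$mol_phylogram$edge.length,
    rep(1.90, length(ratio)))))
  # same chronogram underneath
  expect_equal(pc$chronogram$edge.length, pu$chronogram$edge.length)
})

test_that("uncoupled scenario log rates are uncorrelated on average", {
  # independence Monte-Carlo oracle (reduced from 1e3 to 400 pairs for
  # runtime; the 3-SE criterion is unchanged)
  cors <- vapply(1:400, function(r) {
    sp <- scenario_spec(8, 10, 2, 0.75, coupled = FALSE, master_seed = 77,
                        replicate_id = r)
    p <- generate_scenario_pair(sp)
    stats::cor(log(p$true_rates_mol$rates), log(p$true_rates_morph$rates))
  }, numeric(1))
  se <- stats::sd(cors) / sqrt(length(cors))
  expect_lt(abs(mean(cors)), 3 * se)
})

test_that("scenario generation is bitwise reproducible", {
  sp <- scenario_spec(10, 20, 4, 1.25, TRUE, master_seed = 42,
                      replicate_id = 3)
  p1 <- generate_scenario_pair(sp)
  p2 <- generate_scenario_pair(sp)
  expect_identical(p1$mol_phylogram$edge.length,
                   p2$mol_phylogram$edge.length)
  a1 <- simulate_alignment(p1$mol_phylogram, nuc_model(), 100, seed = 5)
  a2 <- simulate_alignment(p2$mol_phylogram, nuc_model(), 100, seed = 5)
  expect_identical(a1, a2)
})
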