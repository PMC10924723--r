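test_that("spearman utility matches hand computations and enumeration", {
  sp <- spearman_test(1:4, c(2, 1, 4, 3))
  expect_equal(sp$rho, 0.6)                      # 1 - 6*4/(4*15)
  expect_equal(spearman_test(1:5, (1:5)^2)$rho, 1)
  # exact p for n = 5 equals brute force over all 120 permutations
  x <- c(0.3, 1.2, -0.5, 2.0, 0.9)
  y <- c(1.0, 0.4, 0.2, 1.8, 2.2)
  sp5 <- spearman_test(x, y)
  expect_true(sp5$exact)
  perms <- ratelink:::all_permutations(5)
  rx <- rank(x); ry <- rank(y)
  rho_all <- apply(perms, 1, function(p) stats::cor(rx, ry[p]))
  rho_obs <- stats::cor(rx, ry)
  expect_equal(sp5$p_two_sided,
               mean(abs(rho_all) >= abs(rho_obs) - 1e-12))
  expect_equal(sp5$p_one_sided, mean(rho_all >= rho_obs - 1e-12))
  # zero-variance ranks are flagged
  expect_true(spearman_test(rep(1, 4), 1:4)$degenerate)
})

test_that("root-to-tip test: perfect coupling gives r = 1, p = 1/(B+1)", {
  pair <- fixture_pair(n_taxa = 10, seed = 101)
  mol <- pair$mol_phylogram
  morph <- couple_morph_phylogram(mol, 1.90)
  res <- root_to_tip_test(mol, morph, n_perm = 999, seed = 1)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_equal(res$p_value, 1 / 1000)
  expect_true(res$detected)
  expect_equal(res$n_points, 10)
})

test_that("permutation p matches exhaustive enumeration on 5 tips", {
  pair <- fixture_pair(n_taxa = 5, coupled = FALSE, seed = 103)
  mol <- pair$mol_phylogram; morph <- pair$morph_phylogram
  rtt <- function(phy) {
    d <- ape::node.depth.edgelength(phy)[seq_len(5)]
    stats::setNames(d, phy$tip.label)
  }
  x <- rtt(mol); y <- rtt(morph)[names(rtt(mol))]
  r_obs <- stats::cor(x, y)
  perms <- ratelink:::all_permutations(5)
  r_all <- apply(perms, 1, function(p) stats::cor(x, y[p]))
  p_exact <- mean(r_all >= r_obs - 1e-12)
  # with many random permutations the MC p converges to the exact one
  res <- root_to_tip_test(mol, morph, n_perm = 40000, seed = 2)
  expect_lt(abs(res$p_value - p_exact), 0.012)
})

test_that("outlier removal drops extreme tips and can refuse the test", {
  pair <- fixture_pair(n_taxa = 12, seed = 104)
  mol <- pair$mol_phylogram
  morph <- couple_morph_phylogram(mol, 1.9)
  # inflate one tip's root-to-tip distance far outside 1.5 IQR
  tipedge <- which(mol$edge[, 2] == 1L)
  mol$edge.length[tipedge] <- mol$edge.length[tipedge] + 50
  morph$edge.length[tipedge] <- morph$edge.length[tipedge] + 95
  res <- root_to_tip_test(mol, morph, n_perm = 99, seed = 3,
                          remove_outliers = TRUE)
  expect_equal(res$n_points, 11)
  tiny <- load_chronogram("((A:1,B:1):1,C:2);")
  expect_error(root_to_tip_test(ape::unroot(tiny), tiny, n_perm = 9),
               "rooted")
})

test_that("sister pairs are the cherries, disjoint by construction", {
  expect_equal(nrow(extract_sister_pairs(load_chronogram("(A:1,B:1);"))), 1)
  bal8 <- ape::stree(8, "balanced"); bal8$edge.length <- rep(1, nrow(bal8$edge))
  expect_equal(nrow(extract_sister_pairs(bal8)), 4)
  cat7 <- ape::stree(7, "left"); cat7$edge.length <- rep(1, nrow(cat7$edge))
  expect_equal(nrow(extract_sister_pairs(cat7)), 1)
  pairs <- extract_sister_pairs(bal8)
  expect_equal(anyDuplicated(c(pairs$tip1, pairs$tip2)), 0)
})

test_that("sister-pairs contrasts detect proportional branch lengths", {
  pair <- fixture_pair(n_taxa = 16, seed = 105)
  mol <- pair$mol_phylogram
  morph <- couple_morph_phylogram(mol, 2.7)
  res <- sister_pairs_test(pair$chronogram, mol, morph)
  expect_equal(res$statistic, 1, tolerance = 1e-12)
  expect_true(res$detected)
  expect_equal(res$n_points,
               nrow(extract_sister_pairs(pair$chronogram)))
  tiny <- load_chronogram("((A:1,B:1):1,C:2);")
  expect_error(sister_pairs_test(tiny, tiny, tiny), "refused|fewer")
})

test_that("hand-worked three-cherry contrast example gives rho 1", {
  # molecular contrasts {0.2, -0.1, 0.5}, morphological {0.4, -0.2, 1.0}:
  # identical rank order, rho = 1; build trees realizing those contrasts
  chrono <- load_chronogram(
    "((A:1,B:1):3,((C:1,D:1):1,(E:1,F:1):1):2);")
  expect_error(assert_chronogram(chrono), NA)
  mk_phy <- function(contrasts) {
    # cherry tips get lengths exp(c * sqrt(t)) and 1 (t = 1 Myr here)
    phy <- chrono
    pairs <- extract_sister_pairs(chrono)
    phy$edge.length[] <- 1
    for (i in seq_len(nrow(pairs))) {
      e1 <- which(chrono$edge[, 2] ==
                    which(chrono$tip.label == pairs$tip1[i]))
      phy$edge.length[e1] <- exp(contrasts[i])
    }
    phy
  }
  mol <- mk_phy(c(0.2, -0.1, 0.5))
  morph <- mk_phy(c(0.4, -0.2, 1.0))
  res <- sister_pairs_test(chrono, mol, morph, epsilon = 0)
  expect_equal(res$statistic, 1)
})

test_that("bayes branch-rate test counts, drops, and decides", {
  mk_summary <- function(rates, dur) {
    data.frame(branch = paste0("b", seq_along(rates)), duration = dur,
               mean = rates, median = rates)
  }
  set.seed(8)
  dur <- stats::runif(20, 1, 50)
  r <- stats::rlnorm(20)
  s_mol <- mk_summary(r, dur)
  s_morph <- mk_summary(r, dur)       # identical rates: rho 1, detected
  res <- bayes_branchrate_test(s_mol, s_morph, "median")
  expect_equal(res$statistic, 1)
  expect_true(res$detected)
  res2 <- bayes_branchrate_test(s_mol, s_morph, "mean",
                                drop_shortest_fraction = 0.5)
  expect_equal(res2$n_points, 10)
  # dropped branches are the chronologically shortest
  keepers <- s_mol$branch[order(dur)][11:20]
  expect_true(all(sort(keepers) %in% s_mol$branch))
  expect_error(bayes_branchrate_test(s_mol[1:4, ], s_morph[1:4, ],
                                     drop_shortest_fraction = 0.5),
               "refused|fewer")
  # n = 6 exact null: one-sided p agrees with enumeration of rank perms
  s6a <- mk_summary(c(0.1, 0.5, 0.3, 0.9, 0.2, 0.7), rep(10, 6))
  s6b <- mk_summary(c(0.2, 0.6, 0.1, 1.0, 0.4, 0.5), rep(10, 6))
  res6 <- bayes_branchrate_test(s6a, s6b)
  perms <- ratelink:::all_permutations(6)
  ra <- rank(s6a$median); rb <- rank(s6b$median)
  rho_all <- apply(perms, 1, function(p) stats::cor(ra, rb[p]))
  rho_obs <- stats::cor(ra, rb)
  expect_equal(res6$p_value, mean(rho_all >= rho_obs - 1e-12))
})

test_that("tests are invariant to input ordering", {
  pair <- fixture_pair(n_taxa = 9, coupled = FALSE, seed = 106)
  mol <- pair$mol_phylogram; morph <- pair$morph_phylogram
  res1 <- root_to_tip_test(mol, morph, n_perm = 500, seed = 4)
  morph_rot <- ape::rotate(morph, node = 11L)   # same tree, reordered
  res2 <- root_to_tip_test(mol, morph_rot, n_perm = 500, seed = 4)
  expect_equal(res1$statistic, res2$statistic, tolerance = 1e-12)
  expect_equal(res1$p_value, res2$p_value)
})
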