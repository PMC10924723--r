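# Default mean rates for the angiosperm-motivated stated world:
# molecular 9.65e-4 subs/site/Myr, morphological 1.83e-3 changes/character/Myr.
MOL_MEAN_RATE <- 9.65e-4
MORPH_MEAN_RATE <- 1.83e-3

#' Specify an uncorrelated relaxed clock
#'
#' The lognormal family draws each branch rate i.i.d. lognormal with log-scale
#' standard deviation `sigma` and log-scale mean `log(mean_rate) - sigma^2/2`,
#' so that the expectation of every branch rate equals `mean_rate`. The
#' exponential family has a fixed coefficient of rate variation of 1 and
#' ignores `sigma`.
#'
#' @param family `"lognormal"` or `"exponential"`.
#' @param mean_rate Expected branch rate (substitutions/site/Myr or
#'   changes/character/Myr); must be positive.
#' @param sigma Standard deviation of log branch rates (dimensionless
#'   and non-negative); ignored by the exponential family.
#' @return A `clock_spec` object.
#' @export
#' @examples
#' clock_spec("lognormal", 9.65e-4, sigma = 0.75)
clock_spec <- function(family = c("lognormal", "exponential"),
                       mean_rate, sigma = 0) {
  family <- match.arg(family)
  if (!is.numeric(mean_rate) || mean_rate <= 0)
    stop("`mean_rate` must be positive")
  if (family == "lognormal" && (!is.numeric(sigma) || sigma < 0))
    stop("`sigma` must be >= 0")
  structure(list(family = family, mean_rate = mean_rate,
                 sigma = if (family == "lognormal") sigma else NA_real_),
            class = "clock_spec")
}

#' Draw independent branch rates under a relaxed clock
#'
#' @param tree A `phylo` chronogram.
#' @param clock A [clock_spec()].
#' @param seed Integer seed or `NULL`.
#' @return A `rate_assignment`: list with `rates` (one positive rate per
#'   branch, in `tree$edge` order, named by child node) and `clock`.
#' @export
draw_branch_rates <- function(tree, clock, seed = NULL) {
  stopifnot(inherits(clock, "clock_spec"))
  ne <- nrow(tree$edge)
  rates <- with_seed(seed, {
    if (clock$family == "lognormal") {
      if (clock$sigma == 0) rep(clock$mean_rate, ne)
      else stats::rlnorm(ne, meanlog = log(clock$mean_rate) - clock$sigma^2 / 2,
                         sdlog = clock$sigma)
    } else {
      stats::rexp(ne, rate = 1 / clock$mean_rate)
    }
  })
  names(rates) <- edge_ids(tree)
  structure(list(rates = rates, clock = clock), class = "rate_assignment")
}

#' Rescale a chronogram into a phylogram using per-branch rates
#'
#' Each branch length becomes duration (Myr) times rate, giving expected
#' substitutions (or character changes) per site.
#'
#' @param tree A `phylo` chronogram.
#' @param rates A `rate_assignment` from [draw_branch_rates()], or a numeric
#'   vector with one rate per branch in `tree$edge` order.
#' @return A `phylo` phylogram with the same topology.
#' @export
build_phylogram <- function(tree, rates) {
  r <- if (inherits(rates, "rate_assignment")) rates$rates else rates
  if (length(r) != nrow(tree$edge))
    stop("`rates` must cover every branch of the tree")
  if (!is.null(names(r))) {
    ids <- edge_ids(tree)
    if (!setequal(names(r), ids))
      stop("rate names do not match the tree's branches")
    r <- r[ids]
  }
  if (any(!is.finite(r)) || any(r < 0)) stop("rates must be finite and >= 0")
  phy <- tree
  phy$edge.length <- tree$edge.length * unname(r)
  phy
}

#' Scale a molecular phylogram into a coupled morphological phylogram
#'
#' Multiplies every branch length by `scale_factor`, so the per-branch
#' morphological/molecular rate ratio is constant. The default 1.90 is the
#' ratio of the default morphological and molecular mean rates
#' (1.83e-3 / 9.65e-4), rounded to two decimals.
#'
#' @param mol A `phylo` molecular phylogram.
#' @param scale_factor Positive scalar.
#' @return A `phylo` morphological phylogram.
#' @export
couple_morph_phylogram <- function(mol, scale_factor = 1.90) {
  if (!is.numeric(scale_factor) || scale_factor <= 0)
    stop("`scale_factor` must be positive")
  out <- mol
  out$edge.length <- mol$edge.length * scale_factor
  out
}

#' Describe one simulation scenario
#'
#' Bundles the factors of the simulation grid: tree size, number and state
#' count of morphological characters, the spread of log branch rates, and
#' whether morphological rates are coupled to (a fixed multiple of) the
#' molecular rates or drawn independently. When reproducing the reference
#' grid, values come from {18, 45, 111} x {10, 100, 1000} x {2, 4} x
#' {0.25, 0.75, 1.25}; free values are allowed otherwise.
#'
#' @param n_taxa Number of tips.
#' @param n_chars Number of morphological characters.
#' @param k_states Number of character states (2 or 4 in the preset grid).
#' @param sigma Standard deviation of log branch rates.
#' @param coupled Logical; morphological rates a fixed multiple of molecular
#'   rates (`TRUE`) or independent draws (`FALSE`).
#' @param seq_length Alignment length in nucleotides (default 1000).
#' @param scale_factor Morphological branch-length scaling for coupled rates.
#' @param mol_mean,morph_mean Mean molecular and morphological rates.
#' @param replicate_id Replicate number within the scenario.
#' @param master_seed Master seed from which all stage seeds are derived.
#' @return A `scenario_spec` object.
#' @export
scenario_spec <- function(n_taxa, n_chars, k_states = 2L, sigma = 0.75,
                          coupled = TRUE, seq_length = 1000L,
                          scale_factor = 1.90,
                          mol_mean = MOL_MEAN_RATE,
                          morph_mean = MORPH_MEAN_RATE,
                          replicate_id = 1L, master_seed = 1L) {
  stopifnot(n_taxa >= 2, n_chars >= 1, k_states >= 2, sigma >= 0,
            is.logical(coupled), seq_length >= 1, scale_factor > 0,
            mol_mean > 0, morph_mean > 0)
  structure(list(n_taxa = as.integer(n_taxa), n_chars = as.integer(n_chars),
                 k_states = as.integer(k_states), sigma = sigma,
                 coupled = coupled, seq_length = as.integer(seq_length),
                 scale_factor = scale_factor, mol_mean = mol_mean,
                 morph_mean = morph_mean,
                 replicate_id = as.integer(replicate_id),
                 master_seed = as.integer(master_seed)),
            class = "scenario_spec")
}

#' Generate one matched molecular/morphological phylogram pair
#'
#' Draws molecular branch rates under a lognormal relaxed clock on a
#' chronogram and builds the molecular phylogram. Under coupled rates the
#' morphological phylogram is the molecular phylogram scaled by
#' `spec$scale_factor`; under uncoupled rates an independent set of
#' morphological branch rates is drawn with mean `spec$morph_mean` and the
#' same `sigma`, on the same chronogram. All randomness is seeded
#' deterministically from `spec$master_seed` and `spec$replicate_id`.
#'
#' @param spec A [scenario_spec()].
#' @param tree Optional chronogram to reuse; when `NULL`, a chronogram is
#'   simulated with a seed derived from the master seed and `n_taxa` only, so
#'   all scenarios of one tree size share a tree (mirroring a study design
#'   with one fixed tree per size).
#' @return List with `chronogram`, `mol_phylogram`, `morph_phylogram`,
#'   `true_rates_mol`, `true_rates_morph`, and `spec`.
#' @export
generate_scenario_pair <- function(spec, tree = NULL) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (is.null(tree)) {
    tree <- simulate_chronogram(
      spec$n_taxa, seed = derive_seed(spec$master_seed, "tree", spec$n_taxa))
  }
  rep_tag <- c(spec$n_taxa, spec$n_chars, spec$k_states,
               round(spec$sigma * 100), as.integer(spec$coupled),
               spec$replicate_id)
  mol_clock <- clock_spec("lognormal", spec$mol_mean, spec$sigma)
  mol_rates <- draw_branch_rates(
    tree, mol_clock,
    seed = derive_seed(spec$master_seed, "rates_mol", rep_tag))
  mol_phy <- build_phylogram(tree, mol_rates)
  if (spec$coupled) {
    morph_phy <- couple_morph_phylogram(mol_phy, spec$scale_factor)
    morph_rates <- mol_rates
    morph_rates$rates <- mol_rates$rates * spec$scale_factor
    morph_rates$clock <- clock_spec("lognormal",
                                    spec$mol_mean * spec$scale_factor,
                                    spec$sigma)
  } else {
    morph_clock <- clock_spec("lognormal", spec$morph_mean, spec$sigma)
    morph_rates <- draw_branch_rates(
      tree, morph_clock,
      seed = derive_seed(spec$master_seed, "rates_morph", rep_tag))
    morph_phy <- build_phylogram(tree, morph_rates)
  }
  list(chronogram = tree, mol_phylogram = mol_phy,
       morph_phylogram = morph_phy, true_rates_mol = mol_rates,
       true_rates_morph = morph_rates, spec = spec)
}
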