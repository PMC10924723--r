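# Bayesian inference of branch rates under uncorrelated relaxed clocks on a
# fixed topology, by Metropolis-within-Gibbs sampling. Likelihoods use the
# pruning kernels shared with the ML module.

#' Specify a relaxed-clock model for Bayesian inference
#'
#' The lognormal family gives each branch a rate multiplier drawn from a
#' lognormal with mean 1 and an estimated log-scale standard deviation; the
#' exponential family draws multipliers from Exponential(1), whose
#' coefficient of rate variation is fixed at 1 (no spread hyperparameter).
#' With `linkage = "linked"` the molecular and morphological partitions share
#' one set of branch-rate multipliers (and one spread hyperparameter),
#' differing only in their mean clock rates; with `"unlinked"` each partition
#' has its own multipliers.
#'
#' @param family `"lognormal"` or `"exponential"`.
#' @param linkage `"unlinked"` or `"linked"`.
#' @param morph_mean_fixed Fix the morphological mean clock rate to 1
#'   instead of estimating it. Appropriate when node times are expressed in
#'   relative units; the default estimates both partition means because the
#'   package default fixes node times in absolute Myr.
#' @return A `clock_model_spec` object.
#' @export
clock_model_spec <- function(family = c("lognormal", "exponential"),
                             linkage = c("unlinked", "linked"),
                             morph_mean_fixed = FALSE) {
  structure(list(family = match.arg(family), linkage = match.arg(linkage),
                 morph_mean_fixed = morph_mean_fixed),
            class = "clock_model_spec")
}

#' MCMC sampler settings
#'
#' Defaults are desk-scale (chain of 2e5 proposals, thinning 100); the
#' reference-scale settings (1e7 steps, thin 1000) can be requested
#' explicitly for overnight runs.
#'
#' @param chain_length Number of MCMC proposals per chain.
#' @param n_chains Number of independent chains.
#' @param thin Sampling interval (proposals between stored samples).
#' @param burnin_fraction Fraction of each chain discarded before
#'   summarizing (default 0.10).
#' @param ess_threshold Minimum effective sample size below which the result
#'   is flagged (default 200).
#' @param seed Integer seed.
#' @return An `mcmc_settings` object.
#' @export
mcmc_settings <- function(chain_length = 2e5, n_chains = 2L, thin = 100L,
                          burnin_fraction = 0.10, ess_threshold = 200,
                          seed = 1L) {
  stopifnot(chain_length >= 1, n_chains >= 1, thin >= 1,
            burnin_fraction >= 0, burnin_fraction < 1, ess_threshold > 0)
  structure(list(chain_length = as.integer(chain_length),
                 n_chains = as.integer(n_chains), thin = as.integer(thin),
                 burnin_fraction = burnin_fraction,
                 ess_threshold = ess_threshold, seed = as.integer(seed)),
            class = "mcmc_settings")
}

#' Prior specification for the relaxed-clock sampler
#'
#' @param mu_meanlog,mu_sdlog Lognormal prior on each partition's mean clock
#'   rate. The diffuse default is centred on 1e-3 changes per site per Myr
#'   with a log-scale sd of 3 (about four orders of magnitude each way).
#' @param sigma_rate Exponential prior rate on the lognormal clock's
#'   log-scale sd (default mean 1).
#' @param bd_rate Exponential prior rate on birth and death rates when node
#'   times are sampled.
#' @return An `mcmc_priors` object.
#' @export
mcmc_priors <- function(mu_meanlog = log(1e-3), mu_sdlog = 3,
                        sigma_rate = 1, bd_rate = 1) {
  structure(list(mu_meanlog = mu_meanlog, mu_sdlog = mu_sdlog,
                 sigma_rate = sigma_rate, bd_rate = bd_rate),
            class = "mcmc_priors")
}

# log prior density of a vector of branch-rate multipliers
mult_logprior <- function(m, family, sigma) {
  if (family == "lognormal")
    sum(stats::dlnorm(m, meanlog = -sigma^2 / 2, sdlog = sigma, log = TRUE))
  else
    sum(stats::dexp(m, rate = 1, log = TRUE))
}

# Birth-death node-age density (conditioned on the root age), coalescent
# point process form: non-root internal ages i.i.d. with kernel
# r e^{-rt} / (1 - a e^{-rt})^2, r = lambda - mu, a = mu / lambda,
# normalized on [0, T].
bd_age_logdens <- function(ages, T_root, lambda, mu) {
  if (lambda <= mu || lambda <= 0) return(-Inf)
  r <- lambda - mu
  a <- mu / lambda
  kern <- log(r) - r * ages - 2 * log1p(-a * exp(-r * ages))
  if (a < 1e-12) {
    lognorm <- log1p(-exp(-r * T_root))
  } else {
    uT <- exp(-r * T_root)
    lognorm <- log((1 / a) * (1 / (1 - a) - 1 / (1 - a * uT)))
  }
  sum(kern - lognorm)
}

#' Bayesian relaxed-clock MCMC on a fixed topology
#'
#' Metropolis-within-Gibbs sampling of per-branch rate multipliers, partition
#' mean clock rates, the lognormal clock's spread hyperparameter, and
#' (optionally) internal node times under a birth-death prior. Branch lengths
#' for the likelihood are duration x mean rate x multiplier; likelihoods use
#' the same pruning kernels as the ML module. With `likelihood_on = FALSE`
#' the sampler targets the prior, which is used by the validation tests.
#'
#' @param chronogram Rooted binary `phylo` chronogram (supplies the fixed
#'   topology and, when `fix_times = TRUE`, the node times).
#' @param aln Nucleotide alignment matrix, or `NULL` to omit the partition.
#' @param chars Character matrix, or `NULL` to omit.
#' @param clock A [clock_model_spec()].
#' @param settings An [mcmc_settings()].
#' @param nuc_mod,morph_mod Substitution models (parameters held fixed).
#' @param priors An [mcmc_priors()].
#' @param fix_times Keep node times fixed at the chronogram's (default);
#'   otherwise sample internal node ages under a birth-death prior with the
#'   root age fixed.
#' @param likelihood_on Include the data likelihood (default `TRUE`).
#' @param fixed Optional list pinning parameters at known values (used
#'   mainly by validation tests): elements `mu` (named vector, e.g.
#'   `c(mol = 1e-3)`), `sigma` (named vector), and `mult` (named list of
#'   per-branch vectors in postorder edge order, `NA` entries left free).
#' @return A `posterior_samples` object: per-chain trace matrices, fixed
#'   metadata, per-parameter ESS of scalar parameters, and a `flagged` field
#'   naming parameters whose ESS fell below the threshold.
#' @export
run_mcmc <- function(chronogram, aln = NULL, chars = NULL,
                     clock = clock_model_spec(), settings = mcmc_settings(),
                     nuc_mod = nuc_model(), morph_mod = morph_model(),
                     priors = mcmc_priors(), fix_times = TRUE,
                     likelihood_on = TRUE, fixed = list()) {
  assert_chronogram(chronogram)
  po <- postorder_tree(chronogram)
  n_tip <- ape::Ntip(chronogram)
  ne <- nrow(chronogram$edge)
  part_names <- c(if (!is.null(aln)) "mol", if (!is.null(chars)) "morph")
  if (!length(part_names)) part_names <- c("mol", "morph")  # prior-only
  parts <- list()
  if (!is.null(aln)) parts$mol <- build_partition(po$tree, aln, nuc_mod)
  if (!is.null(chars)) parts$morph <- build_partition(po$tree, chars, morph_mod)
  ids <- edge_ids(po$tree)
  ages0 <- node_ages(po$tree)
  chains <- lapply(seq_len(settings$n_chains), function(ci) {
    with_seed(derive_seed(settings$seed, "chain", ci),
              mcmc_one_chain(po, n_tip, ne, ids, ages0, parts, part_names,
                             clock, settings, priors, fix_times,
                             likelihood_on, fixed))
  })
  pooled <- do.call(rbind, lapply(chains, function(m) {
    m[-seq_len(floor(nrow(m) * settings$burnin_fraction)), , drop = FALSE]
  }))
  scalar_cols <- grep("^(mu|sigma|loglik|lambda_bd|mu_bd)", colnames(pooled),
                      value = TRUE)
  ess <- vapply(scalar_cols, function(cn) {
    x <- pooled[, cn]
    if (stats::var(x) == 0) Inf else effective_sample_size(x)
  }, numeric(1))
  flagged <- names(ess)[ess < settings$ess_threshold]
  structure(list(chains = chains, tree = po$tree, branch_ids = ids,
                 durations = stats::setNames(po$tree$edge.length, ids),
                 clock = clock, settings = settings, priors = priors,
                 partitions = part_names, fix_times = fix_times,
                 ess = ess, flagged = flagged),
            class = "posterior_samples")
}

mcmc_one_chain <- function(po, n_tip, ne, ids, ages0, parts, part_names,
                           clock, settings, priors, fix_times,
                           likelihood_on, fixed = list()) {
  linked <- clock$linkage == "linked"
  lognorm <- clock$family == "lognormal"
  edge <- po$tree$edge
  n_node <- max(edge)
  internal_free <- setdiff((n_tip + 1):n_node, n_tip + 1L)  # root age fixed
  parent_of <- integer(n_node)
  parent_of[edge[, 2]] <- edge[, 1]
  edge_of_child <- integer(n_node)
  edge_of_child[edge[, 2]] <- seq_len(ne)
  children_of <- split(edge[, 2], edge[, 1])

  # --- state ---
  ages <- ages0
  durations <- ages[edge[, 1]] - ages[edge[, 2]]
  mu <- c(mol = 1e-3, morph = 2e-3)
  if (clock$morph_mean_fixed) mu["morph"] <- 1
  sigma <- c(mol = 0.5, morph = 0.5, shared = 0.5)
  mult <- if (linked) list(shared = rep(1, ne))
          else list(mol = rep(1, ne), morph = rep(1, ne))
  lambda_bd <- 0.1; mu_bd <- 0.05
  # pinned parameters (validation tests)
  if (!is.null(fixed$mu)) mu[names(fixed$mu)] <- fixed$mu
  if (!is.null(fixed$sigma)) sigma[names(fixed$sigma)] <- fixed$sigma
  mult_free <- lapply(mult, function(m) seq_along(m))
  if (!is.null(fixed$mult)) {
    for (s in names(fixed$mult)) {
      fx <- fixed$mult[[s]]
      mult[[s]][!is.na(fx)] <- fx[!is.na(fx)]
      mult_free[[s]] <- which(is.na(fx))
    }
  }
  mu_is_fixed <- function(p) {
    (p == "morph" && clock$morph_mean_fixed) ||
      (!is.null(fixed$mu) && p %in% names(fixed$mu))
  }
  sigma_is_fixed <- function(s) {
    !is.null(fixed$sigma) && s %in% names(fixed$sigma)
  }

  mult_of <- function(p) if (linked) mult$shared else mult[[p]]
  sigma_of <- function(p) if (linked) sigma["shared"] else sigma[p]

  part_ll <- function(p) {
    if (!likelihood_on || is.null(parts[[p]])) return(0)
    el <- durations * mu[p] * mult_of(p)
    rl_loglik_cpp(edge, n_tip, el, list(parts[[p]]), 1.0)
  }
  ll <- vapply(part_names, part_ll, numeric(1))
  names(ll) <- part_names

  logprior <- function() {
    lp <- 0
    for (p in part_names) {
      if (!(p == "morph" && clock$morph_mean_fixed))
        lp <- lp + stats::dlnorm(mu[p], priors$mu_meanlog, priors$mu_sdlog,
                                 log = TRUE)
    }
    if (lognorm) {
      if (linked) {
        lp <- lp + stats::dexp(sigma["shared"], priors$sigma_rate, log = TRUE)
        lp <- lp + mult_logprior(mult$shared, "lognormal", sigma["shared"])
      } else {
        for (p in part_names) {
          lp <- lp + stats::dexp(sigma[p], priors$sigma_rate, log = TRUE)
          lp <- lp + mult_logprior(mult[[p]], "lognormal", sigma[p])
        }
      }
    } else {
      sets <- if (linked) list(mult$shared) else mult[part_names]
      for (m in sets) lp <- lp + mult_logprior(unlist(m), "exponential", NA)
    }
    if (!fix_times) {
      lp <- lp + bd_age_logdens(ages[internal_free], ages[n_tip + 1L],
                                lambda_bd, mu_bd) +
        stats::dexp(lambda_bd, priors$bd_rate, log = TRUE) +
        stats::dexp(mu_bd, priors$bd_rate, log = TRUE)
    }
    lp
  }
  lp <- logprior()

  # --- proposal bookkeeping (adapt during burn-in, then freeze) ---
  widths <- c(mult = 0.6, mu = 1.0, sigma = 0.8, rescale = 1.0,
              age = 0.1, bd = 0.5)
  n_steps <- settings$chain_length
  adapt_until <- floor(n_steps * settings$burnin_fraction)
  acc <- count <- stats::setNames(numeric(length(widths)), names(widths))

  mult_sets <- if (linked) "shared" else part_names
  blocks <- c("mult", "mu", if (lognorm) "sigma", "rescale")
  if (!fix_times) blocks <- c(blocks, "age", "bd")
  block_w <- c(mult = length(mult_sets) * ne, mu = 2, sigma = 2, rescale = 2,
               age = length(internal_free), bd = 2)[blocks]

  n_keep <- floor(n_steps / settings$thin)
  rate_cols <- unlist(lapply(part_names, function(p) paste0("rate.", p, ".", ids)))
  cols <- c(paste0("mu.", part_names),
            if (lognorm) paste0("sigma.", if (linked) "shared" else part_names),
            rate_cols,
            if (!fix_times) c("lambda_bd", "mu_bd",
                              paste0("age.", internal_free)),
            "loglik", "logprior")
  out <- matrix(NA_real_, n_keep, length(cols),
                dimnames = list(NULL, cols))
  keep_i <- 0L

  for (step in seq_len(n_steps)) {
    bl <- sample(blocks, 1L, prob = block_w)
    adapting <- step <= adapt_until
    if (bl == "mult") {
      ms <- if (length(mult_sets) == 1L) mult_sets else sample(mult_sets, 1L)
      free <- mult_free[[ms]]
      if (length(free)) {
        i <- if (length(free) == 1L) free else sample(free, 1L)
        old <- mult[[ms]][i]
        d <- stats::runif(1, -widths["mult"], widths["mult"])
        new <- old * exp(d)
        mult[[ms]][i] <- new
        affected <- if (linked) part_names else ms
        ll_new <- ll
        for (p in affected) ll_new[p] <- part_ll(p)
        lp_new <- logprior()
        a <- sum(ll_new) - sum(ll) + lp_new - lp + log(new / old)
        if (is.finite(a) && log(stats::runif(1)) < a) {
          ll <- ll_new; lp <- lp_new; acc["mult"] <- acc["mult"] + 1
        } else mult[[ms]][i] <- old
        count["mult"] <- count["mult"] + 1
      }
    } else if (bl == "mu") {
      p <- sample(part_names, 1L)
      if (!mu_is_fixed(p)) {
        old <- mu[p]
        d <- stats::runif(1, -widths["mu"], widths["mu"])
        mu[p] <- old * exp(d)
        ll_new <- ll; ll_new[p] <- part_ll(p)
        lp_new <- logprior()
        a <- ll_new[p] - ll[p] + lp_new - lp + d
        if (is.finite(a) && log(stats::runif(1)) < a) {
          ll <- ll_new; lp <- lp_new; acc["mu"] <- acc["mu"] + 1
        } else mu[p] <- old
        count["mu"] <- count["mu"] + 1
      }
    } else if (bl == "sigma" && lognorm) {
      # joint funnel move: scale sigma and map the multipliers so their
      # standardized log-residuals are preserved; the prior ratio of the
      # multipliers cancels against the Jacobian exactly
      sn <- if (linked) "shared" else sample(part_names, 1L)
      ms <- if (linked) "shared" else sn
      if (!sigma_is_fixed(sn)) {
        old_s <- sigma[sn]
        old_m <- mult[[ms]]
        d <- stats::runif(1, -widths["sigma"], widths["sigma"])
        new_s <- old_s * exp(d)
        sigma[sn] <- new_s
        funnel <- length(mult_free[[ms]]) == ne && stats::runif(1) < 0.5
        if (funnel) {
          z <- (log(old_m) + old_s^2 / 2) / old_s
          new_m <- exp(z * new_s - new_s^2 / 2)
          mult[[ms]] <- new_m
          affected <- if (linked) part_names else sn
          ll_new <- ll
          for (p in affected) ll_new[p] <- part_ll(p)
          jac <- sum(log(new_m / old_m)) + ne * d
        } else {
          ll_new <- ll
          jac <- 0
        }
        lp_new <- logprior()
        a <- sum(ll_new) - sum(ll) + lp_new - lp + jac + d
        if (is.finite(a) && log(stats::runif(1)) < a) {
          ll <- ll_new; lp <- lp_new; acc["sigma"] <- acc["sigma"] + 1
        } else { sigma[sn] <- old_s; if (funnel) mult[[ms]] <- old_m }
        count["sigma"] <- count["sigma"] + 1
      }
    } else if (bl == "rescale") {
      # trade scale between a partition's mean and its multipliers;
      # leaves branch lengths (and the likelihood) unchanged
      p <- if (linked) "mol" else sample(part_names, 1L)
      ms_ok <- length(mult_free[[if (linked) "shared" else p]]) == ne
      if (!mu_is_fixed(p) && ms_ok) {
        ms <- if (linked) "shared" else p
        d <- stats::runif(1, -widths["rescale"], widths["rescale"])
        old_mu <- mu[p]; old_mult <- mult[[ms]]
        old_mu_morph <- mu["morph"]
        mu[p] <- old_mu * exp(d)
        mult[[ms]] <- old_mult * exp(-d)
        link_morph <- linked && "morph" %in% part_names &&
          !clock$morph_mean_fixed
        if (link_morph) mu["morph"] <- old_mu_morph * exp(d)
        # when the shared multipliers rescale but the morph mean cannot
        # move, the morph branch lengths change and its likelihood must be
        # re-evaluated
        ll_new <- ll
        if (linked && "morph" %in% part_names && clock$morph_mean_fixed)
          ll_new["morph"] <- part_ll("morph")
        lp_new <- logprior()
        jac <- d * (1 - ne) + if (link_morph) d else 0
        a <- sum(ll_new) - sum(ll) + lp_new - lp + jac
        if (is.finite(a) && log(stats::runif(1)) < a) {
          ll <- ll_new; lp <- lp_new; acc["rescale"] <- acc["rescale"] + 1
        } else {
          mu[p] <- old_mu; mult[[ms]] <- old_mult
          if (link_morph) mu["morph"] <- old_mu_morph
        }
        count["rescale"] <- count["rescale"] + 1
      }
    } else if (bl == "age") {
      v <- if (length(internal_free) == 1L) internal_free
           else sample(internal_free, 1L)
      lo <- max(ages[children_of[[as.character(v)]]])
      hi <- ages[parent_of[v]]
      old <- ages[v]
      w <- widths["age"] * (hi - lo)
      new <- old + stats::runif(1, -w, w)
      # reflect into (lo, hi)
      while (new < lo || new > hi) {
        if (new < lo) new <- 2 * lo - new
        if (new > hi) new <- 2 * hi - new
      }
      ages[v] <- new
      durations <- ages[edge[, 1]] - ages[edge[, 2]]
      ll_new <- vapply(part_names, part_ll, numeric(1)); names(ll_new) <- part_names
      lp_new <- logprior()
      a <- sum(ll_new) - sum(ll) + lp_new - lp
      if (is.finite(a) && log(stats::runif(1)) < a) {
        ll <- ll_new; lp <- lp_new; acc["age"] <- acc["age"] + 1
      } else {
        ages[v] <- old
        durations <- ages[edge[, 1]] - ages[edge[, 2]]
      }
      count["age"] <- count["age"] + 1
    } else if (bl == "bd") {
      which_bd <- sample(c("lambda", "mu"), 1L)
      d <- stats::runif(1, -widths["bd"], widths["bd"])
      if (which_bd == "lambda") {
        old <- lambda_bd; lambda_bd <- old * exp(d)
      } else {
        old <- mu_bd; mu_bd <- old * exp(d)
      }
      lp_new <- logprior()
      a <- lp_new - lp + d
      if (is.finite(a) && log(stats::runif(1)) < a) {
        lp <- lp_new; acc["bd"] <- acc["bd"] + 1
      } else if (which_bd == "lambda") lambda_bd <- old else mu_bd <- old
      count["bd"] <- count["bd"] + 1
    }
    if (adapting && count[bl] > 0 && count[bl] %% 50 == 0) {
      rate <- acc[bl] / count[bl]
      widths[bl] <- widths[bl] * exp((rate - 0.3) / 2)
      acc[bl] <- count[bl] <- 0
    }
    if (step %% settings$thin == 0L) {
      keep_i <- keep_i + 1L
      row <- c(mu[part_names],
               if (lognorm) sigma[if (linked) "shared" else part_names],
               unlist(lapply(part_names,
                             function(p) mu[p] * mult_of(p))),
               if (!fix_times) c(lambda_bd, mu_bd, ages[internal_free]),
               sum(ll), lp)
      out[keep_i, ] <- row
    }
  }
  out[seq_len(keep_i), , drop = FALSE]
}

#' Write MCMC traces and branch-rate summaries to tab-separated files
#'
#' One state file per chain (`<prefix>_chain<i>.log`): a header line, then
#' one row per retained sample with a leading `state` column, compatible
#' with common trace viewers. Branch-rate summaries are written as one TSV
#' per partition (`<prefix>_rates_<partition>.tsv`), keyed by branch
#' (child-node label).
#'
#' @param samples A `posterior_samples` object.
#' @param prefix Output path prefix.
#' @return Character vector of files written, invisibly.
#' @export
write_traces <- function(samples, prefix) {
  stopifnot(inherits(samples, "posterior_samples"))
  files <- character()
  for (i in seq_along(samples$chains)) {
    m <- samples$chains[[i]]
    df <- data.frame(state = (seq_len(nrow(m)) - 1L) *
                       samples$settings$thin, m, check.names = FALSE)
    f <- sprintf("%s_chain%d.log", prefix, i)
    utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  summ <- summarize_branch_rates(samples)
  for (p in names(summ)) {
    f <- sprintf("%s_rates_%s.tsv", prefix, p)
    utils::write.table(summ[[p]], f, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}

#' Summarize posterior branch rates
#'
#' Pools the chains after discarding the burn-in fraction of each, and
#' reports the per-branch arithmetic mean and empirical median posterior
#' rate for each data partition, together with the branch duration (fixed
#' times) in Myr.
#'
#' @param samples A `posterior_samples` object from [run_mcmc()].
#' @param burnin_fraction Fraction of each chain to discard; defaults to the
#'   sampler's setting.
#' @return Named list of data frames (one per partition) with columns
#'   `branch`, `duration`, `mean`, `median`.
#' @export
summarize_branch_rates <- function(samples,
                                   burnin_fraction = NULL) {
  stopifnot(inherits(samples, "posterior_samples"))
  if (is.null(burnin_fraction))
    burnin_fraction <- samples$settings$burnin_fraction
  pooled <- do.call(rbind, lapply(samples$chains, function(m) {
    m[-seq_len(floor(nrow(m) * burnin_fraction)), , drop = FALSE]
  }))
  if (nrow(pooled) < 2) stop("fewer than 2 retained samples")
  out <- lapply(samples$partitions, function(p) {
    cols <- paste0("rate.", p, ".", samples$branch_ids)
    data.frame(branch = samples$branch_ids,
               duration = unname(samples$durations[samples$branch_ids]),
               mean = colMeans(pooled[, cols, drop = FALSE]),
               median = apply(pooled[, cols, drop = FALSE], 2, stats::median),
               row.names = NULL)
  })
  stats::setNames(out, samples$partitions)
}
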