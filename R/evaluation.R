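# Orchestration of the factorial simulation grid: enumerate scenarios, run
# all requested detection methods on each replicate, and summarize power and
# false-positive rates.

ALL_METHODS <- c("rtt", "sisters", "ml_aicc", "ml_bic",
                 "bayes_rates_mean", "bayes_rates_median", "bayes_bf")

#' Configure a simulation grid
#'
#' The default preset reproduces the reference factorial design:
#' tree sizes {18, 45, 111} x character counts {10, 100, 1000} x state
#' counts {2, 4} x rate-variation levels {0.25, 0.75, 1.25} (54 scenarios),
#' with 20 replicates each, i.e. 1080 data-set pairs per coupling setting.
#'
#' @param tree_sizes,char_counts,state_counts,sigmas Factor value lists.
#' @param n_replicates Replicates per scenario.
#' @param coupled `"both"`, `TRUE` (coupled only) or `FALSE`.
#' @param methods Subset of `rtt`, `sisters`, `ml_aicc`, `ml_bic`,
#'   `bayes_rates_mean`, `bayes_rates_median`, `bayes_bf`.
#' @param inference_scale `"desk"` (reduced MCMC/GSS settings) or `"paper"`
#'   (reference-scale settings; overnight).
#' @param seq_length Alignment length.
#' @param n_perm Permutations for the root-to-tip test.
#' @param master_seed Master seed.
#' @return A `grid_config` object.
#' @export
grid_config <- function(tree_sizes = c(18L, 45L, 111L),
                        char_counts = c(10L, 100L, 1000L),
                        state_counts = c(2L, 4L),
                        sigmas = c(0.25, 0.75, 1.25),
                        n_replicates = 20L,
                        coupled = "both",
                        methods = c("rtt", "sisters", "ml_aicc", "ml_bic"),
                        inference_scale = c("desk", "paper"),
                        seq_length = 1000L,
                        n_perm = 20000L,
                        master_seed = 1L) {
  stopifnot(length(tree_sizes) > 0, length(char_counts) > 0,
            length(state_counts) > 0, length(sigmas) > 0, n_replicates >= 1,
            all(methods %in% ALL_METHODS))
  structure(list(tree_sizes = as.integer(tree_sizes),
                 char_counts = as.integer(char_counts),
                 state_counts = as.integer(state_counts), sigmas = sigmas,
                 n_replicates = as.integer(n_replicates), coupled = coupled,
                 methods = methods,
                 inference_scale = match.arg(inference_scale),
                 seq_length = as.integer(seq_length),
                 n_perm = as.integer(n_perm),
                 master_seed = as.integer(master_seed)),
            class = "grid_config")
}

#' Enumerate the scenarios of a grid
#'
#' Cartesian product of the factor lists in a fixed order (tree size
#' fastest, then character count, state count, sigma), for one coupling
#' setting.
#'
#' @param cfg A [grid_config()].
#' @param coupled Logical coupling flag for the generated specs.
#' @return List of [scenario_spec()]s (length = number of scenarios).
#' @export
enumerate_grid <- function(cfg, coupled = TRUE) {
  g <- expand.grid(n_taxa = cfg$tree_sizes, n_chars = cfg$char_counts,
                   k_states = cfg$state_counts, sigma = cfg$sigmas,
                   KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(g)), function(i) {
    scenario_spec(n_taxa = g$n_taxa[i], n_chars = g$n_chars[i],
                  k_states = g$k_states[i], sigma = g$sigma[i],
                  coupled = coupled, seq_length = cfg$seq_length,
                  master_seed = cfg$master_seed)
  })
}

# desk- and reference-scale Bayesian settings
bayes_scale_settings <- function(inference_scale, seed) {
  if (inference_scale == "paper") {
    list(mcmc = mcmc_settings(chain_length = 1e7, n_chains = 2L,
                              thin = 1000L, seed = seed),
         gss_steps = 25L, gss_chain = 4e5)
  } else {
    list(mcmc = mcmc_settings(chain_length = 6e4, n_chains = 2L,
                              thin = 30L, seed = seed),
         gss_steps = 8L, gss_chain = 1e4)
  }
}

#' Run all requested detection methods on one simulated replicate
#'
#' Generates the data pair for a scenario replicate, performs the inference
#' each method needs (ML branch-length fits for the root-to-tip,
#' sister-pairs and model-selection tests; MCMC and stepping-stone sampling
#' for the Bayesian tests), and returns one `test_result` per method
#' variant. Inference failures are recorded as indeterminate (not detected)
#' results rather than dropped.
#'
#' @param spec A [scenario_spec()] (its `replicate_id` and `master_seed`
#'   drive all sub-seeds).
#' @param methods Methods to run (see [grid_config()]).
#' @param inference_scale `"desk"` or `"paper"`.
#' @param tree Optional chronogram to reuse across replicates.
#' @param n_perm Permutations for the root-to-tip test.
#' @param alpha Significance level for the p-value-based tests.
#' @return Named list of `test_result`s.
#' @export
run_replicate <- function(spec, methods = c("rtt", "sisters", "ml_aicc",
                                            "ml_bic"),
                          inference_scale = "desk", tree = NULL,
                          n_perm = 20000L, alpha = 0.05) {
  stopifnot(all(methods %in% ALL_METHODS))
  pair <- generate_scenario_pair(spec, tree = tree)
  tree <- pair$chronogram
  rep_tag <- c(spec$n_taxa, spec$n_chars, spec$k_states,
               round(spec$sigma * 100), as.integer(spec$coupled),
               spec$replicate_id)
  nm <- nuc_model()
  mm <- morph_model(spec$k_states)
  aln <- simulate_alignment(pair$mol_phylogram, nm, spec$seq_length,
                            seed = derive_seed(spec$master_seed, "aln",
                                               rep_tag))
  chars <- simulate_characters(pair$morph_phylogram, mm, spec$n_chars,
                               seed = derive_seed(spec$master_seed, "chars",
                                                  rep_tag))
  out <- list()
  fail <- function(method) test_result(method, statistic = NA_real_,
                                       detected = FALSE,
                                       options = list(failed = TRUE))

  need_ml <- any(c("rtt", "sisters") %in% methods)
  need_modelsel <- any(c("ml_aicc", "ml_bic") %in% methods)
  if (need_ml || need_modelsel) {
    fit_mol <- tryCatch(optimize_branch_lengths(tree, aln, nm),
                        error = function(e) NULL)
    fit_morph <- tryCatch(optimize_branch_lengths(tree, chars, mm),
                          error = function(e) NULL)
    if ("rtt" %in% methods) {
      out$rtt <- tryCatch({
        mol_r <- root_phylogram(fit_mol$tree, tree)
        morph_r <- root_phylogram(fit_morph$tree, tree)
        root_to_tip_test(mol_r, morph_r, n_perm = n_perm, alpha = alpha,
                         seed = derive_seed(spec$master_seed, "perm",
                                            rep_tag))
      }, error = function(e) fail("root_to_tip"))
    }
    if ("sisters" %in% methods) {
      out$sisters <- tryCatch(
        sister_pairs_test(tree, fit_mol$tree, fit_morph$tree, alpha = alpha),
        error = function(e) fail("sister_pairs"))
    }
    if (need_modelsel) {
      msr <- tryCatch({
        fu <- structure(list(
          linkage = "unlinked",
          log_likelihood = fit_mol$log_likelihood +
            fit_morph$log_likelihood,
          n_free_params = fit_mol$n_free_params + fit_morph$n_free_params,
          n_columns = fit_mol$n_columns + fit_morph$n_columns),
          class = "rl_fit")
        fl <- fit_linked(tree, aln, chars, nm, mm)
        model_selection(fl, fu)
      }, error = function(e) NULL)
      if ("ml_aicc" %in% methods)
        out$ml_aicc <- if (is.null(msr)) fail("ml_modelsel_aicc")
                       else ml_modelsel_test(msr, "aicc")
      if ("ml_bic" %in% methods)
        out$ml_bic <- if (is.null(msr)) fail("ml_modelsel_bic")
                      else ml_modelsel_test(msr, "bic")
    }
  }

  need_rates <- any(c("bayes_rates_mean", "bayes_rates_median") %in% methods)
  if (need_rates) {
    sc <- bayes_scale_settings(inference_scale,
                               derive_seed(spec$master_seed, "mcmc", rep_tag))
    post <- tryCatch(
      run_mcmc(tree, aln, chars, clock = clock_model_spec("lognormal",
                                                          "unlinked"),
               settings = sc$mcmc, nuc_mod = nm, morph_mod = mm),
      error = function(e) NULL)
    summ <- if (is.null(post)) NULL
            else tryCatch(summarize_branch_rates(post),
                          error = function(e) NULL)
    if ("bayes_rates_mean" %in% methods)
      out$bayes_rates_mean <-
        if (is.null(summ)) fail("bayes_branch_rates_mean")
        else bayes_branchrate_test(summ$mol, summ$morph, "mean",
                                   alpha = alpha)
    if ("bayes_rates_median" %in% methods)
      out$bayes_rates_median <-
        if (is.null(summ)) fail("bayes_branch_rates_median")
        else bayes_branchrate_test(summ$mol, summ$morph, "median",
                                   alpha = alpha)
  }
  if ("bayes_bf" %in% methods) {
    sc <- bayes_scale_settings(inference_scale,
                               derive_seed(spec$master_seed, "gss", rep_tag))
    out$bayes_bf <- tryCatch({
      ml_l <- gss_logml(tree, aln, chars,
                        clock = clock_model_spec("lognormal", "linked"),
                        n_steps = sc$gss_steps, chain_length = sc$gss_chain,
                        seed = derive_seed(spec$master_seed, "gss_l",
                                           rep_tag),
                        nuc_mod = nm, morph_mod = mm)
      ml_u <- gss_logml(tree, aln, chars,
                        clock = clock_model_spec("lognormal", "unlinked"),
                        n_steps = sc$gss_steps, chain_length = sc$gss_chain,
                        seed = derive_seed(spec$master_seed, "gss_u",
                                           rep_tag),
                        nuc_mod = nm, morph_mod = mm)
      bayes_modelsel_test(bayes_factor(ml_l, ml_u))
    }, error = function(e) fail("bayes_modelsel"))
  }
  out
}

#' Run a full evaluation grid
#'
#' Loops over scenarios, coupling settings and replicates, running
#' [run_replicate()] for each, and returns the long results table.
#'
#' @param cfg A [grid_config()].
#' @param verbose Print per-replicate progress.
#' @return Data frame with one row per (scenario, replicate, method).
#' @export
evaluate_grid <- function(cfg, verbose = FALSE) {
  coupled_vals <- if (identical(cfg$coupled, "both")) c(TRUE, FALSE)
                  else as.logical(cfg$coupled)
  rows <- list()
  trees <- new.env(parent = emptyenv())
  for (cp in coupled_vals) {
    for (sc in enumerate_grid(cfg, coupled = cp)) {
      key <- as.character(sc$n_taxa)
      if (is.null(trees[[key]]))
        trees[[key]] <- simulate_chronogram(
          sc$n_taxa, seed = derive_seed(cfg$master_seed, "tree", sc$n_taxa))
      for (r in seq_len(cfg$n_replicates)) {
        sc$replicate_id <- r
        t0 <- Sys.time()
        res <- run_replicate(sc, methods = cfg$methods,
                             inference_scale = cfg$inference_scale,
                             tree = trees[[key]], n_perm = cfg$n_perm)
        dt <- as.numeric(Sys.time() - t0, units = "secs")
        if (verbose)
          message(sprintf(
            "n=%d chars=%d k=%d sigma=%.2f coupled=%s rep=%d (%.1fs)",
            sc$n_taxa, sc$n_chars, sc$k_states, sc$sigma, cp, r, dt))
        for (m in names(res)) {
          tr <- res[[m]]
          rows[[length(rows) + 1L]] <- data.frame(
            n_taxa = sc$n_taxa, n_chars = sc$n_chars,
            k_states = sc$k_states, sigma = sc$sigma, coupled = cp,
            replicate = r, method = m, statistic = tr$statistic,
            p_value = tr$p_value, detected = tr$detected,
            seconds = dt)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Aggregate detection rates (power and false-positive rate)
#'
#' Per (scenario, method): the detection rate over coupled replicates is
#' the power; over uncoupled replicates it is the false-positive rate.
#' Indeterminate/failed results count as "not detected".
#'
#' @param results Long results table from [evaluate_grid()] (or rows of the
#'   same shape).
#' @return An `evaluation_table` data frame with columns `n_taxa`,
#'   `n_chars`, `k_states`, `sigma`, `coupled`, `method`, `n_replicates`,
#'   `n_detected`, `detection_rate`.
#' @export
compute_rates <- function(results) {
  agg <- stats::aggregate(
    cbind(n_detected = detected, n_replicates = rep(1, nrow(results))) ~
      n_taxa + n_chars + k_states + sigma + coupled + method,
    data = transform(results, detected = as.integer(detected)),
    FUN = sum)
  agg$detection_rate <- agg$n_detected / agg$n_replicates
  class(agg) <- c("evaluation_table", class(agg))
  agg
}

#' Pooled detection percentages per method
#'
#' Unweighted mean of per-scenario detection rates (equal to the
#' replicate-weighted mean under a balanced design), as a percentage.
#'
#' @param table An `evaluation_table` from [compute_rates()].
#' @return Data frame with `method`, `coupled`, `percent_detected`.
#' @export
pooled_rates <- function(table) {
  agg <- stats::aggregate(detection_rate ~ method + coupled, data = table,
                          FUN = mean)
  agg$percent_detected <- 100 * agg$detection_rate
  agg$detection_rate <- NULL
  agg
}

#' Export evaluation tables as CSV files
#'
#' Writes the long table (`results_long.csv`), one heatmap-shaped wide CSV
#' per method (`heatmap_<method>.csv`; rows sigma x state count, columns
#' character count x tree size), and the pooled summary
#' (`summary_pooled.csv`).
#'
#' @param table An `evaluation_table`.
#' @param outdir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
export_tables <- function(table, outdir) {
  if (!nrow(table)) {
    warning("empty evaluation table; nothing exported")
    return(invisible(character()))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- file.path(outdir, "results_long.csv")
  utils::write.csv(table, files[1], row.names = FALSE)
  for (m in unique(table$method)) {
    for (cp in unique(table$coupled)) {
      sub <- table[table$method == m & table$coupled == cp, ]
      if (!nrow(sub)) next
      sigmas <- sort(unique(sub$sigma))
      ks <- sort(unique(sub$k_states))
      chs <- sort(unique(sub$n_chars))
      nts <- sort(unique(sub$n_taxa))
      wide <- matrix(NA_real_, length(sigmas) * length(ks),
                     length(chs) * length(nts))
      rn <- character(nrow(wide)); cn <- character(ncol(wide))
      for (i in seq_along(sigmas)) for (j in seq_along(ks)) {
        rn[(i - 1) * length(ks) + j] <- sprintf("sigma%.2f_k%d",
                                                sigmas[i], ks[j])
      }
      for (a in seq_along(chs)) for (b in seq_along(nts)) {
        cn[(a - 1) * length(nts) + b] <- sprintf("chars%d_taxa%d",
                                                 chs[a], nts[b])
      }
      dimnames(wide) <- list(rn, cn)
      for (r in seq_len(nrow(sub))) {
        ri <- (match(sub$sigma[r], sigmas) - 1) * length(ks) +
          match(sub$k_states[r], ks)
        ci <- (match(sub$n_chars[r], chs) - 1) * length(nts) +
          match(sub$n_taxa[r], nts)
        wide[ri, ci] <- sub$detection_rate[r]
      }
      f <- file.path(outdir, sprintf("heatmap_%s_%s.csv", m,
                                     if (cp) "coupled" else "uncoupled"))
      utils::write.csv(as.data.frame(wide), f, row.names = TRUE)
      files <- c(files, f)
    }
  }
  f <- file.path(outdir, "summary_pooled.csv")
  utils::write.csv(pooled_rates(table), f, row.names = FALSE)
  files <- c(files, f)
  invisible(files)
}
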