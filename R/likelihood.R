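# Fixed-topology likelihood computation and maximum-likelihood branch-length
# estimation. The pruning kernels live in src/likelihood.cpp; this file
# prepares site-pattern-compressed partitions and exposes the user API.

NUC_CODES <- c(A = 0L, C = 1L, G = 2L, T = 3L)

# Convert a data matrix (taxa x columns) to 0-based integer states with -1
# for missing/ambiguous cells.
data_to_int <- function(data, model) {
  if (inherits(model, "nuc_model")) {
    m <- matrix(NUC_CODES[toupper(data)], nrow(data), ncol(data))
    m[is.na(m)] <- -1L
  } else {
    m <- matrix(as.integer(data), nrow(data), ncol(data))
    if (any(m >= model$k, na.rm = TRUE))
      stop(sprintf("character state >= k_states (%d) in data", model$k))
    if (any(m < 0, na.rm = TRUE)) stop("negative character state in data")
    m[is.na(m)] <- -1L
  }
  rownames(m) <- rownames(data)
  m
}

# Build the partition list consumed by the C++ kernels. `tree_post` must be
# in postorder; tip rows are matched to tip labels.
build_partition <- function(tree_post, data, model) {
  labs <- rownames(data)
  if (is.null(labs) || !setequal(labs, tree_post$tip.label))
    stop("tip labels of the data do not match the tree")
  m <- data_to_int(data, model)[tree_post$tip.label, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = ",")
  lev <- unique(key)
  f <- factor(key, levels = lev)
  weights <- as.numeric(tabulate(f, nbins = length(lev)))
  tipstates <- t(m[, match(lev, key), drop = FALSE])   # npat x ntip
  eig <- model_eigen(model)
  k <- model$k
  # stationary probability of each pattern being compatible with an
  # invariant site (all non-missing tips in the same state)
  invprob <- vapply(seq_len(nrow(tipstates)), function(j) {
    s <- tipstates[j, ]
    ok <- vapply(0:(k - 1), function(st) all(s < 0 | s == st), logical(1))
    sum(eig$pi[ok])
  }, numeric(1))
  crates <- discrete_gamma(model$gamma_shape, model$n_categories)
  list(tipstates = tipstates, weights = weights, U = eig$U, Uinv = eig$Uinv,
       lambda = eig$lambda, pi = eig$pi, crates = crates,
       cweights = rep(1 / model$n_categories, model$n_categories),
       pinv = model$p_inv, invprob = invprob,
       n_columns = ncol(data))
}

# Reorder a tree into postorder and return the permutation that maps original
# tree$edge rows to postorder rows.
postorder_tree <- function(tree) {
  post <- ape::reorder.phylo(tree, "postorder")
  perm <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(tree = post, perm = perm)
}

loglik_partitions <- function(tree, branch_lengths, parts, scalars) {
  po <- postorder_tree(tree)
  rl_loglik_cpp(po$tree$edge, ape::Ntip(tree),
                as.numeric(branch_lengths)[po$perm], parts,
                as.numeric(scalars))
}

#' Log-likelihood of a nucleotide alignment (GTR+G+I)
#'
#' Felsenstein pruning with 4-category discrete-gamma rates and a proportion
#' of invariant sites: the likelihood of a site is
#' `p_inv * I(site invariant-compatible) * pi(state) +
#'  (1 - p_inv) * mean over categories of the category likelihood`.
#'
#' @param topology A `phylo` tree (rooted or unrooted).
#' @param branch_lengths Branch lengths in `topology$edge` order
#'   (substitutions/site); when `NULL`, `topology$edge.length` is used.
#' @param aln Character matrix of nucleotides with tip rownames.
#' @param model A [nuc_model()].
#' @return The log-likelihood (a single number).
#' @export
nucleotide_loglik <- function(topology, branch_lengths = NULL, aln,
                              model = nuc_model()) {
  if (is.null(branch_lengths)) branch_lengths <- topology$edge.length
  if (length(branch_lengths) != nrow(topology$edge))
    stop("`branch_lengths` must have one entry per edge")
  if (any(branch_lengths < 0)) stop("branch lengths must be >= 0")
  po <- postorder_tree(topology)
  part <- build_partition(po$tree, aln, model)
  rl_loglik_cpp(po$tree$edge, ape::Ntip(topology),
                as.numeric(branch_lengths)[po$perm], list(part), 1.0)
}

#' Log-likelihood of a morphological character matrix (Mk+G)
#'
#' Missing cells contribute a partial likelihood of 1 over all states. With
#' `ascertainment = "variable_only"` each character's likelihood is divided
#' by one minus the probability of an invariant pattern (Lewis's conditioning
#' for matrices that exclude invariant characters).
#'
#' @param topology A `phylo` tree.
#' @param branch_lengths Branch lengths in `topology$edge` order
#'   (changes/character); `NULL` uses `topology$edge.length`.
#' @param chars Integer character matrix (`0..k-1`, `NA` missing).
#' @param model A [morph_model()].
#' @param ascertainment `"none"` or `"variable_only"`.
#' @return The log-likelihood.
#' @export
morphology_loglik <- function(topology, branch_lengths = NULL, chars,
                              model = morph_model(),
                              ascertainment = c("none", "variable_only")) {
  ascertainment <- match.arg(ascertainment)
  if (is.null(branch_lengths)) branch_lengths <- topology$edge.length
  if (length(branch_lengths) != nrow(topology$edge))
    stop("`branch_lengths` must have one entry per edge")
  po <- postorder_tree(topology)
  part <- build_partition(po$tree, chars, model)
  el <- as.numeric(branch_lengths)[po$perm]
  ll <- rl_loglik_cpp(po$tree$edge, ape::Ntip(topology), el, list(part), 1.0)
  if (ascertainment == "variable_only") {
    p_const <- prob_constant_patterns(po$tree, el, model)
    ll <- ll - ncol(chars) * log1p(-p_const)
  }
  ll
}

# Probability that a character is invariant (all tips share one state),
# summed over the k constant patterns under the given model and lengths.
prob_constant_patterns <- function(tree_post, el_post, model) {
  n <- ape::Ntip(tree_post)
  lik_s <- vapply(seq_len(model$k) - 1L, function(s) {
    const <- matrix(s, n, 1, dimnames = list(tree_post$tip.label, NULL))
    part <- build_partition(tree_post, const, model)
    exp(rl_loglik_cpp(tree_post$edge, n, el_post, list(part), 1.0))
  }, numeric(1))
  sum(lik_s)
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate-wise Brent optimization of every branch length in
#' `[0, el_max]`, sweeping the tree with cached partial likelihoods until the
#' total log-likelihood improves by less than `tol` between sweeps.
#'
#' @param topology A `phylo` tree; rooted input is unrooted first (the two
#'   root-adjacent branch lengths are not separately identifiable under a
#'   reversible model).
#' @param data Alignment or character matrix matching the model type.
#' @param model A [nuc_model()] or [morph_model()].
#' @param init Initial branch length for all edges.
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_rounds Maximum optimization sweeps; non-convergence sets the
#'   `converged` flag to `FALSE` (with a warning) rather than failing.
#' @param el_max Upper bound on any branch length (changes/site).
#' @return List with `tree` (fitted unrooted phylogram), `branch_lengths`
#'   (in `tree$edge` order), `log_likelihood`, `converged`, `rounds`,
#'   `n_free_params`, `n_columns`.
#' @export
optimize_branch_lengths <- function(topology, data, model, init = 0.05,
                                    tol = 1e-6, max_rounds = 200L,
                                    el_max = 10) {
  tr <- if (ape::is.rooted(topology) && ape::Ntip(topology) > 2)
    ape::unroot(topology) else topology
  po <- postorder_tree(tr)
  part <- build_partition(po$tree, data, model)
  ne <- nrow(tr$edge)
  el0 <- if (length(init) == 1L) rep(init, ne) else as.numeric(init)[po$perm]
  res <- rl_optim_edges_cpp(po$tree$edge, ape::Ntip(tr),
                            if (length(init) == 1L) el0 else el0,
                            list(part), 1.0, el_max, tol,
                            as.integer(max_rounds))
  if (!res$converged)
    warning("branch-length optimization did not converge within max_rounds")
  el <- numeric(ne)
  el[po$perm] <- res$el
  fit_tree <- tr
  fit_tree$edge.length <- el
  list(tree = fit_tree, branch_lengths = el, log_likelihood = res$loglik,
       converged = res$converged, rounds = res$rounds,
       n_free_params = ne, n_columns = part$n_columns)
}

#' Fit the unlinked branch-length model
#'
#' Molecular and morphological branch lengths are optimized independently on
#' the shared (fixed) topology; the total log-likelihood is the sum of the
#' two fits. Free parameters: two full sets of `2n - 3` unrooted branch
#' lengths (substitution-model parameters are held fixed).
#'
#' @param topology Shared `phylo` topology (a chronogram is accepted; it is
#'   unrooted internally).
#' @param aln Nucleotide alignment matrix.
#' @param chars Morphological character matrix.
#' @param nuc_mod,morph_mod Substitution models.
#' @param ... Passed to [optimize_branch_lengths()].
#' @return An `rl_fit` object.
#' @export
fit_unlinked <- function(topology, aln, chars, nuc_mod = nuc_model(),
                         morph_mod = morph_model(), ...) {
  mol <- optimize_branch_lengths(topology, aln, nuc_mod, ...)
  morph <- optimize_branch_lengths(topology, chars, morph_mod, ...)
  structure(list(
    linkage = "unlinked", mol_fit = mol, morph_fit = morph,
    branch_lengths = list(mol = mol$branch_lengths,
                          morph = morph$branch_lengths),
    log_likelihood = mol$log_likelihood + morph$log_likelihood,
    converged = mol$converged && morph$converged,
    n_free_params = mol$n_free_params + morph$n_free_params,
    n_columns = mol$n_columns + morph$n_columns), class = "rl_fit")
}

#' Fit the linked ("proportionate") branch-length model
#'
#' One shared set of branch lengths `b` serves the molecular data; the
#' morphological branch lengths are `c * b` for a single scalar `c >= 0`.
#' `b` and `c` are optimized jointly by alternating coordinate sweeps over
#' `b` (both partitions contributing) with 1-D optimization of `c`.
#'
#' @inheritParams fit_unlinked
#' @param c_init Starting value of the proportionality constant.
#' @param tol Convergence tolerance on the joint log-likelihood.
#' @param max_outer Maximum alternations.
#' @param init Initial shared branch length.
#' @param el_max Upper branch-length bound.
#' @return An `rl_fit` object with elements `c` (the fitted proportionality
#'   constant) and `branch_lengths` (the shared set, molecular scale).
#' @export
fit_linked <- function(topology, aln, chars, nuc_mod = nuc_model(),
                       morph_mod = morph_model(), c_init = 1,
                       init = 0.05, tol = 1e-6, max_outer = 100L,
                       el_max = 10) {
  tr <- if (ape::is.rooted(topology) && ape::Ntip(topology) > 2)
    ape::unroot(topology) else topology
  po <- postorder_tree(tr)
  p_mol <- build_partition(po$tree, aln, nuc_mod)
  p_morph <- build_partition(po$tree, chars, morph_mod)
  parts <- list(p_mol, p_morph)
  ne <- nrow(tr$edge)
  el <- rep(init, ne)
  cc <- c_init
  n_tip <- ape::Ntip(tr)
  ll <- rl_loglik_cpp(po$tree$edge, n_tip, el, parts, c(1, cc))
  converged <- FALSE
  for (i in seq_len(max_outer)) {
    res <- rl_optim_edges_cpp(po$tree$edge, n_tip, el, parts, c(1, cc),
                              el_max, tol, 2L)
    el <- res$el
    # ridge move: rescale the shared lengths for the molecular partition
    # while keeping the morphological lengths c * b fixed (b <- t b,
    # c <- c / t); plain coordinate alternation zigzags along this ridge
    opt_t <- stats::optimize(function(lt) {
      rl_loglik_cpp(po$tree$edge, n_tip, el * exp(lt), list(p_mol), 1.0)
    }, interval = c(-4, 4), maximum = TRUE, tol = 1e-7)
    tt <- exp(opt_t$maximum)
    if (all(el * tt <= el_max)) {
      el <- el * tt
      cc <- cc / tt
    }
    # conditional update of the proportionality constant
    opt <- stats::optimize(function(lc) {
      rl_loglik_cpp(po$tree$edge, n_tip, el, list(p_morph), exp(lc))
    }, interval = c(-8, 8), maximum = TRUE, tol = 1e-7)
    cc <- exp(opt$maximum)
    ll_new <- rl_loglik_cpp(po$tree$edge, n_tip, el, parts, c(1, cc))
    if (ll_new - ll < tol) { ll <- max(ll, ll_new); converged <- TRUE; break }
    ll <- ll_new
  }
  if (!converged)
    warning("linked-model optimization did not converge within max_outer")
  bl <- numeric(ne)
  bl[po$perm] <- el
  fit_tree <- tr
  fit_tree$edge.length <- bl
  structure(list(
    linkage = "linked", tree = fit_tree, c = cc,
    branch_lengths = list(mol = bl, morph = bl * cc),
    log_likelihood = ll, converged = converged,
    n_free_params = ne + 1L,
    n_columns = p_mol$n_columns + p_morph$n_columns), class = "rl_fit")
}

#' Information criteria for a fitted model
#'
#' `AIC = 2k - 2 lnL`; `AICc = AIC + 2k(k+1)/(n-k-1)`;
#' `BIC = k ln(n) - 2 lnL`, with `n` the total number of data columns
#' (alignment sites plus characters). AICc is undefined (`NA`, flagged) when
#' `n <= k + 1`.
#'
#' @param fit An `rl_fit` (or any list with `log_likelihood`,
#'   `n_free_params`, `n_columns`).
#' @return List with `aic`, `aicc`, `bic`, `k`, `n`, `aicc_defined`.
#' @export
information_criteria <- function(fit) {
  k <- fit$n_free_params
  n <- fit$n_columns
  ll <- fit$log_likelihood
  aic <- 2 * k - 2 * ll
  aicc_defined <- n > k + 1
  aicc <- if (aicc_defined) aic + 2 * k * (k + 1) / (n - k - 1) else NA_real_
  list(aic = aic, aicc = aicc, bic = k * log(n) - 2 * ll,
       k = k, n = n, aicc_defined = aicc_defined)
}

#' Compare linked and unlinked branch-length models by AICc and BIC
#'
#' @param fit_linked,fit_unlinked `rl_fit` objects for the same data.
#' @param threshold Decision threshold on the criterion difference
#'   (unlinked minus linked); the default 2.5 declares support for the
#'   linked model when `delta > 2.5` (strict).
#' @return A `model_selection_result`: criterion values, deltas
#'   (unlinked - linked) and decisions (`"linked"`, `"unlinked"` or
#'   `"indeterminate"`).
#' @export
model_selection <- function(fit_linked, fit_unlinked, threshold = 2.5) {
  ic_l <- information_criteria(fit_linked)
  ic_u <- information_criteria(fit_unlinked)
  decide <- function(delta) {
    if (is.na(delta)) "indeterminate"
    else if (delta > threshold) "linked"
    else if (delta < -threshold) "unlinked"
    else "indeterminate"
  }
  d_aicc <- ic_u$aicc - ic_l$aicc
  d_bic <- ic_u$bic - ic_l$bic
  structure(list(
    aicc_linked = ic_l$aicc, aicc_unlinked = ic_u$aicc,
    bic_linked = ic_l$bic, bic_unlinked = ic_u$bic,
    delta_aicc = d_aicc, delta_bic = d_bic,
    decision_aicc = decide(d_aicc), decision_bic = decide(d_bic),
    threshold = threshold), class = "model_selection_result")
}

#' Root an unrooted fitted phylogram at a chronogram's root position
#'
#' ML fits are performed on the unrooted topology, where the two
#' root-adjacent branches of the original chronogram collapse into one. To
#' compute root-to-tip distances the fitted tree is re-rooted on that branch,
#' splitting its fitted length between the two sides in proportion to the
#' chronogram's basal branch durations.
#'
#' @param phy Unrooted fitted `phylo` phylogram.
#' @param chronogram The rooted chronogram defining the root position.
#' @return A rooted `phylo` phylogram.
#' @export
root_phylogram <- function(phy, chronogram) {
  if (ape::is.rooted(phy)) return(phy)
  n <- ape::Ntip(chronogram)
  root <- n + 1L
  basal <- which(chronogram$edge[, 1] == root)
  kids <- chronogram$edge[basal, 2]
  durs <- chronogram$edge.length[basal]
  tips_below <- function(tree, v) {
    if (v <= ape::Ntip(tree)) tree$tip.label[v]
    else ape::extract.clade(tree, v)$tip.label
  }
  clade1 <- tips_below(chronogram, kids[1])
  rt <- ape::root(phy, outgroup = clade1, resolve.root = TRUE)
  rbasal <- which(rt$edge[, 1] == ape::Ntip(rt) + 1L)
  stopifnot(length(rbasal) == 2L)
  total <- sum(rt$edge.length[rbasal])
  rkids <- rt$edge[rbasal, 2]
  side1 <- vapply(rkids, function(v) setequal(tips_below(rt, v), clade1),
                  logical(1))
  f1 <- durs[1] / sum(durs)
  rt$edge.length[rbasal[side1]] <- total * f1
  rt$edge.length[rbasal[!side1]] <- total * (1 - f1)
  rt
}
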