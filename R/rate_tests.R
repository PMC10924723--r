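# The five detection procedures that decide, for one molecular/morphological
# pair, whether evolutionary rates are correlated, plus the shared Spearman
# utility. Each test returns a `test_result` with the statistic, a p-value
# (or criterion difference / log Bayes factor), and the boolean call.

test_result <- function(method, statistic, p_value = NA_real_, detected,
                        n_points = NA_integer_, options = list()) {
  structure(list(method = method, statistic = statistic, p_value = p_value,
                 detected = isTRUE(detected), n_points = n_points,
                 options = options), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g", x$method, x$statistic))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  cat(sprintf(", detected = %s (n = %s)\n", x$detected, x$n_points))
  invisible(x)
}

# cached exact null distributions of the Spearman statistic (by n)
spearman_null_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (pos in seq_len(n)) {
    # insert the value n at position pos of every (n-1)-permutation
    left <- if (pos > 1) sub[, seq_len(pos - 1L), drop = FALSE] else NULL
    right <- if (pos < n) sub[, pos:(n - 1L), drop = FALSE] else NULL
    out[r + seq_len(nrow(sub)), ] <- cbind(left, n, right)
    r <- r + nrow(sub)
  }
  out
}

spearman_exact_null <- function(n) {
  key <- as.character(n)
  if (!is.null(spearman_null_cache[[key]])) return(spearman_null_cache[[key]])
  perms <- all_permutations(n)
  base <- seq_len(n)
  d2 <- rowSums((perms - matrix(base, nrow(perms), n, byrow = TRUE))^2)
  rho <- 1 - 6 * d2 / (n * (n^2 - 1))
  spearman_null_cache[[key]] <- rho
  rho
}

#' Spearman rank correlation with exact small-sample p-values
#'
#' Rank correlation with average ranks for ties. P-values are exact
#' (enumeration of all rank permutations) for n <= 9 with untied data, and
#' use the t approximation otherwise.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return List with `rho`, `p_two_sided`, `p_one_sided` (alternative
#'   rho > 0), `n`, and `exact` (logical).
#' @export
#' @examples
#' spearman_test(1:4, c(2, 1, 4, 3))
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3) stop("need equal-length vectors with n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    return(list(rho = NA_real_, p_two_sided = NA_real_,
                p_one_sided = NA_real_, n = n, exact = FALSE,
                degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  ties <- anyDuplicated(rx) > 0 || anyDuplicated(ry) > 0
  if (n <= 9 && !ties) {
    null_rho <- spearman_exact_null(n)
    eps <- 1e-12
    p2 <- mean(abs(null_rho) >= abs(rho) - eps)
    p1 <- mean(null_rho >= rho - eps)
    return(list(rho = rho, p_two_sided = p2, p_one_sided = p1, n = n,
                exact = TRUE))
  }
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-12))
  p1 <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  p2 <- 2 * min(p1, 1 - p1)
  list(rho = rho, p_two_sided = min(p2, 1), p_one_sided = p1, n = n,
       exact = FALSE)
}

#' Root-to-tip distance correlation test
#'
#' Computes patristic root-to-tip distances on the molecular and
#' morphological phylograms, their Pearson correlation, and a one-sided
#' permutation p-value (tip labels of one vector shuffled `n_perm` times;
#' `p = (1 + #\{r_perm >= r_obs\}) / (n_perm + 1)`). Optionally removes
#' tips lying outside 1.5 times the interquartile range in either distance
#' vector before testing.
#'
#' @param mol,morph Rooted `phylo` phylograms on the same tips.
#' @param n_perm Number of permutations (default 20000).
#' @param alpha Significance level (default 0.05); detection requires
#'   `p < alpha` (strict).
#' @param remove_outliers Apply the 1.5 IQR tip filter first.
#' @param seed Integer seed for the permutations.
#' @param statistic `"pearson"` (default) or `"spearman"` correlation.
#' @param exhaustive Enumerate all `n!` tip permutations instead of random
#'   sampling (only allowed for n <= 7); the p-value is then exact.
#' @return A `test_result`.
#' @export
root_to_tip_test <- function(mol, morph, n_perm = 20000L, alpha = 0.05,
                             remove_outliers = FALSE, seed = NULL,
                             statistic = c("pearson", "spearman"),
                             exhaustive = FALSE) {
  statistic <- match.arg(statistic)
  if (!ape::is.rooted(mol) || !ape::is.rooted(morph))
    stop("root-to-tip distances require rooted phylograms")
  if (!setequal(mol$tip.label, morph$tip.label))
    stop("tip sets differ between the two phylograms")
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  rtt <- function(phy) {
    d <- ape::node.depth.edgelength(phy)[seq_len(ape::Ntip(phy))]
    stats::setNames(d, phy$tip.label)
  }
  x <- rtt(mol)
  y <- rtt(morph)[names(x)]
  if (remove_outliers) {
    out_of <- function(v) {
      q <- stats::quantile(v, c(0.25, 0.75), names = FALSE)
      iqr <- q[2] - q[1]
      v < q[1] - 1.5 * iqr | v > q[2] + 1.5 * iqr
    }
    drop <- out_of(x) | out_of(y)
    x <- x[!drop]; y <- y[!drop]
  }
  n <- length(x)
  if (n < 3) stop("fewer than 3 tips remain after outlier removal")
  if (statistic == "spearman") { x <- rank(x); y <- rank(y) }
  r_obs <- stats::cor(x, y)
  xc <- x - mean(x); yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  if (exhaustive) {
    if (n > 7) stop("exhaustive permutation only supported for n <= 7")
    perms <- all_permutations(n)
    r_perm <- vapply(seq_len(nrow(perms)), function(i)
      sum(xc * yc[perms[i, ]]) / denom, numeric(1))
    p <- mean(r_perm >= r_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    r_perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
      sum(xc * yc[sample.int(n)]) / denom
    }, numeric(1)))
    p <- (1 + sum(r_perm >= r_obs)) / (n_perm + 1)
  }
  test_result("root_to_tip", statistic = r_obs, p_value = p,
              detected = p < alpha, n_points = n,
              options = list(n_perm = n_perm, alpha = alpha,
                             remove_outliers = remove_outliers,
                             statistic = statistic, exhaustive = exhaustive))
}

#' Extract phylogenetically independent sister pairs (cherries)
#'
#' Returns every internal node whose two children are both tips; the
#' resulting pairs are disjoint by construction.
#'
#' @param topology Rooted binary `phylo` tree.
#' @return Data frame with columns `tip1`, `tip2` (lexicographic within the
#'   pair) and `node` (the pair's most recent common ancestor).
#' @export
extract_sister_pairs <- function(topology) {
  n <- ape::Ntip(topology)
  edge <- topology$edge
  is_tip_child <- edge[, 2] <= n
  tab <- tapply(is_tip_child, edge[, 1], sum)
  cherries <- as.integer(names(tab)[tab == 2])
  rows <- lapply(cherries, function(v) {
    tips <- sort(topology$tip.label[edge[edge[, 1] == v & is_tip_child, 2]])
    data.frame(tip1 = tips[1], tip2 = tips[2], node = v)
  })
  if (!length(rows))
    return(data.frame(tip1 = character(), tip2 = character(),
                      node = integer()))
  do.call(rbind, rows)
}

#' Independent sister-pairs contrasts test
#'
#' For each cherry, the contrast in data type X is
#' `[log(b1 + eps) - log(b2 + eps)] / sqrt(t_pair)` where `b1`, `b2` are the
#' two tip branch lengths (taxa ordered lexicographically within the pair)
#' and `t_pair` is the pair's divergence time in Myr from the chronogram.
#' Molecular and morphological contrasts are compared with Spearman's rank
#' correlation (two-sided p); detection requires `p < alpha` and `rho > 0`.
#'
#' @param chrono Rooted chronogram supplying divergence times.
#' @param mol,morph Phylograms on the same topology.
#' @param alpha Significance level.
#' @param epsilon Pseudocount guarding against zero branch lengths.
#' @return A `test_result`.
#' @export
sister_pairs_test <- function(chrono, mol, morph, alpha = 0.05,
                              epsilon = 1e-9) {
  pairs <- extract_sister_pairs(chrono)
  if (nrow(pairs) < 3)
    stop("fewer than 3 sister pairs; test refused")
  ages <- node_ages(chrono)
  tip_lengths <- function(phy) {
    idx <- phy$edge[, 2] <= ape::Ntip(phy)
    stats::setNames(phy$edge.length[idx], phy$tip.label[phy$edge[idx, 2]])
  }
  contrast <- function(phy) {
    b <- tip_lengths(phy)
    (log(b[pairs$tip1] + epsilon) - log(b[pairs$tip2] + epsilon)) /
      sqrt(ages[pairs$node])
  }
  cx <- contrast(mol)
  cy <- contrast(morph)
  sp <- spearman_test(cx, cy)
  detected <- !isTRUE(sp$degenerate) && sp$p_two_sided < alpha && sp$rho > 0
  test_result("sister_pairs", statistic = sp$rho,
              p_value = sp$p_two_sided, detected = detected,
              n_points = nrow(pairs),
              options = list(alpha = alpha, epsilon = epsilon))
}

#' Likelihood-based model-selection test
#'
#' Declares correlated rates when the information criterion of the unlinked
#' model exceeds that of the linked model by more than `threshold`
#' (`delta > 2.5`, strict, by default).
#'
#' @param msr A `model_selection_result` from [model_selection()].
#' @param criterion `"aicc"` or `"bic"`.
#' @param threshold Decision threshold (default 2.5).
#' @return A `test_result` (statistic is the criterion difference,
#'   unlinked minus linked).
#' @export
ml_modelsel_test <- function(msr, criterion = c("aicc", "bic"),
                             threshold = 2.5) {
  criterion <- match.arg(criterion)
  delta <- if (criterion == "aicc") msr$delta_aicc else msr$delta_bic
  detected <- !is.na(delta) && delta > threshold
  test_result(paste0("ml_modelsel_", criterion), statistic = delta,
              detected = detected,
              options = list(threshold = threshold))
}

#' Correlation test on Bayesian posterior branch rates
#'
#' Spearman rank correlation between per-branch posterior rates (mean or
#' median) of the molecular and morphological partitions, with a one-sided
#' p-value for positive correlation. Optionally drops the fraction of
#' branches with the smallest time duration first.
#'
#' @param mol_summary,morph_summary Per-partition data frames from
#'   [summarize_branch_rates()] (columns `branch`, `duration`, `mean`,
#'   `median`).
#' @param statistic `"mean"` or `"median"` posterior rate.
#' @param drop_shortest_fraction Fraction of chronologically shortest
#'   branches to remove, in `[0, 1)`.
#' @param alpha Significance level.
#' @return A `test_result`.
#' @export
bayes_branchrate_test <- function(mol_summary, morph_summary,
                                  statistic = c("median", "mean"),
                                  drop_shortest_fraction = 0,
                                  alpha = 0.05) {
  statistic <- match.arg(statistic)
  if (drop_shortest_fraction < 0 || drop_shortest_fraction >= 1)
    stop("`drop_shortest_fraction` must be in [0, 1)")
  if (!identical(sort(mol_summary$branch), sort(morph_summary$branch)))
    stop("branch sets differ between the two summaries")
  morph_summary <- morph_summary[match(mol_summary$branch,
                                       morph_summary$branch), ]
  keep <- rep(TRUE, nrow(mol_summary))
  if (drop_shortest_fraction > 0) {
    n_drop <- floor(drop_shortest_fraction * nrow(mol_summary))
    keep[order(mol_summary$duration)[seq_len(n_drop)]] <- FALSE
  }
  x <- mol_summary[[statistic]][keep]
  y <- morph_summary[[statistic]][keep]
  if (length(x) < 4) stop("fewer than 4 branches after dropping; test refused")
  sp <- spearman_test(x, y)
  detected <- !isTRUE(sp$degenerate) && sp$p_one_sided < alpha
  test_result(paste0("bayes_branch_rates_", statistic), statistic = sp$rho,
              p_value = sp$p_one_sided, detected = detected,
              n_points = length(x),
              options = list(statistic = statistic,
                             drop_shortest_fraction = drop_shortest_fraction,
                             alpha = alpha))
}

#' Bayesian model-selection test
#'
#' Declares correlated rates when the log Bayes factor in favour of the
#' linked clock model exceeds `threshold` (strict inequality).
#'
#' @param log_bf Log Bayes factor (linked minus unlinked, natural log), or
#'   the list returned by [bayes_factor()].
#' @param threshold Decision threshold (default 1.0).
#' @return A `test_result`.
#' @export
bayes_modelsel_test <- function(log_bf, threshold = 1.0) {
  if (is.list(log_bf)) log_bf <- log_bf$log_bf
  stopifnot(is.finite(log_bf))
  test_result("bayes_modelsel", statistic = log_bf,
              detected = log_bf > threshold,
              options = list(threshold = threshold))
}
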