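## Phylogenetic signal of a discrete trait: Sankoff minimum-transitions
## statistic with a permutation null, and the star-tree AIC comparison.

#' Minimum number of state transitions on a tree (Sankoff parsimony)
#'
#' Unordered states, unit cost per change, branch lengths ignored;
#' polytomies handled natively (the dynamic program sums over all
#' children).
#'
#' @param tree A `phylo`.
#' @param traits A [trait_data] matching the tree's leaf set.
#' @return Integer minimum number of changes.
#' @export
min_transitions <- function(tree, traits) {
  tipstate <- check_tree_traits(tree, traits) + 1L
  enc <- encode_tree(tree)
  k <- length(traits$alphabet)
  sankoff_min(enc, tipstate, k)
}

# Core DP shared with the permutation test (tip states already aligned to
# tree tip order, 1-based).
sankoff_min <- function(enc, tipstate, k) {
  n_total <- enc$ntip + enc$nnode
  cost <- matrix(0, k, n_total)
  cost[, seq_len(enc$ntip)] <- Inf
  cost[cbind(tipstate, seq_len(enc$ntip))] <- 0
  for (e in seq_len(nrow(enc$edge))) {
    p <- enc$edge[e, 1]; ch <- enc$edge[e, 2]
    cc <- cost[, ch]
    cost[, p] <- cost[, p] + pmin(min(cc) + 1, cc)
  }
  as.integer(min(cost[, enc$ntip + 1L]))
}

#' Brute-force minimum transitions by enumeration (test oracle)
#'
#' Exhausts all internal-node labelings (k^m); refuses m > 8.
#'
#' @inheritParams min_transitions
#' @return Integer minimum number of changes.
#' @export
brute_force_min_transitions <- function(tree, traits) {
  tree <- validate_tree(tree)
  m <- tree$Nnode
  if (m > 8L) stop("too many internal nodes for enumeration (", m, " > 8)")
  tipstate <- check_tree_traits(tree, traits) + 1L
  k <- length(traits$alphabet)
  ntip <- length(tree$tip.label)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  parents <- tree$edge[, 1] - ntip  # always internal
  kids <- tree$edge[, 2]
  kid_is_tip <- kids <= ntip
  best <- Inf
  kid_states <- integer(length(kids))
  kid_states[kid_is_tip] <- tipstate[kids[kid_is_tip]]
  for (r in seq_len(nrow(combos))) {
    combo <- combos[r, ]
    kid_states[!kid_is_tip] <- combo[kids[!kid_is_tip] - ntip]
    changes <- sum(combo[parents] != kid_states)
    if (changes < best) best <- changes
  }
  as.integer(best)
}

#' Permutation test for phylogenetic signal
#'
#' Compares the observed minimum number of transitions with a null
#' distribution obtained by uniformly permuting the tip phenotypes across
#' the tips and recomputing the statistic.  One-sided (fewer transitions
#' than the null = clustering = signal); ties count toward significance.
#' The p-value uses the add-one Monte-Carlo estimator
#' `(1 + #\{null <= observed\}) / (1 + n_perm)`, which never returns 0.
#'
#' @param tree A `phylo`.
#' @param traits A [trait_data].
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @return An object of class `signal_report`: `observed`,
#'   `null_distribution`, `null_median`, `p_value`, `n_permutations`,
#'   `seed`, and `delta_AIC_star` (`NA` here; see
#'   [star_tree_delta_aic()]).
#' @export
permutation_test <- function(tree, traits, n_perm = 10000, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  tipstate <- check_tree_traits(tree, traits) + 1L
  enc <- encode_tree(tree)
  k <- length(traits$alphabet)
  observed <- sankoff_min(enc, tipstate, k)
  null_dist <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      sankoff_min(enc, sample(tipstate), k)
    }, integer(1))
  })
  structure(list(observed = observed,
                 null_distribution = null_dist,
                 null_median = median(null_dist),
                 p_value = (1 + sum(null_dist <= observed)) / (1 + n_perm),
                 n_permutations = as.integer(n_perm),
                 seed = as.integer(seed),
                 delta_AIC_star = NA_real_),
            class = "signal_report")
}

#' @export
print.signal_report <- function(x, ...) {
  cat(sprintf(paste0("signal_report: observed min transitions = %d, ",
                     "null median = %g, p = %.4g (%d permutations)\n"),
              x$observed, x$null_median, x$p_value, x$n_permutations))
  if (!is.na(x$delta_AIC_star)) {
    cat(sprintf("  delta AIC (star - tree) = %.3f\n", x$delta_AIC_star))
  }
  invisible(x)
}

#' Star-tree AIC difference (phylogenetic-signal strength)
#'
#' Runs the full eight-model AIC selection on the real tree and on
#' [make_star_tree()] of it, and returns `AIC(star best) - AIC(tree
#' best)`.  Positive values mean the trait fits the real tree better than
#' a structureless star, i.e. phylogenetic signal.
#'
#' @inheritParams select_best
#' @return Scalar AIC difference.
#' @export
star_tree_delta_aic <- function(tree, traits, pi = "uniform", opts = fit_opts()) {
  sel_tree <- select_best(tree, traits, pi, opts)
  sel_star <- select_best(make_star_tree(tree), traits, pi, opts)
  best_aic <- function(sel) min(sel$table$AIC)
  best_aic(sel_star) - best_aic(sel_tree)
}

#' Combined signal report (permutation test + star-tree AIC)
#'
#' @inheritParams permutation_test
#' @param pi Root prior for the ML fits.
#' @param opts [fit_opts()] for the ML fits.
#' @return A `signal_report` with `delta_AIC_star` filled in.
#' @export
phylo_signal <- function(tree, traits, n_perm = 10000, seed = 1L,
                         pi = "uniform", opts = fit_opts()) {
  rep <- permutation_test(tree, traits, n_perm = n_perm, seed = seed)
  rep$delta_AIC_star <- star_tree_delta_aic(tree, traits, pi, opts)
  rep
}

#' Serialize a signal report
#'
#' JSON plus a one-row TSV (statistic, null median, p, delta AIC).
#'
#' @param rep A `signal_report`.
#' @param json_file,tsv_file Output paths (`NULL` to skip).
#' @export
write_signal_report <- function(rep, json_file = NULL, tsv_file = NULL) {
  row <- data.frame(min_transitions = rep$observed,
                    null_median = rep$null_median,
                    p_value = rep$p_value,
                    n_permutations = rep$n_permutations,
                    delta_AIC_star = rep$delta_AIC_star)
  if (!is.null(json_file)) {
    jsonlite::write_json(unclass(rep), json_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  if (!is.null(tsv_file)) {
    write.table(row, tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(row)
}
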