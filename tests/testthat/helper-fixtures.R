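# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code under explicit seeds; no data files.

# Random rooted binary-or-polytomous tree with given tip count: random
# recursive partitioning, so polytomies arise naturally.
random_tree <- function(n_tips, max_bl = 2, p_zero = 0.1) {
  build <- function(labels) {
    if (length(labels) == 1) return(labels)
    n_child <- if (length(labels) == 2) 2 else sample(2:min(3, length(labels)), 1)
    splits <- sort(sample(seq_len(length(labels) - 1), n_child - 1))
    groups <- split(labels, cut(seq_along(labels), c(0, splits, length(labels))))
    inner <- vapply(groups, build, character(1))
    bl <- ifelse(runif(n_child) < p_zero, 0, round(runif(n_child, 0.05, max_bl), 4))
    paste0("(", paste0(inner, ":", bl, collapse = ","), ")")
  }
  labels <- paste0("s", seq_len(n_tips))
  parse_newick(paste0(build(sample(labels)), ";"))
}

random_q <- function(k = 5, max_rate = 1.5) {
  q_matrix(runif(k * (k - 1), 0, max_rate), alphabet = default_alphabet()[seq_len(k)])
}

random_traits <- function(tree, k = 5) {
  trait_data(setNames(sample(default_alphabet()[seq_len(k)],
                             length(tree$tip.label), replace = TRUE),
                      tree$tip.label))
}

# Independent marginal oracle: joint enumeration over ALL internal-node
# states, using the series matrix exponential (not the pruning kernel).
brute_marginal <- function(tree, traits, Q, pi, node) {
  tree <- validate_tree(tree)
  ntip <- length(tree$tip.label)
  m <- tree$Nnode
  k <- nrow(Q)
  stopifnot(m <= 6)
  tipstate <- as.integer(traits$index[tree$tip.label])
  pi <- phenotrans:::resolve_root_prior(pi, Q, k)
  Plist <- lapply(seq_len(nrow(tree$edge)), function(e) {
    phenotrans:::series_expm(unname(Q) * tree$edge.length[e])
  })
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))
  probs <- apply(combos, 1, function(combo) {
    st <- function(v) if (v <= ntip) tipstate[v] else combo[v - ntip]
    p <- pi[combo[1]]  # root is ntip+1 -> combo index 1
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * Plist[[e]][st(tree$edge[e, 1]), st(tree$edge[e, 2])]
    }
    p
  })
  marg <- numeric(k)
  for (s in seq_len(k)) {
    sel <- if (node <= ntip) tipstate[node] == s else combos[, node - ntip] == s
    marg[s] <- sum(probs[sel])
  }
  marg / sum(marg)
}

# O(n^2) rank-based Spearman rho, independent of stats::cor.
spearman_oracle <- function(x, y) {
  rk <- function(v) {
    vapply(seq_along(v), function(i) {
      less <- sum(v < v[i])
      ties <- sum(v == v[i])
      less + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- rk(x); ry <- rk(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Minimal model_counts object for Bayes-factor arithmetic tests.
fake_counts <- function(model, k, n, mu = 100, prior_only = FALSE) {
  structure(list(model = model, k = k, n = n, burn_in = 0,
                 meta = list(mu = mu, prior_only = prior_only,
                             move_probs = rj_moves())),
            class = "model_counts")
}

random_q_seeded <- function(seed) {
  set.seed(seed)
  random_q()
}

# Shuffle trait values across taxa (destroys phylogenetic signal).
with_seed_shuffle <- function(traits, seed) {
  set.seed(seed)
  trait_data(setNames(traits$alphabet[sample(traits$index)],
                      names(traits$index)),
             alphabet = traits$alphabet)
}
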