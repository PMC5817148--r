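## Mk-type likelihood engine: Q matrices, transition probabilities, pruning
## log-likelihood (C++ kernel), node marginals, and brute-force oracles.

#' Build an instantaneous rate matrix
#'
#' @param rates Either a full k x k matrix with nonnegative off-diagonals
#'   (the diagonal is recomputed), or a vector of off-diagonal rates in
#'   [state_pairs()] order (length 20 for the default alphabet).
#' @param alphabet State alphabet (ignored when `rates` is a matrix with
#'   dimnames).
#' @return A k x k `Q` matrix whose rows sum to zero.
#' @export
q_matrix <- function(rates, alphabet = default_alphabet()) {
  k <- length(alphabet)
  if (is.matrix(rates)) {
    if (nrow(rates) != ncol(rates)) stop("Q must be square")
    Q <- rates
    diag(Q) <- 0
  } else {
    pairs <- state_pairs(alphabet)
    if (length(rates) != nrow(pairs)) {
      stop("need ", nrow(pairs), " off-diagonal rates")
    }
    Q <- matrix(0, k, k, dimnames = list(alphabet, alphabet))
    Q[cbind(pairs$from_idx, pairs$to_idx)] <- rates
  }
  if (any(Q[row(Q) != col(Q)] < 0)) stop("off-diagonal rates must be >= 0")
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

#' Equal-rates Q matrix
#'
#' @param rate Shared off-diagonal rate.
#' @param alphabet State alphabet.
#' @export
equal_rates_q <- function(rate, alphabet = default_alphabet()) {
  q_matrix(rep(rate, length(alphabet) * (length(alphabet) - 1L)), alphabet)
}

#' Stationary distribution of a rate matrix
#'
#' Left null vector of Q, normalized to sum 1.  Only meaningful when the
#' chain has a single closed communicating class.
#'
#' @param Q Rate matrix.
#' @export
stationary_dist <- function(Q) {
  e <- eigen(t(Q))
  i <- which.min(abs(e$values))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

# Resolve a root prior spec ("uniform", "stationary", or a numeric vector)
# to a probability vector.
resolve_root_prior <- function(pi, Q = NULL, k = nrow(Q)) {
  if (is.character(pi)) {
    pi <- match.arg(pi, c("uniform", "stationary"))
    pi <- switch(pi,
      uniform = rep(1 / k, k),
      stationary = {
        if (is.null(Q)) stop("stationary prior needs Q")
        stationary_dist(Q)
      })
  }
  if (length(pi) != k) stop("root prior has wrong length")
  if (any(pi < 0)) stop("root prior entries must be >= 0")
  if (abs(sum(pi) - 1) > 1e-12) stop("root prior must sum to 1 (tolerance 1e-12)")
  as.numeric(pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by one-off eigendecomposition of Q with a scaling-and-squaring
#' fallback for defective or ill-conditioned cases (structural zeros in
#' reduced models can make Q non-diagonalizable).  Negative entries above
#' -1e-12 (roundoff) are clamped to zero; anything below errors.
#'
#' @param Q Rate matrix.
#' @param t Branch length, >= 0.
#' @return A stochastic matrix (rows sum to 1 within 1e-9).
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("t must be >= 0")
  P <- cpp_transition_matrix(unname(Q), t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Pruning log-likelihood of trait data on a tree
#'
#' Felsenstein's post-order pruning with per-node rescaling, so trees with
#' hundreds of tips do not underflow.  Returns `-Inf` (not an error) when
#' the data have probability zero under `(Q, pi)` — e.g. an all-zero Q
#' with tips in different states.
#'
#' @param tree A `phylo`.
#' @param traits A [trait_data]; leaf sets must match the tree exactly.
#' @param Q Rate matrix (dimension = alphabet size).
#' @param pi Root prior: `"uniform"` (default), `"stationary"`, or a
#'   probability vector.
#' @return Log-likelihood (scalar, possibly `-Inf`).
#' @export
log_likelihood <- function(tree, traits, Q, pi = "uniform") {
  k <- length(traits$alphabet)
  if (nrow(Q) != k) stop("Q dimension (", nrow(Q), ") != alphabet size (", k, ")")
  tipstate <- check_tree_traits(tree, traits)
  enc <- encode_tree(tree)
  pi <- resolve_root_prior(pi, Q, k)
  cpp_mk_loglik(enc$edge, enc$elen, enc$ntip, enc$nnode, tipstate, unname(Q), pi)
}

# Fast path used by optimizers and the MCMC: tree encoding and tip states
# precomputed once.
loglik_encoded <- function(enc, tipstate, Q, pi) {
  cpp_mk_loglik(enc$edge, enc$elen, enc$ntip, enc$nnode, tipstate, Q, pi)
}

#' Brute-force log-likelihood by enumeration (test oracle)
#'
#' Sums over all internal-node state assignments the product of the root
#' prior and per-edge transition probabilities.  Exponential in the number
#' of internal nodes; refuses more than 8.  Deliberately independent of
#' the pruning kernel: transition matrices come from a truncated power
#' series, not the eigendecomposition path.
#'
#' @inheritParams log_likelihood
#' @return Log-likelihood (scalar, possibly `-Inf`).
#' @export
brute_force_log_likelihood <- function(tree, traits, Q, pi = "uniform") {
  k <- length(traits$alphabet)
  if (nrow(Q) != k) stop("Q dimension mismatch")
  tree <- validate_tree(tree)
  m <- tree$Nnode
  if (m > 8L) stop("too many internal nodes for enumeration (", m, " > 8)")
  tipstate <- check_tree_traits(tree, traits) + 1L
  pi <- resolve_root_prior(pi, Q, k)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  Plist <- lapply(seq_len(nrow(tree$edge)),
                  function(e) series_expm(unname(Q) * tree$edge.length[e]))

  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), m)))  # 5^m x m
  state_of <- function(node, combo) {
    if (node <= ntip) tipstate[node] else combo[node - ntip]
  }
  total <- 0
  for (r in seq_len(nrow(combos))) {
    combo <- combos[r, ]
    p <- pi[combo[root - ntip]]
    for (e in seq_len(nrow(tree$edge))) {
      if (p == 0) break
      p <- p * Plist[[e]][state_of(tree$edge[e, 1], combo),
                          state_of(tree$edge[e, 2], combo)]
    }
    total <- total + p
  }
  if (total <= 0) -Inf else log(total)
}

# Truncated power-series matrix exponential (independent oracle for the
# kernel's exp(Qt); adequate for the small rates/branches used in tests).
series_expm <- function(A, nterms = 60L) {
  k <- nrow(A)
  out <- diag(k)
  term <- diag(k)
  for (m in seq_len(nterms)) {
    term <- term %*% A / m
    out <- out + term
  }
  out
}

#' Marginal posterior state probabilities at a node
#'
#' Combined up-pass/down-pass conditional on the tip data and `(Q, pi)`.
#' Errors when the data have probability zero (the marginal is undefined).
#'
#' @inheritParams log_likelihood
#' @param node Integer node id (ape convention), or `NULL` for a matrix of
#'   marginals at every node.
#' @return Probability vector over states (sums to 1 within 1e-9), or a
#'   (states x nodes) matrix when `node` is `NULL`.
#' @export
node_marginals <- function(tree, traits, Q, pi = "uniform", node = NULL) {
  k <- length(traits$alphabet)
  if (nrow(Q) != k) stop("Q dimension mismatch")
  tipstate <- check_tree_traits(tree, traits)
  enc <- encode_tree(tree)
  pi <- resolve_root_prior(pi, Q, k)
  M <- cpp_mk_marginals(enc$edge, enc$elen, enc$ntip, enc$nnode, tipstate,
                        unname(Q), pi)
  rownames(M) <- traits$alphabet
  if (is.null(node)) return(M)
  n_total <- enc$ntip + enc$nnode
  if (node < 1 || node > n_total) stop("node id out of range")
  M[, node]
}
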