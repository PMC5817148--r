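## Synthetic data: Yule trees, Gillespie trait simulation with recorded
## true histories, and a Wolbachia-like preset scenario (two major clades
## plus a distant outgroup, five phenotype states, heterogeneous rates).

#' Simulate a pure-birth (Yule) tree
#'
#' Starts from a root bifurcation; with k extant lineages the wait to the
#' next split is Exp(birth_rate * k), a uniformly chosen lineage splits,
#' and after reaching `n_tips` a final Exp(birth_rate * n_tips) stretch is
#' added.  The expected height is therefore
#' `sum(1 / (birth_rate * k), k = 2..n_tips)`.  The result is ultrametric
#' with tips labelled `t1..tn`.
#'
#' @param n_tips Number of leaves, >= 2.
#' @param birth_rate Per-lineage speciation rate, > 0.
#' @param seed RNG seed.
#' @return A `phylo`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = 1L) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (birth_rate <= 0) stop("birth_rate must be > 0")
  with_seed(seed, {
    n_internal <- n_tips - 1L
    root <- n_tips + 1L
    next_internal <- root + 1L
    # active lineages: parent node id and time at which they started
    act_parent <- c(root, root)
    act_start <- c(0, 0)
    edge_p <- integer(0); edge_c <- integer(0); edge_len <- numeric(0)
    now <- 0
    k <- 2L
    while (k < n_tips) {
      now <- now + rexp(1, birth_rate * k)
      i <- sample.int(k, 1)
      node <- next_internal
      next_internal <- next_internal + 1L
      edge_p <- c(edge_p, act_parent[i])
      edge_c <- c(edge_c, node)
      edge_len <- c(edge_len, now - act_start[i])
      act_parent <- c(act_parent[-i], node, node)
      act_start <- c(act_start[-i], now, now)
      k <- k + 1L
    }
    now <- now + rexp(1, birth_rate * n_tips)
    # pending lineages become tips 1..n
    for (i in seq_len(n_tips)) {
      edge_p <- c(edge_p, act_parent[i])
      edge_c <- c(edge_c, i)
      edge_len <- c(edge_len, now - act_start[i])
    }
    tr <- list(edge = cbind(edge_p, edge_c),
               edge.length = edge_len,
               tip.label = paste0("t", seq_len(n_tips)),
               Nnode = n_internal)
    class(tr) <- "phylo"
    tr <- ape::reorder.phylo(tr, "cladewise")
    validate_tree(tr)
  })
}

#' Simulate a discrete trait along a tree (Gillespie)
#'
#' Draws the root state from `pi`, then simulates the continuous-time
#' Markov chain along each branch with exponential waiting times, keeping
#' the full event history.
#'
#' @param tree A `phylo`.
#' @param Q Rate matrix.
#' @param pi Root prior (`"uniform"`, `"stationary"`, or a vector).
#' @param seed RNG seed.
#' @param alphabet State alphabet (dimension of `Q`).
#' @return List with `traits` (a [trait_data]), `history` (data frame:
#'   `edge`, `child`, `time`, `from`, `to`), `root_state` (label), and
#'   `node_states` (true state label per node, ape node order).
#' @export
simulate_trait <- function(tree, Q, pi = "uniform", seed = 1L,
                           alphabet = default_alphabet()) {
  tree <- validate_tree(tree)
  k <- nrow(Q)
  if (k != length(alphabet)) stop("Q dimension != alphabet size")
  pi <- resolve_root_prior(pi, Q, k)
  ntip <- length(tree$tip.label)
  pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  with_seed(seed, {
    state <- integer(ntip + tree$Nnode)
    root <- ntip + 1L
    state[root] <- sample.int(k, 1, prob = pi)
    hist_edge <- integer(0); hist_child <- integer(0)
    hist_time <- numeric(0); hist_from <- integer(0); hist_to <- integer(0)
    for (e in seq_len(nrow(pre$edge))) {
      p <- pre$edge[e, 1]; ch <- pre$edge[e, 2]
      s <- state[p]
      tleft <- pre$edge.length[e]
      elapsed <- 0
      repeat {
        exit <- -Q[s, s]
        if (exit <= 0) break
        w <- rexp(1, exit)
        if (w > tleft) break
        tleft <- tleft - w
        elapsed <- elapsed + w
        s_new <- sample.int(k, 1, prob = pmax(Q[s, ], 0) * (seq_len(k) != s))
        hist_edge <- c(hist_edge, e)
        hist_child <- c(hist_child, ch)
        hist_time <- c(hist_time, elapsed)
        hist_from <- c(hist_from, s)
        hist_to <- c(hist_to, s_new)
        s <- s_new
      }
      state[ch] <- s
    }
    history <- data.frame(edge = hist_edge, child = hist_child,
                          time = hist_time,
                          from = alphabet[hist_from], to = alphabet[hist_to],
                          stringsAsFactors = FALSE)
    traits <- trait_data(setNames(alphabet[state[seq_len(ntip)]],
                                  tree$tip.label), alphabet = alphabet)
    list(traits = traits, history = history,
         root_state = alphabet[state[root]],
         node_states = alphabet[state])
  })
}

#' Number of realized state changes in a simulated history
#'
#' Always >= the Sankoff minimum for the same realization (parsimony is a
#' lower bound on the true number of events).
#'
#' @param history History data frame from [simulate_trait()].
#' @return Integer event count.
#' @export
count_realized_transitions <- function(history) {
  nrow(history)
}

# Default 2-class generating model for the preset scenario: a fast class
# (rate 3.0) on the transitions repeatedly flagged as high in comparative
# work (PI->MK, MK->O, O->CI, MK->CI), six structurally-zero pairs among
# the rarely observed FI/PI/O interchanges, and a slow class (rate 0.3)
# on the remaining ten pairs.
scenario_true_model <- function(alphabet = default_alphabet()) {
  pairs <- state_pairs(alphabet)
  assignment <- rep(1L, nrow(pairs))  # slow class
  fast <- c("PI->MK", "MK->O", "O->CI", "MK->CI")
  zero <- c("FI->PI", "PI->FI", "FI->O", "O->FI", "PI->O", "O->PI")
  assignment[pairs$label %in% fast] <- 2L
  assignment[pairs$label %in% zero] <- 0L
  model <- rate_model(assignment, scheme = "true-2class", alphabet = alphabet)
  list(model = model, class_rates = c(0.3, 3.0)[seq_len(model$k)])
}

#' Wolbachia-like preset scenario
#'
#' Emulates the shape of the study system: 53 (`small`) or 71 (`large`)
#' ingroup strains split into two major clades "A" and "B", plus one
#' distant outgroup attached below the ingroup by a long stem (2x the
#' ingroup height).  Clade subtrees are Yule trees rescaled to height 0.8
#' under 0.2-length stems, so the ingroup height is 1.0.  Traits evolve
#' under a 2-class rate model (slow 0.3, fast 3.0, six zero pairs) from a
#' CI-skewed root prior (0.6 CI, 0.1 each other state).
#'
#' @param variant `"small"` (53 ingroup tips) or `"large"` (71).
#' @param seed RNG seed.
#' @return An object of class `sim_scenario`: `tree`, `traits`, `tags`
#'   (leaf-name sets `A`, `B`, `AB`), and `truth` (generating model, class
#'   rates, root prior, root state, history, event count).
#' @export
wolbachia_like_scenario <- function(variant = c("small", "large"), seed = 1L) {
  variant <- match.arg(variant)
  n_in <- if (variant == "small") 53L else 71L
  n_a <- ceiling(n_in / 2); n_b <- n_in - n_a
  alphabet <- default_alphabet()
  with_seed(seed, {
    seeds <- sample.int(2^31 - 1, 3)
    tr_a <- rescale_height(simulate_yule_tree(n_a, 1, seeds[1]), 0.8)
    tr_b <- rescale_height(simulate_yule_tree(n_b, 1, seeds[2]), 0.8)
    tr_a$tip.label <- paste0("A", seq_len(n_a))
    tr_b$tip.label <- paste0("B", seq_len(n_b))
    tree <- join_clades(tr_a, tr_b, stem = 0.2, ingroup_edge = 0.5,
                        outgroup = "OUT", outgroup_stem = 2.0)
    root_prior <- setNames(c(0.6, 0.1, 0.1, 0.1, 0.1), alphabet)
    truth <- scenario_true_model(alphabet)
    Q <- q_matrix(rates_by_pair(truth$model, truth$class_rates), alphabet)
    sim <- simulate_trait(tree, Q, pi = unname(root_prior), seed = seeds[3],
                          alphabet = alphabet)
    structure(list(
      tree = tree,
      traits = sim$traits,
      tags = list(A = tr_a$tip.label, B = tr_b$tip.label,
                  AB = c(tr_a$tip.label, tr_b$tip.label)),
      truth = list(model = truth$model, class_rates = truth$class_rates,
                   root_prior = root_prior, root_state = sim$root_state,
                   node_states = sim$node_states,
                   mrca_states = c(
                     A = sim$node_states[mrca_node(tree, tr_a$tip.label)],
                     B = sim$node_states[mrca_node(tree, tr_b$tip.label)],
                     AB = sim$node_states[mrca_node(tree, c(tr_a$tip.label,
                                                            tr_b$tip.label))]),
                   history = sim$history,
                   n_events = count_realized_transitions(sim$history)),
      variant = variant, seed = as.integer(seed)
    ), class = "sim_scenario")
  })
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf(paste0("sim_scenario '%s' (seed %d): %d leaves ",
                     "(|A| = %d, |B| = %d, 1 outgroup), %d true events, ",
                     "true root state %s\n"),
              x$variant, x$seed, length(x$tree$tip.label),
              length(x$tags$A), length(x$tags$B),
              x$truth$n_events, x$truth$root_state))
  invisible(x)
}

# Rescale all branch lengths so the tree height becomes `h`.
rescale_height <- function(tree, h) {
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length * (h / depth)
  tree
}

# Root((A:stem, B:stem):ingroup_edge, OUT:outgroup_stem)
join_clades <- function(tr_a, tr_b, stem, ingroup_edge, outgroup,
                        outgroup_stem) {
  txt_a <- sub(";$", "", write_newick(tr_a))
  txt_b <- sub(";$", "", write_newick(tr_b))
  parse_newick(sprintf("((%s:%g,%s:%g):%g,%s:%g);",
                       txt_a, stem, txt_b, stem, ingroup_edge,
                       outgroup, outgroup_stem))
}

#' Write a scenario to disk (Newick + trait TSV + truth JSON)
#'
#' @param scenario A `sim_scenario`.
#' @param dir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
write_scenario <- function(scenario, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(tree = file.path(dir, "tree.nwk"),
             traits = file.path(dir, "traits.tsv"),
             truth = file.path(dir, "truth.json"))
  write_newick(scenario$tree, files["tree"])
  write_trait_table(scenario$traits, files["traits"])
  truth <- scenario$truth
  jsonlite::write_json(
    list(variant = scenario$variant, seed = scenario$seed,
         tags = scenario$tags,
         model_signature = model_signature(truth$model),
         assignment = as.list(truth$model$assignment),
         class_rates = truth$class_rates,
         root_prior = as.list(truth$root_prior),
         root_state = truth$root_state,
         n_events = truth$n_events,
         history = truth$history),
    files["truth"], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files
}
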