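## Reversible-jump MCMC over rate-class models.  The chain state is a
## labeled assignment of the 20 ordered state pairs to label 0 (ZERO, rate
## fixed at 0) or to one of 20 class labels, each nonempty class carrying
## one rate.  The target is: uniform over labeled assignments x iid
## exponential(mean mu) rates on nonempty classes x uniform tree index x
## the data likelihood.  New class rates are drawn from the prior, so all
## trans-dimensional acceptance ratios are free of Jacobian terms and a
## likelihood-off chain samples the rate prior exactly (tested).

#' Exponential rate prior
#'
#' @param mean Prior mean `mu` of every free rate parameter (> 0).  The
#'   study design uses `mu` in `{1, 10, 100, 500}`.
#' @export
rj_prior <- function(mean = 100) {
  if (mean <= 0) stop("prior mean must be > 0")
  list(mean = as.numeric(mean))
}

#' Default move mixture for [run_chain()]
#'
#' Per iteration: rate-value update (log-normal multiplicative proposal,
#' sd 0.3, on one random class), reassignment of one pair to a uniformly
#' chosen other label (ZERO included), class split, class merge, tree
#' switch (uniform over supplied trees).
#'
#' @param rate,reassign,split,merge,tree Probabilities; must sum to 1.
#' @export
rj_moves <- function(rate = 0.6, reassign = 0.15, split = 0.1, merge = 0.1,
                     tree = 0.05) {
  p <- c(rate = rate, reassign = reassign, split = split, merge = merge,
         tree = tree)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-12) stop("move probabilities must be >= 0 and sum to 1")
  p
}

#' Run a reversible-jump MCMC over rate-class models
#'
#' Metropolis--Hastings--Green chain over (model, class rates, tree
#' index).  With `prior_only = TRUE` the likelihood term is constant and
#' the chain samples the induced prior; a matched prior-only run is
#' required by [bayes_factors()].
#'
#' @param trees A `phylo` or list of `phylo` sharing one leaf set (e.g. a
#'   posterior tree sample); the tree-switch move integrates over them.
#' @param traits A [trait_data].
#' @param prior An [rj_prior()].
#' @param n_generations Chain length (>= `sample_freq`).  The study-scale
#'   setting is 5e8; the package default is desk-scale.
#' @param sample_freq Record every `sample_freq`-th iteration, so the
#'   trace holds `floor(n_generations / sample_freq)` samples.
#' @param seed RNG seed; the chain is seed-deterministic end to end.
#' @param prior_only Sample the prior (likelihood off).
#' @param pi Root prior for the likelihood.
#' @param move_probs An [rj_moves()] vector.
#' @param proposal_sd Log-scale sd of the rate-update proposal.
#' @return An object of class `chain_trace`: `samples` (data frame:
#'   iteration, signature, k, lnL, tree_index, 20 realized pair rates) and
#'   `meta` (run settings, acceptance counts, pair labels).
#' @export
run_chain <- function(trees, traits, prior = rj_prior(100),
                      n_generations = 1e6, sample_freq = 500, seed = 1L,
                      prior_only = FALSE, pi = "uniform",
                      move_probs = rj_moves(), proposal_sd = 0.3) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (!length(trees)) stop("need at least one tree")
  if (n_generations < sample_freq) stop("n_generations must be >= sample_freq")
  leafsets <- lapply(trees, function(tr) sort(tr$tip.label))
  if (length(trees) > 1 && !all(vapply(leafsets[-1], identical, logical(1),
                                       leafsets[[1]]))) {
    stop("all trees must share one leaf set")
  }
  alphabet <- traits$alphabet
  ka <- length(alphabet)
  pairs <- state_pairs(alphabet)
  npair <- nrow(pairs)
  offdiag_idx <- cbind(pairs$from_idx, pairs$to_idx)
  encs <- lapply(trees, encode_tree)
  tips <- lapply(trees, check_tree_traits, traits = traits)
  pi_vec <- resolve_root_prior(pi, k = ka)
  mu <- prior$mean
  n_trees <- length(trees)

  loglik_state <- function(a, rates, tree_idx) {
    if (prior_only) return(0)
    pr <- numeric(npair)
    nz <- a > 0L
    pr[nz] <- rates[a[nz]]
    Q <- matrix(0, ka, ka)
    Q[offdiag_idx] <- pr
    diag(Q) <- -rowSums(Q)
    loglik_encoded(encs[[tree_idx]], tips[[tree_idx]], Q, pi_vec)
  }

  n_samples <- floor(n_generations / sample_freq)
  samp_iter <- integer(n_samples)
  samp_sig <- character(n_samples)
  samp_k <- integer(n_samples)
  samp_ll <- numeric(n_samples)
  samp_tree <- integer(n_samples)
  samp_rates <- matrix(0, n_samples, npair)
  accept <- c(rate = 0L, reassign = 0L, split = 0L, merge = 0L, tree = 0L)
  propose <- accept
  move_cum <- cumsum(move_probs)
  lp_split <- log(move_probs[["split"]]); lp_merge <- log(move_probs[["merge"]])

  with_seed(seed, {
    a <- rep(1L, npair)                 # start: all pairs in one class
    rates <- rep(NA_real_, npair)       # rate per label 1..20
    rates[1] <- rexp(1, 1 / mu)
    sizes <- integer(npair)             # members per label 1..20
    sizes[1] <- npair
    tree_idx <- 1L
    curr_ll <- loglik_state(a, rates, tree_idx)
    si <- 0L

    for (it in seq_len(n_generations)) {
      u <- runif(1)
      move <- which(u <= move_cum)[1]

      if (move == 1L) {                 # rate update
        ne <- which(sizes > 0L)
        if (length(ne)) {
          propose[1] <- propose[1] + 1L
          lab <- ne[sample.int(length(ne), 1)]
          r_old <- rates[lab]
          r_new <- r_old * exp(rnorm(1, 0, proposal_sd))
          rates[lab] <- r_new
          new_ll <- loglik_state(a, rates, tree_idx)
          log_alpha <- (new_ll - curr_ll) - (r_new - r_old) / mu +
            log(r_new) - log(r_old)
          if (is.finite(log_alpha) && log(runif(1)) < log_alpha) {
            curr_ll <- new_ll
            accept[1] <- accept[1] + 1L
          } else {
            rates[lab] <- r_old
          }
        }

      } else if (move == 2L) {          # reassign one pair
        propose[2] <- propose[2] + 1L
        i <- sample.int(npair, 1)
        old_lab <- a[i]
        cand <- setdiff(0:npair, old_lab)
        new_lab <- cand[sample.int(length(cand), 1)]
        a2 <- a; rates2 <- rates; sizes2 <- sizes
        a2[i] <- new_lab
        if (old_lab > 0L) {
          sizes2[old_lab] <- sizes2[old_lab] - 1L
          if (sizes2[old_lab] == 0L) rates2[old_lab] <- NA_real_
        }
        if (new_lab > 0L) {
          if (sizes2[new_lab] == 0L) rates2[new_lab] <- rexp(1, 1 / mu)
          sizes2[new_lab] <- sizes2[new_lab] + 1L
        }
        new_ll <- loglik_state(a2, rates2, tree_idx)
        log_alpha <- new_ll - curr_ll
        if (!is.nan(log_alpha) && log(runif(1)) < log_alpha) {
          a <- a2; rates <- rates2; sizes <- sizes2; curr_ll <- new_ll
          accept[2] <- accept[2] + 1L
        }

      } else if (move == 3L) {          # split a class
        ne <- which(sizes > 0L)
        n1 <- length(ne)
        empty <- which(sizes == 0L)
        n0 <- length(empty)
        if (n1 >= 1L && n0 >= 1L) {
          cl <- ne[sample.int(n1, 1)]
          members <- which(a == cl)
          m <- length(members)
          if (m >= 2L) {
            propose[3] <- propose[3] + 1L
            sel <- runif(m) < 0.5
            if (any(sel) && !all(sel)) {
              e_lab <- empty[sample.int(n0, 1)]
              a2 <- a; rates2 <- rates; sizes2 <- sizes
              moved <- members[sel]
              a2[moved] <- e_lab
              sizes2[cl] <- sizes2[cl] - length(moved)
              sizes2[e_lab] <- length(moved)
              rates2[e_lab] <- rexp(1, 1 / mu)
              new_ll <- loglik_state(a2, rates2, tree_idx)
              n1p <- n1 + 1L
              log_alpha <- (new_ll - curr_ll) +
                (lp_merge - log(n1p) - log(n1p - 1)) -
                (lp_split - log(n1) - m * log(2) - log(n0))
              if (!is.nan(log_alpha) && log(runif(1)) < log_alpha) {
                a <- a2; rates <- rates2; sizes <- sizes2; curr_ll <- new_ll
                accept[3] <- accept[3] + 1L
              }
            }
          }
        }

      } else if (move == 4L) {          # merge two classes
        ne <- which(sizes > 0L)
        n1 <- length(ne)
        if (n1 >= 2L) {
          propose[4] <- propose[4] + 1L
          pick <- sample.int(n1, 2)     # ordered: keep, dissolve
          keep <- ne[pick[1]]; diss <- ne[pick[2]]
          Mtot <- sizes[keep] + sizes[diss]
          a2 <- a; rates2 <- rates; sizes2 <- sizes
          a2[a2 == diss] <- keep
          sizes2[keep] <- Mtot
          sizes2[diss] <- 0L
          rates2[diss] <- NA_real_
          new_ll <- loglik_state(a2, rates2, tree_idx)
          n1m <- n1 - 1L
          n0p <- npair - n1m            # empty labels after the merge
          log_alpha <- (new_ll - curr_ll) +
            (lp_split - log(n1m) - Mtot * log(2) - log(n0p)) -
            (lp_merge - log(n1) - log(n1 - 1))
          if (!is.nan(log_alpha) && log(runif(1)) < log_alpha) {
            a <- a2; rates <- rates2; sizes <- sizes2; curr_ll <- new_ll
            accept[4] <- accept[4] + 1L
          }
        }

      } else {                          # tree switch
        if (n_trees > 1L) {
          propose[5] <- propose[5] + 1L
          j <- sample.int(n_trees, 1)
          if (j != tree_idx) {
            new_ll <- loglik_state(a, rates, j)
            log_alpha <- new_ll - curr_ll
            if (!is.nan(log_alpha) && log(runif(1)) < log_alpha) {
              tree_idx <- j; curr_ll <- new_ll
              accept[5] <- accept[5] + 1L
            }
          } else {
            accept[5] <- accept[5] + 1L
          }
        }
      }

      if (it %% sample_freq == 0L) {
        si <- si + 1L
        samp_iter[si] <- it
        samp_sig[si] <- model_signature(a)
        samp_k[si] <- length(unique(a[a > 0L]))
        samp_ll[si] <- curr_ll
        samp_tree[si] <- tree_idx
        nz <- a > 0L
        pr <- numeric(npair)
        pr[nz] <- rates[a[nz]]
        samp_rates[si, ] <- pr
      }
    }
  })

  colnames(samp_rates) <- paste0("rate.", gsub("->", ".", pairs$label, fixed = TRUE))
  samples <- data.frame(iteration = samp_iter, signature = samp_sig,
                        k = samp_k, lnL = samp_ll, tree_index = samp_tree,
                        samp_rates, stringsAsFactors = FALSE,
                        check.names = FALSE)
  structure(list(
    samples = samples,
    meta = list(n_generations = n_generations, sample_freq = sample_freq,
                seed = as.integer(seed), mu = mu, prior_only = prior_only,
                move_probs = move_probs, proposal_sd = proposal_sd,
                n_trees = n_trees, pair_labels = pairs$label,
                alphabet = alphabet, root_prior = pi_vec,
                accepted = accept, proposed = propose)
  ), class = "chain_trace")
}

#' @export
print.chain_trace <- function(x, ...) {
  cat(sprintf(paste0("chain_trace: %d samples (every %d of %g generations), ",
                     "mu = %g%s, %d tree(s)\n"),
              nrow(x$samples), x$meta$sample_freq, x$meta$n_generations,
              x$meta$mu, if (x$meta$prior_only) " [prior only]" else "",
              x$meta$n_trees))
  invisible(x)
}

#' Classify sampled models by signature and by number of free parameters
#'
#' The first `burn_in` fraction of samples is discarded.  `k` counts the
#' nonempty free classes; the ZERO class contributes 0.
#'
#' @param trace A `chain_trace`.
#' @param burn_in Fraction of samples to discard (default 0.1).
#' @return An object of class `model_counts`: `model` (named counts by
#'   signature), `k` (named counts by parameter number), `n` (samples
#'   kept), `meta` (from the trace).
#' @export
classify_models <- function(trace, burn_in = 0.1) {
  s <- trace$samples
  if (!nrow(s)) stop("empty trace")
  drop <- floor(burn_in * nrow(s))
  if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
  model_tab <- table(s$signature)
  k_tab <- table(s$k)
  structure(list(model = c(model_tab), k = c(k_tab), n = nrow(s),
                 burn_in = burn_in, meta = trace$meta),
            class = "model_counts")
}

#' Bayes factors from posterior vs prior visit odds
#'
#' For each item (model signature or k-class),
#' `BF = [post/(1-post)] / [prior/(1-prior)]` on add-one-smoothed visit
#' fractions `(count + 1) / (n + 2)`.  Items never visited by the prior
#' chain get `defined = FALSE` (their BF rests entirely on smoothing).
#' The natural-log BF carries Kass--Raftery labels (> 5 "decisive").
#' Both runs must share the prior mean and move kernel, and `prior_counts`
#' must come from a prior-only run.
#'
#' @param posterior_counts,prior_counts [classify_models()] results from a
#'   posterior and a matched prior-only run.
#' @return An object of class `bf_table`: data frames `models` and
#'   `k_classes` with columns item, post_count, prior_count, post_frac,
#'   prior_frac, BF, lnBF, log10BF, defined, label.
#' @export
bayes_factors <- function(posterior_counts, prior_counts) {
  stopifnot(inherits(posterior_counts, "model_counts"),
            inherits(prior_counts, "model_counts"))
  if (!isTRUE(prior_counts$meta$prior_only)) {
    stop("prior_counts must come from a prior_only run")
  }
  if (!isTRUE(all.equal(posterior_counts$meta$mu, prior_counts$meta$mu))) {
    stop("prior means differ between runs")
  }
  if (!isTRUE(all.equal(posterior_counts$meta$move_probs,
                        prior_counts$meta$move_probs))) {
    stop("move kernels differ between runs")
  }
  one <- function(post_tab, prior_tab) {
    items <- union(names(post_tab), names(prior_tab))
    pc <- as.numeric(post_tab[items]); pc[is.na(pc)] <- 0
    qc <- as.numeric(prior_tab[items]); qc[is.na(qc)] <- 0
    pf <- (pc + 1) / (posterior_counts$n + 2)
    qf <- (qc + 1) / (prior_counts$n + 2)
    bf <- (pf / (1 - pf)) / (qf / (1 - qf))
    lnbf <- log(bf)
    lab <- cut(lnbf, c(-Inf, 1, 3, 5, Inf),
               labels = c("weak", "positive", "strong", "decisive"))
    df <- data.frame(item = items, post_count = pc, prior_count = qc,
                     post_frac = pf, prior_frac = qf, BF = bf, lnBF = lnbf,
                     log10BF = lnbf / log(10), defined = qc > 0,
                     label = as.character(lab), stringsAsFactors = FALSE)
    df[order(-df$lnBF), , drop = FALSE]
  }
  structure(list(models = one(posterior_counts$model, prior_counts$model),
                 k_classes = one(posterior_counts$k, prior_counts$k)),
            class = "bf_table")
}

#' @export
print.bf_table <- function(x, ...) {
  cat("Bayes factors by number of free parameters:\n")
  print(x$k_classes[, c("item", "post_frac", "prior_frac", "lnBF", "label")],
        digits = 4, row.names = FALSE)
  cat("Top models:\n")
  print(head(x$models[, c("item", "post_frac", "prior_frac", "lnBF")], 5),
        digits = 4, row.names = FALSE)
  invisible(x)
}

#' Geweke convergence diagnostic
#'
#' z-score comparing the means of the first `frac_first` and last
#' `frac_last` windows of a trace, with spectral-density-at-zero variance
#' estimated by batch means (20 batches per window; fewer if the window is
#' short).  |z| < 1.96 is reported as converged.
#'
#' @param series Numeric vector, length >= 100.
#' @param frac_first,frac_last Window fractions (sum <= 1).
#' @param n_batches Batches per window for the variance estimate.
#' @return List: `z`, `converged`, `undefined` (TRUE when both windows
#'   have zero variance, in which case `z` is `NA`).
#' @export
geweke_diagnostic <- function(series, frac_first = 0.1, frac_last = 0.5,
                              n_batches = 20) {
  n <- length(series)
  if (n < 100) stop("series must have length >= 100")
  if (frac_first + frac_last > 1) stop("frac_first + frac_last must be <= 1")
  w1 <- series[seq_len(floor(frac_first * n))]
  w2 <- series[(n - floor(frac_last * n) + 1):n]
  bm_var <- function(x) {
    nb <- min(n_batches, max(2L, floor(length(x) / 2)))
    bs <- floor(length(x) / nb)
    x <- x[seq_len(nb * bs)]
    means <- colMeans(matrix(x, nrow = bs))
    bs * var(means)  # estimates n * spectral density at zero
  }
  v1 <- bm_var(w1); v2 <- bm_var(w2)
  denom <- v1 / length(w1) + v2 / length(w2)
  if (denom <= 0 || !is.finite(denom)) {
    dm <- mean(w1) - mean(w2)
    if (dm == 0) return(list(z = NA_real_, converged = NA, undefined = TRUE))
    # zero within-window variance but shifted means: definite non-stationarity
    return(list(z = sign(dm) * Inf, converged = FALSE, undefined = FALSE))
  }
  z <- (mean(w1) - mean(w2)) / sqrt(denom)
  list(z = z, converged = abs(z) < 1.96, undefined = FALSE)
}

#' Bayesian ancestral state probabilities at a clade MRCA
#'
#' For every retained sample, the marginal state probabilities are
#' computed at the MRCA of `taxa` on the sampled tree under the sampled
#' rate model, then averaged arithmetically.  Samples under which the
#' data have probability zero are skipped and counted.
#'
#' @param trace A `chain_trace`.
#' @param trees The tree (or list) the chain was run on.
#' @param traits A [trait_data].
#' @param taxa Leaf names defining the clade.
#' @param pi Root prior.
#' @param burn_in Fraction of samples to discard.
#' @return List: `mean` (named probability vector), `mc_error` (per-state
#'   standard error across samples), `n_used`, `n_skipped`.
#' @export
ancestral_at_mrca <- function(trace, trees, traits, taxa, pi = "uniform",
                              burn_in = 0.1) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  alphabet <- traits$alphabet
  ka <- length(alphabet)
  pairs <- state_pairs(alphabet)
  offdiag_idx <- cbind(pairs$from_idx, pairs$to_idx)
  pi_vec <- resolve_root_prior(pi, k = ka)
  encs <- lapply(trees, encode_tree)
  tips <- lapply(trees, check_tree_traits, traits = traits)
  nodes <- vapply(trees, mrca_node, integer(1), taxa = taxa)

  s <- trace$samples
  drop <- floor(burn_in * nrow(s))
  if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
  rate_cols <- paste0("rate.", gsub("->", ".", pairs$label, fixed = TRUE))
  R <- as.matrix(s[, rate_cols])
  out <- matrix(NA_real_, nrow(s), ka)
  for (r in seq_len(nrow(s))) {
    ti <- s$tree_index[r]
    Q <- matrix(0, ka, ka)
    Q[offdiag_idx] <- R[r, ]
    diag(Q) <- -rowSums(Q)
    marg <- tryCatch(
      cpp_mk_marginals(encs[[ti]]$edge, encs[[ti]]$elen, encs[[ti]]$ntip,
                       encs[[ti]]$nnode, tips[[ti]], Q, pi_vec)[, nodes[ti]],
      error = function(e) NULL)
    if (!is.null(marg)) out[r, ] <- marg
  }
  used <- !is.na(out[, 1])
  if (!any(used)) stop("no samples with nonzero data probability")
  m <- colMeans(out[used, , drop = FALSE])
  se <- apply(out[used, , drop = FALSE], 2, sd) / sqrt(sum(used))
  list(mean = setNames(m, alphabet), mc_error = setNames(se, alphabet),
       n_used = sum(used), n_skipped = sum(!used))
}

#' Posterior mean of every pairwise transition rate
#'
#' Per-pair mean of the realized rates across retained samples (ZERO
#' contributes 0), with a per-pair Geweke convergence flag.
#'
#' @param trace A `chain_trace`.
#' @param burn_in Fraction of samples to discard.
#' @return List: `mean` (named 20-vector), `geweke_z`, `converged`
#'   (logical, `NA` where the diagnostic is undefined).
#' @export
posterior_rate_means <- function(trace, burn_in = 0.1) {
  s <- trace$samples
  if (!nrow(s)) stop("empty trace")
  drop <- floor(burn_in * nrow(s))
  if (drop > 0) s <- s[-seq_len(drop), , drop = FALSE]
  labels <- trace$meta$pair_labels
  rate_cols <- paste0("rate.", gsub("->", ".", labels, fixed = TRUE))
  R <- as.matrix(s[, rate_cols])
  gz <- rep(NA_real_, ncol(R))
  conv <- rep(NA, ncol(R))
  if (nrow(R) >= 100) {
    for (j in seq_len(ncol(R))) {
      g <- geweke_diagnostic(R[, j])
      gz[j] <- g$z
      conv[j] <- g$converged
    }
  }
  list(mean = setNames(colMeans(R), labels),
       geweke_z = setNames(gz, labels),
       converged = setNames(conv, labels))
}

#' Write / read a chain trace (TSV + JSON metadata sidecar)
#'
#' The TSV holds one row per sample; `<path>.meta.json` holds the run
#' metadata.  [read_trace()] reconstructs the `chain_trace` losslessly.
#'
#' @param trace A `chain_trace`.
#' @param path TSV output path.
#' @export
write_trace <- function(trace, path) {
  write.table(trace$samples, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  meta <- trace$meta
  meta$move_probs <- as.list(meta$move_probs)
  meta$accepted <- as.list(meta$accepted)
  meta$proposed <- as.list(meta$proposed)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  samples <- read.delim(path, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE, check.names = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  meta$move_probs <- unlist(meta$move_probs)
  meta$accepted <- unlist(meta$accepted)
  meta$proposed <- unlist(meta$proposed)
  structure(list(samples = samples, meta = meta), class = "chain_trace")
}
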