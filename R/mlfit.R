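## Maximum-likelihood fitting of rate models: bounded multi-start
## optimization on log-rates, the eight-model family, AIC selection, and
## ML ancestral states.

#' Optimizer options for [fit_model()]
#'
#' @param n_starts Number of random starts (in addition to the
#'   parsimony-informed start and any warm starts).
#' @param bounds Lower/upper bound on each class rate.
#' @param maxit `optim` iteration cap per start.
#' @param factr L-BFGS-B convergence tolerance factor.
#' @param seed RNG seed; the whole multi-start procedure is deterministic
#'   given it.
#' @param threshold Zero-out cutoff used by the reduced models, in the
#'   tree's branch-length units.
#' @export
fit_opts <- function(n_starts = 5, bounds = c(1e-8, 1e3), maxit = 300,
                     factr = 1e8, seed = 1L, threshold = 0.1) {
  list(n_starts = n_starts, bounds = bounds, maxit = maxit, factr = factr,
       seed = as.integer(seed), threshold = threshold)
}

#' Fit a rate model by maximum likelihood
#'
#' Maximizes the pruning log-likelihood over the model's free class rates
#' (ZERO pairs stay at 0) with L-BFGS-B on the log-rate scale.  Starts:
#' one at the parsimony-informed rate (minimum transitions / total tree
#' length), `opts$n_starts` random ones, plus any `warm_starts` supplied
#' by the caller (used by [select_best()] to chain nested models).
#' The multi-parameter surfaces of this family are multimodal, hence the
#' multi-start; results are bit-reproducible given `opts$seed`.
#'
#' @param tree A `phylo`.
#' @param traits A [trait_data].
#' @param model A [rate_model].
#' @param pi Root prior (see [log_likelihood()]).
#' @param opts A [fit_opts()] list.
#' @param warm_starts Optional list of class-rate vectors (length
#'   `model$k`) used as additional starts.
#' @return An object of class `ml_fit`: fields `model`, `rates` (class
#'   rates `C1..Ck`), `rates_by_pair`, `lnL`, `n_params`, `AIC`
#'   (`2*n_params - 2*lnL` exactly), `converged`, `n_starts`, `seed`.
#' @export
fit_model <- function(tree, traits, model, pi = "uniform", opts = fit_opts(),
                      warm_starts = NULL) {
  stopifnot(inherits(model, "rate_model"))
  k <- model$k
  alpha_n <- length(traits$alphabet)
  tipstate <- check_tree_traits(tree, traits)
  enc <- encode_tree(tree)
  pairs <- state_pairs(traits$alphabet)
  offdiag_idx <- cbind(pairs$from_idx, pairs$to_idx)
  pi_vec <- resolve_root_prior(pi, k = alpha_n)

  assignment <- model$assignment
  pos <- assignment > 0L
  build_q_fast <- function(class_rates) {
    Q <- matrix(0, alpha_n, alpha_n)
    pr <- numeric(length(assignment))
    pr[pos] <- class_rates[assignment[pos]]
    Q[offdiag_idx] <- pr
    diag(Q) <- -rowSums(Q)
    Q
  }
  negll <- function(logr) {
    ll <- loglik_encoded(enc, tipstate, build_q_fast(exp(logr)), pi_vec)
    if (!is.finite(ll)) 1e10 else -ll
  }

  lb <- log(opts$bounds[1]); ub <- log(opts$bounds[2])
  # two deterministic starts bracketing the interesting regimes: the
  # parsimony-informed rate (observed minimum changes per unit tree
  # length) and a near-saturation rate (several expected changes per
  # root-to-leaf path) -- the latter matters when the trait carries little
  # or no signal and the optimum is a saturated Q
  pars_rate <- min_transitions(tree, traits) / max(sum(enc$elen), 1e-12)
  pars_rate <- min(max(pars_rate, opts$bounds[1] * 10), opts$bounds[2] / 10)
  mean_depth <- mean(ape::node.depth.edgelength(tree)[seq_len(enc$ntip)])
  sat_rate <- min(max(5 / max(mean_depth, 1e-12), opts$bounds[1] * 10),
                  opts$bounds[2] / 10)
  starts <- list(rep(log(pars_rate), k), rep(log(sat_rate), k))
  for (ws in warm_starts) {
    if (length(ws) == k) starts <- c(starts, list(pmin(pmax(log(ws), lb), ub)))
  }
  starts <- c(starts, with_seed(opts$seed, {
    lapply(seq_len(opts$n_starts), function(i) runif(k, log(1e-3), log(10)))
  }))

  best <- NULL
  any_conv <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, negll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = opts$maxit, factr = opts$factr)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")
  rates <- setNames(exp(best$par), paste0("C", seq_len(k)))
  lnL <- -best$value
  if (lnL <= -1e9) {
    # likelihood was 0 at every evaluated point: the model's zero pattern
    # cannot produce the observed tips (e.g. an observed state became
    # unreachable).  Flag as infeasible rather than reporting the penalty.
    lnL <- -Inf
    any_conv <- FALSE
  }
  structure(list(model = model,
                 rates = rates,
                 rates_by_pair = rates_by_pair(model, rates),
                 lnL = lnL,
                 n_params = k,
                 AIC = 2 * k - 2 * lnL,
                 converged = any_conv,
                 n_starts = length(starts),
                 seed = opts$seed),
            class = "ml_fit")
}

#' @export
print.ml_fit <- function(x, ...) {
  cat(sprintf("ml_fit '%s': k = %d, lnL = %.4f, AIC = %.4f%s\n",
              x$model$scheme, x$n_params, x$lnL, x$AIC,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  invisible(x)
}

#' Fit the eight-model family and select by AIC
#'
#' Fits `single`, `symmetric`, and `unconstrained`, then the five reduced
#' models built from the unconstrained fit's rates by threshold-and-bin
#' ([reduce_model()]).  Nested models warm-start richer ones (single ->
#' symmetric -> unconstrained), which both speeds fitting and guarantees
#' the nesting property lnL(unconstrained) >= lnL(symmetric) >=
#' lnL(single) up to optimizer tolerance.  Reduced candidates whose
#' reduction leaves no free rates are skipped with a warning.  The best
#' model is the one with the lowest AIC; ties go to fewer parameters.
#'
#' @inheritParams fit_model
#' @return An object of class `model_selection`: `fits` (named list of
#'   `ml_fit`), `best` (name of the winner), `table` (data frame of
#'   scheme, k, lnL, AIC).
#' @export
select_best <- function(tree, traits, pi = "uniform", opts = fit_opts()) {
  fits <- list()
  f_single <- fit_model(tree, traits, build_scheme("single", traits$alphabet),
                        pi, opts)
  fits$single <- f_single
  sym <- build_scheme("symmetric", traits$alphabet)
  f_sym <- fit_model(tree, traits, sym, pi, opts,
                     warm_starts = list(expand_rates(f_single, sym)))
  fits$symmetric <- f_sym
  ard <- build_scheme("unconstrained", traits$alphabet)
  f_ard <- fit_model(tree, traits, ard, pi, opts,
                     warm_starts = list(expand_rates(f_sym, ard),
                                        expand_rates(f_single, ard)))
  fits$unconstrained <- f_ard

  for (k in 1:5) {
    red <- tryCatch(
      reduce_model(f_ard$rates_by_pair, k, threshold = opts$threshold,
                   alphabet = traits$alphabet),
      error = function(e) {
        warning("reduced-", k, " skipped: ", conditionMessage(e))
        NULL
      })
    if (is.null(red)) next
    # warm start at the mean unconstrained rate of each occupied class
    cls_mean <- vapply(seq_len(red$k), function(cl) {
      mean(f_ard$rates_by_pair[red$assignment == cl])
    }, numeric(1))
    fits[[paste0("reduced-", k)]] <-
      fit_model(tree, traits, red, pi, opts, warm_starts = list(cls_mean))
  }

  tab <- data.frame(
    scheme = names(fits),
    k = vapply(fits, function(f) f$n_params, numeric(1)),
    lnL = vapply(fits, function(f) f$lnL, numeric(1)),
    AIC = vapply(fits, function(f) f$AIC, numeric(1)),
    converged = vapply(fits, function(f) f$converged, logical(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  ord <- order(tab$AIC, tab$k)
  structure(list(fits = fits, best = tab$scheme[ord[1]], table = tab),
            class = "model_selection")
}

# Map a simpler scheme's fitted rates onto a richer scheme's classes
# (warm-start construction).
expand_rates <- function(fit, target_model) {
  per_pair <- fit$rates_by_pair
  vapply(seq_len(target_model$k), function(cl) {
    v <- per_pair[target_model$assignment == cl]
    m <- mean(v[v > 0])
    if (!is.finite(m) || m <= 0) 1e-4 else m
  }, numeric(1))
}

#' @export
print.model_selection <- function(x, ...) {
  cat("model_selection: best =", x$best, "\n")
  print(x$table, digits = 6)
  invisible(x)
}

#' ML ancestral state probabilities at the MRCA of a clade
#'
#' @param tree A `phylo`.
#' @param traits A [trait_data].
#' @param fit An `ml_fit` (use the best fit from [select_best()]).
#' @param taxa Leaf names whose MRCA is queried.
#' @param pi Root prior.
#' @return Named probability vector over states (sums to 1).
#' @export
ml_ancestral <- function(tree, traits, fit, taxa, pi = "uniform") {
  Q <- q_matrix(fit$rates_by_pair, traits$alphabet)
  node_marginals(tree, traits, Q, pi, node = mrca_node(tree, taxa))
}

#' Serialize a model selection report
#'
#' JSON per-model records plus a one-row-per-model TSV.
#'
#' @param sel A `model_selection`.
#' @param json_file,tsv_file Output paths (`NULL` to skip).
#' @return The report list, invisibly.
#' @export
write_fit_report <- function(sel, json_file = NULL, tsv_file = NULL) {
  rep <- list(best = sel$best,
              models = lapply(sel$fits, function(f) {
                list(scheme = f$model$scheme, k = f$n_params, lnL = f$lnL,
                     AIC = f$AIC, converged = f$converged,
                     rates_by_pair = as.list(f$rates_by_pair))
              }))
  if (!is.null(json_file)) {
    jsonlite::write_json(rep, json_file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(tsv_file)) {
    write.table(sel$table, tsv_file, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(rep)
}
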