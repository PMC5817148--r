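## Rate models: assignments of the k(k-1) ordered state pairs to a ZERO
## class (rate fixed at 0) or to shared free-rate classes.  For the default
## 5-state alphabet that is 20 ordered pairs.

#' Ordered state pairs of an alphabet
#'
#' Pairs are enumerated row-wise in alphabet order: for the default
#' alphabet `CI->FI, CI->MK, ..., PI->O`.  This fixed order indexes every
#' 20-vector of rates in the package.
#'
#' @param alphabet State alphabet.
#' @return Data frame with columns `from`, `to`, `label` (`"FROM->TO"`).
#' @export
state_pairs <- function(alphabet = default_alphabet()) {
  k <- length(alphabet)
  from <- rep(seq_len(k), each = k)
  to <- rep(seq_len(k), times = k)
  keep <- from != to
  from <- from[keep]; to <- to[keep]
  data.frame(from = alphabet[from], to = alphabet[to],
             from_idx = from, to_idx = to,
             label = paste0(alphabet[from], "->", alphabet[to]),
             stringsAsFactors = FALSE)
}

#' Construct a rate model from a class assignment
#'
#' @param assignment Integer vector over the ordered state pairs: `0` for
#'   the ZERO class (rate fixed at 0), positive integers for free-rate
#'   classes.  Class labels are canonicalized by first appearance, so the
#'   number of free parameters `k` always equals the number of distinct
#'   positive labels.
#' @param scheme Scheme name carried for reporting (e.g. `"single"`,
#'   `"reduced-3"`, `"custom"`).
#' @param alphabet State alphabet.
#' @return An object of class `rate_model` with fields `assignment`
#'   (named integer vector), `k`, `scheme`, `alphabet`.
#' @export
rate_model <- function(assignment, scheme = "custom", alphabet = default_alphabet()) {
  pairs <- state_pairs(alphabet)
  if (length(assignment) != nrow(pairs)) {
    stop("assignment must have length ", nrow(pairs))
  }
  assignment <- as.integer(assignment)
  if (any(assignment < 0L)) stop("class labels must be >= 0")
  assignment <- canonicalize_assignment(assignment)
  names(assignment) <- pairs$label
  structure(list(assignment = assignment,
                 k = length(unique(assignment[assignment > 0L])),
                 scheme = scheme,
                 alphabet = alphabet),
            class = "rate_model")
}

# Relabel free classes by order of first appearance; ZERO stays 0.
canonicalize_assignment <- function(assignment) {
  pos <- assignment[assignment > 0L]
  if (!length(pos)) return(assignment)
  first <- unique(pos)
  out <- assignment
  out[assignment > 0L] <- match(pos, first)
  out
}

#' Canonical model signature string
#'
#' Pairs in fixed lexicographic order, classes relabeled by first
#' appearance, ZERO written as `0`.  Two assignments describe the same
#' model iff their signatures are equal, regardless of arbitrary class
#' labels.
#'
#' @param assignment Integer assignment vector (or a `rate_model`).
#' @return A single string, e.g. `"0,1,1,2,..."`.
#' @export
model_signature <- function(assignment) {
  if (inherits(assignment, "rate_model")) assignment <- assignment$assignment
  paste(canonicalize_assignment(as.integer(assignment)), collapse = ",")
}

#' Build one of the three canonical schemes
#'
#' `single`: one shared rate for all transitions (k = 1).  `symmetric`:
#' rate i->j equals rate j->i, ten classes (k = 10).  `unconstrained`: a
#' free parameter per ordered pair (k = 20).
#'
#' @param name Scheme name.
#' @param alphabet State alphabet.
#' @return A [rate_model].
#' @export
build_scheme <- function(name = c("single", "symmetric", "unconstrained"),
                         alphabet = default_alphabet()) {
  name <- match.arg(name)
  pairs <- state_pairs(alphabet)
  n <- nrow(pairs)
  assignment <- switch(name,
    single = rep(1L, n),
    symmetric = {
      key <- ifelse(pairs$from_idx < pairs$to_idx,
                    paste(pairs$from_idx, pairs$to_idx),
                    paste(pairs$to_idx, pairs$from_idx))
      match(key, unique(key))
    },
    unconstrained = seq_len(n)
  )
  rate_model(assignment, scheme = name, alphabet = alphabet)
}

#' Threshold-and-bin reduction of an unconstrained fit
#'
#' Rates below `threshold` are fixed at zero.  The remaining rates span
#' `[lo, hi]`, which is divided into `k` equal-width intervals (half-open,
#' except the last which is closed at `hi`); pairs in the same interval
#' share one free-rate class.  A value exactly on an interior boundary
#' joins the upper interval.  Empty intervals are dropped, so the model's
#' reported `k` is the number of occupied classes.  If all surviving rates
#' are equal the result collapses to a single class with a message.
#'
#' @param ard_rates Nonnegative rate per ordered pair (length 20 for the
#'   default alphabet), typically from an unconstrained ML fit.
#' @param k Requested number of rate classes, 1..5.
#' @param threshold Zero-out cutoff in the tree's branch-length units.
#' @param alphabet State alphabet.
#' @return A [rate_model] with scheme `"reduced-<k>"`.
#' @export
reduce_model <- function(ard_rates, k, threshold = 0.1,
                         alphabet = default_alphabet()) {
  pairs <- state_pairs(alphabet)
  if (length(ard_rates) != nrow(pairs)) stop("ard_rates must have length ", nrow(pairs))
  if (any(ard_rates < 0)) stop("rates must be >= 0")
  if (k < 1 || k > 5) stop("k must be in 1..5")
  alive <- ard_rates >= threshold
  if (!any(alive)) stop("no free rates remain: all rates below threshold ", threshold)
  lo <- min(ard_rates[alive]); hi <- max(ard_rates[alive])
  assignment <- integer(length(ard_rates))
  if (hi == lo) {
    if (k > 1) message("all surviving rates equal; collapsing to a single class")
    assignment[alive] <- 1L
  } else {
    w <- (hi - lo) / k
    bin <- pmin(k, floor((ard_rates[alive] - lo) / w) + 1L)
    assignment[alive] <- as.integer(bin)
  }
  rate_model(assignment, scheme = paste0("reduced-", k), alphabet = alphabet)
}

#' Rates per ordered pair implied by class rates
#'
#' @param model A [rate_model].
#' @param class_rates Numeric vector of length `model$k` (class `C1..Ck`).
#' @return Named numeric vector over the ordered pairs (0 for ZERO pairs).
#' @export
rates_by_pair <- function(model, class_rates) {
  if (length(class_rates) != model$k) {
    stop("need ", model$k, " class rates, got ", length(class_rates))
  }
  out <- numeric(length(model$assignment))
  pos <- model$assignment > 0L
  out[pos] <- class_rates[model$assignment[pos]]
  setNames(out, names(model$assignment))
}

#' @export
print.rate_model <- function(x, ...) {
  cat("rate_model '", x$scheme, "': k = ", x$k, " free class(es), ",
      sum(x$assignment == 0L), " pair(s) fixed at zero\n", sep = "")
  invisible(x)
}
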