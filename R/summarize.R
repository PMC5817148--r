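## Cross-method synthesis: min-max standardization of rate vectors,
## averaging across method x dataset combinations, transition ranking, and
## Spearman rank-correlation tables.

#' Min-max standardize a rate vector to the unit interval
#'
#' `x' = (x - min) / (max - min)`.  When all entries are equal everything
#' maps to 0 (keeping zero rates at zero), with a message.
#'
#' @param rates Nonnegative numeric vector (one entry per ordered pair).
#' @return Vector in `[0, 1]`, same names.
#' @export
standardize_rates <- function(rates) {
  if (any(rates < 0)) stop("rates must be >= 0")
  lo <- min(rates); hi <- max(rates)
  if (hi == lo) {
    message("all rates equal; standardized vector set to all zeros")
    return(setNames(rep(0, length(rates)), names(rates)))
  }
  (rates - lo) / (hi - lo)
}

#' Average standardized rate vectors across combinations
#'
#' Per-pair arithmetic mean and standard error (sample sd / sqrt(m)) over
#' `m` method-by-dataset combinations.
#'
#' @param vectors List of >= 2 equal-length numeric vectors.
#' @return List with `mean` and `se` vectors.
#' @export
average_standardized <- function(vectors) {
  if (length(vectors) < 2) stop("need >= 2 vectors")
  len <- unique(vapply(vectors, length, integer(1)))
  if (length(len) != 1) stop("vectors have differing lengths")
  M <- do.call(rbind, lapply(vectors, as.numeric))
  m <- colMeans(M)
  se <- apply(M, 2, sd) / sqrt(nrow(M))
  nm <- names(vectors[[1]])
  list(mean = setNames(m, nm), se = setNames(se, nm))
}

#' Rank transitions by mean standardized rate
#'
#' Descending by mean; ties broken lexicographically by pair label.
#'
#' @param mean_vector Named numeric vector over the ordered pairs.
#' @param top_n How many top transitions to flag (default 4).
#' @return Data frame: `pair`, `mean`, `rank`, `top` (logical), plus an
#'   attribute `ties` flagging any tied means.
#' @export
rank_transitions <- function(mean_vector, top_n = 4) {
  if (is.null(names(mean_vector))) {
    names(mean_vector) <- state_pairs()$label[seq_along(mean_vector)]
  }
  ord <- order(-mean_vector, names(mean_vector))
  df <- data.frame(pair = names(mean_vector)[ord],
                   mean = as.numeric(mean_vector[ord]),
                   rank = seq_along(mean_vector),
                   top = seq_along(mean_vector) <= top_n,
                   stringsAsFactors = FALSE)
  attr(df, "ties") <- anyDuplicated(mean_vector) > 0
  df
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Average ranks for ties; two-sided p from
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length >= 4.
#' @return List: `rho`, `p`, `n`, `undefined` (TRUE when either vector is
#'   constant, in which case `rho` is `NA`).
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 4) stop("need length >= 4")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = n, undefined = TRUE))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n, undefined = FALSE)
}

#' Assemble the cross-method analysis report
#'
#' Builds the four study-style tables from whatever inputs are supplied;
#' missing sections are omitted with a note.
#'
#' @param ml_selections Named list of `model_selection` objects (one per
#'   dataset), or `NULL`.
#' @param rate_estimates Named list of per-pair rate vectors, one per
#'   method-by-dataset combination (e.g. ML best-fit rates and posterior
#'   rate means); feeds standardization, ranking and correlations.
#' @param bf_tables Named list of `bf_table` objects, or `NULL`.
#' @param signal_reports Named list of `signal_report` objects, or `NULL`.
#' @param ancestral Named list of ancestral-state results
#'   ([ancestral_at_mrca()] output or plain probability vectors), or
#'   `NULL`.
#' @param out_dir Optional directory; when given, the report is written as
#'   `report.json` plus one TSV per table.
#' @return An object of class `analysis_report` (list of tables).
#' @export
build_report <- function(ml_selections = NULL, rate_estimates = NULL,
                         bf_tables = NULL, signal_reports = NULL,
                         ancestral = NULL, out_dir = NULL) {
  report <- list(notes = character(0))

  if (length(signal_reports)) {
    report$signal <- do.call(rbind, lapply(names(signal_reports), function(nm) {
      r <- signal_reports[[nm]]
      best_k <- best_aic <- NA_real_
      if (!is.null(ml_selections[[nm]])) {
        tab <- ml_selections[[nm]]$table
        i <- which.min(tab$AIC)
        best_k <- tab$k[i]; best_aic <- tab$AIC[i]
      }
      data.frame(dataset = nm, best_model_k = best_k, AIC = best_aic,
                 min_transitions = r$observed, null_median = r$null_median,
                 p_value = r$p_value, delta_AIC_star = r$delta_AIC_star,
                 stringsAsFactors = FALSE)
    }))
  } else {
    report$notes <- c(report$notes, "no signal reports supplied")
  }

  if (length(bf_tables)) {
    report$bayes_factors_k <- do.call(rbind, lapply(names(bf_tables), function(nm) {
      cbind(run = nm, bf_tables[[nm]]$k_classes, stringsAsFactors = FALSE)
    }))
  } else {
    report$notes <- c(report$notes, "no Bayes factor tables supplied")
  }

  if (length(rate_estimates) >= 2) {
    std <- lapply(rate_estimates, standardize_rates)
    avg <- average_standardized(std)
    report$rate_mean_se <- data.frame(pair = names(avg$mean),
                                      mean = as.numeric(avg$mean),
                                      se = as.numeric(avg$se),
                                      stringsAsFactors = FALSE)
    report$ranking <- rank_transitions(avg$mean)
    combos <- names(rate_estimates)
    C <- matrix(1, length(combos), length(combos),
                dimnames = list(combos, combos))
    P <- matrix(NA_real_, length(combos), length(combos),
                dimnames = list(combos, combos))
    for (i in seq_along(combos)) {
      for (j in seq_along(combos)) {
        if (i == j) next
        sc <- spearman_cor(rate_estimates[[i]], rate_estimates[[j]])
        C[i, j] <- sc$rho; P[i, j] <- sc$p
      }
    }
    report$correlations <- C
    report$correlation_p <- P
  } else {
    report$notes <- c(report$notes,
                      "fewer than 2 rate-estimate combos; no synthesis tables")
  }

  if (length(ancestral)) {
    report$ancestral <- do.call(rbind, lapply(names(ancestral), function(nm) {
      a <- ancestral[[nm]]
      v <- if (is.list(a) && !is.null(a$mean)) a$mean else a
      data.frame(clade = nm, state = names(v), probability = as.numeric(v),
                 stringsAsFactors = FALSE)
    }))
  } else {
    report$notes <- c(report$notes, "no ancestral estimates supplied")
  }

  class(report) <- "analysis_report"
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write an analysis report (JSON + TSV tables)
#'
#' @param report An `analysis_report`.
#' @param out_dir Output directory (created if needed).
#' @return Paths of the files written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".tsv"))
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  if (!is.null(report$signal)) emit(report$signal, "table1_signal")
  if (!is.null(report$bayes_factors_k)) emit(report$bayes_factors_k, "table2_bayes_factors")
  if (!is.null(report$correlations)) {
    emit(data.frame(combo = rownames(report$correlations),
                    report$correlations, check.names = FALSE),
         "table3_correlations")
  }
  if (!is.null(report$rate_mean_se)) emit(report$rate_mean_se, "fig3d_rate_mean_se")
  if (!is.null(report$ranking)) emit(report$ranking, "rate_ranking")
  if (!is.null(report$ancestral)) emit(report$ancestral, "ancestral_states")
  json_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report_to_json(report), json_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(files, json_path))
}

report_to_json <- function(report) {
  out <- unclass(report)
  if (!is.null(out$correlations)) {
    out$correlations <- as.data.frame(out$correlations)
  }
  if (!is.null(out$correlation_p)) {
    out$correlation_p <- as.data.frame(out$correlation_p)
  }
  out
}

#' Read back a JSON analysis report
#'
#' @param path Path to `report.json`.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
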