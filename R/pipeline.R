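## End-to-end orchestration: config, the run-all workflow, a manifest with
## checksums, and a plain command-line entry point.

#' Build a validated run configuration
#'
#' Input is either a Newick tree file plus a trait TSV, or a preset
#' synthetic scenario.  Defaults are desk-scale (1e6 MCMC generations,
#' 10000 permutations); study-scale settings (5e8 generations) are
#' reachable only by configuration.
#'
#' @param tree_file Newick file (single tree, or one tree per line).
#' @param trait_file Trait TSV (`taxon<TAB>phenotype`).
#' @param scenario `"small"` or `"large"` to use
#'   [wolbachia_like_scenario()] instead of input files.
#' @param out_dir Output directory.
#' @param seed Master seed; all stage seeds derive from it.
#' @param root_prior `"uniform"` or `"stationary"`.
#' @param n_starts,maxit,threshold ML optimizer options ([fit_opts()]).
#' @param n_perm Permutations for the signal test.
#' @param mu_list Exponential prior means, one MCMC run (plus matched
#'   prior-only run) each.
#' @param n_generations,sample_freq,burn_in MCMC settings.
#' @param ancestral_mu Which run's chain feeds the ancestral estimates
#'   (default: first of `mu_list`).
#' @param clades Named list of leaf-name vectors tagging MRCAs for
#'   ancestral estimation (scenario runs default to its A/B/AB tags).
#' @return A `run_config` list.
#' @export
run_config <- function(tree_file = NULL, trait_file = NULL, scenario = NULL,
                       out_dir = "phenotrans_out", seed = 1L,
                       root_prior = "uniform", n_starts = 5, maxit = 300,
                       threshold = 0.1, n_perm = 10000,
                       mu_list = c(1, 10, 100, 500), n_generations = 1e6,
                       sample_freq = 500, burn_in = 0.1, ancestral_mu = NULL,
                       clades = NULL) {
  if (is.null(scenario)) {
    if (is.null(tree_file) || is.null(trait_file)) {
      stop("supply either `scenario` or both `tree_file` and `trait_file`")
    }
    for (f in c(tree_file, trait_file)) {
      if (!file.exists(f)) stop("input file not found: ", f)
    }
  } else {
    scenario <- match.arg(scenario, c("small", "large"))
  }
  cfg <- list(tree_file = tree_file, trait_file = trait_file,
              scenario = scenario, out_dir = out_dir,
              seed = as.integer(seed), root_prior = root_prior,
              n_starts = n_starts, maxit = maxit, threshold = threshold,
              n_perm = n_perm, mu_list = mu_list,
              n_generations = n_generations, sample_freq = sample_freq,
              burn_in = burn_in,
              ancestral_mu = if (is.null(ancestral_mu)) mu_list[1] else ancestral_mu,
              clades = clades)
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from a JSON file
#'
#' @param path Path to a JSON object whose fields are [run_config()]
#'   arguments.
#' @export
load_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

# Per-stage deterministic sub-seeds (kept well below 2^31).
stage_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1009 + offset) %% (2^31 - 1))
}

#' Run the full analysis workflow
#'
#' Executes, in order: data loading/simulation, eight-model ML selection,
#' the permutation signal test plus star-tree AIC comparison, one RJ-MCMC
#' chain per prior mean with a matched prior-only companion, Bayes
#' factors, posterior rate means, ancestral states per tagged clade, and
#' the cross-method synthesis report.  A failing stage is recorded in the
#' manifest; later independent stages still run.  All outputs land in
#' `config$out_dir` along with `manifest.json` (version, seeds, per-stage
#' status, file checksums).  Outputs are byte-identical across runs with
#' the same config and seed.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the data, stage results and manifest.
#' @export
run_all <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[phenotrans] ", ...)
  stages <- list()
  result <- list(config = config)
  run_stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(expr, error = function(e) {
      say("stage ", name, " FAILED: ", conditionMessage(e))
      structure(list(message = conditionMessage(e)), class = "stage_error")
    })
    elapsed <- proc.time()[["elapsed"]] - t0
    ok <- !inherits(val, "stage_error")
    stages[[name]] <<- list(status = if (ok) "ok" else "error",
                            error = if (ok) NULL else val$message)
    say(sprintf("stage %s %s (%.1fs)", name,
                if (ok) "done" else "failed", elapsed))
    if (ok) val else NULL
  }

  data <- run_stage("data", {
    if (!is.null(config$scenario)) {
      sc <- wolbachia_like_scenario(config$scenario,
                                    seed = stage_seed(config$seed, 1))
      write_scenario(sc, file.path(out, "data"))
      list(tree = sc$tree, traits = sc$traits,
           clades = if (is.null(config$clades)) sc$tags else config$clades,
           trees = list(sc$tree))
    } else {
      trees <- read_newick(config$tree_file)
      if (inherits(trees, "phylo")) trees <- list(trees)
      traits <- read_trait_table(config$trait_file)
      list(tree = trees[[1]], traits = traits, clades = config$clades,
           trees = trees)
    }
  })
  if (is.null(data)) stop("data stage failed; nothing to analyze")
  opts <- fit_opts(n_starts = config$n_starts, maxit = config$maxit,
                   threshold = config$threshold,
                   seed = stage_seed(config$seed, 2))

  sel <- run_stage("fit-ml", {
    s <- select_best(data$tree, data$traits, pi = config$root_prior,
                     opts = opts)
    write_fit_report(s, json_file = file.path(out, "ml_fits.json"),
                     tsv_file = file.path(out, "ml_fits.tsv"))
    s
  })

  signal <- run_stage("signal", {
    r <- permutation_test(data$tree, data$traits, n_perm = config$n_perm,
                          seed = stage_seed(config$seed, 3))
    r$delta_AIC_star <- star_tree_delta_aic(data$tree, data$traits,
                                            pi = config$root_prior,
                                            opts = opts)
    write_signal_report(r, json_file = file.path(out, "signal.json"),
                        tsv_file = file.path(out, "signal.tsv"))
    r
  })

  chains <- list(); priors <- list(); bfs <- list(); rate_means <- list()
  for (i in seq_along(config$mu_list)) {
    mu <- config$mu_list[i]
    tag <- paste0("mu", format(mu, scientific = FALSE))
    ch <- run_stage(paste0("mcmc-", tag), {
      post <- run_chain(data$trees, data$traits, prior = rj_prior(mu),
                        n_generations = config$n_generations,
                        sample_freq = config$sample_freq,
                        seed = stage_seed(config$seed, 10 + i),
                        pi = config$root_prior)
      pri <- run_chain(data$trees, data$traits, prior = rj_prior(mu),
                       n_generations = config$n_generations,
                       sample_freq = config$sample_freq,
                       seed = stage_seed(config$seed, 100 + i),
                       prior_only = TRUE, pi = config$root_prior)
      write_trace(post, file.path(out, paste0("trace_", tag, ".tsv")))
      write_trace(pri, file.path(out, paste0("trace_", tag, "_prior.tsv")))
      list(post = post, pri = pri)
    })
    if (is.null(ch)) next
    chains[[tag]] <- ch$post
    priors[[tag]] <- ch$pri
    bfs[[tag]] <- bayes_factors(classify_models(ch$post, config$burn_in),
                                classify_models(ch$pri, config$burn_in))
    rate_means[[tag]] <- posterior_rate_means(ch$post, config$burn_in)
  }

  anc <- NULL
  anc_tag <- paste0("mu", format(config$ancestral_mu, scientific = FALSE))
  if (!is.null(chains[[anc_tag]]) && length(data$clades)) {
    anc <- run_stage("ancestral", {
      lapply(data$clades, function(taxa) {
        ancestral_at_mrca(chains[[anc_tag]], data$trees, data$traits, taxa,
                          pi = config$root_prior, burn_in = config$burn_in)
      })
    })
  }

  report <- run_stage("summarize", {
    estimates <- list()
    if (!is.null(sel)) {
      # per-pair ML rate estimates come from the unconstrained fit: the
      # AIC-best model may constrain many pairs to one value (or zero),
      # which carries no rank information for the cross-method synthesis
      estimates[["ml"]] <- sel$fits[["unconstrained"]]$rates_by_pair
    }
    for (tag in names(rate_means)) {
      estimates[[paste0("bayes_", tag)]] <- rate_means[[tag]]$mean
    }
    build_report(
      ml_selections = if (is.null(sel)) NULL else list(main = sel),
      rate_estimates = if (length(estimates) >= 2) estimates else NULL,
      bf_tables = bfs,
      signal_reports = if (is.null(signal)) NULL else list(main = signal),
      ancestral = anc,
      out_dir = out)
  })

  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out, "manifest.json"))
  manifest <- list(
    package = "phenotrans",
    version = as.character(utils::packageVersion("phenotrans")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    traces = lapply(names(chains), function(tag) {
      list(mu = chains[[tag]]$meta$mu,
           posterior = paste0("trace_", tag, ".tsv"),
           prior_only = paste0("trace_", tag, "_prior.tsv"))
    }),
    files = data.frame(path = substring(files, nchar(out) + 2),
                       md5 = as.character(tools::md5sum(files)),
                       stringsAsFactors = FALSE)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(data = data, selection = sel, signal = signal,
                 chains = chains, prior_chains = priors, bayes_factors = bfs,
                 rate_means = rate_means, ancestral = anc, report = report,
                 manifest = manifest))
}

# ---------------------------------------------------------------------------
# Command-line interface.  Subcommands: simulate, fit-ml, signal, mcmc,
# ancestral, summarize, run-all.  Flags are --name value pairs.

parse_cli_args <- function(args) {
  if (!length(args)) stop("usage: phenotrans <subcommand> [--flag value ...]")
  cmd <- args[1]
  args <- args[-1]
  flags <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      flags[[key]] <- TRUE
      i <- i + 1
    } else {
      flags[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  list(cmd = cmd, flags = flags)
}

cli_flag <- function(flags, name, default = NULL, as = identity) {
  if (is.null(flags[[name]])) default else as(flags[[name]])
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `fit-ml`, `signal`, `mcmc`, `ancestral`,
#' `summarize`, `run-all`.  Shared flags: `--seed`, `--out`, `--config`
#' (JSON), `--tree`, `--traits`.  Returns (and, for non-zero, exits with)
#' a status code: 0 only if all requested stages succeed.
#'
#' @param args Character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Integer exit status, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  parsed <- tryCatch(parse_cli_args(args), error = function(e) {
    message(conditionMessage(e)); NULL
  })
  if (is.null(parsed)) return(invisible(1L))
  fl <- parsed$flags
  seed <- cli_flag(fl, "seed", 1L, as.integer)
  out <- cli_flag(fl, "out", "phenotrans_out")
  status <- tryCatch({
    switch(parsed$cmd,
      "simulate" = {
        sc <- wolbachia_like_scenario(cli_flag(fl, "variant", "small"), seed)
        write_scenario(sc, out)
        message("scenario written to ", out)
        0L
      },
      "run-all" = {
        cfg <- if (!is.null(fl$config)) load_config(fl$config) else {
          run_config(tree_file = fl$tree, trait_file = fl$traits,
                     scenario = cli_flag(fl, "variant", if (is.null(fl$tree)) "small"),
                     out_dir = out, seed = seed)
        }
        res <- run_all(cfg)
        bad <- vapply(res$manifest$stages,
                      function(s) identical(s$status, "error"), logical(1))
        if (any(bad)) 1L else 0L
      },
      "fit-ml" = {
        tree <- read_newick(fl$tree); if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree[[1]]
        traits <- read_trait_table(fl$traits)
        sel <- select_best(tree, traits, opts = fit_opts(seed = seed))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_fit_report(sel, file.path(out, "ml_fits.json"),
                         file.path(out, "ml_fits.tsv"))
        message("best model: ", sel$best)
        0L
      },
      "signal" = {
        tree <- read_newick(fl$tree); if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree[[1]]
        traits <- read_trait_table(fl$traits)
        rep <- phylo_signal(tree, traits,
                            n_perm = cli_flag(fl, "n-perm", 10000, as.numeric),
                            seed = seed, opts = fit_opts(seed = seed))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_signal_report(rep, file.path(out, "signal.json"),
                            file.path(out, "signal.tsv"))
        print(rep)
        0L
      },
      "mcmc" = {
        trees <- read_newick(fl$tree); if (inherits(trees, "phylo")) trees <- list(trees)
        traits <- read_trait_table(fl$traits)
        tr <- run_chain(trees, traits,
                        prior = rj_prior(cli_flag(fl, "mu", 100, as.numeric)),
                        n_generations = cli_flag(fl, "generations", 1e6, as.numeric),
                        sample_freq = cli_flag(fl, "sample-freq", 500, as.numeric),
                        seed = seed,
                        prior_only = isTRUE(fl[["prior-only"]]))
        dir.create(out, recursive = TRUE, showWarnings = FALSE)
        write_trace(tr, file.path(out, "trace.tsv"))
        print(tr)
        0L
      },
      "ancestral" = {
        trees <- read_newick(fl$tree); if (inherits(trees, "phylo")) trees <- list(trees)
        traits <- read_trait_table(fl$traits)
        trace <- read_trace(fl$trace)
        taxa <- strsplit(cli_flag(fl, "taxa", stop("--taxa required")), ",")[[1]]
        est <- ancestral_at_mrca(trace, trees, traits, taxa)
        print(round(est$mean, 4))
        0L
      },
      "summarize" = {
        stop("`summarize` is reached through run-all; see build_report()")
      },
      {
        message("unknown subcommand: ", parsed$cmd)
        1L
      })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(as.integer(status))
}
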