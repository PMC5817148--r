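test_that("standardize_rates: min-max formula and degenerate rule", {
  x <- c(2, 5, 8, rep(2, 17))
  s <- standardize_rates(x)
  expect_equal(range(s), c(0, 1))
  expect_equal(s[2], 0.5)
  expect_message(z <- standardize_rates(rep(3, 20)), "all rates equal")
  expect_equal(z, setNames(rep(0, 20), NULL), ignore_attr = TRUE)
  expect_error(standardize_rates(c(-1, rep(1, 19))), ">= 0")

  set.seed(3)
  for (i in 1:20) {
    v <- runif(20)
    s <- standardize_rates(v)
    expect_equal(min(s), 0)
    expect_equal(max(s), 1)
  }
})

test_that("average_standardized: mean and sample-sd standard error", {
  v <- runif(20)
  a <- average_standardized(list(v, v))
  expect_equal(a$mean, v, ignore_attr = TRUE)
  expect_equal(a$se, rep(0, 20), ignore_attr = TRUE)

  a2 <- average_standardized(list(rep(0, 20), rep(1, 20)))
  expect_equal(a2$mean, rep(0.5, 20), ignore_attr = TRUE)
  expect_equal(a2$se, rep(0.5, 20), ignore_attr = TRUE)  # sd = 0.7071, /sqrt(2)
  expect_true(all(a2$mean >= 0 & a2$mean <= 1))

  expect_error(average_standardized(list(v)), ">= 2")
  expect_error(average_standardized(list(v, v[1:5])), "length")
})

test_that("rank_transitions orders descending with lexicographic ties and flags top 4", {
  labels <- state_pairs()$label
  v <- setNames(runif(20, 0, 0.5), labels)
  tops <- c("PI->MK", "MK->O", "O->CI", "MK->CI")
  v[tops] <- c(0.99, 0.98, 0.97, 0.96)
  r <- rank_transitions(v)
  expect_equal(r$pair[1:4], tops)
  expect_true(all(r$top[1:4]) && !any(r$top[-(1:4)]))
  expect_setequal(r$pair, labels)
  expect_equal(r$rank, 1:20)

  req <- rank_transitions(setNames(rep(0.5, 20), labels))
  expect_equal(req$pair, sort(labels))
  expect_true(attr(req, "ties"))
})

test_that("spearman_cor: exact cases, oracle agreement, null behaviour", {
  x <- c(3, 1, 4, 1.5, 9, 2.6)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  expect_true(spearman_cor(rep(1, 5), 1:5)$undefined)
  expect_error(spearman_cor(1:3, 1:3), ">= 4")

  set.seed(8)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    a <- sample(round(runif(n, 0, 5), 1))  # ties likely
    b <- rnorm(n)
    expect_equal(spearman_cor(a, b)$rho, spearman_oracle(a, b),
                 tolerance = 1e-12)
  }

  rhos <- vapply(1:500, function(i) spearman_cor(runif(20), runif(20))$rho,
                 numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
})

test_that("synthesis pipeline is invariant to combo order", {
  set.seed(21)
  combos <- replicate(4, runif(20, 0, 3), simplify = FALSE)
  names(combos) <- paste0("c", 1:4)
  run <- function(lst) {
    rank_transitions(average_standardized(lapply(lst, standardize_rates))$mean)
  }
  expect_equal(run(combos), run(rev(combos)), ignore_attr = TRUE)
})

test_that("build_report assembles all tables and round-trips", {
  tr <- simulate_yule_tree(15, 1, seed = 91)
  sim <- simulate_trait(tr, equal_rates_q(0.4), seed = 92)
  sel <- select_best(tr, sim$traits, opts = fit_opts(n_starts = 1))
  sig <- permutation_test(tr, sim$traits, n_perm = 99, seed = 93)
  ch <- run_chain(tr, sim$traits, rj_prior(10), n_generations = 2000,
                  sample_freq = 20, seed = 94)
  pri <- run_chain(tr, sim$traits, rj_prior(10), n_generations = 2000,
                   sample_freq = 20, seed = 95, prior_only = TRUE)
  bf <- bayes_factors(classify_models(ch), classify_models(pri))
  pm <- posterior_rate_means(ch)
  anc <- ancestral_at_mrca(ch, tr, sim$traits, tr$tip.label[1:3])

  out <- withr::local_tempdir()
  rep <- build_report(
    ml_selections = list(main = sel),
    rate_estimates = list(ml = sel$fits[[sel$best]]$rates_by_pair,
                          bayes = pm$mean),
    bf_tables = list(mu10 = bf),
    signal_reports = list(main = sig),
    ancestral = list(clade1 = anc),
    out_dir = out)

  expect_s3_class(rep, "analysis_report")
  expect_true(all(file.exists(file.path(out, c(
    "table1_signal.tsv", "table2_bayes_factors.tsv",
    "table3_correlations.tsv", "fig3d_rate_mean_se.tsv",
    "ancestral_states.tsv", "report.json")))))
  # correlation matrix symmetric with unit diagonal
  C <- rep$correlations
  expect_equal(diag(C), rep(1, nrow(C)), ignore_attr = TRUE)
  expect_equal(C, t(C), tolerance = 1e-12)
  # round-trip
  back <- read_report(file.path(out, "report.json"))
  expect_equal(back$signal$min_transitions, rep$signal$min_transitions)
  expect_equal(back$rate_mean_se$mean, rep$rate_mean_se$mean, tolerance = 1e-12)

  # missing sections are noted, not fatal
  rep2 <- build_report(rate_estimates = NULL)
  expect_true(length(rep2$notes) >= 3)
})
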