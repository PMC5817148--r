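# Chains here are deliberately short; the calibration-grade checks (prior
# mean to 5%, TV distance between seeds) live in test-acceptance.R.

small_chain_data <- function() {
  tr <- simulate_yule_tree(12, 1, seed = 81)
  sim <- simulate_trait(tr, equal_rates_q(0.5), seed = 82)
  list(tree = tr, traits = sim$traits)
}

test_that("run_chain is seed-deterministic and has the right trace shape", {
  d <- small_chain_data()
  c1 <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 5000,
                  sample_freq = 50, seed = 4)
  c2 <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 5000,
                  sample_freq = 50, seed = 4)
  expect_identical(c1$samples, c2$samples)
  expect_equal(nrow(c1$samples), 100L)  # floor(n_generations / sample_freq)
  expect_equal(c1$samples$iteration, seq(50, 5000, by = 50))
  expect_true(all(c1$samples$k >= 0 & c1$samples$k <= 20))
  # k column consistent with signature
  k_from_sig <- vapply(strsplit(c1$samples$signature, ","), function(s) {
    length(unique(s[s != "0"]))
  }, integer(1))
  expect_equal(c1$samples$k, k_from_sig)

  c3 <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 5000,
                  sample_freq = 50, seed = 5)
  expect_false(identical(c1$samples$lnL, c3$samples$lnL))
})

test_that("prior-only chain recovers the exponential rate mean (coarsely)", {
  d <- small_chain_data()
  pri <- run_chain(d$tree, d$traits, rj_prior(100), n_generations = 5e4,
                   sample_freq = 10, seed = 6, prior_only = TRUE)
  R <- as.matrix(pri$samples[, grep("^rate\\.", names(pri$samples))])
  expect_equal(mean(R[R > 0]), 100, tolerance = 0.10)
  expect_true(all(pri$samples$lnL == 0))
})

test_that("likelihood pulls change rates down when tips share one state", {
  # all tips CI: the data penalize any rate that moves lineages out of CI,
  # so realized CI-exit rates must shrink relative to a matched prior-only
  # chain (rates of unvisited states stay prior-like, so the pooled
  # nonzero mean is not a sharp statistic)
  tr <- simulate_yule_tree(12, 1, seed = 83)
  td <- trait_data(setNames(rep("CI", 12), tr$tip.label))
  post <- run_chain(tr, td, rj_prior(100), n_generations = 3e4,
                    sample_freq = 10, seed = 7)
  pri <- run_chain(tr, td, rj_prior(100), n_generations = 3e4,
                   sample_freq = 10, seed = 7, prior_only = TRUE)
  ci_exit <- paste0("rate.CI.", c("FI", "MK", "O", "PI"))
  m_post <- mean(as.matrix(post$samples[, ci_exit]))
  m_pri <- mean(as.matrix(pri$samples[, ci_exit]))
  expect_lt(m_post, m_pri / 2)
})

test_that("fixed-model chain on a flat-likelihood dataset samples the prior", {
  # 2-leaf zero-length identical tips: likelihood is constant, so with
  # jump moves disabled the single class rate is exactly Exp(mu)
  tr <- parse_newick("(a:0,b:0);")
  td <- trait_data(c(a = "CI", b = "CI"))
  ch <- run_chain(tr, td, rj_prior(50), n_generations = 4e4, sample_freq = 10,
                  seed = 8, move_probs = rj_moves(1, 0, 0, 0, 0))
  expect_true(all(ch$samples$k == 1))
  r <- ch$samples[["rate.CI.FI"]]
  mc_se <- sd(r) / sqrt(50)  # generous ESS guess given autocorrelation
  expect_lt(abs(mean(r) - 50), 3 * mc_se + 5)
})

test_that("classify_models counts partition the retained samples", {
  d <- small_chain_data()
  ch <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 2e4,
                  sample_freq = 20, seed = 9)
  cl <- classify_models(ch, burn_in = 0.1)
  expect_equal(sum(cl$model), cl$n)
  expect_equal(sum(cl$k), cl$n)
  expect_equal(cl$n, nrow(ch$samples) - floor(0.1 * nrow(ch$samples)))
  # classification is a pure function of the trace
  expect_identical(cl$model, classify_models(ch, burn_in = 0.1)$model)
})

test_that("bayes_factors implements the smoothed odds ratio and guards mismatches", {
  # smoothed fractions: post 9/10 = 0.9, prior 5/10 = 0.5 -> BF = 9
  post <- fake_counts(model = c(m1 = 8), k = c("1" = 8), n = 8)
  pri <- fake_counts(model = c(m1 = 4, m2 = 4), k = c("1" = 4, "2" = 4),
                     n = 8, prior_only = TRUE)
  bf <- bayes_factors(post, pri)
  row <- bf$models[bf$models$item == "m1", ]
  expect_equal(row$BF, 9, tolerance = 1e-12)
  expect_equal(row$lnBF, log(9), tolerance = 1e-12)
  expect_equal(row$log10BF, log10(9), tolerance = 1e-12)

  # post == prior -> BF = 1, lnBF = 0
  bf2 <- bayes_factors(fake_counts(c(m1 = 4, m2 = 4), c("1" = 8), 8),
                       fake_counts(c(m1 = 4, m2 = 4), c("1" = 8), 8,
                                   prior_only = TRUE))
  expect_equal(bf2$models$lnBF, c(0, 0), tolerance = 1e-12)

  # labels: lnBF > 5 is "decisive"
  big <- fake_counts(c(m1 = 9998), c("1" = 9998), 9998)
  small <- fake_counts(c(m1 = 8, m2 = 9990), c("1" = 8, "13" = 9990), 9998,
                       prior_only = TRUE)
  bf3 <- bayes_factors(big, small)
  expect_gt(bf3$models$lnBF[1], 5)
  expect_equal(bf3$models$label[1], "decisive")
  # unseen-in-prior items are flagged
  expect_false(bf3$models$defined[bf3$models$item == "m1"] == FALSE)

  expect_error(bayes_factors(post, fake_counts(c(m1 = 1), c("1" = 1), 1)),
               "prior_only")
  pri_bad <- fake_counts(c(m1 = 4), c("1" = 4), 8, mu = 10, prior_only = TRUE)
  expect_error(bayes_factors(post, pri_bad), "prior means")
})

test_that("geweke diagnostic: iid normal passes, shifted series fails, constant undefined", {
  set.seed(19)
  zs <- vapply(1:60, function(i) geweke_diagnostic(rnorm(5000))$z, numeric(1))
  expect_gte(mean(abs(zs) < 4), 0.98)

  g2 <- geweke_diagnostic(c(rep(0, 5000), rep(1, 5000)))
  expect_false(g2$converged)
  expect_gt(abs(g2$z), 1.96)

  g3 <- geweke_diagnostic(rep(2.5, 1000))
  expect_true(g3$undefined)
  expect_true(is.na(g3$z))

  expect_error(geweke_diagnostic(rnorm(50)), "length")
  expect_error(geweke_diagnostic(rnorm(500), 0.6, 0.6), "<= 1")
})

test_that("ancestral_at_mrca: forced cherry and degenerate-chain cross-check", {
  tr <- parse_newick("((a:0,b:0):1,c:1);")
  td <- trait_data(c(a = "FI", b = "FI", c = "CI"))
  ch <- run_chain(tr, td, rj_prior(10), n_generations = 2000, sample_freq = 20,
                  seed = 10)
  est <- ancestral_at_mrca(ch, tr, td, c("a", "b"))
  expect_equal(unname(est$mean["FI"]), 1, tolerance = 1e-9)
  expect_equal(sum(est$mean), 1, tolerance = 1e-9)

  # a trace pinned to one Q must reproduce node_marginals exactly
  rates <- runif(20, 0.1, 1)
  Q <- q_matrix(rates)
  pinned <- ch
  rate_cols <- grep("^rate\\.", names(pinned$samples))
  for (i in seq_along(rate_cols)) pinned$samples[, rate_cols[i]] <- rates[i]
  est2 <- ancestral_at_mrca(pinned, tr, td, c("a", "c"), burn_in = 0)
  direct <- node_marginals(tr, td, Q, node = mrca_node(tr, c("a", "c")))
  expect_equal(unname(est2$mean), unname(direct), tolerance = 1e-9)
  expect_equal(unname(est2$mc_error), rep(0, 5), tolerance = 1e-12)
})

test_that("posterior_rate_means: pinned rates and ZERO pairs are exact", {
  d <- small_chain_data()
  ch <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 2000,
                  sample_freq = 20, seed = 11)
  ch$samples[["rate.PI.MK"]] <- 2.0
  ch$samples[["rate.CI.FI"]] <- 0.0
  pm <- posterior_rate_means(ch, burn_in = 0.1)
  expect_equal(unname(pm$mean["PI->MK"]), 2.0)
  expect_equal(unname(pm$mean["CI->FI"]), 0.0)
  expect_length(pm$mean, 20)
})

test_that("trace TSV + metadata sidecar round-trips losslessly", {
  d <- small_chain_data()
  ch <- run_chain(d$tree, d$traits, rj_prior(10), n_generations = 2000,
                  sample_freq = 20, seed = 12)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trace(ch, path)
  back <- read_trace(path)
  expect_equal(back$samples$signature, ch$samples$signature)
  expect_equal(as.matrix(back$samples[, grep("^rate\\.", names(back$samples))]),
               as.matrix(ch$samples[, grep("^rate\\.", names(ch$samples))]),
               tolerance = 1e-12)
  expect_equal(back$meta$mu, ch$meta$mu)
  expect_equal(back$meta$move_probs, ch$meta$move_probs)
  # classification built from the reread trace matches
  expect_identical(classify_models(back)$model, classify_models(ch)$model)
})

test_that("leaf-set mismatch across trees is rejected", {
  t1 <- simulate_yule_tree(6, 1, seed = 1)
  t2 <- simulate_yule_tree(7, 1, seed = 2)
  sim <- simulate_trait(t1, equal_rates_q(0.3), seed = 3)
  expect_error(run_chain(list(t1, t2), sim$traits, rj_prior(10),
                         n_generations = 100, sample_freq = 10, seed = 1),
               "leaf set")
})
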