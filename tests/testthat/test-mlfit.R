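opts_fast <- fit_opts(n_starts = 2, maxit = 200, seed = 7)

test_that("AIC identity is exact and nesting holds on a simulated dataset", {
  tr <- simulate_yule_tree(60, 1, seed = 21)
  sim <- simulate_trait(tr, equal_rates_q(0.4), seed = 22)
  f1 <- fit_model(tr, sim$traits, build_scheme("single"), opts = opts_fast)
  expect_identical(f1$AIC, 2 * f1$n_params - 2 * f1$lnL)
  # AIC arithmetic inverts: lnL = -(AIC - 2k)/2
  expect_equal(f1$lnL, -(f1$AIC - 2 * f1$n_params) / 2)

  sel <- select_best(tr, sim$traits, opts = opts_fast)
  for (f in sel$fits) expect_identical(f$AIC, 2 * f$n_params - 2 * f$lnL)
  lnl <- setNames(sel$table$lnL, sel$table$scheme)
  expect_gte(lnl["unconstrained"], lnl["symmetric"] - 1e-6)
  expect_gte(lnl["symmetric"], lnl["single"] - 1e-6)
})

test_that("flat likelihood: zero-length identical cherry gives log(0.2) under every model", {
  tr <- parse_newick("(a:0,b:0);")
  td <- trait_data(c(a = "CI", b = "CI"))
  for (scheme in c("single", "symmetric", "unconstrained")) {
    f <- fit_model(tr, td, build_scheme(scheme), opts = fit_opts(n_starts = 1))
    expect_equal(f$lnL, log(0.2), tolerance = 1e-8)
    expect_true(is.finite(f$lnL))
  }
})

test_that("multi-start fitting is deterministic given the seed", {
  tr <- simulate_yule_tree(30, 1, seed = 31)
  sim <- simulate_trait(tr, equal_rates_q(0.5), seed = 32)
  m <- build_scheme("symmetric")
  f1 <- fit_model(tr, sim$traits, m, opts = fit_opts(n_starts = 3, seed = 9))
  f2 <- fit_model(tr, sim$traits, m, opts = fit_opts(n_starts = 3, seed = 9))
  expect_identical(f1$rates, f2$rates)
  expect_identical(f1$lnL, f2$lnL)
})

test_that("single-rate estimate recovers the truth on moderate data", {
  # rate 0.5 on ~8 expected-length trees: enough changes to inform the fit
  errs <- vapply(1:5, function(i) {
    tr <- simulate_yule_tree(100, 1, seed = 100 + i)
    sim <- simulate_trait(tr, equal_rates_q(0.5), seed = 200 + i)
    f <- fit_model(tr, sim$traits, build_scheme("single"), opts = opts_fast)
    abs(f$rates[1] - 0.5) / 0.5
  }, numeric(1))
  expect_lt(median(errs), 0.35)
})

test_that("select_best structure: 3..8 fits, argmin AIC, parsimony tie-break", {
  tr <- simulate_yule_tree(40, 1, seed = 51)
  sim <- simulate_trait(tr, equal_rates_q(0.4), seed = 52)
  sel <- select_best(tr, sim$traits, opts = opts_fast)
  expect_gte(nrow(sel$table), 3)
  expect_lte(nrow(sel$table), 8)
  best_row <- sel$table[sel$table$scheme == sel$best, ]
  expect_equal(best_row$AIC, min(sel$table$AIC))
  ties <- sel$table[abs(sel$table$AIC - min(sel$table$AIC)) < 1e-12, ]
  expect_equal(best_row$k, min(ties$k))
})

test_that("2-class recovery: reduced models beat the unconstrained model", {
  # truth has 2 classes (0.3 / 3.0) and six zero pairs; AIC should prefer
  # few-parameter reductions over the 20-parameter model
  wins <- 0L
  for (i in 1:6) {
    sc <- wolbachia_like_scenario("small", seed = 300 + i)
    sel <- select_best(sc$tree, sc$traits, opts = fit_opts(n_starts = 1, seed = i))
    best_k <- sel$table$k[sel$table$scheme == sel$best]
    if (best_k <= 3) wins <- wins + 1L
    expect_false(sel$best == "unconstrained")
  }
  expect_gte(wins, 4L)
})

test_that("ml_ancestral returns normalized marginals at the requested clade", {
  tr <- parse_newick("((a:0,b:0):1,c:1);")
  td <- trait_data(c(a = "FI", b = "FI", c = "CI"))
  f <- fit_model(tr, td, build_scheme("single"), opts = fit_opts(n_starts = 1))
  p <- ml_ancestral(tr, td, f, c("a", "b"))
  expect_equal(sum(p), 1, tolerance = 1e-9)
  expect_equal(unname(p["FI"]), 1, tolerance = 1e-9)  # zero-length cherry

  # all tips one state: that state dominates at every internal node
  tr2 <- simulate_yule_tree(12, 1, seed = 61)
  td2 <- trait_data(setNames(rep("MK", 12), tr2$tip.label))
  f2 <- fit_model(tr2, td2, build_scheme("single"), opts = fit_opts(n_starts = 1))
  Q2 <- q_matrix(f2$rates_by_pair)
  M <- node_marginals(tr2, td2, Q2)
  internal <- (12 + 1):(12 + tr2$Nnode)
  expect_true(all(apply(M[, internal, drop = FALSE], 2, which.max) ==
                    match("MK", default_alphabet())))
})

test_that("fit report serializes to JSON and TSV", {
  tr <- simulate_yule_tree(20, 1, seed = 71)
  sim <- simulate_trait(tr, equal_rates_q(0.4), seed = 72)
  sel <- select_best(tr, sim$traits, opts = fit_opts(n_starts = 1))
  jf <- withr::local_tempfile(fileext = ".json")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fit_report(sel, jf, tf)
  j <- jsonlite::read_json(jf, simplifyVector = TRUE)
  expect_equal(j$best, sel$best)
  tab <- read.delim(tf)
  expect_equal(nrow(tab), nrow(sel$table))
})
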