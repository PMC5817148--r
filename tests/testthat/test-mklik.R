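test_that("transition probabilities: identity at t=0, closed form, series oracle", {
  Q <- random_q()
  expect_equal(transition_probabilities(Q, 0), diag(5), ignore_attr = TRUE)
  expect_error(transition_probabilities(Q, -1), ">= 0")

  # equal-rates closed form P_ii(t) = 1/k + (1 - 1/k) exp(-k r t)
  Qe <- equal_rates_q(0.1)
  P <- transition_probabilities(Qe, 2)
  expect_equal(diag(P), rep(1 / 5 + (4 / 5) * exp(-5 * 0.1 * 2), 5),
               tolerance = 1e-9, ignore_attr = TRUE)

  set.seed(31)
  for (i in 1:25) {
    Q <- random_q()
    t <- runif(1, 0, 1.5)
    P <- transition_probabilities(Q, t)
    expect_lt(max(abs(P - phenotrans:::series_expm(unname(Q) * t))), 1e-8)
    expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
    expect_true(all(P >= 0 & P <= 1))
  }
})

test_that("defective Q (structural zeros) falls back gracefully", {
  # absorbing-ish Q: only CI->MK and MK->CI nonzero, rest zero rows
  rates <- rep(0, 20)
  rates[which(state_pairs()$label == "CI->MK")] <- 0.7
  Q <- q_matrix(rates)
  P <- transition_probabilities(Q, 3)
  expect_equal(rowSums(P), rep(1, 5), tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(P[2, 2], 1)  # MK absorbing here
})

test_that("log-likelihood: forced-root and impossible-data cases", {
  tr <- parse_newick("(a:0,b:0);")
  td <- trait_data(c(a = "CI", b = "CI"))
  expect_equal(log_likelihood(tr, td, random_q()), log(0.2), tolerance = 1e-12)

  td2 <- trait_data(c(a = "CI", b = "MK"))
  Q0 <- q_matrix(rep(0, 20))
  expect_identical(log_likelihood(tr, td2, Q0), -Inf)

  expect_error(log_likelihood(tr, td, matrix(0, 3, 3)), "dimension")
})

test_that("pruning equals brute-force enumeration on random instances", {
  set.seed(77)
  for (i in 1:60) {
    tr <- random_tree(sample(2:6, 1))
    td <- random_traits(tr)
    Q <- random_q()
    ll <- log_likelihood(tr, td, Q)
    bf <- brute_force_log_likelihood(tr, td, Q)
    if (is.finite(bf)) expect_equal(ll, bf, tolerance = 1e-9) else expect_identical(ll, bf)
  }
  # stationary root prior route as well
  tr <- random_tree(5); td <- random_traits(tr); Q <- random_q()
  expect_equal(log_likelihood(tr, td, Q, pi = "stationary"),
               brute_force_log_likelihood(tr, td, Q, pi = "stationary"),
               tolerance = 1e-9)
})

test_that("likelihood is invariant to child-order permutation", {
  set.seed(99)
  tr <- parse_newick("((a:1,b:0.5):0.2,(c:0.3,d:0.4,e:0.1):0.6);")
  tr2 <- parse_newick("((c:0.3,e:0.1,d:0.4):0.6,(b:0.5,a:1):0.2);")
  td <- random_traits(tr)
  Q <- random_q()
  expect_equal(log_likelihood(tr, td, Q), log_likelihood(tr2, td, Q),
               tolerance = 1e-12)
})

test_that("star-tree likelihood matches the independent-tips closed form", {
  set.seed(13)
  tr <- make_star_tree(random_tree(8, p_zero = 0))
  td <- random_traits(tr)
  Q <- random_q()
  pi <- rep(0.2, 5)
  Ps <- lapply(tr$edge.length, function(b) transition_probabilities(Q, b))
  states <- td$index[tr$tip.label]
  closed <- log(sum(vapply(1:5, function(s) {
    pi[s] * prod(vapply(seq_along(states),
                        function(i) Ps[[i]][s, states[i]], numeric(1)))
  }, numeric(1))))
  expect_equal(log_likelihood(tr, td, Q), closed, tolerance = 1e-10)
})

test_that("no underflow on a 500-leaf tree (per-node rescaling)", {
  tr <- simulate_yule_tree(500, 1, seed = 5)
  sim <- simulate_trait(tr, equal_rates_q(0.3), seed = 6)
  ll <- log_likelihood(tr, sim$traits, equal_rates_q(0.3))
  expect_true(is.finite(ll))
  expect_lt(ll, 0)
})

test_that("node marginals: forced cherry, stationarity limit, brute-force match", {
  tr <- parse_newick("(a:0,b:0);")
  td <- trait_data(c(a = "MK", b = "MK"))
  m <- node_marginals(tr, td, random_q(), node = 3)
  expect_equal(unname(m["MK"]), 1, tolerance = 1e-12)

  # long branches under equal rates: marginals approach the uniform
  # stationary distribution
  tr2 <- parse_newick("((a:10000,b:10000):10000,c:10000);")
  td2 <- trait_data(c(a = "CI", b = "PI", c = "O"))
  m2 <- node_marginals(tr2, td2, equal_rates_q(0.05), node = 4)
  expect_equal(unname(m2), rep(0.2, 5), tolerance = 1e-3)

  set.seed(41)
  for (i in 1:25) {
    tr <- random_tree(3)
    td <- random_traits(tr)
    Q <- random_q()
    pi <- rep(0.2, 5)
    for (node in seq_len(3 + tr$Nnode)) {
      expect_equal(unname(node_marginals(tr, td, Q, pi, node = node)),
                   brute_marginal(tr, td, Q, pi, node), tolerance = 1e-9)
    }
  }

  # zero-probability data: marginal undefined
  tr3 <- parse_newick("(a:0,b:0);")
  td3 <- trait_data(c(a = "CI", b = "MK"))
  expect_error(node_marginals(tr3, td3, q_matrix(rep(0, 20)), node = 3),
               "probability 0")
})

test_that("marginal vectors always sum to 1", {
  set.seed(55)
  tr <- random_tree(6)
  td <- random_traits(tr)
  M <- node_marginals(tr, td, random_q())
  expect_equal(colSums(M), rep(1, ncol(M)), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("root priors validate and stationary prior is a left null vector", {
  Q <- random_q()
  s <- stationary_dist(Q)
  expect_equal(sum(s), 1, tolerance = 1e-12)
  expect_lt(max(abs(s %*% Q)), 1e-10)
  expect_error(phenotrans:::resolve_root_prior(c(0.5, 0.5, 0, 0, 0.1), k = 5),
               "sum to 1")
  expect_error(phenotrans:::resolve_root_prior(rep(0.2, 4), k = 5), "length")
})
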