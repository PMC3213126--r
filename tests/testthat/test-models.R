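test_that("transition matrices satisfy stochasticity, identity at t=0, and closed forms", {
  g <- gtr_gamma(rates = c(1, 3, 1, 1, 6, 1), freqs = c(0.4, 0.1, 0.2, 0.3))
  expect_equal(transition_matrix(g, 0), diag(4), ignore_attr = TRUE)
  P <- transition_matrix(g, 0.37)
  expect_equal(rowSums(P), rep(1, 4), ignore_attr = TRUE)

  # equal rates and frequencies reduce to Jukes-Cantor
  jc <- gtr_gamma()
  for (t in c(0.01, 0.2, 1.5)) {
    P <- transition_matrix(jc, t)
    expect_equal(P[1, 1], 0.25 + 0.75 * exp(-4 * t / 3), tolerance = 1e-12)
    expect_equal(P[1, 2], 0.25 - 0.25 * exp(-4 * t / 3), tolerance = 1e-12)
  }

  # symmetric binary model: P(stay) = (1 + exp(-2t)) / 2 under unit scaling
  bm <- binary_markov("one_parameter")
  for (t in c(0.05, 0.4, 2)) {
    P <- transition_matrix(bm, t)
    expect_equal(P[1, 1], (1 + exp(-2 * t)) / 2, tolerance = 1e-12)
  }

  expect_error(transition_matrix(g, NaN))
})

test_that("all models obey detailed balance at unit expected rate", {
  set.seed(5)
  for (rep in 1:4) {
    fr <- rgamma(4, 1); fr <- fr / sum(fr)
    rt <- rgamma(6, 1)
    g <- gtr_gamma(rates = rt, freqs = fr)
    for (t in c(0.1, 0.9)) {
      P <- transition_matrix(g, t)
      expect_equal(fr * P, t(fr * P), tolerance = 1e-10, ignore_attr = TRUE)
    }
    # unit scaling: derivative of P at 0 has expected rate 1
    Q <- ribopart:::gtr_rate_matrix(rt / sum(rt), fr)
    expect_equal(-sum(fr * diag(Q)), 1, tolerance = 1e-12)
  }
  b2 <- binary_markov("two_parameter", freqs = c(0.8, 0.2))
  P <- transition_matrix(b2, 0.7)
  expect_equal(c(0.8, 0.2) * P, t(c(0.8, 0.2) * P),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gamma discretization has mean 1 and matches a quadrature oracle", {
  expect_equal(discretize_gamma(0.5, 1), 1)
  expect_equal(mean(discretize_gamma(0.3, 4)), 1, tolerance = 1e-12)
  expect_equal(mean(discretize_gamma(7, 6)), 1, tolerance = 1e-12)

  # shape -> infinity: all category rates -> 1
  expect_equal(discretize_gamma(1e6, 4), rep(1, 4), tolerance = 1e-2)

  # independent numeric-integration oracle for the bin means
  oracle <- function(shape, k) {
    q <- qgamma(seq(0, 1, length.out = k + 1), shape, rate = shape)
    sapply(seq_len(k), function(i) {
      stats::integrate(function(x) x * dgamma(x, shape, rate = shape),
                       q[i], q[i + 1], rel.tol = 1e-10)$value * k
    })
  }
  for (shape in c(0.5, 1.7)) {
    r <- discretize_gamma(shape, 4)
    ro <- oracle(shape, 4)
    expect_equal(r, ro / mean(ro), tolerance = 1e-6)
  }
})

test_that("pruning equals brute-force enumeration and pairwise closed forms", {
  # enumeration oracle on 5- and 6-taxon trees with gaps and ambiguity
  for (seed in 1:3) {
    tr <- random_test_tree(5, seed)
    set.seed(seed + 50)
    mat <- matrix(sample(c("A", "C", "G", "T", "-", "N", "R"), 5 * 12, TRUE,
                         prob = c(rep(0.22, 4), 0.05, 0.04, 0.03)),
                  5, 12, dimnames = list(tr$tip.label, NULL))
    g <- gtr_gamma(rates = c(1, 2, 1, 1, 4, 1), freqs = c(0.3, 0.2, 0.3, 0.2),
                   shape = 0.7)
    expect_equal(pruning_loglik(tr, mat, g), brute_force_loglik(tr, mat, g),
                 tolerance = 1e-8)
  }
  tr6 <- random_test_tree(6, 9)
  mat6 <- random_test_alignment(6, 30, seed = 10)$mat
  g6 <- gtr_gamma(shape = 0.4)
  expect_equal(pruning_loglik(tr6, mat6, g6),
               brute_force_loglik(tr6, mat6, g6), tolerance = 1e-8)

  # two-taxon Jukes-Cantor closed form
  tr2 <- read_newick(text = "(a:0.1,b:0.2);")
  mat2 <- matrix(c("A", "A", "A", "C"), 2, 2,
                 dimnames = list(c("a", "b"), NULL))
  jc <- gtr_gamma(n_categories = 1)
  t <- 0.3
  expect_equal(pruning_loglik(tr2, mat2, jc),
               log(c(0.25 * (0.25 + 0.75 * exp(-4 * t / 3)),
                     0.25 * (0.25 - 0.25 * exp(-4 * t / 3)))),
               tolerance = 1e-12)

  # all-missing column has likelihood 1
  allq <- matrix("?", 2, 1, dimnames = list(c("a", "b"), NULL))
  expect_equal(pruning_loglik(tr2, allq, jc), 0)

  # label mismatch errors
  bad <- matrix("A", 2, 1, dimnames = list(c("a", "zzz"), NULL))
  expect_error(pruning_loglik(tr2, bad, jc), "match")
})

test_that("likelihood agrees with an independent implementation on larger data", {
  tr <- random_test_tree(12, 77)
  set.seed(78)
  mat <- random_test_alignment(12, 200, seed = 79, gap_prob = 0.05)$mat
  g <- gtr_gamma(rates = c(2, 5, 1, 1, 9, 1.5), freqs = c(0.35, 0.15, 0.2, 0.3),
                 shape = 0.6)
  mine <- sum(pruning_loglik(tr, mat, g))
  fit <- phangorn::pml(tr, phangorn::phyDat(mat), bf = g$freqs,
                       Q = g$rates / g$rates[6], shape = g$shape, k = 4)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("mixture likelihoods reduce, mix, and dominate correctly", {
  tr <- random_test_tree(5, 21)
  mat <- random_test_alignment(5, 40, seed = 22)$mat
  g1 <- gtr_gamma(rates = c(1, 2, 1, 1, 4, 1), freqs = c(0.3, 0.2, 0.3, 0.2),
                  shape = 0.8)
  g2 <- gtr_gamma(rates = c(3, 1, 1, 1, 1, 3), freqs = c(0.1, 0.4, 0.4, 0.1),
                  shape = 0.8)

  # K = 1 equals the single-model likelihood to machine precision
  expect_equal(mixture_loglik(tr, mat, mixture_spec(list(g1))),
               pruning_loglik(tr, mat, g1), tolerance = 1e-14)

  # identical components with any weights degenerate to K = 1
  expect_equal(mixture_loglik(tr, mat, mixture_spec(list(g1, g1),
                                                    weights = c(0.8, 0.2))),
               pruning_loglik(tr, mat, g1), tolerance = 1e-12)

  # K = 2 equals the directly computed weighted sum of per-site likelihoods
  w <- c(0.3, 0.7)
  direct <- log(w[1] * exp(pruning_loglik(tr, mat, g1)) +
                  w[2] * exp(pruning_loglik(tr, mat, g2)))
  expect_equal(mixture_loglik(tr, mat, mixture_spec(list(g1, g2), w)),
               direct, tolerance = 1e-10)

  # and matches the brute-force oracle
  mix <- mixture_spec(list(g1, g2), w)
  expect_equal(mixture_loglik(tr, mat[, 1:5], mix),
               brute_force_loglik(tr, mat[, 1:5, drop = FALSE], mix),
               tolerance = 1e-8)

  expect_error(mixture_spec(list(g1, g2), weights = c(0, 0)))
})

test_that("ascertainment correction matches the two-taxon closed form and bounds", {
  bm <- binary_markov("one_parameter", correction = "variable_only")
  tr2 <- read_newick(text = "(a:0.1,b:0.2);")
  m01 <- matrix(c("0", "1"), 2, 1, dimnames = list(c("a", "b"), NULL))
  t <- 0.3
  # P(variable) = 1 - (P(00) + P(11)) = 1 - (1 + exp(-2t))/2
  denom <- 1 - (1 + exp(-2 * t)) / 2
  expected <- log(0.5 * 0.5 * (1 - exp(-2 * t))) - log(denom)
  expect_equal(ascertainment_corrected_loglik(tr2, m01, bm), expected,
               tolerance = 1e-12)

  # correction strictly increases per-character lnL when t > 0
  raw <- sum(pruning_loglik(tr2, m01, bm))
  expect_gt(ascertainment_corrected_loglik(tr2, m01, bm), raw)

  # t -> infinity: the constant-pattern mass tends to 1/2
  trb <- read_newick(text = "(a:60,b:60);")
  lpc <- ribopart:::constant_pattern_logprob(trb, c("a", "b"), bm)
  expect_equal(exp(lpc), 0.5, tolerance = 1e-10)

  expect_error(ascertainment_corrected_loglik(
    tr2, m01, binary_markov("one_parameter", correction = "none")),
    "variable_only")
})

test_that("partitioned totals sum per-partition likelihoods and check coverage", {
  tr <- random_test_tree(6, 33)
  a <- random_test_alignment(6, 60, seed = 34)
  charsets(a) <- list(p1 = 1:25, p2 = 26:60)
  parts <- prepare_partitions(a)
  g1 <- gtr_gamma(shape = 0.5)
  g2 <- gtr_gamma(rates = c(1, 5, 1, 1, 5, 1), shape = 2)
  pm <- partitioned_model(list(p1 = g1, p2 = g2))
  tot <- total_loglik(tr, parts, pm)
  byhand <- sum(pruning_loglik(tr, parts$p1, g1)) +
    sum(pruning_loglik(tr, parts$p2, g2))
  expect_equal(tot, byhand, tolerance = 1e-12)

  # permuting the part order leaves the total unchanged
  expect_equal(total_loglik(tr, rev(parts),
                            partitioned_model(list(p2 = g2, p1 = g1))), tot)

  expect_error(total_loglik(tr, parts["p1"], pm), "differ")
  expect_error(prepare_partitions(a, list(q = "nope")), "missing charset")
})

test_that("refining a partition never lowers the maximized likelihood (nesting)", {
  # same fixed tree; coarse = one JC-style model for all sites, refined = free
  # parameters per block; optimize shape+rates numerically for both
  tr <- random_test_tree(8, 55)
  sim <- evolve_alignment(
    tr, partitioned_model(list(
      x = gtr_gamma(rates = c(1, 6, 1, 1, 6, 1), shape = 0.4),
      y = gtr_gamma(rates = c(4, 1, 4, 4, 1, 4), shape = 2))),
    c(x = 150L, y = 150L), seed = 56)
  parts <- prepare_partitions(sim$alignment)
  obj <- function(logshape, mat) {
    -sum(pruning_loglik(tr, mat, gtr_gamma(shape = exp(logshape))))
  }
  opt_block <- function(mat)
    -stats::optimize(function(s) obj(s, mat), c(-3, 3))$objective
  coarse <- opt_block(cbind(parts$x, parts$y))
  refined <- opt_block(parts$x) + opt_block(parts$y)
  expect_gte(refined, coarse - 1e-6)
})

test_that("likelihood decreases as a branch is stretched on variable data", {
  tr <- random_test_tree(6, 60)
  g <- gtr_gamma(shape = 1)
  mat <- evolve_alignment(tr, partitioned_model(list(p = g)),
                          c(p = 80L), seed = 61)$alignment$mat
  lls <- sapply(c(2, 5, 20, 100), function(f) {
    t2 <- tr
    t2$edge.length[3] <- tr$edge.length[3] * f
    sum(pruning_loglik(t2, mat, g))
  })
  expect_true(all(diff(lls) < 0))
})

test_that("optimally weighted mixtures dominate the best single component", {
  tr <- random_test_tree(6, 88)
  mix_true <- mixture_spec(list(
    gtr_gamma(rates = c(1, 7, 1, 1, 7, 1), shape = 0.6),
    gtr_gamma(rates = c(4, 1, 4, 4, 1, 4), shape = 0.6)))
  mat <- evolve_alignment(tr, partitioned_model(list(p = mix_true)),
                          c(p = 200L), seed = 89)$alignment$mat
  g1 <- mix_true$components[[1]]
  g2 <- mix_true$components[[2]]
  best_single <- max(sum(pruning_loglik(tr, mat, g1)),
                     sum(pruning_loglik(tr, mat, g2)))
  wgrid <- seq(0.01, 0.99, by = 0.01)
  mix_ll <- vapply(wgrid, function(w)
    sum(mixture_loglik(tr, mat, mixture_spec(list(g1, g2), c(w, 1 - w)))), 0)
  expect_gte(max(mix_ll), best_single)
})
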