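test_that("identical seeds reproduce chains bit-for-bit", {
  sim <- simulate_study(n_taxa = 8, part_lengths = c(A = 80L, B = 80L),
                        indel_rate = 0, seed = 3)
  parts <- prepare_partitions(sim$alignment)
  pm <- partitioned_model(list(A = gtr_gamma(), B = gtr_gamma()))
  cfg <- mcmc_config(n_generations = 600L, sample_interval = 10L,
                     burn_in_generations = 100L, seed = 42L)
  t1 <- run_chain(parts, pm, cfg)
  t2 <- run_chain(parts, pm, cfg)
  expect_identical(t1$samples, t2$samples)
  expect_identical(ape::write.tree(t1$trees), ape::write.tree(t2$trees))

  cfg2 <- cfg; cfg2$seed <- 43L
  t3 <- run_chain(parts, pm, cfg2)
  expect_false(identical(t1$samples$lnL, t3$samples$lnL))
})

test_that("prior-only sampling recovers the prior moments", {
  taxa <- paste0("t", 1:6)
  empty <- matrix("A", 6, 1, dimnames = list(taxa, NULL))
  pm <- partitioned_model(list(p = gtr_gamma(shape = 0.5)))
  cfg <- mcmc_config(n_generations = 40000L, sample_interval = 4L,
                     burn_in_generations = 2000L, seed = 7L,
                     prior_only = TRUE,
                     prior_branch_mean = 0.1, prior_shape_mean = 1)
  trace <- run_chain(list(p = empty), pm, cfg)
  pb <- post_burnin(trace)

  # branch lengths: 9 edges, iid Exp(mean 0.1) -> TL mean 0.9
  n_edge <- nrow(trace$trees[[1]]$edge)
  tl <- pb$TL
  se_tl <- sd(tl) / sqrt(effective_sample_size(tl))
  expect_lt(abs(mean(tl) - 0.1 * n_edge), 3 * se_tl + 1e-9)

  # gamma shape: Exp(mean 1)
  sh <- pb$p.shape
  se_sh <- sd(sh) / sqrt(effective_sample_size(sh))
  expect_lt(abs(mean(sh) - 1), 3 * se_sh)

  # base frequencies: Dirichlet(1) -> mean 1/4
  for (v in paste0("p.pi.", c("A", "C", "G", "T"))) {
    x <- pb[[v]]
    se <- sd(x) / sqrt(effective_sample_size(x))
    expect_lt(abs(mean(x) - 0.25), 3 * se + 0.005)
  }
})

test_that("the posterior concentrates on the truth as signal accumulates", {
  # strong-signal 4-taxon data: the true topology reaches high posterior
  tr <- read_newick(text = "((a:0.08,b:0.08):0.12,(c:0.08,d:0.08):0.12);")
  tr <- ape::unroot(tr)
  g <- gtr_gamma(shape = 1, n_categories = 1)
  sim <- evolve_alignment(tr, partitioned_model(list(p = g)), c(p = 800L),
                          seed = 11)
  cfg <- mcmc_config(n_generations = 4000L, sample_interval = 10L,
                     burn_in_generations = 1000L, seed = 13L)
  trace <- run_chain(prepare_partitions(sim$alignment),
                     partitioned_model(list(p = gtr_gamma())), cfg)
  pp <- clade_posterior(post_burnin_trees(trace), c("a", "b"))
  expect_gt(pp, 0.95)
})

test_that("zero-likelihood starts raise an actionable error", {
  taxa <- c("a", "b", "c", "d")
  mat <- matrix(c("0", "0", "1", "1"), 4, 1, dimnames = list(taxa, NULL))
  # a start tree with all branch lengths zero makes a variable binary
  # character impossible under the ascertainment-corrected model
  start <- read_newick(text = "(a:0,b:0,(c:0,d:0):0);")
  pm <- partitioned_model(list(p = binary_markov("one_parameter")))
  cfg <- mcmc_config(n_generations = 100L, burn_in_generations = 10L,
                     sample_interval = 10L)
  expect_error(run_chain(list(p = mat), pm, cfg, init_tree = start),
               "seed|start|likelihood")
})

test_that("ESS tracks independence and AR(1) autocorrelation", {
  set.seed(5)
  iid <- rnorm(1000)
  expect_lt(abs(effective_sample_size(iid) - 1000) / 1000, 0.15)

  rho <- 0.9
  n <- 5000
  x <- as.numeric(arima.sim(list(ar = rho), n))
  target <- n * (1 - rho) / (1 + rho)
  expect_lt(abs(effective_sample_size(x) - target) / target, 0.25)

  cst <- effective_sample_size(rep(1, 50))
  expect_equal(as.numeric(cst), 50)
  expect_true(attr(cst, "constant"))

  expect_error(effective_sample_size(1:5), ">= 10")
})

test_that("split-frequency divergence is zero for identical runs and exact on a toy", {
  t1 <- read_newick(text = "((a:1,b:1):1,(c:1,d:1):1,e:1);")
  t2 <- read_newick(text = "((a:1,c:1):1,(b:1,d:1):1,e:1);")
  runA <- list(t1, t1, t1, t1)
  expect_equal(as.numeric(split_frequency_divergence(list(runA, runA))), 0)
  expect_true(attr(split_frequency_divergence(list(runA, runA)), "converged"))

  # run1 samples t1 only; run2 samples t2 only: every split has per-run
  # frequencies (1, 0), so each SD = sd(c(1, 0)) and the mean equals it
  runB <- list(t2, t2, t2, t2)
  asdsf <- split_frequency_divergence(list(runA, runB))
  expect_equal(as.numeric(asdsf), sd(c(1, 0)))
  expect_false(attr(asdsf, "converged"))

  expect_error(split_frequency_divergence(list(runA)), ">= 2")
})

test_that("trace tidiers summarise parameters and glance reports run health", {
  sim <- simulate_study(n_taxa = 6, part_lengths = c(A = 60L),
                        indel_rate = 0, seed = 9)
  cfg <- mcmc_config(n_generations = 1500L, sample_interval = 5L,
                     burn_in_generations = 300L, seed = 2L)
  trace <- run_chain(prepare_partitions(sim$alignment),
                     partitioned_model(list(A = gtr_gamma())), cfg)
  td <- tidy(trace)
  expect_true(all(c("lnL", "TL", "A.shape", "A.pi.A", "A.r.AC") %in% td$term))
  expect_true(all(td$low <= td$mean & td$mean <= td$high))
  gl <- glance(trace)
  expect_equal(gl$n_samples, 300L)
  expect_lte(gl$lnml, max(trace$samples$lnL))
  p <- ggplot2::ggplot_build(autoplot(trace))
  expect_s3_class(p, "ggplot_built")
})

test_that("traces round-trip through flat parameter and tree files", {
  sim <- simulate_study(n_taxa = 6, part_lengths = c(A = 50L),
                        indel_rate = 0, seed = 14)
  cfg <- mcmc_config(n_generations = 400L, sample_interval = 10L,
                     burn_in_generations = 100L, seed = 3L)
  trace <- run_chain(prepare_partitions(sim$alignment),
                     partitioned_model(list(A = gtr_gamma())), cfg)
  pp <- withr::local_tempfile(fileext = ".tsv")
  tp <- withr::local_tempfile(fileext = ".nwk")
  write_trace(trace, pp, tp)
  back <- read_trace(pp, tp, config = cfg)
  expect_equal(back$samples$lnL, trace$samples$lnL, tolerance = 1e-6)
  expect_equal(names(back$samples), names(trace$samples))
  expect_equal(length(back$trees), length(trace$trees))
  # restored traces feed the comparison machinery
  cmp <- suppressWarnings(comparison_table(list(a = back, b = trace)))
  expect_lt(abs(cmp$bf_matrix["a", "b"]), 1e-6)
})
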