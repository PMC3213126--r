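# Metropolis-Hastings sampler over topology (NNI), branch lengths and
# substitution parameters of a partitioned model.  Single cold chain; one
# proposal per generation; all randomness flows from the config seed, so runs
# are bit-for-bit reproducible.

#' MCMC configuration
#'
#' @param n_generations Total generations (one proposal each).
#' @param sample_interval Record a sample every this many generations.
#' @param burn_in_generations Generations discarded by downstream summaries.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param proposal_weights Named numeric weights for move types
#'   `topology`, `branch`, `rates`, `freqs`, `shape`, `weights`.
#' @param prior_branch_mean Mean of the exponential branch-length prior.
#' @param prior_shape_mean Mean of the exponential prior on the gamma shape.
#' @param tune_branch,tune_shape Log-scale multiplier window widths.
#' @param dirichlet_concentration Concentration of the Dirichlet proposal
#'   kernels on simplex parameters.
#' @param prior_only If `TRUE` the likelihood is held at 0 and the chain
#'   samples the prior (used for validation).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_generations = 20000L, sample_interval = 20L,
                        burn_in_generations = n_generations %/% 4L,
                        seed = 1L,
                        proposal_weights = c(topology = 3, branch = 8,
                                             rates = 2, freqs = 2,
                                             shape = 1, weights = 1),
                        prior_branch_mean = 0.1,
                        prior_shape_mean = 1,
                        tune_branch = 2, tune_shape = 1.5,
                        dirichlet_concentration = 300,
                        prior_only = FALSE) {
  stopifnot(burn_in_generations < n_generations, sample_interval >= 1L)
  structure(list(n_generations = as.integer(n_generations),
                 sample_interval = as.integer(sample_interval),
                 burn_in_generations = as.integer(burn_in_generations),
                 seed = as.integer(seed),
                 proposal_weights = proposal_weights,
                 prior_branch_mean = prior_branch_mean,
                 prior_shape_mean = prior_shape_mean,
                 tune_branch = tune_branch, tune_shape = tune_shape,
                 dirichlet_concentration = dirichlet_concentration,
                 prior_only = isTRUE(prior_only)),
            class = "mcmc_config")
}

ldirichlet <- function(x, alpha) {
  sum((alpha - 1) * log(x)) + lgamma(sum(alpha)) - sum(lgamma(alpha))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# --- internal chain state ----------------------------------------------------

# prepared partition: the site patterns are compressed once up front (they
# never change during a chain); ascertainment-corrected binary partitions get
# the two constant patterns appended with weight 0 so one pruning call yields
# both the data likelihood and the correction denominator
prepare_chain_data <- function(parts, models) {
  out <- lapply(names(parts), function(nm) {
    mat <- parts[[nm]]
    if (inherits(mat, "rb_alignment") || inherits(mat, "rb_indel_matrix"))
      mat <- mat$mat
    model <- models[[nm]]
    states <- model_states(model)
    asc <- inherits(model, "binary_markov") &&
      model$correction == "variable_only"
    n_char <- ncol(mat)
    if (n_char == 0L)
      return(list(name = nm, n_char = 0L, asc = asc, taxa = rownames(mat)))
    if (asc) {
      const_mat <- matrix(rep(c("0", "1"), each = nrow(mat)), nrow(mat), 2L,
                          dimnames = list(rownames(mat), NULL))
      mat <- cbind(mat, const_mat)
    }
    cp <- compress_patterns(mat, states)
    w <- cp$weights
    if (asc) {
      # patterns occupied only by the appended constant columns get weight 0
      occ <- tabulate(cp$pattern_of_site[seq_len(n_char)], length(w))
      w <- occ
    }
    list(name = nm, n_char = n_char, asc = asc, cp = cp, pat_weight = w,
         const_pat = if (asc) cp$pattern_of_site[n_char + 1:2] else NULL,
         taxa = rownames(mat))
  })
  stats::setNames(out, names(parts))
}

# per-partition log-likelihood from precompressed patterns
partition_loglik <- function(tp, pd, model) {
  if (pd$n_char == 0L) return(0)
  classes <- model_classes(model)
  partition_loglik_cached(tp, pd, classes, vapply(classes, `[[`, 0, "logw"))
}

partition_loglik_cached <- function(tp, pd, classes, logw) {
  perpat <- pattern_loglik_mixed(tp, pd$cp, classes, logw)
  ll <- sum(perpat * pd$pat_weight)
  if (pd$asc) {
    lc <- perpat[pd$const_pat]
    mx <- max(lc)
    lpc <- mx + log(sum(exp(lc - mx)))
    if (lpc >= 0) stop("numerical failure: P(constant) >= 1")
    ll <- ll - pd$n_char * log1p(-exp(lpc))
  }
  ll
}

log_prior <- function(tree, models, cfg) {
  lp <- sum(stats::dexp(tree$edge.length, rate = 1 / cfg$prior_branch_mean,
                        log = TRUE))
  for (m in models) {
    if (inherits(m, "gtr_gamma"))
      lp <- lp + stats::dexp(m$shape, 1 / cfg$prior_shape_mean, log = TRUE)
    else if (inherits(m, "mixture_spec"))
      lp <- lp + stats::dexp(m$components[[1L]]$shape, 1 / cfg$prior_shape_mean,
                             log = TRUE)
    # Dirichlet(1) priors on simplices are flat: constant, omitted
  }
  lp
}

flatten_params <- function(models) {
  out <- numeric(0)
  rate_names <- c("AC", "AG", "AT", "CG", "CT", "GT")
  for (nm in names(models)) {
    m <- models[[nm]]
    if (inherits(m, "gtr_gamma")) {
      out <- c(out,
               stats::setNames(m$freqs, paste0(nm, ".pi.", DNA_STATES)),
               stats::setNames(m$rates, paste0(nm, ".r.", rate_names)),
               stats::setNames(m$shape, paste0(nm, ".shape")))
    } else if (inherits(m, "binary_markov")) {
      if (m$variant == "two_parameter")
        out <- c(out, stats::setNames(m$freqs[2L], paste0(nm, ".pi1")))
    } else if (inherits(m, "mixture_spec")) {
      for (k in seq_along(m$components)) {
        cm <- m$components[[k]]
        out <- c(out,
                 stats::setNames(cm$freqs,
                                 paste0(nm, ".c", k, ".pi.", DNA_STATES)),
                 stats::setNames(cm$rates,
                                 paste0(nm, ".c", k, ".r.", rate_names)))
      }
      out <- c(out,
               stats::setNames(m$components[[1L]]$shape, paste0(nm, ".shape")),
               stats::setNames(m$weights,
                               paste0(nm, ".w", seq_along(m$weights))))
    }
  }
  out
}

#' Run a Metropolis-Hastings chain
#'
#' Samples topology, branch lengths and all unlinked substitution parameters
#' of a partitioned model.  Priors: exponential on branch lengths and gamma
#' shape, Dirichlet(1) on simplex parameters, uniform on topologies.
#'
#' @param parts Named list of character matrices (see [prepare_partitions()]);
#'   may be an empty-column dataset together with `cfg$prior_only = TRUE` for
#'   prior-recovery checks.
#' @param pm A [partitioned_model()] providing the initial parameter values;
#'   assignment names must match `names(parts)`.
#' @param cfg An [mcmc_config()].
#' @param init_tree Optional starting `phylo`; default a random topology with
#'   exponential branch lengths drawn from the prior.
#' @param run_label Label stored with the trace.
#' @return An object of class `mcmc_trace`: list with `samples` (tibble:
#'   `generation`, `lnL`, `TL`, then one column per free parameter), `trees`
#'   (`multiPhylo`, one per sample), `config`, `run_label`.
#' @export
run_chain <- function(parts, pm, cfg = mcmc_config(), init_tree = NULL,
                      run_label = "run1") {
  stopifnot(inherits(pm, "partitioned_model"), inherits(cfg, "mcmc_config"))
  if (!setequal(names(parts), names(pm$assignments)))
    stop("partition names of data and model differ")
  pd <- prepare_chain_data(parts, pm$assignments)
  taxa_labels <- pd[[1L]]$taxa
  set.seed(cfg$seed)

  tree <- init_tree %||% random_start_tree(taxa_labels, cfg$prior_branch_mean)
  tree <- ape::unroot(tree)
  models <- pm$assignments[names(parts)]

  classes_cache <- lapply(models, model_classes)
  logw_cache <- lapply(classes_cache, function(cl) vapply(cl, `[[`, 0, "logw"))
  eval_part <- function(tp, nm, model = models[[nm]],
                        classes = classes_cache[[nm]],
                        logw = logw_cache[[nm]]) {
    if (cfg$prior_only || pd[[nm]]$n_char == 0L) return(0)
    partition_loglik_cached(tp, pd[[nm]], classes, logw)
  }
  tp <- tree_pieces(tree, taxa_labels)
  part_ll <- vapply(names(parts), function(nm)
    tryCatch(eval_part(tp, nm), error = function(e) -Inf), 0)
  if (!all(is.finite(part_ll)))
    stop("zero likelihood at the initial state; try another seed or start tree")
  lp <- log_prior(tree, models, cfg)

  # feasible move types given the models
  w <- cfg$proposal_weights
  has_nuc <- any(vapply(models, function(m) !inherits(m, "binary_markov"), TRUE))
  has_mix <- any(vapply(models, inherits, TRUE, "mixture_spec"))
  has_freeb <- any(vapply(models, function(m)
    inherits(m, "binary_markov") && m$variant == "two_parameter", TRUE))
  if (!has_nuc) { w["rates"] <- 0; w["shape"] <- 0 }
  if (!has_nuc && !has_freeb) w["freqs"] <- 0
  if (!has_mix) w["weights"] <- 0
  if (length(taxa_labels) <= 3L) w["topology"] <- 0
  w <- w[w > 0]

  n_samp <- cfg$n_generations %/% cfg$sample_interval
  par0 <- flatten_params(models)
  samp <- matrix(NA_real_, n_samp, 3L + length(par0))
  colnames(samp) <- c("generation", "lnL", "TL", names(par0))
  tree_samples <- vector("list", n_samp)
  si <- 0L
  n_acc <- 0L
  acc_by_move <- stats::setNames(integer(length(w)), names(w))
  n_by_move <- acc_by_move

  nuc_parts <- names(models)[vapply(models, function(m)
    !inherits(m, "binary_markov"), TRUE)]
  freq_parts <- names(models)[vapply(models, function(m)
    !inherits(m, "binary_markov") ||
      m$variant == "two_parameter", TRUE)]
  mix_parts <- names(models)[vapply(models, inherits, TRUE, "mixture_spec")]
  conc <- cfg$dirichlet_concentration

  for (gen in seq_len(cfg$n_generations)) {
    move <- sample(names(w), 1L, prob = w)
    new_tree <- tree
    new_models <- models
    lhast <- 0
    changed <- character(0)  # partitions needing likelihood recomputation

    if (move == "topology") {
      new_tree <- phangorn::rNNI(tree, moves = 1L)
      changed <- names(parts)
    } else if (move == "branch") {
      e <- sample.int(nrow(tree$edge), 1L)
      m_ <- exp(cfg$tune_branch * (stats::runif(1L) - 0.5))
      new_tree$edge.length[e] <- tree$edge.length[e] * m_
      lhast <- log(m_)
      changed <- names(parts)
    } else if (move == "shape") {
      nm <- if (length(nuc_parts) == 1L) nuc_parts else sample(nuc_parts, 1L)
      m_ <- exp(cfg$tune_shape * (stats::runif(1L) - 0.5))
      new_models[[nm]] <- set_shape(new_models[[nm]],
                                    get_shape(new_models[[nm]]) * m_)
      lhast <- log(m_)
      changed <- nm
    } else if (move == "rates") {
      nm <- if (length(nuc_parts) == 1L) nuc_parts else sample(nuc_parts, 1L)
      upd <- propose_simplex_slot(new_models[[nm]], "rates", conc)
      new_models[[nm]] <- upd$model; lhast <- upd$lhast
      changed <- nm
    } else if (move == "freqs") {
      nm <- if (length(freq_parts) == 1L) freq_parts else sample(freq_parts, 1L)
      upd <- propose_simplex_slot(new_models[[nm]], "freqs", conc)
      new_models[[nm]] <- upd$model; lhast <- upd$lhast
      changed <- nm
    } else if (move == "weights") {
      nm <- if (length(mix_parts) == 1L) mix_parts else sample(mix_parts, 1L)
      cur <- new_models[[nm]]$weights
      prop <- rdirichlet1(conc * cur + 0.05)
      lhast <- ldirichlet(cur, conc * prop + 0.05) -
        ldirichlet(prop, conc * cur + 0.05)
      new_models[[nm]]$weights <- prop
      changed <- nm
    }

    tree_moved <- move %in% c("topology", "branch")
    new_tp <- if (tree_moved) tree_pieces(new_tree, taxa_labels) else tp
    new_part_ll <- part_ll
    new_classes <- classes_cache
    new_logw <- logw_cache
    ok <- TRUE
    for (nm in changed) {
      if (!tree_moved) {
        new_classes[[nm]] <- model_classes(new_models[[nm]])
        new_logw[[nm]] <- vapply(new_classes[[nm]], `[[`, 0, "logw")
      }
      v <- tryCatch(eval_part(new_tp, nm, new_models[[nm]],
                              new_classes[[nm]], new_logw[[nm]]),
                    error = function(e) -Inf)
      if (!is.finite(v) && !(cfg$prior_only || pd[[nm]]$n_char == 0L)) ok <- FALSE
      new_part_ll[nm] <- v
    }
    if (ok) {
      new_lp <- log_prior(new_tree, new_models, cfg)
      la <- (sum(new_part_ll) + new_lp) - (sum(part_ll) + lp) + lhast
      if (la >= 0 || log(stats::runif(1L)) < la) {
        tree <- new_tree; models <- new_models
        part_ll <- new_part_ll; lp <- new_lp; tp <- new_tp
        classes_cache <- new_classes; logw_cache <- new_logw
        n_acc <- n_acc + 1L
        acc_by_move[move] <- acc_by_move[move] + 1L
      }
    }
    n_by_move[move] <- n_by_move[move] + 1L

    if (gen %% cfg$sample_interval == 0L) {
      si <- si + 1L
      samp[si, ] <- c(gen, sum(part_ll), sum(tree$edge.length),
                      flatten_params(models))
      tree_samples[[si]] <- tree
    }
  }

  class(tree_samples) <- "multiPhylo"
  structure(list(samples = tibble::as_tibble(as.data.frame(samp)),
                 trees = tree_samples,
                 config = cfg, run_label = run_label,
                 acceptance_rate = n_acc / cfg$n_generations,
                 acceptance_by_move = ifelse(n_by_move > 0,
                                             acc_by_move / pmax(n_by_move, 1L),
                                             NA_real_)),
            class = "mcmc_trace")
}

random_start_tree <- function(taxa_labels, branch_mean) {
  tr <- ape::rtree(length(taxa_labels), tip.label = sample(taxa_labels))
  tr$edge.length <- stats::rexp(nrow(tr$edge), rate = 1 / branch_mean)
  ape::unroot(tr)
}

get_shape <- function(m) {
  if (inherits(m, "mixture_spec")) m$components[[1L]]$shape else m$shape
}

set_shape <- function(m, s) {
  if (inherits(m, "mixture_spec")) {
    m$components <- lapply(m$components, function(cm) { cm$shape <- s; cm })
  } else m$shape <- s
  m
}

# propose a Dirichlet-kernel update of `slot` ("rates"/"freqs"); for mixtures
# a random component is updated
propose_simplex_slot <- function(m, slot, conc) {
  if (inherits(m, "mixture_spec")) {
    k <- sample.int(length(m$components), 1L)
    cur <- m$components[[k]][[slot]]
    prop <- rdirichlet1(conc * cur + 0.05)
    m$components[[k]][[slot]] <- prop
  } else {
    cur <- m[[slot]]
    prop <- rdirichlet1(conc * cur + 0.05)
    m[[slot]] <- prop
  }
  list(model = m,
       lhast = ldirichlet(cur, conc * prop + 0.05) -
         ldirichlet(prop, conc * cur + 0.05))
}

#' @export
print.mcmc_trace <- function(x, ...) {
  cat(sprintf("<mcmc_trace> '%s': %d samples over %d generations (burn-in %d)\n",
              x$run_label, nrow(x$samples), x$config$n_generations,
              x$config$burn_in_generations))
  cat(sprintf("acceptance rate %.3f; mean lnL %.2f\n", x$acceptance_rate,
              mean(post_burnin(x)$lnL)))
  invisible(x)
}

#' Post-burn-in samples of a trace
#' @param trace An `mcmc_trace`.
#' @return Tibble of samples with `generation > burn_in_generations`.
#' @export
post_burnin <- function(trace) {
  out <- dplyr::filter(trace$samples,
                       .data$generation > trace$config$burn_in_generations)
  if (nrow(out) < 2L) stop("need >= 2 post-burn-in samples")
  out
}

#' Post-burn-in trees of a trace
#' @param trace An `mcmc_trace`.
#' @export
post_burnin_trees <- function(trace) {
  keep <- trace$samples$generation > trace$config$burn_in_generations
  out <- trace$trees[keep]
  class(out) <- "multiPhylo"
  out
}

# --- diagnostics -------------------------------------------------------------

#' Effective sample size from the autocorrelation time
#'
#' ESS = n / (1 + 2 * sum of initial positive autocorrelations), capped at n.
#' A constant series returns n with attribute `constant = TRUE`.
#'
#' @param values Numeric vector, length >= 10.
#' @return Scalar ESS.
#' @export
effective_sample_size <- function(values) {
  n <- length(values)
  if (n < 10L) stop("need >= 10 values for an ESS estimate")
  if (stats::sd(values) == 0)
    return(structure(as.numeric(n), constant = TRUE))
  rho <- stats::acf(values, lag.max = min(n - 1L, 10L * floor(sqrt(n))),
                    plot = FALSE)$acf[-1L]
  neg <- which(rho <= 0)
  if (length(neg)) rho <- rho[seq_len(neg[1L] - 1L)]
  tau <- 1 + 2 * sum(rho)
  min(n, n / max(tau, 1e-12))
}

#' Average standard deviation of split frequencies across runs
#'
#' The topological convergence diagnostic: for every split observed in any
#' run, the SD of its per-run frequencies is computed (absent = 0), and the
#' mean over splits returned.  Zero iff the runs sample identical split
#' distributions.
#'
#' @param traces List of `mcmc_trace` objects (>= 2) over identical taxa, or
#'   a list of `multiPhylo` samples.
#' @param converged_below Threshold under which runs are flagged converged.
#' @return Scalar with attribute `converged`.
#' @export
split_frequency_divergence <- function(traces, converged_below = 0.01) {
  if (length(traces) < 2L) stop("need >= 2 runs to compare split frequencies")
  tree_sets <- lapply(traces, function(tr) {
    if (inherits(tr, "mcmc_trace")) post_burnin_trees(tr) else tr
  })
  sfs <- lapply(tree_sets, split_frequencies)
  all_splits <- unique(unlist(lapply(sfs, `[[`, "split")))
  if (!length(all_splits)) return(structure(0, converged = TRUE))
  fmat <- vapply(sfs, function(sf) {
    f <- sf$freq[match(all_splits, sf$split)]
    ifelse(is.na(f), 0, f)
  }, numeric(length(all_splits)))
  fmat <- matrix(fmat, nrow = length(all_splits))
  asdsf <- mean(apply(fmat, 1L, stats::sd))
  structure(asdsf, converged = asdsf < converged_below)
}

#' Neighbor-joining starting tree from nucleotide data
#'
#' A deterministic, data-informed chain start: JC69 distances and
#' neighbor-joining, with non-positive branch lengths clamped to a small
#' constant.  Falls back to raw p-distances if JC distances are undefined
#' (saturation).
#'
#' @param mat Character matrix (taxa x sites) or `rb_alignment`.
#' @return Unrooted `phylo`.
#' @export
nj_start_tree <- function(mat) {
  if (inherits(mat, "rb_alignment")) mat <- mat$mat
  dn <- ape::as.DNAbin(tolower(mat))
  d <- ape::dist.dna(dn, model = "JC69", pairwise.deletion = TRUE)
  if (anyNA(d) || any(!is.finite(d)))
    d <- ape::dist.dna(dn, model = "raw", pairwise.deletion = TRUE)
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length <= 0] <- 1e-6
  ape::unroot(tr)
}

#' Write / read an MCMC trace as plain files
#'
#' The parameter trace goes to a tab-separated file (`generation`, `lnL`,
#' `TL`, then one column per parameter) and the sampled trees to a Newick
#' file, one per sampled generation.  `read_trace()` restores an object
#' usable by all summaries ([post_burnin()], [comparison_table()],
#' [majority_rule_consensus()] via [post_burnin_trees()], ...).
#'
#' @param trace An `mcmc_trace`.
#' @param params_path Path for the tab-separated parameter file.
#' @param trees_path Path for the Newick tree samples (optional for write,
#'   `NULL` to skip).
#' @export
write_trace <- function(trace, params_path, trees_path = NULL) {
  utils::write.table(trace$samples, params_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(trees_path)) ape::write.tree(trace$trees, file = trees_path)
  invisible(params_path)
}

#' @rdname write_trace
#' @param config The [mcmc_config()] the chain was run with (burn-in and
#'   sampling metadata are not stored in the flat files).
#' @param run_label Label for the restored trace.
#' @export
read_trace <- function(params_path, trees_path = NULL, config = mcmc_config(),
                       run_label = basename(params_path)) {
  samples <- tibble::as_tibble(utils::read.delim(params_path, sep = "\t",
                                                 check.names = FALSE))
  trees <- if (!is.null(trees_path)) {
    tr <- ape::read.tree(trees_path)
    if (inherits(tr, "phylo")) { tr <- list(tr); class(tr) <- "multiPhylo" }
    tr
  } else NULL
  structure(list(samples = samples, trees = trees, config = config,
                 run_label = run_label, acceptance_rate = NA_real_),
            class = "mcmc_trace")
}
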