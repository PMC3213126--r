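# The 15 standard partitioning regimes: 2/4/6-partition
# layouts of the ribosomal loci plus the binary indel partition, the indel
# partition modeled by a one- or two-parameter binary Markov model (always
# with the variable-only ascertainment correction), and 1..7-component
# GTR+Gamma mixtures on the nucleotide partitions.

#' Catalog of the partitioning regimes
#'
#' @return A tibble with one row per regime: `name`, `n_partitions` (2, 4 or
#'   6, counting the indel partition), `indel_model` (`"one_parameter"` /
#'   `"two_parameter"`), `n_matrices` (mixture components K on the nucleotide
#'   partitions) and `engine` (which classic MCMC software family this kind
#'   of regime is conventionally run in; informational).
#' @export
regime_catalog <- function() {
  tibble::tribble(
    ~name,             ~n_partitions, ~indel_model,    ~n_matrices, ~engine,
    "2 partitions A",  2L, "one_parameter", 1L, "MB",
    "4 partitions A",  4L, "one_parameter", 1L, "MB",
    "6 partitions A",  6L, "one_parameter", 1L, "MB",
    "2 partitions B",  2L, "two_parameter", 1L, "MB",
    "4 partitions B",  4L, "two_parameter", 1L, "MB",
    "6 partitions B",  6L, "two_parameter", 1L, "MB",
    "2 partitions C",  2L, "one_parameter", 1L, "BP",
    "4 partitions C",  4L, "one_parameter", 1L, "BP",
    "6 partitions C",  6L, "one_parameter", 1L, "BP",
    "6 partitions D",  6L, "one_parameter", 2L, "BP",
    "6 partitions E",  6L, "one_parameter", 3L, "BP",
    "6 partitions F",  6L, "one_parameter", 4L, "BP",
    "6 partitions G",  6L, "one_parameter", 5L, "BP",
    "6 partitions H",  6L, "one_parameter", 6L, "BP",
    "6 partitions I",  6L, "one_parameter", 7L, "BP")
}

# charset groupings per layout; the dataset must carry either the five
# fine charsets (ITS1, 5.8S, ITS2, LSU, SSU) or the coarser ITS/LSU/SSU set
regime_layout <- function(n_partitions, available) {
  fine <- c("ITS1", "5.8S", "ITS2", "LSU", "SSU")
  coarse <- c("ITS", "LSU", "SSU")
  if (n_partitions == 6L) {
    need <- fine
    groups <- stats::setNames(as.list(fine), fine)
  } else if (n_partitions == 4L) {
    if (all(coarse %in% available)) {
      need <- coarse
      groups <- stats::setNames(as.list(coarse), coarse)
    } else {
      need <- fine
      groups <- list(ITS = c("ITS1", "5.8S", "ITS2"), LSU = "LSU", SSU = "SSU")
    }
  } else if (n_partitions == 2L) {
    need <- if (all(coarse %in% available)) coarse else fine
    groups <- list(nuc = need)
  } else stop("unsupported layout")
  missing <- setdiff(need, available)
  if (length(missing))
    stop("dataset lacks required charset(s): ", paste(missing, collapse = ", "))
  groups
}

# build the partitioned model for a regime with default initial parameters
regime_model <- function(regime_row, part_names) {
  K <- regime_row$n_matrices
  nuc_model <- if (K == 1L) gtr_gamma()
  else mixture_spec(replicate(K, gtr_gamma(), simplify = FALSE))
  models <- stats::setNames(rep(list(nuc_model), length(part_names)), part_names)
  models$indel <- binary_markov(regime_row$indel_model,
                                correction = "variable_only")
  partitioned_model(models)
}

#' Run one partitioning regime on a dataset
#'
#' @param dataset List with `alignment` (an `rb_alignment` whose charsets
#'   include `ITS1`, `5.8S`, `ITS2`, `LSU`, `SSU` -- or the coarser `ITS`,
#'   `LSU`, `SSU`) and `indel` (`rb_indel_matrix`, may be `NULL` only if the
#'   regime is run without the indel partition).
#' @param regime Regime name from [regime_catalog()].
#' @param cfg An [mcmc_config()].
#' @param run_label Label for the trace.
#' @return An `mcmc_trace`.
#' @export
run_regime <- function(dataset, regime, cfg = mcmc_config(),
                       run_label = regime) {
  cat_ <- regime_catalog()
  row <- cat_[cat_$name == regime, ]
  if (!nrow(row)) stop("unknown regime '", regime, "'; see regime_catalog()")
  a <- dataset$alignment
  groups <- regime_layout(row$n_partitions, names(charsets(a)))
  parts <- prepare_partitions(a, groups, indel = dataset$indel)
  if (is.null(dataset$indel)) parts$indel <- NULL
  pm <- regime_model(row, setdiff(names(parts), "indel"))
  if (is.null(dataset$indel)) pm$assignments$indel <- NULL
  run_chain(parts, pm, cfg, init_tree = nj_start_tree(a),
            run_label = run_label)
}

#' Run a multi-regime comparison study
#'
#' Runs each regime (optionally with replicate chains), builds the comparison
#' table and Bayes-factor matrix, and -- for the best regime by lnML -- pools
#' replicate tree samples into a majority-rule consensus, refusing to pool
#' when the split-frequency divergence check fails (unless `force`).
#'
#' @param dataset As in [run_regime()].
#' @param regimes Character vector of regime names.
#' @param cfg Base [mcmc_config()]; replicate r uses `seed + r - 1`.
#' @param replicates Chains per regime.
#' @param asdsf_threshold Convergence threshold for pooling.
#' @param force Pool even when replicates diverge.
#' @return List: `traces` (regime -> list of traces), `comparison`
#'   (`regime_comparison`), `best_regime`, `asdsf`, `consensus` (`phylo` or
#'   `NULL` when refused).
#' @export
run_study <- function(dataset, regimes, cfg = mcmc_config(), replicates = 1L,
                      asdsf_threshold = 0.01, force = FALSE) {
  stopifnot(length(regimes) >= 1L)
  traces <- lapply(regimes, function(rg) {
    lapply(seq_len(replicates), function(r) {
      cfg_r <- cfg
      cfg_r$seed <- cfg$seed + r - 1L
      run_regime(dataset, rg, cfg_r, run_label = sprintf("%s/rep%d", rg, r))
    })
  })
  names(traces) <- regimes
  first <- lapply(traces, `[[`, 1L)
  comparison <- if (length(regimes) >= 2L) comparison_table(first) else NULL
  best <- if (!is.null(comparison))
    comparison$table$regime[which.max(comparison$table$lnml)] else regimes[[1L]]
  asdsf <- NA_real_
  pooled_ok <- TRUE
  if (replicates >= 2L) {
    asdsf <- split_frequency_divergence(traces[[best]],
                                        converged_below = asdsf_threshold)
    pooled_ok <- isTRUE(attr(asdsf, "converged"))
  }
  consensus <- NULL
  if (pooled_ok || force) {
    pooled <- do.call(pool_tree_samples, lapply(traces[[best]],
                                                post_burnin_trees))
    consensus <- majority_rule_consensus(pooled)
  } else {
    warning("replicates diverge (ASDSF = ", signif(as.numeric(asdsf), 3),
            "); consensus refused -- rerun longer or use force = TRUE")
  }
  list(traces = traces, comparison = comparison, best_regime = best,
       asdsf = as.numeric(asdsf), consensus = consensus)
}

#' Mixture-saturation sweep
#'
#' Runs the 6-partition mixture regimes for K in `k_values` and summarises
#' the likelihood saturation.
#'
#' @param dataset As in [run_regime()].
#' @param k_values Mixture component counts, strictly increasing from 1.
#' @param cfg An [mcmc_config()].
#' @param fraction Plateau rule passed to [saturation_analysis()].
#' @return The [saturation_analysis()] tibble, with the traces attached as
#'   attribute `traces`.
#' @export
saturation_sweep <- function(dataset, k_values = 1:3, cfg = mcmc_config(),
                             fraction = 0.1) {
  kregimes <- c("6 partitions C", "6 partitions D", "6 partitions E",
                "6 partitions F", "6 partitions G", "6 partitions H",
                "6 partitions I")
  stopifnot(all(k_values %in% 1:7))
  traces <- lapply(k_values, function(K)
    run_regime(dataset, kregimes[K], cfg, run_label = sprintf("K=%d", K)))
  lnl <- vapply(traces, function(tr) mean(post_burnin(tr)$lnL), 0)
  out <- saturation_analysis(k_values, lnl, fraction)
  attr(out, "traces") <- traces
  out
}

#' Deposit-style alignment statistics
#'
#' Reproduces the statistics reported for a multi-locus ribosomal deposit:
#' per-locus alignment lengths and parsimony-informative counts, the
#' simple-indel-coding character and PI counts of the ITS block, and the
#' concatenated nucleotide length.
#'
#' @param a An `rb_alignment` with charsets (at least an ITS-like block named
#'   `ITS` or `ITS1`/`5.8S`/`ITS2`).
#' @return A tibble with `statistic` and `value`.
#' @export
deposit_statistics <- function(a) {
  cs <- charsets(a)
  if (is.null(cs)) stop("alignment has no charsets")
  its_cols <- if ("ITS" %in% names(cs)) cs$ITS
  else sort(unlist(cs[intersect(c("ITS1", "5.8S", "ITS2"), names(cs))]))
  if (!length(its_cols)) stop("no ITS-like charset found")
  its <- alignment(a$mat[, its_cols, drop = FALSE])
  sic <- sic_encode(its)
  st <- alignment_stats(a)
  dplyr::bind_rows(
    tibble::tibble(statistic = paste0("n_sites_", st$charset),
                   value = as.numeric(st$n_sites)),
    tibble::tibble(statistic = paste0("n_pi_", st$charset),
                   value = as.numeric(st$n_parsimony_informative)),
    tibble::tibble(statistic = c("n_sites_total", "n_indel_characters",
                                 "n_indel_pi"),
                   value = c(n_col(a),
                             indel_matrix_stats(sic)$n_characters,
                             indel_matrix_stats(sic)$n_parsimony_informative)))
}
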