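# broom-style tidiers for traces and comparison objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy parameter summaries of an MCMC trace
#'
#' @param x An `mcmc_trace`.
#' @param mass HPD mass for the interval columns.
#' @param ... Unused.
#' @return A tibble with one row per sampled quantity (`lnL`, `TL` and every
#'   free parameter): posterior `mean`, `sd`, HPD `low`/`high`, `ess`.
#' @export
tidy.mcmc_trace <- function(x, mass = 0.95, ...) {
  pb <- post_burnin(x)
  vars <- setdiff(names(pb), "generation")
  purrr::map_dfr(vars, function(v) {
    vals <- pb[[v]]
    h <- if (length(vals) >= 20L) hpd_interval(vals, mass)
    else c(low = NA_real_, high = NA_real_)
    tibble::tibble(term = v, mean = mean(vals), sd = stats::sd(vals),
                   low = unname(h["low"]), high = unname(h["high"]),
                   ess = if (length(vals) >= 10L)
                     as.numeric(effective_sample_size(vals)) else NA_real_)
  })
}

#' One-row summary of an MCMC trace
#'
#' @param x An `mcmc_trace`.
#' @param ... Unused.
#' @return A tibble: sample counts, acceptance rate, mean lnL and TL, lnL
#'   ESS, and the harmonic-mean log marginal likelihood with its bootstrap
#'   SE.
#' @export
glance.mcmc_trace <- function(x, ...) {
  pb <- post_burnin(x)
  lml <- suppressWarnings(log_marginal_likelihood(x))
  tibble::tibble(
    n_samples = nrow(x$samples),
    n_post_burnin = nrow(pb),
    acceptance_rate = x$acceptance_rate,
    mean_lnl = mean(pb$lnL),
    mean_tl = mean(pb$TL),
    ess_lnl = as.numeric(effective_sample_size(pb$lnL)),
    lnml = as.numeric(lml),
    lnml_se = attr(lml, "se"))
}

#' @rdname tidy.mcmc_trace
#' @export
tidy.regime_comparison <- function(x, ...) x$table

#' @rdname glance.mcmc_trace
#' @export
glance.regime_comparison <- function(x, ...) {
  tibble::tibble(n_regimes = nrow(x$table),
                 best_regime = x$table$regime[which.max(x$table$lnml)],
                 max_logbf = max(x$bf_matrix))
}
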