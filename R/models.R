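# Substitution models: GTR+Gamma for nucleotides, one- and two-parameter
# binary Markov models (optionally with the variable-characters-only
# ascertainment correction) for the indel partition, and K-component GTR+Gamma
# site mixtures.  All rate matrices are reversible and scaled to one expected
# substitution per site per unit branch length, so tree lengths are comparable
# across models.

#' GTR+Gamma model specification
#'
#' @param rates Six exchangeabilities in the order AC, AG, AT, CG, CT, GT
#'   (relative; normalised internally to sum to 1).
#' @param freqs Base frequencies (A, C, G, T); must sum to 1.
#' @param shape Gamma shape alpha > 0 for among-site rate variation.
#' @param n_categories Number of discrete gamma categories (default 4, the
#'   field convention).
#' @return An object of class `gtr_gamma`.
#' @export
gtr_gamma <- function(rates = rep(1, 6), freqs = rep(0.25, 4),
                      shape = 1, n_categories = 4L) {
  stopifnot(length(rates) == 6L, all(rates >= 0), any(rates > 0),
            length(freqs) == 4L, all(freqs > 0),
            abs(sum(freqs) - 1) < 1e-8, shape > 0, n_categories >= 1L)
  structure(list(rates = rates / sum(rates), freqs = freqs, shape = shape,
                 n_categories = as.integer(n_categories)),
            class = c("gtr_gamma", "rb_model"))
}

#' Binary Markov model for indel characters
#'
#' The one-parameter variant is the symmetric two-state model (state
#' frequencies fixed at 1/2); the two-parameter variant frees the stationary
#' frequencies.  With `correction = "variable_only"` the likelihood is
#' conditioned on characters being variable, as required when constant
#' characters are absent by construction (an indel matrix).
#'
#' @param variant `"one_parameter"` or `"two_parameter"`.
#' @param freqs Stationary frequencies (state 0, state 1).
#' @param correction `"variable_only"` or `"none"`.
#' @return An object of class `binary_markov`.
#' @export
binary_markov <- function(variant = c("one_parameter", "two_parameter"),
                          freqs = c(0.5, 0.5),
                          correction = c("variable_only", "none")) {
  variant <- match.arg(variant)
  correction <- match.arg(correction)
  if (variant == "one_parameter") freqs <- c(0.5, 0.5)
  stopifnot(length(freqs) == 2L, all(freqs > 0), abs(sum(freqs) - 1) < 1e-8)
  structure(list(variant = variant, freqs = freqs, correction = correction),
            class = c("binary_markov", "rb_model"))
}

#' K-component GTR+Gamma site-mixture specification
#'
#' All components share the gamma shape, the number of categories and the
#' branch lengths; each has its own exchangeabilities and base frequencies.
#' Per-site likelihoods are the weight-mixture over components.
#'
#' @param components List of [gtr_gamma()] objects (K >= 1).
#' @param weights Mixture weights on the K-simplex.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(components, weights = NULL) {
  stopifnot(is.list(components), length(components) >= 1L,
            all(vapply(components, inherits, TRUE, "gtr_gamma")))
  k <- length(components)
  if (is.null(weights)) weights <- rep(1 / k, k)
  stopifnot(length(weights) == k, all(weights >= 0), sum(weights) > 0)
  shp <- components[[1L]]$shape
  nct <- components[[1L]]$n_categories
  components <- lapply(components, function(cm) {
    cm$shape <- shp; cm$n_categories <- nct; cm
  })
  structure(list(components = components, weights = weights / sum(weights)),
            class = c("mixture_spec", "rb_model"))
}

#' Partitioned model: one model object per partition
#'
#' Topology and branch lengths are shared; substitution parameters are
#' unlinked between partitions.
#'
#' @param assignments Named list mapping partition name to a model object
#'   (`gtr_gamma`, `binary_markov` or `mixture_spec`).
#' @return An object of class `partitioned_model`.
#' @export
partitioned_model <- function(assignments) {
  stopifnot(is.list(assignments), length(assignments) >= 1L,
            !is.null(names(assignments)),
            all(vapply(assignments, inherits, TRUE, "rb_model")))
  structure(list(assignments = assignments), class = "partitioned_model")
}

#' Discrete gamma category rates (mean-of-category discretization)
#'
#' Equiprobable quantile bins of Gamma(shape, rate = shape); each category
#' rate is the conditional mean within its bin, so the rates average to 1.
#'
#' @param shape Gamma shape > 0.
#' @param n_categories Number of categories >= 1.
#' @return Numeric vector of category rates, mean 1.
#' @export
discretize_gamma <- function(shape, n_categories) {
  stopifnot(shape > 0, n_categories >= 1L)
  k <- as.integer(n_categories)
  if (k == 1L) return(1)
  q <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = shape, rate = shape)
  # E[X ; a < X < b] for X ~ Gamma(shape, shape) equals
  # pgamma(b, shape+1, shape) - pgamma(a, shape+1, shape); bins have mass 1/k
  upper <- stats::pgamma(q[-1L], shape = shape + 1, rate = shape)
  lower <- stats::pgamma(q[-(k + 1L)], shape = shape + 1, rate = shape)
  r <- (upper - lower) * k
  r / mean(r)
}

# Reversible rate matrix for a GTR parameterisation, scaled to unit expected
# rate: -sum_i pi_i Q_ii = 1.
gtr_rate_matrix <- function(rates, freqs) {
  Q <- matrix(0, 4, 4, dimnames = list(DNA_STATES, DNA_STATES))
  idx <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  for (m in seq_len(6)) {
    i <- idx[m, 1L]; j <- idx[m, 2L]
    Q[i, j] <- rates[m] * freqs[j]
    Q[j, i] <- rates[m] * freqs[i]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

binary_rate_matrix <- function(freqs) {
  Q <- matrix(c(-freqs[2L], freqs[2L], freqs[1L], -freqs[1L]),
              2, 2, byrow = TRUE, dimnames = list(c("0", "1"), c("0", "1")))
  mu <- -sum(freqs * diag(Q))
  Q / mu
}

# Eigendecomposition of a reversible Q via the symmetrised matrix; returns
# U, lambda, Uinv with Q = U diag(lambda) Uinv.
reversible_eigen <- function(Q, freqs) {
  d <- sqrt(freqs)
  B <- t(t(Q * d) / d)  # B = D^{1/2} Q D^{-1/2}, symmetric for reversible Q
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, lambda = e$values, Uinv = t(e$vectors) * rep(d, each = nrow(Q)))
}

#' Transition probability matrix P(t)
#'
#' @param model A `gtr_gamma` or `binary_markov` object.
#' @param branch_length Branch length t >= 0 (expected substitutions/site).
#' @param rate_multiplier Site-rate multiplier (e.g. a gamma category rate).
#' @return Row-stochastic matrix `P` with `P[i, j] = P(j at the child | i at
#'   the parent)`.
#' @export
transition_matrix <- function(model, branch_length, rate_multiplier = 1) {
  stopifnot(is.finite(branch_length), branch_length >= 0,
            is.finite(rate_multiplier), rate_multiplier >= 0)
  if (inherits(model, "gtr_gamma")) {
    if (!all(is.finite(model$rates)) || !all(is.finite(model$freqs)))
      stop("non-finite model parameters")
    Q <- gtr_rate_matrix(model$rates, model$freqs)
    fr <- model$freqs
  } else if (inherits(model, "binary_markov")) {
    Q <- binary_rate_matrix(model$freqs)
    fr <- model$freqs
  } else stop("unsupported model class")
  ed <- reversible_eigen(Q, fr)
  P <- ed$U %*% (exp(ed$lambda * branch_length * rate_multiplier) * ed$Uinv)
  P[P < 0] <- 0
  P / rowSums(P)
}

# Expand a model into per-"mixture class" pieces for the pruning engine: one
# class per (component x gamma category) with its eigendecomposition, root
# frequencies, rate multiplier and log weight.
model_classes <- function(model) {
  if (inherits(model, "gtr_gamma")) {
    Q <- gtr_rate_matrix(model$rates, model$freqs)
    ed <- reversible_eigen(Q, model$freqs)
    r <- discretize_gamma(model$shape, model$n_categories)
    lapply(seq_along(r), function(c_) {
      list(U = ed$U, lambda = ed$lambda, Uinv = ed$Uinv, pi = model$freqs,
           rate = r[c_], logw = -log(length(r)))
    })
  } else if (inherits(model, "binary_markov")) {
    Q <- binary_rate_matrix(model$freqs)
    ed <- reversible_eigen(Q, model$freqs)
    list(list(U = ed$U, lambda = ed$lambda, Uinv = ed$Uinv, pi = model$freqs,
              rate = 1, logw = 0))
  } else if (inherits(model, "mixture_spec")) {
    w <- model$weights
    if (all(w == 0)) stop("mixture weights are all zero")
    out <- list()
    for (k in seq_along(model$components)) {
      cls <- model_classes(model$components[[k]])
      for (cl in cls) {
        cl$logw <- cl$logw + log(w[k])
        out[[length(out) + 1L]] <- cl
      }
    }
    out
  } else stop("unsupported model class")
}
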