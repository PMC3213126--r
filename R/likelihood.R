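# Likelihood layer: site-pattern compression, tip partials from IUPAC codes,
# pruning log-likelihoods (single model, mixtures), the variable-only
# ascertainment correction for binary matrices, and partitioned totals.

# Compress columns of a character matrix into unique patterns.
# Returns list(pat = S x npat x ntip array of tip partials, weights,
#              site_of_pattern mapping, taxa order).
compress_patterns <- function(mat, states) {
  S <- length(states)
  key <- apply(mat, 2L, paste0, collapse = "\r")
  upat <- match(key, unique(key))
  keep <- !duplicated(key)
  sub <- mat[, keep, drop = FALSE]
  npat <- ncol(sub)
  tipp <- array(0, dim = c(S, npat, nrow(mat)))
  for (tx in seq_len(nrow(mat))) {
    for (p in seq_len(npat)) {
      tipp[, p, tx] <- symbol_partial(sub[tx, p], states)
    }
  }
  list(tipp = tipp, weights = tabulate(upat, nbins = npat),
       pattern_of_site = upat, taxa = rownames(mat))
}

symbol_partial <- function(sym, states) {
  if (length(states) == 4L) {
    comp <- IUPAC_SETS[[sym]]
    if (is.null(comp)) stop("unknown symbol '", sym, "'")
    as.numeric(states %in% comp)
  } else {
    switch(sym,
           "0" = c(1, 0), "1" = c(0, 1), "?" = c(1, 1),
           "-" = c(1, 1),
           stop("unknown binary symbol '", sym, "'"))
  }
}

# Align a phylo's tips with the data rows; returns postorder pieces.
tree_pieces <- function(tree, data_taxa) {
  if (!inherits(tree, "phylo")) stop("tree must be a 'phylo'")
  if (!setequal(tree$tip.label, data_taxa))
    stop("tree tip labels do not match alignment taxa")
  tr <- ape::reorder.phylo(tree, "postorder")
  list(edge = tr$edge, el = tr$edge.length,
       tip_index = match(tr$tip.label, data_taxa), ntip = length(tr$tip.label))
}

# Weighted mixture over classes, computed in one compiled pass
pattern_loglik_mixed <- function(tp, cp, classes, logw) {
  pruning_mixture_loglik_cpp(tp$edge, tp$el, tp$ntip, tp$tip_index, cp$tipp,
                             classes, logw)
}

#' Per-site log-likelihoods by Felsenstein pruning
#'
#' Ambiguity and missing states contribute partial likelihood 1 over their
#' compatible states; gaps in nucleotide data are treated as missing.
#'
#' @param tree An `ape::phylo` with branch lengths; tips must match the rows
#'   of `mat`.
#' @param mat Character matrix (taxa x sites): an alignment's columns or a
#'   binary indel matrix's columns.
#' @param model A `gtr_gamma`, `binary_markov` or `mixture_spec`.
#' @return Numeric vector of per-site log-likelihoods.
#' @export
pruning_loglik <- function(tree, mat, model) {
  if (inherits(mat, "rb_alignment") || inherits(mat, "rb_indel_matrix"))
    mat <- mat$mat
  if (ncol(mat) == 0L) return(numeric(0))
  states <- model_states(model)
  cp <- compress_patterns(mat, states)
  tp <- tree_pieces(tree, rownames(mat))
  classes <- model_classes(model)
  logw <- vapply(classes, `[[`, 0, "logw")
  perpat <- pattern_loglik_mixed(tp, cp, classes, logw)
  perpat[cp$pattern_of_site]
}

model_states <- function(model) {
  if (inherits(model, "binary_markov")) c("0", "1") else DNA_STATES
}

#' Per-site log-likelihoods under a site mixture
#'
#' Convenience wrapper: with K = 1 this is identical to [pruning_loglik()]
#' with the single component.
#'
#' @inheritParams pruning_loglik
#' @param mix A [mixture_spec()].
#' @export
mixture_loglik <- function(tree, mat, mix) {
  stopifnot(inherits(mix, "mixture_spec"))
  pruning_loglik(tree, mat, mix)
}

#' Ascertainment-corrected log-likelihood of a binary matrix
#'
#' Conditions each character's likelihood on being variable: subtracts
#' `log(1 - P(constant))`, where `P(constant)` is the model probability of the
#' all-0 and all-1 patterns on the tree.  Required when constant characters
#' are absent by construction, as in a simple-indel-coding matrix.
#'
#' @param tree `ape::phylo`.
#' @param m An `rb_indel_matrix` or binary character matrix.
#' @param model A [binary_markov()] with `correction = "variable_only"`.
#' @return Total log-likelihood (scalar).
#' @export
ascertainment_corrected_loglik <- function(tree, m, model) {
  stopifnot(inherits(model, "binary_markov"))
  if (model$correction != "variable_only")
    stop("model correction must be 'variable_only'")
  mat <- if (inherits(m, "rb_indel_matrix")) m$mat else m
  per_site <- pruning_loglik(tree, mat, model)
  log_p_const <- constant_pattern_logprob(tree, rownames(mat), model)
  if (log_p_const >= 0)
    stop("numerical failure: P(constant) >= 1")
  log1m <- log1p(-exp(log_p_const))
  sum(per_site) - ncol(mat) * log1m
}

# log P(all-0 pattern) + P(all-1 pattern) under a binary model on the tree
constant_pattern_logprob <- function(tree, taxa_labels, model) {
  const_mat <- cbind(rep("0", length(taxa_labels)), rep("1", length(taxa_labels)))
  rownames(const_mat) <- taxa_labels
  ll <- pruning_loglik(tree, const_mat, model)
  m <- max(ll)
  m + log(sum(exp(ll - m)))
}

#' Total log-likelihood of a partitioned dataset
#'
#' Sums each partition's log-likelihood under its assigned model.  Nucleotide
#' partitions use plain pruning (or mixture) likelihoods; binary partitions
#' with `correction = "variable_only"` get the ascertainment correction.
#'
#' @param tree `ape::phylo`.
#' @param parts Named list of character matrices (one per partition); a
#'   partitioned dataset from [prepare_partitions()] also works.
#' @param pm A [partitioned_model()] whose assignment names match `parts`.
#' @return Total log-likelihood (scalar).
#' @export
total_loglik <- function(tree, parts, pm) {
  stopifnot(inherits(pm, "partitioned_model"))
  nms <- names(pm$assignments)
  if (!setequal(nms, names(parts)))
    stop("partition names of data and model differ: data has {",
         paste(names(parts), collapse = ","), "}, model has {",
         paste(nms, collapse = ","), "}")
  tot <- 0
  for (nm in nms) {
    mod <- pm$assignments[[nm]]
    dat <- parts[[nm]]
    mat <- if (inherits(dat, "rb_alignment") || inherits(dat, "rb_indel_matrix"))
      dat$mat else dat
    tot <- tot + if (inherits(mod, "binary_markov") &&
                     mod$correction == "variable_only")
      ascertainment_corrected_loglik(tree, mat, mod)
    else sum(pruning_loglik(tree, mat, mod))
  }
  tot
}

#' Split a dataset into per-partition matrices
#'
#' @param a An `rb_alignment` with charsets.
#' @param scheme Named list mapping partition name to charset name(s) to pool,
#'   or `NULL` to use each charset as one partition.
#' @param indel Optional `rb_indel_matrix` appended as partition `"indel"`.
#' @return Named list of character matrices.
#' @export
prepare_partitions <- function(a, scheme = NULL, indel = NULL) {
  cs <- charsets(a)
  if (is.null(cs)) stop("alignment has no charsets")
  if (is.null(scheme)) scheme <- stats::setNames(as.list(names(cs)), names(cs))
  parts <- lapply(scheme, function(nms) {
    missing <- setdiff(nms, names(cs))
    if (length(missing))
      stop("missing charset(s): ", paste(missing, collapse = ", "))
    a$mat[, sort(unlist(cs[nms])), drop = FALSE]
  })
  if (!is.null(indel)) parts$indel <- indel$mat
  parts
}
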