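# Tree I/O and summaries: Newick round-trips (via ape), split tabulation over
# tree samples, majority-rule consensus phylograms with posterior supports,
# clade posterior probabilities and tree length.

#' Read / write Newick trees
#'
#' Thin wrappers over `ape::read.tree` / `ape::write.tree` that validate leaf
#' uniqueness and preserve internal-node support labels.
#'
#' @param path File path (or for `read_newick`, alternatively `text`).
#' @param text Newick string.
#' @return `phylo` or `multiPhylo`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick input")
  chk <- function(t) {
    if (anyDuplicated(t$tip.label))
      stop("duplicate leaf label: ",
           t$tip.label[duplicated(t$tip.label)][1L])
    t
  }
  if (inherits(tr, "multiPhylo")) {
    for (t in tr) chk(t)
  } else chk(tr)
  tr
}

#' @rdname read_newick
#' @param tree `phylo` or `multiPhylo`.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Tree length (sum of branch lengths)
#' @param tree `phylo`.
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  sum(tree$edge.length)
}

# --- split machinery ---------------------------------------------------------
# A split is a bipartition of the taxon set, encoded as a 0/1 string over the
# reference taxon order, normalised so the side containing the first taxon is
# '0'.  Ties in tabulation break lexicographically on this bitmask.

# For one tree: tibble(split, size, length) for each internal edge; also
# terminal edge lengths (named).
tree_splits <- function(tree, ref_taxa) {
  tr <- ape::reorder.phylo(ape::unroot(tree), "postorder")
  ntip <- length(tr$tip.label)
  tipidx <- match(tr$tip.label, ref_taxa)
  maxnode <- max(tr$edge)
  below <- matrix(FALSE, maxnode, length(ref_taxa))
  below[cbind(seq_len(ntip), tipidx)] <- TRUE
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    below[par, ] <- below[par, ] | below[ch, ]
  }
  internal <- tr$edge[, 2L] > ntip
  masks <- below[tr$edge[internal, 2L], , drop = FALSE]
  flip <- masks[, 1L]
  masks[flip, ] <- !masks[flip, , drop = FALSE]
  key <- apply(masks, 1L, function(m) paste0(as.integer(m), collapse = ""))
  sz <- pmin(rowSums(masks), length(ref_taxa) - rowSums(masks))
  keep <- sz >= 2L  # non-trivial splits only
  term_len <- stats::setNames(rep(NA_real_, length(ref_taxa)), ref_taxa)
  tl <- tr$edge.length[tr$edge[, 2L] <= ntip]
  term_len[tr$tip.label[tr$edge[tr$edge[, 2L] <= ntip, 2L]]] <- tl
  list(splits = tibble::tibble(split = key[keep],
                               length = tr$edge.length[internal][keep]),
       terminal_lengths = term_len)
}

#' Tabulate split frequencies over a tree sample
#'
#' @param trees `multiPhylo` (or list of `phylo`) over identical leaf sets.
#' @return A tibble with columns `split` (normalised bitmask over the sorted
#'   taxon order), `freq` (fraction of trees containing the split),
#'   `mean_length` (mean branch length over trees containing it).  The taxon
#'   order is attached as attribute `taxa`.
#' @export
split_frequencies <- function(trees) {
  trees <- as_tree_list(trees)
  ref <- sort(trees[[1L]]$tip.label)
  for (t in trees)
    if (!setequal(t$tip.label, ref)) stop("trees have differing leaf sets")
  per <- lapply(trees, tree_splits, ref_taxa = ref)
  all_splits <- dplyr::bind_rows(lapply(per, `[[`, "splits"))
  out <- all_splits |>
    dplyr::group_by(.data$split) |>
    dplyr::summarise(n = dplyr::n(), mean_length = mean(.data$length),
                     .groups = "drop") |>
    dplyr::mutate(freq = .data$n / length(trees)) |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$split) |>
    dplyr::select("split", "freq", "mean_length")
  attr(out, "taxa") <- ref
  attr(out, "terminal_lengths") <-
    rowMeans(do.call(cbind, lapply(per, `[[`, "terminal_lengths")), na.rm = TRUE)
  out
}

as_tree_list <- function(trees) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  stopifnot(length(trees) >= 1L)
  trees
}

#' Majority-rule consensus tree with posterior supports
#'
#' Splits occurring in strictly more than `threshold` of the trees are
#' retained (ties at the threshold are excluded, which guarantees pairwise
#' compatibility for `threshold >= 0.5`); support values are the split
#' frequencies (the Bayesian posterior probabilities), branch lengths are
#' means over the trees containing each split, and unresolved regions are
#' left as polytomies.
#'
#' @param trees `multiPhylo` or list of `phylo` over one leaf set.
#' @param threshold Minimum (exclusive) split frequency; must be >= 0.5.
#' @return `phylo` with node labels giving supports.
#' @export
majority_rule_consensus <- function(trees, threshold = 0.5) {
  if (threshold < 0.5)
    stop("threshold below 0.5 can select incompatible splits; use >= 0.5")
  sf <- split_frequencies(trees)
  ref <- attr(sf, "taxa")
  term <- attr(sf, "terminal_lengths")
  keep <- sf[sf$freq > threshold, , drop = FALSE]
  clades <- lapply(keep$split,
                   function(s) which(strsplit(s, "")[[1L]] == "1"))
  info <- data.frame(i = seq_along(clades), size = lengths(clades),
                     freq = keep$freq, len = keep$mean_length)
  # clades exclude taxon 1 by normalisation; build the rooted-at-taxon-1 tree
  build <- function(tipset, cl_idx) {
    # maximal clades among cl_idx strictly inside tipset
    inside <- cl_idx[vapply(cl_idx, function(i)
      all(clades[[i]] %in% tipset) && length(clades[[i]]) < length(tipset),
      TRUE)]
    maximal <- inside[vapply(inside, function(i)
      !any(vapply(inside, function(j)
        j != i && length(clades[[j]]) > length(clades[[i]]) &&
          all(clades[[i]] %in% clades[[j]]), TRUE)), TRUE)]
    used <- unique(unlist(clades[maximal]))
    solo <- setdiff(tipset, used)
    parts <- c(
      lapply(maximal, function(i) {
        sub <- build(clades[[i]], setdiff(inside, i))
        sprintf("%s%s:%.10g", sub, format_support(info$freq[info$i == i]),
                info$len[info$i == i])
      }),
      lapply(solo, function(tp)
        sprintf("%s:%.10g", escape_label(ref[tp]), term[ref[tp]])))
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  all_but_1 <- seq_along(ref)[-1L]
  inner <- build(all_but_1, seq_along(clades))
  nwk <- sprintf("(%s:%.10g,%s);", escape_label(ref[1L]), term[ref[1L]],
                 substr(inner, 2L, nchar(inner) - 1L))
  out <- ape::read.tree(text = nwk)
  out
}

format_support <- function(f) sprintf("%.4g", f)

escape_label <- function(x) {
  if (grepl("[ ()\\[\\]:;,']", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Posterior probability of a clade
#'
#' Fraction of sampled trees in which `taxon_subset` forms one side of a
#' split.
#'
#' @param trees `multiPhylo` or list of `phylo`.
#' @param taxon_subset Character vector of leaf labels; must be non-trivial
#'   (size between 2 and n - 2).
#' @return Numeric probability in `[0, 1]`.
#' @export
clade_posterior <- function(trees, taxon_subset) {
  trees <- as_tree_list(trees)
  ref <- sort(trees[[1L]]$tip.label)
  if (!all(taxon_subset %in% ref)) stop("subset contains unknown taxa")
  k <- length(unique(taxon_subset))
  if (k < 2L || k > length(ref) - 2L)
    stop("subset is trivial (size must be in [2, n-2])")
  mask <- ref %in% taxon_subset
  if (mask[1L]) mask <- !mask
  key <- paste0(as.integer(mask), collapse = "")
  sf <- split_frequencies(trees)
  hit <- sf$freq[sf$split == key]
  if (length(hit)) hit else 0
}

#' Pool tree samples from several runs
#'
#' @param ... `multiPhylo` objects or lists of `phylo` over one leaf set.
#' @return A single `multiPhylo`.  Pooling is order-invariant for all
#'   downstream split summaries.
#' @export
pool_tree_samples <- function(...) {
  lst <- unlist(lapply(list(...), as_tree_list), recursive = FALSE)
  class(lst) <- "multiPhylo"
  lst
}
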