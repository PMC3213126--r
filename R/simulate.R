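# Synthetic data with known truth: Yule trees, sequence evolution under
# partitioned GTR+Gamma (optionally K-component mixtures) along the tree, and
# a superimposed indel process producing codable gap extents -- emulating a
# multi-locus ribosomal dataset with a gap-rich ITS-like block.  Every stage
# is seed-deterministic and the emitted truth fully determines the dataset.

#' Sample a Yule tree with exponential branch lengths
#'
#' Topology is a pure-birth (Yule) tree; branch lengths are redrawn i.i.d.
#' exponential with mean `target_tl / n_edges`, so tree length averages
#' `target_tl` over draws.
#'
#' @param n_taxa Number of tips (>= 3).
#' @param birth_rate Birth rate of the Yule process (topology only).
#' @param seed Integer seed.
#' @param target_tl Target expected tree length; default 0.1 per edge.
#' @return Unrooted `phylo` with tip labels `t1..tn`.
#' @export
sample_tree <- function(n_taxa, birth_rate = 1, seed = 1L, target_tl = NULL) {
  if (n_taxa < 3L) stop("need at least 3 taxa")
  set.seed(seed)
  tr <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  tr <- ape::unroot(tr)
  nedge <- nrow(tr$edge)
  target_tl <- target_tl %||% (0.1 * nedge)
  tr$edge.length <- stats::rexp(nedge, rate = nedge / target_tl)
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  tr
}

#' Evolve an alignment down a tree under a partitioned model
#'
#' Site-wise CTMC simulation: each partition evolves under its own model;
#' mixture partitions draw a component per site (recorded in the truth).
#'
#' @param tree `phylo` with branch lengths.
#' @param pm A [partitioned_model()].
#' @param lengths Named integer vector of partition lengths (sites), names
#'   matching `pm`'s assignments.
#' @param seed Integer seed.
#' @return List with `alignment` (an `rb_alignment` with one charset per
#'   partition) and `truth` (list: `tree`, `models`, `site_component`
#'   per-partition component assignments, `seed`).
#' @export
evolve_alignment <- function(tree, pm, lengths, seed = 1L) {
  stopifnot(inherits(pm, "partitioned_model"))
  if (is.null(names(lengths)) || !setequal(names(lengths), names(pm$assignments)))
    stop("lengths must be named to match the partitioned model")
  if (any(lengths < 1L)) stop("zero-length partition")
  set.seed(seed)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  blocks <- list()
  site_component <- list()
  for (nm in names(pm$assignments)) {
    model <- pm$assignments[[nm]]
    L <- as.integer(lengths[[nm]])
    sim <- simulate_partition(tr, model, L)
    blocks[[nm]] <- sim$mat
    site_component[[nm]] <- sim$component
  }
  mat <- do.call(cbind, blocks)
  rownames(mat) <- tr$tip.label
  offs <- cumsum(c(0L, vapply(blocks, ncol, 0L)))
  cs <- stats::setNames(lapply(seq_along(blocks), function(k)
    offs[k] + seq_len(ncol(blocks[[k]]))), names(blocks))
  list(alignment = alignment(mat, charsets = cs),
       truth = list(tree = tree, models = pm$assignments,
                    site_component = site_component, seed = seed))
}

# simulate one partition; returns taxa x L character matrix + per-site
# component index (1 for non-mixtures)
simulate_partition <- function(tr, model, L) {
  ntip <- length(tr$tip.label)
  if (inherits(model, "mixture_spec")) {
    comp <- sample.int(length(model$components), L, replace = TRUE,
                       prob = model$weights)
    comps <- model$components
  } else if (inherits(model, "gtr_gamma")) {
    comp <- rep(1L, L)
    comps <- list(model)
  } else stop("can only simulate nucleotide partitions")
  states <- DNA_STATES
  ncat <- comps[[1L]]$n_categories
  cat_of_site <- sample.int(ncat, L, replace = TRUE)
  crates <- lapply(comps, function(cm)
    discretize_gamma(cm$shape, cm$n_categories))
  eds <- lapply(comps, function(cm) {
    Q <- gtr_rate_matrix(cm$rates, cm$freqs)
    reversible_eigen(Q, cm$freqs)
  })
  # preorder traversal: root state then children
  maxnode <- max(tr$edge)
  root <- tr$edge[nrow(tr$edge), 1L]
  node_state <- matrix(0L, maxnode, L)
  for (k in seq_along(comps)) {
    idx <- which(comp == k)
    if (length(idx))
      node_state[root, idx] <- sample.int(4L, length(idx), replace = TRUE,
                                          prob = comps[[k]]$freqs)
  }
  for (e in rev(seq_len(nrow(tr$edge)))) {  # reverse postorder = preorder
    par <- tr$edge[e, 1L]; ch <- tr$edge[e, 2L]
    t <- tr$edge.length[e]
    for (k in seq_along(comps)) {
      for (c_ in seq_len(ncat)) {
        idx <- which(comp == k & cat_of_site == c_)
        if (!length(idx)) next
        ed <- eds[[k]]
        P <- ed$U %*% (exp(ed$lambda * t * crates[[k]][c_]) * ed$Uinv)
        P[P < 0] <- 0
        P <- P / rowSums(P)
        ps <- node_state[par, idx]
        for (s in 1:4) {
          sel <- idx[ps == s]
          if (length(sel))
            node_state[ch, sel] <- sample.int(4L, length(sel), replace = TRUE,
                                              prob = P[s, ])
        }
      }
    }
  }
  mat <- matrix(states[node_state[seq_len(ntip), , drop = FALSE]], ntip, L)
  rownames(mat) <- tr$tip.label
  list(mat = mat, component = comp)
}

#' Superimpose an indel (deletion) process on an alignment
#'
#' Deletion events are placed on branches with Poisson counts proportional to
#' branch length, have geometric lengths with the given mean, and are
#' inherited by all descendant taxa.  The emitted gap extents are recorded as
#' truth, so simple-indel-coding recovery can be scored exactly.
#'
#' @param a An `rb_alignment` (taxa must match the tree tips).
#' @param tree `phylo` used to place events.
#' @param indel_rate Events per site per unit branch length.
#' @param mean_length Mean event length in columns.
#' @param seed Integer seed.
#' @param cols Optional column range (integer vector) in which to place
#'   events, e.g. the ITS-like block; default all columns.
#' @return List with `alignment` (gapped) and `events` (tibble: `start`,
#'   `end`, `taxa` list-column).
#' @export
superimpose_indels <- function(a, tree, indel_rate, mean_length = 4,
                               seed = 1L, cols = NULL) {
  stopifnot(indel_rate >= 0, mean_length >= 1)
  set.seed(seed)
  cols <- cols %||% seq_len(n_col(a))
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  if (!setequal(tr$tip.label, taxa(a)))
    stop("tree tips do not match alignment taxa")
  maxnode <- max(tr$edge)
  below <- matrix(FALSE, maxnode, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tr$edge)))
    below[tr$edge[e, 1L], ] <- below[tr$edge[e, 1L], ] | below[tr$edge[e, 2L], ]
  mat <- a$mat
  events <- list()
  for (e in seq_len(nrow(tr$edge))) {
    n_ev <- stats::rpois(1L, indel_rate * tr$edge.length[e] * length(cols))
    if (!n_ev) next
    desc <- tr$tip.label[below[tr$edge[e, 2L], ]]
    for (i in seq_len(n_ev)) {
      len <- stats::rgeom(1L, prob = 1 / mean_length) + 1L
      s_rel <- sample.int(length(cols), 1L)
      s <- cols[s_rel]
      ee <- min(cols[length(cols)], s + len - 1L)
      mat[desc, s:ee] <- "-"
      events[[length(events) + 1L]] <-
        tibble::tibble(start = s, end = ee, taxa = list(desc))
    }
  }
  ev <- if (length(events)) dplyr::bind_rows(events) |>
    dplyr::arrange(.data$start, .data$end)
  else tibble::tibble(start = integer(), end = integer(), taxa = list())
  out <- a
  out$mat <- mat
  list(alignment = out, events = ev)
}

#' Simulate a full ribosomal-style study dataset
#'
#' Convenience generator: a Yule tree, heterogeneous nucleotide partitions
#' (distinct exchangeabilities and base frequencies), an ITS-like gap-rich
#' block, and its simple-indel-coding binary partition.
#'
#' @param n_taxa Number of taxa.
#' @param part_lengths Named lengths of the nucleotide partitions.
#' @param models Optional named list of models (defaults to heterogeneous
#'   GTR+Gamma set generated from the seed).
#' @param indel_rate,mean_indel_length Indel process intensity on the first
#'   partition (the ITS-like block); 0 disables.
#' @param seed Integer seed.
#' @param target_tl Target tree length.
#' @return List: `alignment`, `indel` (`rb_indel_matrix` or NULL), `tree`,
#'   `truth`.
#' @export
simulate_study <- function(n_taxa = 30L,
                           part_lengths = c(ITS = 600L, LSU = 700L, SSU = 500L),
                           models = NULL,
                           indel_rate = 0.03, mean_indel_length = 4,
                           seed = 1L, target_tl = NULL) {
  tree <- sample_tree(n_taxa, seed = seed, target_tl = target_tl)
  if (is.null(models)) models <- heterogeneous_models(names(part_lengths), seed)
  pm <- partitioned_model(models)
  sim <- evolve_alignment(tree, pm, part_lengths, seed = seed + 1L)
  a <- sim$alignment
  ev <- NULL
  indel <- NULL
  if (indel_rate > 0) {
    its_cols <- charsets(a)[[1L]]
    g <- superimpose_indels(a, tree, indel_rate, mean_indel_length,
                            seed = seed + 2L, cols = its_cols)
    a <- g$alignment
    ev <- g$events
    its <- alignment(a$mat[, its_cols, drop = FALSE])
    indel <- sic_encode(its)
  }
  list(alignment = a, indel = indel, tree = tree,
       truth = c(sim$truth, list(indel_events = ev)))
}

# distinctly parameterised GTR+Gamma models, one per partition name
heterogeneous_models <- function(part_names, seed = 1L) {
  set.seed(seed + 1000L)
  base <- list(
    list(rates = c(1, 4, 1, 1, 8, 1), freqs = c(0.35, 0.15, 0.15, 0.35),
         shape = 0.4),
    list(rates = c(2, 1, 2, 2, 1, 2), freqs = c(0.15, 0.35, 0.35, 0.15),
         shape = 2),
    list(rates = c(1, 1, 6, 6, 1, 1), freqs = c(0.4, 0.3, 0.2, 0.1),
         shape = 0.8),
    list(rates = c(6, 1, 1, 1, 1, 6), freqs = c(0.1, 0.2, 0.3, 0.4),
         shape = 1.2),
    list(rates = c(1, 2, 3, 3, 2, 1), freqs = c(0.25, 0.25, 0.25, 0.25),
         shape = 0.6))
  stats::setNames(lapply(seq_along(part_names), function(i) {
    b <- base[[(i - 1L) %% length(base) + 1L]]
    gtr_gamma(rates = b$rates, freqs = b$freqs, shape = b$shape)
  }), part_names)
}

#' Write a simulation truth file (plain-text key-value format)
#'
#' @param truth Truth list from [evolve_alignment()] / [simulate_study()].
#' @param path Output path.
#' @export
write_truth <- function(truth, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("seed\t", truth$seed), con)
  writeLines(paste0("tree\t", ape::write.tree(truth$tree)), con)
  for (nm in names(truth$site_component))
    writeLines(paste0("site_component\t", nm, "\t",
                      paste(truth$site_component[[nm]], collapse = ",")), con)
  if (!is.null(truth$indel_events) && nrow(truth$indel_events))
    for (i in seq_len(nrow(truth$indel_events)))
      writeLines(paste0("indel\t", truth$indel_events$start[i], "\t",
                        truth$indel_events$end[i], "\t",
                        paste(truth$indel_events$taxa[[i]], collapse = ",")),
                 con)
  invisible(path)
}
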