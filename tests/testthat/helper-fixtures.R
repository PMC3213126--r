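# Shared fixtures and independent oracles, built in code at test time.

aln_from_strings <- function(seqs) {
  mat <- do.call(rbind, strsplit(unname(unlist(seqs)), ""))
  rownames(mat) <- names(seqs)
  alignment(mat)
}

# Brute-force likelihood oracle: sums over all internal-node state
# assignments; independent of the pruning code path.
brute_force_loglik <- function(tree, mat, model) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  root <- tree$edge[nrow(tree$edge), 1L]
  internals <- sort(unique(tree$edge[, 1L]))
  states <- if (inherits(model, "binary_markov")) c("0", "1")
  else c("A", "C", "G", "T")
  S <- length(states)
  comps <- if (inherits(model, "mixture_spec"))
    Map(list, model$components, w = model$weights)
  else list(list(model, w = 1))
  tip_compat <- function(sym) {
    if (S == 2L) switch(sym, "0" = 1L, "1" = 2L, "?" = 1:2, "-" = 1:2)
    else which(states %in% ribopart:::IUPAC_SETS[[sym]])
  }
  vapply(seq_len(ncol(mat)), function(s) {
    tot <- 0
    for (cw in comps) {
      m <- cw[[1L]]
      rates <- if (inherits(m, "gtr_gamma"))
        discretize_gamma(m$shape, m$n_categories) else 1
      for (r in rates) {
        Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
          transition_matrix(m, tree$edge.length[e], r))
        grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internals))))
        lik <- 0
        for (g in seq_len(nrow(grid))) {
          asgn <- grid[g, ]
          p <- m$freqs[asgn[match(root, internals)]]
          for (e in seq_len(nrow(tree$edge))) {
            par <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
            ps <- asgn[match(par, internals)]
            p <- p * if (ch <= ntip)
              sum(Ps[[e]][ps, tip_compat(mat[tree$tip.label[ch], s])])
            else Ps[[e]][ps, asgn[match(ch, internals)]]
          }
          lik <- lik + p
        }
        tot <- tot + cw$w * lik / length(rates)
      }
    }
    log(tot)
  }, 0)
}

random_test_alignment <- function(n_taxa, n_col, seed, gap_prob = 0) {
  set.seed(seed)
  pool <- c("A", "C", "G", "T")
  mat <- matrix(sample(pool, n_taxa * n_col, TRUE), n_taxa, n_col,
                dimnames = list(paste0("t", seq_len(n_taxa)), NULL))
  if (gap_prob > 0)
    mat[stats::runif(length(mat)) < gap_prob] <- "-"
  alignment(mat)
}

random_test_tree <- function(n_taxa, seed, min_bl = 0.02, max_bl = 0.5) {
  set.seed(seed)
  tr <- ape::unroot(ape::rtree(n_taxa, tip.label = paste0("t", seq_len(n_taxa))))
  tr$edge.length <- stats::runif(nrow(tr$edge), min_bl, max_bl)
  tr
}
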