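# Preprocessing used before indel coding and model fitting: terminal-gap
# trimming, concatenation of loci into a supermatrix, column exclusion
# experiments, and alignment statistics.

#' Convert terminal gap runs to missing data
#'
#' Leading and trailing gap runs in each row are unsequenced flanks, not
#' indels: they are rewritten to `?`.  Columns that end up missing in every
#' taxon are deleted (with charsets re-indexed).  Interior gaps are untouched.
#' The operation is idempotent.
#'
#' @param a An `rb_alignment`.
#' @return The trimmed `rb_alignment`.
#' @export
strip_flanking_gaps <- function(a) {
  mat <- a$mat
  nc <- ncol(mat)
  for (i in seq_len(nrow(mat))) {
    row <- mat[i, ]
    j <- 1L
    while (j <= nc && row[j] %in% c("-", "?")) { row[j] <- "?"; j <- j + 1L }
    j <- nc
    while (j >= 1L && row[j] %in% c("-", "?")) { row[j] <- "?"; j <- j - 1L }
    mat[i, ] <- row
  }
  keep <- which(colSums(mat == "?") < nrow(mat))
  if (!length(keep)) stop("alignment reduced to zero columns")
  subset_columns(alignment_like(a, mat), keep)
}

# rebuild an alignment keeping attrs except charsets handled separately
alignment_like <- function(a, mat) {
  out <- a
  out$mat <- mat
  out
}

# keep the given (sorted) columns, re-indexing charsets onto the new coords
subset_columns <- function(a, keep) {
  keep <- sort(unique(as.integer(keep)))
  mat <- a$mat[, keep, drop = FALSE]
  newpos <- integer(n_col(a))
  newpos[keep] <- seq_along(keep)
  cs <- charsets(a)
  out <- alignment_like(a, mat)
  if (!is.null(cs)) {
    cs <- lapply(cs, function(v) newpos[intersect(v, keep)])
    attr(out, "charsets") <- cs
  }
  out
}

#' Concatenate alignments into a supermatrix
#'
#' Taxon sets may differ; blocks absent for a taxon are filled with `?`.
#' The returned alignment carries one charset per input block, in input order.
#'
#' @param alignments List of `rb_alignment` objects.
#' @param charset_names Character vector of block names (default names of the
#'   list, or `block1`, `block2`, ...).
#' @return An `rb_alignment` with charsets delimiting the input blocks.
#' @export
concatenate <- function(alignments, charset_names = NULL) {
  stopifnot(length(alignments) >= 1L)
  if (is.null(charset_names))
    charset_names <- names(alignments) %||% paste0("block", seq_along(alignments))
  if (anyDuplicated(charset_names)) stop("duplicate charset names")
  all_taxa <- unique(unlist(lapply(alignments, taxa)))
  widths <- vapply(alignments, n_col, 0L)
  offs <- cumsum(c(0L, widths[-length(widths)]))
  mat <- matrix("?", length(all_taxa), sum(widths),
                dimnames = list(all_taxa, NULL))
  for (k in seq_along(alignments)) {
    blk <- alignments[[k]]
    mat[taxa(blk), offs[k] + seq_len(widths[k])] <- blk$mat
  }
  cs <- stats::setNames(
    lapply(seq_along(alignments), function(k) offs[k] + seq_len(widths[k])),
    charset_names)
  alignment(mat, charsets = cs)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Exclude a set of columns from an alignment
#'
#' Remaining columns preserve order; attached charsets are re-indexed.  Used
#' for the charset-exclusion dataset designs (e.g. dropping the ITS block or
#' the gap-rich regions).
#'
#' @param a An `rb_alignment`.
#' @param cols Integer vector of columns to drop, or a charset name.
#' @return The reduced `rb_alignment`.
#' @export
exclude_columns <- function(a, cols) {
  if (is.character(cols)) {
    cs <- charsets(a)
    if (is.null(cs) || !cols %in% names(cs))
      stop("no charset named '", cols, "'")
    cols <- cs[[cols]]
  }
  cols <- as.integer(cols)
  if (!length(cols)) return(a)
  if (min(cols) < 1L || max(cols) > n_col(a))
    stop("columns to exclude out of range")
  keep <- setdiff(seq_len(n_col(a)), cols)
  if (!length(keep)) stop("exclusion would leave an empty alignment")
  subset_columns(a, keep)
}

#' Count parsimony-informative columns
#'
#' A column is parsimony-informative when at least two distinct unambiguous
#' nucleotide states are each present in at least two taxa.  Gaps, `?` and
#' IUPAC ambiguity codes are excluded from the tally.
#'
#' @param a An `rb_alignment` (or binary indel matrix).
#' @param cols Optional integer column subset or charset name; default all.
#' @return Integer count.
#' @export
count_parsimony_informative <- function(a, cols = NULL) {
  states <- if (inherits(a, "rb_indel_matrix")) c("0", "1") else DNA_STATES
  if (is.character(cols)) {
    cs <- charsets(a)
    if (is.null(cs) || !cols %in% names(cs))
      stop("no charset named '", cols, "'")
    cols <- cs[[cols]]
  }
  mat <- if (is.null(cols)) a$mat else a$mat[, cols, drop = FALSE]
  sum(apply(mat, 2L, function(col) {
    tab <- table(col[col %in% states])
    sum(tab >= 2L) >= 2L
  }))
}

#' Per-charset alignment statistics
#'
#' @param a An `rb_alignment` with charsets (or without, giving one row).
#' @return A tibble with columns `charset`, `n_sites`,
#'   `n_parsimony_informative`, `prop_gap`, `prop_missing`.
#' @export
alignment_stats <- function(a) {
  cs <- charsets(a) %||% list(all = seq_len(n_col(a)))
  purrr::map_dfr(names(cs), function(nm) {
    sub <- a$mat[, cs[[nm]], drop = FALSE]
    tibble::tibble(
      charset = nm,
      n_sites = length(cs[[nm]]),
      n_parsimony_informative = count_parsimony_informative(a, cs[[nm]]),
      prop_gap = mean(sub == "-"),
      prop_missing = mean(sub == "?"))
  })
}
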