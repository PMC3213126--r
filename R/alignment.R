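# Alignment container: a rectangular taxa x columns character matrix over the
# DNA alphabet plus IUPAC ambiguity codes, '-' (gap / indel) and '?' (missing
# data).  Charsets (named, disjoint column index sets) ride along as an
# attribute so preprocessing can re-index them consistently.

DNA_STATES <- c("A", "C", "G", "T")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"),
  "-" = c("A", "C", "G", "T"), "?" = c("A", "C", "G", "T")
)

VALID_SYMBOLS <- c(names(IUPAC_SETS))

#' Construct an alignment
#'
#' @param mat Character matrix, one row per taxon (rownames are the taxon
#'   labels), one column per alignment site.  Symbols must be IUPAC nucleotide
#'   codes, `-` (gap) or `?` (missing).
#' @param charsets Named list of integer vectors of column indices (1-based),
#'   or `NULL`.
#' @return An object of class `rb_alignment`.
#' @export
alignment <- function(mat, charsets = NULL) {
  stopifnot(is.matrix(mat), is.character(mat))
  if (is.null(rownames(mat))) stop("alignment matrix must have taxon rownames")
  if (anyDuplicated(rownames(mat)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]), collapse = ", "))
  if (ncol(mat) < 1L) stop("alignment has zero columns")
  mat[] <- toupper(mat)
  bad <- matrix(!(mat %in% VALID_SYMBOLS), nrow(mat))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    stop(sprintf("unknown symbol '%s' for taxon '%s' at column %d",
                 mat[idx[1L], idx[2L]], rownames(mat)[idx[1L]], idx[2L]))
  }
  charsets <- validate_charsets(charsets, ncol(mat))
  structure(list(mat = mat), charsets = charsets, class = "rb_alignment")
}

validate_charsets <- function(charsets, n_col) {
  if (is.null(charsets)) return(NULL)
  stopifnot(is.list(charsets))
  if (is.null(names(charsets)) || any(names(charsets) == ""))
    stop("charsets must be named")
  if (anyDuplicated(names(charsets))) stop("duplicate charset names")
  lapply(charsets, function(v) {
    v <- as.integer(sort(unique(v)))
    if (length(v) && (min(v) < 1L || max(v) > n_col))
      stop("charset columns out of alignment bounds")
    v
  })
}

#' @export
print.rb_alignment <- function(x, ...) {
  cs <- charsets(x)
  cat(sprintf("<rb_alignment> %d taxa x %d columns\n", n_taxa(x), n_col(x)))
  if (!is.null(cs))
    cat("charsets:", paste(sprintf("%s[%d]", names(cs), lengths(cs)),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Taxon labels of an alignment
#' @param a An `rb_alignment`.
#' @export
taxa <- function(a) rownames(a$mat)

#' @rdname taxa
#' @export
n_taxa <- function(a) nrow(a$mat)

#' Number of alignment columns
#' @param a An `rb_alignment`.
#' @export
n_col <- function(a) ncol(a$mat)

#' Charsets attached to an alignment
#' @param a An `rb_alignment`.
#' @return Named list of integer column-index vectors, or `NULL`.
#' @export
charsets <- function(a) attr(a, "charsets")

#' @rdname charsets
#' @param value Named list of integer vectors.
#' @export
`charsets<-` <- function(a, value) {
  attr(a, "charsets") <- validate_charsets(value, n_col(a))
  a
}

#' Convert charset intervals to a tidy table
#'
#' Each charset is reported as its maximal runs of consecutive columns
#' (1-based inclusive), the form in which NEXUS `charset` lines are written.
#'
#' @param a An `rb_alignment`.
#' @return A tibble with columns `charset`, `start`, `end`.
#' @export
charset_table <- function(a) {
  cs <- charsets(a)
  if (is.null(cs)) return(tibble::tibble(charset = character(),
                                         start = integer(), end = integer()))
  purrr::map_dfr(names(cs), function(nm) {
    iv <- columns_to_intervals(cs[[nm]])
    tibble::tibble(charset = nm, start = iv[, 1L], end = iv[, 2L])
  })
}

# integer column vector -> matrix of [start, end] inclusive runs
columns_to_intervals <- function(v) {
  if (!length(v)) return(matrix(integer(), ncol = 2L))
  v <- sort(unique(as.integer(v)))
  brk <- c(0L, which(diff(v) != 1L), length(v))
  starts <- v[brk[-length(brk)] + 1L]
  ends <- v[brk[-1L]]
  cbind(starts, ends)
}
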