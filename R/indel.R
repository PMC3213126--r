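# Simple indel coding (SIC): every distinct interior gap extent observed in
# the alignment becomes one binary presence/absence character.  A taxon scores
# 1 when it carries a gap of exactly that extent, '?' when one of its gaps
# strictly contains the extent (the character is inapplicable inside a larger
# deletion), and 0 otherwise -- including partial, non-nested overlap.  Taxa
# whose sequence is entirely missing across the extent also score '?'.

#' Enumerate distinct interior gap extents
#'
#' Terminal gaps should have been converted to missing beforehand (see
#' [strip_flanking_gaps()]); `?` never opens, extends or closes a gap run.
#'
#' @param a An `rb_alignment`.
#' @return A tibble with columns `start`, `end` (1-based inclusive columns),
#'   `n_supporting` and list-column `supporting_taxa`, sorted by
#'   `(start, end)`.
#' @export
extract_gap_extents <- function(a) {
  runs <- gap_runs_by_taxon(a)
  flat <- dplyr::bind_rows(runs)
  if (!nrow(flat))
    return(tibble::tibble(start = integer(), end = integer(),
                          n_supporting = integer(),
                          supporting_taxa = list()))
  flat |>
    dplyr::group_by(.data$start, .data$end) |>
    dplyr::summarise(n_supporting = dplyr::n(),
                     supporting_taxa = list(sort(.data$taxon)),
                     .groups = "drop") |>
    dplyr::arrange(.data$start, .data$end)
}

# per-taxon maximal runs of '-' as a list of tibbles(taxon, start, end)
gap_runs_by_taxon <- function(a) {
  lapply(taxa(a), function(tx) {
    isgap <- a$mat[tx, ] == "-"
    if (!any(isgap))
      return(tibble::tibble(taxon = character(), start = integer(),
                            end = integer()))
    r <- rle(isgap)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    tibble::tibble(taxon = tx, start = starts[r$values], end = ends[r$values])
  })
}

#' Simple indel coding of an alignment
#'
#' @param a An `rb_alignment` (typically the gap-rich ITS block).
#' @return An `rb_indel_matrix`: taxa x characters matrix over
#'   `{"0","1","?"}` with the event table as attribute `events`.
#' @export
sic_encode <- function(a) {
  events <- extract_gap_extents(a)
  runs <- gap_runs_by_taxon(a)
  names(runs) <- taxa(a)
  nchar_ <- nrow(events)
  mat <- matrix("0", n_taxa(a), nchar_,
                dimnames = list(taxa(a),
                                if (nchar_) paste0("indel_", events$start,
                                                   "_", events$end)))
  for (tx in taxa(a)) {
    tr <- runs[[tx]]
    for (j in seq_len(nchar_)) {
      s <- events$start[j]; e <- events$end[j]
      if (nrow(tr)) {
        if (any(tr$start == s & tr$end == e)) { mat[tx, j] <- "1"; next }
        if (any(tr$start <= s & tr$end >= e)) { mat[tx, j] <- "?"; next }
      }
      # unsequenced across the whole extent: absence cannot be asserted
      if (all(a$mat[tx, s:e] == "?")) mat[tx, j] <- "?"
    }
  }
  structure(list(mat = mat), events = events, class = "rb_indel_matrix")
}

#' @export
print.rb_indel_matrix <- function(x, ...) {
  cat(sprintf("<rb_indel_matrix> %d taxa x %d indel characters\n",
              nrow(x$mat), ncol(x$mat)))
  invisible(x)
}

#' Event table of an indel matrix
#' @param m An `rb_indel_matrix`.
#' @export
indel_events <- function(m) attr(m, "events")

#' Summary statistics of a binary indel matrix
#'
#' @param m An `rb_indel_matrix`.
#' @return A tibble with `n_characters` and `n_parsimony_informative`
#'   (parsimony-informative over states `{0,1}`, `?` ignored).
#' @export
indel_matrix_stats <- function(m) {
  tibble::tibble(
    n_characters = ncol(m$mat),
    n_parsimony_informative =
      if (ncol(m$mat)) count_parsimony_informative(m) else 0L)
}

#' Write a binary indel matrix as a NEXUS standard-datatype block
#' @param m An `rb_indel_matrix`.
#' @param path Output path.
#' @export
write_indel_nexus <- function(m, path) {
  write_nexus(m, path, datatype = "standard", symbols = "01")
}
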