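# Reading and writing alignments: relaxed FASTA (via seqinr) and NEXUS with
# DATA + SETS blocks.  NEXUS charsets are 1-based inclusive per the standard;
# that is also the internal convention, so I/O is index-preserving.

#' Read an alignment from FASTA or NEXUS
#'
#' FASTA taxon labels are the header up to the first whitespace.  NEXUS files
#' may carry a SETS (or ASSUMPTIONS) block with `charset` lines; these are
#' attached to the returned alignment.
#'
#' @param path File path.
#' @param format `"fasta"` or `"nexus"`; default guesses from the extension.
#' @return An [alignment()] (`rb_alignment`).
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(nex|nexus|nxs)$", path, ignore.case = TRUE))
      "nexus" else "fasta"
  }
  if (format == "fasta") read_fasta_alignment(path) else read_nexus_alignment(path)
}

read_fasta_alignment <- function(path) {
  seqs <- tryCatch(
    seqinr::read.fasta(path, seqtype = "DNA", as.string = FALSE,
                       forceDNAtolower = FALSE, set.attributes = FALSE),
    error = function(e) stop("could not parse FASTA '", path, "': ",
                             conditionMessage(e)))
  if (!length(seqs)) stop("empty alignment file: ", path)
  if (any(!lengths(seqs))) stop("empty sequence in ", path)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: taxon '", names(seqs)[which(lens != lens[1L])[1L]],
         "' has length ", lens[lens != lens[1L]][1L], ", expected ", lens[1L])
  mat <- do.call(rbind, seqs)
  rownames(mat) <- names(seqs)
  alignment(mat)
}

#' Write an alignment to FASTA
#' @param a An `rb_alignment`.
#' @param path Output path.
#' @export
write_fasta <- function(a, path) {
  seqinr::write.fasta(apply(a$mat, 1L, paste0, collapse = ""),
                      names = taxa(a), file.out = path, nbchar = 70)
  invisible(path)
}

read_nexus_alignment <- function(path) {
  txt <- readLines(path, warn = FALSE)
  one <- paste(txt, collapse = "\n")
  # matrix block: between MATRIX and ';'
  m <- regmatches(one, regexpr("(?is)matrix\\s*\\n(.*?);", one, perl = TRUE))
  if (!length(m)) stop("no MATRIX block found in ", path)
  body <- sub("(?is)^matrix\\s*\\n", "", m, perl = TRUE)
  body <- sub(";\\s*$", "", body)
  rows <- strsplit(body, "\n")[[1L]]
  rows <- trimws(rows)
  rows <- rows[nzchar(rows) & !grepl("^\\[", rows)]
  if (!length(rows)) stop("empty alignment file: ", path)
  labs <- sub("\\s.*$", "", rows)
  seqs <- gsub("\\s", "", sub("^\\S+\\s+", "", rows))
  # interleaved files repeat labels; concatenate per label in first-seen order
  ord <- unique(labs)
  seqchr <- vapply(ord, function(l) paste0(seqs[labs == l], collapse = ""), "")
  if (anyDuplicated(ord)) stop("duplicate taxon labels")
  lens <- nchar(seqchr)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: taxon '", ord[which(lens != lens[1L])[1L]], "'")
  mat <- do.call(rbind, strsplit(seqchr, ""))
  rownames(mat) <- ord
  a <- alignment(mat)
  charsets(a) <- parse_nexus_charsets(txt, ncol(mat))
  a
}

# Parse "charset NAME = 1-659 700 702-710;" lines (1-based inclusive)
parse_nexus_charsets <- function(lines, n_col) {
  hits <- grep("^\\s*charset\\s", lines, ignore.case = TRUE, value = TRUE)
  if (!length(hits)) return(NULL)
  out <- list()
  for (h in hits) {
    h <- sub(";\\s*$", "", trimws(h))
    nm <- sub("(?i)^charset\\s+(\\S+)\\s*=.*$", "\\1", h, perl = TRUE)
    rhs <- trimws(sub("^[^=]*=", "", h))
    cols <- integer()
    for (tok in strsplit(rhs, "\\s+")[[1L]]) {
      if (grepl("^\\d+-\\d+$", tok)) {
        ab <- as.integer(strsplit(tok, "-")[[1L]])
        cols <- c(cols, seq.int(ab[1L], ab[2L]))
      } else if (grepl("^\\d+$", tok)) {
        cols <- c(cols, as.integer(tok))
      } else stop("cannot parse charset token '", tok, "'")
    }
    out[[nm]] <- cols
  }
  validate_charsets(out, n_col)
}

#' Write an alignment to NEXUS (DATA + SETS blocks)
#'
#' Charsets are emitted as 1-based inclusive `a-b` ranges and round-trip
#' bit-exactly through [read_alignment()].
#'
#' @param a An `rb_alignment`.
#' @param path Output path.
#' @param datatype `"dna"` or `"standard"` (binary indel matrices).
#' @param symbols Symbols string for standard data.
#' @export
write_nexus <- function(a, path, datatype = "dna", symbols = "01") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#NEXUS", con)
  writeLines("BEGIN DATA;", con)
  writeLines(sprintf("  DIMENSIONS NTAX=%d NCHAR=%d;", n_taxa(a), n_col(a)), con)
  fmt <- if (datatype == "dna")
    "  FORMAT DATATYPE=DNA GAP=- MISSING=?;"
  else sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=?;", symbols)
  writeLines(fmt, con)
  writeLines("  MATRIX", con)
  labs <- format(taxa(a))
  seqs <- apply(a$mat, 1L, paste0, collapse = "")
  writeLines(paste0("    ", labs, "  ", seqs), con)
  writeLines("  ;", con)
  writeLines("END;", con)
  cs <- charsets(a)
  if (!is.null(cs) && length(cs)) {
    writeLines("BEGIN SETS;", con)
    for (nm in names(cs)) {
      iv <- columns_to_intervals(cs[[nm]])
      toks <- ifelse(iv[, 1L] == iv[, 2L], as.character(iv[, 1L]),
                     paste0(iv[, 1L], "-", iv[, 2L]))
      writeLines(sprintf("  charset %s = %s;", nm, paste(toks, collapse = " ")), con)
    }
    writeLines("END;", con)
  }
  invisible(path)
}
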