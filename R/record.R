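#' Create a validated DNA sequence record
#'
#' A `seq_record` is the unit every scanner in the package consumes: an
#' identifier plus a DNA string over the alphabet \{A, C, G, T, N\}.
#' Lowercase input is accepted and normalized to upper case; any other
#' character is rejected with the position of the first offender. U is
#' rejected: this is a DNA tool.
#'
#' @param id Character scalar, the sequence label.
#' @param seq Character scalar, the DNA sequence.
#' @return An object of class `seq_record` with elements `id`, `seq`
#'   (upper-cased) and `length`.
#' @examples
#' rec <- seq_record("oligo1", "aaGGGtgggT")
#' rec$length
#' @export
seq_record <- function(id, seq) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  if (nchar(seq) < 1L)
    stop("empty sequence for record '", id, "'")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L)
    stop("invalid character '", substr(seq, bad, bad),
         "' at position ", bad, " in record '", id, "'")
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  shown <- if (x$length > 60L) paste0(substr(x$seq, 1L, 57L), "...") else x$seq
  cat("<seq_record> ", x$id, " (", x$length, " nt)\n  ", shown, "\n", sep = "")
  invisible(x)
}

# Accept a seq_record, a plain string, or a named string.
as_seq_record <- function(x, id = "seq") {
  if (inherits(x, "seq_record")) return(x)
  if (is.character(x) && length(x) == 1L) {
    if (!is.null(names(x))) id <- names(x)
    return(seq_record(id, x))
  }
  stop("expected a seq_record or a single DNA string")
}

#' Reverse complement of a DNA string
#'
#' @param seq A `seq_record` or DNA string. N maps to N.
#' @return A character scalar.
#' @export
revcomp <- function(seq) {
  s <- if (inherits(seq, "seq_record")) seq$seq else toupper(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Read a FASTA file into a list of sequence records
#'
#' Identifiers are taken from the header up to the first whitespace;
#' sequences are normalized and validated. Gzipped files are accepted.
#'
#' @param path Path to a FASTA file.
#' @return A list of `seq_record` objects in file order; empty list (with a
#'   warning) for an empty file.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) {
    warning("no records in ", path)
    return(list())
  }
  ids <- sub("\\s.*$", "", names(set))
  mapply(seq_record, ids, as.character(set), SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write sequence records to a FASTA file
#'
#' @param records A list of `seq_record` objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (inherits(records, "seq_record")) records <- list(records)
  set <- Biostrings::DNAStringSet(vapply(records, `[[`, "", "seq"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
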