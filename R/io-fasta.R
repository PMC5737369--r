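#' Read a FASTA file into a named sequence vector
#'
#' Sequences are uppercased on ingest and any character outside the
#' \code{A,C,G,T,N} alphabet is replaced by \code{N}; the number of
#' replacements is reported with a warning so dirty inputs are visible but
#' do not stop a run.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector, one element per record.  Names are the
#'   first whitespace-delimited token of each header.  The number of
#'   replaced characters is attached as attribute \code{"n_replaced"}.
#' @examples
#' tf <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s) in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(ss))
  bad <- sum(vapply(gregexpr("[^ACGTN]", seqs), function(m)
    if (m[1L] == -1L) 0L else length(m), integer(1)))
  if (bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(bad, " character(s) outside {A,C,G,T,N} replaced by N in ", path)
  }
  if (any(nchar(seqs) == 0L)) stop("zero-length sequence in ", path)
  names(seqs) <- ids
  attr(seqs, "n_replaced") <- bad
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return Invisibly, \code{path}.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(length(seqs) >= 0, !is.null(names(seqs)) || length(seqs) == 0L)
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}
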