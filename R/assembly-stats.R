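#' Partition sequences by a minimum-length threshold
#'
#' The boundary is inclusive: a sequence exactly \code{min_len} long is kept,
#' mirroring the usual ">= 1,000 bases" draft-assembly release rule.
#'
#' @param seqs Named character vector of sequences (see [read_fasta()]).
#' @param min_len Minimum length in bp, \code{>= 1}.
#' @return A list with elements \code{kept}, \code{removed} (both named
#'   character vectors) and \code{removed_total_bp}.
#' @export
filter_by_length <- function(seqs, min_len) {
  stopifnot(is.numeric(min_len), length(min_len) == 1L, min_len >= 1)
  len <- nchar(seqs)
  keep <- len >= min_len
  list(kept = seqs[keep],
       removed = seqs[!keep],
       removed_total_bp = sum(len[!keep]))
}

#' Assembly-level summary statistics
#'
#' N50 is the smallest length L such that sequences of length >= L sum to at
#' least half the assembly.  GC percent is computed over called bases only
#' (Ns excluded from the denominator); \code{n_len} counts the Ns.
#'
#' @param seqs Named character vector of sequences over \code{A,C,G,T,N}.
#' @return An object of class \code{assembly_summary}: a list with
#'   \code{n_seqs}, \code{total_len}, \code{n50}, \code{longest},
#'   \code{gc_percent}, \code{n_len}.
#' @export
assembly_summary <- function(seqs) {
  if (length(seqs) == 0L) stop("assembly_summary() needs at least one sequence")
  len <- nchar(seqs)
  ss <- Biostrings::DNAStringSet(seqs)
  af <- Biostrings::letterFrequency(ss, c("A", "C", "G", "T", "N"))
  tot <- colSums(af)
  acgt <- sum(tot[c("A", "C", "G", "T")])
  srt <- sort(len, decreasing = TRUE)
  n50 <- srt[which(cumsum(as.numeric(srt)) >= sum(as.numeric(len)) / 2)[1L]]
  structure(list(
    n_seqs = length(seqs),
    total_len = sum(as.numeric(len)),
    n50 = unname(n50),
    longest = max(len),
    gc_percent = if (acgt > 0) 100 * sum(tot[c("G", "C")]) / acgt else NA_real_,
    n_len = unname(tot[["N"]])
  ), class = "assembly_summary")
}

#' @export
print.assembly_summary <- function(x, ...) {
  cat("Assembly summary\n")
  cat(sprintf("  sequences : %s\n", format(x$n_seqs, big.mark = ",")))
  cat(sprintf("  total bp  : %s\n", format(x$total_len, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  N50 (bp)  : %s\n", format(x$n50, big.mark = ",")))
  cat(sprintf("  longest   : %s\n", format(x$longest, big.mark = ",")))
  cat(sprintf("  GC %%      : %.1f\n", x$gc_percent))
  cat(sprintf("  N bases   : %s\n", format(x$n_len, big.mark = ",", scientific = FALSE)))
  invisible(x)
}
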