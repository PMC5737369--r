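#' Construct a k-mer histogram object
#'
#' @param counts Named numeric vector mapping depth (multiplicity, integer
#'   \code{>= 1}) to the number of distinct canonical k-mers observed at
#'   that depth.
#' @param k The k-mer length.
#' @return An object of class \code{kmer_histogram}.
#' @export
kmer_histogram <- function(counts, k) {
  depths <- as.integer(names(counts))
  if (any(is.na(depths)) || any(depths < 1))
    stop("histogram depths must be integers >= 1")
  if (any(counts < 0)) stop("histogram counts must be >= 0")
  o <- order(depths)
  structure(list(k = as.integer(k), counts = setNames(as.numeric(counts)[o],
                                                      depths[o])),
            class = "kmer_histogram")
}

#' @export
print.kmer_histogram <- function(x, ...) {
  cat(sprintf("k-mer histogram (k = %d): %d depth classes, %s distinct k-mers\n",
              x$k, length(x$counts),
              format(sum(x$counts), big.mark = ",", scientific = FALSE)))
  invisible(x)
}

#' Count canonical k-mers in a set of sequences
#'
#' Each k-length window free of \code{N} (or any non-ACGT character) is
#' counted under its canonical form, the lexicographic minimum of the
#' window and its reverse complement, then occurrence counts are aggregated
#' into a depth histogram -- the same convention as mainstream k-mer
#' counters.
#'
#' @param seqs Character vector of reads or sequences.
#' @param k K-mer length, 1..31 (odd values recommended so no k-mer is its
#'   own reverse complement; 17 is the classical genome-survey choice).
#' @return A [kmer_histogram()].
#' @export
count_kmers <- function(seqs, k = 17L) {
  k <- as.integer(k)
  if (length(seqs) == 0L) stop("count_kmers() needs at least one sequence")
  if (k < 1L || k > 31L) stop("k must be in 1..31")
  if (max(nchar(seqs)) < k)
    stop("k = ", k, " is longer than every input sequence")
  counts <- .count_kmers_cpp(seqs, k)
  if (length(counts) == 0L)
    stop("no countable k-mer window (all windows contain N)")
  kmer_histogram(counts, k)
}

#' Call coverage peaks in a k-mer histogram
#'
#' The histogram is smoothed with a window-3 moving average.  The error
#' cutoff is the first local minimum as depth increases (the trough between
#' the sequencing-error spike and the coverage peaks); if counts rise from
#' the smallest depth there is no error component and the cutoff is that
#' smallest depth.  Local maxima above the cutoff are peak candidates; the
#' two tallest are kept.  The homozygous peak is the candidate at the
#' greater depth; the other is reported as the heterozygous peak only if
#' its depth lies within \code{het_band} times the homozygous depth.
#'
#' A depth-resolution-free refinement of the homozygous peak
#' (\code{hom_depth_refined}) is also returned: the count-weighted mean
#' depth over the contiguous region around the peak where counts are at
#' least half the peak count.  It removes the integer-quantisation bias of
#' the modal depth and is what [estimate_genome_size()] divides by.
#'
#' @param hist A [kmer_histogram()].
#' @param het_band Numeric length-2: the het/hom depth-ratio band.
#' @param min_peak_frac Candidate peaks shorter than this fraction of the
#'   tallest peak are ignored (filters the two-copy-repeat shoulder at
#'   twice the coverage depth).
#' @return A \code{peak_call} list: \code{het_depth} (or \code{NA}),
#'   \code{hom_depth}, \code{hom_depth_refined}, \code{error_cutoff}.
#' @export
detect_peaks <- function(hist, het_band = c(0.4, 0.6), min_peak_frac = 0.1) {
  stopifnot(inherits(hist, "kmer_histogram"))
  depths <- as.integer(names(hist$counts))
  maxd <- max(depths)
  cnt <- numeric(maxd)
  cnt[depths] <- hist$counts
  n <- length(cnt)
  sm <- cnt
  if (n >= 3L)
    sm[2:(n - 1L)] <- (cnt[1:(n - 2L)] + cnt[2:(n - 1L)] + cnt[3:n]) / 3

  cutoff <- NA_integer_
  if (n >= 2L && sm[1L] < sm[2L]) {
    cutoff <- 1L                        # rising from the start: no error spike
  } else if (n >= 3L) {
    for (d in 2:(n - 1L)) {
      if (sm[d] <= sm[d - 1L] && sm[d] < sm[d + 1L]) { cutoff <- d; break }
    }
  }
  if (is.na(cutoff)) stop("no coverage peak (histogram monotone decreasing)")

  is_max <- rep(FALSE, n)
  lo_d <- max(2L, cutoff + 1L)
  if (n - 1L >= lo_d) {
    for (d in lo_d:(n - 1L)) {
      if (sm[d] > sm[d - 1L] && sm[d] >= sm[d + 1L]) is_max[d] <- TRUE
    }
  }
  if (n >= 2L && sm[n] > sm[n - 1L]) is_max[n] <- TRUE
  cand <- which(is_max & sm > 0)
  if (length(cand) == 0L) stop("no coverage peak")
  # drop negligible bumps (e.g. the two-copy-repeat shoulder at double
  # depth) before picking the two dominant peaks
  cand <- cand[sm[cand] >= min_peak_frac * max(sm[cand])]
  cand <- cand[order(sm[cand], decreasing = TRUE)][seq_len(min(2L, length(cand)))]
  hom <- max(cand)
  het <- NA_integer_
  if (length(cand) == 2L) {
    lo <- min(cand)
    r <- lo / hom
    if (r >= het_band[1L] && r <= het_band[2L]) het <- lo
  }

  # half-height centroid refinement of the homozygous peak
  half <- cnt[hom] / 2
  left <- hom; while (left > cutoff && cnt[left - 1L] >= half) left <- left - 1L
  right <- hom; while (right < n && cnt[right + 1L] >= half) right <- right + 1L
  reg <- left:right
  hom_ref <- sum(reg * cnt[reg]) / sum(cnt[reg])

  structure(list(het_depth = het, hom_depth = hom,
                 hom_depth_refined = hom_ref, error_cutoff = cutoff),
            class = "peak_call")
}

#' @export
print.peak_call <- function(x, ...) {
  cat(sprintf("peak call: hom %d (refined %.2f), het %s, error cutoff %d\n",
              x$hom_depth, x$hom_depth_refined,
              if (is.na(x$het_depth)) "absent" else x$het_depth,
              x$error_cutoff))
  invisible(x)
}

#' Estimate genome size from a k-mer histogram
#'
#' Size = (total k-mer mass at depths >= the error cutoff) divided by the
#' homozygous peak depth.  The refined (fractional) peak depth is used by
#' default; set \code{use_refined = FALSE} to divide by the integer modal
#' depth instead.
#'
#' @param hist A [kmer_histogram()].
#' @param peaks A \code{peak_call} from [detect_peaks()].
#' @param error_cutoff Optional override of the peak call's cutoff.
#' @param use_refined Divide by the half-height-centroid peak depth
#'   (default) rather than the integer mode.
#' @return Estimated genome size in bp (rounded to integer).
#' @export
estimate_genome_size <- function(hist, peaks, error_cutoff = NULL,
                                 use_refined = TRUE) {
  stopifnot(inherits(hist, "kmer_histogram"), inherits(peaks, "peak_call"))
  hom <- if (use_refined) peaks$hom_depth_refined else peaks$hom_depth
  if (is.na(hom) || hom <= 0) stop("homozygous peak depth must be > 0")
  cutoff <- error_cutoff %||% peaks$error_cutoff
  depths <- as.integer(names(hist$counts))
  keep <- depths >= cutoff
  round(sum(depths[keep] * hist$counts[keep]) / hom)
}
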