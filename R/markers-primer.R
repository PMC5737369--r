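# Nearest-neighbor duplex parameters (unified set): dH kcal/mol, dS cal/(mol K)
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4, CT = -7.8,
           GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2, CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)

#' Nearest-neighbor melting temperature of a primer
#'
#' Unified nearest-neighbor thermodynamics with terminal initiation
#' corrections, at the stated salt and oligo concentrations, plus the
#' classical monovalent-salt correction \code{16.6 log10[Na+]}.
#'
#' @param primer Primer sequence (5'->3', over ACGT).
#' @param na_mM Monovalent cation concentration in mM (default 50).
#' @param oligo_nM Oligo concentration in nM (default 50).
#' @return Tm in degrees Celsius.
#' @export
primer_tm <- function(primer, na_mM = 50, oligo_nM = 50) {
  s <- toupper(primer)
  n <- nchar(s)
  stopifnot(n >= 2L, grepl("^[ACGT]+$", s))
  nn <- substring(s, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[nn]); ds <- sum(NN_DS[nn])
  for (termbase in c(substr(s, 1L, 1L), substr(s, n, n))) {
    if (termbase %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds + (-2.8) }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ct <- oligo_nM * 1e-9
  tm_k <- dh * 1000 / (ds + 1.987 * log(ct / 4))
  tm_k - 273.15 + 16.6 * log10(na_mM / 1000)
}

gc_percent <- function(s) {
  100 * lengths(regmatches(s, gregexpr("[GC]", s))) / nchar(s)
}

max_homopolymer <- function(s) {
  r <- rle(strsplit(s, "", fixed = TRUE)[[1L]])
  max(r$lengths)
}

# 3'-terminal 5-mer self-complementarity: the outer bases of the 5-mer
# pair with themselves in antiparallel orientation (middle base ignored --
# an odd-length word can never be a perfect palindrome).
self_comp_3prime <- function(s) {
  n <- nchar(s)
  if (n < 5L) return(FALSE)
  p <- substr(s, n - 4L, n)
  substr(p, 1L, 2L) == revcomp(substr(p, 4L, 5L))
}

#' Primer-design constraints
#' @param len_min,len_max Primer length range (default 18-25).
#' @param tm_min,tm_max Allowed Tm range in Celsius (default 55-62).
#' @param gc_min,gc_max Allowed GC percentage (default 30-70).
#' @param max_homo Maximum homopolymer run (default 4).
#' @param max_dtm Maximum |Tm difference| within a pair (default 3).
#' @param product_min,product_max Product-size range in bp (default
#'   80-300).
#' @return A list of class \code{primer_constraints}.
#' @export
primer_constraints <- function(len_min = 18L, len_max = 25L, tm_min = 55,
                               tm_max = 62, gc_min = 30, gc_max = 70,
                               max_homo = 4L, max_dtm = 3,
                               product_min = 80L, product_max = 300L) {
  structure(list(len_min = as.integer(len_min), len_max = as.integer(len_max),
                 tm_min = tm_min, tm_max = tm_max, gc_min = gc_min,
                 gc_max = gc_max, max_homo = as.integer(max_homo),
                 max_dtm = max_dtm, product_min = as.integer(product_min),
                 product_max = as.integer(product_max)),
            class = "primer_constraints")
}

# vectorised Tm for equal-length primer sets
tm_vec <- function(p, na_mM = 50, oligo_nM = 50) {
  if (length(p) == 0L) return(numeric(0))
  len <- nchar(p[1L])
  nn <- vapply(seq_len(len - 1L), function(i) substring(p, i, i + 1L),
               character(length(p)))
  if (length(p) == 1L) nn <- matrix(nn, nrow = 1L)
  dh <- rowSums(matrix(NN_DH[nn], nrow = length(p)))
  ds <- rowSums(matrix(NN_DS[nn], nrow = length(p)))
  for (term in list(substr(p, 1L, 1L), substr(p, len, len))) {
    is_gc <- term %in% c("G", "C")
    dh <- dh + ifelse(is_gc, 0.1, 2.3)
    ds <- ds + ifelse(is_gc, -2.8, 4.1)
  }
  dh * 1000 / (ds + 1.987 * log(oligo_nM * 1e-9 / 4)) - 273.15 +
    16.6 * log10(na_mM / 1000)
}

# all single-primer candidates in [lo, hi] of the template (forward
# orientation within the window; `rev = TRUE` takes reverse-complements)
primer_candidates <- function(template, lo, hi, cons, rev = FALSE,
                              tally = NULL) {
  out <- list()
  homo_pat <- paste0("([ACGT])\\1{", cons$max_homo, "}")
  for (len in cons$len_min:cons$len_max) {
    if (hi < lo || hi - lo + 1L < len) next
    starts <- lo:(hi - len + 1L)
    words <- substring(template, starts, starts + len - 1L)
    ok <- !grepl("[^ACGT]", words)
    tally_add_n(tally, "alphabet", sum(!ok))
    p <- character(length(words)); p[ok] <- if (rev) revcomp(words[ok]) else words[ok]
    gc <- ifelse(ok, 100 * nchar(gsub("[^GC]", "", p)) / len, NA)
    bad_gc <- ok & (gc < cons$gc_min | gc > cons$gc_max)
    tally_add_n(tally, "gc", sum(bad_gc)); ok <- ok & !bad_gc
    bad_h <- ok & grepl(homo_pat, p)
    tally_add_n(tally, "homopolymer", sum(bad_h)); ok <- ok & !bad_h
    five <- substr(p, len - 4L, len)
    bad_sc <- ok & substr(five, 1L, 2L) ==
      chartr("ACGT", "TGCA", paste0(substr(five, 5L, 5L), substr(five, 4L, 4L)))
    tally_add_n(tally, "self_comp", sum(bad_sc)); ok <- ok & !bad_sc
    tm <- rep(NA_real_, length(p))
    if (any(ok)) tm[ok] <- tm_vec(p[ok])
    bad_tm <- ok & (tm < cons$tm_min | tm > cons$tm_max)
    tally_add_n(tally, "tm", sum(bad_tm)); ok <- ok & !bad_tm
    if (any(ok))
      out[[length(out) + 1L]] <- data.frame(
        seq = p[ok], start = starts[ok], end = starts[ok] + len - 1L,
        tm = tm[ok], gc = gc[ok], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(seq = character(0), start = integer(0),
                      end = integer(0), tm = numeric(0), gc = numeric(0)))
  do.call(rbind, out)
}

tally_add_n <- function(tally, what, n) {
  if (is.null(tally) || n == 0L) return(invisible(NULL))
  cur <- if (exists(what, envir = tally, inherits = FALSE))
    get(what, envir = tally) else 0L
  assign(what, cur + n, envir = tally)
  invisible(NULL)
}

#' Design a primer pair flanking a target interval
#'
#' Exhaustively scans candidate primers of length 18-25 in the flanks of
#' the target, applies the Tm/GC/homopolymer/3'-self-complementarity
#' constraints, then enumerates feasible pairs whose product contains the
#' target within the size range and whose Tm difference is at most
#' \code{max_dtm}.  Among feasible pairs the one with the smallest |dTm|
#' wins; ties break by shortest product, then leftmost left primer, then
#' leftmost right primer -- fully deterministic.
#'
#' @param template Template sequence string.
#' @param target_start,target_end Target interval (1-based inclusive) the
#'   product must contain.
#' @param cons A [primer_constraints()] list.
#' @return A \code{primer_pair} list (left/right sequence, position, Tm,
#'   GC, \code{product_len}).  When no feasible pair exists a
#'   \code{primer_failure} object is returned whose \code{$tally} counts
#'   candidates rejected per constraint; test with [primer_found()].
#' @export
design_primer_pair <- function(template, target_start, target_end,
                               cons = primer_constraints()) {
  stopifnot(target_start >= 1L, target_end >= target_start,
            target_end <= nchar(template))
  tally <- new.env(parent = emptyenv())
  lefts <- primer_candidates(template, 1L, target_start - 1L, cons,
                             rev = FALSE, tally = tally)
  rights <- primer_candidates(template, target_end + 1L, nchar(template),
                              cons, rev = TRUE, tally = tally)
  best <- NULL
  if (nrow(lefts) && nrow(rights)) {
    li <- rep(seq_len(nrow(lefts)), each = nrow(rights))
    ri <- rep(seq_len(nrow(rights)), times = nrow(lefts))
    prod_len <- rights$end[ri] - lefts$start[li] + 1L
    ok <- prod_len >= cons$product_min & prod_len <= cons$product_max
    tally_add_n(tally, "product", sum(!ok))
    dtm <- abs(lefts$tm[li] - rights$tm[ri])
    bad_dtm <- ok & dtm > cons$max_dtm
    tally_add_n(tally, "dtm", sum(bad_dtm))
    ok <- ok & !bad_dtm
    if (any(ok)) {
      idx <- which(ok)
      o <- idx[order(round(dtm[idx], 12), prod_len[idx],
                     lefts$start[li[idx]], rights$start[ri[idx]])][1L]
      best <- list(left = lefts[li[o], ], right = rights[ri[o], ],
                   product_len = prod_len[o])
    }
  }
  if (is.null(best))
    return(structure(list(tally = as.list(tally)), class = "primer_failure"))
  structure(list(
    left_seq = best$left$seq, left_start = best$left$start,
    left_end = best$left$end, left_tm = best$left$tm, left_gc = best$left$gc,
    right_seq = best$right$seq, right_start = best$right$start,
    right_end = best$right$end, right_tm = best$right$tm,
    right_gc = best$right$gc, product_len = best$product_len),
    class = "primer_pair")
}

#' Did primer design succeed?
#' @param x Result of [design_primer_pair()].
#' @return \code{TRUE} for a \code{primer_pair}, \code{FALSE} for a
#'   \code{primer_failure}.
#' @export
primer_found <- function(x) inherits(x, "primer_pair")

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("primer pair: product %d bp\n  L %s (Tm %.1f, GC %.0f%%)\n  R %s (Tm %.1f, GC %.0f%%)\n",
              x$product_len, x$left_seq, x$left_tm, x$left_gc,
              x$right_seq, x$right_tm, x$right_gc))
  invisible(x)
}
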