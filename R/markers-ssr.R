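#' Parameters for imperfect microsatellite (SSR) detection
#'
#' Scoring follows the mismatched-penalty school of SSR finders: +1 per
#' base matching the repeat pattern, \code{-mismatch_penalty} per
#' interrupting base, loci reported when the best-scoring extent reaches
#' \code{min_score}.  Detection is seeded by \code{seed_repeats}
#' consecutive perfect copies of a primitive unit.
#'
#' @param unit_min,unit_max Repeat-unit length range (default 2-6;
#'   mononucleotide runs are excluded).
#' @param min_score Minimum score to report a locus (default 15).
#' @param mismatch_penalty Penalty per interrupting base (default 5; use
#'   \code{Inf} for perfect repeats only).
#' @param seed_repeats Perfect unit copies required to seed a locus
#'   (default 3).
#' @param x_drop Stop extending once the running score falls this far
#'   below the best seen (a performance heuristic for long sequences;
#'   \code{Inf} makes the extension exact).  Default
#'   \code{4 * mismatch_penalty + 4}.
#' @return A list of class \code{ssr_params}.
#' @export
ssr_params <- function(unit_min = 2L, unit_max = 6L, min_score = 15,
                       mismatch_penalty = 5, seed_repeats = 3L,
                       x_drop = 4 * mismatch_penalty + 4) {
  stopifnot(unit_min >= 1L, unit_min <= unit_max, min_score > 0,
            mismatch_penalty > 0, seed_repeats >= 2L)
  structure(list(unit_min = as.integer(unit_min),
                 unit_max = as.integer(unit_max), min_score = min_score,
                 mismatch_penalty = mismatch_penalty,
                 seed_repeats = as.integer(seed_repeats), x_drop = x_drop),
            class = "ssr_params")
}

is_primitive_unit <- function(unit) {
  u <- nchar(unit)
  for (d in seq_len(u - 1L)) {
    if (u %% d == 0L && unit == strrep(substr(unit, 1L, d), u %/% d))
      return(FALSE)
  }
  TRUE
}

#' Canonical representative of an SSR unit
#'
#' The lexicographic minimum over all rotations of the unit and all
#' rotations of its reverse complement, so every report of the same repeat
#' class (either strand, any phase) shares one motif name.
#'
#' @param unit Repeat unit over \code{A,C,G,T}, length 1-6, primitive (not
#'   itself a repeat of a shorter unit).
#' @return The canonical motif string.
#' @export
canonical_motif <- function(unit) {
  if (!grepl("^[ACGT]+$", unit)) stop("unit must be over ACGT: ", unit)
  if (nchar(unit) > 6L) stop("unit longer than 6 bp: ", unit)
  if (!is_primitive_unit(unit))
    stop("degenerate unit (repeat of a shorter unit): ", unit)
  u <- nchar(unit)
  rot <- function(x) vapply(seq_len(u) - 1L, function(i)
    paste0(substr(x, i + 1L, u), substr(x, 1L, i)), character(1))
  min(c(rot(unit), rot(revcomp(unit))))
}

# Greedy scored extension away from a perfect seed.  Walks `chars` in
# order, tracking the best score per repeat phase; a mismatching base
# costs `pen` and leaves the phase free (so a 1-bp interruption does not
# desynchronise the rest of the repeat).  Returns the extension prefix
# with the maximum cumulative score.  An X-drop rule stops the walk once
# the running score falls `x_drop` below the best seen.
extend_run <- function(chars, unit_chars, pen, x_drop = 4 * pen + 4) {
  u <- length(unit_chars)
  sc <- rep(-Inf, u)
  sc[1L] <- 0
  best <- 0; best_len <- 0L
  for (t in seq_along(chars)) {
    m <- max(sc)
    if (m < best - x_drop || m == -Inf) break
    ns <- rep(if (is.finite(pen)) m - pen else -Inf, u)
    b <- chars[t]
    for (p in seq_len(u)) {
      if (is.finite(sc[p]) && b == unit_chars[p]) {
        q <- if (p == u) 1L else p + 1L
        if (sc[p] + 1 > ns[q]) ns[q] <- sc[p] + 1
      }
    }
    sc <- ns
    mt <- max(sc)
    if (mt > best) { best <- mt; best_len <- t }
  }
  list(score = best, len = best_len)
}

#' Detect imperfect SSR loci in a sequence
#'
#' Seeds are maximal perfect tandem runs of at least
#' \code{params$seed_repeats} copies of a primitive 2-6 bp unit.  Each
#' seed is extended greedily in both directions under the +1/-penalty
#' scoring, trimmed back to the maximum-score extent.  Overlapping reports
#' of the same region (different seeds or unit lengths) are resolved by
#' highest score, then shortest unit.  \code{N} never matches.
#'
#' @param seq A single sequence string over \code{A,C,G,T,N}.
#' @param params An [ssr_params()] list.
#' @param seq_id Sequence name recorded in the output.
#' @return Data frame of loci: \code{seq_id}, \code{start}, \code{end}
#'   (1-based inclusive), \code{unit}, \code{canonical_motif},
#'   \code{unit_len}, \code{score}, \code{n_mismatches}.
#' @export
find_ssrs <- function(seq, params = ssr_params(), seq_id = "seq") {
  stopifnot(length(seq) == 1L)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  cand <- list()
  for (u in params$unit_min:params$unit_max) {
    pat <- paste0("([ACGT]{", u, "})\\1{", params$seed_repeats - 1L, ",}")
    m <- gregexpr(pat, seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) next
    for (j in seq_along(m)) {
      s <- m[j]
      len <- attr(m, "match.length")[j]
      unit <- substr(seq, s, s + u - 1L)
      if (!is_primitive_unit(unit)) next
      e <- s + (len %/% u) * u - 1L       # whole copies only; rest via extension
      uc <- strsplit(unit, "", fixed = TRUE)[[1L]]
      seed_len <- e - s + 1L
      rt <- if (e < nchar(seq))
        extend_run(chars[(e + 1L):length(chars)], uc,
                   params$mismatch_penalty, params$x_drop)
      else list(score = 0, len = 0L)
      lt <- if (s > 1L)
        extend_run(chars[(s - 1L):1L], rev(uc),
                   params$mismatch_penalty, params$x_drop)
      else list(score = 0, len = 0L)
      score <- seed_len + rt$score + lt$score
      if (score < params$min_score) next
      start <- s - lt$len; end <- e + rt$len
      span <- end - start + 1L
      nm <- if (is.finite(params$mismatch_penalty))
        as.integer(round((span - score) / (1 + params$mismatch_penalty)))
      else 0L
      cand[[length(cand) + 1L]] <- data.frame(
        seq_id = seq_id, start = start, end = end, unit = unit,
        canonical_motif = canonical_motif(unit), unit_len = u,
        score = score, n_mismatches = nm, stringsAsFactors = FALSE)
    }
  }
  if (!length(cand))
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), unit = character(0),
                      canonical_motif = character(0), unit_len = integer(0),
                      score = numeric(0), n_mismatches = integer(0)))
  df <- do.call(rbind, cand)
  df <- df[order(-df$score, df$unit_len, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df))
  taken_start <- integer(0); taken_end <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= taken_end & df$end[i] >= taken_start)) {
      keep[i] <- TRUE
      taken_start <- c(taken_start, df$start[i])
      taken_end <- c(taken_end, df$end[i])
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Scan a whole sequence set for SSR loci
#' @param seqs Named character vector of sequences.
#' @param params An [ssr_params()] list.
#' @return Combined loci data frame (see [find_ssrs()]).
#' @export
find_ssrs_all <- function(seqs, params = ssr_params()) {
  do.call(rbind, lapply(names(seqs), function(id)
    find_ssrs(seqs[[id]], params, seq_id = id)))
}

#' Is an SSR locus genic?
#'
#' Genic means the locus interval overlaps any gene span (introns
#' included) by at least one bp on the same sequence.
#'
#' @param locus One-row data frame (or list) with \code{seq_id},
#'   \code{start}, \code{end}.
#' @param gene_models A \code{gene_models} data.frame.
#' @return Logical.
#' @export
classify_genic <- function(locus, gene_models) {
  any(gene_models$seq_id == locus$seq_id &
        gene_models$end >= locus$start &
        gene_models$start <= locus$end)
}

#' Write SSR loci as BED (0-based half-open)
#' @param loci Data frame from [find_ssrs()].
#' @param path Output path.
#' @export
write_ssr_bed <- function(loci, path) {
  bed <- data.frame(loci$seq_id, loci$start - 1L, loci$end,
                    paste0("SSR_", loci$canonical_motif), loci$score, "+")
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
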