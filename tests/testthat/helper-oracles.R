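# Independent oracles used by the unit and acceptance tests.  Each is a
# deliberately different route to the same defined quantity as the
# implementation it checks.

oracle_revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTN", "TGCAN", x), "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# N50 by direct cumulative enumeration
oracle_n50 <- function(lens) {
  srt <- sort(lens, decreasing = TRUE)
  half <- sum(lens) / 2
  for (i in seq_along(srt)) if (sum(srt[1:i]) >= half) return(srt[i])
}

# In-silico digest: count overlapping IUPAC-site occurrences with
# Biostrings pattern matching (fixed = FALSE expands ambiguity codes).
oracle_site_count <- function(window, site) {
  Biostrings::countPattern(site, Biostrings::DNAString(window),
                           fixed = FALSE)
}

oracle_caps <- function(snp, genome, enzymes) {
  hits <- character(0)
  chrom <- genome[[snp$chrom]]
  for (i in seq_len(nrow(enzymes))) {
    m <- nchar(enzymes$site[i])
    lo <- snp$pos - (m - 1L); hi <- snp$pos + (m - 1L)
    if (lo < 1L || hi > nchar(chrom)) next
    wref <- substr(chrom, lo, hi)
    walt <- wref
    substr(walt, m, m) <- snp$alt
    if (oracle_site_count(wref, enzymes$site[i]) !=
        oracle_site_count(walt, enzymes$site[i]))
      hits <- c(hits, enzymes$name[i])
  }
  hits
}

# Full-CDS retranslation oracle for variant-effect calls (coding SNPs):
# rebuilds the entire mutant CDS, translates both proteins, and derives
# the term from the protein-level difference.
oracle_effect_snp <- function(site, gm_row, genome) {
  cd <- gm_row$cds[[1L]]
  chrom <- genome[[gm_row$seq_id]]
  mut <- chrom
  substr(mut, site$pos, site$pos) <- site$alt
  splice <- function(seqstr) {
    s <- paste(vapply(seq_len(nrow(cd)), function(j)
      substr(seqstr, cd[j, 1L], cd[j, 2L]), character(1)), collapse = "")
    if (gm_row$strand == "-") oracle_revcomp(s) else s
  }
  tr <- function(s) as.character(Biostrings::translate(Biostrings::DNAString(s)))
  cds_ref <- splice(chrom); cds_alt <- splice(mut)
  p_ref <- tr(cds_ref); p_alt <- tr(cds_alt)
  if (substr(cds_ref, 1L, 3L) == "ATG" && substr(cds_alt, 1L, 3L) != "ATG")
    return("start_lost")
  a_ref <- strsplit(p_ref, "")[[1L]]; a_alt <- strsplit(p_alt, "")[[1L]]
  changed <- which(a_ref != a_alt)
  if (length(changed) == 0L) return("synonymous_variant")
  i <- changed[1L]
  if (a_ref[i] == "*" && a_alt[i] != "*") return("stop_lost")
  if (a_ref[i] != "*" && a_alt[i] == "*") return("stop_gained")
  "missense_variant"
}

# Perfect-repeat oracle (mismatch penalty = Inf): maximal period-u runs
# found by direct character comparison s[i] == s[i - u].
oracle_perfect_ssrs <- function(seq, params) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cand <- list()
  for (u in params$unit_min:params$unit_max) {
    if (n < u * params$seed_repeats) next
    same <- c(rep(FALSE, u), ch[(u + 1L):n] == ch[1:(n - u)] &
                ch[(u + 1L):n] %in% c("A", "C", "G", "T"))
    i <- 1L
    while (i <= n - u) {
      if (all(ch[i:(i + u - 1L)] %in% c("A", "C", "G", "T")) &&
          all(same[(i + u):min(n, i + u * params$seed_repeats - 1L)]) &&
          i + u * params$seed_repeats - 1L <= n) {
        j <- i + u
        while (j <= n && same[j]) j <- j + 1L
        len <- j - i
        unit <- paste(ch[i:(i + u - 1L)], collapse = "")
        prim <- TRUE
        for (d in seq_len(u - 1L))
          if (u %% d == 0L &&
              unit == strrep(substr(unit, 1L, d), u %/% d)) prim <- FALSE
        if (prim && len >= u * params$seed_repeats &&
            len >= params$min_score) {
          cand[[length(cand) + 1L]] <- data.frame(
            start = i, end = i + len - 1L, unit_len = u, score = len,
            stringsAsFactors = FALSE)
        }
        i <- j - u + 1L
      } else i <- i + 1L
    }
  }
  if (!length(cand)) return(data.frame(start = integer(0), end = integer(0),
                                       unit_len = integer(0),
                                       score = numeric(0)))
  df <- unique(do.call(rbind, cand))
  df <- df[order(-df$score, df$unit_len, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df)); ts <- integer(0); te <- integer(0)
  for (i in seq_len(nrow(df))) {
    if (!any(df$start[i] <= te & df$end[i] >= ts)) {
      keep[i] <- TRUE; ts <- c(ts, df$start[i]); te <- c(te, df$end[i])
    }
  }
  df <- df[keep, , drop = FALSE]
  df[order(df$start), , drop = FALSE]
}

# Memoised-recursion scoring oracle for imperfect-SSR extension: the best
# achievable extension score walking `chars` with phased unit `uc`,
# mismatches costing `pen` and freeing the phase.
oracle_extension_score <- function(chars, uc, pen) {
  u <- length(uc)
  n <- length(chars)
  memo <- array(NA_real_, dim = c(n + 1L, u))
  rec <- function(t, p) {
    if (t > n) return(0)
    if (!is.na(memo[t, p])) return(memo[t, p])
    best <- 0                                  # stop here
    if (chars[t] == uc[p]) {
      q <- if (p == u) 1L else p + 1L
      best <- max(best, 1 + rec(t + 1L, q))
    }
    if (is.finite(pen)) {
      cont <- max(vapply(1:u, function(q) rec(t + 1L, q), numeric(1)))
      best <- max(best, -pen + cont)
    }
    memo[t, p] <<- best
    best
  }
  rec(1L, 1L)
}

# Nearest-neighbor Tm computed independently (tabulated over the ten
# unique duplex steps, complementing keys on lookup).
oracle_tm <- function(s, na_mM = 50, oligo_nM = 50) {
  dH10 <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS10 <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  n <- nchar(s)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1L)) {
    step <- substr(s, i, i + 1L)
    if (!step %in% names(dH10)) step <- oracle_revcomp(step)
    dh <- dh + dH10[[step]]; ds <- ds + dS10[[step]]
  }
  for (b in c(substr(s, 1L, 1L), substr(s, n, n))) {
    if (b %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  dh * 1000 / (ds + 1.987 * log(oligo_nM * 1e-9 / 4)) - 273.15 +
    16.6 * log10(na_mM / 1000)
}

# Exhaustive primer-pair oracle: enumerate every candidate pair, recheck
# every constraint with locally written predicates, and rank by the
# stated deterministic order.
oracle_primer_pair <- function(template, t_start, t_end, cons) {
  ok_primer <- function(p) {
    if (grepl("[^ACGT]", p)) return(FALSE)
    gc <- 100 * sum(strsplit(p, "")[[1L]] %in% c("G", "C")) / nchar(p)
    if (gc < cons$gc_min || gc > cons$gc_max) return(FALSE)
    runs <- rle(strsplit(p, "")[[1L]])$lengths
    if (max(runs) > cons$max_homo) return(FALSE)
    n <- nchar(p)
    five <- substr(p, n - 4L, n)
    if (substr(five, 1L, 2L) == oracle_revcomp(substr(five, 4L, 5L)))
      return(FALSE)
    tm <- oracle_tm(p)
    tm >= cons$tm_min && tm <= cons$tm_max
  }
  cands <- function(lo, hi, rev) {
    out <- list()
    if (hi < lo) return(out)
    for (len in cons$len_min:cons$len_max) {
      if (hi - lo + 1L < len) next
      for (s in lo:(hi - len + 1L)) {
        w <- substr(template, s, s + len - 1L)
        p <- if (rev) oracle_revcomp(w) else w
        if (ok_primer(p))
          out[[length(out) + 1L]] <- list(seq = p, start = s,
                                          end = s + len - 1L,
                                          tm = oracle_tm(p))
      }
    }
    out
  }
  lefts <- cands(1L, t_start - 1L, FALSE)
  rights <- cands(t_end + 1L, nchar(template), TRUE)
  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a[1L] < b[1L] - 1e-12) return(TRUE)
    if (a[1L] > b[1L] + 1e-12) return(FALSE)
    for (i in 2:4) {
      if (a[i] < b[i]) return(TRUE)
      if (a[i] > b[i]) return(FALSE)
    }
    FALSE
  }
  best <- NULL
  for (L in lefts) for (R in rights) {
    pl <- R$end - L$start + 1L
    if (pl < cons$product_min || pl > cons$product_max) next
    dtm <- abs(L$tm - R$tm)
    if (dtm > cons$max_dtm) next
    key <- c(dtm, pl, L$start, R$start)
    if (better(key, best$key)) best <- list(left = L, right = R, key = key)
  }
  best
}

# random sequence helper for property tests
rand_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Recursive (score, shortest-length) extension oracle: among all scored
# extension prefixes, the maximum score and the shortest prefix achieving
# it.
oracle_extension2 <- function(chars, uc, pen) {
  u <- length(uc); n <- length(chars)
  memo <- new.env(parent = emptyenv())
  rec <- function(t, p) {
    if (t > n) return(c(0, 0))
    key <- paste0(t, ":", p)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- c(0, 0)
    pick <- function(cand) {
      if (cand[1L] > best[1L] ||
          (cand[1L] == best[1L] && cand[2L] < best[2L])) best <<- cand
    }
    if (chars[t] == uc[p]) {
      q <- if (p == u) 1L else p + 1L
      r <- rec(t + 1L, q)
      pick(c(1 + r[1L], 1 + r[2L]))
    }
    if (is.finite(pen)) {
      sub <- c(-Inf, Inf)
      for (q in 1:u) {
        r <- rec(t + 1L, q)
        if (r[1L] > sub[1L] || (r[1L] == sub[1L] && r[2L] < sub[2L])) sub <- r
      }
      pick(c(-pen + sub[1L], 1 + sub[2L]))
    }
    memo[[key]] <- best
    best
  }
  rec(1L, 1L)
}

# Full SSR-locus oracle: seeds from direct character comparison, exact
# recursive extension, identical reporting and overlap-resolution rules.
oracle_ssr_loci <- function(seq, params) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  cand <- list()
  for (u in params$unit_min:params$unit_max) {
    if (n < u * params$seed_repeats) next
    i <- 1L
    while (i + u * params$seed_repeats - 1L <= n) {
      block <- ch[i:(i + u * params$seed_repeats - 1L)]
      is_seed <- all(block %in% c("A", "C", "G", "T")) &&
        all(block[(u + 1L):length(block)] == block[1:(length(block) - u)])
      if (!is_seed) { i <- i + 1L; next }
      unit <- paste(ch[i:(i + u - 1L)], collapse = "")
      prim <- TRUE
      for (d in seq_len(u - 1L))
        if (u %% d == 0L && unit == strrep(substr(unit, 1L, d), u %/% d))
          prim <- FALSE
      if (!prim) { i <- i + 1L; next }
      # grow the perfect whole-copy seed
      e <- i + u * params$seed_repeats - 1L
      while (e + u <= n &&
             all(ch[(e + 1L):(e + u)] == ch[(e + 1L - u):e]) &&
             all(ch[(e + 1L):(e + u)] %in% c("A", "C", "G", "T")))
        e <- e + u
      uc <- strsplit(unit, "", fixed = TRUE)[[1L]]
      rt <- if (e < n) oracle_extension2(ch[(e + 1L):n], uc,
                                         params$mismatch_penalty) else c(0, 0)
      lt <- if (i > 1L) oracle_extension2(ch[(i - 1L):1L], rev(uc),
                                          params$mismatch_penalty) else c(0, 0)
      score <- (e - i + 1L) + rt[1L] + lt[1L]
      if (score >= params$min_score) {
        start <- as.integer(i - lt[2L]); end <- as.integer(e + rt[2L])
        span <- end - start + 1L
        nm <- if (is.finite(params$mismatch_penalty))
          as.integer(round((span - score) / (1 + params$mismatch_penalty)))
        else 0L
        cand[[length(cand) + 1L]] <- data.frame(
          start = start, end = end, unit = unit,
          canonical_motif = canonical_motif(unit), unit_len = u,
          score = score, n_mismatches = nm, stringsAsFactors = FALSE)
      }
      i <- e - u + 2L   # past this perfect run
    }
  }
  if (!length(cand))
    return(data.frame(start = integer(0), end = integer(0),
                      unit_len = integer(0), score = numeric(0),
                      n_mismatches = integer(0)))
  df <- unique(do.call(rbind, cand))
  df <- df[order(-df$score, df$unit_len, df$start), , drop = FALSE]
  keep <- rep(FALSE, nrow(df)); ts <- integer(0); te <- integer(0)
  for (k in seq_len(nrow(df))) {
    if (!any(df$start[k] <= te & df$end[k] >= ts)) {
      keep[k] <- TRUE; ts <- c(ts, df$start[k]); te <- c(te, df$end[k])
    }
  }
  df <- df[keep, , drop = FALSE]
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  df
}
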