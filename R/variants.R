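#' Construct a variant set
#'
#' The in-memory container for VCF-style variants: a site table plus
#' per-sample genotype (GT), depth (DP) and genotype-quality (GQ) matrices
#' with one row per site.
#'
#' @param sites Data frame with columns \code{chrom}, \code{pos} (1-based),
#'   \code{ref}, \code{alt} (comma-separated for multi-allelic sites),
#'   \code{qual}; optional \code{id}, \code{filter}.
#' @param gt Character matrix of genotypes (\code{"0/1"}, \code{"./."}
#'   ...), or \code{NULL} for site-only sets.
#' @param dp,gq Numeric matrices aligned with \code{gt}, or \code{NULL}.
#' @return An object of class \code{variant_set}.
#' @export
variant_set <- function(sites, gt = NULL, dp = NULL, gq = NULL) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "qual") %in% names(sites)))
  if (any(sites$pos < 1)) stop("positions must be 1-based (>= 1)")
  if (any(!grepl("^[ACGT]+$", sites$ref))) stop("ref alleles must be over ACGT")
  if (any(sites$alt == sites$ref)) stop("alt allele equal to ref")
  if (is.null(sites$id)) sites$id <- "."
  if (is.null(sites$filter)) sites$filter <- "."
  n <- nrow(sites)
  for (m in list(gt, dp, gq))
    if (!is.null(m) && nrow(m) != n) stop("genotype matrix row mismatch")
  structure(list(sites = sites, gt = gt, dp = dp, gq = gq,
                 samples = if (is.null(gt)) character(0) else colnames(gt)),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant set: %d site(s), %d sample(s)\n",
              nrow(x$sites), length(x$samples)))
  invisible(x)
}

n_variants <- function(vs) nrow(vs$sites)

subset_variants <- function(vs, idx) {
  variant_set(vs$sites[idx, , drop = FALSE],
              gt = if (!is.null(vs$gt)) vs$gt[idx, , drop = FALSE],
              dp = if (!is.null(vs$dp)) vs$dp[idx, , drop = FALSE],
              gq = if (!is.null(vs$gq)) vs$gq[idx, , drop = FALSE])
}

#' Read a VCF file into a [variant_set()]
#'
#' @param path Path to a VCF (plain or bgzipped).
#' @return A \code{variant_set}.
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF not found: ", path)
  v <- VariantAnnotation::readVcf(path, genome = "unknown")
  rr <- SummarizedExperiment::rowRanges(v)
  alt <- vapply(VariantAnnotation::alt(v), function(a)
    paste(as.character(a), collapse = ","), character(1))
  sites <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    id = names(rr) %||% ".",
    ref = as.character(VariantAnnotation::ref(v)),
    alt = alt,
    qual = as.numeric(VariantAnnotation::qual(v)),
    filter = as.character(VariantAnnotation::filt(v)),
    stringsAsFactors = FALSE)
  rownames(sites) <- NULL
  g <- VariantAnnotation::geno(v)
  grab <- function(name, as_num = TRUE) {
    if (!name %in% names(g)) return(NULL)
    m <- g[[name]]
    if (as_num) storage.mode(m) <- "numeric"
    m
  }
  gt <- grab("GT", as_num = FALSE)
  variant_set(sites, gt = gt, dp = grab("DP"), gq = grab("GQ"))
}

#' Write a [variant_set()] as VCF 4.2
#' @param vs A \code{variant_set}.
#' @param path Output path.
#' @export
write_vcf <- function(vs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=anchorage",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           '##FORMAT=<ID=GQ,Number=1,Type=Integer,Description="Genotype quality">')
  cols <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  has_geno <- !is.null(vs$gt)
  if (has_geno) cols <- c(cols, "FORMAT", vs$samples)
  writeLines(c(hdr, paste(cols, collapse = "\t")), con)
  n <- n_variants(vs)
  if (n == 0L) return(invisible(path))
  fixed <- paste(vs$sites$chrom, vs$sites$pos, vs$sites$id, vs$sites$ref,
                 vs$sites$alt,
                 ifelse(is.na(vs$sites$qual), ".", vs$sites$qual),
                 vs$sites$filter, ".", sep = "\t")
  if (has_geno) {
    fmt <- "GT:DP:GQ"
    geno <- apply(cbind(seq_len(n)), 1L, function(i) {
      paste(paste(vs$gt[i, ],
                  ifelse(is.na(vs$dp[i, ]), ".", vs$dp[i, ]),
                  ifelse(is.na(vs$gq[i, ]), ".", vs$gq[i, ]), sep = ":"),
            collapse = "\t")
    })
    fixed <- paste(fixed, fmt, geno, sep = "\t")
  }
  writeLines(fixed, con)
  invisible(path)
}

#' Split multi-allelic sites into biallelic records
#'
#' Each alternate allele becomes its own record.  Genotype allele codes are
#' recoded against the extracted allele: the matching alt becomes \code{1},
#' the reference stays \code{0}, and calls to any other alt become missing
#' (\code{.}).
#'
#' @param vs A \code{variant_set}.
#' @return A biallelic \code{variant_set}.
#' @export
split_multiallelic <- function(vs) {
  alts <- strsplit(vs$sites$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  if (all(n_alt == 1L)) return(vs)
  idx <- rep(seq_len(n_variants(vs)), n_alt)
  which_alt <- unlist(lapply(n_alt, seq_len))
  sites <- vs$sites[idx, , drop = FALSE]
  sites$alt <- unlist(alts)
  gt <- vs$gt
  if (!is.null(gt)) {
    gt <- gt[idx, , drop = FALSE]
    for (r in seq_len(nrow(gt))) {
      a <- which_alt[r]
      gt[r, ] <- vapply(gt[r, ], function(g) {
        if (is.na(g) || g %in% c(".", "./.", ".|.")) return("./.")
        sep <- if (grepl("|", g, fixed = TRUE)) "|" else "/"
        al <- strsplit(g, "[/|]")[[1L]]
        al <- vapply(al, function(x) {
          if (x == ".") "." else if (x == "0") "0"
          else if (x == as.character(a)) "1" else "."
        }, character(1))
        paste(al, collapse = sep)
      }, character(1))
    }
  }
  rownames(sites) <- NULL
  variant_set(sites, gt = gt,
              dp = if (!is.null(vs$dp)) vs$dp[idx, , drop = FALSE],
              gq = if (!is.null(vs$gq)) vs$gq[idx, , drop = FALSE])
}

#' Normalise variants to minimal left-anchored representation
#'
#' Trims shared trailing then leading bases from ref/alt (always keeping at
#' least one base of each), adjusting \code{pos} for leading trims.
#'
#' @param vs A biallelic \code{variant_set}.
#' @return A \code{variant_set}.
#' @export
normalize_variants <- function(vs) {
  s <- vs$sites
  for (i in seq_len(nrow(s))) {
    r <- s$ref[i]; a <- s$alt[i]; p <- s$pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L); a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    s$ref[i] <- r; s$alt[i] <- a; s$pos[i] <- p
  }
  vs$sites <- s
  vs
}

is_snp <- function(vs) nchar(vs$sites$ref) == 1L & nchar(vs$sites$alt) == 1L

indel_len <- function(vs) abs(nchar(vs$sites$ref) - nchar(vs$sites$alt))

#' Hard-filter parameter presets
#'
#' \code{filter_params()} builds a parameter list; the two presets mirror
#' common reduced-representation (ddRAD) and whole-genome-resequencing
#' pipelines.  The ddRAD preset uses a strict \code{>} on site quality
#' (quality value must exceed 10); the resequencing preset uses \code{>=}
#' thresholds in line with VCFtools semantics.
#'
#' @param min_dp Minimum per-sample depth (every genotyped sample).
#' @param max_dp Optional maximum per-sample depth.
#' @param min_site_q Minimum site QUAL.
#' @param site_q_strict If \code{TRUE}, QUAL must be strictly greater than
#'   \code{min_site_q}.
#' @param min_gq Optional minimum per-sample genotype quality.
#' @param min_maf Optional minimum minor-allele frequency over called
#'   alleles.
#' @param max_missing_rate Optional strict upper bound on the fraction of
#'   samples with missing genotypes.
#' @return A list of class \code{filter_params}.
#' @export
filter_params <- function(min_dp = 0, max_dp = NULL, min_site_q = 0,
                          site_q_strict = FALSE, min_gq = NULL,
                          min_maf = NULL, max_missing_rate = NULL) {
  stopifnot(min_dp >= 0)
  if (!is.null(max_dp)) stopifnot(max_dp >= min_dp)
  if (!is.null(min_maf)) stopifnot(min_maf >= 0, min_maf <= 0.5)
  if (!is.null(max_missing_rate))
    stopifnot(max_missing_rate >= 0, max_missing_rate <= 1)
  structure(list(min_dp = min_dp, max_dp = max_dp, min_site_q = min_site_q,
                 site_q_strict = site_q_strict, min_gq = min_gq,
                 min_maf = min_maf, max_missing_rate = max_missing_rate),
            class = "filter_params")
}

#' @rdname filter_params
#' @export
filter_params_ddrad <- function() {
  filter_params(min_dp = 5, min_site_q = 10, site_q_strict = TRUE,
                min_maf = 0.2, max_missing_rate = 0.5)
}

#' @rdname filter_params
#' @export
filter_params_reseq <- function() {
  filter_params(min_dp = 10, max_dp = 100, min_site_q = 50,
                site_q_strict = FALSE, min_gq = 20)
}

#' Hard-filter a variant set
#'
#' A site passes when its QUAL clears the quality threshold, every
#' genotyped sample satisfies the DP bounds and the GQ floor, the missing
#' rate is strictly below the cap, and the minor-allele frequency over
#' called alleles clears the floor.  Rejections are counted against the
#' first failing criterion in the fixed order quality, depth, GQ, missing,
#' MAF.
#'
#' @param vs A \code{variant_set}.
#' @param params A [filter_params()] list.
#' @return List with \code{pass} (a \code{variant_set}),
#'   \code{rejections} (named count vector) and \code{fail} (the rejected
#'   \code{variant_set} with \code{filter} annotated with the failed
#'   criterion).
#' @export
hard_filter <- function(vs, params) {
  stopifnot(inherits(vs, "variant_set"), inherits(params, "filter_params"))
  n <- n_variants(vs)
  need_geno <- params$min_dp > 0 || !is.null(params$max_dp) ||
    !is.null(params$min_gq) || !is.null(params$min_maf) ||
    !is.null(params$max_missing_rate)
  if (need_geno && is.null(vs$gt))
    stop("filter requires genotype field GT but the VCF has none")
  if ((params$min_dp > 0 || !is.null(params$max_dp)) && is.null(vs$dp))
    stop("filter requires genotype field DP but the VCF has none")
  if (!is.null(params$min_gq) && is.null(vs$gq))
    stop("filter requires genotype field GQ but the VCF has none")

  called <- if (!is.null(vs$gt)) !apply(vs$gt, 2L, grepl, pattern = "\\.")
  if (!is.null(called) && n == 1L) called <- matrix(called, nrow = 1L)
  fail_as <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    q <- vs$sites$qual[i]
    ok_q <- if (params$site_q_strict) isTRUE(q > params$min_site_q)
            else isTRUE(q >= params$min_site_q)
    if (!ok_q) { fail_as[i] <- "quality"; next }
    cal <- if (!is.null(vs$gt)) called[i, ] else logical(0)
    if (params$min_dp > 0 || !is.null(params$max_dp)) {
      dp <- vs$dp[i, cal]
      bad <- any(is.na(dp)) || any(dp < params$min_dp) ||
        (!is.null(params$max_dp) && any(dp > params$max_dp))
      if (any(cal) && bad) { fail_as[i] <- "depth"; next }
    }
    if (!is.null(params$min_gq)) {
      gq <- vs$gq[i, cal]
      if (any(cal) && (any(is.na(gq)) || any(gq < params$min_gq))) {
        fail_as[i] <- "gq"; next
      }
    }
    if (!is.null(params$max_missing_rate)) {
      miss <- mean(!called[i, ])
      if (!(miss < params$max_missing_rate)) { fail_as[i] <- "missing"; next }
    }
    if (!is.null(params$min_maf)) {
      al <- unlist(strsplit(vs$gt[i, ], "[/|]"))
      al <- al[al != "."]
      if (length(al) == 0L) { fail_as[i] <- "maf"; next }
      f <- mean(al != "0")
      if (min(f, 1 - f) < params$min_maf) { fail_as[i] <- "maf"; next }
    }
  }
  crits <- c("quality", "depth", "gq", "missing", "maf")
  rej <- setNames(vapply(crits, function(cr)
    sum(fail_as == cr, na.rm = TRUE), numeric(1)), crits)
  pass <- is.na(fail_as)
  fail <- subset_variants(vs, !pass)
  fail$sites$filter <- fail_as[!pass]
  list(pass = subset_variants(vs, pass), rejections = rej, fail = fail)
}

#' Substitution spectrum and Ts/Tv ratio of biallelic SNPs
#'
#' Counts fall into the six direction-collapsed substitution classes
#' (unordered base pairs): transitions A/G and C/T, transversions A/C,
#' A/T, C/G and G/T.
#'
#' @param vs A biallelic \code{variant_set} (non-SNPs are ignored).
#' @return List with \code{classes} (named count vector), \code{ts},
#'   \code{tv} and \code{ts_tv}.
#' @export
substitution_spectrum <- function(vs) {
  snp <- subset_variants(vs, is_snp(vs))
  cls <- c("A/G", "C/T", "A/C", "A/T", "C/G", "G/T")
  counts <- setNames(numeric(6), cls)
  if (n_variants(snp) > 0L) {
    pair <- paste(pmin(snp$sites$ref, snp$sites$alt),
                  pmax(snp$sites$ref, snp$sites$alt), sep = "/")
    tb <- table(pair)
    counts[names(tb)] <- as.numeric(tb)
  }
  ts <- sum(counts[c("A/G", "C/T")])
  tv <- sum(counts[c("A/C", "A/T", "C/G", "G/T")])
  ratio <- if (tv == 0) {
    warning(if (ts == 0) "no SNPs: Ts/Tv undefined" else
      "zero transversions: Ts/Tv reported as Inf")
    if (ts == 0) NA_real_ else Inf
  } else ts / tv
  list(classes = counts, ts = ts, tv = tv, ts_tv = ratio)
}

#' Variant density per window of sequence
#'
#' Density = count x per_bp / denominator.  The conventional denominator is
#' the assembly's non-N length (total length minus the N count), so gaps do
#' not dilute the density.
#'
#' @param variant_count Number of variants.
#' @param non_n_length_bp Denominator length in bp (must be > 0).
#' @param per_bp Window size (default 100 kb).
#' @return Density (full precision; round to one decimal for reporting).
#' @export
variant_density <- function(variant_count, non_n_length_bp, per_bp = 1e5) {
  stopifnot(non_n_length_bp > 0)
  variant_count * per_bp / non_n_length_bp
}

#' Per-sample heterozygosity summary
#'
#' A site is heterozygous for a sample when its two called alleles differ.
#' Per-chromosome counts (and densities per 100 kb when chromosome lengths
#' are supplied) support the scan for low-heterozygosity chromosomes.
#'
#' @param vs A \code{variant_set} with genotypes.
#' @param chrom_lengths Optional named vector of (non-N) chromosome
#'   lengths for densities.
#' @return List with \code{per_sample} (named het-site counts) and
#'   \code{per_chrom} (data.frame chrom x sample counts, plus densities
#'   when lengths are given).
#' @export
heterozygosity_summary <- function(vs, chrom_lengths = NULL) {
  if (is.null(vs$gt)) stop("heterozygosity_summary() needs genotypes")
  al <- strsplit(vs$gt, "[/|]")           # column-major over the matrix
  if (any(lengths(al) == 1L & unlist(lapply(al, `[`, 1L)) != "."))
    stop("haploid genotype encountered")
  het <- matrix(vapply(al, function(a)
    length(a) == 2L && a[1L] != "." && a[2L] != "." && a[1L] != a[2L],
    logical(1)), nrow = n_variants(vs), dimnames = dimnames(vs$gt))
  per_sample <- colSums(het)
  agg <- stats::aggregate(het, by = list(chrom = vs$sites$chrom), FUN = sum)
  if (!is.null(chrom_lengths)) {
    for (s in vs$samples)
      agg[[paste0(s, "_per100kb")]] <-
        round(agg[[s]] * 1e5 / unname(chrom_lengths[agg$chrom]), 1)
  }
  list(per_sample = per_sample, per_chrom = agg)
}
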