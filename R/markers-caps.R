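IUPAC_CLASS <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
                 K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
                 H = "[ACT]", V = "[ACG]", N = "[ACGT]")

iupac_regex <- function(site) {
  paste(IUPAC_CLASS[strsplit(toupper(site), "")[[1L]]], collapse = "")
}

# overlapping occurrence count of an IUPAC site on the forward strand
count_sites <- function(seq, site) {
  m <- gregexpr(paste0("(?=", iupac_regex(site), ")"), seq, perl = TRUE)[[1L]]
  if (m[1L] == -1L) 0L else length(m)
}

#' The built-in restriction-enzyme table for CAPS design
#'
#' Nineteen common enzymes with 4-6 bp palindromic recognition sites, the
#' classical low-cost panel for cleaved-amplified-polymorphic-sequence
#' genotyping.  Palindromicity is asserted at load time; with palindromic
#' sites, counting occurrences on the forward strand alone is sufficient.
#'
#' @param path Optional TSV (columns \code{name}, \code{site}) overriding
#'   the built-in table.
#' @return Data frame with columns \code{name} and \code{site}.
#' @export
caps_enzymes <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "anchorage")
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "site") %in% names(df)))
  if (!all(df$site == revcomp(df$site)))
    stop("non-palindromic recognition site(s): ",
         paste(df$name[df$site != revcomp(df$site)], collapse = ", "))
  df
}

#' Test whether a SNP is a CAPS candidate for each enzyme
#'
#' For each enzyme a window of length \code{2*(site length - 1) + 1}
#' centred on the SNP is extracted for both alleles and the recognition
#' site occurrences are counted on the forward strand (sufficient because
#' the sites are palindromic).  The enzyme qualifies when the two allelic
#' counts differ.  Enzymes whose window would run past a sequence end are
#' skipped and listed in the \code{"skipped"} attribute.
#'
#' @param snp List or one-row data frame with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (single-base alleles).
#' @param genome Named character vector of sequences.
#' @param enzymes Data frame from [caps_enzymes()].
#' @return Character vector of qualifying enzyme names.
#' @export
caps_scan <- function(snp, genome, enzymes = caps_enzymes()) {
  stopifnot(nchar(snp$ref) == 1L, nchar(snp$alt) == 1L)
  chrom <- genome[[snp$chrom]]
  if (is.null(chrom)) stop("unknown sequence: ", snp$chrom)
  if (substr(chrom, snp$pos, snp$pos) != snp$ref)
    stop("reference allele mismatch at ", snp$chrom, ":", snp$pos)
  hits <- character(0); skipped <- character(0)
  for (i in seq_len(nrow(enzymes))) {
    m <- nchar(enzymes$site[i])
    lo <- snp$pos - (m - 1L); hi <- snp$pos + (m - 1L)
    if (lo < 1L || hi > nchar(chrom)) { skipped <- c(skipped, enzymes$name[i]); next }
    win_ref <- substr(chrom, lo, hi)
    win_alt <- win_ref
    substr(win_alt, m, m) <- snp$alt
    if (count_sites(win_ref, enzymes$site[i]) !=
        count_sites(win_alt, enzymes$site[i]))
      hits <- c(hits, enzymes$name[i])
  }
  attr(hits, "skipped") <- skipped
  hits
}

#' Select indel markers from a variant set
#'
#' Keeps indels whose ref/alt length difference is between 1 and
#' \code{max_len} bp; SNPs and longer events are excluded.
#'
#' @param vs A normalised biallelic \code{variant_set}.
#' @param max_len Maximum length difference (default 15).
#' @return A \code{variant_set} of selected indels.
#' @export
select_indel_markers <- function(vs, max_len = 15L) {
  d <- indel_len(vs)
  subset_variants(vs, d >= 1L & d <= max_len)
}
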