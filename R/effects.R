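IMPACT_OF <- c(
  stop_gained = "HIGH", stop_lost = "HIGH", start_lost = "HIGH",
  frameshift_variant = "HIGH",
  missense_variant = "MODERATE", inframe_insertion = "MODERATE",
  inframe_deletion = "MODERATE",
  synonymous_variant = "LOW",
  intron_variant = "MODIFIER", intergenic_variant = "MODIFIER",
  noncoding_exon_variant = "MODIFIER")

IMPACT_RANK <- c(HIGH = 4L, MODERATE = 3L, LOW = 2L, MODIFIER = 1L)

#' Map a sequence-ontology term to its impact category
#' @param so_term Character vector of SO terms.
#' @return Character vector of \code{HIGH}/\code{MODERATE}/\code{LOW}/
#'   \code{MODIFIER}.
#' @export
impact_of <- function(so_term) {
  out <- unname(IMPACT_OF[so_term])
  if (any(is.na(out))) stop("unknown SO term: ",
                            paste(so_term[is.na(out)], collapse = ", "))
  out
}

# spliced CDS nucleotide sequence of one gene-model row (5'->3' of the
# coding strand)
cds_sequence <- function(gm_row, genome) {
  cd <- gm_row$cds[[1L]]
  chrom <- genome[[gm_row$seq_id]]
  segs <- vapply(seq_len(nrow(cd)), function(j)
    substr(chrom, cd[j, 1L], cd[j, 2L]), character(1))
  s <- paste(segs, collapse = "")
  if (gm_row$strand == "-") s <- revcomp(s)
  s
}

# position within the spliced CDS (1-based, coding-strand) of a genomic
# coordinate, or NA if not in CDS
cds_position <- function(gm_row, pos) {
  cd <- gm_row$cds[[1L]]
  total <- sum(cd[, 2L] - cd[, 1L] + 1L)
  off <- 0L
  for (j in seq_len(nrow(cd))) {
    if (pos >= cd[j, 1L] && pos <= cd[j, 2L]) {
      p_fwd <- off + (pos - cd[j, 1L] + 1L)
      return(if (gm_row$strand == "+") p_fwd else total - p_fwd + 1L)
    }
    off <- off + (cd[j, 2L] - cd[j, 1L] + 1L)
  }
  NA_integer_
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) "X" else aa
}

classify_one_gene <- function(site, gm_row, genome) {
  ref_span <- c(site$pos, site$pos + nchar(site$ref) - 1L)
  cd <- gm_row$cds[[1L]]
  in_cds <- nrow(cd) > 0L &&
    any(ref_span[2L] >= cd[, 1L] & ref_span[1L] <= cd[, 2L])
  if (in_cds) {
    if (nchar(site$ref) == 1L && nchar(site$alt) == 1L) {
      cp <- cds_position(gm_row, site$pos)
      cds_seq <- cds_sequence(gm_row, genome)
      codon_i <- (cp - 1L) %/% 3L
      codon <- substr(cds_seq, codon_i * 3L + 1L, codon_i * 3L + 3L)
      within <- (cp - 1L) %% 3L + 1L
      alt_base <- if (gm_row$strand == "+") site$alt else revcomp(site$alt)
      alt_codon <- codon
      substr(alt_codon, within, within) <- alt_base
      ref_aa <- translate_codon(codon)
      alt_aa <- translate_codon(alt_codon)
      term <-
        if (codon_i == 0L && codon == "ATG" && alt_codon != "ATG") "start_lost"
        else if (ref_aa == "*" && alt_aa != "*") "stop_lost"
        else if (ref_aa != "*" && alt_aa == "*") "stop_gained"
        else if (ref_aa == alt_aa) "synonymous_variant"
        else "missense_variant"
      return(term)
    }
    d <- nchar(site$ref) - nchar(site$alt)
    if (d %% 3L != 0L) return("frameshift_variant")
    return(if (d > 0L) "inframe_deletion" else "inframe_insertion")
  }
  ex <- gm_row$exons[[1L]]
  in_exon <- nrow(ex) > 0L &&
    any(ref_span[2L] >= ex[, 1L] & ref_span[1L] <= ex[, 2L])
  if (!in_exon) return("intron_variant")
  "noncoding_exon_variant"
}

#' Classify the functional effect of one variant
#'
#' Feature precedence when a variant overlaps several annotations:
#' CDS > intron > non-coding exon > intergenic.  Coding SNPs are resolved
#' by translating the reference and alternate codons (standard genetic
#' code, strand-aware): start-codon disruption, stop gain/loss, synonymous
#' or missense.  Coding indels are frameshift when the length difference is
#' not a multiple of three, otherwise in-frame insertions/deletions.  When
#' a variant overlaps several genes the most severe call wins, ties broken
#' by gene id.
#'
#' @param site One-row data frame (or list) with \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} -- normalised, biallelic.
#' @param gene_models A \code{gene_models} data.frame.
#' @param genome Named character vector of sequences.
#' @return List with \code{so_term}, \code{impact} and \code{gene_id}
#'   (\code{NA} for intergenic calls).
#' @export
classify_effect <- function(site, gene_models, genome) {
  if (is.null(genome[[site$chrom]])) stop("unknown sequence: ", site$chrom)
  if (site$pos + nchar(site$ref) - 1L > nchar(genome[[site$chrom]]))
    stop("variant beyond end of ", site$chrom)
  span <- c(site$pos, site$pos + nchar(site$ref) - 1L)
  gm <- gene_models[gene_models$seq_id == site$chrom &
                      gene_models$end >= span[1L] &
                      gene_models$start <= span[2L], , drop = FALSE]
  if (nrow(gm) == 0L)
    return(list(so_term = "intergenic_variant", impact = "MODIFIER",
                gene_id = NA_character_))
  terms <- vapply(seq_len(nrow(gm)), function(i)
    classify_one_gene(site, gm[i, , drop = FALSE], genome), character(1))
  sev <- IMPACT_RANK[impact_of(terms)]
  o <- order(-sev, gm$gene_id)
  best <- o[1L]
  list(so_term = terms[best], impact = unname(impact_of(terms[best])),
       gene_id = gm$gene_id[best])
}

#' Classify every variant in a set
#'
#' @param vs A normalised biallelic \code{variant_set}.
#' @inheritParams classify_effect
#' @return Data frame with one row per variant: \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt}, \code{so_term}, \code{impact},
#'   \code{gene_id}.
#' @export
classify_effects <- function(vs, gene_models, genome) {
  n <- n_variants(vs)
  res <- vector("list", n)
  for (i in seq_len(n)) {
    site <- vs$sites[i, , drop = FALSE]
    res[[i]] <- classify_effect(site, gene_models, genome)
  }
  data.frame(chrom = vs$sites$chrom, pos = vs$sites$pos, ref = vs$sites$ref,
             alt = vs$sites$alt,
             so_term = vapply(res, `[[`, character(1), "so_term"),
             impact = vapply(res, `[[`, character(1), "impact"),
             gene_id = vapply(res, `[[`, character(1), "gene_id"),
             stringsAsFactors = FALSE)
}
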