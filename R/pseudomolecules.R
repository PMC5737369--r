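#' Concatenate scaffolds into pseudomolecule sequences plus AGP
#'
#' Consecutive scaffolds are separated by exactly \code{layout$spacer_len}
#' Ns (no leading or trailing spacer); minus-oriented scaffolds are
#' reverse-complemented.  The AGP (v2.1) alternates component (\code{W})
#' and gap (\code{U}, \code{gap_type contig}, \code{linkage no}) rows in
#' 1-based inclusive coordinates.
#'
#' @param layout A [build_layout()] result.
#' @param scaffolds Named character vector of scaffold sequences.
#' @return List with \code{seqs} (named character vector of
#'   pseudomolecules), \code{agp} (data.frame with the nine AGP columns)
#'   and \code{unplaced} (ids of scaffolds absent from the layout).
#' @export
build_pseudomolecules <- function(layout, scaffolds) {
  stopifnot(inherits(layout, "pseudomolecule_layout"))
  spacer <- strrep("N", layout$spacer_len)
  seqs <- character(0)
  agp <- list()
  for (chr in names(layout$chromosomes)) {
    lay <- layout$chromosomes[[chr]]
    if (nrow(lay) == 0L) { warning("empty chromosome: ", chr); next }
    missing <- setdiff(lay$scaffold_id, names(scaffolds))
    if (length(missing))
      stop("missing scaffold sequence(s): ", paste(missing, collapse = ", "))
    pieces <- character(nrow(lay))
    pos <- 0L; part <- 0L
    for (i in seq_len(nrow(lay))) {
      sc <- lay$scaffold_id[i]
      s <- scaffolds[[sc]]
      if (lay$orientation[i] == "-") s <- revcomp(s)
      if (i > 1L && layout$spacer_len > 0L) {
        part <- part + 1L
        agp[[length(agp) + 1L]] <- data.frame(
          object = chr, object_beg = pos + 1L,
          object_end = pos + layout$spacer_len, part_number = part,
          component_type = "U", component_id = layout$spacer_len,
          component_beg = "contig", component_end = "no", orientation = "na",
          stringsAsFactors = FALSE)
        pos <- pos + layout$spacer_len
      }
      part <- part + 1L
      agp[[length(agp) + 1L]] <- data.frame(
        object = chr, object_beg = pos + 1L, object_end = pos + nchar(s),
        part_number = part, component_type = "W", component_id = sc,
        component_beg = "1", component_end = as.character(nchar(scaffolds[[sc]])),
        orientation = lay$orientation[i], stringsAsFactors = FALSE)
      pos <- pos + nchar(s)
      pieces[i] <- s
    }
    seqs[[chr]] <- paste(pieces, collapse = spacer)
  }
  placed <- unlist(lapply(layout$chromosomes, `[[`, "scaffold_id"))
  list(seqs = seqs,
       agp = if (length(agp)) do.call(rbind, agp) else NULL,
       unplaced = setdiff(names(scaffolds), placed))
}

#' Write an AGP v2.1 file
#' @param agp AGP data.frame from [build_pseudomolecules()].
#' @param path Output path.
#' @export
write_agp <- function(agp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##agp-version\t2.1", con)
  write.table(agp, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read an AGP file written by [write_agp()]
#' @param path Input path.
#' @export
read_agp <- function(path) {
  df <- read.delim(path, header = FALSE, comment.char = "#",
                   stringsAsFactors = FALSE,
                   col.names = c("object", "object_beg", "object_end",
                                 "part_number", "component_type",
                                 "component_id", "component_beg",
                                 "component_end", "orientation"))
  df$component_id <- as.character(df$component_id)
  df
}

#' Rebuild pseudomolecule sequences from AGP plus scaffolds
#'
#' The inverse of [build_pseudomolecules()]; used for the AGP round-trip
#' identity.
#'
#' @param agp AGP data.frame.
#' @param scaffolds Named character vector of scaffold sequences.
#' @return Named character vector of pseudomolecule sequences.
#' @export
agp_to_fasta <- function(agp, scaffolds) {
  out <- character(0)
  for (chr in unique(agp$object)) {
    rows <- agp[agp$object == chr, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    pieces <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      if (rows$component_type[i] %in% c("U", "N")) {
        pieces[i] <- strrep("N", as.integer(rows$component_id[i]))
      } else {
        s <- scaffolds[[rows$component_id[i]]]
        if (is.null(s)) stop("missing scaffold: ", rows$component_id[i])
        s <- substr(s, as.integer(rows$component_beg[i]),
                    as.integer(rows$component_end[i]))
        if (rows$orientation[i] == "-") s <- revcomp(s)
        pieces[i] <- s
      }
    }
    out[[chr]] <- paste(pieces, collapse = "")
  }
  out
}

# offsets (0-based) and oriented lengths of each scaffold inside the
# pseudomolecules, derived from the layout
layout_offsets <- function(layout, scaffolds) {
  res <- list()
  for (chr in names(layout$chromosomes)) {
    lay <- layout$chromosomes[[chr]]
    pos <- 0L
    for (i in seq_len(nrow(lay))) {
      sc <- lay$scaffold_id[i]
      L <- nchar(scaffolds[[sc]])
      res[[sc]] <- list(chrom = chr, offset = pos, len = L,
                        orientation = lay$orientation[i])
      pos <- pos + L + if (i < nrow(lay)) layout$spacer_len else 0L
    }
  }
  res
}

# lift one interval (1-based inclusive, with strand) from scaffold to
# pseudomolecule coordinates
lift_interval <- function(off, start, end, strand = "+") {
  if (off$orientation == "+") {
    list(start = off$offset + start, end = off$offset + end, strand = strand)
  } else {
    list(start = off$offset + off$len - end + 1L,
         end = off$offset + off$len - start + 1L,
         strand = if (strand == "+") "-" else "+")
  }
}

#' Lift gene models from scaffold to pseudomolecule coordinates
#'
#' Coordinates shift by the scaffold's offset; on minus-oriented scaffolds
#' intervals are mirrored and strands flipped.  Genes on unplaced
#' scaffolds are returned unchanged in the \code{"unlifted"} attribute.
#'
#' @param layout A [build_layout()] result.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param gene_models \code{gene_models} in scaffold coordinates.
#' @return \code{gene_models} in pseudomolecule coordinates.
#' @export
lift_gene_models <- function(layout, scaffolds, gene_models) {
  offs <- layout_offsets(layout, scaffolds)
  keep <- gene_models$seq_id %in% names(offs)
  gm <- gene_models[keep, , drop = FALSE]
  for (i in seq_len(nrow(gm))) {
    off <- offs[[gm$seq_id[i]]]
    li <- lift_interval(off, gm$start[i], gm$end[i], gm$strand[i])
    seg_lift <- function(m) {
      if (nrow(m) == 0L) return(m)
      res <- t(apply(m, 1L, function(r) {
        x <- lift_interval(off, r[[1L]], r[[2L]])
        c(x$start, x$end)
      }))
      res <- res[order(res[, 1L]), , drop = FALSE]
      colnames(res) <- c("start", "end")
      res
    }
    gm$cds[[i]] <- seg_lift(gm$cds[[i]])
    gm$exons[[i]] <- seg_lift(gm$exons[[i]])
    gm$start[i] <- li$start; gm$end[i] <- li$end; gm$strand[i] <- li$strand
    gm$seq_id[i] <- off$chrom
  }
  attr(gm, "unlifted") <- gene_models$gene_id[!keep]
  gm
}

#' Lift genetic-map loci to pseudomolecule coordinates
#' @inheritParams lift_gene_models
#' @param map_loci Data frame from [read_genetic_map()].
#' @export
lift_map <- function(layout, scaffolds, map_loci) {
  offs <- layout_offsets(layout, scaffolds)
  keep <- !is.na(map_loci$scaffold_id) & map_loci$scaffold_id %in% names(offs)
  mp <- map_loci[keep, , drop = FALSE]
  for (i in seq_len(nrow(mp))) {
    off <- offs[[mp$scaffold_id[i]]]
    li <- lift_interval(off, mp$position_bp[i], mp$position_bp[i])
    mp$position_bp[i] <- li$start
    mp$scaffold_id[i] <- off$chrom
  }
  rownames(mp) <- NULL
  mp
}

#' Emit pseudomolecule artifacts to a directory
#'
#' Writes the pseudomolecule FASTA, AGP, lifted GFF3, lifted map TSV and a
#' FASTA of unplaced scaffolds.
#'
#' @param layout A [build_layout()] result.
#' @param scaffolds Named character vector of scaffold sequences.
#' @param gene_models \code{gene_models} in scaffold coordinates (optional).
#' @param map_loci Genetic-map data frame (optional).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list of the in-memory artifacts.
#' @export
emit_pseudomolecules <- function(layout, scaffolds, gene_models = NULL,
                                 map_loci = NULL, out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pm <- build_pseudomolecules(layout, scaffolds)
  write_fasta(pm$seqs, file.path(out_dir, "pseudomolecules.fasta"))
  if (!is.null(pm$agp)) write_agp(pm$agp, file.path(out_dir, "pseudomolecules.agp"))
  if (length(pm$unplaced))
    write_fasta(scaffolds[pm$unplaced], file.path(out_dir, "unplaced.fasta"))
  lifted_gm <- NULL; lifted_map <- NULL
  if (!is.null(gene_models)) {
    lifted_gm <- lift_gene_models(layout, scaffolds, gene_models)
    write_gene_models(lifted_gm, file.path(out_dir, "genes_lifted.gff3"))
  }
  if (!is.null(map_loci)) {
    lifted_map <- lift_map(layout, scaffolds, map_loci)
    write_genetic_map(lifted_map, file.path(out_dir, "map_lifted.tsv"))
  }
  invisible(list(seqs = pm$seqs, agp = pm$agp, unplaced = pm$unplaced,
                 genes = lifted_gm, map = lifted_map))
}

#' Per-chromosome anchoring report (assembly-integration table)
#'
#' For each chromosome and in total: number of assigned scaffolds and their
#' percentage of all assembly scaffolds, assigned bp and percentage of
#' assembly bp, genes on assigned scaffolds and percentage of all predicted
#' genes.  Percentages are reported to one decimal.
#'
#' @param layout A [build_layout()] result.
#' @param scaffolds Named character vector of all assembly scaffolds.
#' @param gene_models \code{gene_models} in scaffold coordinates (may be
#'   \code{NULL}; gene columns are then zero).
#' @param summary An [assembly_summary()] of the whole assembly.
#' @param total_gene_count Denominator for the gene percentage.
#' @return Data frame with one row per chromosome plus a \code{Total} row.
#' @export
table2_report <- function(layout, scaffolds, gene_models, summary,
                          total_gene_count) {
  rows <- list()
  for (chr in names(layout$chromosomes)) {
    lay <- layout$chromosomes[[chr]]
    bp <- sum(as.numeric(nchar(scaffolds[lay$scaffold_id])))
    ng <- if (is.null(gene_models)) 0L
          else sum(gene_models$seq_id %in% lay$scaffold_id)
    rows[[chr]] <- data.frame(chromosome = chr, n_scaffolds = nrow(lay),
                              scaffold_pct = NA_real_, assigned_bp = bp,
                              bp_pct = NA_real_, n_genes = ng,
                              gene_pct = NA_real_, stringsAsFactors = FALSE)
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chromosome = character(0), n_scaffolds = integer(0),
               scaffold_pct = numeric(0), assigned_bp = numeric(0),
               bp_pct = numeric(0), n_genes = integer(0),
               gene_pct = numeric(0))
  tot <- data.frame(chromosome = "Total", n_scaffolds = sum(df$n_scaffolds),
                    scaffold_pct = NA_real_, assigned_bp = sum(df$assigned_bp),
                    bp_pct = NA_real_, n_genes = sum(df$n_genes),
                    gene_pct = NA_real_, stringsAsFactors = FALSE)
  df <- rbind(df, tot)
  df$scaffold_pct <- round(100 * df$n_scaffolds / summary$n_seqs, 1)
  df$bp_pct <- round(100 * df$assigned_bp / summary$total_len, 1)
  df$gene_pct <- if (total_gene_count > 0)
    round(100 * df$n_genes / total_gene_count, 1) else NA_real_
  rownames(df) <- NULL
  df
}
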