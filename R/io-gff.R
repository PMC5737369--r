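#' Read protein-coding gene models from GFF3
#'
#' Parses \code{gene}/\code{mRNA}/\code{exon}/\code{CDS} features linked by
#' \code{ID}/\code{Parent} attributes into a flat gene-model table.  One
#' transcript per gene is assumed (the first mRNA is used; others are
#' ignored with a warning).
#'
#' @param path Path to a GFF3 file.
#' @return A \code{gene_models} data.frame: one row per gene with columns
#'   \code{gene_id}, \code{seq_id}, \code{start}, \code{end}, \code{strand}
#'   (1-based inclusive) and list columns \code{cds}, \code{exons}, each a
#'   two-column matrix of segment \code{start}/\code{end} sorted by start.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  g <- as.data.frame(rtracklayer::readGFF(
    path, columns = c("seqid", "type", "start", "end", "strand"),
    tags = c("ID", "Parent")))
  g$Parent <- vapply(g$Parent, function(p)
    if (length(p)) as.character(p[[1L]]) else NA_character_, character(1))
  genes <- g[g$type == "gene", , drop = FALSE]
  mrna <- g[g$type == "mRNA", , drop = FALSE]
  if (any(duplicated(mrna$Parent)))
    warning("multiple mRNAs per gene; using the first of each")
  mrna <- mrna[!duplicated(mrna$Parent), , drop = FALSE]
  tx_of_gene <- setNames(mrna$ID, mrna$Parent)
  seg <- function(type, tx) {
    s <- g[g$type == type & !is.na(g$Parent) & g$Parent == tx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    cbind(start = s$start, end = s$end)
  }
  n <- nrow(genes)
  cds <- vector("list", n); exons <- vector("list", n)
  for (i in seq_len(n)) {
    tx <- unname(tx_of_gene[genes$ID[i]])
    empty <- cbind(start = integer(0), end = integer(0))
    cds[[i]] <- if (is.na(tx)) empty else seg("CDS", tx)
    exons[[i]] <- if (is.na(tx)) empty else seg("exon", tx)
  }
  out <- data.frame(gene_id = genes$ID, seq_id = as.character(genes$seqid),
                    start = genes$start, end = genes$end,
                    strand = as.character(genes$strand),
                    stringsAsFactors = FALSE)
  out$cds <- cds
  out$exons <- exons
  class(out) <- c("gene_models", "data.frame")
  validate_gene_models(out)
  out
}

validate_gene_models <- function(gm) {
  stopifnot(all(gm$start <= gm$end), all(gm$strand %in% c("+", "-")))
  for (i in seq_len(nrow(gm))) {
    cd <- gm$cds[[i]]
    if (nrow(cd) == 0L) next
    if (any(cd[, 1L] > cd[, 2L])) stop("CDS segment with start > end in ", gm$gene_id[i])
    if (any(cd[, 1L] < gm$start[i]) || any(cd[, 2L] > gm$end[i]))
      stop("CDS outside gene span in ", gm$gene_id[i])
    if (nrow(cd) > 1L && any(cd[-1L, 1L] <= cd[-nrow(cd), 2L]))
      stop("overlapping CDS segments in ", gm$gene_id[i])
  }
  invisible(gm)
}

#' Write gene models as GFF3
#' @param gm A \code{gene_models} data.frame (see [read_gene_models()]).
#' @param path Output path.
#' @export
write_gene_models <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  row <- function(seqid, type, start, end, strand, attrs)
    paste(seqid, "anchorage", type, start, end, ".", strand, ".", attrs,
          sep = "\t")
  for (i in seq_len(nrow(gm))) {
    gid <- gm$gene_id[i]; tid <- paste0(gid, ".t1")
    lines <- c(
      row(gm$seq_id[i], "gene", gm$start[i], gm$end[i], gm$strand[i],
          paste0("ID=", gid)),
      row(gm$seq_id[i], "mRNA", gm$start[i], gm$end[i], gm$strand[i],
          paste0("ID=", tid, ";Parent=", gid)))
    ex <- gm$exons[[i]]
    for (j in seq_len(nrow(ex)))
      lines <- c(lines, row(gm$seq_id[i], "exon", ex[j, 1L], ex[j, 2L],
                            gm$strand[i], paste0("Parent=", tid)))
    cd <- gm$cds[[i]]
    for (j in seq_len(nrow(cd)))
      lines <- c(lines, row(gm$seq_id[i], "CDS", cd[j, 1L], cd[j, 2L],
                            gm$strand[i], paste0("Parent=", tid)))
    writeLines(lines, con)
  }
  invisible(path)
}
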