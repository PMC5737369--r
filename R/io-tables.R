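#' Read a genetic-map table
#'
#' Expects a tab-separated file with header columns \code{marker_id},
#' \code{linkage_group}, \code{cM}, \code{scaffold_id}, \code{position_bp}.
#' Rows whose scaffold placement is missing (empty or \code{NA}) are kept
#' but flagged \code{placed = FALSE} so map statistics still see them.
#'
#' @param path Path to the TSV.
#' @return A data.frame with the five schema columns plus logical
#'   \code{placed}.
#' @export
read_genetic_map <- function(path) {
  if (!file.exists(path)) stop("map file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("marker_id", "linkage_group", "cM", "scaffold_id", "position_bp")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  num <- function(col) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) & !(is.na(df[[col]]) | df[[col]] == ""))
    if (length(bad))
      stop("malformed numeric field '", col, "' at line ", bad[1L] + 1L,
           " of ", path)
    x
  }
  cm <- num("cM")
  pos <- num("position_bp")
  if (any(is.na(cm))) stop("missing cM value in ", path)
  if (any(cm < 0)) stop("negative cM value in ", path)
  if (any(!is.na(pos) & pos < 1)) stop("position_bp must be 1-based (>= 1)")
  dup <- df$marker_id[duplicated(df$marker_id)]
  if (length(dup))
    stop("duplicate marker_id(s): ", paste(unique(dup), collapse = ", "))
  placed <- !(is.na(df$scaffold_id) | df$scaffold_id == "") & !is.na(pos)
  data.frame(marker_id = df$marker_id, linkage_group = df$linkage_group,
             cM = cm, scaffold_id = ifelse(placed, df$scaffold_id, NA),
             position_bp = pos, placed = placed, stringsAsFactors = FALSE)
}

#' Write a genetic-map table
#' @param map Data frame as returned by [read_genetic_map()].
#' @param path Output path.
#' @export
write_genetic_map <- function(map, path) {
  cols <- c("marker_id", "linkage_group", "cM", "scaffold_id", "position_bp")
  write.table(map[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an ortholog hit table
#'
#' Tab-separated with header columns \code{query_gene_id},
#' \code{ref_gene_id}, \code{ref_chrom}, \code{ref_start_bp},
#' \code{ref_end_bp}, \code{evalue}, \code{bitscore} (the tabular output of
#' a protein similarity search).  Hits with E-value above \code{max_evalue}
#' are dropped; the drop count is attached as attribute \code{"n_dropped"}.
#'
#' @param path Path to the TSV.
#' @param max_evalue E-value ceiling; hits above it are discarded.
#' @return Data frame of retained hits.
#' @export
read_hit_table <- function(path, max_evalue = 1e-5) {
  if (!file.exists(path)) stop("hit table not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("query_gene_id", "ref_gene_id", "ref_chrom", "ref_start_bp",
            "ref_end_bp", "evalue", "bitscore")
  if (!all(need %in% names(df)))
    stop("hit table must have columns: ", paste(need, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty hit table: ", path)
    attr(df, "n_dropped") <- 0L
    return(df)
  }
  if (any(df$ref_start_bp < 0 | df$ref_end_bp < 0))
    stop("negative reference coordinates in ", path)
  if (any(df$ref_start_bp > df$ref_end_bp))
    stop("ref_start_bp > ref_end_bp in ", path)
  if (any(df$evalue < 0)) stop("negative evalue in ", path)
  drop <- df$evalue > max_evalue
  out <- df[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(drop)
  out
}

#' Write a k-mer histogram as two-column TSV (depth, count)
#' @param hist A \code{kmer_histogram} (see [count_kmers()]).
#' @param path Output path.
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_histogram"))
  df <- data.frame(depth = as.integer(names(hist$counts)),
                   count = as.numeric(hist$counts))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a two-column (depth, count) k-mer histogram TSV
#' @param path Input path.
#' @param k The k-mer size the histogram was computed with.
#' @export
read_kmer_histogram <- function(path, k = 17L) {
  df <- read.delim(path, header = FALSE, col.names = c("depth", "count"))
  if (any(df$depth < 1)) stop("histogram depths must be >= 1")
  kmer_histogram(setNames(df$count, df$depth), k = k)
}
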