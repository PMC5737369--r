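#' Anchoring parameters
#'
#' Houses the constants of the two-stage anchoring procedure: the minimum
#' number of continuous ortholog-bearing genes for a synteny block, the
#' strict R-squared acceptance threshold of the block's linear fit, the
#' N-spacer length between concatenated scaffolds, and the minimum number
#' of mapped marker loci needed to orient a scaffold from the genetic map.
#'
#' @param min_genes Minimum genes in a collinear run (default 5).
#' @param r2_threshold Strict lower bound on the run's OLS R-squared
#'   (default 0.6; acceptance requires \code{r2 > r2_threshold}).
#' @param spacer_len Ns inserted between consecutive scaffolds (default
#'   10000).
#' @param min_markers_to_orient Minimum mapped loci (at distinct cM and bp)
#'   to call a map-based orientation (default 2).
#' @return A list of class \code{anchoring_params}.
#' @export
anchoring_params <- function(min_genes = 5L, r2_threshold = 0.6,
                             spacer_len = 10000L,
                             min_markers_to_orient = 2L) {
  stopifnot(min_genes >= 2L, r2_threshold > 0, r2_threshold < 1,
            spacer_len >= 0L, min_markers_to_orient >= 2L)
  structure(list(min_genes = as.integer(min_genes),
                 r2_threshold = r2_threshold,
                 spacer_len = as.integer(spacer_len),
                 min_markers_to_orient = as.integer(min_markers_to_orient)),
            class = "anchoring_params")
}

empty_assignments <- function() {
  data.frame(scaffold_id = character(0), chromosome = character(0),
              orientation = character(0), order_key = numeric(0),
              key_type = character(0), evidence = character(0),
              n_support = integer(0), r2 = numeric(0),
              cM = numeric(0), conflict = logical(0),
              stringsAsFactors = FALSE)
}

#' Assign scaffolds to chromosomes from a genetic map
#'
#' A scaffold is assigned to the linkage group that holds a strict majority
#' of its mapped loci (ties and pluralities below half leave it unassigned,
#' recorded in the \code{"unassigned"} attribute).  Its ordering key is the
#' median cM of those loci.  Orientation is the sign of the least-squares
#' slope of cM on scaffold bp, called only when the scaffold carries at
#' least \code{min_markers_to_orient} loci at distinct cM and distinct bp.
#'
#' @param map_loci Data frame from [read_genetic_map()].
#' @param params An [anchoring_params()] list.
#' @return Assignment data.frame (one row per assigned scaffold) with
#'   columns \code{scaffold_id}, \code{chromosome}, \code{orientation},
#'   \code{order_key} (median cM), \code{key_type = "cM"},
#'   \code{evidence = "map"}, \code{n_support}, \code{r2} (NA), \code{cM},
#'   \code{conflict}.
#' @export
map_assign <- function(map_loci, params = anchoring_params()) {
  loci <- map_loci[map_loci$placed %||% TRUE & !is.na(map_loci$scaffold_id), ,
                   drop = FALSE]
  out <- empty_assignments()
  unassigned <- character(0)
  for (sc in unique(loci$scaffold_id)) {
    l <- loci[loci$scaffold_id == sc, , drop = FALSE]
    tab <- table(l$linkage_group)
    if (max(tab) * 2L <= nrow(l)) {       # no strict majority
      unassigned <- c(unassigned, sc)
      next
    }
    lg <- names(tab)[which.max(tab)]
    lm_ <- l[l$linkage_group == lg, , drop = FALSE]
    ori <- "unknown"
    if (nrow(lm_) >= params$min_markers_to_orient &&
        length(unique(lm_$cM)) > 1L && length(unique(lm_$position_bp)) > 1L) {
      slope <- coef(lm(lm_$cM ~ lm_$position_bp))[2L]
      if (is.finite(slope) && slope != 0)
        ori <- if (slope > 0) "+" else "-"
    }
    out <- rbind(out, data.frame(
      scaffold_id = sc, chromosome = lg, orientation = ori,
      order_key = median(lm_$cM), key_type = "cM", evidence = "map",
      n_support = nrow(lm_), r2 = NA_real_, cM = median(lm_$cM),
      conflict = FALSE, stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  attr(out, "unassigned") <- unassigned
  out
}

#' Reduce an ortholog hit table to best hits per query gene
#'
#' Per query gene the hit with the lowest E-value wins; ties break by
#' highest bitscore, then smallest reference start, then lexicographic
#' reference gene id -- a fully deterministic order.
#'
#' @param hits Data frame from [read_hit_table()].
#' @return Data frame with one row per query gene.
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0L) return(hits)
  o <- order(hits$query_gene_id, hits$evalue, -hits$bitscore,
             hits$ref_start_bp, hits$ref_gene_id)
  h <- hits[o, , drop = FALSE]
  h <- h[!duplicated(h$query_gene_id), , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Find collinear runs of ortholog-bearing genes along scaffolds
#'
#' Walks each scaffold's genes in positional order, keeping only genes
#' with a best hit.  A run is a maximal block of consecutive hit-bearing
#' genes whose hits all lie on one reference chromosome; genes with no hit
#' are transparent (they do not break a run), while a best hit on a
#' different chromosome terminates it.  Runs shorter than
#' \code{params$min_genes} are discarded.
#'
#' @param gene_models A \code{gene_models} data.frame (scaffold
#'   coordinates).
#' @param bhits Output of [best_hits()].
#' @param params An [anchoring_params()] list.
#' @return List of runs; each run is a list with \code{scaffold_id},
#'   \code{ref_chrom}, \code{gene_id}, \code{scaffold_mid}, \code{ref_mid}.
#' @export
collinear_runs <- function(gene_models, bhits, params = anchoring_params()) {
  runs <- list()
  if (nrow(bhits) == 0L) return(runs)
  hit_of <- split(bhits, bhits$query_gene_id)
  for (sc in unique(gene_models$seq_id)) {
    gm <- gene_models[gene_models$seq_id == sc, , drop = FALSE]
    gm <- gm[order(gm$start), , drop = FALSE]
    cur <- NULL
    flush <- function(cur) {
      if (!is.null(cur) && length(cur$gene_id) >= params$min_genes)
        runs[[length(runs) + 1L]] <<- cur
    }
    for (i in seq_len(nrow(gm))) {
      h <- hit_of[[gm$gene_id[i]]]
      if (is.null(h)) next                       # hitless: transparent
      chrom <- h$ref_chrom[1L]
      smid <- (gm$start[i] + gm$end[i]) / 2
      rmid <- (h$ref_start_bp[1L] + h$ref_end_bp[1L]) / 2
      if (is.null(cur) || cur$ref_chrom != chrom) {
        flush(cur)
        cur <- list(scaffold_id = sc, ref_chrom = chrom,
                    gene_id = character(0), scaffold_mid = numeric(0),
                    ref_mid = numeric(0))
      }
      cur$gene_id <- c(cur$gene_id, gm$gene_id[i])
      cur$scaffold_mid <- c(cur$scaffold_mid, smid)
      cur$ref_mid <- c(cur$ref_mid, rmid)
    }
    flush(cur)
  }
  runs
}

#' Turn one collinear run into a synteny assignment
#'
#' Ordinary least squares of reference gene midpoint on scaffold gene
#' midpoint.  The run is accepted iff its R-squared strictly exceeds
#' \code{params$r2_threshold}; orientation is the sign of the slope and the
#' ordering key is the median reference midpoint.
#'
#' @param run One element of [collinear_runs()] output.
#' @param params An [anchoring_params()] list.
#' @return A one-row assignment data.frame, or \code{NULL} for a rejected
#'   run (rejection reason and R-squared in attributes \code{"reason"} /
#'   \code{"r2"} of the returned \code{NULL} are not possible, so
#'   rejections are returned as a list \code{list(rejected = TRUE, reason,
#'   r2)}).
#' @export
synteny_assign <- function(run, params = anchoring_params()) {
  n <- length(run$gene_id)
  if (n < params$min_genes)
    return(list(rejected = TRUE, reason = "too few genes", r2 = NA_real_))
  if (length(unique(run$scaffold_mid)) < 2L)
    return(list(rejected = TRUE, reason = "zero variance in scaffold positions",
                r2 = NA_real_))
  fit <- lm(run$ref_mid ~ run$scaffold_mid)
  slope <- coef(fit)[2L]
  ssr <- sum(residuals(fit)^2)
  sst <- sum((run$ref_mid - mean(run$ref_mid))^2)
  r2 <- if (sst == 0) 0 else 1 - ssr / sst
  if (!(r2 > params$r2_threshold))
    return(list(rejected = TRUE, reason = "r2 below threshold", r2 = r2))
  data.frame(scaffold_id = run$scaffold_id, chromosome = run$ref_chrom,
             orientation = if (slope >= 0) "+" else "-",
             order_key = median(run$ref_mid), key_type = "bp",
             evidence = "synteny", n_support = n, r2 = r2, cM = NA_real_,
             conflict = FALSE, stringsAsFactors = FALSE)
}

#' Synteny-assign every run, resolving multi-run scaffolds
#'
#' Accepted runs are reduced to one assignment per scaffold: the run with
#' the most genes wins, ties by higher R-squared then by chromosome name.
#' Rejected runs are recorded in the \code{"rejections"} attribute.
#'
#' @param runs Output of [collinear_runs()].
#' @param params An [anchoring_params()] list.
#' @return Assignment data.frame.
#' @export
synteny_assign_all <- function(runs, params = anchoring_params()) {
  acc <- list(); rej <- list()
  for (run in runs) {
    a <- synteny_assign(run, params)
    if (is.data.frame(a)) acc[[length(acc) + 1L]] <- a
    else rej[[length(rej) + 1L]] <- data.frame(
      scaffold_id = run$scaffold_id, ref_chrom = run$ref_chrom,
      n = length(run$gene_id), reason = a$reason, r2 = a$r2,
      stringsAsFactors = FALSE)
  }
  out <- if (length(acc)) do.call(rbind, acc) else empty_assignments()
  if (nrow(out)) {
    o <- order(out$scaffold_id, -out$n_support, -out$r2, out$chromosome)
    out <- out[o, , drop = FALSE]
    out <- out[!duplicated(out$scaffold_id), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "rejections") <- if (length(rej)) do.call(rbind, rej) else NULL
  out
}

#' Merge map- and synteny-based assignments
#'
#' Map evidence takes precedence.  A scaffold with both evidences on the
#' same chromosome keeps the map chromosome and orientation but inherits
#' the synteny ordering key (reference bp), which lets map- and
#' synteny-placed scaffolds interleave on a common scale.  When the two
#' evidences disagree on the chromosome, the map wins and the row is
#' flagged \code{conflict = TRUE} (also listed in the \code{"conflicts"}
#' attribute).  If the map did not orient the scaffold, the synteny
#' orientation fills in.
#'
#' @param map_assigns,synteny_assigns Assignment data.frames.
#' @return Merged assignment data.frame.
#' @export
merge_assignments <- function(map_assigns, synteny_assigns) {
  out <- map_assigns
  conflicts <- character(0)
  syn_idx <- setNames(seq_len(nrow(synteny_assigns)),
                      synteny_assigns$scaffold_id)
  for (i in seq_len(nrow(out))) {
    j <- syn_idx[out$scaffold_id[i]]
    if (is.na(j)) next
    syn <- synteny_assigns[j, ]
    if (identical(syn$chromosome, out$chromosome[i])) {
      out$order_key[i] <- syn$order_key
      out$key_type[i] <- "bp"
      out$r2[i] <- syn$r2
      if (out$orientation[i] == "unknown") out$orientation[i] <- syn$orientation
    } else {
      out$conflict[i] <- TRUE
      conflicts <- c(conflicts, out$scaffold_id[i])
    }
  }
  syn_only <- synteny_assigns[!(synteny_assigns$scaffold_id %in%
                                  out$scaffold_id), , drop = FALSE]
  out <- rbind(out, syn_only)
  rownames(out) <- NULL
  attr(out, "conflicts") <- conflicts
  out
}

#' Build an ordered, oriented pseudomolecule layout
#'
#' Within each chromosome scaffolds are sorted by a bp-scale ordering key.
#' Scaffolds carrying only a cM key are projected to bp by linear
#' interpolation between the bp-keyed scaffolds that bracket them in cM
#' rank (linear extrapolation at the ends, clamped to \code{[0, ref
#' length]}); a chromosome with fewer than two such dual-keyed anchors
#' falls back to scaling cM by the chromosome length.  Ties break by
#' descending scaffold length, then id.  Unknown orientations are emitted
#' as \code{+} and flagged.
#'
#' @param assignments Merged assignment data.frame.
#' @param ref_chrom_lengths Named numeric vector of reference chromosome
#'   lengths (bp), used for extrapolation clamps and the cM fallback.
#' @param scaffold_lengths Optional named vector of scaffold lengths for
#'   tie-breaking.
#' @param spacer_len Spacer length stored in the layout.
#' @return A \code{pseudomolecule_layout}: list with \code{chromosomes}
#'   (named list of data.frames with \code{scaffold_id}, \code{orientation},
#'   \code{orientation_flag}) and \code{spacer_len}.
#' @export
build_layout <- function(assignments, ref_chrom_lengths,
                         scaffold_lengths = NULL, spacer_len = 10000L) {
  miss <- setdiff(unique(assignments$chromosome), names(ref_chrom_lengths))
  if (length(miss))
    stop("chromosome(s) missing from ref lengths: ", paste(miss, collapse = ", "))
  # global cM -> bp relation over all dual-keyed anchors, the fallback for
  # chromosomes with fewer than two local anchors (assumes a roughly
  # uniform genome-wide recombination density)
  g_anch <- assignments$key_type == "bp" & !is.na(assignments$cM)
  g_fit <- if (sum(g_anch) >= 2L &&
               length(unique(assignments$cM[g_anch])) >= 2L)
    coef(lm(assignments$order_key[g_anch] ~ assignments$cM[g_anch]))
  else NULL
  chroms <- list()
  for (chr in sort(unique(assignments$chromosome))) {
    a <- assignments[assignments$chromosome == chr, , drop = FALSE]
    key <- a$order_key
    is_cm <- a$key_type == "cM"
    if (any(is_cm)) {
      anchors <- which(!is_cm & !is.na(a$cM))
      if (length(anchors) >= 2L) {
        o <- order(a$cM[anchors])
        xs <- a$cM[anchors][o]; ys <- a$order_key[anchors][o]
        for (i in which(is_cm)) {
          key[i] <- interp_extrap(a$cM[i], xs, ys)
        }
      } else if (!is.null(g_fit)) {
        key[is_cm] <- g_fit[1L] + g_fit[2L] * a$cM[is_cm]
      } else {
        cmax <- max(a$cM[is_cm], 1e-9)
        key[is_cm] <- a$cM[is_cm] / cmax * ref_chrom_lengths[[chr]]
      }
      key[is_cm] <- pmin(pmax(key[is_cm], 0), ref_chrom_lengths[[chr]])
    }
    slen <- if (is.null(scaffold_lengths)) rep(0, nrow(a))
            else unname(scaffold_lengths[a$scaffold_id])
    o <- order(key, -slen, a$scaffold_id)
    ori <- a$orientation[o]
    flag <- ori == "unknown"
    ori[flag] <- "+"
    chroms[[chr]] <- data.frame(scaffold_id = a$scaffold_id[o],
                                orientation = ori,
                                orientation_flag = flag,
                                stringsAsFactors = FALSE)
  }
  dup <- unlist(lapply(chroms, `[[`, "scaffold_id"))
  if (any(duplicated(dup)))
    stop("scaffold placed on more than one chromosome: ",
         paste(unique(dup[duplicated(dup)]), collapse = ", "))
  structure(list(chromosomes = chroms, spacer_len = as.integer(spacer_len)),
            class = "pseudomolecule_layout")
}

# piecewise-linear interpolation with linear extrapolation from the
# outermost two anchors
interp_extrap <- function(x, xs, ys) {
  n <- length(xs)
  if (x <= xs[1L]) {
    if (n == 1L || xs[2L] == xs[1L]) return(ys[1L])
    return(ys[1L] + (x - xs[1L]) * (ys[2L] - ys[1L]) / (xs[2L] - xs[1L]))
  }
  if (x >= xs[n]) {
    if (n == 1L || xs[n] == xs[n - 1L]) return(ys[n])
    return(ys[n] + (x - xs[n]) * (ys[n] - ys[n - 1L]) / (xs[n] - xs[n - 1L]))
  }
  stats::approx(xs, ys, xout = x, ties = mean)$y
}

#' @export
print.pseudomolecule_layout <- function(x, ...) {
  cat("pseudomolecule layout:",
      length(x$chromosomes), "chromosome(s),",
      sum(vapply(x$chromosomes, nrow, integer(1))), "scaffold(s), spacer",
      x$spacer_len, "bp\n")
  invisible(x)
}
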