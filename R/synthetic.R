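random_bases <- function(n, gc = 0.38) {
  paste(sample(BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

random_cds <- function(n_codons) {
  codons <- as.vector(outer(as.vector(outer(BASES, BASES, paste0)), BASES,
                            paste0))
  sense <- setdiff(codons, STOP_CODONS)
  paste0("ATG", paste(sample(sense, n_codons - 2L, replace = TRUE),
                      collapse = ""), sample(STOP_CODONS, 1L))
}

#' Generate a seeded synthetic reference genome with gene models
#'
#' Bases are i.i.d. at the target GC (no repeat families -- this emulates
#' the gene space of a compact plant genome, not its repeat content).
#' Protein-coding gene models (1-3 exons, real ATG...stop open reading
#' frames written into the sequence, short UTRs, random strand) are placed
#' non-overlapping; optional SSR motifs are implanted at recorded
#' intergenic intervals.  Identical seeds give identical output.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_len Chromosome length in bp (single value or per-chrom
#'   vector).
#' @param gc Target GC fraction (default 0.38, a typical compact
#'   rosaceous-genome value).
#' @param gene_density Genes per Mb (default 400).
#' @param ssr_implants Either \code{NULL}, a count of random intergenic
#'   SSR implants, or a data.frame with \code{chrom}, \code{pos},
#'   \code{motif}, \code{copies}.
#' @param seed Mandatory RNG seed.
#' @return List with \code{genome} (named character vector),
#'   \code{genes} (a \code{gene_models} data.frame) and \code{truth}
#'   (list with \code{genes}, \code{ssrs}).
#' @export
generate_genome <- function(n_chrom = 8L, chrom_len = 125000L, gc = 0.38,
                            gene_density = 400, ssr_implants = NULL, seed) {
  stopifnot(n_chrom >= 1L, all(chrom_len > 0), gc > 0, gc < 1,
            gene_density >= 0)
  lens <- rep_len(as.integer(chrom_len), n_chrom)
  with_seed(seed, {
    genome <- setNames(vapply(lens, random_bases, character(1), gc = gc),
                       paste0("chr", seq_len(n_chrom)))
    gm_rows <- list()
    for (ci in seq_len(n_chrom)) {
      chr <- names(genome)[ci]
      n_genes <- round(lens[ci] * gene_density / 1e6)
      if (n_genes == 0L) next
      n_cod <- sample(60:240, n_genes, replace = TRUE)
      n_ex <- sample(1:3, n_genes, replace = TRUE)
      utr5 <- sample(0:30, n_genes, replace = TRUE)
      utr3 <- sample(0:30, n_genes, replace = TRUE)
      intron_total <- ifelse(n_ex > 1L, (n_ex - 1L) *
                               sample(40:200, n_genes, replace = TRUE), 0L)
      span <- n_cod * 3L + intron_total + utr5 + utr3
      min_gap <- 60L
      free <- lens[ci] - sum(span) - (n_genes + 1L) * min_gap
      if (free < 0)
        stop("gene_density infeasible for chromosome length ", lens[ci])
      extra <- stats::rmultinom(1L, free, rep(1, n_genes + 1L))[, 1L]
      pos <- min_gap + extra[1L] + 1L
      seqchars <- strsplit(genome[[chr]], "", fixed = TRUE)[[1L]]
      for (gi in seq_len(n_genes)) {
        gstart <- pos
        gend <- gstart + span[gi] - 1L
        strand <- sample(c("+", "-"), 1L)
        # segment the CDS across exons (coding-strand order)
        cds_len <- n_cod[gi] * 3L
        cuts <- if (n_ex[gi] > 1L)
          sort(sample(seq_len(cds_len %/% 3L - 1L), n_ex[gi] - 1L)) * 3L
        else integer(0)
        seg_lens <- diff(c(0L, cuts, cds_len))
        intron_len <- if (n_ex[gi] > 1L)
          rep(intron_total[gi] %/% (n_ex[gi] - 1L), n_ex[gi] - 1L)
        else integer(0)
        # lay segments left-to-right along the chromosome
        left_utr <- if (strand == "+") utr5[gi] else utr3[gi]
        right_utr <- if (strand == "+") utr3[gi] else utr5[gi]
        if (strand == "-") seg_lens <- rev(seg_lens)
        cds <- matrix(0L, nrow = length(seg_lens), ncol = 2L,
                      dimnames = list(NULL, c("start", "end")))
        p <- gstart + left_utr
        for (si in seq_along(seg_lens)) {
          cds[si, ] <- c(p, p + seg_lens[si] - 1L)
          p <- p + seg_lens[si] + if (si < length(seg_lens)) intron_len[si] else 0L
        }
        gend <- cds[nrow(cds), 2L] + right_utr
        exons <- cds
        exons[1L, 1L] <- exons[1L, 1L] - left_utr
        exons[nrow(exons), 2L] <- exons[nrow(exons), 2L] + right_utr
        # write a real ORF into the sequence
        orf <- random_cds(n_cod[gi])
        orf_chrom <- if (strand == "+") orf else revcomp(orf)
        # fill segments in chromosome order with consecutive ORF chunks
        off <- 0L
        for (si in seq_len(nrow(cds))) {
          L <- cds[si, 2L] - cds[si, 1L] + 1L
          seqchars[cds[si, 1L]:cds[si, 2L]] <-
            strsplit(substr(orf_chrom, off + 1L, off + L), "", fixed = TRUE)[[1L]]
          off <- off + L
        }
        gm_rows[[length(gm_rows) + 1L]] <- list(
          gene_id = sprintf("%s_g%03d", chr, gi), seq_id = chr,
          start = exons[1L, 1L], end = exons[nrow(exons), 2L],
          strand = strand, cds = cds, exons = exons)
        pos <- gend + min_gap + extra[gi + 1L] + 1L
      }
      genome[[chr]] <- paste(seqchars, collapse = "")
    }
    gm <- data.frame(
      gene_id = vapply(gm_rows, `[[`, character(1), "gene_id"),
      seq_id = vapply(gm_rows, `[[`, character(1), "seq_id"),
      start = vapply(gm_rows, `[[`, numeric(1), "start"),
      end = vapply(gm_rows, `[[`, numeric(1), "end"),
      strand = vapply(gm_rows, `[[`, character(1), "strand"),
      stringsAsFactors = FALSE)
    gm$cds <- lapply(gm_rows, `[[`, "cds")
    gm$exons <- lapply(gm_rows, `[[`, "exons")
    class(gm) <- c("gene_models", "data.frame")

    ssr_truth <- data.frame(chrom = character(0), start = integer(0),
                            end = integer(0), motif = character(0),
                            copies = integer(0))
    if (!is.null(ssr_implants)) {
      if (is.numeric(ssr_implants) && length(ssr_implants) == 1L) {
        n_ssr <- as.integer(ssr_implants)
        motifs <- c("AG", "AT", "AAG", "AAT", "AAAT", "AAAAT", "AAAAAT")
        imp <- data.frame(
          chrom = sample(names(genome), n_ssr, replace = TRUE),
          pos = NA_integer_,
          motif = sample(motifs, n_ssr, replace = TRUE),
          copies = sample(8:15, n_ssr, replace = TRUE),
          stringsAsFactors = FALSE)
      } else imp <- as.data.frame(ssr_implants)
      for (i in seq_len(nrow(imp))) {
        chr <- imp$chrom[i]
        rep_seq <- strrep(imp$motif[i], imp$copies[i])
        L <- nchar(rep_seq)
        pos <- imp$pos[i]
        if (is.na(pos)) {
          gspans <- gm[gm$seq_id == chr, , drop = FALSE]
          ok <- FALSE
          for (try in 1:200) {
            pos <- sample.int(nchar(genome[[chr]]) - L - 1L, 1L)
            clash <- nrow(gspans) > 0L &&
              any(gspans$end >= pos - 10L & gspans$start <= pos + L + 10L)
            prior_clash <- nrow(ssr_truth) > 0L &&
              any(ssr_truth$chrom == chr & ssr_truth$end >= pos - 30L &
                    ssr_truth$start <= pos + L + 30L)
            if (!clash && !prior_clash) { ok <- TRUE; break }
          }
          if (!ok) stop("could not place SSR implant on ", chr)
        }
        substr(genome[[chr]], pos, pos + L - 1L) <- rep_seq
        ssr_truth <- rbind(ssr_truth, data.frame(
          chrom = chr, start = pos, end = pos + L - 1L,
          motif = canonical_motif(imp$motif[i]), copies = imp$copies[i]))
      }
    }
    list(genome = genome, genes = gm,
         truth = list(genes = gm, ssrs = ssr_truth))
  })
}

#' Fragment a reference genome into shuffled, randomly oriented scaffolds
#'
#' Chromosomes are cut at breakpoints sampled outside gene spans (so gene
#' models stay intact), each scaffold is reverse-complemented with
#' probability 0.5, and the output order is shuffled.  Gene models are
#' re-coordinated onto the scaffolds.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param gene_models \code{gene_models} in reference coordinates.
#' @param n_scaffolds Approximate total number of scaffolds.
#' @param seed Mandatory RNG seed.
#' @return List with \code{scaffolds} (named character vector),
#'   \code{genes} (\code{gene_models} in scaffold coordinates) and
#'   \code{truth} (data.frame: \code{scaffold_id}, \code{chrom},
#'   \code{start}, \code{end}, \code{orientation}, \code{length}).
#' @export
fragment_scaffolds <- function(genome, gene_models, n_scaffolds, seed) {
  total <- sum(nchar(genome))
  with_seed(seed, {
    pieces <- list()
    for (chr in names(genome)) {
      len <- nchar(genome[[chr]])
      n_frag <- max(1L, round(n_scaffolds * len / total))
      gs <- gene_models[gene_models$seq_id == chr, , drop = FALSE]
      allowed <- rep(TRUE, len - 1L)        # breakpoint after position i
      for (i in seq_len(nrow(gs))) {
        lo <- max(1L, gs$start[i] - 1L); hi <- min(len - 1L, gs$end[i])
        allowed[lo:hi] <- FALSE
      }
      ok_pos <- which(allowed)
      n_bp <- min(n_frag - 1L, length(ok_pos))
      bps <- if (n_bp > 0L) sort(sample(ok_pos, n_bp)) else integer(0)
      starts <- c(1L, bps + 1L)
      ends <- c(bps, len)
      for (k in seq_along(starts)) {
        pieces[[length(pieces) + 1L]] <- list(
          chrom = chr, start = starts[k], end = ends[k])
      }
    }
    n <- length(pieces)
    ord <- sample(n)
    flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
    ids <- sprintf("sc%04d", seq_len(n))
    scaffolds <- character(n)
    truth <- data.frame(scaffold_id = ids, chrom = character(n),
                        start = integer(n), end = integer(n),
                        orientation = character(n), length = integer(n),
                        stringsAsFactors = FALSE)
    gm <- gene_models
    for (k in seq_len(n)) {
      p <- pieces[[ord[k]]]
      s <- substr(genome[[p$chrom]], p$start, p$end)
      ori <- if (flip[ord[k]]) "-" else "+"
      if (ori == "-") s <- revcomp(s)
      scaffolds[k] <- s
      truth$chrom[k] <- p$chrom; truth$start[k] <- p$start
      truth$end[k] <- p$end; truth$orientation[k] <- ori
      truth$length[k] <- p$end - p$start + 1L
      # re-coordinate genes fully inside this piece
      sel <- which(gm$seq_id == p$chrom & gene_models$start >= p$start &
                     gene_models$end <= p$end)
      for (i in sel) {
        tr <- function(x) if (ori == "+") x - p$start + 1L else p$end - x + 1L
        seg <- function(m) {
          res <- cbind(start = pmin(tr(m[, 1L]), tr(m[, 2L])),
                       end = pmax(tr(m[, 1L]), tr(m[, 2L])))
          res[order(res[, 1L]), , drop = FALSE]
        }
        ns <- tr(gene_models$start[i]); ne <- tr(gene_models$end[i])
        gm$start[i] <- min(ns, ne); gm$end[i] <- max(ns, ne)
        gm$strand[i] <- if (ori == "+") gene_models$strand[i]
                        else if (gene_models$strand[i] == "+") "-" else "+"
        gm$cds[[i]] <- seg(gene_models$cds[[i]])
        gm$exons[[i]] <- seg(gene_models$exons[[i]])
        gm$seq_id[i] <- ids[k]
      }
    }
    names(scaffolds) <- ids
    keep <- gm$seq_id %in% ids
    gm <- gm[keep, , drop = FALSE]
    list(scaffolds = scaffolds, genes = gm, truth = truth)
  })
}

#' Simulate a genetic map over a fragmented genome
#'
#' Markers are placed uniformly along each chromosome; their cM positions
#' are the true bp scaled by \code{cM_per_Mb} plus Gaussian noise, and
#' their scaffold placements are derived from the fragmentation truth
#' (orientation-aware).
#'
#' @param truth Fragmentation truth from [fragment_scaffolds()].
#' @param chrom_lengths Named chromosome lengths.
#' @param markers_per_chrom Markers per chromosome.
#' @param cM_per_Mb Map expansion (default 4 cM/Mb, a typical plant
#'   recombination density).
#' @param positional_noise_cM SD of Gaussian cM noise (default 0).
#' @param seed Mandatory RNG seed.
#' @return Genetic-map data frame ([read_genetic_map()] schema).
#' @export
simulate_map <- function(truth, chrom_lengths, markers_per_chrom = 10L,
                         cM_per_Mb = 4, positional_noise_cM = 0, seed) {
  with_seed(seed, {
    rows <- list()
    mi <- 0L
    for (chr in names(chrom_lengths)) {
      if (markers_per_chrom == 0L) next
      pos <- sort(sample.int(chrom_lengths[[chr]], markers_per_chrom))
      cm <- pos / 1e6 * cM_per_Mb +
        rnorm(markers_per_chrom, 0, positional_noise_cM)
      cm <- pmax(cm, 0)
      tr <- truth[truth$chrom == chr, , drop = FALSE]
      for (j in seq_along(pos)) {
        k <- which(tr$start <= pos[j] & tr$end >= pos[j])[1L]
        local <- if (tr$orientation[k] == "+") pos[j] - tr$start[k] + 1L
                 else tr$end[k] - pos[j] + 1L
        mi <- mi + 1L
        rows[[mi]] <- data.frame(
          marker_id = sprintf("m%04d", mi), linkage_group = chr,
          cM = cm[j], scaffold_id = tr$scaffold_id[k], position_bp = local,
          placed = TRUE, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(marker_id = character(0), linkage_group = character(0),
                        cM = numeric(0), scaffold_id = character(0),
                        position_bp = numeric(0), placed = logical(0)))
    do.call(rbind, rows)
  })
}

#' Simulate an ortholog hit table against the reference genome
#'
#' Each scaffold gene hits its true reference ortholog (the gene it was
#' fragmented from) with probability \code{1 - miss_rate}, at a strong
#' E-value; spurious hits to random chromosomes are added with probability
#' \code{spurious_rate} per gene at weaker scores, so they only become
#' best hits when the true hit is missing.
#'
#' @param scaffold_genes \code{gene_models} in scaffold coordinates.
#' @param ref_genes \code{gene_models} in reference coordinates (same
#'   gene ids).
#' @param miss_rate,spurious_rate Probabilities in [0, 1].
#' @param seed Mandatory RNG seed.
#' @return Hit-table data frame ([read_hit_table()] schema).
#' @export
simulate_hits <- function(scaffold_genes, ref_genes, miss_rate = 0,
                          spurious_rate = 0, seed) {
  stopifnot(miss_rate >= 0, miss_rate <= 1,
            spurious_rate >= 0, spurious_rate <= 1)
  ref_idx <- setNames(seq_len(nrow(ref_genes)), ref_genes$gene_id)
  chroms <- unique(ref_genes$seq_id)
  chrom_max <- vapply(chroms, function(ch)
    max(ref_genes$end[ref_genes$seq_id == ch]), numeric(1))
  with_seed(seed, {
    rows <- list()
    for (i in seq_len(nrow(scaffold_genes))) {
      gid <- scaffold_genes$gene_id[i]
      j <- ref_idx[gid]
      if (!is.na(j) && runif(1) >= miss_rate) {
        rows[[length(rows) + 1L]] <- data.frame(
          query_gene_id = gid, ref_gene_id = paste0(gid, "_ref"),
          ref_chrom = ref_genes$seq_id[j],
          ref_start_bp = ref_genes$start[j], ref_end_bp = ref_genes$end[j],
          evalue = 1e-50, bitscore = 500, stringsAsFactors = FALSE)
      }
      if (runif(1) < spurious_rate) {
        ch <- sample(chroms, 1L)
        st <- sample.int(max(1, chrom_max[[ch]] - 1000L), 1L)
        rows[[length(rows) + 1L]] <- data.frame(
          query_gene_id = gid, ref_gene_id = sprintf("spur_%05d", length(rows)),
          ref_chrom = ch, ref_start_bp = st, ref_end_bp = st + 999L,
          evalue = 1e-8, bitscore = 80, stringsAsFactors = FALSE)
      }
    }
    if (!length(rows))
      return(data.frame(query_gene_id = character(0),
                        ref_gene_id = character(0), ref_chrom = character(0),
                        ref_start_bp = numeric(0), ref_end_bp = numeric(0),
                        evalue = numeric(0), bitscore = numeric(0)))
    do.call(rbind, rows)
  })
}

#' Simulate a diploid variant set over a genome
#'
#' SNP substitutions are drawn to hit the target Ts/Tv in expectation;
#' indel lengths are uniform on 1..15; per-sample genotypes are
#' heterozygous with probability \code{het_fraction} (otherwise hom-ref or
#' hom-alt equally); DP, GQ and site QUAL are sampled so hard filters are
#' exercisable.  Variant spans never overlap.
#'
#' @param genome Named character vector of sequences.
#' @param snp_rate,indel_rate Expected variants per bp.
#' @param ts_tv Target transition/transversion ratio (default 1.5).
#' @param het_fraction Per-sample heterozygote probability.
#' @param n_samples Number of samples.
#' @param dp_mean Mean of the Poisson per-sample depth (default 30).
#' @param qual_range,gq_range Ranges for site QUAL and per-sample GQ.
#' @param seed Mandatory RNG seed.
#' @return List with \code{variants} (a \code{variant_set}) and
#'   \code{truth} (data.frame with \code{type} and \code{is_transition}).
#' @export
simulate_variants <- function(genome, snp_rate = 0.002, indel_rate = 3e-4,
                              ts_tv = 1.5, het_fraction = 0.3,
                              n_samples = 6L, dp_mean = 30,
                              qual_range = c(100, 999), gq_range = c(30, 99),
                              seed) {
  TS <- c(A = "G", G = "A", C = "T", T = "C")
  TV <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"),
             T = c("A", "G"))
  with_seed(seed, {
    sites <- list()
    for (chr in names(genome)) {
      len <- nchar(genome[[chr]])
      n_snp <- round(len * snp_rate)
      n_ind <- round(len * indel_rate)
      pos <- sample.int(len - 20L, n_snp + n_ind)
      is_ind <- c(rep(FALSE, n_snp), rep(TRUE, n_ind))
      # drop overlapping spans (16 bp safety) by rejection
      o <- order(pos)
      pos <- pos[o]; is_ind <- is_ind[o]
      keep <- c(TRUE, diff(pos) > 16L)
      pos <- pos[keep]; is_ind <- is_ind[keep]
      base <- substring(genome[[chr]], pos, pos)
      ok <- base %in% BASES
      pos <- pos[ok]; is_ind <- is_ind[ok]; base <- base[ok]
      for (i in seq_along(pos)) {
        if (!is_ind[i]) {
          transition <- runif(1) < ts_tv / (1 + ts_tv)
          alt <- if (transition) TS[[base[i]]] else sample(TV[[base[i]]], 1L)
          sites[[length(sites) + 1L]] <- data.frame(
            chrom = chr, pos = pos[i], ref = base[i], alt = alt,
            type = "snp", is_transition = transition,
            stringsAsFactors = FALSE)
        } else {
          L <- sample.int(15L, 1L)
          if (runif(1) < 0.5) {        # insertion after pos
            ins <- paste(sample(BASES, L, replace = TRUE), collapse = "")
            sites[[length(sites) + 1L]] <- data.frame(
              chrom = chr, pos = pos[i], ref = base[i],
              alt = paste0(base[i], ins), type = "ins",
              is_transition = NA, stringsAsFactors = FALSE)
          } else {                     # deletion of L bases after pos
            refseq <- substr(genome[[chr]], pos[i], pos[i] + L)
            if (grepl("N", refseq)) next
            sites[[length(sites) + 1L]] <- data.frame(
              chrom = chr, pos = pos[i], ref = refseq, alt = base[i],
              type = "del", is_transition = NA, stringsAsFactors = FALSE)
          }
        }
      }
    }
    truth <- do.call(rbind, sites)
    n <- nrow(truth)
    samples <- sprintf("S%02d", seq_len(n_samples))
    gt <- matrix("0/0", n, n_samples, dimnames = list(NULL, samples))
    draw <- matrix(runif(n * n_samples), n, n_samples)
    gt[draw < het_fraction] <- "0/1"
    gt[draw >= het_fraction & draw < het_fraction + (1 - het_fraction) / 2] <- "1/1"
    dp <- matrix(rpois(n * n_samples, dp_mean), n, n_samples,
                 dimnames = list(NULL, samples))
    gq <- matrix(sample(gq_range[1L]:gq_range[2L], n * n_samples,
                        replace = TRUE), n, n_samples,
                 dimnames = list(NULL, samples))
    vs <- variant_set(
      data.frame(chrom = truth$chrom, pos = truth$pos, ref = truth$ref,
                 alt = truth$alt,
                 qual = round(runif(n, qual_range[1L], qual_range[2L]), 1),
                 stringsAsFactors = FALSE),
      gt = gt, dp = dp, gq = gq)
    list(variants = vs, truth = truth)
  })
}

#' Simulate uniform-coverage reads from a genome
#'
#' Read starts are uniform within each chromosome, strands are drawn
#' 50/50, and per-base substitution errors occur at \code{error_rate}.
#'
#' @param genome Named character vector of sequences.
#' @param coverage Target fold coverage.
#' @param read_len Read length (default 93).
#' @param error_rate Per-base substitution probability (default 0).
#' @param seed Mandatory RNG seed.
#' @return Character vector of reads (named \code{read000001}...).
#' @export
simulate_reads <- function(genome, coverage, read_len = 93L, error_rate = 0,
                           seed) {
  lens <- nchar(genome)
  if (read_len > max(lens)) stop("read_len longer than every sequence")
  with_seed(seed, {
    out <- list()
    for (chr in names(genome)) {
      len <- lens[[chr]]
      if (read_len > len) next
      n <- round(coverage * len / read_len)
      starts <- sample.int(len - read_len + 1L, n, replace = TRUE)
      reads <- substring(genome[[chr]], starts, starts + read_len - 1L)
      flip <- sample(c(TRUE, FALSE), n, replace = TRUE)
      if (any(flip)) reads[flip] <- revcomp(reads[flip])
      if (error_rate > 0) {
        n_err <- rbinom(1L, n * read_len, error_rate)
        if (n_err > 0L) {
          ri <- sample.int(n, n_err, replace = TRUE)
          pi <- sample.int(read_len, n_err, replace = TRUE)
          for (e in seq_len(n_err)) {
            old <- substr(reads[ri[e]], pi[e], pi[e])
            new <- sample(setdiff(BASES, old), 1L)
            substr(reads[ri[e]], pi[e], pi[e]) <- new
          }
        }
      }
      out[[chr]] <- reads
    }
    reads <- unlist(out, use.names = FALSE)
    names(reads) <- sprintf("read%06d", seq_along(reads))
    reads
  })
}

#' Write reads as FASTQ (constant quality)
#' @param reads Named character vector of reads.
#' @param path Output path.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", names(reads), "\n", reads, "\n+\n",
                    strrep("I", nchar(reads))), con)
  invisible(path)
}
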