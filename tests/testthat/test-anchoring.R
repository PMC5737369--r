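mk_map <- function(...) {
  rows <- list(...)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(marker_id = r[[1L]], linkage_group = r[[2L]],
               cM = as.numeric(r[[3L]]), scaffold_id = r[[4L]],
               position_bp = as.numeric(r[[5L]]), placed = TRUE,
               stringsAsFactors = FALSE)))
  df
}

test_that("map_assign: majority chromosome, median key, slope orientation", {
  mp <- mk_map(list("m1", "LG2", 5, "sc1", 1000),
               list("m2", "LG2", 7, "sc1", 5000),
               list("m3", "LG2", 9, "sc1", 9000))
  a <- map_assign(mp)
  expect_identical(a$chromosome, "LG2")
  expect_identical(a$orientation, "+")      # cM increases with bp
  expect_equal(a$order_key, 7)
  expect_identical(a$n_support, 3L)

  # decreasing cM with bp -> minus orientation
  a2 <- map_assign(mk_map(list("m1", "LG1", 9, "sc1", 1000),
                          list("m2", "LG1", 5, "sc1", 8000)))
  expect_identical(a2$orientation, "-")

  # 1 locus each on two groups: no strict majority -> unassigned
  a3 <- map_assign(mk_map(list("m1", "LG1", 1, "sc1", 100),
                          list("m2", "LG3", 2, "sc1", 900)))
  expect_identical(nrow(a3), 0L)
  expect_identical(attr(a3, "unassigned"), "sc1")

  # single locus: assigned but unorientable
  a4 <- map_assign(mk_map(list("m1", "LG1", 3, "sc1", 100)))
  expect_identical(a4$orientation, "unknown")
})

test_that("best_hits is fully deterministic under the stated tie order", {
  h <- data.frame(
    query_gene_id = c("g", "g"), ref_gene_id = c("rA", "rB"),
    ref_chrom = "chr1", ref_start_bp = c(10, 20), ref_end_bp = c(19, 29),
    evalue = c(1e-20, 1e-8), bitscore = c(100, 500),
    stringsAsFactors = FALSE)
  expect_identical(best_hits(h)$ref_gene_id, "rA")     # lowest evalue

  h$evalue <- c(1e-20, 1e-20); h$bitscore <- c(200, 150)
  expect_identical(best_hits(h)$ref_gene_id, "rA")     # higher bitscore

  h$bitscore <- c(150, 150); h$ref_start_bp <- c(50, 20)
  expect_identical(best_hits(h)$ref_gene_id, "rB")     # smaller ref_start

  h$ref_start_bp <- c(20, 20)
  expect_identical(best_hits(h)$ref_gene_id, "rA")     # lexicographic id
})

mk_genes <- function(sc, n, start0 = 1000, step = 1000) {
  gm <- data.frame(gene_id = sprintf("%s_g%d", sc, 1:n), seq_id = sc,
                   start = start0 + (0:(n - 1)) * step,
                   end = start0 + (0:(n - 1)) * step + 200,
                   strand = "+", stringsAsFactors = FALSE)
  gm$cds <- replicate(n, cbind(start = integer(0), end = integer(0)),
                      simplify = FALSE)
  gm$exons <- gm$cds
  class(gm) <- c("gene_models", "data.frame")
  gm
}

mk_hits <- function(gene_ids, chroms, ref_mids) {
  data.frame(query_gene_id = gene_ids, ref_gene_id = paste0(gene_ids, "_r"),
             ref_chrom = chroms, ref_start_bp = ref_mids - 50,
             ref_end_bp = ref_mids + 50, evalue = 1e-50, bitscore = 500,
             stringsAsFactors = FALSE)
}

test_that("collinear_runs segments by chromosome, hitless genes transparent", {
  gm <- mk_genes("sc1", 6)
  bh <- mk_hits(gm$gene_id, rep("chr3", 6), seq(10000, 60000, by = 10000))
  runs <- collinear_runs(gm, bh, anchoring_params())
  expect_length(runs, 1L)
  expect_length(runs[[1L]]$gene_id, 6L)

  # chr3,chr3,chr1,chr3x4 -> runs of 2 and 4, both below min 5 -> none
  gm7 <- mk_genes("sc1", 7)
  bh7 <- mk_hits(gm7$gene_id, c("chr3", "chr3", "chr1", rep("chr3", 4)),
                 seq(1e4, 7e4, by = 1e4))
  expect_length(collinear_runs(gm7, bh7, anchoring_params()), 0L)
  # ... but visible at min_genes = 2
  runs7 <- collinear_runs(gm7, bh7, anchoring_params(min_genes = 2))
  expect_identical(vapply(runs7, function(r) length(r$gene_id), integer(1)),
                   c(2L, 4L))

  # a hitless gene does not break the run
  gm6 <- mk_genes("sc1", 6)
  bh6 <- mk_hits(gm6$gene_id[-2L], rep("chr3", 5), seq(1e4, 5e4, by = 1e4))
  runs6 <- collinear_runs(gm6, bh6, anchoring_params())
  expect_length(runs6, 1L)
  expect_length(runs6[[1L]]$gene_id, 5L)
})

test_that("synteny_assign accepts by strict R2 and signs orientation", {
  run <- list(scaffold_id = "sc1", ref_chrom = "chr2",
              gene_id = paste0("g", 1:5),
              scaffold_mid = c(1, 2, 3, 4, 5) * 1000,
              ref_mid = c(1, 2, 3, 4, 5) * 10000)
  a <- synteny_assign(run, anchoring_params())
  expect_s3_class(a, "data.frame")
  expect_identical(a$orientation, "+")
  expect_equal(a$r2, 1)
  expect_equal(a$order_key, 30000)

  run$ref_mid <- rev(run$ref_mid)
  expect_identical(synteny_assign(run, anchoring_params())$orientation, "-")

  # R2 checked against an independent OLS (squared correlation)
  set.seed(99)
  run$ref_mid <- sample(c(1, 5, 2, 4, 3) * 10000)
  r2_oracle <- cor(run$scaffold_mid, run$ref_mid)^2
  res <- synteny_assign(run, anchoring_params())
  if (r2_oracle > 0.6) {
    expect_equal(res$r2, r2_oracle, tolerance = 1e-12)
  } else {
    expect_true(is.list(res) && isTRUE(res$rejected))
    expect_equal(res$r2, r2_oracle, tolerance = 1e-12)
  }

  # zero variance in scaffold positions is a stated rejection
  run0 <- list(scaffold_id = "s", ref_chrom = "c", gene_id = paste0("g", 1:5),
               scaffold_mid = rep(1000, 5), ref_mid = 1:5 * 1000)
  expect_match(synteny_assign(run0, anchoring_params())$reason,
               "zero variance")
})

test_that("merge_assignments: map precedence, synteny key inheritance", {
  ma <- data.frame(scaffold_id = "sc1", chromosome = "chr1",
                   orientation = "+", order_key = 12, key_type = "cM",
                   evidence = "map", n_support = 3L, r2 = NA_real_,
                   cM = 12, conflict = FALSE, stringsAsFactors = FALSE)
  sa <- data.frame(scaffold_id = c("sc1", "sc2"),
                   chromosome = c("chr1", "chr5"),
                   orientation = c("-", "+"), order_key = c(2.3e6, 1e6),
                   key_type = "bp", evidence = "synteny",
                   n_support = c(6L, 5L), r2 = c(0.95, 0.99),
                   cM = NA_real_, conflict = FALSE, stringsAsFactors = FALSE)
  m <- merge_assignments(ma, sa)
  r1 <- m[m$scaffold_id == "sc1", ]
  expect_identical(r1$chromosome, "chr1")
  expect_identical(r1$orientation, "+")          # map orientation kept
  expect_equal(r1$order_key, 2.3e6)              # synteny bp key inherited
  expect_identical(r1$key_type, "bp")
  expect_false(r1$conflict)
  # synteny-only scaffold passes through unchanged
  expect_identical(m[m$scaffold_id == "sc2", "chromosome"], "chr5")

  # disagreeing chromosome: map wins, conflict flagged
  sa2 <- sa; sa2$chromosome[1L] <- "chr2"
  m2 <- merge_assignments(ma, sa2)
  r2 <- m2[m2$scaffold_id == "sc1", ]
  expect_identical(r2$chromosome, "chr1")
  expect_true(r2$conflict)
  expect_identical(attr(m2, "conflicts"), "sc1")
})

test_that("build_layout sorts by key, interpolates cM-only, breaks ties", {
  a <- data.frame(scaffold_id = c("A", "B", "C"), chromosome = "chr1",
                  orientation = "+", order_key = c(5e6, 1e6, 3e6),
                  key_type = "bp", evidence = "synteny", n_support = 5L,
                  r2 = 0.9, cM = NA_real_, conflict = FALSE,
                  stringsAsFactors = FALSE)
  lay <- build_layout(a, c(chr1 = 6e6))
  expect_identical(lay$chromosomes$chr1$scaffold_id, c("B", "C", "A"))

  # cM-only scaffold interpolated between dual-keyed anchors
  b <- data.frame(scaffold_id = c("A", "B", "M"), chromosome = "chr1",
                  orientation = "+", order_key = c(1e6, 5e6, 30),
                  key_type = c("bp", "bp", "cM"), evidence = "map",
                  n_support = 2L, r2 = NA_real_, cM = c(10, 50, 30),
                  conflict = FALSE, stringsAsFactors = FALSE)
  lay2 <- build_layout(b, c(chr1 = 6e6))
  expect_identical(lay2$chromosomes$chr1$scaffold_id, c("A", "M", "B"))

  # equal keys: longer scaffold first
  d <- a; d$order_key <- 1e6
  lay3 <- build_layout(d, c(chr1 = 6e6),
                       scaffold_lengths = c(A = 8000, B = 10000, C = 9000))
  expect_identical(lay3$chromosomes$chr1$scaffold_id, c("B", "C", "A"))

  # unknown chromosome errors
  expect_error(build_layout(a, c(chr9 = 1e6)), "missing from ref")
})

test_that("raising r2 or min_genes never increases synteny assignments", {
  gen <- generate_genome(n_chrom = 2L, chrom_len = 100000L,
                         gene_density = 500, seed = 21)
  frag <- fragment_scaffolds(gen$genome, gen$genes, n_scaffolds = 25L,
                             seed = 22)
  hits <- simulate_hits(frag$genes, gen$genes, miss_rate = 0.2,
                        spurious_rate = 0.2, seed = 23)
  bh <- best_hits(hits)
  n_assigned <- function(min_genes, r2) {
    p <- anchoring_params(min_genes = min_genes, r2_threshold = r2)
    nrow(synteny_assign_all(collinear_runs(frag$genes, bh, p), p))
  }
  for (r2s in list(c(0.3, 0.6, 0.9))) {
    ns <- vapply(r2s, function(r) n_assigned(5, r), numeric(1))
    expect_true(all(diff(ns) <= 0))
  }
  ns2 <- vapply(c(2, 5, 8), function(mg) n_assigned(mg, 0.6), numeric(1))
  expect_true(all(diff(ns2) <= 0))
})
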