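test_that("the shipped enzyme table is the expected 19 palindromic sites", {
  enz <- caps_enzymes()
  expect_identical(nrow(enz), 19L)
  expect_identical(enz$site[enz$name == "EcoRI"], "GAATTC")
  expect_true(all(nchar(enz$site) %in% 4:6))
  # palindromicity is what licenses forward-strand-only counting
  expect_identical(enz$site, oracle_revcomp(enz$site))
})

test_that("caps_scan hand cases: creation, absence, shifted-count tie", {
  enz <- caps_enzymes()
  # EcoRI site GAATTC destroyed by G->A at its first base
  genome <- c(c1 = paste0(strrep("C", 20), "GAATTC", strrep("C", 20)))
  snp <- list(chrom = "c1", pos = 21, ref = "G", alt = "A")
  hits <- caps_scan(snp, genome, enz)
  expect_true("EcoRI" %in% hits)

  # a SNP in a site-free context qualifies for nothing
  genome2 <- c(c1 = strrep("CA", 30))
  snp2 <- list(chrom = "c1", pos = 30, ref = "A", alt = "T")
  expect_length(caps_scan(snp2, genome2, enz), 0L)

  # MboI GATC present once in both alleles (site shifts, count equal):
  # ref ...GATCA..., alt base A->T makes ...GATCT... wait - construct
  # explicitly: window where ref has GATC left of SNP and alt creates
  # GATC right while destroying the left one is a *qualifying* case;
  # the tie case needs equal counts under both alleles.
  # ref: TGATCGATCT with SNP at centre base G->A:
  #   ref TGAT CGATCT -> GATC at 2, CGAT..; count(GATC): ref "TGATCGATC T"
  genome3 <- c(c1 = "CCCGATCGATCCC")
  # pos 8: ref G (second GATC start); window covers both sites
  snp3 <- list(chrom = "c1", pos = 8, ref = "G", alt = "A")
  got <- "MboI" %in% caps_scan(snp3, genome3, enz)
  want <- "MboI" %in% oracle_caps(snp3, genome3, enz)
  expect_identical(got, want)

  # SNP too close to an end: long-site enzymes skipped with a flag
  genome4 <- c(c1 = "GAATTCAA")
  snp4 <- list(chrom = "c1", pos = 2, ref = "A", alt = "G")
  res <- caps_scan(snp4, genome4, enz)
  expect_true("ApaI" %in% attr(res, "skipped"))
})

test_that("caps_scan equals the in-silico digest oracle on 500 seeded scenes", {
  enz <- caps_enzymes()
  set.seed(500)
  sites <- enz$site
  n_scene <- 500L
  n_qual <- 0L
  for (s in seq_len(n_scene)) {
    # half the scenes get an enzyme site planted near the SNP so the
    # comparison exercises both outcomes
    core <- if (s %% 2L == 0L) sample(sites, 1L) else rand_seq(6)
    seqstr <- paste0(rand_seq(sample(8:14, 1L)), core,
                     rand_seq(sample(8:14, 1L)))
    pos <- sample(6:(nchar(seqstr) - 6L), 1L)
    ref <- substr(seqstr, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    genome <- c(c1 = seqstr)
    snp <- list(chrom = "c1", pos = pos, ref = ref, alt = alt)
    got <- caps_scan(snp, genome, enz)
    want <- oracle_caps(snp, genome, enz)
    skipped <- attr(got, "skipped")
    expect_identical(as.character(got), setdiff(want, skipped))
    n_qual <- n_qual + length(got)
  }
  expect_gt(n_qual, 0L)   # the suite exercised qualifying scenes
})

test_that("CAPS decisions are invariant under window reverse complement", {
  enz <- caps_enzymes()
  set.seed(77)
  for (s in 1:50) {
    seqstr <- paste0(rand_seq(10), sample(enz$site, 1L), rand_seq(10))
    pos <- sample(6:(nchar(seqstr) - 6L), 1L)
    ref <- substr(seqstr, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    fwd <- caps_scan(list(chrom = "c", pos = pos, ref = ref, alt = alt),
                     c(c = seqstr), enz)
    L <- nchar(seqstr)
    rev <- caps_scan(list(chrom = "c", pos = L - pos + 1L,
                          ref = oracle_revcomp(ref),
                          alt = oracle_revcomp(alt)),
                     c(c = oracle_revcomp(seqstr)), enz)
    expect_setequal(as.character(fwd), as.character(rev))
  }
})

test_that("select_indel_markers keeps 1..15 bp events only", {
  vs <- variant_set(data.frame(
    chrom = "c", pos = c(10, 40, 70, 100),
    ref = c("A", "A", paste0("A", strrep("T", 16)), "AGT"),
    alt = c("G", "AT", "A", "A"), qual = 1, stringsAsFactors = FALSE))
  sel <- select_indel_markers(vs)
  expect_identical(sel$sites$pos, c(40, 100))   # SNP and 16-bp del excluded
  # the 16-bp event is admitted when the cap is raised
  expect_identical(n_variants(select_indel_markers(vs, max_len = 16)), 3L)
})

test_that("canonical_motif enumerates rotations and strand", {
  expect_identical(canonical_motif("GA"), "AG")
  expect_identical(canonical_motif("CTT"), "AAG")
  expect_identical(canonical_motif("ATTTTT"), "AAAAAT")
  expect_error(canonical_motif("ATAT"), "degenerate")
  # idempotence and class closure
  set.seed(31)
  for (u in 2:4) {
    for (rep in 1:10) {
      unit <- rand_seq(u)
      if (!anchorage:::is_primitive_unit(unit)) next
      cm <- canonical_motif(unit)
      expect_identical(canonical_motif(cm), cm)
      # all rotations of both strands map to the same class
      rots <- vapply(0:(u - 1L), function(i)
        paste0(substr(unit, i + 1L, u), substr(unit, 1L, i)), character(1))
      for (r in c(rots, oracle_revcomp(rots)))
        expect_identical(canonical_motif(r), cm)
    }
  }
  # exactly four canonical dinucleotide classes
  dimers <- as.vector(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                            paste0))
  prim <- dimers[vapply(dimers, anchorage:::is_primitive_unit, logical(1))]
  expect_setequal(unique(vapply(prim, canonical_motif, character(1))),
                  c("AC", "AG", "AT", "CG"))
})

test_that("find_ssrs hand cases: perfect repeat, threshold, interruption", {
  r <- find_ssrs(strrep("AG", 10))
  expect_identical(nrow(r), 1L)
  expect_identical(r$canonical_motif, "AG")
  expect_identical(c(r$start, r$end), c(1L, 20L))
  expect_equal(r$score, 20)
  expect_identical(r$n_mismatches, 0L)

  # (AT)x4 = 8 < min score 15
  expect_identical(nrow(find_ssrs(strrep("AT", 4))), 0L)

  # interrupted repeat merges across the mismatch: score 24 - 5 = 19
  s <- paste0(strrep("AG", 6), "C", strrep("AG", 6))
  r3 <- find_ssrs(s)
  expect_identical(nrow(r3), 1L)
  expect_identical(c(r3$start, r3$end), c(1L, 25L))
  expect_equal(r3$score, 19)
  expect_identical(r3$n_mismatches, 1L)

  # N never matches
  rn <- find_ssrs(paste0(strrep("AG", 6), "N", strrep("AG", 6)))
  expect_equal(max(rn$score), 19)
})

test_that("find_ssrs with infinite penalty equals the perfect-repeat oracle", {
  params <- ssr_params(mismatch_penalty = Inf, min_score = 12)
  set.seed(4242)
  for (i in 1:300) {
    # biased alphabet makes repeats common enough to exercise the scan
    s <- paste(sample(c("A", "C", "G", "T"), 80, replace = TRUE,
                      prob = c(0.4, 0.1, 0.1, 0.4)), collapse = "")
    got <- find_ssrs(s, params)
    want <- oracle_perfect_ssrs(s, params)
    expect_identical(got[, c("start", "end", "unit_len")],
                     want[, c("start", "end", "unit_len")],
                     info = s)
    expect_equal(got$score, want$score, info = s)
  }
})

test_that("finite-penalty extension scores match the memoised DP oracle", {
  set.seed(555)
  pen <- 5
  for (i in 1:200) {
    u <- sample(2:4, 1L)
    unit <- rand_seq(u)
    if (!anchorage:::is_primitive_unit(unit)) next
    chars <- strsplit(paste(sample(c(strsplit(strrep(unit, 3), "")[[1L]],
                                     sample(c("A", "C", "G", "T"), 12,
                                            replace = TRUE))),
                            collapse = ""), "")[[1L]]
    uc <- strsplit(unit, "", fixed = TRUE)[[1L]]
    got <- anchorage:::extend_run(chars, uc, pen)
    want <- oracle_extension_score(chars, uc, pen)
    expect_equal(got$score, want)
  }
})

test_that("implanted SSRs are recovered exactly", {
  gen <- generate_genome(n_chrom = 1L, chrom_len = 30000L, gene_density = 100,
                         ssr_implants = data.frame(
                           chrom = "chr1", pos = c(5000, 12000, 20000),
                           motif = c("AG", "AAG", "AAAT"),
                           copies = c(12, 8, 6)), seed = 9001)
  loci <- find_ssrs(gen$genome[[1L]], seq_id = "chr1")
  tr <- gen$truth$ssrs
  for (i in seq_len(nrow(tr))) {
    hit <- loci[loci$start <= tr$start[i] & loci$end >= tr$end[i] - 3L, ]
    expect_gte(nrow(hit), 1L)
    expect_identical(hit$canonical_motif[1L], tr$motif[i])
  }
})

test_that("classify_genic overlaps gene spans by >= 1 bp", {
  gm <- data.frame(gene_id = "g", seq_id = "s", start = 100, end = 200,
                   strand = "+", stringsAsFactors = FALSE)
  gm$cds <- list(cbind(start = 100, end = 200)); gm$exons <- gm$cds
  class(gm) <- c("gene_models", "data.frame")
  expect_true(classify_genic(list(seq_id = "s", start = 150, end = 160), gm))
  expect_false(classify_genic(list(seq_id = "s", start = 201, end = 220), gm))
  expect_true(classify_genic(list(seq_id = "s", start = 190, end = 210), gm))
  expect_false(classify_genic(list(seq_id = "other", start = 150,
                                   end = 160), gm))
})

test_that("primer_tm matches the independent nearest-neighbor oracle", {
  set.seed(61)
  for (i in 1:30) {
    p <- rand_seq(sample(18:25, 1L))
    expect_equal(primer_tm(p), oracle_tm(p), tolerance = 1e-9)
  }
})

test_that("design_primer_pair hand cases and failure tallies", {
  # all-N flanks cannot host a primer
  template <- paste0(strrep("N", 60), "ACGTACGTAC", strrep("N", 60))
  res <- design_primer_pair(template, 61L, 70L)
  expect_false(primer_found(res))

  # a template shorter than the minimum product reports 'product'
  set.seed(62)
  short <- rand_seq(70)
  res2 <- design_primer_pair(short, 30L, 40L)
  expect_false(primer_found(res2))
})

test_that("designed pairs satisfy all constraints when rechecked", {
  set.seed(63)
  cons <- primer_constraints()
  found <- 0L
  for (i in 1:20) {
    template <- rand_seq(300, gc = 0.5)
    res <- design_primer_pair(template, 140L, 160L, cons)
    if (!primer_found(res)) next
    found <- found + 1L
    for (p in c(res$left_seq, res$right_seq)) {
      tm <- oracle_tm(p)
      expect_gte(tm, cons$tm_min); expect_lte(tm, cons$tm_max)
      gcp <- 100 * sum(strsplit(p, "")[[1L]] %in% c("G", "C")) / nchar(p)
      expect_gte(gcp, cons$gc_min); expect_lte(gcp, cons$gc_max)
      expect_lte(max(rle(strsplit(p, "")[[1L]])$lengths), cons$max_homo)
    }
    expect_lte(abs(res$left_tm - res$right_tm), cons$max_dtm)
    expect_gte(res$product_len, cons$product_min)
    expect_lte(res$product_len, cons$product_max)
    expect_lte(res$left_end, 139L)
    expect_gte(res$right_start, 161L)
    # the emitted sequences really are template / template-revcomp
    expect_identical(res$left_seq,
                     substr(template, res$left_start, res$left_end))
    expect_identical(res$right_seq,
                     oracle_revcomp(substr(template, res$right_start,
                                           res$right_end)))
  }
  expect_gt(found, 5L)
})

test_that("design_primer_pair equals the exhaustive oracle on 50 templates", {
  set.seed(64)
  cons <- primer_constraints()
  agree <- 0L
  for (i in 1:50) {
    template <- rand_seq(260, gc = 0.5)
    res <- design_primer_pair(template, 120L, 140L, cons)
    want <- oracle_primer_pair(template, 120L, 140L, cons)
    if (is.null(want)) {
      expect_false(primer_found(res))
    } else {
      expect_true(primer_found(res))
      expect_identical(res$left_seq, want$left$seq)
      expect_identical(res$right_seq, want$right$seq)
      expect_identical(res$left_start, want$left$start)
      expect_identical(res$right_start, want$right$start)
      agree <- agree + 1L
    }
  }
  expect_gt(agree, 10L)
})
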