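# Seed-chain-refine spliced mapping: exact intron recovery on constructed
# gene structures, strand handling, small-gap fusion, hit selection rules and
# cross-arm junction matching.

make_structure <- function(exon_lens, intron_lens) {
  stopifnot(length(intron_lens) == length(exon_lens) - 1L)
  exons <- vapply(exon_lens, oracle_random_dna, character(1))
  introns <- vapply(intron_lens, oracle_random_dna, character(1))
  # pin the exon/intron boundaries: an intron whose first (last) base equals
  # the first (last) base of the neighboring exon makes the junction position
  # shift-ambiguous, so force them to differ for exact-position assertions
  for (i in seq_along(introns)) {
    nx <- substr(exons[i + 1L], 1, 1)
    substr(introns[i], 1, 1) <-
      sample(setdiff(c("A", "C", "G", "T"), nx), 1)
    pv <- substr(exons[i], nchar(exons[i]), nchar(exons[i]))
    substr(introns[i], nchar(introns[i]), nchar(introns[i])) <-
      sample(setdiff(c("A", "C", "G", "T"), pv), 1)
  }
  pieces <- character(0)
  for (i in seq_along(exons)) {
    pieces <- c(pieces, exons[i])
    if (i <= length(introns)) pieces <- c(pieces, introns[i])
  }
  list(transcript = paste(exons, collapse = ""),
       segment = paste(pieces, collapse = ""),
       exon_lens = exon_lens, intron_lens = intron_lens)
}

test_that("a single-exon transcript maps as one block with no introns", {
  set.seed(21)
  st <- make_structure(300L, integer(0))
  scaffold <- paste0(oracle_random_dna(500), st$segment, oracle_random_dna(500))
  chains <- find_exon_blocks(st$transcript, scaffold)
  expect_gte(length(chains), 1L)
  best <- chains[[1]]
  expect_equal(best$strand, "+")
  expect_equal(nrow(best$blocks), 1L)
  expect_equal(best$query_coverage, 1)
  expect_equal(nrow(infer_introns(best)), 0L)
})

test_that("intron sizes and junction positions are recovered exactly", {
  set.seed(22)
  st <- make_structure(c(150L, 120L, 180L), c(250L, 90L))
  scaffold <- paste0(oracle_random_dna(800), st$segment, oracle_random_dna(400))
  chains <- find_exon_blocks(st$transcript, scaffold)
  best <- chains[[1]]
  introns <- infer_introns(best)
  expect_equal(introns$gap_bp, c(250L, 90L))
  expect_equal(introns$junction_query_pos, c(150L, 270L))
  expect_equal(best$score, nchar(st$transcript))  # every base matched
})

test_that("minus-strand genes yield transcript-coordinate junctions", {
  set.seed(23)
  st <- make_structure(c(140L, 160L), 200L)
  scaffold <- paste0(oracle_random_dna(300), oracle_rc(st$segment),
                     oracle_random_dna(300))
  gene <- tiny_gene("gm", st$transcript)
  panels <- list(V = genome_panel(c(sV = scaffold), "V"))
  hit <- map_gene_to_panel(gene, panels)[["V"]]
  expect_equal(hit$strand, "-")
  expect_equal(hit$introns$gap_bp, 200L)
  expect_equal(hit$introns$junction_query_pos, 140L)
})

test_that("genomic gaps below min_intron_bp are fused, not called introns", {
  set.seed(24)
  exon1 <- oracle_random_dna(200)
  exon2 <- oracle_random_dna(200)
  small_insert <- oracle_random_dna(20)   # < 40 bp: alignment artifact
  scaffold <- paste0(oracle_random_dna(300), exon1, small_insert, exon2,
                     oracle_random_dna(300))
  chains <- find_exon_blocks(paste0(exon1, exon2), scaffold)
  expect_equal(nrow(infer_introns(chains[[1]])), 0L)

  cfg_small <- pipeline_config(min_intron_bp = 10L)
  chains2 <- find_exon_blocks(paste0(exon1, exon2), scaffold, cfg_small)
  expect_equal(infer_introns(chains2[[1]], cfg_small)$gap_bp, 20L)
})

test_that("equal-scoring hits resolve to the lexicographically first scaffold", {
  set.seed(25)
  st <- make_structure(c(120L, 120L), 100L)
  scaffold <- paste0(oracle_random_dna(200), st$segment, oracle_random_dna(200))
  gene <- tiny_gene("gt", st$transcript)
  panels <- list(A = genome_panel(c(zz = scaffold, aa = scaffold), "A"))
  hit <- map_gene_to_panel(gene, panels)[["A"]]
  expect_equal(hit$scaffold_id, "aa")
})

test_that("arms below the query-coverage floor are dropped", {
  set.seed(26)
  present <- oracle_random_dna(200)
  absent <- oracle_random_dna(300)
  scaffold <- paste0(oracle_random_dna(300), present, oracle_random_dna(300))
  gene <- tiny_gene("gc", paste0(present, absent))
  panels <- list(A = genome_panel(c(s1 = scaffold), "A"))
  hits <- map_gene_to_panel(gene, panels)   # coverage 0.4 < 0.5
  expect_false("A" %in% names(hits))
  hits2 <- map_gene_to_panel(gene, panels,
                             pipeline_config(min_query_cov = 0.3))
  expect_true("A" %in% names(hits2))
})

test_that("map_genes_to_panels returns per-gene hits in id order", {
  set.seed(27)
  st1 <- make_structure(c(100L, 100L), 80L)
  st2 <- make_structure(c(120L, 120L), 60L)
  scaffold <- paste0(oracle_random_dna(200), st1$segment,
                     oracle_random_dna(2000), st2$segment,
                     oracle_random_dna(200))
  genes <- list(tiny_gene("gB", st2$transcript), tiny_gene("gA", st1$transcript))
  panels <- list(A = genome_panel(c(s1 = scaffold), "A"),
                 V = genome_panel(c(s1 = scaffold), "V"))
  hits <- map_genes_to_panels(genes, panels)
  expect_equal(names(hits), c("gA", "gB"))
  expect_equal(hits$gA$A$introns$gap_bp, 80L)
  expect_equal(hits$gB$V$introns$gap_bp, 60L)
})

test_that("junction matching respects the transcript-position tolerance", {
  mk_hit <- function(positions, gaps, gid = "g1") {
    list(gene_id = gid,
         introns = data.frame(junction_index = seq_along(gaps),
                              gap_bp = gaps,
                              junction_query_pos = positions))
  }
  hits <- list(A = mk_hit(100L, 500L), B = mk_hit(105L, 480L),
               D = mk_hit(92L, 510L), V = mk_hit(100L, 300L))
  q <- match_homologous_introns(hits, tolerance_bp = 12L)
  expect_equal(nrow(q), 1L)
  expect_equal(q$size_V, 300L)
  expect_equal(q$size_B, 480L)

  # one wheat junction drifts beyond tolerance: the quartet is incomplete
  hits$B <- mk_hit(120L, 480L)
  expect_equal(nrow(match_homologous_introns(hits, tolerance_bp = 12L)), 0L)

  # nearest junction wins when several are in range
  hits$B <- mk_hit(c(95L, 104L), c(450L, 480L))
  q2 <- match_homologous_introns(hits, tolerance_bp = 12L)
  expect_equal(q2$size_B, 480L)

  # no alien-arm junctions: nothing to match
  hits$V <- mk_hit(integer(0), integer(0))
  expect_equal(nrow(match_homologous_introns(hits, tolerance_bp = 12L)), 0L)
})
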