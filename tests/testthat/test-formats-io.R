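# On-disk formats, the genome_panel / gene_model constructors and the
# 0-based half-open <-> GFF3 1-based closed coordinate boundary.

test_that("genome_panel validates and normalizes its scaffolds", {
  p <- genome_panel(c(s1 = "acgtNRx!"), "A")
  expect_equal(unname(p$scaffolds["s1"]), "ACGTNRNN")
  expect_equal(p$arm_id, "A")

  expect_error(genome_panel(c("ACGT"), "A"), class = "intronit_format_error")
  expect_error(genome_panel(c(s1 = "ACGT", s1 = "GGGG"), "A"),
               class = "intronit_format_error")
  expect_error(genome_panel(c(s1 = ""), "A"), class = "intronit_format_error")
})

test_that("gene_model enforces exon structure and transcript length", {
  ok <- gene_model("g1", "src", "s1", "+", cbind(c(0L, 30L), c(10L, 40L)),
                   paste(rep("A", 20), collapse = ""))
  expect_s3_class(ok, "gene_model")
  expect_equal(ok$position, 0L)

  expect_error(gene_model("g", "src", "s1", "+", cbind(10L, 10L), ""),
               class = "intronit_format_error")          # empty interval
  expect_error(gene_model("g", "src", "s1", "+",
                          cbind(c(0L, 5L), c(10L, 15L)), "AAAAAAAAAAAAAAAAAAAA"),
               class = "intronit_format_error")          # overlapping exons
  expect_error(gene_model("g", "src", "s1", "*", cbind(0L, 4L), "ACGT"),
               class = "intronit_format_error")          # bad strand
  expect_error(gene_model("g", "src", "s1", "+", cbind(0L, 4L), "ACGTACGT"),
               class = "intronit_format_error")          # length mismatch
})

test_that("spliced_sequence honors strand", {
  scaf <- "AAACCCGGGTTT"
  ex <- cbind(start = c(0L, 9L), end = c(3L, 12L))
  expect_equal(intronIT:::spliced_sequence(scaf, ex, "+"), "AAATTT")
  expect_equal(intronIT:::spliced_sequence(scaf, ex, "-"), "AAATTT")
  ex2 <- cbind(start = c(0L, 6L), end = c(3L, 9L))
  expect_equal(intronIT:::spliced_sequence(scaf, ex2, "+"), "AAAGGG")
  expect_equal(intronIT:::spliced_sequence(scaf, ex2, "-"), "CCCTTT")
})

test_that("FASTA round-trips and headers are cut at the first whitespace", {
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(chr1 = "ACGTACGT", chr2 = "GGGGCCCC"), path)
  p <- read_genome_panel(path, "V")
  expect_equal(p$scaffolds, c(chr1 = "ACGTACGT", chr2 = "GGGGCCCC"))

  desc <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr9 assembly=test extra words", "ACACACAC"), desc)
  expect_equal(names(read_genome_panel(desc, "V")$scaffolds), "chr9")

  expect_error(read_genome_panel(file.path(tempdir(), "nope.fa"), "V"),
               class = "intronit_format_error")
  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_genome_panel(empty, "V"), class = "intronit_format_error")
})

test_that("gene models round-trip through GFF3 on both strands", {
  set.seed(5)
  scaf <- intronIT:::random_dna(600)
  panel <- genome_panel(c(sc1 = scaf), "src")
  ex_p <- cbind(start = c(50L, 200L), end = c(120L, 280L))
  ex_m <- cbind(start = c(300L, 450L), end = c(380L, 520L))
  g_p <- gene_model("gPLUS", "anno", "sc1", "+", ex_p,
                    intronIT:::spliced_sequence(scaf, ex_p, "+"))
  g_m <- gene_model("gMINUS", "anno", "sc1", "-", ex_m,
                    intronIT:::spliced_sequence(scaf, ex_m, "-"))
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gene_models_gff3(list(g_p, g_m), path)
  back <- read_gene_models(panel, path, source = "anno")
  expect_length(back, 2L)
  ids <- vapply(back, `[[`, character(1), "gene_id")
  expect_equal(sort(ids), c("gMINUS", "gPLUS"))
  for (g in back) {
    orig <- if (g$gene_id == "gPLUS") g_p else g_m
    expect_equal(g$exons, orig$exons)
    expect_equal(g$strand, orig$strand)
    expect_equal(g$transcript_seq, orig$transcript_seq)
  }
})

test_that("multi-transcript genes keep the longest transcript, ties by id", {
  scaf <- paste(rep("ACGT", 100), collapse = "")
  panel <- genome_panel(c(sc1 = scaf), "src")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tx\tgene\t1\t200\t.\t+\t.\tID=g1",
    "sc1\tx\tmRNA\t1\t200\t.\t+\t.\tID=g1.a;Parent=g1",
    "sc1\tx\texon\t1\t50\t.\t+\t.\tID=e1;Parent=g1.a",
    "sc1\tx\tmRNA\t1\t200\t.\t+\t.\tID=g1.b;Parent=g1",
    "sc1\tx\texon\t1\t80\t.\t+\t.\tID=e2;Parent=g1.b",
    "sc1\tx\texon\t150\t200\t.\t+\t.\tID=e3;Parent=g1.b"), gff)
  g <- read_gene_models(panel, gff)
  expect_length(g, 1L)
  expect_equal(nrow(g[[1]]$exons), 2L)          # the 131-bp g1.b wins over 50
  expect_equal(nchar(g[[1]]$transcript_seq), 131L)

  tie <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tx\tgene\t1\t200\t.\t+\t.\tID=g1",
    "sc1\tx\tmRNA\t1\t200\t.\t+\t.\tID=g1.zz;Parent=g1",
    "sc1\tx\texon\t1\t50\t.\t+\t.\tID=e1;Parent=g1.zz",
    "sc1\tx\tmRNA\t1\t200\t.\t+\t.\tID=g1.aa;Parent=g1",
    "sc1\tx\texon\t101\t150\t.\t+\t.\tID=e2;Parent=g1.aa"), tie)
  g2 <- read_gene_models(panel, tie)
  # equal lengths: lexicographically first transcript id (g1.aa) wins
  expect_equal(unname(g2[[1]]$exons[1, "start"]), 100L)
})

test_that("orphan exons warn and out-of-bounds exons error", {
  scaf <- paste(rep("ACGT", 25), collapse = "")  # 100 bp
  panel <- genome_panel(c(sc1 = scaf), "src")
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tx\tgene\t1\t60\t.\t+\t.\tID=g1",
    "sc1\tx\tmRNA\t1\t60\t.\t+\t.\tID=g1.t;Parent=g1",
    "sc1\tx\texon\t1\t60\t.\t+\t.\tID=e1;Parent=g1.t",
    "sc1\tx\texon\t1\t30\t.\t+\t.\tID=e2;Parent=ghost"), gff)
  expect_warning(g <- read_gene_models(panel, gff), "Parent")
  expect_length(g, 1L)

  oob <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "sc1\tx\tgene\t1\t500\t.\t+\t.\tID=g1",
    "sc1\tx\tmRNA\t1\t500\t.\t+\t.\tID=g1.t;Parent=g1",
    "sc1\tx\texon\t1\t500\t.\t+\t.\tID=e1;Parent=g1.t"), oob)
  expect_error(read_gene_models(panel, oob), class = "intronit_format_error")
})

test_that("marker tables round-trip, including the empty table", {
  path <- withr::local_tempfile(fileext = ".tsv")
  write_marker_table(NULL, path)
  empty <- read_marker_table(path)
  expect_equal(nrow(empty), 0L)
  expect_equal(names(empty), intronIT:::marker_table_columns)

  df <- data.frame(
    marker_id = c("ITM0002", "ITM0001"), gene_id = c("g2", "g1"),
    junction_index = c(1L, 2L),
    forward_primer = c("ACGTACGTACGTACGTAC", "TTGCAGGACATTGCAGGA"),
    reverse_primer = c("GGCCAATTGGCCAATTGG", "CAGTCAGTCAGTCAGTCA"),
    tm_forward = c(55.5, 60.1), tm_reverse = c(56.5, 59.9),
    intron_A = c(100L, 200L), intron_B = c(110L, 210L),
    intron_D = c(120L, 220L), intron_V = c(160L, 300L),
    product_A = c(180L, 280L), product_B = c(190L, 290L),
    product_D = c(200L, 300L), product_V = c(240L, 380L),
    type = c("I", "V/VII"), is_specific = c(TRUE, FALSE),
    stringsAsFactors = FALSE)
  write_marker_table(df, path)
  back <- read_marker_table(path)
  expect_equal(back$marker_id, c("ITM0001", "ITM0002"))  # sorted on write
  expect_equal(back$intron_V, c(300L, 160L))
  expect_equal(back$is_specific, c(FALSE, TRUE))

  not_marker <- withr::local_tempfile(fileext = ".tsv")
  writeLines("a\tb\n1\t2", not_marker)
  expect_error(read_marker_table(not_marker), class = "intronit_format_error")
})

test_that("alignment tables require exactly 12 columns", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5\t500\t5\t1\t1\t500\t1\t500\t1e-100\t900", path)
  al <- read_alignment_table(path)
  expect_equal(al$qid, "q1")
  expect_equal(al$evalue, 1e-100)
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines("q1\ts1\t98.5", bad)
  expect_error(read_alignment_table(bad), class = "intronit_format_error")
})
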