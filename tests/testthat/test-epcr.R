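# In-silico PCR: binding-site rules (mismatch budget, exact 3' anchor),
# convergent product formation, gel band clustering, band-pattern
# classification and translocation-line bin assignment.

test_that("binding sites respect the mismatch budget and the 3' anchor", {
  set.seed(51)
  primer <- "TGCAAGGTCATCGGTACCTA"
  bg <- oracle_random_dna(400)
  template <- paste0(substr(bg, 1, 100), primer, substr(bg, 101, 400))
  sites <- find_binding_sites(primer, template)
  plus <- sites[sites$strand == "+", ]
  expect_true(100 %in% plus$position)       # 0-based plant position
  expect_equal(plus$mismatches[plus$position == 100], 0L)

  # two internal mismatches still bind; three exceed the budget
  mut2 <- primer
  substr(mut2, 3, 3) <- "A"; substr(mut2, 7, 7) <- "C"
  t2 <- paste0(substr(bg, 1, 100), mut2, substr(bg, 101, 400))
  s2 <- find_binding_sites(primer, t2)
  expect_true(any(s2$position == 100 & s2$mismatches == 2L))
  mut3 <- mut2
  substr(mut3, 11, 11) <- "G"
  t3 <- paste0(substr(bg, 1, 100), mut3, substr(bg, 101, 400))
  s3 <- find_binding_sites(primer, t3)
  expect_false(any(s3$position == 100))

  # a mismatch in the 5 terminal 3' bases breaks the anchor even with budget left
  mut_anchor <- primer
  substr(mut_anchor, 19, 19) <- "G"   # primer ends ...CCTA -> anchor broken
  t4 <- paste0(substr(bg, 1, 100), mut_anchor, substr(bg, 101, 400))
  s4 <- find_binding_sites(primer, t4)
  expect_false(any(s4$position == 100))

  # minus-strand site: plant the reverse complement; anchor is the left end
  t5 <- paste0(substr(bg, 1, 100), oracle_rc(primer), substr(bg, 101, 400))
  s5 <- find_binding_sites(primer, t5)
  expect_true(any(s5$position == 100 & s5$strand == "-"))

  # N in the template counts as a mismatch
  mutN <- primer
  substr(mutN, 3, 3) <- "N"
  t6 <- paste0(substr(bg, 1, 100), mutN, substr(bg, 101, 400))
  s6 <- find_binding_sites(primer, t6)
  expect_true(any(s6$position == 100 & s6$mismatches == 1L))

  expect_error(find_binding_sites("ACGTNACGTACGTACG", template),
               class = "intronit_domain_error")
})

test_that("simulate_pcr amplifies convergent pairs in either arrangement", {
  set.seed(52)
  fwd <- "GGATCGGAAGCTTCAGATCGA"
  rev <- "TGCAAGGTCATCGGTACCTA"
  insert <- oracle_random_dna(300)
  bg1 <- oracle_random_dna(200)
  bg2 <- oracle_random_dna(200)
  # canonical arrangement: F ...insert... rc(R)
  tA <- paste0(bg1, fwd, insert, oracle_rc(rev), bg2)
  panel <- genome_panel(c(s1 = tA), "A")
  amp <- simulate_pcr(fwd, rev, panel)
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$size, nchar(fwd) + 300L + nchar(rev))
  expect_equal(amp$start, 200L)

  # flipped arrangement: R ...insert... rc(F) amplifies the same product size
  tB <- paste0(bg1, rev, insert, oracle_rc(fwd), bg2)
  ampB <- simulate_pcr(fwd, rev, genome_panel(c(s1 = tB), "A"))
  expect_equal(nrow(ampB), 1L)
  expect_equal(ampB$size, nchar(fwd) + 300L + nchar(rev))

  # divergent orientation never amplifies
  tC <- paste0(bg1, oracle_rc(fwd), insert, rev, bg2)
  expect_equal(nrow(simulate_pcr(fwd, rev, genome_panel(c(s1 = tC), "A"))), 0L)

  # products beyond the size cap are suppressed
  tD <- paste0(bg1, fwd, oracle_random_dna(3500), oracle_rc(rev), bg2)
  expect_equal(nrow(simulate_pcr(fwd, rev, genome_panel(c(s1 = tD), "A"))), 0L)
})

test_that("band clustering reproduces the published three-band example", {
  cfg <- pipeline_config()
  # CINAU646-style sizes: 348/354/357 resolve into two wheat bands plus V
  bands <- cluster_bands(c(A = 348, B = 354, D = 357, V = 495), cfg)
  expect_length(bands, 3L)
  sizes <- vapply(bands, `[[`, numeric(1), "size")
  expect_equal(sizes[1], 495)
  expect_true(any(vapply(bands, function(b)
    setequal(b$arms, c("B", "D")), logical(1))))

  # absolute floor: 4 bp apart co-migrates, 5 bp apart resolves (small sizes)
  expect_length(cluster_bands(c(A = 100, V = 104), cfg), 1L)
  expect_length(cluster_bands(c(A = 100, V = 105), cfg), 2L)
  # relative rule at large sizes: 1% of the mean
  expect_length(cluster_bands(c(A = 1000, V = 1009), cfg), 1L)
  expect_length(cluster_bands(c(A = 1000, V = 1012), cfg), 2L)

  expect_error(cluster_bands(c(A = NA_real_)), class = "intronit_domain_error")
})

test_that("band patterns map onto the published type taxonomy", {
  cfg <- pipeline_config()
  type_of <- function(products) {
    classify_marker(cluster_bands(products, cfg))
  }
  four <- type_of(c(A = 682, B = 595, D = 737, V = 483))
  expect_equal(four$type_label, "I")
  expect_true(four$is_specific)
  expect_equal(four$n_bands, 4L)

  expect_equal(type_of(c(A = 300, B = 301, D = 350, V = 250))$type_label, "II")
  expect_equal(type_of(c(A = 300, B = 350, D = 301, V = 250))$type_label, "III")
  expect_equal(type_of(c(A = 350, B = 300, D = 301, V = 250))$type_label, "IV/VI")
  expect_equal(type_of(c(A = 300, B = 301, D = 302, V = 250))$type_label, "V/VII")

  vmerge <- type_of(c(A = 250, B = 400, D = 500, V = 251))
  expect_equal(vmerge$type_label, "unclassified")
  expect_false(vmerge$is_specific)

  noV <- classify_marker(cluster_bands(c(A = 300, B = 400, D = 500,
                                         V = NA_real_), cfg))
  expect_equal(noV$type_label, "no-V")
  expect_false(noV$is_specific)
})

test_that("specificity summary reports counts and the percent rate", {
  s <- rep(c("specific", "amplified-not-specific", "no-amplification"),
           c(3, 2, 1))
  r <- specificity_summary(s)
  expect_equal(r$n_markers, 6L)
  expect_equal(r$n_specific, 3L)
  expect_equal(r$n_amplified, 5L)
  expect_equal(r$n_no_amplification, 1L)
  expect_equal(r$specific_rate_pct, 50)
  expect_true(is.na(specificity_summary(character(0))$specific_rate_pct))
})

test_that("presence matrices are validated and bins assigned from nesting", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\tL1\tL2\tL3",
               "m_all\t1\t1\t1",
               "m_mid\t0\t1\t1",
               "m_prox\t0\t0\t1",
               "m_none\t0\t0\t0",
               "m_bad\t1\t0\t1"), path)
  m <- read_presence_matrix(path)
  expect_equal(dim(m), c(5L, 3L))

  bins <- assign_bins(m, line_order = c("L1", "L2", "L3"))
  by_id <- stats::setNames(bins$bin, bins$marker_id)
  expect_equal(unname(by_id["m_all"]), 1L)    # present everywhere: distal bin
  expect_equal(unname(by_id["m_mid"]), 2L)
  expect_equal(unname(by_id["m_prox"]), 3L)
  expect_equal(unname(by_id["m_none"]), 4L)   # proximal of every breakpoint
  expect_true(is.na(by_id["m_bad"]))
  expect_false(bins$consistent[bins$marker_id == "m_bad"])
  expect_equal(bins$bin_label[bins$marker_id == "m_all"], "distal_of_L1")

  expect_error(assign_bins(m, c("L1", "ghost")),
               class = "intronit_config_error")
  expect_error(assign_bins(m, c("L1", "L2", "L3"), segments = c(3, 2, 5)),
               class = "intronit_config_error")
  b2 <- assign_bins(m, c("L1", "L2", "L3"), segments = c(10, 20, 30))
  expect_equal(b2$bin, bins$bin)

  badval <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("marker\tL1", "m1\t2"), badval)
  expect_error(read_presence_matrix(badval), class = "intronit_format_error")
})
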