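# Independent reference implementations ("oracles") used to cross-check the
# package's algorithms. They deliberately share no code with the package:
# the spliced mapper is checked against a quadratic dynamic program, in-silico
# PCR against an exhaustive position scan, and the nearest-neighbor Tm model
# against values frozen from an external thermodynamics implementation.

# --- plain helpers (no package internals) -----------------------------------

oracle_rc <- function(x) {
  intToUtf8(rev(utf8ToInt(chartr("ACGTN", "TGCAN", x))))
}

oracle_random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- quadratic-DP spliced alignment oracle ----------------------------------
#
# Global in the query, local in the target. Moves: diagonal (match +1 /
# mismatch -1) or an intron jump in the target of length >= min_intron at
# cost jump_pen. No indels. Returns the optimal score; for a transcript whose
# exons occur verbatim in the target separated by k introns (each >=
# min_intron) the optimum is nchar(query) - jump_pen * k, which is exactly
# what an optimal spliced alignment must achieve.
dp_spliced_score <- function(query, target, min_intron = 40L, jump_pen = 2) {
  q <- utf8ToInt(query)
  tt <- utf8ToInt(target)
  m <- length(q)
  n <- length(tt)
  NEG <- -1e9
  prev <- rep(0, n + 1L)  # M[0, j] for j = 0..n: free start anywhere
  for (i in seq_len(m)) {
    s <- (tt == q[i]) * 2 - 1
    diagv <- prev[1:n]            # M[i-1, j-1]
    best_prefix <- cummax(prev)   # index k holds max over j' = 0..k-1
    jump <- rep(NEG, n)
    if (n > min_intron)           # intron j'..j needs j - j' - 1 >= min_intron
      jump[(min_intron + 1L):n] <- best_prefix[1:(n - min_intron)] - jump_pen
    prev <- c(NEG, s + pmax(diagv, jump))
  }
  max(prev[-1L])
}

# --- exhaustive e-PCR oracle -------------------------------------------------
#
# Binding sites by scanning every template offset on both strands, applying
# the documented rules: at most max_mm mismatches over the window, the e3
# 3'-terminal primer bases exact (the right end of the window for a
# plus-strand site, the left end for a minus-strand one), N in the template
# counting as a mismatch.
oracle_scan_sites <- function(primer, template, max_mm, e3) {
  out <- list()
  tv <- strsplit(template, "")[[1]]
  n <- length(tv)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else oracle_rc(primer)
    L <- nchar(pat)
    if (n < L) next
    pv <- strsplit(pat, "")[[1]]
    starts <- 1:(n - L + 1L)
    mm <- integer(length(starts))
    for (k in 1:L) mm <- mm + (tv[starts + k - 1L] != pv[k])
    anchor_idx <- if (strand == "+") (L - e3 + 1L):L else 1:e3
    anc <- rep(TRUE, length(starts))
    for (k in anchor_idx) anc <- anc & (tv[starts + k - 1L] == pv[k])
    keep <- mm <= max_mm & anc
    if (any(keep))
      out[[strand]] <- data.frame(position = starts[keep] - 1L,
                                  strand = strand,
                                  mismatches = mm[keep],
                                  stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# All amplicons from the documented convergence rule: a plus-strand site of
# one primer paired with a downstream minus-strand site of the other, in both
# arrangements, with the product holding both footprints and capped at
# max_product. Returns a character vector of canonical row keys for set
# comparison.
oracle_amplicon_keys <- function(forward_primer, reverse_primer, template,
                                 max_mm, e3, max_product) {
  sf <- oracle_scan_sites(forward_primer, template, max_mm, e3)
  sr <- oracle_scan_sites(reverse_primer, template, max_mm, e3)
  lf <- nchar(forward_primer)
  lr <- nchar(reverse_primer)
  keys <- character(0)
  combos <- list(list(left = sf, right = sr, rlen = lr, left_is_f = TRUE),
                 list(left = sr, right = sf, rlen = lf, left_is_f = FALSE))
  for (cb in combos) {
    lp <- cb$left[cb$left$strand == "+", , drop = FALSE]
    rp <- cb$right[cb$right$strand == "-", , drop = FALSE]
    if (nrow(lp) == 0L || nrow(rp) == 0L) next
    for (i in seq_len(nrow(lp))) {
      for (j in seq_len(nrow(rp))) {
        if (rp$position[j] < lp$position[i]) next
        size <- rp$position[j] + cb$rlen - lp$position[i]
        if (size < max(lf, lr) || size > max_product) next
        fm <- if (cb$left_is_f) lp$mismatches[i] else rp$mismatches[j]
        rm <- if (cb$left_is_f) rp$mismatches[j] else lp$mismatches[i]
        keys <- c(keys, sprintf("%d:%d:%d:%d:%d", lp$position[i],
                                rp$position[j] + cb$rlen, size, fm, rm))
      }
    }
  }
  sort(unique(keys))
}

# --- frozen nearest-neighbor Tm reference values -----------------------------
#
# Computed once with an independent, widely used thermodynamics
# implementation (SantaLucia unified NN parameters, entropy salt correction
# 0.368 (N-1) ln[Na+] at 50 mM, duplex concentration CT/4 for 250 nM total
# oligonucleotide) and frozen here as plain numbers.
FROZEN_TM <- c(
  ACAGCTCATCATGCAGGACA      = 55.741782,
  GATTACAGATTACAGATT        = 39.765681,
  CCGGAATTCCGGAATTCCGGAATTC = 60.060437,
  TTTTAAAATTTTAAAATT        = 32.263799,
  GCGCGCGCATATATATGCGC      = 59.915198,
  ATGCATGCATGCATGCATGCATGCA = 63.436178,
  CAGTGGATCCTTAGGCAT        = 49.862721,
  ACGTACGTACGTACGTACGT      = 55.221961,
  TGCAAGGTCATCGGTACCTA      = 54.502081,
  GGATCGGAAGCTTCAGATCGA     = 55.965505,
  CTCGTCTCAAGCAGTTCAGC      = 55.452125,
  GGTTTAGGTGGTTGTGCTGGTC    = 57.806915)

# --- tiny construction helpers for structural tests --------------------------

# A gene model with a single exon covering a given transcript.
tiny_gene <- function(id, tx, source = "test", scaffold = "s1", strand = "+",
                      position = NULL) {
  gene_model(id, source, scaffold, strand,
             cbind(0L, nchar(tx)), tx, position = position)
}

# Bulk-create n single-exon gene models with distinct random transcripts.
tiny_gene_set <- function(n, prefix, source, len = 24L) {
  lapply(seq_len(n), function(i)
    tiny_gene(sprintf("%s%05d", prefix, i), oracle_random_dna(len),
              source = source))
}
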