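# Internal sequence / misc helpers. All sequences are plain uppercase character
# strings internally; Biostrings objects are used at I/O and matching boundaries.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

it_error <- function(msg, class) {
  stop(structure(
    class = c(class, "intronit_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

format_error <- function(msg) it_error(msg, "intronit_format_error")
config_error <- function(msg) it_error(msg, "intronit_config_error")
domain_error <- function(msg) it_error(msg, "intronit_domain_error")

#' Reverse-complement a nucleotide string
#' @param x character scalar (IUPAC letters)
#' @return character scalar
#' @keywords internal
revcomp <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", x)
  intToUtf8(rev(utf8ToInt(comp)))
}

# Uppercase and map non-IUPAC letters to N
normalize_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGTRYSWKMBDHVN]", "N", x)
}

# Count of positions where two equal-length strings agree (exact base match)
n_matching <- function(a, b) {
  if (nchar(a) == 0L) return(0L)
  sum(utf8ToInt(a) == utf8ToInt(b))
}

is_acgt <- function(x) grepl("^[ACGT]+$", x)

gc_fraction <- function(x) {
  v <- strsplit(x, "")[[1]]
  sum(v %in% c("G", "C")) / length(v)
}

max_homopolymer_run <- function(x) {
  r <- rle(strsplit(x, "")[[1]])
  max(r$lengths)
}

# Longest contiguous complementary run between a primer and itself
# (self-dimer / hairpin proxy): slide primer against its reverse complement.
max_self_complementarity <- function(x) {
  n <- nchar(x)
  a <- utf8ToInt(x)
  b <- utf8ToInt(revcomp(x))
  best <- 0L
  for (off in (-(n - 1L)):(n - 1L)) {
    ia <- max(1L, 1L + off):min(n, n + off)
    ib <- ia - off
    eq <- a[ia] == b[ib]
    if (any(eq)) {
      r <- rle(eq)
      m <- max(r$lengths[r$values])
      if (m > best) best <- m
    }
  }
  best
}

# TRUE when the longest contiguous self-complementary stretch exceeds `cap`:
# equivalent to the primer sharing a (cap+1)-mer with its reverse complement.
self_complementarity_exceeds <- function(x, cap) {
  k <- cap + 1L
  n <- nchar(x)
  if (n < k) return(FALSE)
  a <- substring(x, 1:(n - k + 1L), k:n)
  any(a %in% substring(revcomp(x), 1:(n - k + 1L), k:n))
}

random_dna <- function(n, rng = NULL) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Composition-preserving shuffle of a sequence (decoy background)
shuffle_seq <- function(x) {
  paste(sample(strsplit(x, "")[[1]]), collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
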