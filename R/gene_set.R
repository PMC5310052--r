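# Non-redundant query gene set: merge two annotation sources, keeping every
# gene from the preferred source and dropping its redundant partners from the
# other source.

# Ungapped Karlin-Altschul constants for blastn-default nucleotide scoring
# (match +1 / mismatch -2); used to convert local alignment scores into
# e-values over the two-sequence search space.
KA_LAMBDA <- 1.28
KA_K <- 0.46

alignment_evalue <- function(score, m, n) {
  KA_K * as.numeric(m) * as.numeric(n) * exp(-KA_LAMBDA * score)
}

#' Filter genes to a pseudomolecule window
#'
#' Retains genes whose pseudomolecule start position lies strictly below
#' `max_position` (the published workflow kept annotated genes within the
#' first 60 Mb of the donor pseudomolecule, the presumed short arm). Genes
#' without position metadata make the filter a warning no-op.
#'
#' @param genes list of [gene_model()].
#' @param max_position window end in bp.
#' @return filtered list, input order preserved.
#' @export
window_filter <- function(genes, max_position) {
  pos <- vapply(genes, function(g) g$position %||% NA_real_, numeric(1))
  if (all(is.na(pos))) {
    warning("genes carry no pseudomolecule positions; window_filter is a no-op",
            call. = FALSE)
    return(genes)
  }
  genes[!is.na(pos) & pos < max_position]
}

#' Find redundant gene pairs between two sets
#'
#' A pair is redundant when a local alignment of the two transcripts reaches
#' e-value at most `dedup_evalue_cutoff` and covers more than
#' `dedup_coverage_cutoff` of the reference transcript (the shorter one by
#' default). Alignment uses striped local alignment with blastn-like scores
#' (match +1, mismatch -2, gap open 5, gap extend 2) and an ungapped
#' Karlin-Altschul e-value on the two-sequence search space. Symmetric in its
#' inputs.
#'
#' @param set_a,set_b lists of [gene_model()].
#' @param cfg a [pipeline_config()] (or NULL for defaults).
#' @return data.frame: `a_id`, `b_id`, `identity`, `coverage`, `evalue`.
#' @export
find_redundant_pairs <- function(set_a, set_b, cfg = NULL) {
  cfg <- as_config(cfg)
  if (length(set_a) == 0L || length(set_b) == 0L)
    domain_error("both gene sets must be non-empty")
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                     baseOnly = TRUE)
  rows <- list()
  for (a in set_a) {
    for (b in set_b) {
      r <- transcript_pair_alignment(a$transcript_seq, b$transcript_seq,
                                     submat, cfg)
      if (r$evalue <= cfg$dedup_evalue_cutoff &&
          r$coverage > cfg$dedup_coverage_cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          a_id = a$gene_id, b_id = b$gene_id,
          identity = r$identity, coverage = r$coverage, evalue = r$evalue,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(a_id = character(0), b_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      evalue = numeric(0)))
  do.call(rbind, rows)
}

transcript_pair_alignment <- function(sa, sb, submat, cfg) {
  # align so the coverage reference is the pattern
  denom_shorter <- cfg$dedup_coverage_denominator == "shorter"
  ref_is_a <- xor(nchar(sa) <= nchar(sb), !denom_shorter)
  p <- if (ref_is_a) sa else sb
  s <- if (ref_is_a) sb else sa
  aln <- Biostrings::pairwiseAlignment(
    pattern = p, subject = s, type = "local",
    substitutionMatrix = submat, gapOpening = 5, gapExtension = 2)
  sc <- Biostrings::score(aln)
  pr <- Biostrings::pattern(aln)
  cov_len <- Biostrings::end(pr) - Biostrings::start(pr) + 1L
  list(
    evalue = alignment_evalue(sc, nchar(sa), nchar(sb)),
    coverage = cov_len / nchar(p),
    identity = Biostrings::pid(aln) / 100
  )
}

#' Derive redundant pairs from a precomputed alignment table
#'
#' Bypass for [find_redundant_pairs()]: applies the same e-value and coverage
#' thresholds to rows of a 12-column tabular alignment file
#' (see [read_alignment_table()]) computed by an external aligner.
#'
#' @param alignments data.frame from [read_alignment_table()].
#' @param set_a,set_b lists of [gene_model()]; query ids are matched against
#'   `set_a`, subject ids against `set_b`.
#' @param cfg a [pipeline_config()].
#' @return data.frame as in [find_redundant_pairs()].
#' @export
redundant_pairs_from_alignments <- function(alignments, set_a, set_b,
                                            cfg = NULL) {
  cfg <- as_config(cfg)
  len_a <- stats::setNames(vapply(set_a, function(g) nchar(g$transcript_seq),
                                  numeric(1)),
                           vapply(set_a, `[[`, character(1), "gene_id"))
  len_b <- stats::setNames(vapply(set_b, function(g) nchar(g$transcript_seq),
                                  numeric(1)),
                           vapply(set_b, `[[`, character(1), "gene_id"))
  al <- alignments[alignments$qid %in% names(len_a) &
                   alignments$sid %in% names(len_b), , drop = FALSE]
  if (nrow(al) == 0L)
    return(data.frame(a_id = character(0), b_id = character(0),
                      identity = numeric(0), coverage = numeric(0),
                      evalue = numeric(0)))
  ref_len <- if (cfg$dedup_coverage_denominator == "shorter")
    pmin(len_a[al$qid], len_b[al$sid]) else pmax(len_a[al$qid], len_b[al$sid])
  cov <- al$length / ref_len
  keep <- al$evalue <= cfg$dedup_evalue_cutoff & cov > cfg$dedup_coverage_cutoff
  out <- data.frame(a_id = al$qid[keep], b_id = al$sid[keep],
                    identity = al$pident[keep] / 100,
                    coverage = cov[keep], evalue = al$evalue[keep],
                    stringsAsFactors = FALSE)
  unique(out)
}

#' Merge two gene sets, removing redundancy from the non-preferred set
#'
#' All genes of the preferred source are retained; genes of the other source
#' appearing in any redundant pair are removed. Mirrors the published merge in
#' which every donor-genome gene was kept and redundant wheat genes dropped.
#'
#' @param set_a,set_b lists of [gene_model()]; `set_a` is the preferred set.
#' @param redundant data.frame from [find_redundant_pairs()].
#' @param prefer source label that must match the common `source` tag of
#'   `set_a` (configuration error otherwise).
#' @return object of class `merged_gene_set`: list with `genes` (retained
#'   models, set_a then surviving set_b), `removed` (dropped gene ids) and
#'   `provenance` (data.frame gene_id / kept_reason / redundant_partner).
#' @export
merge_gene_sets <- function(set_a, set_b, redundant, prefer) {
  src_a <- unique(vapply(set_a, `[[`, character(1), "source"))
  src_b <- unique(vapply(set_b, `[[`, character(1), "source"))
  if (!prefer %in% src_a) {
    if (prefer %in% src_b)
      config_error("prefer label matches set_b; pass the preferred set as set_a")
    config_error(sprintf("prefer label '%s' matches neither gene set", prefer))
  }
  ids_a <- vapply(set_a, `[[`, character(1), "gene_id")
  ids_b <- vapply(set_b, `[[`, character(1), "gene_id")
  if (nrow(redundant) > 0) {
    bad <- setdiff(c(redundant$a_id, redundant$b_id), c(ids_a, ids_b))
    if (length(bad))
      config_error(sprintf("redundant pairs reference unknown gene id(s): %s",
                           paste(bad, collapse = ", ")))
  }
  drop_b <- ids_b %in% redundant$b_id
  partner <- vapply(ids_b, function(id) {
    hit <- redundant$a_id[redundant$b_id == id]
    if (length(hit)) hit[1] else NA_character_
  }, character(1))
  prov <- rbind(
    data.frame(gene_id = ids_a, kept_reason = "preferred_source",
               redundant_partner = NA_character_, stringsAsFactors = FALSE),
    data.frame(gene_id = ids_b,
               kept_reason = ifelse(drop_b, "removed_redundant", "unique"),
               redundant_partner = partner, stringsAsFactors = FALSE))
  structure(list(genes = c(set_a, set_b[!drop_b]),
                 removed = ids_b[drop_b],
                 provenance = prov),
            class = "merged_gene_set")
}

#' @export
print.merged_gene_set <- function(x, ...) {
  cat(sprintf("<merged_gene_set: %d gene(s) retained, %d removed as redundant>\n",
              length(x$genes), length(x$removed)))
  invisible(x)
}
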