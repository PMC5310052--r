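# Exon-anchored primer design over the selected targeted introns. The alien
# (V) genomic sequence is the design template; exon conservation across arms
# is assumed, so per-arm product sizes follow from the shared exonic
# footprint plus each arm's intron size.

# Nearest-neighbor thermodynamics, unified parameter set (kcal/mol enthalpy,
# cal/(mol K) entropy), including both strand readings of each stack.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
INIT_GC <- c(dh = 0.1, ds = -2.8)   # per G/C-terminal end
INIT_AT <- c(dh = 2.3, ds = 4.1)    # per A/T-terminal end
GAS_R <- 1.987                      # cal/(mol K)

#' Primer melting temperature
#'
#' Nearest-neighbor thermodynamic Tm with the unified duplex parameter set,
#' entropy salt correction `0.368 (N-1) ln[Na+]` and total strand
#' concentration `CT/4` (non-self-complementary duplex, equal strands);
#' defaults 50 mM monovalent salt and 250 nM oligonucleotide. A Wallace-rule
#' fallback (`tm_method = "wallace"`) is available for quick estimates.
#'
#' @param primer primer sequence, 5'->3', ACGT only, length >= 8.
#' @param cfg a [pipeline_config()] (salt, concentration, method).
#' @return temperature in degC.
#' @examples
#' melting_temperature("ACAGCTCATCATGCAGGACA")
#' @export
melting_temperature <- function(primer, cfg = NULL) {
  cfg <- as_config(cfg)
  primer <- toupper(primer)
  if (nchar(primer) < 8L)
    domain_error("primer must be at least 8 nt for Tm estimation")
  if (!is_acgt(primer))
    domain_error("ambiguous or non-ACGT base in primer")
  if (cfg$tm_method == "wallace") {
    v <- strsplit(primer, "")[[1]]
    return(2 * sum(v %in% c("A", "T")) + 4 * sum(v %in% c("G", "C")))
  }
  n <- nchar(primer)
  dinucs <- substring(primer, 1:(n - 1L), 2:n)
  dh <- sum(NN_DH[dinucs])
  ds <- sum(NN_DS[dinucs])
  for (endbase in c(substr(primer, 1, 1), substr(primer, n, n))) {
    init <- if (endbase %in% c("G", "C")) INIT_GC else INIT_AT
    dh <- dh + init[["dh"]]
    ds <- ds + init[["ds"]]
  }
  ds <- ds + 0.368 * (n - 1L) * log(cfg$monovalent_mM / 1000)
  ct <- cfg$oligo_nM * 1e-9 / 4
  1000 * dh / (ds + GAS_R * log(ct)) - 273.15
}

primer_passes_filters <- function(seq, cfg) {
  if (!is_acgt(seq)) return(FALSE)                       # no N, no ambiguity
  v <- strsplit(seq, "")[[1]]
  gc <- sum(v %in% c("G", "C")) / length(v)
  if (gc < cfg$gc_min || gc > cfg$gc_max) return(FALSE)
  if (max(rle(v)$lengths) > cfg$max_homopolymer) return(FALSE)
  if (self_complementarity_exceeds(seq, cfg$max_self_comp)) return(FALSE)
  TRUE
}

# Enumerate single-primer windows on one flank. side "left": windows anchored
# anywhere in the trailing max_flank_bp of the exon, primer = sense strand;
# side "right": windows in the leading max_flank_bp, primer = antisense
# (reverse complement), 5'->3'. footprint = exonic bases between the primer's
# outer end and the intron.
flank_windows <- function(exon, side, cfg) {
  n <- nchar(exon)
  lo <- if (side == "left") max(1L, n - cfg$max_flank_bp + 1L) else 1L
  hi <- if (side == "left") n else min(n, cfg$max_flank_bp)
  rows <- list()
  for (len in cfg$primer_len_min:cfg$primer_len_max) {
    starts <- if (side == "left") lo:(hi - len + 1L) else lo:(hi - len + 1L)
    starts <- starts[starts >= 1L & starts + len - 1L <= hi]
    for (s in starts) {
      window <- substr(exon, s, s + len - 1L)
      seq <- if (side == "left") window else revcomp(window)
      if (!primer_passes_filters(seq, cfg)) next
      tm <- melting_temperature(seq, cfg)
      if (tm < cfg$tm_min || tm > cfg$tm_max) next
      fp <- if (side == "left") n - s + 1L else s + len - 1L
      rows[[length(rows) + 1L]] <- data.frame(
        seq = seq, tm = tm, len = len, footprint = fp,
        score = abs(tm - cfg$tm_opt) + abs(len - cfg$primer_len_opt),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(seq = character(0), tm = numeric(0), len = integer(0),
                      footprint = integer(0), score = numeric(0)))
  do.call(rbind, rows)
}

MAX_SINGLES_PER_SIDE <- 50L  # pairing cap; best singles by score

#' Enumerate candidate primer pairs on the exons flanking an intron
#'
#' All windows of length `primer_len_min..primer_len_max` within
#' `max_flank_bp` of the intron on either flanking exon that satisfy the Tm,
#' GC-content, homopolymer-run and self-complementarity constraints; the
#' best singles per side (by `|Tm - tm_opt| + |len - len_opt|`) are combined
#' into pairs with a pair Tm-difference penalty.
#'
#' @param left_exon exon sequence 5' of the intron (transcript orientation).
#' @param right_exon exon sequence 3' of the intron.
#' @param cfg a [pipeline_config()].
#' @return data.frame of candidate pairs, best first: `forward_seq`,
#'   `reverse_seq`, `tm_f`, `tm_r`, `fwd_footprint`, `rev_footprint`
#'   (exonic bp each primer contributes to the product), `score`. Zero rows
#'   when either side yields no valid window.
#' @export
enumerate_primer_candidates <- function(left_exon, right_exon, cfg = NULL) {
  cfg <- as_config(cfg)
  empty <- data.frame(forward_seq = character(0), reverse_seq = character(0),
                      tm_f = numeric(0), tm_r = numeric(0),
                      fwd_footprint = integer(0), rev_footprint = integer(0),
                      score = numeric(0))
  if (nchar(left_exon) < cfg$primer_len_min ||
      nchar(right_exon) < cfg$primer_len_min) return(empty)
  fw <- flank_windows(normalize_seq(left_exon), "left", cfg)
  rv <- flank_windows(normalize_seq(right_exon), "right", cfg)
  if (nrow(fw) == 0L || nrow(rv) == 0L) return(empty)
  fw <- fw[order(fw$score, fw$footprint, fw$seq), , drop = FALSE]
  rv <- rv[order(rv$score, rv$footprint, rv$seq), , drop = FALSE]
  fw <- utils::head(fw, MAX_SINGLES_PER_SIDE)
  rv <- utils::head(rv, MAX_SINGLES_PER_SIDE)
  grid <- expand.grid(f = seq_len(nrow(fw)), r = seq_len(nrow(rv)))
  out <- data.frame(
    forward_seq = fw$seq[grid$f], reverse_seq = rv$seq[grid$r],
    tm_f = fw$tm[grid$f], tm_r = rv$tm[grid$r],
    fwd_footprint = fw$footprint[grid$f],
    rev_footprint = rv$footprint[grid$r],
    stringsAsFactors = FALSE)
  out$score <- fw$score[grid$f] + rv$score[grid$r] + abs(out$tm_f - out$tm_r)
  out[order(out$score, out$fwd_footprint, out$rev_footprint, out$forward_seq), ,
      drop = FALSE]
}

#' Pick the primer pair for one targeted intron
#'
#' Applies the product-size rule: the alien-arm (V) product must exceed the
#' targeted intron by at least `product_overhead_bp`, with a soft optimum of
#' `intron + overhead + 2 (len_opt - len_min)` folded into the score. Per-arm
#' product sizes are the shared exonic footprint plus each arm's intron size.
#'
#' @param candidates data.frame from [enumerate_primer_candidates()].
#' @param intron_sizes named per-arm intron sizes of the target (bp).
#' @param cfg a [pipeline_config()].
#' @param v_arm alien arm label.
#' @return list (`marker_candidate`): `forward_seq`, `reverse_seq`, `tm_f`,
#'   `tm_r`, `fwd_footprint`, `rev_footprint`, `intron_sizes`,
#'   `product_sizes`; or `NULL` when no candidate qualifies.
#' @export
pick_primer_pair <- function(candidates, intron_sizes, cfg = NULL,
                             v_arm = "V") {
  cfg <- as_config(cfg)
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  if (!v_arm %in% names(intron_sizes))
    domain_error(sprintf("intron_sizes lacks alien arm '%s'", v_arm))
  iv <- intron_sizes[[v_arm]]
  footprint <- candidates$fwd_footprint + candidates$rev_footprint
  prod_v <- footprint + iv
  ok <- prod_v >= iv + cfg$product_overhead_bp
  if (!any(ok)) return(NULL)
  cand <- candidates[ok, , drop = FALSE]
  opt <- iv + cfg$product_overhead_bp +
    2L * (cfg$primer_len_opt - cfg$primer_len_min)
  total <- cand$score +
    0.05 * abs(cand$fwd_footprint + cand$rev_footprint + iv - opt)
  o <- order(total, cand$fwd_footprint, cand$rev_footprint, cand$forward_seq)
  best <- cand[o[1], , drop = FALSE]
  fp <- best$fwd_footprint + best$rev_footprint
  products <- vapply(intron_sizes, function(x) as.integer(x + fp), integer(1))
  structure(list(forward_seq = best$forward_seq,
                 reverse_seq = best$reverse_seq,
                 tm_f = best$tm_f, tm_r = best$tm_r,
                 fwd_footprint = best$fwd_footprint,
                 rev_footprint = best$rev_footprint,
                 intron_sizes = intron_sizes,
                 product_sizes = products),
            class = "marker_candidate")
}

#' Design markers for all selected targeted introns
#'
#' For each gene's selected target the flanking exon sequences are extracted
#' from the alien-arm (design template) hit, primer pairs enumerated and the
#' best qualifying pair kept. Marker ids are `ITM` plus a zero-padded ordinal
#' in ascending gene-id order.
#'
#' @param targets data.frame of selected targets, one row per gene, with
#'   `gene_id`, `junction_index` and `size_<arm>` columns (see
#'   [select_marker_intron()]).
#' @param hits named list gene id -> per-arm hits (from
#'   [map_genes_to_panels()]).
#' @param panels named list of [genome_panel()].
#' @param cfg a [pipeline_config()].
#' @param v_arm alien arm label.
#' @return list with `markers` (data.frame in marker-table layout, products
#'   set to the bookkeeping prediction) and `failures` (gene ids with no
#'   qualifying primer pair).
#' @export
design_all <- function(targets, hits, panels, cfg = NULL, v_arm = "V") {
  cfg <- as_config(cfg)
  failures <- character(0)
  rows <- list()
  if (nrow(targets) > 0L) {
    targets <- targets[order(targets$gene_id), , drop = FALSE]
    for (i in seq_len(nrow(targets))) {
      gid <- targets$gene_id[i]
      j <- targets$junction_index[i]
      hit <- hits[[gid]][[v_arm]]
      if (is.null(hit)) { failures <- c(failures, gid); next }
      exons <- hit_exons_transcript_order(hit, panels[[v_arm]], NA)
      if (j + 1L > length(exons)) { failures <- c(failures, gid); next }
      sizes <- as.list(targets[i, grep("^size_", names(targets)), drop = FALSE])
      names(sizes) <- sub("^size_", "", names(sizes))
      cand <- enumerate_primer_candidates(exons[j], exons[j + 1L], cfg)
      mk <- pick_primer_pair(cand, sizes, cfg, v_arm)
      if (is.null(mk)) { failures <- c(failures, gid); next }
      row <- data.frame(gene_id = gid, junction_index = j,
                        forward_primer = mk$forward_seq,
                        reverse_primer = mk$reverse_seq,
                        tm_forward = round(mk$tm_f, 2),
                        tm_reverse = round(mk$tm_r, 2),
                        stringsAsFactors = FALSE)
      for (arm in names(sizes)) {
        row[[paste0("intron_", arm)]] <- as.integer(sizes[[arm]])
        row[[paste0("product_", arm)]] <- mk$product_sizes[[arm]]
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  markers <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), junction_index = integer(0),
               forward_primer = character(0), reverse_primer = character(0),
               tm_forward = numeric(0), tm_reverse = numeric(0))
  if (nrow(markers)) {
    markers <- markers[order(markers$gene_id), , drop = FALSE]
    markers <- cbind(marker_id = sprintf("ITM%04d", seq_len(nrow(markers))),
                     markers, stringsAsFactors = FALSE)
    rownames(markers) <- NULL
  } else markers <- cbind(marker_id = character(0), markers)
  list(markers = markers, failures = sort(failures))
}
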