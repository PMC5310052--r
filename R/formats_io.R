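# On-disk formats and the internal coordinate convention.
#
# One convention everywhere: 0-based half-open intervals on the forward strand
# of the scaffold. GFF3 I/O (1-based closed) converts at this boundary and
# nowhere else.

#' Construct a genome panel
#'
#' A genome panel is one labelled homoeologous chromosome-arm assembly:
#' an arm identifier (conventionally `"A"`, `"B"`, `"D"` for the wheat arms
#' and `"V"` for the alien arm) plus its scaffold sequences.
#'
#' @param scaffolds named character vector or `DNAStringSet` of scaffold
#'   sequences; names are scaffold ids.
#' @param arm_id arm label.
#' @return object of class `genome_panel` with fields `arm_id` and
#'   `scaffolds` (named character, uppercase; non-IUPAC letters become `N`).
#' @export
genome_panel <- function(scaffolds, arm_id) {
  if (inherits(scaffolds, "DNAStringSet"))
    scaffolds <- as.character(scaffolds)
  if (is.null(names(scaffolds)) || any(!nzchar(names(scaffolds))))
    format_error("every scaffold must be named")
  dup <- names(scaffolds)[duplicated(names(scaffolds))]
  if (length(dup))
    format_error(sprintf("duplicate scaffold id(s): %s",
                         paste(unique(dup), collapse = ", ")))
  if (any(!nzchar(scaffolds)))
    format_error("empty scaffold sequence")
  scaffolds <- vapply(scaffolds, normalize_seq, character(1))
  structure(list(arm_id = as.character(arm_id), scaffolds = scaffolds),
            class = "genome_panel")
}

#' @export
print.genome_panel <- function(x, ...) {
  cat(sprintf("<genome_panel arm=%s: %d scaffold(s), %s bp>\n",
              x$arm_id, length(x$scaffolds),
              format(sum(nchar(x$scaffolds)), big.mark = ",")))
  invisible(x)
}

#' Read a genome panel from FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @param arm_id arm label to attach.
#' @return a [genome_panel()].
#' @export
read_genome_panel <- function(path, arm_id) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  seqs <- tryCatch(Biostrings::readDNAStringSet(path),
                   error = function(e) format_error(
                     sprintf("not FASTA-parseable: %s (%s)", path, conditionMessage(e))))
  if (length(seqs) == 0L) format_error(sprintf("empty FASTA file: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  x <- as.character(seqs)
  names(x) <- ids
  genome_panel(x, arm_id)
}

#' Construct a gene model
#'
#' @param gene_id gene identifier.
#' @param source free-text source tag (e.g. annotation provenance).
#' @param scaffold_id scaffold carrying the gene.
#' @param strand `"+"` or `"-"`.
#' @param exons integer matrix with columns `start`, `end`; 0-based half-open,
#'   sorted, non-overlapping, in genomic order.
#' @param transcript_seq spliced transcript (reverse-complemented for `-`).
#' @param position optional pseudomolecule position (bp) used by
#'   [window_filter()]; defaults to the gene start.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, source, scaffold_id, strand, exons,
                       transcript_seq, position = NULL) {
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) == 0L) format_error("gene model needs at least one exon")
  if (any(exons[, 2] <= exons[, 1]))
    format_error(sprintf("gene %s: empty or inverted exon interval", gene_id))
  if (is.unsorted(exons[, 1], strictly = TRUE) && nrow(exons) > 1L)
    format_error(sprintf("gene %s: exons not sorted", gene_id))
  if (nrow(exons) > 1L && any(exons[-1, 1] < exons[-nrow(exons), 2]))
    format_error(sprintf("gene %s: overlapping exons", gene_id))
  if (!strand %in% c("+", "-"))
    format_error(sprintf("gene %s: strand must be + or -", gene_id))
  transcript_seq <- normalize_seq(transcript_seq)
  if (nchar(transcript_seq) != sum(exons[, 2] - exons[, 1]))
    format_error(sprintf("gene %s: transcript length != sum of exon lengths",
                         gene_id))
  structure(list(gene_id = gene_id, source = source,
                 scaffold_id = scaffold_id, strand = strand, exons = exons,
                 transcript_seq = transcript_seq,
                 position = if (is.null(position)) unname(exons[1, 1]) else
                   as.numeric(position)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model %s [%s] %s:%s %d exon(s), transcript %d nt>\n",
              x$gene_id, x$source, x$scaffold_id, x$strand, nrow(x$exons),
              nchar(x$transcript_seq)))
  invisible(x)
}

# Extract the spliced transcript of a gene from its scaffold sequence.
spliced_sequence <- function(scaffold_seq, exons, strand) {
  parts <- substring(scaffold_seq, exons[, 1] + 1L, exons[, 2])
  tx <- paste(parts, collapse = "")
  if (strand == "-") revcomp(tx) else tx
}

#' Read gene models from a GFF3 annotation
#'
#' Accepts gene/mRNA/exon features with resolvable `Parent` links. GFF3
#' 1-based closed coordinates are converted to the internal 0-based half-open
#' convention. For multi-transcript genes the longest transcript (by summed
#' exon length) is kept. Exons with unresolvable parents are skipped with a
#' warning; exons outside scaffold bounds are an error.
#'
#' @param genome a [genome_panel()] providing the scaffold sequences.
#' @param annotation GFF3 file path.
#' @param source source tag recorded on each gene model.
#' @return list of [gene_model()] objects, ordered by gene id.
#' @export
read_gene_models <- function(genome, annotation, source = "annotation") {
  if (!file.exists(annotation))
    format_error(sprintf("file not found: %s", annotation))
  gff <- read_gff3_table(annotation)
  genes <- gff[gff$type == "gene", , drop = FALSE]
  mrnas <- gff[gff$type == "mRNA", , drop = FALSE]
  exons <- gff[gff$type == "exon", , drop = FALSE]
  mrna_parent <- stats::setNames(mrnas$parent, mrnas$id)
  gene_strand <- stats::setNames(genes$strand, genes$id)
  gene_seqid <- stats::setNames(genes$seqid, genes$id)
  gene_start <- stats::setNames(genes$start, genes$id)

  keep <- !is.na(exons$parent) & exons$parent %in% names(mrna_parent)
  if (any(!keep)) {
    warning(sprintf("skipping %d exon(s) with missing/unresolvable Parent",
                    sum(!keep)), call. = FALSE)
    exons <- exons[keep, , drop = FALSE]
  }
  out <- list()
  for (gid in sort(names(gene_strand))) {
    tx_ids <- names(mrna_parent)[mrna_parent == gid]
    if (length(tx_ids) == 0L) next
    tx_len <- vapply(tx_ids, function(tid) {
      e <- exons[exons$parent == tid, , drop = FALSE]
      sum(e$end - e$start + 1L)
    }, numeric(1))
    # longest transcript; deterministic tie-break by id
    tid <- tx_ids[order(-tx_len, tx_ids)][1]
    e <- exons[exons$parent == tid, , drop = FALSE]
    if (nrow(e) == 0L) next
    e <- e[order(e$start), , drop = FALSE]
    scaf <- gene_seqid[[gid]]
    if (!scaf %in% names(genome$scaffolds))
      format_error(sprintf("gene %s: scaffold %s absent from panel", gid, scaf))
    slen <- nchar(genome$scaffolds[[scaf]])
    if (any(e$end > slen) || any(e$start < 1L))
      format_error(sprintf("gene %s: exon outside scaffold bounds", gid))
    ex <- cbind(start = e$start - 1L, end = e$end)  # to 0-based half-open
    tx <- spliced_sequence(genome$scaffolds[[scaf]], ex, gene_strand[[gid]])
    out[[gid]] <- gene_model(gid, source, scaf, gene_strand[[gid]], ex, tx,
                             position = gene_start[[gid]] - 1L)
  }
  unname(out)
}

# Structural GFF3 read via rtracklayer: seqid/type/start/end/strand/id/parent
# as a plain data.frame (coordinates still 1-based closed at this point).
read_gff3_table <- function(path) {
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e) format_error(
                   sprintf("not GFF3-parseable: %s (%s)", path, conditionMessage(e))))
  if (length(gr) == 0L) format_error(sprintf("empty GFF3: %s", path))
  mc <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(mc)) {
    vapply(as.list(mc$Parent), function(p)
      if (length(p)) p[[1]] else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             type = as.character(mc$type),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             id = if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_,
             parent = parent,
             stringsAsFactors = FALSE)
}

#' Write gene models to GFF3
#'
#' Inverse of [read_gene_models()]: emits gene/mRNA/exon rows (1-based closed)
#' for each model.
#'
#' @param genes list of [gene_model()].
#' @param path output file.
#' @export
write_gene_models_gff3 <- function(genes, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    gs <- min(g$exons[, 1]) + 1L; ge <- max(g$exons[, 2])
    writeLines(sprintf("%s\tintronIT\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$scaffold_id, gs, ge, g$strand, g$gene_id), con)
    tid <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\tintronIT\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$scaffold_id, gs, ge, g$strand, tid, g$gene_id), con)
    for (i in seq_len(nrow(g$exons))) {
      writeLines(sprintf("%s\tintronIT\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
                         g$scaffold_id, g$exons[i, 1] + 1L, g$exons[i, 2],
                         g$strand, tid, i, tid), con)
    }
  }
  invisible(path)
}

marker_table_columns <- c(
  "marker_id", "gene_id", "junction_index",
  "forward_primer", "reverse_primer", "tm_forward", "tm_reverse",
  "intron_A", "intron_B", "intron_D", "intron_V",
  "product_A", "product_B", "product_D", "product_V",
  "type", "is_specific")

#' Write a marker table
#'
#' One row per marker: primers, Tm pair, per-arm intron and predicted product
#' sizes, band-pattern type and the arm-specificity flag. Rows are written in
#' ascending `marker_id` order; the layout mirrors published IT-marker tables.
#'
#' @param markers data.frame of markers (see [design_all()] /
#'   [call_specific_markers()]) or an empty data.frame.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_marker_table <- function(markers, path) {
  if (is.null(markers) || nrow(markers) == 0L) {
    markers <- as.data.frame(stats::setNames(
      replicate(length(marker_table_columns), character(0), simplify = FALSE),
      marker_table_columns))
  } else {
    missing_cols <- setdiff(marker_table_columns, names(markers))
    for (mc in missing_cols) markers[[mc]] <- NA
    markers <- markers[order(markers$marker_id), marker_table_columns]
  }
  ok <- tryCatch({
    utils::write.table(markers, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) it_error(sprintf("cannot write marker table: %s", path),
                    "intronit_io_error")
  invisible(path)
}

#' Read a marker table written by [write_marker_table()]
#' @param path TSV path
#' @return data.frame with the marker-table columns
#' @export
read_marker_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (!all(marker_table_columns %in% names(df)))
    format_error("not a marker table: missing columns")
  df$is_specific <- as.logical(df$is_specific)
  df[order(df$marker_id), marker_table_columns]
}

#' Read a 12-column tabular alignment file
#'
#' BLAST-style tabular layout: qid, sid, pident, length, mismatches, gapopen,
#' qstart, qend, sstart, send, evalue, bitscore (coordinates 1-based
#' inclusive). Used as the precomputed-alignment bypass of the native
#' aligner.
#'
#' @param path TSV path (no header).
#' @return data.frame with those columns.
#' @export
read_alignment_table <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) != 12L)
    format_error(sprintf("expected 12 columns, found %d", ncol(df)))
  names(df) <- c("qid", "sid", "pident", "length", "mismatches", "gapopen",
                 "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  df
}

#' Write a FASTA file from a named character vector
#' @param seqs named character vector
#' @param path output path
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
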