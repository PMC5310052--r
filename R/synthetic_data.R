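# Synthetic homoeologous four-genome panels with known gene structure and
# controlled intron-size divergence. The generator is the ground truth
# against which every pipeline stage is testable without genome downloads:
# per-junction intron sizes are drawn per arm (alien-arm divergence large for
# designated "targeted" junctions, small otherwise), exonic substitutions are
# applied per arm sparing designated primer windows, and the truth table is
# recomputed from the realized (rounded) sizes with the actual filter rule.

#' Parameters of the synthetic-family generator
#'
#' @param n_exons_range inclusive range of exon counts for intron-containing
#'   genes.
#' @param exon_len_range inclusive range of exon lengths (bp); the minimum
#'   must leave room for a primer window on either side.
#' @param intron_base_range inclusive range of ancestral intron sizes (bp).
#' @param targeted_divergence range of the relative alien-arm size change at
#'   a targeted junction.
#' @param background_divergence range of the alien-arm size change at
#'   non-targeted junctions.
#' @param wheat_jitter half-width of the uniform relative jitter applied
#'   independently to each wheat arm's intron sizes.
#' @param substitution_rate per-base exonic substitution probability per arm.
#' @param indel_rate per-base exonic indel probability per arm (small
#'   1-3 bp events).
#' @param primer_window conserved window length (bp) at each exon end when
#'   `primer_site_conserved`.
#' @param primer_site_conserved spare primer windows from substitutions.
#' @return named list of generator parameters.
#' @export
family_params <- function(n_exons_range = c(2L, 6L),
                          exon_len_range = c(60L, 240L),
                          intron_base_range = c(100L, 600L),
                          targeted_divergence = c(0.18, 0.45),
                          background_divergence = c(0, 0.08),
                          wheat_jitter = 0.04,
                          substitution_rate = 0.02,
                          indel_rate = 0,
                          primer_window = 35L,
                          primer_site_conserved = TRUE) {
  if (substitution_rate < 0 || substitution_rate > 0.2 ||
      indel_rate < 0 || indel_rate > 0.2)
    config_error("substitution/indel rates must lie in [0, 0.2]")
  if (exon_len_range[1] < 2L * 25L)
    config_error("minimum exon length must fit a primer at either end")
  list(n_exons_range = as.integer(n_exons_range),
       exon_len_range = as.integer(exon_len_range),
       intron_base_range = as.integer(intron_base_range),
       targeted_divergence = targeted_divergence,
       background_divergence = background_divergence,
       wheat_jitter = wheat_jitter,
       substitution_rate = substitution_rate,
       indel_rate = indel_rate,
       primer_window = as.integer(primer_window),
       primer_site_conserved = primer_site_conserved)
}

mutate_exon <- function(seq, rate, indel_rate, spare_ends) {
  v <- strsplit(seq, "")[[1]]
  n <- length(v)
  mutable <- rep(TRUE, n)
  if (spare_ends > 0L) {
    mutable[seq_len(min(spare_ends, n))] <- FALSE
    mutable[seq(max(1L, n - spare_ends + 1L), n)] <- FALSE
  }
  idx <- which(mutable & stats::runif(n) < rate)
  for (i in idx) {
    v[i] <- sample(setdiff(c("A", "C", "G", "T"), v[i]), 1L)
  }
  if (indel_rate > 0) {
    pos <- which(mutable & stats::runif(n) < indel_rate)
    for (i in rev(pos)) {
      len <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5) {
        v <- append(v, sample(c("A", "C", "G", "T"), len, replace = TRUE),
                    after = i)
      } else {
        drop <- i:min(n, i + len - 1L)
        drop <- drop[mutable[pmin(drop, n)]]
        if (length(drop) < length(v)) v <- v[-drop]
      }
      n <- length(v)
    }
  }
  paste(v, collapse = "")
}

draw_v_size <- function(base, div_range, wheat_sizes, want_targeted, cfg) {
  for (try in 1:200) {
    f <- stats::runif(1, div_range[1], div_range[2]) *
      sample(c(-1, 1), 1)
    size <- max(cfg$min_intron_bp, as.integer(round(base * (1 + f))))
    rel <- vapply(wheat_sizes, function(w)
      relative_difference(size, w, cfg$polymorphism_denominator), numeric(1))
    hit <- all(rel >= cfg$polymorphism_threshold)
    if (hit == want_targeted) return(size)
  }
  config_error("could not realize requested divergence class; widen ranges")
}

#' Generate one homoeologous gene family
#'
#' Draws an ancestral gene (exon count, exon lengths, intron sizes), realizes
#' it on every arm with per-arm intron-size perturbation (alien arm by the
#' targeted or background divergence, wheat arms by independent small jitter)
#' and per-arm exonic substitutions that spare the primer windows when
#' requested. The targeted/non-targeted status of every junction is verified
#' against the realized sizes with the actual filter rule (resampling the
#' alien size until the intended class holds), so the truth table is exact.
#'
#' @param gene_id identifier.
#' @param params a [family_params()] list.
#' @param arms arm labels.
#' @param v_arm alien arm label.
#' @param targeted should the family carry one targeted junction?
#' @param intronless single-exon family (no junctions)?
#' @param cfg a [pipeline_config()] (filter rule used for the truth).
#' @param seed optional integer; when given, `set.seed(seed)` is applied so
#'   the family is reproducible in isolation.
#' @return list: `gene_id`, `segments` (named per-arm genomic sequence),
#'   `exons` (per-arm list of exon sequences), `exon_offsets` (per-arm exon
#'   intervals within the segment, 0-based half-open), `transcripts` (per-arm
#'   spliced sequence), `truth` (data.frame: gene_id, junction_index,
#'   `size_<arm>`, is_targeted, primer_site_conserved).
#' @export
generate_family <- function(gene_id, params = family_params(),
                            arms = c("A", "B", "D", "V"), v_arm = "V",
                            targeted = TRUE, intronless = FALSE,
                            cfg = NULL, seed = NULL) {
  cfg <- as_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  if (!v_arm %in% arms) config_error("v_arm must be one of arms")
  n_ex <- if (intronless) 1L else
    sample(params$n_exons_range[1]:params$n_exons_range[2], 1L)
  exon_len <- sample(params$exon_len_range[1]:params$exon_len_range[2], n_ex,
                     replace = TRUE)
  anc_exons <- vapply(exon_len, random_dna, character(1))
  n_introns <- n_ex - 1L
  base_introns <- if (n_introns > 0L)
    sample(params$intron_base_range[1]:params$intron_base_range[2],
           n_introns, replace = TRUE) else integer(0)
  target_j <- if (targeted && n_introns > 0L) sample(n_introns, 1L) else 0L

  wheat_arms <- setdiff(arms, v_arm)
  sizes <- matrix(0L, nrow = n_introns, ncol = length(arms),
                  dimnames = list(NULL, arms))
  for (j in seq_len(n_introns)) {
    for (arm in wheat_arms) {
      f <- stats::runif(1, -params$wheat_jitter, params$wheat_jitter)
      sizes[j, arm] <- max(cfg$min_intron_bp,
                           as.integer(round(base_introns[j] * (1 + f))))
    }
    div <- if (j == target_j) params$targeted_divergence else
      params$background_divergence
    sizes[j, v_arm] <- draw_v_size(base_introns[j], div,
                                   sizes[j, wheat_arms], j == target_j, cfg)
  }

  spare <- if (params$primer_site_conserved) params$primer_window else 0L
  segments <- character(0)
  exon_seqs <- list(); exon_offsets <- list(); transcripts <- character(0)
  for (arm in arms) {
    ex <- vapply(anc_exons, mutate_exon, character(1),
                 rate = params$substitution_rate,
                 indel_rate = params$indel_rate, spare_ends = spare)
    introns <- if (n_introns > 0L)
      vapply(sizes[, arm], random_dna, character(1)) else character(0)
    pieces <- character(2L * n_ex - 1L)
    pieces[seq(1L, by = 2L, length.out = n_ex)] <- ex
    if (n_introns > 0L)
      pieces[seq(2L, by = 2L, length.out = n_introns)] <- introns
    seg <- paste(pieces, collapse = "")
    lens <- nchar(pieces)
    starts <- cumsum(c(0L, lens[-length(lens)]))
    ex_idx <- seq(1L, by = 2L, length.out = n_ex)
    exon_offsets[[arm]] <- cbind(start = starts[ex_idx],
                                 end = starts[ex_idx] + lens[ex_idx])
    segments[arm] <- seg
    exon_seqs[[arm]] <- unname(ex)
    transcripts[arm] <- paste(ex, collapse = "")
  }

  truth <- if (n_introns > 0L) {
    df <- data.frame(gene_id = gene_id, junction_index = seq_len(n_introns),
                     stringsAsFactors = FALSE)
    for (arm in arms) df[[paste0("size_", arm)]] <- sizes[, arm]
    df$is_targeted <- vapply(seq_len(n_introns), function(j) {
      sz <- stats::setNames(as.numeric(sizes[j, arms]), arms)
      is_targeted_intron(sz, cfg, v_arm)$targeted
    }, logical(1))
    df$primer_site_conserved <- params$primer_site_conserved
    df
  } else {
    df <- data.frame(gene_id = character(0), junction_index = integer(0),
                     stringsAsFactors = FALSE)
    for (arm in arms) df[[paste0("size_", arm)]] <- integer(0)
    df$is_targeted <- logical(0)
    df$primer_site_conserved <- logical(0)
    df
  }
  list(gene_id = gene_id, segments = segments, exons = exon_seqs,
       exon_offsets = exon_offsets, transcripts = transcripts, truth = truth)
}

decoy_seq <- function(n, composition_source) {
  freqs <- table(factor(strsplit(composition_source, "")[[1]],
                        levels = c("A", "C", "G", "T")))
  if (sum(freqs) == 0) freqs <- c(A = 1, C = 1, G = 1, T = 1)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = as.numeric(freqs) / sum(freqs)), collapse = "")
}

#' Generate a four-genome synthetic panel with ground truth
#'
#' Families are embedded in composition-matched decoy background with at
#' least 2 kb spacing, grouped several per scaffold per arm, each on a random
#' strand. Gene models (GFF3-convention exon structure) are annotated on the
#' source arm; the composition of targeted / untargeted / intronless families
#' is exact.
#'
#' @param n_families number of gene families.
#' @param fraction_targeted fraction carrying one targeted junction.
#' @param fraction_intronless fraction of single-exon families.
#' @param seed RNG seed (deterministic output).
#' @param params a [family_params()] list.
#' @param arms arm labels; `v_arm` the alien arm, `source_arm` the annotated
#'   source genome.
#' @param v_arm,source_arm see above.
#' @param families_per_scaffold grouping of families onto scaffolds.
#' @param cfg a [pipeline_config()].
#' @return list of class `panel_bundle`: `panels` (named list of
#'   [genome_panel()]), `genes` (source-arm [gene_model()] list),
#'   `transcripts` (named character), `truth` (per-junction truth table),
#'   `composition` (per-family class).
#' @export
generate_panel <- function(n_families = 50L, fraction_targeted = 0.4,
                           fraction_intronless = 0.2, seed = 1L,
                           params = family_params(),
                           arms = c("A", "B", "D", "V"), v_arm = "V",
                           source_arm = "D",
                           families_per_scaffold = 10L, cfg = NULL) {
  cfg <- as_config(cfg)
  if (fraction_targeted + fraction_intronless > 1)
    config_error("fractions must sum to at most 1")
  set.seed(seed)
  n_t <- round(n_families * fraction_targeted)
  n_il <- round(n_families * fraction_intronless)
  status <- sample(rep(c("targeted", "intronless", "background"),
                       c(n_t, n_il, n_families - n_t - n_il)))
  ids <- sprintf("FAM%04d", seq_len(n_families))

  fams <- lapply(seq_len(n_families), function(i)
    generate_family(ids[i], params, arms, v_arm,
                    targeted = status[i] == "targeted",
                    intronless = status[i] == "intronless", cfg = cfg))

  scaff_group <- ceiling(seq_len(n_families) / families_per_scaffold)
  panels <- list()
  gene_meta <- list()  # source-arm exon coordinates per family
  for (arm in arms) {
    scaffolds <- character(0)
    for (g in unique(scaff_group)) {
      sid <- sprintf("%s_scf%03d", arm, g)
      members <- which(scaff_group == g)
      seq_parts <- character(0)
      offset <- 0L
      for (i in members) {
        fam <- fams[[i]]
        spacer <- 2000L + sample(0:500, 1L)
        seq_parts <- c(seq_parts, decoy_seq(spacer, fam$segments[[arm]]))
        offset <- offset + spacer
        strand <- sample(c("+", "-"), 1L)
        seg <- fam$segments[[arm]]
        placed <- if (strand == "+") seg else revcomp(seg)
        if (arm == source_arm) {
          S <- nchar(seg)
          eo <- fam$exon_offsets[[arm]]
          genomic <- if (strand == "+")
            cbind(start = offset + eo[, "start"], end = offset + eo[, "end"])
          else {
            gi <- cbind(start = offset + S - eo[, "end"],
                        end = offset + S - eo[, "start"])
            gi[order(gi[, "start"]), , drop = FALSE]
          }
          gene_meta[[fam$gene_id]] <- list(scaffold_id = sid, strand = strand,
                                           exons = genomic)
        }
        seq_parts <- c(seq_parts, placed)
        offset <- offset + nchar(placed)
      }
      tail_spacer <- 2000L + sample(0:500, 1L)
      seq_parts <- c(seq_parts,
                     decoy_seq(tail_spacer, fams[[members[1]]]$segments[[arm]]))
      scaffolds[sid] <- paste(seq_parts, collapse = "")
    }
    panels[[arm]] <- genome_panel(scaffolds, arm)
  }

  genes <- lapply(fams, function(fam) {
    meta <- gene_meta[[fam$gene_id]]
    gene_model(fam$gene_id, source = "synthetic", meta$scaffold_id,
               meta$strand, meta$exons,
               transcript_seq = fam$transcripts[[source_arm]],
               position = meta$exons[1, 1])
  })
  truth <- do.call(rbind, c(lapply(fams, `[[`, "truth"),
                            list(make.row.names = FALSE)))
  transcripts <- stats::setNames(
    vapply(fams, function(f) f$transcripts[[source_arm]], character(1)), ids)
  structure(list(panels = panels, genes = genes, transcripts = transcripts,
                 truth = truth,
                 composition = data.frame(gene_id = ids, status = status,
                                          stringsAsFactors = FALSE)),
            class = "panel_bundle")
}

#' @export
print.panel_bundle <- function(x, ...) {
  cat(sprintf("<panel_bundle: %d families (%s), arms %s>\n",
              length(x$genes),
              paste(sprintf("%s=%d", names(table(x$composition$status)),
                            table(x$composition$status)), collapse = ", "),
              paste(names(x$panels), collapse = ",")))
  invisible(x)
}

#' Write a panel bundle to disk
#'
#' Emits one FASTA per arm, a transcript FASTA, a GFF3 of the source-arm gene
#' models and the TSV truth table.
#'
#' @param bundle a [generate_panel()] result.
#' @param dir output directory (created if needed).
#' @return named list of written paths.
#' @export
write_panel_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (arm in names(bundle$panels)) {
    p <- file.path(dir, sprintf("panel_%s.fa", arm))
    write_fasta(bundle$panels[[arm]]$scaffolds, p)
    paths[[paste0("panel_", arm)]] <- p
  }
  paths$transcripts <- file.path(dir, "transcripts.fa")
  write_fasta(bundle$transcripts, paths$transcripts)
  paths$gff3 <- file.path(dir, "genes.gff3")
  write_gene_models_gff3(bundle$genes, paths$gff3)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(bundle$truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
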