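# Spliced transcript-to-genome mapping by exact k-mer seeding, collinear
# chaining and boundary refinement. Intron sizes are the strand-normalized
# genomic gaps between adjacent exon blocks of the best chain.
#
# Coordinates: "mapping space" inside a chain means the oriented query
# (reverse complement of the transcript for minus-strand hits) against
# ascending scaffold positions; all public junction positions are converted
# back to transcript coordinates.

MAX_KMER_HITS <- 32L     # repeat guard: k-mers with more scaffold hits ignored
SEED_JOIN_GAP <- 60L     # max same-diagonal / query gap bridged by chaining
END_EXT_MIN_IDENT <- 0.6 # required identity to extend a chain to query ends

seq_kmers <- function(x, k) {
  n <- nchar(x)
  if (n < k) return(character(0))
  substring(x, 1:(n - k + 1L), k:n)
}

# Exact k-mer seed positions (0-based) of `query` in `scaffold`, via hashed
# membership of the scaffold k-mer vector (precomputable, see
# panel_kmer_index) in the query k-mer set.
kmer_seeds <- function(query, scaffold, k, scaffold_kmers = NULL) {
  empty <- data.frame(qpos = integer(0), tpos = integer(0))
  qk <- seq_kmers(query, k)
  ok <- which(!grepl("[^ACGT]", qk))
  if (!length(ok)) return(empty)
  if (is.null(scaffold_kmers)) scaffold_kmers <- seq_kmers(scaffold, k)
  uq <- unique(qk[ok])
  tidx <- which(scaffold_kmers %in% uq)
  if (!length(tidx)) return(empty)
  mq <- match(scaffold_kmers[tidx], uq)
  # repeat guard: ignore k-mers with too many scaffold occurrences
  heavy <- which(tabulate(mq, nbins = length(uq)) > MAX_KMER_HITS)
  if (length(heavy)) {
    keep <- !(mq %in% heavy)
    tidx <- tidx[keep]; mq <- mq[keep]
    if (!length(tidx)) return(empty)
  }
  qpos_by_kmer <- split(ok - 1L, factor(qk[ok], levels = uq))
  counts <- lengths(qpos_by_kmer)[mq]
  data.frame(qpos = unlist(qpos_by_kmer[mq], use.names = FALSE),
             tpos = rep(tidx - 1L, times = counts))
}

# Precomputed k-mer vectors for every scaffold of a panel; reused across all
# genes mapped against it.
panel_kmer_index <- function(panel, k) {
  lapply(panel$scaffolds, seq_kmers, k = k)
}

# Group seeds into diagonal blocks (qstart/qend/tstart/tend, 0-based half-open).
seeds_to_blocks <- function(seeds, k) {
  if (nrow(seeds) == 0L) return(NULL)
  d <- seeds$tpos - seeds$qpos
  o <- order(d, seeds$qpos)
  d <- d[o]; q <- seeds$qpos[o]
  new_run <- c(TRUE, d[-1] != d[-length(d)] |
                 (q[-1] - q[-length(q)]) > SEED_JOIN_GAP)
  run <- cumsum(new_run)
  qs <- tapply(q, run, min); qe <- tapply(q, run, max) + k
  dd <- tapply(d, run, `[`, 1)
  data.frame(qstart = as.integer(qs), qend = as.integer(qe),
             tstart = as.integer(qs + dd), tend = as.integer(qe + dd))
}

# Highest-scoring collinear chain of blocks (DP over blocks by query start).
chain_blocks <- function(blocks, max_target_gap, k) {
  b <- blocks[order(blocks$qstart, blocks$tstart), , drop = FALSE]
  nb <- nrow(b)
  len <- b$qend - b$qstart
  best <- len
  prev <- rep(NA_integer_, nb)
  slop <- k - 1L
  for (v in seq_len(nb)) {
    if (v == 1L) next
    for (u in seq_len(v - 1L)) {
      if (b$qstart[v] < b$qend[u] - slop) next
      if (b$tstart[v] < b$tend[u] - slop) next
      if (b$tend[v] <= b$tend[u]) next
      if (b$tstart[v] - b$tend[u] > max_target_gap) next
      if (b$qstart[v] - b$qend[u] > SEED_JOIN_GAP) next
      cand <- best[u] + len[v]
      if (cand > best[v]) { best[v] <- cand; prev[v] <- u }
    }
  }
  end <- which.max(best)
  path <- end
  while (!is.na(prev[path[1]])) path <- c(prev[path[1]], path)
  b[path, , drop = FALSE]
}

seg_matches <- function(query, scaffold, qs, ts, len) {
  if (len <= 0L) return(0L)
  n_matching(substr(query, qs + 1L, qs + len), substr(scaffold, ts + 1L, ts + len))
}

# Coordinate-only trimming of query/target overlaps between adjacent blocks.
# Emptying a block is a malformed chain.
trim_block_overlaps <- function(b) {
  nb <- nrow(b)
  if (nb < 2L) return(b)
  for (i in seq_len(nb - 1L)) {
    ovq <- b$qend[i] - b$qstart[i + 1L]
    if (ovq > 0L) {
      b$qstart[i + 1L] <- b$qstart[i + 1L] + ovq
      b$tstart[i + 1L] <- b$tstart[i + 1L] + ovq
    }
    ovt <- b$tend[i] - b$tstart[i + 1L]
    if (ovt > 0L) {
      b$qend[i] <- b$qend[i] - ovt
      b$tend[i] <- b$tend[i] - ovt
    }
    if (b$qend[i] <= b$qstart[i] || b$qend[i + 1L] <= b$qstart[i + 1L] ||
        b$tend[i] <= b$tstart[i] || b$tend[i + 1L] <= b$tstart[i + 1L])
      it_error("overlap trimming emptied an exon block (malformed chain)",
               "intronit_chain_error")
  }
  b
}

# Trim block overlaps, distribute inter-block query gaps between the flanking
# exon boundaries by maximizing matched bases, and extend the chain ends.
refine_chain <- function(query, scaffold, b) {
  nb <- nrow(b)
  tlen <- nchar(scaffold)
  b <- trim_block_overlaps(b)
  if (nb > 1L) {
    for (i in seq_len(nb - 1L)) {
      g <- b$qstart[i + 1L] - b$qend[i]
      G <- b$tstart[i + 1L] - b$tend[i]
      m <- min(g, G)
      if (m > 0L) {
        sc <- vapply(0:m, function(s) {
          e <- m - s
          seg_matches(query, scaffold, b$qend[i], b$tend[i], s) +
            seg_matches(query, scaffold, b$qstart[i + 1L] - e,
                        b$tstart[i + 1L] - e, e)
        }, numeric(1))
        s <- which.max(sc) - 1L   # ties -> smallest extension of the left exon
        e <- m - s
        b$qend[i] <- b$qend[i] + s;       b$tend[i] <- b$tend[i] + s
        b$qstart[i + 1L] <- b$qstart[i + 1L] - e
        b$tstart[i + 1L] <- b$tstart[i + 1L] - e
      }
    }
  }
  # end extensions to cover the query termini where identity supports it
  s0 <- min(b$qstart[1L], b$tstart[1L])
  if (s0 > 0L) {
    mm <- seg_matches(query, scaffold, b$qstart[1L] - s0, b$tstart[1L] - s0, s0)
    if (mm / s0 >= END_EXT_MIN_IDENT) {
      b$qstart[1L] <- b$qstart[1L] - s0
      b$tstart[1L] <- b$tstart[1L] - s0
    }
  }
  s1 <- min(nchar(query) - b$qend[nb], tlen - b$tend[nb])
  if (s1 > 0L) {
    mm <- seg_matches(query, scaffold, b$qend[nb], b$tend[nb], s1)
    if (mm / s1 >= END_EXT_MIN_IDENT) {
      b$qend[nb] <- b$qend[nb] + s1
      b$tend[nb] <- b$tend[nb] + s1
    }
  }
  b$matches <- vapply(seq_len(nrow(b)), function(i)
    seg_matches(query, scaffold, b$qstart[i], b$tstart[i],
                min(b$qend[i] - b$qstart[i], b$tend[i] - b$tstart[i])),
    numeric(1))
  b$identity <- b$matches / pmax(b$qend - b$qstart, b$tend - b$tstart)
  b
}

# Fuse adjacent blocks whose refined target gap is below min_intron_bp
# (alignment artifacts / small indels, not introns).
fuse_small_gaps <- function(b, min_intron_bp) {
  if (nrow(b) < 2L) return(b)
  repeat {
    gaps <- b$tstart[-1] - b$tend[-nrow(b)]
    idx <- which(gaps < min_intron_bp)
    if (!length(idx)) break
    i <- idx[1]
    b$qend[i] <- b$qend[i + 1L]; b$tend[i] <- b$tend[i + 1L]
    b$matches[i] <- b$matches[i] + b$matches[i + 1L]
    b <- b[-(i + 1L), , drop = FALSE]
    b$identity <- b$matches / pmax(b$qend - b$qstart, b$tend - b$tstart)
  }
  rownames(b) <- NULL
  b
}

#' Find candidate exon-block chains of a transcript on one scaffold
#'
#' Seeds exact k-mers of the transcript (both orientations) on the scaffold,
#' chains collinear seed groups, refines exon boundaries by redistributing
#' inter-block query gaps, and returns the highest-scoring chain per
#' orientation. Intron-sized genomic gaps between adjacent blocks are the
#' inferred introns.
#'
#' @param transcript transcript sequence (character).
#' @param scaffold scaffold sequence (character).
#' @param cfg a [pipeline_config()].
#' @param scaffold_kmers optional precomputed `seq_kmers(scaffold, seed_k)`
#'   vector (internal reuse across genes).
#' @return list of chains sorted by decreasing score; each chain is a list
#'   with `strand`, `blocks` (data.frame `qstart`,`qend`,`tstart`,`tend`,
#'   `matches`,`identity`; query coordinates in the oriented query),
#'   `score` (matched bases) and `query_coverage`. Empty list when the
#'   transcript is shorter than two seeds or nothing chains.
#' @export
find_exon_blocks <- function(transcript, scaffold, cfg = NULL,
                             scaffold_kmers = NULL) {
  cfg <- as_config(cfg)
  transcript <- normalize_seq(transcript)
  scaffold <- normalize_seq(scaffold)
  k <- cfg$seed_k
  if (nchar(transcript) < 2L * k) return(list())
  chains <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") transcript else revcomp(transcript)
    seeds <- kmer_seeds(q, scaffold, k, scaffold_kmers)
    blocks <- seeds_to_blocks(seeds, k)
    if (is.null(blocks)) next
    chain <- chain_blocks(blocks, max_target_gap = cfg$epcr_max_product_bp * 5L,
                          k = k)
    b <- tryCatch(refine_chain(q, scaffold, chain),
                  intronit_chain_error = function(e) NULL)
    if (is.null(b)) next
    b <- fuse_small_gaps(b, cfg$min_intron_bp)
    chains[[length(chains) + 1L]] <- list(
      strand = strand, blocks = b,
      score = sum(b$matches),
      query_coverage = sum(b$qend - b$qstart) / nchar(transcript))
  }
  chains[order(vapply(chains, `[[`, numeric(1), "score"), decreasing = TRUE)]
}

#' Infer introns from an exon-block chain
#'
#' For each adjacent block pair the intron size is the strand-normalized
#' genomic gap `tstart(next) - tend(prev)`. Gaps below `min_intron_bp` have
#' already been fused by the chain builder; when called on raw blocks the
#' same fusion and overlap-trimming rules are applied first.
#'
#' @param hit a `spliced_hit` (see [map_gene_to_panel()]) or a chain as
#'   returned by [find_exon_blocks()].
#' @param cfg a [pipeline_config()].
#' @return data.frame: `junction_index` (ordinal along the oriented query),
#'   `gap_bp`, `junction_query_pos` (oriented-query coordinate of the
#'   junction, i.e. `qend` of the upstream block).
#' @export
infer_introns <- function(hit, cfg = NULL) {
  cfg <- as_config(cfg)
  b <- hit$blocks
  if (is.null(b$matches)) b$matches <- b$qend - b$qstart
  b <- trim_block_overlaps(b)
  b <- fuse_small_gaps(b, cfg$min_intron_bp)
  if (nrow(b) < 2L)
    return(data.frame(junction_index = integer(0), gap_bp = integer(0),
                      junction_query_pos = integer(0)))
  gaps <- b$tstart[-1] - b$tend[-nrow(b)]
  data.frame(junction_index = seq_along(gaps),
             gap_bp = as.integer(gaps),
             junction_query_pos = as.integer(b$qend[-nrow(b)]))
}

# Convert oriented-query junction positions to transcript coordinates and
# order junctions along the transcript.
transcript_junctions <- function(chain, tx_len, cfg) {
  introns <- infer_introns(chain, cfg)
  if (nrow(introns) == 0L) return(introns)
  if (chain$strand == "-")
    introns$junction_query_pos <- tx_len - introns$junction_query_pos
  introns <- introns[order(introns$junction_query_pos), , drop = FALSE]
  introns$junction_index <- seq_len(nrow(introns))
  rownames(introns) <- NULL
  introns
}

#' Map a gene onto a panel of genome assemblies
#'
#' Runs the spliced mapper against every scaffold of every arm and keeps the
#' best hit per arm (highest chain score; ties broken by query coverage, then
#' lexicographic scaffold id, then `+` strand). Arms whose best chain covers
#' less than `min_query_cov` of the transcript are absent from the result.
#'
#' @param gene a [gene_model()].
#' @param panels named list of [genome_panel()] objects (names are arm ids).
#' @param cfg a [pipeline_config()].
#' @return named list arm id -> `spliced_hit`; a `spliced_hit` is a list with
#'   `gene_id`, `arm_id`, `scaffold_id`, `strand`, `blocks`, `score`,
#'   `query_coverage` and `introns` (junction table in transcript
#'   coordinates).
#' @param indices optional precomputed per-arm scaffold k-mer indices
#'   (internal; built by [map_genes_to_panels()]).
#' @export
map_gene_to_panel <- function(gene, panels, cfg = NULL, indices = NULL) {
  cfg <- as_config(cfg)
  tx <- gene$transcript_seq
  out <- list()
  for (arm in names(panels)) {
    panel <- panels[[arm]]
    best <- NULL
    for (sid in sort(names(panel$scaffolds))) {
      chains <- find_exon_blocks(tx, panel$scaffolds[[sid]], cfg,
                                 scaffold_kmers = indices[[arm]][[sid]])
      for (ch in chains) {
        cand <- list(scaffold_id = sid, chain = ch)
        if (is.null(best) || better_hit(cand, best)) best <- cand
      }
    }
    if (is.null(best)) next
    if (best$chain$query_coverage < cfg$min_query_cov) next
    hit <- list(gene_id = gene$gene_id, arm_id = arm,
                scaffold_id = best$scaffold_id,
                strand = best$chain$strand,
                blocks = best$chain$blocks,
                score = best$chain$score,
                query_coverage = best$chain$query_coverage)
    hit$introns <- transcript_junctions(best$chain, nchar(tx), cfg)
    class(hit) <- "spliced_hit"
    out[[arm]] <- hit
  }
  out
}

better_hit <- function(cand, best) {
  a <- cand$chain; b <- best$chain
  if (a$score != b$score) return(a$score > b$score)
  if (a$query_coverage != b$query_coverage)
    return(a$query_coverage > b$query_coverage)
  if (cand$scaffold_id != best$scaffold_id)
    return(cand$scaffold_id < best$scaffold_id)
  a$strand == "+" && b$strand == "-"
}

#' @export
print.spliced_hit <- function(x, ...) {
  cat(sprintf("<spliced_hit %s on %s/%s(%s): %d block(s), %d intron(s), cov %.2f>\n",
              x$gene_id, x$arm_id, x$scaffold_id, x$strand, nrow(x$blocks),
              nrow(x$introns), x$query_coverage))
  invisible(x)
}

#' Map many genes onto a panel
#'
#' @param genes list of [gene_model()].
#' @param panels named list of [genome_panel()].
#' @param cfg a [pipeline_config()].
#' @return named list gene id -> result of [map_gene_to_panel()].
#' @export
map_genes_to_panels <- function(genes, panels, cfg = NULL) {
  cfg <- as_config(cfg)
  indices <- lapply(panels, panel_kmer_index, k = cfg$seed_k)
  ids <- vapply(genes, `[[`, character(1), "gene_id")
  out <- lapply(genes, map_gene_to_panel, panels = panels, cfg = cfg,
                indices = indices)
  names(out) <- ids
  out[order(ids)]
}

#' Match homologous introns across arms into quartets
#'
#' Exon-exon junctions of the alien-arm hit are matched to junctions of every
#' wheat-arm hit by transcript position within `tolerance_bp` (nearest wins;
#' ties go to the smaller position). Only junctions represented on all arms
#' yield a quartet.
#'
#' @param hits named list arm -> `spliced_hit` for one gene.
#' @param tolerance_bp matching tolerance in transcript bp.
#' @param v_arm label of the alien arm (junction ordinals follow its hit).
#' @return data.frame with columns `gene_id`, `junction_index`,
#'   `junction_query_pos` and one `size_<arm>` column per arm; zero rows when
#'   no junction is complete.
#' @export
match_homologous_introns <- function(hits, tolerance_bp = 12L, v_arm = "V") {
  arms <- names(hits)
  if (!v_arm %in% arms || nrow(hits[[v_arm]]$introns) == 0L)
    return(empty_quartets(arms))
  vj <- hits[[v_arm]]$introns
  rows <- list()
  for (i in seq_len(nrow(vj))) {
    pos <- vj$junction_query_pos[i]
    sizes <- stats::setNames(numeric(length(arms)), arms)
    sizes[v_arm] <- vj$gap_bp[i]
    ok <- TRUE
    for (arm in setdiff(arms, v_arm)) {
      aj <- hits[[arm]]$introns
      if (nrow(aj) == 0L) { ok <- FALSE; break }
      dd <- abs(aj$junction_query_pos - pos)
      j <- order(dd, aj$junction_query_pos)[1]
      if (dd[j] > tolerance_bp) { ok <- FALSE; break }
      sizes[arm] <- aj$gap_bp[j]
    }
    if (!ok) next
    row <- data.frame(gene_id = hits[[v_arm]]$gene_id,
                      junction_index = i,
                      junction_query_pos = pos,
                      stringsAsFactors = FALSE)
    for (arm in arms) row[[paste0("size_", arm)]] <- as.integer(sizes[arm])
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) return(empty_quartets(arms))
  out <- do.call(rbind, rows)
  out[order(out$junction_index), , drop = FALSE]
}

empty_quartets <- function(arms) {
  df <- data.frame(gene_id = character(0), junction_index = integer(0),
                   junction_query_pos = integer(0))
  for (arm in arms) df[[paste0("size_", arm)]] <- integer(0)
  df
}

# Exon sequences of a hit in transcript orientation, plus the transcript
# position of each junction; used for exon-anchored primer design.
hit_exons_transcript_order <- function(hit, panel, tx_len) {
  scaf <- panel$scaffolds[[hit$scaffold_id]]
  b <- hit$blocks
  seqs <- substring(scaf, b$tstart + 1L, b$tend)
  if (hit$strand == "-") {
    seqs <- rev(vapply(seqs, revcomp, character(1)))
  }
  unname(seqs)
}
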