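# In-silico PCR against all four arms, gel band-pattern clustering, type
# classification, the alien-arm specificity call, and deletion-bin assignment
# across nested translocation lines.

#' Find primer binding sites on a scaffold
#'
#' All positions where the primer anneals on either strand with at most
#' `epcr_max_mismatch` mismatches and an exact match over the
#' `epcr_3prime_exact_bp` 3'-terminal bases. `N` in the template counts as a
#' mismatch.
#'
#' @param primer primer sequence 5'->3' (ACGT only).
#' @param scaffold template sequence.
#' @param cfg a [pipeline_config()].
#' @return data.frame: `position` (0-based start of the occupied window on
#'   the plus strand), `strand` (`"+"` = extension rightward), `mismatches`.
#' @export
find_binding_sites <- function(primer, scaffold, cfg = NULL) {
  cfg <- as_config(cfg)
  primer <- toupper(primer)
  if (!is_acgt(primer)) domain_error("primer must be ACGT only")
  scaffold <- normalize_seq(scaffold)
  L <- nchar(primer)
  e <- min(cfg$epcr_3prime_exact_bp, L)
  subj <- Biostrings::DNAString(scaffold)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") primer else revcomp(primer)
    m <- Biostrings::matchPattern(pat, subj,
                                  max.mismatch = cfg$epcr_max_mismatch,
                                  with.indels = FALSE, fixed = TRUE)
    if (length(m) == 0L) next
    starts <- Biostrings::start(m)
    windows <- substring(scaffold, starts, starts + L - 1L)
    mm <- L - vapply(windows, n_matching, numeric(1), b = pat)
    # exact 3' anchor: right end of the window for "+", left end for "-"
    three_prime <- if (strand == "+") {
      substring(windows, L - e + 1L, L) == substr(pat, L - e + 1L, L)
    } else {
      substring(windows, 1L, e) == substr(pat, 1L, e)
    }
    keep <- mm <= cfg$epcr_max_mismatch & three_prime
    if (!any(keep)) next
    out[[strand]] <- data.frame(position = starts[keep] - 1L,
                                strand = strand,
                                mismatches = as.integer(mm[keep]))
  }
  if (!length(out))
    return(data.frame(position = integer(0), strand = character(0),
                      mismatches = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$position, res$strand), , drop = FALSE]
}

#' Simulate PCR of a primer pair against a genome panel
#'
#' Emits an amplicon for every convergent forward/reverse binding-site pair
#' on the same scaffold with product size at most `epcr_max_product_bp`.
#' Both arrangements count (forward site on either strand, reverse site
#' facing it).
#'
#' @param forward_primer,reverse_primer primer sequences 5'->3'.
#' @param panel a [genome_panel()].
#' @param cfg a [pipeline_config()].
#' @return data.frame of amplicons sorted by size: `arm_id`, `scaffold_id`,
#'   `start`, `end` (0-based half-open), `size`, `f_mismatches`,
#'   `r_mismatches`.
#' @export
simulate_pcr <- function(forward_primer, reverse_primer, panel, cfg = NULL) {
  cfg <- as_config(cfg)
  rows <- list()
  lf <- nchar(forward_primer); lr <- nchar(reverse_primer)
  for (sid in sort(names(panel$scaffolds))) {
    scaf <- panel$scaffolds[[sid]]
    sf <- find_binding_sites(forward_primer, scaf, cfg)
    sr <- find_binding_sites(reverse_primer, scaf, cfg)
    if (nrow(sf) == 0L || nrow(sr) == 0L) next
    combos <- list(list(left = sf, llen = lf, lmm = "f",
                        right = sr, rlen = lr, rmm = "r"),
                   list(left = sr, llen = lr, lmm = "r",
                        right = sf, rlen = lf, rmm = "f"))
    for (cb in combos) {
      lp <- cb$left[cb$left$strand == "+", , drop = FALSE]
      rp <- cb$right[cb$right$strand == "-", , drop = FALSE]
      if (nrow(lp) == 0L || nrow(rp) == 0L) next
      for (i in seq_len(nrow(lp))) {
        start <- lp$position[i]
        ends <- rp$position + cb$rlen
        size <- ends - start
        # convergent: the minus-strand site must lie at/after the plus-strand
        # site, and the product must hold both primer footprints
        ok <- rp$position >= start & size >= max(cb$llen, cb$rlen) &
          size <= cfg$epcr_max_product_bp
        for (j in which(ok)) {
          fm <- if (cb$lmm == "f") lp$mismatches[i] else rp$mismatches[j]
          rm <- if (cb$lmm == "f") rp$mismatches[j] else lp$mismatches[i]
          rows[[length(rows) + 1L]] <- data.frame(
            arm_id = panel$arm_id, scaffold_id = sid,
            start = start, end = ends[j], size = size[j],
            f_mismatches = fm, r_mismatches = rm,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows))
    return(data.frame(arm_id = character(0), scaffold_id = character(0),
                      start = integer(0), end = integer(0), size = integer(0),
                      f_mismatches = integer(0), r_mismatches = integer(0)))
  res <- unique(do.call(rbind, rows))
  res <- res[order(res$size, res$scaffold_id, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cluster predicted products into co-migrating gel bands
#'
#' Single-linkage clustering in which two product sizes co-migrate when their
#' difference is at most `max(comigration_abs_bp, comigration_rel * mean of
#' the pair)`; on a line this reduces to merging adjacent sorted sizes.
#'
#' @param products named numeric vector, arm -> product size (bp); `NA`
#'   entries (no product) are dropped.
#' @param cfg a [pipeline_config()].
#' @return list of band clusters ordered by mean size, descending; each is a
#'   list with `arms` (member arm ids) and `size` (mean, 1 decimal).
#' @export
cluster_bands <- function(products, cfg = NULL) {
  cfg <- as_config(cfg)
  products <- products[!is.na(products)]
  if (!length(products)) domain_error("cluster_bands requires >= 1 product")
  o <- order(unlist(products), names(products))
  sz <- as.numeric(products[o]); arms <- names(products)[o]
  cl <- integer(length(sz)); cl[1] <- 1L
  if (length(sz) > 1L) {
    for (i in 2:length(sz)) {
      d <- sz[i] - sz[i - 1L]
      thr <- max(cfg$comigration_abs_bp,
                 cfg$comigration_rel * mean(c(sz[i], sz[i - 1L])))
      cl[i] <- if (d <= thr) cl[i - 1L] else cl[i - 1L] + 1L
    }
  }
  bands <- lapply(split(seq_along(sz), cl), function(idx)
    list(arms = arms[idx], size = round(mean(sz[idx]), 1)))
  bands <- unname(bands)
  bands[order(vapply(bands, `[[`, numeric(1), "size"), decreasing = TRUE)]
}

#' Classify a marker's band pattern and call arm specificity
#'
#' Four distinct bands are Type I. Three-band patterns with a distinct
#' alien (V) band are labelled by the surviving wheat bands: `II` = \{A,D,V\}
#' (B co-migrating), `III` = \{B,D,V\} (A co-migrating), `IV/VI` = \{A,B,V\}
#' (D co-migrating; both published labels are treated as aliases). Two-band
#' patterns with a distinct V band are `V/VII`. A V band co-migrating with
#' any wheat product is `unclassified` and not specific; a missing V product
#' is `no-V`.
#'
#' @param bands cluster list from [cluster_bands()].
#' @param v_arm alien arm label.
#' @return list: `type_label`, `is_specific`, `n_bands`.
#' @export
classify_marker <- function(bands, v_arm = "V") {
  n <- length(bands)
  has_v <- vapply(bands, function(b) v_arm %in% b$arms, logical(1))
  if (!any(has_v))
    return(list(type_label = "no-V", is_specific = FALSE, n_bands = n))
  vband <- bands[[which(has_v)]]
  specific <- length(vband$arms) == 1L
  if (!specific)
    return(list(type_label = "unclassified", is_specific = FALSE, n_bands = n))
  merged <- lapply(bands[!has_v], `[[`, "arms")
  pair <- merged[lengths(merged) == 2L]
  label <- if (n == 4L) "I"
  else if (n == 3L && length(pair) == 1L) {
    # label by which wheat pair co-migrates (published three-band taxonomy)
    p <- sort(pair[[1]])
    if (identical(p, c("A", "B"))) "II"
    else if (identical(p, c("A", "D"))) "III"
    else if (identical(p, c("B", "D"))) "IV/VI"
    else "unclassified"
  } else if (n == 2L) "V/VII"
  else "unclassified"
  list(type_label = label, is_specific = TRUE, n_bands = n)
}

# Representative product per arm from an amplicon table: best-supported
# (fewest total mismatches), tie -> smallest size.
representative_product <- function(amplicons) {
  if (nrow(amplicons) == 0L) return(NA_integer_)
  o <- order(amplicons$f_mismatches + amplicons$r_mismatches, amplicons$size)
  amplicons$size[o[1]]
}

#' Validate markers by in-silico PCR across a panel set and flag specificity
#'
#' Each marker is amplified in silico against every arm. Markers with zero
#' amplicons in at least one template are flagged `no-amplification`; the
#' rest are band-clustered and classified, yielding `specific` or
#' `amplified-not-specific`.
#'
#' @param markers marker data.frame from [design_all()].
#' @param panels named list of [genome_panel()] (must include `v_arm`).
#' @param cfg a [pipeline_config()].
#' @param v_arm alien arm label.
#' @return the marker data.frame with per-arm `product_<arm>` replaced by the
#'   in-silico sizes and columns `n_bands`, `type`, `is_specific`, `status`
#'   appended.
#' @export
call_specific_markers <- function(markers, panels, cfg = NULL, v_arm = "V") {
  cfg <- as_config(cfg)
  if (!v_arm %in% names(panels))
    config_error(sprintf("panels lack alien arm '%s'", v_arm))
  arms <- names(panels)
  if (nrow(markers) == 0L) {
    for (arm in arms) markers[[paste0("product_", arm)]] <- integer(0)
    markers$n_bands <- integer(0); markers$type <- character(0)
    markers$is_specific <- logical(0); markers$status <- character(0)
    return(markers)
  }
  for (i in seq_len(nrow(markers))) {
    products <- stats::setNames(rep(NA_integer_, length(arms)), arms)
    for (arm in arms) {
      amp <- simulate_pcr(markers$forward_primer[i], markers$reverse_primer[i],
                          panels[[arm]], cfg)
      products[arm] <- representative_product(amp)
    }
    for (arm in arms) markers[i, paste0("product_", arm)] <- products[arm]
    if (any(is.na(products))) {
      markers$status[i] <- "no-amplification"
      markers$n_bands[i] <- NA_integer_
      markers$type[i] <- if (is.na(products[v_arm])) "no-V" else NA_character_
      markers$is_specific[i] <- FALSE
      next
    }
    cls <- classify_marker(cluster_bands(products, cfg), v_arm)
    markers$n_bands[i] <- cls$n_bands
    markers$type[i] <- cls$type_label
    markers$is_specific[i] <- cls$is_specific
    markers$status[i] <- if (cls$is_specific) "specific" else
      "amplified-not-specific"
  }
  markers
}

#' Summarize specificity flags
#'
#' @param status character vector of marker statuses
#'   (`no-amplification` / `amplified-not-specific` / `specific`).
#' @return list: `n_markers`, `n_no_amplification`, `n_amplified`,
#'   `n_specific`, `specific_rate_pct` (percent of all markers, 2 decimals).
#' @examples
#' s <- rep(c("specific", "amplified-not-specific", "no-amplification"),
#'          c(232, 113, 14))
#' specificity_summary(s)$specific_rate_pct  # 64.62
#' @export
specificity_summary <- function(status) {
  n <- length(status)
  ns <- sum(status == "specific")
  list(n_markers = n,
       n_no_amplification = sum(status == "no-amplification"),
       n_amplified = sum(status != "no-amplification"),
       n_specific = ns,
       specific_rate_pct = if (n > 0) round(100 * ns / n, 2) else NA_real_)
}

#' Read a marker presence/absence matrix
#'
#' TSV with marker ids in the first column, one column per translocation
#' line, values 1 (present) / 0 (absent).
#'
#' @param path TSV path.
#' @return integer matrix, markers as rownames, lines as colnames.
#' @export
read_presence_matrix <- function(path) {
  if (!file.exists(path)) format_error(sprintf("file not found: %s", path))
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (!all(m %in% c(0L, 1L))) format_error("presence matrix values must be 0/1")
  storage.mode(m) <- "integer"
  if (anyDuplicated(rownames(m))) format_error("duplicate marker ids")
  if (anyDuplicated(colnames(m))) format_error("duplicate line ids")
  m
}

#' Assign markers to physical bins from nested translocation lines
#'
#' Lines must retain nested distal segments of the alien arm; `line_order`
#' lists them from the smallest retained segment (most distal breakpoint) to
#' the largest. A marker's bin is the interval between the breakpoint of the
#' largest non-retaining line and that of the smallest retaining line: bin 1
#' is distal of the first breakpoint (marker present in every line), bin
#' `n+1` is proximal of all breakpoints (absent everywhere). Presence
#' patterns that are not monotone along the nesting (present in a smaller
#' segment but absent in a larger one) are flagged inconsistent and get no
#' bin.
#'
#' @param presence 0/1 matrix from [read_presence_matrix()].
#' @param line_order character vector of line ids, distal-most breakpoint
#'   first (ascending retained segment).
#' @param segments optional numeric retained-segment lengths matching
#'   `line_order`; must be strictly increasing (nested), else a
#'   configuration error.
#' @return data.frame: `marker_id`, `bin` (1..n+1, NA when inconsistent),
#'   `bin_label`, `consistent`.
#' @export
assign_bins <- function(presence, line_order, segments = NULL) {
  if (!all(line_order %in% colnames(presence)))
    config_error("line_order names lines absent from the presence matrix")
  if (!is.null(segments)) {
    if (length(segments) != length(line_order) ||
        any(diff(segments) <= 0))
      config_error("line segments must be strictly increasing (nested)")
  }
  m <- presence[, line_order, drop = FALSE]
  n <- length(line_order)
  labels <- c(paste0("distal_of_", line_order[1]),
              if (n > 1) paste(line_order[-n], line_order[-1], sep = ".."),
              paste0("proximal_of_", line_order[n]))
  res <- lapply(rownames(m), function(mk) {
    v <- m[mk, ]
    consistent <- !is.unsorted(v)  # 0...0 1...1 along ascending segments
    bin <- if (!consistent) NA_integer_
    else if (all(v == 1L)) 1L
    else if (all(v == 0L)) n + 1L
    else which(v == 1L)[1]
    data.frame(marker_id = mk, bin = bin,
               bin_label = if (is.na(bin)) NA_character_ else labels[bin],
               consistent = consistent, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
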