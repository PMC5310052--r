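# The >= 10% intron-length-polymorphism criterion and one-intron-per-gene
# selection, plus the funnel report summarizing how many genes survive each
# pipeline stage.

#' Relative intron-size difference
#'
#' `|v - w| / ref` where `ref` is the wheat intron size by default (the
#' criterion reads "differed at least 10\% from that of" each wheat
#' homoeolog); `max` and `mean` of the two sizes are available alternatives.
#'
#' @param v_size alien (V) intron size in bp.
#' @param wheat_size wheat intron size in bp.
#' @param denominator `"wheat"`, `"max"` or `"mean"`.
#' @return fraction (vectorized).
#' @export
relative_difference <- function(v_size, wheat_size,
                                denominator = c("wheat", "max", "mean")) {
  denominator <- match.arg(denominator)
  if (any(v_size <= 0) || any(wheat_size <= 0))
    domain_error("intron sizes must be positive")
  ref <- switch(denominator,
                wheat = wheat_size,
                max = pmax(v_size, wheat_size),
                mean = (v_size + wheat_size) / 2)
  abs(v_size - wheat_size) / ref
}

quartet_sizes <- function(quartet, v_arm = "V") {
  if (is.data.frame(quartet)) {
    sz <- unlist(quartet[1, grep("^size_", names(quartet)), drop = FALSE])
    names(sz) <- sub("^size_", "", names(sz))
  } else sz <- unlist(quartet)
  if (!v_arm %in% names(sz))
    domain_error(sprintf("quartet lacks alien arm '%s'", v_arm))
  if (any(is.na(sz)))
    domain_error("incomplete quartet: sizes must be defined for all arms")
  sz
}

#' Decide whether an intron quartet is a targeted intron
#'
#' TRUE iff the alien-arm intron size differs by at least
#' `polymorphism_threshold` (relative, see [relative_difference()]) from the
#' size in every wheat arm simultaneously.
#'
#' @param quartet named numeric vector of per-arm intron sizes (e.g.
#'   `c(A = 632, B = 545, D = 687, V = 433)`) or a one-row quartet
#'   data.frame with `size_<arm>` columns.
#' @param cfg a [pipeline_config()].
#' @param v_arm alien arm label.
#' @return list with `targeted` (logical), `rel_diffs` (named fractions per
#'   wheat arm) and `min_rel_diff`.
#' @examples
#' is_targeted_intron(c(A = 632, B = 545, D = 687, V = 433))$targeted
#' @export
is_targeted_intron <- function(quartet, cfg = NULL, v_arm = "V") {
  cfg <- as_config(cfg)
  sz <- quartet_sizes(quartet, v_arm)
  wheat <- setdiff(names(sz), v_arm)
  if (!length(wheat)) domain_error("quartet has no wheat arms")
  rel <- vapply(wheat, function(a)
    relative_difference(sz[[v_arm]], sz[[a]], cfg$polymorphism_denominator),
    numeric(1))
  list(targeted = all(rel >= cfg$polymorphism_threshold),
       rel_diffs = rel,
       min_rel_diff = min(rel))
}

#' Filter a quartet table down to targeted introns
#'
#' @param quartets data.frame from [match_homologous_introns()] (rows may
#'   span many genes).
#' @param cfg a [pipeline_config()].
#' @param v_arm alien arm label.
#' @return the targeted subset with `min_rel_diff` appended.
#' @export
filter_targeted_introns <- function(quartets, cfg = NULL, v_arm = "V") {
  cfg <- as_config(cfg)
  if (nrow(quartets) == 0L) {
    quartets$min_rel_diff <- numeric(0)
    return(quartets)
  }
  res <- lapply(seq_len(nrow(quartets)), function(i)
    is_targeted_intron(quartets[i, , drop = FALSE], cfg, v_arm))
  keep <- vapply(res, `[[`, logical(1), "targeted")
  out <- quartets[keep, , drop = FALSE]
  out$min_rel_diff <- vapply(res[keep], `[[`, numeric(1), "min_rel_diff")
  rownames(out) <- NULL
  out
}

#' Select the single marker intron of a gene
#'
#' The "one genome marker" rule: among a gene's targeted introns, keep the
#' one with maximal minimum relative difference; ties go to the smallest
#' junction index.
#'
#' @param targets data.frame of targeted introns for one gene (rows of
#'   [filter_targeted_introns()] output).
#' @return the selected one-row data.frame.
#' @export
select_marker_intron <- function(targets) {
  if (is.null(targets) || nrow(targets) == 0L)
    domain_error("select_marker_intron requires at least one targeted intron")
  o <- order(-targets$min_rel_diff, targets$junction_index)
  out <- targets[o[1], , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the pipeline funnel report
#'
#' Stage-by-stage bookkeeping of the marker-design funnel: input genes, genes
#' hitting all arms, intron-containing genes, total introns, mean introns per
#' intron-containing gene (2 decimals), targeted introns, genes with at least
#' one target, and designed markers.
#'
#' @param n_genes_input,n_genes_hit_all_arms,n_genes_with_junction,
#'   n_introns_total,n_targeted_introns,n_genes_with_target,n_markers_designed
#'   stage counts.
#' @return object of class `funnel_report` (named list including
#'   `mean_introns_per_gene`, `NA` when no gene has an intron).
#' @examples
#' r <- build_funnel_report(n_genes_with_junction = 626, n_introns_total = 1774)
#' r$mean_introns_per_gene  # 2.83
#' @export
build_funnel_report <- function(n_genes_input = NA_integer_,
                                n_genes_hit_all_arms = NA_integer_,
                                n_genes_with_junction = NA_integer_,
                                n_introns_total = NA_integer_,
                                n_targeted_introns = NA_integer_,
                                n_genes_with_target = NA_integer_,
                                n_markers_designed = NA_integer_) {
  mean_ipg <- if (!is.na(n_genes_with_junction) && n_genes_with_junction > 0 &&
                  !is.na(n_introns_total))
    round(n_introns_total / n_genes_with_junction, 2) else NA_real_
  structure(list(
    n_genes_input = n_genes_input,
    n_genes_hit_all_arms = n_genes_hit_all_arms,
    n_genes_with_junction = n_genes_with_junction,
    n_introns_total = n_introns_total,
    mean_introns_per_gene = mean_ipg,
    n_targeted_introns = n_targeted_introns,
    n_genes_with_target = n_genes_with_target,
    n_markers_designed = n_markers_designed), class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("Marker-design funnel:\n")
  for (f in names(x)) cat(sprintf("  %-24s %s\n", f, format(x[[f]])))
  invisible(x)
}
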