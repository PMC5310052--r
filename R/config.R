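#' Pipeline configuration
#'
#' Bundles every tunable threshold of the marker-design pipeline. Defaults
#' reproduce the published design criteria: duplicate-gene removal at
#' e-value <= 1e-5 and coverage > 80\%, a 10\% intron-length-polymorphism
#' threshold referenced to each wheat homoeolog, primer melting temperature
#' 55-65 degC (optimum 60), primer length 18-25 nt (optimum 20), and PCR
#' products at least ~50 bp larger than the targeted intron.
#'
#' @param dedup_evalue_cutoff maximum e-value for a transcript pair to count
#'   as redundant during gene-set merging.
#' @param dedup_coverage_cutoff minimum aligned coverage (fraction, exclusive
#'   bound: coverage must exceed it) for redundancy.
#' @param dedup_coverage_denominator `"shorter"` (default, conservative) or
#'   `"longer"`: which transcript length divides the aligned length.
#' @param min_intron_bp smallest genomic gap treated as an intron; smaller
#'   gaps are fused as alignment artifacts.
#' @param polymorphism_threshold minimum relative intron-size difference of
#'   the alien (V) intron from every wheat homoeolog.
#' @param polymorphism_denominator `"wheat"` (default), `"max"` or `"mean"`:
#'   reference size in the relative difference.
#' @param tm_min,tm_opt,tm_max primer melting temperature bounds (degC).
#' @param primer_len_min,primer_len_opt,primer_len_max primer lengths (nt).
#' @param gc_min,gc_max primer GC-content bounds (fractions).
#' @param max_homopolymer longest allowed mononucleotide run in a primer.
#' @param max_self_comp longest allowed contiguous self-complementary stretch
#'   (hairpin / self-dimer proxy).
#' @param product_overhead_bp required excess of the V-genome product size
#'   over the targeted intron size.
#' @param max_flank_bp how far into each flanking exon primer windows are
#'   enumerated, measured from the intron.
#' @param comigration_abs_bp,comigration_rel two predicted products co-migrate
#'   (one gel band) when their size difference is at most
#'   `max(comigration_abs_bp, comigration_rel * mean size)`.
#' @param epcr_max_product_bp largest product reported by in-silico PCR.
#' @param epcr_max_mismatch maximum mismatches tolerated per primer site.
#' @param epcr_3prime_exact_bp number of 3'-terminal primer bases that must
#'   match the template exactly.
#' @param seed_k exact k-mer seed length of the spliced mapper.
#' @param junction_tol_bp tolerance (transcript bp) when matching exon-exon
#'   junctions across homoeologous arms.
#' @param min_query_cov minimum fraction of the transcript aligned for an arm
#'   to count as having a hit.
#' @param tm_method `"nn"` (nearest-neighbor thermodynamics) or `"wallace"`.
#' @param monovalent_mM,oligo_nM salt and total oligonucleotide concentration
#'   used by the nearest-neighbor Tm model.
#' @param rng_seed seed used by stochastic components (synthetic data).
#' @return an object of class `pipeline_config` (a validated named list).
#' @examples
#' cfg <- pipeline_config()
#' cfg$polymorphism_threshold
#' @export
pipeline_config <- function(dedup_evalue_cutoff = 1e-5,
                            dedup_coverage_cutoff = 0.80,
                            dedup_coverage_denominator = c("shorter", "longer"),
                            min_intron_bp = 40L,
                            polymorphism_threshold = 0.10,
                            polymorphism_denominator = c("wheat", "max", "mean"),
                            tm_min = 55, tm_opt = 60, tm_max = 65,
                            primer_len_min = 18L, primer_len_opt = 20L,
                            primer_len_max = 25L,
                            gc_min = 0.30, gc_max = 0.70,
                            max_homopolymer = 4L,
                            max_self_comp = 8L,
                            product_overhead_bp = 50L,
                            max_flank_bp = 150L,
                            comigration_abs_bp = 4L,
                            comigration_rel = 0.01,
                            epcr_max_product_bp = 3000L,
                            epcr_max_mismatch = 2L,
                            epcr_3prime_exact_bp = 5L,
                            seed_k = 15L,
                            junction_tol_bp = 12L,
                            min_query_cov = 0.5,
                            tm_method = c("nn", "wallace"),
                            monovalent_mM = 50,
                            oligo_nM = 250,
                            rng_seed = 1L) {
  cfg <- list(
    dedup_evalue_cutoff = dedup_evalue_cutoff,
    dedup_coverage_cutoff = dedup_coverage_cutoff,
    dedup_coverage_denominator = match.arg(dedup_coverage_denominator),
    min_intron_bp = as.integer(min_intron_bp),
    polymorphism_threshold = polymorphism_threshold,
    polymorphism_denominator = match.arg(polymorphism_denominator),
    tm_min = tm_min, tm_opt = tm_opt, tm_max = tm_max,
    primer_len_min = as.integer(primer_len_min),
    primer_len_opt = as.integer(primer_len_opt),
    primer_len_max = as.integer(primer_len_max),
    gc_min = gc_min, gc_max = gc_max,
    max_homopolymer = as.integer(max_homopolymer),
    max_self_comp = as.integer(max_self_comp),
    product_overhead_bp = as.integer(product_overhead_bp),
    max_flank_bp = as.integer(max_flank_bp),
    comigration_abs_bp = as.integer(comigration_abs_bp),
    comigration_rel = comigration_rel,
    epcr_max_product_bp = as.integer(epcr_max_product_bp),
    epcr_max_mismatch = as.integer(epcr_max_mismatch),
    epcr_3prime_exact_bp = as.integer(epcr_3prime_exact_bp),
    seed_k = as.integer(seed_k),
    junction_tol_bp = as.integer(junction_tol_bp),
    min_query_cov = min_query_cov,
    tm_method = match.arg(tm_method),
    monovalent_mM = monovalent_mM,
    oligo_nM = oligo_nM,
    rng_seed = as.integer(rng_seed)
  )
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  pos <- c("dedup_evalue_cutoff", "dedup_coverage_cutoff", "min_intron_bp",
           "polymorphism_threshold", "product_overhead_bp",
           "comigration_abs_bp", "epcr_max_product_bp",
           "epcr_3prime_exact_bp", "seed_k", "junction_tol_bp",
           "monovalent_mM", "oligo_nM")
  for (p in pos) {
    if (!is.numeric(cfg[[p]]) || length(cfg[[p]]) != 1L || cfg[[p]] <= 0)
      config_error(sprintf("config field '%s' must be a positive scalar", p))
  }
  if (cfg$epcr_max_mismatch < 0)
    config_error("epcr_max_mismatch must be non-negative")
  if (!(cfg$tm_min <= cfg$tm_opt && cfg$tm_opt <= cfg$tm_max))
    config_error("require tm_min <= tm_opt <= tm_max")
  if (!(cfg$primer_len_min <= cfg$primer_len_opt &&
        cfg$primer_len_opt <= cfg$primer_len_max))
    config_error("require primer_len_min <= primer_len_opt <= primer_len_max")
  invisible(cfg)
}

as_config <- function(cfg) {
  if (is.null(cfg)) return(pipeline_config())
  if (inherits(cfg, "pipeline_config")) return(cfg)
  if (is.list(cfg)) return(do.call(pipeline_config, cfg))
  config_error("cfg must be NULL, a pipeline_config or a named list")
}

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment; keys must be
#' `pipeline_config()` arguments. Unknown keys raise a configuration error.
#'
#' @param path text file path
#' @return a `pipeline_config`
#' @export
read_config <- function(path) {
  if (!file.exists(path)) config_error(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      config_error(sprintf("malformed config line: '%s'", ln))
    key <- trimws(kv[1]); val <- trimws(kv[2])
    num <- suppressWarnings(as.numeric(val))
    args[[key]] <- if (is.na(num)) val else num
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(args), known)
  if (length(bad))
    config_error(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  do.call(pipeline_config, args)
}
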