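#' Published reference IT markers
#'
#' The six representative published 4VS intron-targeting markers (primer
#' pairs and per-subgenome intron sizes, one per reported band-pattern
#' type), shipped as input data for worked examples and validation of the
#' targeted-intron criterion.
#'
#' @return data.frame: `marker_id`, `forward_primer`, `reverse_primer`,
#'   `intron_A`, `intron_B`, `intron_D`, `intron_V`, `reported_type`.
#' @examples
#' ref <- published_marker_table()
#' is_targeted_intron(c(A = ref$intron_A[1], B = ref$intron_B[1],
#'                      D = ref$intron_D[1], V = ref$intron_V[1]))$targeted
#' @export
published_marker_table <- function() {
  path <- system.file("extdata", "published_it_markers.tsv",
                      package = "intronIT", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
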