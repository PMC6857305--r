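#' Bundled reference signature sets (synthetic)
#'
#' Loads one of the signature matrices shipped with the package. Both sets
#' are *synthetic stand-ins*, generated deterministically by
#' `scripts/make_reference_data.R`: they encode the documented qualitative
#' shapes of their published namesakes (class weights, context emphasis,
#' and for the flat "featureless" pair Sig3/Sig5 the published cosine
#' similarity of ~0.83 between them), not the published numerical values.
#'
#' * `"cosmic_v2_synthetic"` — 96 channels x 30 SNV signatures
#'   (`Sig1`..`Sig30`), in the style of the COSMIC v2 set. `Sig3` plays the
#'   role of the HR-deficiency signature, `Sig1`/`Sig5` of the clock-like
#'   background processes, `Sig6/15/20/26` of the mismatch-repair set and
#'   `Sig11` of the POLE-like confounder.
#' * `"rs_breast_synthetic"` — 32 rearrangement channels x 6 signatures
#'   (`RS1`..`RS6`), in the style of the breast-cancer rearrangement
#'   signatures; `RS5` is the small/mid-size non-clustered deletion
#'   signature characteristic of BRCA2-type HR loss.
#'
#' @param set Which set to load.
#' @return Numeric matrix, channels x signatures, columns summing to 1,
#'   channel labels as row names.
#' @export
reference_signatures <- function(set = c("cosmic_v2_synthetic",
                                         "rs_breast_synthetic")) {
  set <- match.arg(set)
  file <- switch(set,
                 cosmic_v2_synthetic = "cosmic_v2_synthetic_signatures.tsv",
                 rs_breast_synthetic = "rs32_synthetic_signatures.tsv")
  path <- system.file("extdata", file, package = "hrsig", mustWork = TRUE)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab$channel
  # columns are stored rounded; renormalize to exact unit sums
  sweep(m, 2, colSums(m), "/")
}
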