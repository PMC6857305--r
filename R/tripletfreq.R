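#' Strand-collapsed triplet frequencies of a genome
#'
#' Counts every overlapping trinucleotide of the genome, collapses purine-
#' centred triplets onto their reverse complement, and normalizes to a
#' 32-entry frequency table over the pyrimidine-centred triplets. Windows
#' containing ambiguous bases are skipped.
#'
#' These tables drive the cross-species context adjustment: a signature
#' derived in one genome is mapped onto another genome's triplet
#' availability with [adjust_triplet_frequencies()].
#'
#' @param genome Reference genome (see [as_genome()]).
#' @return Named numeric vector over [pyrimidine_triplets()], summing to 1.
#' @export
count_triplet_frequencies <- function(genome) {
  genome <- as_genome(genome)
  if (length(genome) == 0 || all(Biostrings::width(genome) < 3))
    stop("genome too short to contain a triplet")
  counts64 <- colSums(Biostrings::trinucleotideFrequency(genome))
  trip <- pyrimidine_triplets()
  out <- stats::setNames(numeric(32), trip)
  for (t3 in names(counts64)) {
    centre <- substr(t3, 2, 2)
    key <- if (centre %in% c("C", "T")) t3 else revcomp(t3)
    out[key] <- out[key] + counts64[[t3]]
  }
  if (sum(out) == 0) stop("no unambiguous triplet in genome")
  out / sum(out)
}

#' Map a 96-channel signature between genomes with different triplet content
#'
#' Each channel is re-weighted by the ratio of its pyrimidine-centred
#' triplet's frequency in the target genome to that in the source genome,
#' then every signature column is renormalized to sum 1. Applying the
#' adjustment with source and target swapped inverts it.
#'
#' @param sig 96 x k signature matrix (or a 96-vector), channels in the
#'   fixed order.
#' @param source_freq,target_freq 32-entry triplet frequency tables
#'   (see [count_triplet_frequencies()]); all source entries must be > 0.
#' @return Adjusted signature matrix with columns summing to 1.
#' @export
adjust_triplet_frequencies <- function(sig, source_freq, target_freq) {
  if (is.null(dim(sig))) sig <- matrix(sig, ncol = 1)
  if (nrow(sig) != 96) stop("signature must have 96 channels")
  trip <- sbs_channels()$triplet
  src <- source_freq[trip]; tgt <- target_freq[trip]
  if (any(is.na(src)) || any(is.na(tgt)))
    stop("frequency table missing triplet entries")
  if (any(src == 0)) stop("zero source triplet frequency")
  out <- sig * (tgt / src)
  out <- sweep(out, 2, colSums(out), "/")
  out
}
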