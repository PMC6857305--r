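#' Longest breakpoint microhomology of a deletion
#'
#' Microhomology is sequence identity between the two deletion breakpoints:
#' the longest prefix of the deleted sequence that reappears at the start of
#' the right flank, or the longest suffix of the deleted sequence that also
#' ends the left flank — whichever is longer. Either one allows the deletion
#' to be explained by end joining across the shared bases. The value is
#' capped at one below the deletion length: a full-length match means the
#' deleted sequence has an intact adjacent copy, which is a tandem repeat,
#' not microhomology.
#'
#' @param deleted_seq Deleted sequence (non-empty).
#' @param left_flank Reference sequence ending at the left breakpoint.
#' @param right_flank Reference sequence starting at the right breakpoint.
#' @return Integer microhomology length >= 0.
#' @export
max_microhomology <- function(deleted_seq, left_flank, right_flank) {
  L <- nchar(deleted_seq)
  if (L == 0) stop("empty deleted sequence")
  k1 <- 0L
  while (k1 < L && k1 < nchar(right_flank) &&
           substr(deleted_seq, k1 + 1, k1 + 1) ==
           substr(right_flank, k1 + 1, k1 + 1))
    k1 <- k1 + 1L
  k2 <- 0L
  nl <- nchar(left_flank)
  while (k2 < L && k2 < nl &&
           substr(deleted_seq, L - k2, L - k2) ==
           substr(left_flank, nl - k2, nl - k2))
    k2 <- k2 + 1L
  min(max(k1, k2), L - 1L)
}

#' Tandem copy number of a deleted sequence
#'
#' Counts the consecutive exact copies of the deleted sequence present in
#' the reference around the deletion site: the deleted copy itself plus
#' adjacent copies scanning outward left and right.
#'
#' @inheritParams max_microhomology
#' @return Integer >= 1.
#' @export
tandem_copies <- function(deleted_seq, left_flank, right_flank) {
  L <- nchar(deleted_seq)
  if (L == 0) stop("empty deleted sequence")
  copies <- 1L
  lf <- left_flank
  while (nchar(lf) >= L &&
           substr(lf, nchar(lf) - L + 1, nchar(lf)) == deleted_seq) {
    copies <- copies + 1L
    lf <- substr(lf, 1, nchar(lf) - L)
  }
  rf <- right_flank
  while (nchar(rf) >= L && substr(rf, 1, L) == deleted_seq) {
    copies <- copies + 1L
    rf <- substr(rf, L + 1, nchar(rf))
  }
  copies
}

# flanks around an anchored indel; deleted bases occupy pos+1 .. pos+L
indel_flanks <- function(record, genome, span) {
  genome <- as_genome(genome)
  L <- nchar(record$ref) - 1L
  chrom_len <- Biostrings::width(genome[record$chrom])
  left <- genome_slice(genome, record$chrom,
                       record$pos - span + 1L, record$pos)
  right <- genome_slice(genome, record$chrom,
                        record$pos + L + 1L, record$pos + L + span)
  list(left = left, right = right,
       truncated = nchar(left) < span || nchar(right) < span,
       chrom_len = chrom_len)
}

#' Classify a short deletion by sequence context
#'
#' A deletion is `repeat` when the deleted sequence is present in at least
#' two tandem copies in the reference (the deleted copy plus at least one
#' adjacent copy); otherwise `microhomology` when the two breakpoints share
#' at least 1 bp of homology; otherwise `none`. Repeat takes precedence over
#' microhomology. The record is left-aligned before classification, which
#' makes the call independent of where the caller placed the event inside a
#' repeat tract.
#'
#' @param record One catalog row with `kind == "DEL"` (anchored
#'   representation).
#' @param genome Reference genome (see [as_genome()]).
#' @return One-row `data.frame`: the record columns plus `deleted_seq`,
#'   `del_length`, `context_class`, `mh_length`, `tandem_copies`.
#' @export
classify_deletion <- function(record, genome) {
  if (record$kind != "DEL") stop("classify_deletion expects a DEL record")
  genome <- as_genome(genome)
  record <- left_align_indel(record, genome)
  deleted <- substr(record$ref, 2, nchar(record$ref))
  L <- nchar(deleted)
  span <- max(L * 6L, L + 10L)
  fl <- indel_flanks(record, genome, span)
  if (nchar(fl$left) < L || nchar(fl$right) < L)
    warning("deletion at contig edge: flank truncated at ",
            record$chrom, ":", record$pos)
  copies <- tandem_copies(deleted, fl$left, fl$right)
  mh <- max_microhomology(deleted, fl$left, fl$right)
  cls <- if (copies >= 2) "repeat" else if (mh >= 1) "microhomology"
         else "none"
  out <- record
  out$deleted_seq <- deleted
  out$del_length <- L
  out$context_class <- cls
  out$mh_length <- if (cls == "none") 0L else mh
  out$tandem_copies <- copies
  out
}

# pyrimidine-normalized identity of a single inserted/deleted base
pyr_base <- function(b) if (b %in% c("A", "G")) COMPLEMENT[[b]] else b

#' 83-channel classification of a short insertion or deletion
#'
#' Assigns the PCAWG / COSMIC v3 indel channel (see [id83_channels()]).
#' Deletions qualifying for both a tandem-repeat and a microhomology reading
#' are assigned to repeat channels.
#'
#' @param record One catalog row, `kind` `"INS"` or `"DEL"`.
#' @param genome Reference genome (see [as_genome()]).
#' @return The channel label (character); match against [id83_channels()]
#'   for the index.
#' @export
classify_indel_id83 <- function(record, genome) {
  if (record$kind == "SNV") stop("SNV passed to indel classification")
  genome <- as_genome(genome)
  record <- left_align_indel(record, genome)
  if (record$kind == "DEL") {
    deleted <- substr(record$ref, 2, nchar(record$ref))
    L <- nchar(deleted)
    fl <- indel_flanks(record, genome, max(L * 6L, L + 10L))
    copies <- tandem_copies(deleted, fl$left, fl$right)
    if (L == 1)
      return(paste0("1:Del:", pyr_base(deleted), ":", min(copies - 1L, 5L)))
    len_bin <- min(L, 5L)
    if (copies >= 2)
      return(paste0(len_bin, ":Del:R:", min(copies - 1L, 5L)))
    mh <- max_microhomology(deleted, fl$left, fl$right)
    if (mh >= 1)
      return(paste0(len_bin, ":Del:M:", min(mh, 5L)))
    return(paste0(len_bin, ":Del:R:0"))
  }
  inserted <- substr(record$alt, 2, nchar(record$alt))
  L <- nchar(inserted)
  fl <- indel_flanks_ins(record, genome, max(L * 6L, L + 10L))
  copies <- adjacent_copies(inserted, fl$left, fl$right)
  if (L == 1)
    return(paste0("1:Ins:", pyr_base(inserted), ":", min(copies, 5L)))
  paste0(min(L, 5L), ":Ins:R:", min(copies, 5L))
}

# flanks around an insertion point (between pos and pos + 1)
indel_flanks_ins <- function(record, genome, span) {
  genome <- as_genome(genome)
  list(left = genome_slice(genome, record$chrom,
                           record$pos - span + 1L, record$pos),
       right = genome_slice(genome, record$chrom,
                            record$pos + 1L, record$pos + span))
}

# pre-existing adjacent copies of an inserted unit in the reference
adjacent_copies <- function(unit, left_flank, right_flank) {
  L <- nchar(unit)
  copies <- 0L
  lf <- left_flank
  while (nchar(lf) >= L &&
           substr(lf, nchar(lf) - L + 1, nchar(lf)) == unit) {
    copies <- copies + 1L
    lf <- substr(lf, 1, nchar(lf) - L)
  }
  rf <- right_flank
  while (nchar(rf) >= L && substr(rf, 1, L) == unit) {
    copies <- copies + 1L
    rf <- substr(rf, L + 1, nchar(rf))
  }
  copies
}

#' Classify every short indel of a catalog
#'
#' @param catalog Catalog `data.frame`.
#' @param genome Reference genome.
#' @param max_len Length bound for "short" indels (default 50 bp,
#'   exclusive); longer events belong to the rearrangement analysis and are
#'   skipped with a count.
#' @return List with `deletions` (classified deletion calls, one row each),
#'   `id83` (samples x 83 count matrix), `n_long` (skipped events).
#' @export
classify_indels <- function(catalog, genome, max_len = 50) {
  genome <- as_genome(genome)
  idx <- which(catalog$kind != "SNV")
  samples <- unique(catalog$sample)
  id83 <- matrix(0L, length(samples), 83,
                 dimnames = list(samples, id83_channels()))
  dels <- list(); n_long <- 0L
  for (i in idx) {
    rec <- catalog[i, ]
    len <- abs(nchar(rec$ref) - nchar(rec$alt))
    if (len >= max_len) { n_long <- n_long + 1L; next }
    ch <- classify_indel_id83(rec, genome)
    id83[rec$sample, ch] <- id83[rec$sample, ch] + 1L
    if (rec$kind == "DEL")
      dels[[length(dels) + 1]] <- classify_deletion(rec, genome)
  }
  deletions <- if (length(dels)) do.call(rbind, dels) else NULL
  list(deletions = deletions, id83 = id83, n_long = n_long)
}

#' Deletion size distribution
#'
#' Empirical cumulative distribution of deletion lengths with the median
#' under the lower-midpoint convention (for an even count, the lower of the
#' two central order statistics).
#'
#' @param calls Classified deletion calls (output rows of
#'   [classify_deletion()]), or a numeric vector of deletion lengths.
#' @return List with `ecdf` (a function), `median`, `lengths` (sorted).
#' @export
deletion_size_ecdf <- function(calls) {
  lengths <- if (is.numeric(calls)) calls else calls$del_length
  if (length(lengths) == 0) stop("no deletions")
  s <- sort(lengths)
  n <- length(s)
  med <- if (n %% 2 == 1) s[(n + 1) / 2] else s[n / 2]
  list(ecdf = stats::ecdf(s), median = med, lengths = s)
}
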