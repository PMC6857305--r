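#' Trinucleotide channel of a single SNV
#'
#' Looks up the reference triplet around an SNV and returns its channel in
#' the fixed 96-channel order. Purine reference bases are reverse-
#' complemented (mutation and context together) so the reported class is
#' pyrimidine-referenced.
#'
#' @param genome Reference genome (see [as_genome()]).
#' @param record One catalog row with `kind == "SNV"`.
#' @return Integer channel index in 1..96, or `NA` (with attribute) if a
#'   flanking base is not A/C/G/T.
#' @export
triplet_class <- function(genome, record) {
  genome <- as_genome(genome)
  if (record$kind != "SNV") stop("triplet_class expects an SNV record")
  chrom <- record$chrom; pos <- record$pos
  len <- Biostrings::width(genome[chrom])
  if (pos - 1 < 1 || pos + 1 > len)
    stop("SNV context out of chromosome bounds at ", chrom, ":", pos)
  ctx <- genome_slice(genome, chrom, pos - 1L, pos + 1L)
  if (substr(ctx, 2, 2) != record$ref)
    stop("reference mismatch at ", chrom, ":", pos, ": genome has ",
         substr(ctx, 2, 2), ", record says ", record$ref)
  ref <- record$ref; alt <- record$alt
  if (ref %in% c("A", "G")) {
    ctx <- revcomp(ctx)
    ref <- COMPLEMENT[[ref]]
    alt <- COMPLEMENT[[alt]]
  }
  five <- substr(ctx, 1, 1); three <- substr(ctx, 3, 3)
  if (grepl("[^ACGT]", paste0(five, three))) return(NA_integer_)
  cls <- paste0(ref, ">", alt)
  match(paste0(five, "[", cls, "]", three), SBS_LABELS)
}

#' Build 96-channel trinucleotide spectra from a catalog
#'
#' Tallies the SNVs of a catalog into the 96 trinucleotide substitution
#' channels, one spectrum per sample (or one overall). Non-SNV records are
#' ignored and counted; SNVs whose flanking context contains an ambiguous
#' base are skipped with a warning.
#'
#' @param catalog Catalog `data.frame` (see [load_catalog()]).
#' @param genome Reference genome (see [as_genome()]).
#' @param by `"sample"` (default) for one spectrum per sample, or `NULL`
#'   for a single pooled spectrum.
#' @return A numeric matrix, samples x 96, with channel labels as column
#'   names; attribute `n_skipped` gives the number of context-skipped SNVs,
#'   `n_non_snv` the number of ignored non-SNV records. Each row sums to the
#'   number of its classified SNVs.
#' @export
build_spectrum <- function(catalog, genome, by = "sample") {
  ch <- sbs_channels()
  labels <- ch$label
  if (is.null(by)) {
    samples <- "all"
    grp <- rep("all", nrow(catalog))
  } else {
    grp <- catalog$sample
    samples <- unique(grp)
  }
  mat <- matrix(0, nrow = length(samples), ncol = 96,
                dimnames = list(samples, labels))
  n_skipped <- 0L; n_non_snv <- 0L
  if (nrow(catalog) > 0) {
    genome <- as_genome(genome)
    for (i in seq_len(nrow(catalog))) {
      rec <- catalog[i, ]
      if (rec$kind != "SNV") { n_non_snv <- n_non_snv + 1L; next }
      k <- triplet_class(genome, rec)
      if (is.na(k)) { n_skipped <- n_skipped + 1L; next }
      mat[grp[i], k] <- mat[grp[i], k] + 1
    }
  }
  if (n_skipped > 0)
    warning(n_skipped, " SNV(s) skipped: ambiguous flanking base")
  attr(mat, "n_skipped") <- n_skipped
  attr(mat, "n_non_snv") <- n_non_snv
  mat
}

#' Aggregate per-sample spectra by group
#'
#' @param spectra Samples x channels matrix (any channel system).
#' @param groups Character vector, one group label per row of `spectra`.
#' @param method `"sum"` (default; pooled counts per group, the form fed to
#'   de novo signature extraction) or `"mean"` (average of per-sample
#'   spectra).
#' @return Groups x channels matrix.
#' @export
aggregate_spectra <- function(spectra, groups, method = c("sum", "mean")) {
  method <- match.arg(method)
  stopifnot(length(groups) == nrow(spectra))
  f <- if (method == "sum") colSums else colMeans
  out <- t(vapply(split(seq_along(groups), groups)[unique(groups)],
                  function(ix) f(spectra[ix, , drop = FALSE]),
                  numeric(ncol(spectra))))
  colnames(out) <- colnames(spectra)
  out
}

#' Write spectra to a tab-separated file
#'
#' One row per channel: substitution class, 5' base, 3' base, then one count
#' column per sample/group.
#' @param spectra Samples x 96 matrix from [build_spectrum()].
#' @param path Output file path.
#' @export
write_spectrum <- function(spectra, path) {
  ch <- sbs_channels()
  out <- data.frame(class = ch$class, five = ch$five, three = ch$three,
                    t(spectra), check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
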