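#' Channel definitions for mutation classification schemes
#'
#' The package classifies mutations into three fixed channel systems:
#' the 96-channel pyrimidine-referenced trinucleotide substitution scheme,
#' the 83-channel short-indel scheme (COSMIC v3 / PCAWG nomenclature), and
#' the 32-channel rearrangement scheme (clustered / non-clustered x type x
#' size bin, plus translocations).
#'
#' Channel order is fixed throughout: substitution classes in the order
#' C>A, C>G, C>T, T>A, T>C, T>G; within a class the 16 flanking contexts are
#' ordered by the 5' base then the 3' base, both alphabetical.
#'
#' @name channels
NULL

SBS_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a DNA string (base R, used on short alleles)
#' @param x character vector of DNA strings over A/C/G/T/N.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' The 96 trinucleotide substitution channels
#'
#' @return A data.frame with 96 rows and columns `class` (substitution class,
#'   pyrimidine-referenced), `five` (5' base), `three` (3' base), `label`
#'   (e.g. `"A[C>A]A"`), and `triplet` (the pyrimidine-centred reference
#'   triplet, e.g. `"ACA"`), in the fixed channel order.
#' @export
sbs_channels <- function() {
  grid <- expand.grid(three = BASES, five = BASES, class = SBS_CLASSES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$class, SBS_CLASSES), grid$five, grid$three), ]
  rownames(grid) <- NULL
  grid$label <- paste0(grid$five, "[", grid$class, "]", grid$three)
  grid$triplet <- paste0(grid$five, substr(grid$class, 1, 1), grid$three)
  grid[, c("class", "five", "three", "label", "triplet")]
}

#' The 32 pyrimidine-centred triplets
#'
#' Strand-collapsed triplet identities (centre base C or T), the context
#' dimension over which genome triplet frequencies are tabulated.
#'
#' @return Character vector of 32 triplets, centre C first then centre T,
#'   flanks alphabetical (5' major, 3' minor).
#' @export
pyrimidine_triplets <- function() {
  out <- c()
  for (centre in c("C", "T"))
    for (five in BASES)
      for (three in BASES)
        out <- c(out, paste0(five, centre, three))
  out
}

#' The 83 short-indel channels (PCAWG / COSMIC v3 nomenclature)
#'
#' Channels are labelled `LEN:TYPE:SUBTYPE:BIN`:
#' * `1:Del:C|T:0..5` — 1 bp deletions by deleted base (purines complemented),
#'   binned by the number of additional copies of the base flanking the
#'   deleted one (homopolymer length minus one), capped at 5+.
#' * `1:Ins:C|T:0..5` — 1 bp insertions, binned by the pre-existing run
#'   length of the inserted base, capped at 5+.
#' * `2..5+:Del:R:0..5` — >=2 bp deletions by length (capped 5+) and number
#'   of additional tandem copies of the deleted sequence (capped 5+).
#' * `2..5+:Ins:R:0..5` — >=2 bp insertions, same binning.
#' * `2..5+:Del:M:1..` — deletions with breakpoint microhomology but no
#'   tandem copy, by length and microhomology length (mh < length, mh
#'   capped at 5+): 2:M:1; 3:M:1-2; 4:M:1-3; 5+:M:1-5+.
#'
#' @return Character vector of the 83 channel labels in canonical order.
#' @export
id83_channels <- function() {
  ch <- c()
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Del:", b, ":", 0:5))
  for (b in c("C", "T")) ch <- c(ch, paste0("1:Ins:", b, ":", 0:5))
  for (l in c("2", "3", "4", "5")) ch <- c(ch, paste0(l, ":Del:R:", 0:5))
  for (l in c("2", "3", "4", "5")) ch <- c(ch, paste0(l, ":Ins:R:", 0:5))
  ch <- c(ch,
          "2:Del:M:1",
          paste0("3:Del:M:", 1:2),
          paste0("4:Del:M:", 1:3),
          paste0("5:Del:M:", 1:5))
  ch
}

#' The 32 rearrangement channels
#'
#' Clustered and non-clustered rearrangements, each split into deletion,
#' tandem duplication and inversion across five size bins (half-open:
#' 1-10 kb, 10-100 kb, 100 kb-1 Mb, 1-10 Mb, >=10 Mb) plus interchromosomal
#' translocation.
#'
#' @return Character vector of 32 channel labels, e.g.
#'   `"clustered:del:1-10kb"`, `"non-clustered:trans"`.
#' @export
rearrangement_channels <- function() {
  bins <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
  ch <- c()
  for (cl in c("clustered", "non-clustered")) {
    for (ty in c("del", "dup", "inv"))
      ch <- c(ch, paste0(cl, ":", ty, ":", bins))
    ch <- c(ch, paste0(cl, ":trans"))
  }
  ch
}

SBS_LABELS <- local({
  grid <- expand.grid(three = BASES, five = BASES, class = SBS_CLASSES,
                      stringsAsFactors = FALSE)
  grid <- grid[order(match(grid$class, SBS_CLASSES), grid$five, grid$three), ]
  paste0(grid$five, "[", grid$class, "]", grid$three)
})

# size bin index for an intra-chromosomal SV; half-open, upper-exclusive
sv_size_bin <- function(size) {
  stopifnot(size >= 0)
  if (size < 1e4) 1L
  else if (size < 1e5) 2L
  else if (size < 1e6) 3L
  else if (size < 1e7) 4L
  else 5L
}
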