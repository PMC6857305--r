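#' Read a somatic mutation catalog
#'
#' Reads per-sample somatic SNV/indel calls from a tab-separated table or a
#' VCF file into the package's catalog representation: one row per mutation
#' with columns `sample`, `chrom`, `pos` (1-based, first reference base
#' affected), `ref`, `alt` and `kind` (`"SNV"`, `"INS"` or `"DEL"`).
#'
#' Alleles are normalized to the anchored (VCF-style) representation: indels
#' carry one shared anchor base, so a deletion has `ref = anchor + deleted`
#' and `alt = anchor`. Records already minimal are kept as-is; redundant
#' shared prefixes/suffixes are trimmed. Complex substitutions that cannot
#' be reduced to an SNV or a pure insertion/deletion are rejected.
#'
#' @param path Path to the catalog file.
#' @param format `"tsv"` (header must contain sample/chrom/pos/ref/alt,
#'   any order) or `"vcf"` (one sample per file; the sample is taken from
#'   the VCF sample column when present, otherwise from the file name).
#' @return A `data.frame` catalog in file order.
#' @export
load_catalog <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("catalog file not found: ", path)
  if (format == "tsv") {
    tab <- utils::read.table(path, header = TRUE, sep = "\t",
                             colClasses = "character", comment.char = "")
    names(tab) <- tolower(names(tab))
    names(tab)[names(tab) == "sample_id"] <- "sample"
    need <- c("sample", "chrom", "pos", "ref", "alt")
    if (!all(need %in% names(tab)))
      stop("catalog is missing column(s): ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    tab <- tab[, need]
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    smp <- colnames(v@gt)
    smp <- if (!is.null(smp) && length(smp) > 1) smp[2]
           else sub("\\.vcf(\\.gz)?$", "", basename(path))
    # expand comma-separated ALT alleles into one record each
    alts <- strsplit(fix$ALT, ",", fixed = TRUE)
    idx <- rep(seq_len(nrow(fix)), lengths(alts))
    tab <- data.frame(sample = smp, chrom = fix$CHROM[idx], pos = fix$POS[idx],
                      ref = fix$REF[idx], alt = unlist(alts),
                      stringsAsFactors = FALSE)
  }
  tab$pos <- as.integer(tab$pos)
  tab$ref <- toupper(tab$ref)
  tab$alt <- toupper(tab$alt)
  bad <- grepl("[^ACGT]", tab$ref) | grepl("[^ACGT]", tab$alt) |
    tab$ref == "" | tab$alt == ""
  if (any(bad))
    stop("malformed allele (non-ACGT) at line ", which(bad)[1], ": ",
         tab$ref[which(bad)[1]], ">", tab$alt[which(bad)[1]])
  out <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i)
    normalize_record(tab$sample[i], tab$chrom[i], tab$pos[i],
                     tab$ref[i], tab$alt[i])))
  rownames(out) <- NULL
  key <- paste(out$chrom, out$pos, out$alt, sep = "\r")
  n_samples_per_call <- tapply(out$sample, key, function(s) length(unique(s)))
  if (any(n_samples_per_call > 1))
    warning("identical chrom/pos/alt calls appear in more than one sample; ",
            "unique-per-sample calling is an input assumption")
  out
}

# reduce one call to anchored minimal representation and infer its kind
normalize_record <- function(sample, chrom, pos, ref, alt) {
  if (ref == alt) stop("ref equals alt at ", chrom, ":", pos)
  # trim shared suffix
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1)
    alt <- substr(alt, 1, nchar(alt) - 1)
  }
  # trim shared prefix, keeping one anchor base for length changes
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref)); alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1L
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    kind <- "SNV"
  } else if (nchar(ref) > nchar(alt) && alt == substr(ref, 1, nchar(alt))) {
    kind <- "DEL"
    if (nchar(alt) != 1) stop("unnormalizable deletion at ", chrom, ":", pos)
  } else if (nchar(alt) > nchar(ref) && ref == substr(alt, 1, nchar(ref))) {
    kind <- "INS"
    if (nchar(ref) != 1) stop("unnormalizable insertion at ", chrom, ":", pos)
  } else {
    stop("complex substitution not representable as SNV/INS/DEL at ",
         chrom, ":", pos, " (", ref, ">", alt, ")")
  }
  data.frame(sample = sample, chrom = chrom, pos = pos, ref = ref, alt = alt,
             kind = kind, stringsAsFactors = FALSE)
}

# fetch genome[chrom][from..to] as a character string; genome is a
# DNAStringSet (or a path to a FASTA, resolved by as_genome)
genome_slice <- function(genome, chrom, from, to) {
  if (!chrom %in% names(genome))
    stop("chromosome not in genome: ", chrom)
  len <- Biostrings::width(genome[chrom])
  from <- max(1L, from); to <- min(len, to)
  if (from > to) return("")
  as.character(Biostrings::subseq(genome[[chrom]], from, to))
}

#' Coerce a genome argument to a DNAStringSet
#'
#' Accepts a `Biostrings::DNAStringSet`, a named character vector of
#' chromosome sequences, or the path of a FASTA file.
#' @param genome The genome in any accepted form.
#' @return A `DNAStringSet` named by chromosome.
#' @export
as_genome <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    g <- Biostrings::readDNAStringSet(genome)
    names(g) <- sub("\\s.*$", "", names(g))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome)))
    return(Biostrings::DNAStringSet(genome))
  stop("genome must be a DNAStringSet, a named character vector, ",
       "or a FASTA path")
}

#' Left-align an anchored indel against the reference
#'
#' Shifts an insertion or deletion to its leftmost equivalent representation,
#' which makes repeat-context classification independent of how the caller
#' chose to place the event inside a repeat tract.
#'
#' @param record One catalog row (`kind` `"INS"` or `"DEL"`).
#' @param genome Reference genome (see [as_genome()]).
#' @return The record, possibly with `pos`, `ref`, `alt` shifted left.
#' @export
left_align_indel <- function(record, genome) {
  if (record$kind == "SNV") return(record)
  genome <- as_genome(genome)
  seq <- if (record$kind == "DEL") substr(record$ref, 2, nchar(record$ref))
         else substr(record$alt, 2, nchar(record$alt))
  pos <- record$pos
  repeat {
    if (pos <= 1) break
    prev <- genome_slice(genome, record$chrom, pos, pos)  # current anchor base
    last <- substr(seq, nchar(seq), nchar(seq))
    if (prev == "") break
    # shifting left by one replaces the event sequence's last base with the
    # anchor base; valid iff they are equal
    if (last != prev) break
    seq <- paste0(prev, substr(seq, 1, nchar(seq) - 1))
    pos <- pos - 1L
  }
  anchor <- genome_slice(genome, record$chrom, pos, pos)
  record$pos <- pos
  if (record$kind == "DEL") {
    record$ref <- paste0(anchor, seq); record$alt <- anchor
  } else {
    record$ref <- anchor; record$alt <- paste0(anchor, seq)
  }
  record
}
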