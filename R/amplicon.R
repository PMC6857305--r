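#' Alignment scoring parameters
#'
#' Defaults reproduce the EMBOSS Needle defaults for DNA: match +5,
#' mismatch -4 (EDNAFULL), gap opening penalty 10, gap extension 0.5, so an
#' affine gap of length L costs `gap_open + (L - 1) * gap_extend`. End gaps
#' are not penalized (ends-free global alignment), so length-trimmed reads
#' do not register terminal artefacts. `N` is scored 0 against everything.
#'
#' @param match,mismatch Substitution scores.
#' @param gap_open,gap_extend Positive gap penalties.
#' @return List of class `"alignment_params"`.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 10, gap_extend = 0.5) {
  if (!(gap_open >= gap_extend && gap_extend >= 0))
    stop("need gap_open >= gap_extend >= 0")
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global pairwise alignment of a read against a reference amplicon
#'
#' Optimal ends-free global alignment under affine gap cost (a gap of
#' length L costs `gap_open + (L - 1) * gap_extend`).
#'
#' @param query,reference Non-empty DNA strings over A/C/G/T/N.
#' @param params See [alignment_params()].
#' @return List of class `"amplicon_alignment"`: `query_aln` and `ref_aln`
#'   (gapped strings of equal length), `score`, `ref_start` (1-based
#'   reference offset of the first aligned reference base).
#' @export
global_align <- function(query, reference, params = alignment_params()) {
  if (nchar(query) == 0 || nchar(reference) == 0)
    stop("empty sequence")
  if (grepl("[^ACGTN]", query) || grepl("[^ACGTN]", reference))
    stop("sequences must be over A/C/G/T/N")
  sub <- matrix(params$mismatch, 5, 5,
                dimnames = list(c("A", "C", "G", "T", "N"),
                                c("A", "C", "G", "T", "N")))
  diag(sub) <- params$match
  sub["N", ] <- 0; sub[, "N"] <- 0
  # Biostrings gap cost is gapOpening + L * gapExtension; shifting the
  # opening by one extension reproduces gap_open + (L - 1) * gap_extend
  aln <- Biostrings::pairwiseAlignment(
    pattern = query, subject = reference, type = "overlap",
    substitutionMatrix = sub,
    gapOpening = params$gap_open - params$gap_extend,
    gapExtension = params$gap_extend)
  out <- list(query_aln = as.character(Biostrings::alignedPattern(aln)),
              ref_aln = as.character(Biostrings::alignedSubject(aln)),
              score = Biostrings::score(aln),
              ref_start = Biostrings::start(Biostrings::subject(aln)))
  class(out) <- "amplicon_alignment"
  out
}

#' @export
print.amplicon_alignment <- function(x, ...) {
  cat("Pairwise amplicon alignment (score ", x$score, ")\n", sep = "")
  cat("  ref:   ", x$ref_aln, "\n  query: ", x$query_aln, "\n", sep = "")
  invisible(x)
}

#' Extract indel events from an amplicon alignment
#'
#' Gap runs in the query become deletions, gap runs in the reference become
#' insertions (with the inserted sequence). A deletion and an insertion
#' whose reference positions are within 3 bp of each other are merged into
#' one `mixed` event. Events whose reference interval does not intersect
#' `cut_site +/- window` are discarded as background sequencing noise; a
#' read with no retained event is wildtype. Substitutions are not events.
#'
#' @param alignment An `"amplicon_alignment"` (see [global_align()]).
#' @param cut_site 1-based reference offset of the Cas9 blunt cut.
#' @param window Noise window around the cut site in bp (default 20).
#' @return List with `wildtype` (logical) and `events` (`data.frame` with
#'   columns `kind`, `start`, `length`, `inserted_seq`).
#' @export
extract_events <- function(alignment, cut_site, window = 20) {
  ref_len <- nchar(gsub("-", "", alignment$ref_aln))
  if (cut_site < 1 || cut_site > ref_len)
    stop("cut site outside the reference amplicon")
  q <- strsplit(alignment$query_aln, "")[[1]]
  r <- strsplit(alignment$ref_aln, "")[[1]]
  ref_pos <- alignment$ref_start - 1L
  events <- list()
  i <- 1L
  n <- length(q)
  while (i <= n) {
    if (q[i] == "-" && r[i] != "-") {          # deletion run
      start <- ref_pos + 1L
      len <- 0L
      while (i <= n && q[i] == "-") {
        ref_pos <- ref_pos + 1L; len <- len + 1L; i <- i + 1L
      }
      events[[length(events) + 1]] <-
        data.frame(kind = "deletion", start = start, length = len,
                   inserted_seq = "", stringsAsFactors = FALSE)
    } else if (r[i] == "-" && q[i] != "-") {   # insertion run
      start <- ref_pos                          # inserted after this base
      ins <- c()
      while (i <= n && r[i] == "-") { ins <- c(ins, q[i]); i <- i + 1L }
      events[[length(events) + 1]] <-
        data.frame(kind = "insertion", start = start,
                   length = length(ins),
                   inserted_seq = paste(ins, collapse = ""),
                   stringsAsFactors = FALSE)
    } else {
      ref_pos <- ref_pos + 1L
      i <- i + 1L
    }
  }
  ev <- if (length(events)) do.call(rbind, events) else
    data.frame(kind = character(), start = integer(), length = integer(),
               inserted_seq = character(), stringsAsFactors = FALSE)
  # merge adjacent deletion + insertion (<= 3 bp apart) into mixed events
  if (nrow(ev) >= 2) {
    ev <- ev[order(ev$start), ]
    merged <- list(); skip <- FALSE
    for (j in seq_len(nrow(ev))) {
      if (skip) { skip <- FALSE; next }
      if (j < nrow(ev) && ev$kind[j] != ev$kind[j + 1]) {
        end_j <- if (ev$kind[j] == "deletion")
          ev$start[j] + ev$length[j] - 1 else ev$start[j]
        if (abs(ev$start[j + 1] - end_j) <= 3) {
          merged[[length(merged) + 1]] <- data.frame(
            kind = "mixed", start = min(ev$start[j], ev$start[j + 1]),
            length = sum(ev$length[j:(j + 1)]),
            inserted_seq = paste0(ev$inserted_seq[j:(j + 1)],
                                  collapse = ""),
            stringsAsFactors = FALSE)
          skip <- TRUE
          next
        }
      }
      merged[[length(merged) + 1]] <- ev[j, ]
    }
    ev <- do.call(rbind, merged)
  }
  # retain events intersecting the cut-site window
  if (nrow(ev) > 0) {
    lo <- cut_site - window; hi <- cut_site + window
    ev_end <- ifelse(ev$kind == "insertion", ev$start,
                     ev$start + ev$length - 1)
    keep <- ev$start <= hi & ev_end >= lo
    ev <- ev[keep, , drop = FALSE]
    rownames(ev) <- NULL
  }
  list(wildtype = nrow(ev) == 0, events = ev)
}

#' Read merged amplicon reads
#'
#' @param path FASTA or FASTQ file of merged reads.
#' @return Named character vector of read sequences.
#' @export
read_amplicons <- function(path) {
  fmt <- if (grepl("\\.f(ast)?q(\\.gz)?$", path)) "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = fmt)
  stats::setNames(as.character(x), names(x))
}

#' Align amplicon reads and summarize cut-site events
#'
#' Runs [global_align()] and [extract_events()] for every read.
#'
#' @param reads Character vector of merged read sequences.
#' @param reference Reference amplicon sequence.
#' @param cut_site 1-based reference offset of the cut.
#' @param window Noise window (default 20).
#' @param params Alignment parameters.
#' @return List of per-read event sets (as from [extract_events()]).
#' @export
call_amplicon_events <- function(reads, reference, cut_site, window = 20,
                                 params = alignment_params()) {
  lapply(reads, function(rd)
    extract_events(global_align(rd, reference, params), cut_site, window))
}

#' Cut-site mutation spectrum over amplicon reads
#'
#' Percentages are computed over all reads (wildtype reads stay in the
#' denominator); the deletion size distribution is computed over deletion
#' events with [deletion_size_ecdf()].
#'
#' @param events List of per-read event sets (see
#'   [call_amplicon_events()]).
#' @return List: `n_reads`, `pct_wildtype`, `pct_deletion`, `pct_insertion`,
#'   `pct_mixed`, `deletion_lengths` (per deletion event),
#'   `deletion_pct_by_length` (percent of all reads carrying a deletion of
#'   each length), `deletion_median`, `deletion_ecdf`.
#' @export
event_spectrum <- function(events) {
  n <- length(events)
  if (n == 0) stop("no reads")
  has_kind <- function(e, k) any(e$events$kind == k)
  wt <- vapply(events, `[[`, logical(1), "wildtype")
  del_lengths <- unlist(lapply(events, function(e)
    e$events$length[e$events$kind == "deletion"]))
  del_reads <- vapply(events, has_kind, logical(1), "deletion")
  by_len <- if (length(del_lengths))
    100 * table(factor(del_lengths, levels = seq_len(max(del_lengths)))) / n
  else table(numeric(0))
  ec <- if (length(del_lengths)) deletion_size_ecdf(del_lengths) else NULL
  list(n_reads = n,
       pct_wildtype = 100 * mean(wt),
       pct_deletion = 100 * mean(del_reads),
       pct_insertion = 100 * mean(vapply(events, has_kind, logical(1),
                                         "insertion")),
       pct_mixed = 100 * mean(vapply(events, has_kind, logical(1),
                                     "mixed")),
       deletion_lengths = del_lengths,
       deletion_pct_by_length = by_len,
       deletion_median = if (is.null(ec)) NA_real_ else ec$median,
       deletion_ecdf = if (is.null(ec)) NULL else ec$ecdf)
}
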