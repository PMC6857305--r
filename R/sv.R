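#' Read structural-variant calls from a CREST-like table
#'
#' @param path Tab-separated file with header columns `sample`, `chrom1`,
#'   `pos1`, `chrom2`, `pos2`, `type` (deletion / insertion /
#'   tandem-duplication / inversion / ITX / CTX), `softclips`.
#' @return `data.frame` of SV records with an added `size` column
#'   (`abs(pos2 - pos1)` for intra-chromosomal records, `NA` otherwise).
#' @export
read_sv_calls <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  names(tab) <- tolower(names(tab))
  need <- c("sample", "chrom1", "pos1", "chrom2", "pos2", "type",
            "softclips")
  if (!all(need %in% names(tab)))
    stop("SV table missing column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$pos1 <- as.integer(tab$pos1); tab$pos2 <- as.integer(tab$pos2)
  tab$size <- ifelse(tab$chrom1 == tab$chrom2, abs(tab$pos2 - tab$pos1),
                     NA_integer_)
  tab
}

#' Post-filter structural-variant candidates
#'
#' Retains a candidate when (i) neither of its breakpoints occurs (within
#' `tol` bp) in any other sample — germline and systematic artefacts recur
#' across an isogenic panel, true de novo events are unique to one clone;
#' (ii) every sample has sequencing coverage at both breakpoints, so the
#' event's absence elsewhere is informative; and (iii) it is supported by at
#' least `min_softclip` soft-clipped reads.
#'
#' @param candidates SV `data.frame` (see [read_sv_calls()]).
#' @param coverage `data.frame` with columns `sample`, `chrom`, `pos`,
#'   `depth`: per-sample read depth at every breakpoint position. A missing
#'   entry is an error naming the sample and position.
#' @param min_softclip Minimum soft-clip support (default 5).
#' @param tol Breakpoint matching tolerance in bp for the cross-sample
#'   uniqueness test (default 10).
#' @return The retained subset of `candidates`, in input order.
#' @export
filter_svs <- function(candidates, coverage, min_softclip = 5, tol = 10) {
  n <- nrow(candidates)
  if (n == 0) return(candidates)
  bp <- rbind(
    data.frame(i = seq_len(n), sample = candidates$sample,
               chrom = candidates$chrom1, pos = candidates$pos1),
    data.frame(i = seq_len(n), sample = candidates$sample,
               chrom = candidates$chrom2, pos = candidates$pos2))
  # (i) cross-sample uniqueness within +/- tol
  unique_ok <- rep(TRUE, n)
  for (r in seq_len(nrow(bp))) {
    hit <- bp$chrom == bp$chrom[r] & abs(bp$pos - bp$pos[r]) <= tol &
      bp$sample != bp$sample[r]
    if (any(hit)) unique_ok[bp$i[r]] <- FALSE
  }
  # (ii) coverage in all samples at both breakpoints
  samples <- unique(c(candidates$sample, coverage$sample))
  cov_key <- paste(coverage$sample, coverage$chrom, coverage$pos)
  depth_at <- function(smp, chrom, pos) {
    j <- match(paste(smp, chrom, pos), cov_key)
    if (is.na(j))
      stop("missing coverage entry for sample ", smp, " at ",
           chrom, ":", pos)
    coverage$depth[j]
  }
  covered_ok <- vapply(seq_len(n), function(i) {
    all(vapply(samples, function(smp)
      depth_at(smp, candidates$chrom1[i], candidates$pos1[i]) >= 1 &&
      depth_at(smp, candidates$chrom2[i], candidates$pos2[i]) >= 1,
      logical(1)))
  }, logical(1))
  # (iii) soft-clip support
  support_ok <- candidates$softclips >= min_softclip
  candidates[unique_ok & covered_ok & support_ok, , drop = FALSE]
}

# exact O(n^2) dynamic program: least-squares piecewise-constant fit of y
# with penalty gamma per additional segment and minimum segment size kmin;
# returns the segment index per observation
pcf_segment <- function(y, kmin, gamma) {
  n <- length(y)
  if (n < 2 * kmin) return(rep(1L, n))
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  sse <- function(i, j) {            # segment cost for y[i..j]
    s <- cs[j + 1] - cs[i]
    cs2[j + 1] - cs2[i] - s^2 / (j - i + 1)
  }
  best <- rep(Inf, n + 1); best[1] <- -gamma   # first segment pays no penalty
  back <- integer(n + 1)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      if (j - i + 1 < kmin) next
      if (i > 1 && i - 1 < kmin) next
      cand <- best[i] + gamma + sse(i, j)
      if (cand < best[j + 1]) { best[j + 1] <- cand; back[j + 1] <- i }
    }
  }
  seg <- integer(n)
  j <- n
  bounds <- c()
  while (j >= 1) { bounds <- c(back[j + 1], bounds); j <- back[j + 1] - 1 }
  for (b in seq_along(bounds)) {
    from <- bounds[b]
    to <- if (b < length(bounds)) bounds[b + 1] - 1 else n
    seg[from:to] <- b
  }
  seg
}

#' Detect clustered rearrangement breakpoints
#'
#' Within each chromosome, the sorted breakpoint positions are converted to
#' inter-breakpoint distances (each breakpoint's distance to its nearest
#' sorted neighbour), and log10 distances are segmented by an exact
#' least-squares piecewise-constant fit with penalty `gamma` per changepoint
#' and minimum segment size `kmin`. A segment is called clustered when its
#' mean inter-breakpoint distance is at least 10-fold below the chromosome
#' average.
#'
#' @param breakpoints `data.frame` with columns `chrom` and `pos` (one row
#'   per breakpoint), or a numeric vector of positions on one chromosome.
#' @param kmin Minimum breakpoints per segment (default 10).
#' @param gamma Changepoint penalty (default 25).
#' @return Logical vector, one flag per input row (in input order): `TRUE`
#'   for breakpoints in clustered segments.
#' @export
detect_clusters <- function(breakpoints, kmin = 10, gamma = 25) {
  if (is.numeric(breakpoints))
    breakpoints <- data.frame(chrom = "chr", pos = breakpoints)
  flags <- rep(FALSE, nrow(breakpoints))
  for (chrom in unique(breakpoints$chrom)) {
    idx <- which(breakpoints$chrom == chrom)
    if (length(idx) < kmin) next
    ord <- order(breakpoints$pos[idx])
    p <- breakpoints$pos[idx][ord]
    n <- length(p)
    gaps <- diff(p)
    d <- pmin(c(gaps[1], gaps), c(gaps, gaps[n - 1]))  # nearest-neighbour
    seg <- pcf_segment(log10(pmax(d, 1)), kmin, gamma)
    chrom_mean <- mean(d)
    for (s in unique(seg)) {
      in_seg <- seg == s
      if (mean(d[in_seg]) <= chrom_mean / 10)
        flags[idx[ord][in_seg]] <- TRUE
    }
  }
  flags
}

#' Classify structural variants into the 32 rearrangement channels
#'
#' Each filtered SV is assigned to exactly one channel by clustered status,
#' type and size bin (see [rearrangement_channels()]). CREST types map as:
#' `deletion` to del, `insertion` and `tandem-duplication` to dup,
#' `inversion` to inv, `CTX` to translocation. `ITX` calls lack a one-to-one
#' mapping onto the scheme and are excluded from the catalog, counted in the
#' `n_itx` attribute. Intra-chromosomal events below 1 kb fall into the
#' smallest bin, with a warning.
#'
#' @param svs SV `data.frame` (see [read_sv_calls()]).
#' @param clustered Logical vector, one flag per SV (e.g. from
#'   [detect_clusters()] applied to the breakpoints); recycled if length 1.
#' @return Named 32-vector of counts (class `"rearrangement_catalog"`);
#'   attribute `n_itx` counts excluded ITX records.
#' @export
classify_rearrangements <- function(svs, clustered = FALSE) {
  if (length(clustered) == 1) clustered <- rep(clustered, nrow(svs))
  stopifnot(length(clustered) == nrow(svs))
  channels <- rearrangement_channels()
  counts <- stats::setNames(numeric(32), channels)
  type_map <- c(deletion = "del", insertion = "dup",
                "tandem-duplication" = "dup", inversion = "inv")
  n_itx <- 0L; n_small <- 0L
  for (i in seq_len(nrow(svs))) {
    cl <- if (clustered[i]) "clustered" else "non-clustered"
    ty <- svs$type[i]
    if (ty == "ITX") { n_itx <- n_itx + 1L; next }
    if (ty == "CTX") {
      ch <- paste0(cl, ":trans")
    } else {
      if (!ty %in% names(type_map)) stop("unknown SV type: ", ty)
      size <- svs$size[i]
      if (size < 1e3) n_small <- n_small + 1L
      bins <- c("1-10kb", "10-100kb", "100kb-1Mb", "1-10Mb", ">10Mb")
      ch <- paste0(cl, ":", type_map[[ty]], ":", bins[sv_size_bin(size)])
    }
    counts[ch] <- counts[ch] + 1
  }
  if (n_small > 0)
    warning(n_small, " intra-chromosomal SV(s) below 1 kb counted in the ",
            "1-10 kb bin")
  attr(counts, "n_itx") <- n_itx
  class(counts) <- c("rearrangement_catalog", class(counts))
  counts
}

#' Fit rearrangement-signature contributions by NNLS
#'
#' @param catalog 32-channel count vector (see
#'   [classify_rearrangements()]).
#' @param rs 32 x k rearrangement signature matrix, columns summing to 1.
#' @return Object of class `"signature_fit"` (see [fit_signatures()]) with
#'   contributions normalized to fractions; no pruning is applied
#'   (`min_contribution = 0`).
#' @export
fit_rearrangement_signatures <- function(catalog, rs) {
  if (sum(catalog) == 0) stop("empty rearrangement catalog")
  fit_signatures(as.numeric(catalog), rs, min_contribution = 0)
}
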