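# Independent brute-force oracles used across the suite. These deliberately
# re-derive results by enumeration / direct string scanning, not by calling
# the package's own code paths.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# --- microhomology / tandem-copy string oracles ------------------------

oracle_mh <- function(deleted, left, right) {
  L <- nchar(deleted)
  dch <- strsplit(deleted, "")[[1]]
  rch <- strsplit(right, "")[[1]]
  lch <- strsplit(left, "")[[1]]
  k1 <- 0
  for (k in seq_len(min(L, length(rch)))) {
    if (all(dch[1:k] == rch[1:k])) k1 <- k else break
  }
  k2 <- 0
  nl <- length(lch)
  for (k in seq_len(min(L, nl))) {
    if (all(dch[(L - k + 1):L] == lch[(nl - k + 1):nl])) k2 <- k else break
  }
  min(max(k1, k2), L - 1)
}

oracle_tandem <- function(deleted, left, right) {
  L <- nchar(deleted)
  copies <- 1
  # sliding exact-match scan leftwards then rightwards
  k <- 0
  while (TRUE) {
    seg_from <- nchar(left) - (k + 1) * L + 1
    if (seg_from < 1) break
    if (substr(left, seg_from, seg_from + L - 1) == deleted) k <- k + 1
    else break
  }
  copies <- copies + k
  k <- 0
  while (TRUE) {
    seg_from <- k * L + 1
    if (seg_from + L - 1 > nchar(right)) break
    if (substr(right, seg_from, seg_from + L - 1) == deleted) k <- k + 1
    else break
  }
  copies + k
}

# --- exhaustive ends-free affine alignment oracle ----------------------

# Enumerates every alignment (move strings over M/D/I), scoring runs:
# substitution scores per M; each maximal gap run costs
# gap_open + (len-1)*gap_extend, except the first and last run of the
# alignment when they are gap runs (free end gaps). N scores 0.
oracle_align_score <- function(a, b, match = 5, mismatch = -4,
                               gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  la <- length(av); lb <- length(bv)
  subsc <- function(x, y) {
    if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
  }
  best <- -Inf
  score_moves <- function(moves) {
    r <- rle(moves)
    total <- 0
    i <- 0; j <- 0
    pos <- 0
    for (q in seq_along(r$lengths)) {
      m <- r$values[q]; len <- r$lengths[q]
      if (m == "M") {
        for (t in seq_len(len)) {
          total <- total + subsc(av[i + t], bv[j + t])
        }
        i <- i + len; j <- j + len
      } else {
        terminal <- (q == 1) || (q == length(r$lengths))
        if (!terminal) total <- total - (gap_open + (len - 1) * gap_extend)
        if (m == "D") i <- i + len else j <- j + len
      }
    }
    total
  }
  rec <- function(i, j, moves) {
    if (i == la && j == lb) {
      s <- score_moves(moves)
      if (s > best) best <<- s
      return(invisible())
    }
    if (i < la && j < lb) rec(i + 1, j + 1, c(moves, "M"))
    if (i < la) rec(i + 1, j, c(moves, "D"))
    if (j < lb) rec(i, j + 1, c(moves, "I"))
  }
  rec(0, 0, character(0))
  best
}

# --- exact segmentation oracle by composition enumeration --------------

oracle_segment <- function(y, kmin, gamma) {
  n <- length(y)
  sse <- function(ix) sum((y[ix] - mean(y[ix]))^2)
  best <- list(cost = Inf, bounds = NULL)
  rec <- function(start, bounds) {
    if (start > n) {
      segs <- mapply(function(f, t) f:t, bounds,
                     c(bounds[-1] - 1, n)[seq_along(bounds)],
                     SIMPLIFY = FALSE)
      cost <- sum(vapply(segs, sse, numeric(1))) +
        gamma * (length(bounds) - 1)
      if (cost < best$cost) best <<- list(cost = cost, bounds = bounds)
      return(invisible())
    }
    for (len in kmin:(n - start + 1)) {
      if (n - (start + len) + 1 %in% c(0, kmin:n))
        rec(start + len, c(bounds, start))
    }
  }
  if (n >= kmin) rec(1, integer(0)) else
    best <- list(cost = sum((y - mean(y))^2), bounds = 1L)
  best
}

# --- NNLS helpers ------------------------------------------------------

# KKT conditions for min ||A x - b||^2, x >= 0
kkt_ok <- function(A, b, x, tol = 1e-8) {
  g <- 2 * t(A) %*% (A %*% x - b)
  active <- x > tol
  all(abs(g[active]) < sqrt(tol)) && all(g[!active] > -sqrt(tol))
}

# two-signature mixture by exhaustive grid search over total and fraction
oracle_nnls2 <- function(A, b, n_grid = 400) {
  stopifnot(ncol(A) == 2)
  tot <- sum(b) / max(colSums(A))
  best <- c(NA, NA); best_err <- Inf
  for (f in seq(0, 1, length.out = n_grid + 1)) {
    for (s in seq(0, 2 * sum(b), length.out = n_grid + 1)) {
      x <- c(f * s, (1 - f) * s)
      err <- sum((A %*% x - b)^2)
      if (err < best_err) { best_err <- err; best <- x }
    }
  }
  best
}

# --- rank-based correlation oracle -------------------------------------

oracle_spearman <- function(a, b) {
  ra <- rank(a); rb <- rank(b)   # average ranks for ties
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# a tiny deterministic two-chromosome genome for catalog tests
fixture_genome <- function() {
  Biostrings::DNAStringSet(c(
    chr1 = "ACGTACGTTTTGCCAGGCTAACGATCGATCGGCTAGCTAAACCCGGGTTT",
    chr2 = "TTGCACACACATTGCGCGCGTTAACCGGTTAAGGCCTTAA"))
}
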