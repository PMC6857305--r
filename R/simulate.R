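#' Simulate 96-channel spectra from a signature mixture
#'
#' Draws each sample's channel counts multinomially from its
#' exposure-weighted mixture of signatures, recording the generating truth.
#' With a fixed seed the output is reproducible bit-for-bit.
#'
#' @param signatures 96 x k signature matrix, columns summing to 1.
#' @param exposures n x k matrix of per-sample signature exposures (counts);
#'   a sample's burden is its row sum.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @return List with `spectra` (n x 96 counts) and `truth` (the exposure
#'   matrix).
#' @export
simulate_catalog <- function(signatures, exposures, seed = NULL) {
  signatures <- as.matrix(signatures)
  exposures <- as.matrix(exposures)
  stopifnot(ncol(exposures) == ncol(signatures))
  if (any(exposures < 0)) stop("negative exposure")
  if (any(rowSums(exposures) == 0))
    stop("sample with zero total exposure")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(exposures)
  spectra <- matrix(0, n, nrow(signatures))
  colnames(spectra) <- rownames(signatures)
  rownames(spectra) <- rownames(exposures) %||% paste0("sample", seq_len(n))
  for (i in seq_len(n)) {
    p <- as.numeric(signatures %*% exposures[i, ])
    p <- p / sum(p)
    burden <- round(sum(exposures[i, ]))
    spectra[i, ] <- stats::rmultinom(1, burden, p)
  }
  list(spectra = spectra, truth = exposures)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Signature separability simulation
#'
#' Measures how well rank-2 NMF separates two similar ("featureless")
#' signatures at realistic mutation burdens. For each replicate, `n_samples`
#' samples are simulated with mixture proportions cycled over
#' `mixture_grid` and `muts_per_sample` mutations each; rank-2 NMF is run,
#' recovered signatures are matched to the generators by best cosine, and
#' the mean absolute error between recovered and generating probability
#' entries (over the 2 x 96 values, in percentage points) is recorded. The
#' defaults mirror the scale of an isogenic clone panel: 33 samples (11
#' genotypes x 3 clones), 1,000 mutations per sample, mixtures from 20% to
#' 80%, 10 replicates.
#'
#' @param sig_a,sig_b Generating 96-channel signatures (columns sum to 1,
#'   not identical).
#' @param mixture_grid Proportions of `sig_a` cycled over samples.
#' @param n_samples,muts_per_sample,replicates Simulation scale.
#' @param seed Integer seed.
#' @param n_restarts NMF restarts per replicate (default 20).
#' @return List: `mae` (mean over replicates, percentage points),
#'   `mae_by_replicate`, `cosines` (replicates x 2 matched cosines).
#' @export
separability_experiment <- function(sig_a, sig_b,
                                    mixture_grid = c(0.2, 0.35, 0.5,
                                                     0.65, 0.8),
                                    n_samples = 33,
                                    muts_per_sample = 1000,
                                    replicates = 10,
                                    seed = 1,
                                    n_restarts = 20) {
  sig_a <- as.numeric(sig_a); sig_b <- as.numeric(sig_b)
  if (isTRUE(all.equal(sig_a, sig_b)) ||
        cosine_similarity(sig_a, sig_b) >= 1 - 1e-12)
    stop("generating signatures are identical: mixture not identifiable")
  gen <- cbind(A = sig_a, B = sig_b)
  maes <- numeric(replicates)
  cosines <- matrix(NA_real_, replicates, 2)
  for (r in seq_len(replicates)) {
    mix <- rep_len(mixture_grid, n_samples)
    expo <- cbind(A = mix, B = 1 - mix) * muts_per_sample
    sim <- simulate_catalog(gen, expo, seed = seed + r - 1)
    fit <- nmf_extract(sim$spectra, rank = 2, n_restarts = n_restarts,
                       seed = seed + r - 1)
    m <- match_signatures(fit$signatures, gen)
    cosines[r, ] <- attr(m, "cosines")
    rec <- fit$signatures[, order(m)]      # columns in generator order
    maes[r] <- mean(abs(rec - gen)) * 100
  }
  list(mae = mean(maes), mae_by_replicate = maes, cosines = cosines)
}

# sample one deletion length from a distribution given as a named
# probability vector (names = lengths)
sample_length <- function(length_dist) {
  lens <- as.integer(names(length_dist))
  sample(lens, 1, prob = length_dist)
}

#' Simulate a genome with planted context-classified deletions
#'
#' Builds a random genome and plants non-overlapping deletions whose local
#' sequence context forces a requested classification: `repeat` deletions
#' are embedded in a tandem array of at least two copies of the deleted
#' unit; `microhomology` deletions get a copy of a k-bp prefix of the
#' deleted sequence placed immediately past the 3' breakpoint (and no
#' tandem copy); `none` sites are re-randomized until they carry neither
#' homology nor a tandem copy. The emitted genome is the reference
#' (pre-deletion) sequence; the catalog lists the deletions against it,
#' together with machine-readable truth labels.
#'
#' @param genome_length Genome length in bp.
#' @param class_mix Named fractions `c(repeat=, microhomology=, none=)`,
#'   summing to 1.
#' @param length_dist Named probability vector over deletion lengths
#'   (names are lengths in bp). The default emulates a wild-type clone:
#'   dominated by 1 bp events with a geometric tail.
#' @param n_events Number of deletions to plant.
#' @param seed Integer seed.
#' @param gc GC fraction of the background genome (default 0.5, i.i.d.).
#' @return List: `genome` (`DNAStringSet`, one chromosome `"chr1"`),
#'   `catalog` (anchored DEL records), `truth` (`data.frame` with
#'   `truth_class`, `truth_mh_length`, `truth_copies` per event).
#' @export
simulate_genome_with_indels <- function(genome_length,
                                        class_mix = c("repeat" = 1 / 3,
                                          microhomology = 1 / 3,
                                          none = 1 / 3),
                                        length_dist = stats::setNames(
                                          c(0.6, 0.25, 0.15 *
                                              0.5^(0:5) / sum(0.5^(0:5))),
                                          c(1, 2, 3:8)),
                                        n_events = 50,
                                        seed = 1,
                                        gc = 0.5) {
  stopifnot(abs(sum(class_mix) - 1) < 1e-9)
  max_len <- max(as.integer(names(length_dist)))
  if (n_events > 0 && genome_length < n_events * (15 * max_len + 40))
    stop("genome too short to place ", n_events,
         " events without overlap; increase genome_length")
  set.seed(seed)
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  g <- sample(names(probs), genome_length, replace = TRUE, prob = probs)
  truth <- list(); records <- list()
  if (n_events > 0) {
    classes <- sample(names(class_mix), n_events, replace = TRUE,
                      prob = class_mix)
    # evenly spaced site slots with jitter keep events non-overlapping
    slot <- genome_length / n_events
    for (e in seq_len(n_events)) {
      L <- sample_length(length_dist)
      base <- round((e - 0.5) * slot)
      pos <- base + sample.int(20, 1)    # anchor position
      cls <- classes[e]
      if (cls == "repeat") {
        unit <- sample(BASES, L, replace = TRUE)
        n_copies <- sample(2:3, 1)
        # write the array starting at pos + 1; deleted copy is the first
        span <- L * n_copies
        g[pos + seq_len(span)] <- rep(unit, n_copies)
        # guard: break any accidental extra copy just before/after
        g[pos] <- setdiff(BASES, unit[L])[1]
        if (pos + span + 1 <= genome_length)
          g[pos + span + 1] <- setdiff(BASES, unit[1])[1]
        deleted <- paste(unit, collapse = "")
      } else if (cls == "microhomology") {
        if (L < 2) L <- 2L
        deleted_v <- sample(BASES, L, replace = TRUE)
        mh <- sample.int(L - 1, 1)
        g[pos + seq_len(L)] <- deleted_v
        # plant the homologous prefix right after the 3' breakpoint
        g[pos + L + seq_len(mh)] <- deleted_v[seq_len(mh)]
        # break longer homology and tandem copies
        if (pos + L + mh + 1 <= genome_length)
          g[pos + L + mh + 1] <- setdiff(BASES, deleted_v[mh + 1])[1]
        g[pos] <- setdiff(BASES, deleted_v[L])[1]
        deleted <- paste(deleted_v, collapse = "")
      } else {
        deleted <- paste(g[pos + seq_len(L)], collapse = "")
      }
      rec <- data.frame(sample = "sim", chrom = "chr1", pos = pos,
                        ref = paste0(g[pos], deleted), alt = g[pos],
                        kind = "DEL", stringsAsFactors = FALSE)
      if (cls == "none") {
        # rejection: re-randomize the local context until clean
        repeat {
          left <- paste(g[max(1, pos - 6 * L):pos], collapse = "")
          right <- paste(g[(pos + L + 1):min(genome_length,
                                             pos + L + 6 * L)],
                         collapse = "")
          if (tandem_copies(deleted, left, right) == 1 &&
                max_microhomology(deleted, left, right) == 0) break
          g[pos + seq_len(L)] <- sample(BASES, L, replace = TRUE)
          deleted <- paste(g[pos + seq_len(L)], collapse = "")
        }
        rec$ref <- paste0(g[pos], deleted); rec$alt <- g[pos]
      }
      records[[e]] <- rec
      truth[[e]] <- data.frame(truth_class = cls,
                               truth_mh_length =
                                 if (cls == "microhomology") mh else 0L,
                               truth_length = L,
                               stringsAsFactors = FALSE)
    }
  }
  genome <- Biostrings::DNAStringSet(paste(g, collapse = ""))
  names(genome) <- "chr1"
  list(genome = genome,
       catalog = if (length(records)) do.call(rbind, records) else NULL,
       truth = if (length(truth)) do.call(rbind, truth) else NULL)
}

#' Simulate a structural-variant catalog from rearrangement signatures
#'
#' Channel counts are drawn multinomially from the contribution-weighted
#' signature mixture; each event then gets a size log-uniform within its
#' size bin and coordinates on a synthetic karyotype (10 chromosomes of
#' 100 Mb). Events in clustered channels are laid down in dense runs (at
#' least `kmin` breakpoints within a short range) on a dedicated
#' chromosome, non-clustered events are scattered uniformly.
#'
#' @param rs 32 x k rearrangement signature matrix.
#' @param contributions Nonnegative mixing weights of length k.
#' @param n_events Total number of SVs to draw.
#' @param seed Integer seed.
#' @param kmin Minimum clustered run length (default 10).
#' @return List: `svs` (SV `data.frame` as in [read_sv_calls()]),
#'   `truth_channels` (drawn 32-channel counts), `truth_contributions`.
#' @export
simulate_sv_catalog <- function(rs, contributions, n_events, seed = 1,
                                kmin = 10) {
  rs <- as.matrix(rs)
  stopifnot(nrow(rs) == 32, length(contributions) == ncol(rs))
  if (any(contributions < 0) || sum(contributions) == 0)
    stop("contributions must be nonnegative and not all zero")
  set.seed(seed)
  p <- as.numeric(rs %*% contributions); p <- p / sum(p)
  channels <- rearrangement_channels()
  if (n_events == 0)
    return(list(svs = data.frame(), truth_channels =
                  stats::setNames(numeric(32), channels),
                truth_contributions = contributions))
  counts <- as.numeric(stats::rmultinom(1, n_events, p))
  names(counts) <- channels
  bin_lo <- c("1-10kb" = 1e3, "10-100kb" = 1e4, "100kb-1Mb" = 1e5,
              "1-10Mb" = 1e6, ">10Mb" = 1e7)
  chrom_len <- 1e8
  type_back <- c(del = "deletion", dup = "tandem-duplication",
                 inv = "inversion")
  rows <- list()
  cluster_cursor <- 1e6   # dense run laid along chr1
  for (ch in channels[counts > 0]) {
    parts <- strsplit(ch, ":", fixed = TRUE)[[1]]
    clustered <- parts[1] == "clustered"
    for (j in seq_len(counts[ch])) {
      if (parts[2] == "trans") {
        chroms <- sample(paste0("chr", 1:9), 2, replace = FALSE)
        row <- data.frame(sample = "sim", chrom1 = chroms[1],
                          pos1 = sample.int(chrom_len, 1),
                          chrom2 = chroms[2],
                          pos2 = sample.int(chrom_len, 1),
                          type = "CTX", stringsAsFactors = FALSE)
      } else {
        lo <- bin_lo[[parts[3]]]
        size <- round(10^stats::runif(1, log10(lo), log10(lo * 10) -
                                           1e-9))
        if (clustered) {
          pos1 <- cluster_cursor + sample.int(5e3, 1)
          cluster_cursor <- cluster_cursor + 5e3
          chrom <- "chr1"
        } else {
          pos1 <- sample.int(chrom_len - size - 1, 1)
          chrom <- sample(paste0("chr", 1:9), 1)
        }
        row <- data.frame(sample = "sim", chrom1 = chrom, pos1 = pos1,
                          chrom2 = chrom, pos2 = pos1 + size,
                          type = type_back[[parts[2]]],
                          stringsAsFactors = FALSE)
      }
      row$softclips <- 5L + stats::rpois(1, 10)
      row$truth_channel <- ch
      rows[[length(rows) + 1]] <- row
    }
  }
  svs <- do.call(rbind, rows)
  svs$size <- ifelse(svs$chrom1 == svs$chrom2, abs(svs$pos2 - svs$pos1),
                     NA_integer_)
  rownames(svs) <- NULL
  list(svs = svs, truth_channels = counts,
       truth_contributions = contributions)
}

#' Write a simulated genome to FASTA
#'
#' @param genome `DNAStringSet`.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}
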