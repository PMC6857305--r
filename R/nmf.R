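#' De novo mutational signature extraction by NMF
#'
#' Factorizes a nonnegative samples x channels count matrix `V ~ W H` under
#' Frobenius loss using multiplicative updates (Lee-Seung), with random
#' nonnegative initialization and `n_restarts` restarts; the factorization
#' with the lowest residual sum of squares is kept. Signatures (columns of
#' `W`) are normalized to probability vectors with the scale folded into the
#' exposures, and ordered by total exposure, descending. A fixed `seed`
#' makes the result deterministic.
#'
#' Rank diagnostics follow the consensus-clustering procedure: over the
#' restarts each sample is assigned to its dominant signature, the consensus
#' matrix records co-assignment frequencies, and the cophenetic correlation
#' coefficient measures how tree-like (stable) the consensus is.
#'
#' @param spectra Samples x channels nonnegative matrix (rows are samples).
#' @param rank Number of signatures to extract (>= 1, < number of samples
#'   kept and < channels).
#' @param n_restarts Random restarts (default 50).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param max_iter,tol Update iterations cap and relative-RSS convergence
#'   tolerance per restart.
#' @return Object of class `"hr_nmf"`: `signatures` (channels x rank,
#'   columns sum to 1), `exposures` (samples x rank, counts), `rss`,
#'   `cophenetic`, `spectra` (input after dropping all-zero samples),
#'   `consensus`.
#' @export
nmf_extract <- function(spectra, rank, n_restarts = 50, seed = NULL,
                        max_iter = 2000, tol = 1e-9) {
  spectra <- as.matrix(spectra)
  if (any(spectra < 0)) stop("spectra must be nonnegative")
  zero <- rowSums(spectra) == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s) excluded from NMF")
    spectra <- spectra[!zero, , drop = FALSE]
  }
  if (rank < 1) stop("rank must be >= 1")
  if (rank > nrow(spectra))
    stop("rank exceeds the number of (non-empty) samples")
  if (rank >= ncol(spectra)) stop("rank must be below the channel count")
  if (!is.null(seed)) set.seed(seed)
  V <- t(spectra)                       # channels x samples
  m <- nrow(V); n <- ncol(V)
  eps <- .Machine$double.eps
  best <- NULL
  assign_runs <- matrix(NA_integer_, nrow = n_restarts, ncol = n)
  for (r in seq_len(n_restarts)) {
    W <- matrix(stats::runif(m * rank, 0.1, 1), m, rank)
    H <- matrix(stats::runif(rank * n, 0.1, 1), rank, n)
    rss_prev <- Inf
    for (it in seq_len(max_iter)) {
      H <- H * (crossprod(W, V)) / (crossprod(W, W %*% H) + eps)
      W <- W * (V %*% t(H)) / (W %*% tcrossprod(H) + eps)
      if (it %% 10 == 0) {
        rss <- sum((V - W %*% H)^2)
        if (is.finite(rss_prev) &&
              (rss_prev - rss) <= tol * max(rss_prev, eps)) break
        rss_prev <- rss
      }
    }
    rss <- sum((V - W %*% H)^2)
    # dominant-signature assignment for the consensus matrix, with the
    # scale folded into H so assignments are comparable across restarts
    s <- colSums(W)
    Hs <- H * s
    assign_runs[r, ] <- apply(Hs, 2, which.max)
    if (is.null(best) || rss < best$rss)
      best <- list(W = W, H = H, rss = rss)
  }
  consensus <- matrix(0, n, n)
  for (r in seq_len(n_restarts))
    consensus <- consensus + outer(assign_runs[r, ], assign_runs[r, ], "==")
  consensus <- consensus / n_restarts
  coph <- cophenetic_coefficient(consensus)
  # normalize signatures, fold scale into exposures, order by activity
  W <- best$W; H <- best$H
  s <- colSums(W)
  W <- sweep(W, 2, s, "/")
  H <- H * s
  ord <- order(rowSums(H), decreasing = TRUE)
  W <- W[, ord, drop = FALSE]; H <- H[ord, , drop = FALSE]
  colnames(W) <- rownames(H) <- paste0("S", seq_len(rank))
  rownames(W) <- colnames(spectra)
  colnames(H) <- rownames(spectra)
  out <- list(signatures = W, exposures = t(H), rss = best$rss,
              cophenetic = coph, rank = rank, n_restarts = n_restarts,
              spectra = spectra, consensus = consensus)
  class(out) <- "hr_nmf"
  out
}

# cophenetic correlation of a consensus matrix (average linkage on 1 - C);
# a perfectly consistent consensus has coefficient 1
cophenetic_coefficient <- function(consensus) {
  d <- stats::as.dist(1 - consensus)
  if (length(d) < 2) return(1)
  if (is.na(stats::sd(d)) || stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  cc <- stats::cophenetic(hc)
  if (stats::sd(cc) == 0) return(1)
  stats::cor(d, cc)
}

#' Survey NMF ranks with cophenetic and RSS diagnostics
#'
#' Runs [nmf_extract()] over a range of ranks and reports, per rank, the
#' cophenetic correlation coefficient and the residual sum of squares. The
#' chosen rank is the one with the highest cophenetic coefficient
#' (ties broken toward the smaller rank); RSS is reported alongside, as it
#' decreases in rank by construction and marks diminishing returns.
#'
#' @param spectra Samples x channels matrix.
#' @param ranks Integer vector of ranks to try.
#' @inheritParams nmf_extract
#' @return `data.frame` with columns `rank`, `cophenetic`, `rss`;
#'   attribute `chosen_rank`.
#' @export
nmf_rank_survey <- function(spectra, ranks = 1:5, n_restarts = 50,
                            seed = NULL, max_iter = 2000, tol = 1e-9) {
  rows <- lapply(ranks, function(k) {
    fit <- nmf_extract(spectra, k, n_restarts = n_restarts, seed = seed,
                       max_iter = max_iter, tol = tol)
    data.frame(rank = k, cophenetic = fit$cophenetic, rss = fit$rss)
  })
  out <- do.call(rbind, rows)
  attr(out, "chosen_rank") <- out$rank[which.max(out$cophenetic)]
  out
}

#' Match signature sets by greedy best-cosine assignment
#'
#' NMF column order is arbitrary; this matches each recovered signature to
#' a distinct reference signature, greedily taking the highest remaining
#' cosine pair.
#'
#' @param recovered,reference Channels x k matrices (equal k).
#' @return Integer vector `m` with `reference[, m[j]]` matched to
#'   `recovered[, j]`, plus attribute `cosines`.
#' @export
match_signatures <- function(recovered, reference) {
  k <- ncol(recovered)
  stopifnot(ncol(reference) == k)
  sim <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    sim[i, j] <- cosine_similarity(recovered[, i], reference[, j])
  m <- integer(k); cosines <- numeric(k)
  free_i <- seq_len(k); free_j <- seq_len(k)
  while (length(free_i) > 0) {
    sub <- sim[free_i, free_j, drop = FALSE]
    ij <- arrayInd(which.max(sub), dim(sub))
    i <- free_i[ij[1]]; j <- free_j[ij[2]]
    m[i] <- j; cosines[i] <- sim[i, j]
    free_i <- setdiff(free_i, i); free_j <- setdiff(free_j, j)
  }
  attr(m, "cosines") <- cosines
  m
}

#' @export
print.hr_nmf <- function(x, ...) {
  cat("De novo signature extraction (NMF, multiplicative updates)\n")
  cat(sprintf("  rank %d, %d samples x %d channels, %d restarts\n",
              x$rank, nrow(x$spectra), ncol(x$spectra), x$n_restarts))
  cat(sprintf("  RSS %.4g, cophenetic %.3f\n", x$rss, x$cophenetic))
  tot <- colSums(x$exposures)
  cat("  total exposures:",
      paste(sprintf("%s=%.0f", names(tot), tot), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.hr_nmf <- function(object, ...) {
  frac <- sweep(object$exposures, 1, rowSums(object$exposures), "/")
  out <- list(rank = object$rank, rss = object$rss,
              cophenetic = object$cophenetic,
              exposure_fractions = frac,
              reconstruction_rmsd = vapply(seq_len(nrow(object$spectra)),
                function(i) reconstruction_rmsd(object$spectra[i, ],
                                                object$signatures,
                                                object$exposures[i, ]),
                numeric(1)))
  class(out) <- "summary.hr_nmf"
  out
}

#' @export
print.summary.hr_nmf <- function(x, ...) {
  cat(sprintf("NMF rank %d: RSS %.4g, cophenetic %.3f\n",
              x$rank, x$rss, x$cophenetic))
  cat("Per-sample exposure fractions:\n")
  print(round(x$exposure_fractions, 3))
  invisible(x)
}

#' @export
coef.hr_nmf <- function(object, ...) object$exposures

#' @export
fitted.hr_nmf <- function(object, ...)
  object$exposures %*% t(object$signatures)

#' @export
residuals.hr_nmf <- function(object, ...) object$spectra - fitted(object)

#' Plot extracted signature profiles
#'
#' One barplot panel per signature, channels in the fixed 96-channel order,
#' coloured by substitution class.
#'
#' @param x An `"hr_nmf"` object.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.hr_nmf <- function(x, ...) {
  k <- ncol(x$signatures)
  cls <- sbs_channels()$class
  cols <- c("C>A" = "#03BCEE", "C>G" = "#010101", "C>T" = "#E32926",
            "T>A" = "#CAC9C9", "T>C" = "#A1CE63", "T>G" = "#EBC6C4")
  old <- graphics::par(mfrow = c(k, 1), mar = c(2, 4, 2, 1))
  on.exit(graphics::par(old))
  for (j in seq_len(k))
    graphics::barplot(x$signatures[, j], col = cols[cls], border = NA,
                      names.arg = rep("", 96),
                      main = colnames(x$signatures)[j],
                      ylab = "probability", ...)
  invisible(x)
}
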