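#' Fit a spectrum against reference signatures by non-negative least squares
#'
#' Finds nonnegative signature exposures minimizing the squared error
#' between the observed spectrum and the reference reconstruction, then
#' applies one pruning pass: signatures whose normalized contribution falls
#' below `min_contribution` are zeroed and the remaining set is refit.
#'
#' With column-normalized reference signatures and a count spectrum, the
#' exposures are in mutation-count units; `contributions` are the same
#' rescaled to fractions.
#'
#' @param spectrum Nonnegative channel vector (96, 83 or 32 channels).
#' @param reference Channels x k reference signature matrix with columns
#'   summing to 1.
#' @param min_contribution Minimum normalized contribution retained after
#'   the pruning pass (default 0.06).
#' @return Object of class `"signature_fit"`: `exposures` (named, zeros for
#'   pruned signatures), `contributions` (fractions), `fitted`
#'   (reconstructed spectrum), `rmsd` (root-mean-square deviation between
#'   observed and reconstructed channel fractions), `spectrum`.
#' @export
fit_signatures <- function(spectrum, reference, min_contribution = 0.06) {
  reference <- as.matrix(reference)
  if (ncol(reference) < 1 || nrow(reference) == 0)
    stop("empty reference signature set")
  if (length(spectrum) != nrow(reference))
    stop("spectrum length does not match reference channels")
  if (any(spectrum < 0)) stop("negative spectrum entry")
  if (any(colSums(reference) == 0)) stop("all-zero reference signature")
  if (is.null(colnames(reference)))
    colnames(reference) <- paste0("S", seq_len(ncol(reference)))
  nnls_fit <- function(cols) {
    A <- reference[, cols, drop = FALSE]
    stats::setNames(pracma::lsqnonneg(A, as.numeric(spectrum))$x, cols)
  }
  e <- nnls_fit(colnames(reference))
  if (sum(e) > 0) {
    contrib <- e / sum(e)
    keep <- names(contrib)[contrib >= min_contribution]
    if (length(keep) > 0 && length(keep) < length(e)) {
      e[] <- 0
      e[keep] <- nnls_fit(keep)
    }
  }
  fitted <- as.numeric(reference %*% e)
  out <- list(exposures = e,
              contributions = if (sum(e) > 0) e / sum(e) else e,
              fitted = fitted,
              rmsd = reconstruction_rmsd(spectrum, reference, e),
              spectrum = as.numeric(spectrum))
  class(out) <- "signature_fit"
  out
}

#' Reconstruction error of a signature fit
#'
#' Root-mean-square deviation over channels between the observed and the
#' reconstructed spectrum, both expressed as channel fractions (an all-zero
#' spectrum or reconstruction is compared on raw values).
#'
#' @param spectrum Observed channel vector.
#' @param reference Channels x k signature matrix.
#' @param exposures Exposure vector of length k.
#' @return RMSD (>= 0).
#' @export
reconstruction_rmsd <- function(spectrum, reference, exposures) {
  recon <- as.numeric(as.matrix(reference) %*% exposures)
  frac <- function(x) if (sum(x) > 0) x / sum(x) else x
  a <- frac(as.numeric(spectrum)); b <- frac(recon)
  sqrt(mean((a - b)^2))
}

#' @export
print.signature_fit <- function(x, digits = 3, ...) {
  cat("Signature fit (non-negative least squares)\n")
  pos <- x$contributions[x$contributions > 0]
  cat("  contributions:",
      paste(sprintf("%s=%.*f", names(pos), digits, pos), collapse = ", "),
      "\n")
  cat(sprintf("  reconstruction RMSD: %.*g\n", digits, x$rmsd))
  invisible(x)
}

#' @export
coef.signature_fit <- function(object, ...) object$exposures

#' @export
fitted.signature_fit <- function(object, ...) object$fitted

#' @export
residuals.signature_fit <- function(object, ...)
  object$spectrum - object$fitted

#' Flag samples whose spectra suggest confounding repair defects
#'
#' Samples dominated by mismatch-repair or POLE-exonuclease mutational
#' processes confound HR-deficiency calling. Given per-sample fractional
#' contributions over a COSMIC v2-style signature set, flags `MMR` when the
#' summed fraction of the MMR-associated signatures (default 6, 15, 20, 26)
#' exceeds 0.40, else `POLE` when the POLE-associated signature (default 11)
#' exceeds 0.40, else `none`.
#'
#' @param contributions Named fraction vector for one sample, or a samples x
#'   signatures matrix, names like `"Sig6"`.
#' @param mmr_ids,pole_ids Signature ids for the two rules.
#' @param threshold Triggering fraction (default 0.40, strict).
#' @return `data.frame` with columns `sample`, `flag`, `fraction`
#'   (the triggering fraction: MMR sum if flagged MMR, POLE fraction if
#'   flagged POLE, otherwise the larger of the two).
#' @export
flag_confounded <- function(contributions, mmr_ids = c(6, 15, 20, 26),
                            pole_ids = 11, threshold = 0.40) {
  if (is.null(dim(contributions)))
    contributions <- matrix(contributions, nrow = 1,
                            dimnames = list("sample1",
                                            names(contributions)))
  mmr_cols <- intersect(paste0("Sig", mmr_ids), colnames(contributions))
  pole_cols <- intersect(paste0("Sig", pole_ids), colnames(contributions))
  rows <- lapply(seq_len(nrow(contributions)), function(i) {
    x <- contributions[i, ]
    mmr <- sum(x[mmr_cols]); pole <- sum(x[pole_cols])
    if (mmr > threshold)
      data.frame(sample = rownames(contributions)[i], flag = "MMR",
                 fraction = mmr, stringsAsFactors = FALSE)
    else if (pole > threshold)
      data.frame(sample = rownames(contributions)[i], flag = "POLE",
                 fraction = pole, stringsAsFactors = FALSE)
    else
      data.frame(sample = rownames(contributions)[i], flag = "none",
                 fraction = max(mmr, pole), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
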