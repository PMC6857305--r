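#' Tune post-filter score thresholds against control samples
#'
#' Single-cell-derived ancestral clones act as internal negative controls:
#' any call unique to an ancestral clone is treated as a false positive.
#' Given scored candidate calls, this finds the smallest uniform score
#' thresholds (one for SNVs, one for indels) such that after filtering every
#' control sample retains at most `max_snv` SNVs and `max_indel` indels.
#' Filtering keeps calls with score strictly greater than the threshold;
#' a threshold of 0 keeps everything with positive score.
#'
#' @param candidates `data.frame` with columns `sample`, `type` (`"snv"` or
#'   `"indel"`) and `score` (higher = more confident, scores > 0).
#' @param control_ids Character vector of control sample ids.
#' @param max_snv,max_indel Maximum calls a control may retain (defaults 5
#'   and 1).
#' @return Named list `snv` / `indel` of thresholds; `Inf` with a warning
#'   when score ties make the limit unattainable.
#' @export
tune_control_threshold <- function(candidates, control_ids,
                                   max_snv = 5, max_indel = 1) {
  one <- function(type, cap) {
    thr <- 0
    for (ctl in control_ids) {
      sc <- sort(candidates$score[candidates$sample == ctl &
                                    candidates$type == type])
      n <- length(sc)
      if (n <= cap) next
      # must remove the n - cap lowest-scoring calls: strict threshold at
      # the (n - cap)-th smallest score
      thr <- max(thr, sc[n - cap])
    }
    # verify (ties at the threshold may still leave a control over the cap)
    for (ctl in control_ids) {
      sc <- candidates$score[candidates$sample == ctl &
                               candidates$type == type]
      if (sum(sc > thr) > cap) {
        warning("control limit unattainable for type '", type,
                "' due to score ties; returning Inf")
        return(Inf)
      }
    }
    thr
  }
  list(snv = one("snv", max_snv), indel = one("indel", max_indel))
}

#' Apply tuned thresholds to scored candidate calls
#'
#' @param candidates As in [tune_control_threshold()].
#' @param thresholds List with elements `snv` and `indel`.
#' @return The subset of `candidates` with score strictly above the
#'   threshold for its type.
#' @export
apply_thresholds <- function(candidates, thresholds) {
  keep <- ifelse(candidates$type == "snv",
                 candidates$score > thresholds$snv,
                 candidates$score > thresholds$indel)
  candidates[keep, , drop = FALSE]
}

#' Tally mutation counts per sample from a catalog
#'
#' @param catalog Catalog `data.frame` (see [load_catalog()]).
#' @return `data.frame` with columns `sample`, `snv`, `ins`, `del`.
#' @export
count_mutations <- function(catalog) {
  samples <- unique(catalog$sample)
  out <- data.frame(sample = samples,
                    snv = 0L, ins = 0L, del = 0L, stringsAsFactors = FALSE)
  for (k in c("SNV", "INS", "DEL")) {
    tab <- table(catalog$sample[catalog$kind == k])
    col <- tolower(k)
    out[[col]] <- as.integer(tab[samples])
    out[[col]][is.na(out[[col]])] <- 0L
  }
  out
}

#' Per-genotype mutation-rate summary with chi-square tests against wild type
#'
#' Computes, for each genotype, the mean and SEM of per-clone mutation
#' counts, the fold change of the tested measure relative to the wild-type
#' group, and a chi-square p-value comparing the summed counts of the
#' genotype's clones against the summed wild-type counts (expected
#' proportions given by clone numbers; every genome is assumed to present
#' equal mutational opportunity), Bonferroni-multiplied by `n_comparisons`
#' and capped at 1.
#'
#' @param counts `data.frame` with columns `sample`, `genotype`, `snv`,
#'   `ins`, `del` (see [count_mutations()]).
#' @param wt_label Genotype label of the wild-type group.
#' @param n_comparisons Number of comparisons for the Bonferroni correction
#'   (default: number of non-wild-type genotypes).
#' @param measure Which count the fold change and test apply to
#'   (`"snv"`, `"ins"` or `"del"`).
#' @return `data.frame` of class `"genotype_summary"`, one row per genotype:
#'   `genotype`, `n_clones`, `mean_snv`, `sem_snv`, `mean_ins`, `mean_del`,
#'   `fold_vs_wt`, `p_adjusted` (NA for the wild type row).
#' @export
summarize_rates <- function(counts, wt_label = "WT", n_comparisons = NULL,
                            measure = c("snv", "ins", "del")) {
  measure <- match.arg(measure)
  if (!wt_label %in% counts$genotype)
    stop("wild-type group '", wt_label, "' not present")
  genotypes <- unique(counts$genotype)
  if (is.null(n_comparisons)) n_comparisons <- sum(genotypes != wt_label)
  wt <- counts[counts$genotype == wt_label, ]
  wt_mean <- mean(wt[[measure]])
  if (wt_mean == 0)
    warning("wild-type mean is zero; fold changes undefined (NaN)")
  sem <- function(x) if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0
  rows <- lapply(genotypes, function(g) {
    gg <- counts[counts$genotype == g, ]
    fold <- if (wt_mean == 0) NaN else mean(gg[[measure]]) / wt_mean
    p_adj <- NA_real_
    if (g != wt_label) {
      obs <- c(sum(gg[[measure]]), sum(wt[[measure]]))
      expp <- c(nrow(gg), nrow(wt)) / (nrow(gg) + nrow(wt))
      p <- if (sum(obs) == 0) 1 else
        suppressWarnings(stats::chisq.test(obs, p = expp)$p.value)
      p_adj <- min(1, p * n_comparisons)
    }
    data.frame(genotype = g, n_clones = nrow(gg),
               mean_snv = mean(gg$snv), sem_snv = sem(gg$snv),
               mean_ins = mean(gg$ins), mean_del = mean(gg$del),
               fold_vs_wt = fold, p_adjusted = p_adj,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("genotype_summary", "data.frame")
  attr(out, "measure") <- measure
  out
}

#' @export
print.genotype_summary <- function(x, digits = 3, ...) {
  cat("Per-genotype mutation rates (measure: ", attr(x, "measure"),
      ")\n\n", sep = "")
  print.data.frame(x, digits = digits, row.names = FALSE)
  invisible(x)
}
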