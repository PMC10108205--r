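#' Allele-frequency variance of a locus
#'
#' Statistically uninformative trajectories -- those whose observed
#' frequency barely moves over the whole experiment -- inflate both the
#' estimated selection coefficient and the Bayes factor, so they are
#' screened out before inference. The default statistic is the
#' population variance (denominator n) of the observed frequencies
#' `c/C`, pooled over all replicates and time points with non-zero
#' depth. `mode = "increments"` instead pools the per-replicate
#' step-to-step frequency differences and takes their population
#' variance; it is offered as the alternative reading of
#' "frequency increments".
#'
#' @param counts A [locus_counts()] object.
#' @param mode `"frequencies"` (default) or `"increments"`.
#' @return The variance, or `NA_real_` when fewer than two covered
#'   samples (or, for `"increments"`, no consecutive covered pair)
#'   are available.
#' @export
frequency_variance <- function(counts, mode = c("frequencies", "increments")) {
  mode <- match.arg(mode)
  covered <- counts$coverage > 0
  pvar <- function(x) mean((x - mean(x))^2)
  if (mode == "frequencies") {
    p <- (counts$focal / counts$coverage)[covered]
    if (length(p) < 2L) return(NA_real_)
    pvar(p)
  } else {
    incs <- unlist(lapply(seq_len(nrow(counts$focal)), function(r) {
      ok <- which(covered[r, ])
      if (length(ok) < 2L) return(numeric(0))
      diff(counts$focal[r, ok] / counts$coverage[r, ok])
    }))
    if (length(incs) < 1L) return(NA_real_)
    pvar(incs)
  }
}

#' Variance pre-filter verdict for a locus
#'
#' A locus passes when its frequency variance is at least `threshold`
#' (default 0.01; variance strictly lower than the threshold fails).
#' Loci with undefined variance (fewer than two covered samples) fail.
#'
#' @inheritParams frequency_variance
#' @param threshold Keep threshold on the variance; default 0.01.
#' @return An object of class `filter_verdict`: list with `variance`
#'   and logical `passed`.
#' @export
apply_filter <- function(counts, threshold = 0.01,
                         mode = c("frequencies", "increments")) {
  v <- frequency_variance(counts, mode)
  structure(list(variance = v, passed = !is.na(v) && v >= threshold),
            class = "filter_verdict")
}
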