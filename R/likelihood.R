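#' Cache of Moran models across loci
#'
#' Inference revisits the same (N, sigma) pairs for every locus; the
#' spectral decomposition of each model is the expensive part (an
#' eigendecomposition of the interior block), so models are memoised in
#' an environment keyed by `(N, sigma)`. Pass one cache through a whole
#' run; at N = 1000 each cached model holds roughly 8 MB.
#'
#' @return An environment to pass as `cache` to the likelihood and
#'   inference functions.
#' @export
model_cache <- function() new.env(parent = emptyenv())

cached_model <- function(N, sigma, cache = NULL) {
  if (is.null(cache)) return(moran_model(N, sigma))
  key <- sprintf("%d@%.17g", as.integer(N), sigma)
  m <- cache[[key]]
  if (is.null(m)) {
    m <- moran_model(N, sigma)
    cache[[key]] <- m
  }
  m
}

# Forward (HMM) log marginal likelihood for all replicates at once.
# counts: locus_counts; model: moran_model. Returns vector of per-replicate
# log-likelihoods. Distributions are renormalised after every emission and
# the log scale factors accumulated (log-sum-exp style rescaling).
forward_loglik <- function(counts, model, emission = emission_model(),
                           method = c("forward", "plugin")) {
  method <- match.arg(method)
  N <- model$N
  R <- nrow(counts$focal)
  Tn <- length(counts$generations)
  emis <- function(t) {
    # rows: replicates; cols: states
    t(vapply(seq_len(R),
             function(r) emission_logprob(counts$focal[r, t], counts$coverage[r, t],
                                          N, emission),
             numeric(N + 1L)))
  }
  ll <- numeric(R)
  if (method == "forward") {
    F0 <- exp(emis(1L))
    Fm <- F0 / (N + 1)           # uniform state prior at t0
    s <- rowSums(Fm)
    ll <- log(s)
    Fm <- Fm / s
  } else {
    # plug-in smoothing: each time point's state posterior replaces the
    # emission; the t0 term carries no marginal-likelihood contribution
    Fm <- t(vapply(seq_len(R),
                   function(r) as.numeric(state_posterior(counts$focal[r, 1L],
                                                          counts$coverage[r, 1L],
                                                          N, emission)),
                   numeric(N + 1L)))
  }
  if (Tn >= 2L) {
    for (t in 2:Tn) {
      dt <- counts$generations[t] - counts$generations[t - 1L]
      Fm <- propagate_state(model, Fm, dt)
      E <- if (method == "forward") exp(emis(t)) else
        t(vapply(seq_len(R),
                 function(r) as.numeric(state_posterior(counts$focal[r, t],
                                                        counts$coverage[r, t],
                                                        N, emission)),
                 numeric(N + 1L)))
      Fm <- Fm * E
      s <- rowSums(Fm)
      if (any(s <= 0)) return(ll + ifelse(s > 0, 0, -Inf))
      ll <- ll + log(s)
      Fm <- Fm / s
    }
  }
  ll
}

#' Log-likelihood of one replicate's allele-frequency trajectory
#'
#' Marginal log-probability of the observed counts of a single
#' replicate under the Moran model, integrating over the hidden allele
#' copy-number path by a forward recursion: the initial distribution is
#' the pool-seq state posterior at the first time point (uniform state
#' prior times the emission kernel), and each subsequent step propagates
#' by the transition kernel over the elapsed generations and multiplies
#' by the emission probability of the observed count.
#'
#' `method = "plugin"` replaces the joint marginalisation with
#' independently smoothed per-time-point state posteriors ("virtual
#' trajectories"); it is provided for comparison and is not the
#' default.
#'
#' @param counts A [locus_counts()] object.
#' @param r Replicate index.
#' @param model A [moran_model()].
#' @param emission An [emission_model()].
#' @param method `"forward"` (exact HMM marginal, default) or
#'   `"plugin"`.
#' @return Log-likelihood (real scalar).
#' @export
replicate_loglik <- function(counts, r, model, emission = emission_model(),
                             method = c("forward", "plugin")) {
  sub <- counts
  sub$focal <- counts$focal[r, , drop = FALSE]
  sub$coverage <- counts$coverage[r, , drop = FALSE]
  forward_loglik(sub, model, emission, method)[1L]
}

#' Log-likelihood of a locus across independent replicates
#'
#' Replicate populations are assumed independent given the selection
#' coefficient, so the locus log-likelihood is the sum of the
#' per-replicate forward log-likelihoods.
#'
#' @inheritParams replicate_loglik
#' @param sigma Selection coefficient (> -1).
#' @param N Population size used for inference (user-supplied effective
#'   population size).
#' @param cache Optional [model_cache()] shared across loci.
#' @return Log-likelihood (real scalar).
#' @export
locus_loglik <- function(counts, sigma, N, emission = emission_model(),
                         method = c("forward", "plugin"), cache = NULL) {
  model <- cached_model(N, sigma, cache)
  sum(forward_loglik(counts, model, emission, method))
}
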