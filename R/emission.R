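#' Pool-seq emission model
#'
#' Describes how observed allele counts arise from the latent population
#' state. With a pool of effectively infinite size relative to depth,
#' reads are binomial draws at the population frequency \eqn{n/N};
#' overdispersed libraries can be modelled with a beta-binomial kernel
#' of the same mean and overdispersion `rho`.
#'
#' The beta-binomial uses shape parameters
#' \eqn{a = p(1-\rho)/\rho}, \eqn{b = (1-p)(1-\rho)/\rho} so that
#' `rho = 0` recovers the binomial exactly; boundary states
#' (\eqn{p \in \{0, 1\}}) fall back to the degenerate binomial kernel.
#'
#' @param kind `"binomial"` or `"beta-binomial"`.
#' @param rho Overdispersion in `[0, 1)`; only used by the
#'   beta-binomial kernel.
#' @return An object of class `emission_model`.
#' @export
emission_model <- function(kind = c("binomial", "beta-binomial"), rho = 0) {
  kind <- match.arg(kind)
  if (length(rho) != 1L || !is.finite(rho) || rho < 0 || rho >= 1)
    stop("'rho' must lie in [0, 1)")
  if (kind == "binomial" && rho != 0)
    stop("'rho' must be 0 for the binomial kernel")
  if (rho == 0) kind <- "binomial"
  structure(list(kind = kind, rho = rho), class = "emission_model")
}

# log p(c | C, state n) for all states n = 0..N; includes choose(C, c)
emission_logprob <- function(c, C, N, emission = emission_model()) {
  if (c < 0 || C < 0 || c > C) stop("need 0 <= c <= C")
  p <- (0:N) / N
  if (C == 0) return(rep(0, N + 1L))
  if (emission$kind == "binomial") {
    stats::dbinom(c, C, p, log = TRUE)
  } else {
    rho <- emission$rho
    a <- p * (1 - rho) / rho
    b <- (1 - p) * (1 - rho) / rho
    out <- lchoose(C, c) + lbeta(c + a, C - c + b) - lbeta(a, b)
    # boundary states: degenerate kernel (allele absent or fixed)
    out[1L] <- stats::dbinom(c, C, 0, log = TRUE)
    out[N + 1L] <- stats::dbinom(c, C, 1, log = TRUE)
    out
  }
}

#' Posterior over Moran states given one pooled observation
#'
#' The probability of each allele copy-number state \eqn{n} given an
#' observed focal-allele count `c` at depth `C`, assuming a uniform
#' prior over the \eqn{N+1} states and a binomial (or beta-binomial)
#' read-sampling kernel at frequency \eqn{n/N}. This is the "virtual
#' trajectory" correction for pool-seq sampling noise: it spreads an
#' observed frequency over nearby states rather than taking `c/C` at
#' face value, which matters most at low depth and extreme frequencies.
#'
#' @param c Observed focal-allele read count.
#' @param C Total depth (focal + reference reads). `C = 0` yields the
#'   uniform distribution (no information).
#' @param N Population size of the Moran chain.
#' @param emission An [emission_model()].
#' @return A normalised numeric vector of length \eqn{N+1} (class
#'   `state_distribution`).
#' @examples
#' state_posterior(1, 2, 2)  # polymorphic read pair: mass (0, 1, 0)
#' @export
state_posterior <- function(c, C, N, emission = emission_model()) {
  lk <- emission_logprob(c, C, N, emission)
  w <- exp(lk - max(lk))
  structure(w / sum(w), class = "state_distribution")
}
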