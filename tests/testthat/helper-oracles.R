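# Independent numerical oracles and small fixture builders shared by the
# test files. These deliberately avoid the package's spectral code path.

# Truncated power series e^{Q dt} = sum_k (Q dt)^k / k!
expm_series <- function(Q, dt, kmax = 400L) {
  n <- nrow(Q)
  term <- diag(n)
  acc <- diag(n)
  A <- Q * dt
  for (k in seq_len(kmax)) {
    term <- term %*% A / k
    acc <- acc + term
    if (max(abs(term)) < 1e-18) break
  }
  acc
}

# Brute-force hidden-path enumeration of the forward marginal likelihood:
# uniform state prior times emission at t0, series-oracle transitions,
# emission at every later time point. Only feasible for tiny N and T.
brute_force_loglik <- function(counts, sigma, N, emission = emission_model()) {
  total <- 0
  Tn <- length(counts$generations)
  for (r in seq_len(nrow(counts$focal))) {
    emit <- lapply(seq_len(Tn), function(t)
      exp(emission_logprob(counts$focal[r, t], counts$coverage[r, t], N, emission)))
    Ps <- lapply(seq_len(Tn - 1L), function(t) {
      m <- moran_model(N, sigma)
      expm_series(m$Q, counts$generations[t + 1L] - counts$generations[t])
    })
    states <- expand.grid(rep(list(0:N), Tn))
    lik <- 0
    for (i in seq_len(nrow(states))) {
      path <- as.integer(states[i, ])
      p <- emit[[1L]][path[1L] + 1L] / (N + 1)
      if (Tn >= 2L) for (t in 2:Tn)
        p <- p * Ps[[t - 1L]][path[t - 1L] + 1L, path[t] + 1L] *
          emit[[t]][path[t] + 1L]
      lik <- lik + p
    }
    total <- total + log(lik)
  }
  total
}

# quick locus_counts builder from frequency matrices at fixed depth
make_counts <- function(freqs, coverage = 60, generations = NULL,
                        chrom = "t", pos = 1L) {
  freqs <- as.matrix(freqs)
  if (is.null(generations)) generations <- seq(0, by = 10, length.out = ncol(freqs))
  C <- matrix(coverage, nrow(freqs), ncol(freqs))
  locus_counts(chrom, pos, round(freqs * C), C, generations)
}

# fixation probability from the generator: solve the absorption system
# Q_int h = -q_fix for interior states (independent linear-algebra route)
fixation_from_Q <- function(N, sigma) {
  m <- moran_model(N, sigma)
  Q <- m$Q
  int <- 2:N
  A <- Q[int, int]
  b <- -Q[int, N + 1L]
  h <- solve(A, b)
  c(0, h, 1)
}
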