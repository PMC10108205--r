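#' Named time-sampling schemes
#'
#' Standard sampling schedules for simulated experiments, expressed in
#' generations relative to the effective population size: TS1 two
#' points spanning 0.2 Ne; TS2 five uniform points over 0.2 Ne (the
#' base experiment); TS3 five points weighted towards the start; TS4
#' towards the end; TS5 five uniform points over 0.4 Ne; TS6 eleven
#' uniform points over 0.2 Ne.
#'
#' @param name One of `"TS1"` .. `"TS6"`.
#' @return Numeric vector of sampling times relative to Ne.
#' @export
time_scheme <- function(name) {
  schemes <- list(
    TS1 = c(0, 0.2),
    TS2 = c(0, 0.05, 0.10, 0.15, 0.20),
    TS3 = c(0, 0.04, 0.08, 0.12, 0.20),
    TS4 = c(0, 0.08, 0.12, 0.16, 0.20),
    TS5 = c(0, 0.1, 0.2, 0.3, 0.4),
    TS6 = seq(0, 0.2, by = 0.02)
  )
  if (!name %in% names(schemes))
    stop(sprintf("unknown time scheme '%s'; available: %s",
                 name, paste(names(schemes), collapse = ", ")))
  schemes[[name]]
}

#' Simulation scenario
#'
#' Bundles the population and experimental parameters of a simulated
#' E&R design. Defaults are the base experiment: Ne = 300, five
#' replicates, five uniform time points spanning 0.2 Ne generations,
#' 60x coverage.
#'
#' @param Ne Effective population size.
#' @param p0 Initial focal-allele frequency in (0, 1); the initial copy
#'   number is `round(p0 * Ne)`.
#' @param sigma Selection coefficient (> -1). Scaled selection
#'   `Ne * sigma` of 0, 1 and 10 correspond to neutral, drift-dominated
#'   and selection-dominated regimes.
#' @param time_scheme Name of a [time_scheme()] preset, or a numeric
#'   vector of times relative to Ne (starting at 0, increasing).
#' @param replicates Number of replicate populations.
#' @param coverage Sequencing depth per sample (fixed by default).
#' @param emission An [emission_model()] used for pool-seq sampling.
#' @param poisson_coverage If `TRUE`, depths are Poisson with mean
#'   `coverage` instead of fixed.
#' @param seed Integer seed making panel generation fully reproducible.
#' @return An object of class `sim_scenario` with the resolved
#'   `generations` vector.
#' @export
sim_scenario <- function(Ne = 300, p0 = 0.5, sigma = 0, time_scheme = "TS2",
                         replicates = 5, coverage = 60,
                         emission = emission_model(),
                         poisson_coverage = FALSE, seed = 1L) {
  if (p0 <= 0 || p0 >= 1) stop("'p0' must lie strictly in (0, 1)")
  if (sigma <= -1) stop("'sigma' must exceed -1")
  rel <- if (is.character(time_scheme)) time_scheme(time_scheme) else as.numeric(time_scheme)
  if (rel[1] != 0 || any(diff(rel) <= 0))
    stop("time scheme must start at 0 and be strictly increasing")
  structure(list(Ne = as.integer(Ne), p0 = p0, sigma = sigma,
                 generations = rel * Ne, replicates = as.integer(replicates),
                 coverage = as.integer(coverage), emission = emission,
                 poisson_coverage = poisson_coverage, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Exact Moran trajectory simulation
#'
#' Event-driven (Gillespie) simulation of the continuous-time Moran
#' chain with per-generation clock (one generation = Ne Moran events):
#' from state n, the next jump occurs after an exponential waiting time
#' with total rate \eqn{Ne (n/Ne)((Ne-n)/Ne)(2+\sigma)} and goes up
#' with probability \eqn{(1+\sigma)/(2+\sigma)}. The state is recorded
#' at the exact requested generations; absorbed trajectories stay
#' absorbed.
#'
#' @param Ne Population size.
#' @param sigma Selection coefficient.
#' @param n0 Initial copy number in 0..Ne.
#' @param generations Recording times in generations (increasing, first
#'   typically 0).
#' @return Integer vector of states at `generations`.
#' @export
simulate_trajectory <- function(Ne, sigma, n0, generations) {
  if (n0 < 0 || n0 > Ne) stop("'n0' must lie in 0..Ne")
  Tn <- length(generations)
  out <- integer(Tn)
  n <- as.integer(n0)
  t <- 0
  up_prob <- (1 + sigma) / (2 + sigma)
  k <- 1L
  chunk <- 256L
  ze <- stats::rexp(chunk); zu <- stats::runif(chunk); zi <- 1L
  while (k <= Tn) {
    if (n == 0L || n == Ne) {          # absorbed: fill remaining records
      out[k:Tn] <- n
      break
    }
    rate <- Ne * (n / Ne) * ((Ne - n) / Ne) * (2 + sigma)
    if (zi > chunk) { ze <- stats::rexp(chunk); zu <- stats::runif(chunk); zi <- 1L }
    tnext <- t + ze[zi] / rate
    while (k <= Tn && generations[k] <= tnext) {  # record states passed over
      out[k] <- n
      k <- k + 1L
    }
    n <- if (zu[zi] < up_prob) n + 1L else n - 1L
    zi <- zi + 1L
    t <- tnext
  }
  out
}

#' Monte-Carlo fixation fractions of the Moran chain
#'
#' Runs many independent chains from copy number `n0` until absorption
#' and returns the fraction fixed at Ne. Only the embedded jump chain
#' is simulated: each jump is up with probability
#' \eqn{(1+\sigma)/(2+\sigma)} regardless of the current state, and the
#' exponential holding times do not affect which boundary is hit, so
#' the fixation law is identical to the full event-driven chain. Runs
#' are vectorised across walkers.
#'
#' The closed-form comparison is the birth-death absorption formula
#' \eqn{(1-\gamma^{n_0})/(1-\gamma^{Ne})} with
#' \eqn{\gamma = 1/(1+\sigma)}, reducing to \eqn{n_0/Ne} under
#' neutrality.
#'
#' @inheritParams simulate_trajectory
#' @param n_runs Number of independent chains.
#' @return Fraction of runs absorbed at Ne.
#' @export
estimate_fixation <- function(Ne, sigma, n0, n_runs = 10000L) {
  if (n0 <= 0) return(0)
  if (n0 >= Ne) return(1)
  n <- rep(as.integer(n0), n_runs)
  up_prob <- (1 + sigma) / (2 + sigma)
  active <- seq_len(n_runs)
  fixed <- 0L
  while (length(active) > 0L) {
    step <- ifelse(stats::runif(length(active)) < up_prob, 1L, -1L)
    n[active] <- n[active] + step
    hit_top <- n[active] == Ne
    fixed <- fixed + sum(hit_top)
    active <- active[!(hit_top | n[active] == 0L)]
  }
  fixed / n_runs
}

#' Pool-seq sampling of a latent trajectory
#'
#' Draws observed counts from recorded states: depth is the scenario
#' coverage (or Poisson around it), and the focal count is binomial (or
#' beta-binomial) at the population frequency `n/Ne`.
#'
#' @param states Integer matrix replicates x time points of latent copy
#'   numbers.
#' @param scn A [sim_scenario()].
#' @return A [locus_counts()] object (chrom/pos unset).
#' @export
sample_pool_seq <- function(states, scn) {
  states <- as.matrix(states)
  R <- nrow(states); Tn <- ncol(states)
  C <- if (scn$poisson_coverage)
    matrix(stats::rpois(R * Tn, scn$coverage), R, Tn)
  else matrix(scn$coverage, R, Tn)
  p <- states / scn$Ne
  if (scn$emission$kind == "binomial") {
    cts <- matrix(stats::rbinom(R * Tn, as.vector(C), as.vector(p)), R, Tn)
  } else {
    rho <- scn$emission$rho
    q <- as.vector(p)
    interior <- q > 0 & q < 1
    pp <- q
    pp[interior] <- stats::rbeta(sum(interior),
                                 q[interior] * (1 - rho) / rho,
                                 (1 - q[interior]) * (1 - rho) / rho)
    cts <- matrix(stats::rbinom(R * Tn, as.vector(C), pp), R, Tn)
  }
  locus_counts("sim", 1L, cts, C, scn$generations,
               focal_allele = "T", ref = "A")
}

simulate_locus <- function(scn) {
  n0 <- as.integer(round(scn$p0 * scn$Ne))
  states <- t(vapply(seq_len(scn$replicates),
                     function(r) simulate_trajectory(scn$Ne, scn$sigma, n0,
                                                     scn$generations),
                     integer(length(scn$generations))))
  counts <- sample_pool_seq(states, scn)
  list(counts = counts, states = states, n0 = n0)
}

locus_to_sync_record <- function(counts, layout, chrom = "sim", pos = 1L) {
  ns <- layout$replicates * layout$time_points
  m <- matrix(0L, ns, 6L, dimnames = list(NULL, SEXTET))
  fc <- counts$focal[cbind(layout$replicate, layout$time)]
  cv <- counts$coverage[cbind(layout$replicate, layout$time)]
  m[, "T"] <- fc          # focal allele written as T
  m[, "A"] <- cv - fc     # reference as A
  structure(list(chrom = chrom, pos = as.integer(pos), ref = "A", counts = m),
            class = "sync_record")
}

#' Simulate a panel of independent loci as a sync file
#'
#' Generates `n_loci` independent trajectories under one scenario,
#' pool-seq samples them, and writes a sync file (focal allele written
#' as T against an A reference, time-major sample columns) plus a
#' tab-separated truth table with the initial frequency, true selection
#' coefficient, and per-locus counts of fixed and lost replicates at
#' the final time point. Fully determined by `scn$seed`.
#'
#' @param scn A [sim_scenario()].
#' @param n_loci Number of loci.
#' @param sync_path,truth_path Optional output paths; omit to only
#'   return the in-memory panel.
#' @param chrom Chromosome label written to the files.
#' @return Invisibly, a list with `counts` (list of [locus_counts()]),
#'   `truth` (data frame) and `layout`.
#' @export
generate_panel <- function(scn, n_loci, sync_path = NULL, truth_path = NULL,
                           chrom = "sim") {
  set.seed(scn$seed)
  layout <- sync_layout(scn$replicates, length(scn$generations))
  counts <- vector("list", n_loci)
  truth <- data.frame(chrom = rep(chrom, n_loci), pos = seq_len(n_loci),
                      p0 = scn$p0, sigma = scn$sigma,
                      scaled_sigma = scn$Ne * scn$sigma,
                      fixed_reps = 0L, lost_reps = 0L)
  recs <- vector("list", n_loci)
  for (i in seq_len(n_loci)) {
    sim <- simulate_locus(scn)
    sim$counts$chrom <- chrom
    sim$counts$pos <- i
    counts[[i]] <- sim$counts
    final <- sim$states[, ncol(sim$states)]
    truth$fixed_reps[i] <- sum(final == scn$Ne)
    truth$lost_reps[i] <- sum(final == 0L)
    recs[[i]] <- locus_to_sync_record(sim$counts, layout, chrom, i)
  }
  if (!is.null(sync_path)) write_sync(recs, sync_path)
  if (!is.null(truth_path))
    utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(list(counts = counts, truth = truth, layout = layout,
                 records = recs))
}

#' Mixed base-experiment panel
#'
#' A panel of base-experiment loci cycling deterministically through
#' the crossed scaled-selection and starting-frequency settings
#' (default `Ne * sigma` in \{0, 1, 10\} by `p0` in \{0.05, 0.5\}),
#' as used for the population-size misspecification experiment.
#'
#' @param n_loci Total number of loci.
#' @param Ne,replicates,coverage,time_scheme Base-experiment settings.
#' @param scaled_sigma,p0 Values to cross and cycle through.
#' @param seed Integer seed.
#' @return A list as from [generate_panel()], with `truth` recording
#'   each locus' settings.
#' @export
generate_mixed_panel <- function(n_loci = 100L, Ne = 300,
                                 scaled_sigma = c(0, 1, 10),
                                 p0 = c(0.05, 0.5), replicates = 5,
                                 coverage = 60, time_scheme = "TS2",
                                 seed = 1L) {
  combos <- expand.grid(scaled_sigma = scaled_sigma, p0 = p0)
  idx <- rep_len(seq_len(nrow(combos)), n_loci)
  counts <- vector("list", n_loci)
  recs <- vector("list", n_loci)
  truth <- NULL
  for (j in seq_len(nrow(combos))) {
    loci <- which(idx == j)
    if (length(loci) == 0L) next
    scn <- sim_scenario(Ne = Ne, p0 = combos$p0[j],
                        sigma = combos$scaled_sigma[j] / Ne,
                        time_scheme = time_scheme, replicates = replicates,
                        coverage = coverage,
                        seed = seed + j)   # independent stream per setting
    panel <- generate_panel(scn, length(loci))
    for (k in seq_along(loci)) {
      i <- loci[k]
      panel$counts[[k]]$pos <- i
      panel$records[[k]]$pos <- i
      counts[[i]] <- panel$counts[[k]]
      recs[[i]] <- panel$records[[k]]
    }
    tt <- panel$truth
    tt$pos <- loci
    truth <- rbind(truth, tt)
  }
  truth <- truth[order(truth$pos), ]
  rownames(truth) <- NULL
  rel <- if (is.character(time_scheme)) time_scheme(time_scheme) else time_scheme
  layout <- sync_layout(replicates, length(rel))
  invisible(list(counts = counts, truth = truth, layout = layout,
                 records = recs))
}
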