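---
title: "Inferring selection from E&R time series with moranER"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring selection from E&R time series with moranER}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Evolve-and-Resequence (E&R) experiments keep replicate populations under a
controlled selective pressure and sequence pooled samples of each replicate
at several time points. The data for one biallelic locus are focal-allele
read counts $c_{rt}$ out of depths $C_{rt}$ for replicates $r = 1..R$ and
time points $t = 1..T$ at known generations $g_t$. The question for every
locus in the genome is whether its frequency trajectory is better explained
by drift alone or by directional selection, and if the latter, how strong
selection is.

Two features make this statistically awkward: experimental populations are
small, so drift is strong and easily mistaken for selection; and pool-seq
read counts are noisy estimates of the population frequency, especially at
low depth and extreme frequencies. `moranER` addresses both with a fully
probabilistic model and summarises each locus by a posterior mean selection
coefficient and a log Bayes factor.

## Model

**Latent dynamics.** Allele copy number $n \in \{0, \dots, N\}$ evolves as a
continuous-time Moran birth-death chain: at event scale, transitions
$n \to n-1$ occur at rate $\frac{n}{N}\frac{N-n}{N}$ and $n \to n+1$ at rate
$\frac{n}{N}\frac{N-n}{N}(1+\sigma)$, where $1+\sigma$ is the relative
fitness of focal-allele offspring. Overlapping generations (as in insect
cage experiments) are a natural fit for a Moran rather than a Wright-Fisher
chain. One generation equals $N$ Moran events, so the per-generation
generator is $Q = N \cdot Q_{\text{event}}$; `N` is the user-supplied
effective population size. The boundaries $0$ and $N$ are absorbing (no
mutation). Transition kernels over $d_t$ generations are
$P(d_t) = e^{Q d_t}$.

**Observation model.** Given state $n$, a sample of depth $C$ yields a
binomial count $c \sim \mathrm{Bin}(C, n/N)$, or a beta-binomial with the
same mean and overdispersion $\rho \in [0, 1)$ for noisier libraries
($\rho = 0$ recovers the binomial; boundary states use the degenerate
kernel). Conversely, one observation induces a posterior over states
(`state_posterior()`), the "virtual trajectory" correction for pool-seq
noise.

**Likelihood.** The default likelihood is the exact hidden-Markov marginal
of this generative model: a forward recursion starts from a uniform state
prior times the emission at $t_1$, then alternates propagation by
$P(g_t - g_{t-1})$ and multiplication by the emission at $t$, with
per-step rescaling in log space. Replicates are independent given
$\sigma$, so the locus log-likelihood sums over replicates. A simpler
plug-in route (independently smoothed per-time-point state posteriors in
place of emissions) is available via `method = "plugin"` for comparison;
the joint HMM marginal is the default because it is the exact marginal of
the stated generative model.

**Posterior and gamma surface.** With a gamma prior on the fitness
$\varphi = 1 + \sigma$ (default shape = rate = 0.001), the unnormalised log
posterior is evaluated on a small grid of $\sigma$ values and fitted by
ordinary least squares to the gamma-density surface

$$\log p(\sigma \mid c, C) = c + (\alpha - 1)\log \varphi - \beta \varphi.$$

The fit has a closed form in the grid moments $s_1, \dots, s_8$
(`fit_gamma_surface()`), verified in the tests against a generic
design-matrix solve. Five grid points describe both neutral and selected
log-posterior surfaces well; fitting a two-parameter density keeps the
per-locus cost at a handful of likelihood evaluations, which is what makes
genome-wide scans affordable.

**Why fitness space.** A gamma density has support $(0, \infty)$ and so
cannot represent posterior mass at $\sigma \le 0$ if fitted in $\sigma$
directly, yet negative estimates must be representable and the Bayes
factor must compare selection against counter-selection. Fitting in
$\varphi = 1+\sigma$ gives support $\sigma \in (-1, \infty)$ and a natural
two-sided split at $\varphi = 1$. The prior sits on $\varphi$ for the same
reason; it is numerically inert (flattening it to near-improper moves
estimates by $<10^{-4}$ in the tests).

**Summaries.** The fitted gamma has mean $\alpha/\beta$ and variance
$\alpha/\beta^2$ in fitness space, so
$\hat\sigma = \alpha/\beta - 1$ and
$\mathrm{Var}(\sigma) = \alpha/\beta^2$. The log Bayes factor is the log
posterior odds across $\varphi = 1$:
$\log \mathrm{BF} = \log\{(1 - F(1))/F(1)\}$ with $F$ the fitted gamma CDF.
A tail-odds ratio (rather than a Savage-Dickey density ratio) is used
because it reproduces the conventional "very strong evidence" anchor
$\log(0.99/0.01) \approx 4.6$ exactly. Saturated odds are clamped at
$\pm 709$ (the largest finite log double) with a flag. We report raw log
BFs and leave thresholding to the user; 4.6 is the conventional cut-off.
No multiple-testing correction is applied.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `Population_size` (N) | required | effective population size; state space 0..N |
| `Generations` | required | sampling times of the T time points, in generations |
| `Prior_parameters` | 0.001, 0.001 | gamma prior shape/rate on fitness |
| `Emission`, `Rho` | binomial, 0 | read-sampling kernel and overdispersion |
| `Filter_threshold` | 0.01 | variance below which a locus is flagged uninformative |
| `Grid_range`, `Grid_points` | [-0.5, 0.5], 21 | coarse scan of per-generation sigma |
| `Likelihood` | forward | HMM marginal vs plug-in smoothing |
| `Layout` | time_major | sync sample-column ordering |

The coarse scan covers per-generation $\sigma \in [-0.5, 0.5]$, generous
for any realistic E&R effect ($N_e \sigma \le 10$ at $N_e \ge 100$ is
$\sigma \le 0.1$). The five final points are centred on the *interpolated*
peak (a parabola through the three scan values around the argmax) and span
three posterior standard deviations as judged by the local
curvature, capped at two coarse steps and floored at a tenth of one to
keep the design matrix well conditioned. Continuous placement matters:
when the posterior is much narrower than the coarse step (large $N$),
snapping the window to the scan lattice makes the fitted tail mass at
$\varphi = 1$ -- and hence the Bayes factor -- jump erratically between
near-identical loci, which visibly degrades the rank stability of BFs
across assumed $N_e$. An argmax at the edge of the coarse range keeps the
lattice window ending at the boundary (never beyond); a completely flat
scan falls back to the symmetric window around 0.

## Pre-filter

Loci whose observed frequencies barely move are statistically
uninformative and tend to produce inflated $\hat\sigma$ and BFs. Before
inference, the population variance of $c_{rt}/C_{rt}$, pooled over all
covered samples, is compared against 0.01; strictly smaller fails. Filtered
loci are retained in the output with `filtered = 1` and `NA` statistics.
Pooling across replicates (rather than per replicate) and the variance of
frequencies (rather than of step-to-step increments) are the default
readings; the increments statistic is available via `Filter_mode
increments`. Zero-coverage samples are excluded; loci with fewer than two
covered samples fail with undefined variance.

## Simulator: what it emulates, and what it does not

`simulate_trajectory()` is an exact event-driven (Gillespie) simulation of
the same continuous-time chain the likelihood uses, recorded at the exact
requested generations; `sample_pool_seq()` adds binomial (or
beta-binomial) reads at fixed (or Poisson) depth. `generate_panel()` writes
sync files (focal allele as T against an A reference, time-major columns)
plus a truth table, fully determined by the seed. Defaults are the
reference design used throughout: $N_e = 300$, five replicates, five
uniform time points spanning $0.2 N_e$ generations, 60x coverage; initial
copy number is `round(p0 * Ne)`. Named time schemes TS1-TS6 cover the
usual variations (2-11 time points, $0.2 N_e$ or $0.4 N_e$ spans, uneven
sampling).

Because simulator and likelihood share the same latent model, recovery
tests exercise the inference machinery without model mismatch. That is
deliberate, and it bounds what a green test establishes: real data add
linked selection, varying coverage, DNA pooling artefacts and model
misspecification (e.g. truly discrete generations), none of which the
generator emulates. Monte-Carlo fixation checks use the embedded jump
chain (up-step probability $(1+\sigma)/(2+\sigma)$), whose fixation law
is exactly that of the continuous-time chain.

## Numerical choices

- **Transition kernels.** The interior of $Q$ is a birth-death
  sub-generator, symmetrisable by detailed-balance weights
  $w_{i+1}/w_i = (1+\sigma)$-type ratios. We eigendecompose the symmetrised
  tridiagonal block (log-space weights, since $w$ grows like
  $(1+\sigma)^i$), giving $e^{Q dt}$ for any $dt$ from one decomposition;
  absorbed mass is accumulated via the closed-form time integral
  $\int_0^{dt} e^{\lambda s}\,ds$. A Poisson-weighted uniformization series
  is kept as an independent route and the two agree to $<10^{-9}$ in the
  tests. Negative round-off entries are clipped and rows renormalised.
- **Caching.** Models are memoised per $(N, \sigma)$; once more rows than
  states have been propagated for a given $dt$, the full kernel for that
  $dt$ is built once and reused (identical results, much faster panels).
- **Underflow.** Forward recursions renormalise after every emission and
  accumulate log scale factors.
- **Round-off noise floor.** The detailed-balance weights span
  $e^{N \log(1+\sigma)}$, so at large $N$ and strongly non-zero $\sigma$
  the rescaling can amplify eigen-sum round-off
  ($\sim \varepsilon \lVert x/\sqrt{w} \rVert_2$) into spurious
  transition probability for states far "uphill" of the drift -- enough,
  in rare cases, to fake a global likelihood maximum at an absurd
  $\sigma$. Every propagated entry below ten times its computable error
  bound is therefore zeroed. This can only shrink the likelihood of
  parameter values the data already rule out (implausible $\sigma$ may
  correctly come back as $-\infty$), and is a $\sim 10^{-12}$ relative
  perturbation near the peak.
- **Degenerate fits.** $\hat\alpha \le 0$ or $\hat\beta \le 0$ cannot be a
  gamma density; such loci are flagged `degenerate = 1`, keep their
  shape/rate for diagnosis, and carry `NA` summaries. They are reported,
  never dropped.
- **Ties.** Focal-allele ties break in fixed A,T,C,G order; the grid
  argmax tie (flat likelihood) resolves to the window around 0.

## Design choices that were genuinely open

- **Joint vs plug-in marginalisation.** Whether observations should be
  marginalised jointly over the hidden path or smoothed per time point is
  ambiguous in informal descriptions of this family of methods; both are
  implemented, the exact HMM marginal is the default.
- **Sample-column order.** Sync files carry no replicate/time metadata;
  time-major blocks are the default and the layout is config-exposed,
  with a test proving the mapping is a pure function of the declaration.
- **Evidence monotonicity.** Duplicating an arbitrary replicate can
  legitimately *lower* the log BF when that replicate is flat or falling
  (it doubles evidence for neutrality). The monotonicity property is
  therefore stated for the replicate with the largest observed frequency
  rise, where it holds without exception in the test panels.
- **Fixation-check scale.** Closed-form absorption checks use the
  vectorised jump chain ($10^4$ walkers) rather than $10^4$ full
  event-driven runs, which would be needlessly slow in R; the
  event-driven simulator is checked against the same closed form at
  smaller n.

## Known limitations

- Strictly biallelic: third alleles at a locus are dropped from coverage.
- Independence across loci: linked selection inflates coefficients at
  hitchhiking sites and is not modelled.
- Codominance is assumed; no dominance parameter.
- $N_e$ is an input, not an estimate. Misspecifying it rescales the Moran
  clock; point estimates and BF ranks are robust to this (the validation
  experiment reports Spearman correlations of log BFs across assumed
  $N_e$), but absolute BFs shift, so a stricter threshold is advisable
  when $N_e$ is poorly known.
- The gamma surface is fitted from five points; posteriors that are
  strongly multi-modal (not observed in practice) would not be captured.

## A worked run

```{r, eval = FALSE}
library(moranER)

# simulate the reference design: 100 loci, Ne*sigma = 10, p0 = 0.5
scn <- sim_scenario(Ne = 300, p0 = 0.5, sigma = 10/300, seed = 1)
generate_panel(scn, 100, "panel.sync", "panel.truth.tsv")

writeLines(c("Population_size 300",
             "Generations 0, 15, 30, 45, 60",
             "Replicates 5",
             "Prior_parameters 0.001, 0.001"), "run.cfg")

run_infer("run.cfg", "panel.sync", "results.tsv")
res <- read_results("results.tsv")
median(300 * res$mean_sigma, na.rm = TRUE)  # recovers ~10 on the Ne scale
```

Every empirical number quoted in this vignette is computed by the test
suite (`tests/testthat/`) or the acceptance script
(`scripts/acceptance.R`); nothing is asserted that the package does not
itself reproduce.
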