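---
title: "Disease mapping with bymrates: model, sampler and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disease mapping with bymrates: model, sampler and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bymrates` estimates age-standardised incidence and mortality rates for a
set of regions from registry count panels whose capture is incomplete and
improving over time. This vignette is the package's own account of the
science: the model and its assumptions, what the tunable parameters mean,
what the synthetic-data generator does and does not emulate, the numerical
choices inside the sampler, and the places where the design was genuinely
open and a convention had to be picked.

## Indirect standardisation and the data model

The raw inputs are counts `O` by region × period, female populations by
region × 5-year age band × year (census years only; intermediate years are
interpolated), region-level covariates, and a region adjacency graph.

Expected counts come from indirect standardisation: national age-specific
reference rates for a single reference year are applied to each region's
person-years,

\[E_{ip} = \sum_{t \in p} \sum_a r_a \, P_{iat},\]

summing over the calendar years of each interval (with the default
periods, 4 + 4 + 3 years). Intercensal populations use the exponential
growth formula \(P_t = P_a (P_b/P_a)^{(t-a)/(b-a)}\), exact at census
years; extrapolation is allowed up to five years beyond the last census,
mirroring a study window that ends shortly after the final census.
`compute_expected()` is linear in both rates and populations, which the
test suite exploits as a superposition property.

The ratio `O/E` is the standardised incidence (or mortality) ratio; the
model below smooths it.

**Registry completeness.** A registry that captures a fraction `c` of true
cases is modelled as binomial thinning of the counts. Rather than
inflating observed counts by `1/c` (which destroys their integer Poisson
character), the default `offset` mode multiplies the expected counts,
`E' = E c`, so fitted means live on the observed-count scale and the
relative risk keeps its interpretation net of registration. The
`completeness = "covariate"` option of `bym_analysis()` additionally (or
instead) enters log-completeness as a regression column with a free
coefficient, which lets the data speak about residual registration
artefacts; `inflate` mode exists only for descriptive comparison and is
rejected by the count likelihood by design.

## The Besag–York–Mollié model

\[O_{ip} \sim \mathrm{Poisson}(E'_{ip}\,\theta_{ip}), \qquad
\log \theta_{ip} = \alpha + x_{ip}^\top \beta + u_i + v_i.\]

The spatial effect `u` has the intrinsic conditional autoregressive
(ICAR) prior — the improper pairwise-difference Gaussian,

\[p(u \mid \tau_u) \propto \tau_u^{(n-k)/2}
\exp\!\Big(-\tfrac{\tau_u}{2} \sum_{i \sim j} (u_i - u_j)^2\Big),\]

with one rank deficiency per connected component (`k` components); `v` is
iid Gaussian heterogeneity with precision `tau_v`. The cross-region
variance thus splits empirically into a spatially structured and an
unstructured part, and regions with little data borrow strength from
their neighbours.

Assumptions worth stating: counts are conditionally independent Poisson
given `theta` (no extra-Poisson clustering within cells beyond `v`);
covariate effects are log-linear and shared across regions; the adjacency
graph is a fixed, known description of "neighbourliness"; and the periods
are exchangeable given their own parameters — the default analysis fits
each period independently, matching per-interval reporting conventions,
rather than a spatio-temporal interaction model (deliberately out of
scope). `run_mcmc()` will happily fit a multi-period panel jointly with
shared parameters when handed one directly; that is what the
parameter-recovery tests do.

### Priors and tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau_prior` | Gamma(0.5, 0.0005) | precision hyperprior for both `tau_u` and `tau_v`; the vague disease-mapping convention of the BUGS model family |
| `prior_sd_fixed` | 10 | Gaussian prior sd for `alpha` and each `beta` on the standardised covariate scale |
| `n_iter`, `n_burnin`, `thin`, `n_chains` | 20000, 10000, 5, 3 | sweeps per chain, discarded sweeps, thinning, chains |
| `proposal_sd` | 0.05 (fixed effects), 0.3 (region effects) | initial random-walk scales, adapted during burn-in |

Covariates are standardised internally (mean 0, sd 1 over the modelled
cells; constant columns are centred only) and the mapping is stored in the
fit, so coefficient priors act on a comparable scale and the posterior is
exactly invariant to shifting a covariate by a constant — a property the
test suite checks bitwise with matched seeds. Covariates default to
urbanisation and mean years of schooling; the wealth index is never a
regression column, only a stratifier for reporting.

## The Metropolis-within-Gibbs sampler

Each sweep updates:

1. `tau_u ~ Gamma(a + (n-k)/2, b + S_u/2)` with
   `S_u = sum over edges of (u_i - u_j)^2` — the conjugate full
   conditional under the ICAR quadratic form;
2. `tau_v ~ Gamma(a + n/2, b + sum(v^2)/2)`;
3. `alpha` by scalar random-walk Metropolis — a proposal `alpha + d`
   rescales every fitted mean by `exp(d)`, so the likelihood ratio has
   the closed form `sum(O) d - (e^d - 1) sum(mu)`;
4. each `beta_j` by scalar random-walk Metropolis;
5. `u` in *graph-colour blocks*: regions are greedily coloured so that no
   two regions of one colour share an edge; within a colour the
   single-site full conditionals do not interact, so all proposals in the
   block are evaluated and accepted element-wise in one vectorised pass.
   This keeps the sampler pure R at useful speed without changing the
   stationary distribution relative to a site-by-site scan;
6. `v` element-wise in one vectorised pass (no cross-terms at all);
7. recentring: the mean of `u` within each graph component is subtracted
   and folded into `alpha`. On a connected graph this is an exact
   reparametrisation (the likelihood depends only on `alpha + u_i`), and
   it removes the ICAR null direction so `u` is identified; the suite
   verifies `|mean(u)| < 1e-12` in every retained draw. On a
   disconnected graph the global fold-in is approximate and the fitted
   means are refreshed from scratch each sweep; the lattice generator
   only produces connected graphs.

During burn-in the proposal scales adapt every 50 sweeps towards a 20–50%
acceptance window (shrink by 0.8 below, grow by 1.25 above); adaptation
stops at the end of burn-in so the retained chain is a fixed Markov
kernel. Initial values are over-dispersed but deterministic functions of
the seed; each chain draws its RNG stream from an independent sub-stream
of `config$seed`, so a fit is bitwise-reproducible and chains still
differ from one another.

Cells with zero adjusted expected count cannot inform a multiplicative
relative risk: they are excluded from the likelihood with a warning
rather than silently imputed, and an observed count in such a cell makes
the standalone log-likelihood `-Inf` (signalled, not an error).

The sampler's correctness is checked three ways: the single-region
intercept-only posterior against a 1-D quadrature oracle
(Kolmogorov–Smirnov distance below 0.02 at 20,000 retained draws);
recovery of generating coefficients on the 31-region panel; and interval
calibration — with the generating distribution matched to the fitting
priors, nominal 95% credible intervals for `theta` cover the truth at
the nominal rate (±3 percentage points pooled over 200 replicates of a
16-region lattice with 2,000 retained draws each). Those problem sizes
are the package's chosen trade-off between statistical resolution of the
checks and keeping the default suite comfortably runnable.

## Diagnostics

**Residual Moran's I.** Pearson residuals on posterior-mean fitted
values, `(O - mu_hat)/sqrt(mu_hat)`, averaged over periods to one value
per region (deviance residuals sit behind a flag). Moran's I uses binary
symmetric weights by default; row-standardised weights — under which the
statistic is the slope of the neighbour-mean regression — are an option.
Significance comes from random relabelling with the observed
configuration included in the null set (`p >= 1/(n_perm+1)`), two-sided
around the null expectation `-1/(n-1)`, 999 permutations by default. On
data simulated from the model itself the test should be quiet, and is:
the suite requires `p > 0.05` in at least 90% of 50 replicates, and the
permutation p is verified super-uniform under a pure-noise null.

**DIC.** `DIC = Dbar + pD` with the plug-in deviance evaluated at the
posterior means of `alpha`, `beta`, `u`, `v` — the relative-risk focus
that BUGS reports. The additive `log(O!)` constant is omitted everywhere
consistently, so DIC differences between models on the same data are
unaffected; absolute DIC values are not comparable across datasets.

**Convergence.** Split-Rhat (floored at 1) and a Geyer
initial-monotone-sequence effective sample size per monitored scalar,
with flagging above 1.05.

## The synthetic-data generator

`simulate_panel()` emulates the study conditions end to end at their
real dimensions: 31 regions, 11 age bands (30–34 … 80+), three periods
(2000–2003, 2004–2007, 2008–2010), censuses at 1996/2006/2011, registry
completeness rising linearly from 0.22 in the first period to 0.75 in
the last, and a reference year of 2010. Specific choices:

* **Lattice** — a rook-adjacency grid by default (31 regions become a
  5×7 grid with four trailing cells dropped, staying connected); ring
  and random-planar (Gabriel graph) topologies exist for property tests.
  A toy lattice stands in for the real province map, whose shapefile is
  deliberately out of scope.
* **Populations** — every region starts from the same 30+ female total
  (default 200,000, a plausible mid-size province) split by a noisy
  declining pyramid, then grows geometrically at a region-specific
  annual rate drawn from 0.5–3%/yr.
* **Age-specific rates** — a schedule rising roughly tenfold from the
  30–34 band to 80+, scaled so the implied reference ASR lands near 40
  per 100,000, the order of magnitude of the emulated national
  incidence scale in the reference year. Age bands are configurable
  because source reporting conventions vary; 5-year bands from 30 are
  the default.
* **Completeness** — one national value per period (the emulated
  registry derives completeness from a single insurer's records and
  applies it to all patients), hitting the endpoints exactly.
* **Wealth index** — a Gaussian field smoothed one step towards the
  neighbour mean (weight 0.7), so quintiles form contiguous-ish blocks
  as real asset indices do. It is generated, not built from household
  assets: the index is only ever consumed as a stratifier.
* **Truth** — spatial effects drawn from the ICAR distribution proper
  on its zero-mean subspace via the Laplacian pseudo-inverse;
  `tau_u = 10`, `tau_v = 25` by default give region relative risks
  mostly within ±50% of national, consistent with the heterogeneity a
  subnational cancer atlas shows.
* **Under-registration** — binomial thinning of the true counts,
  cell-wise, which is the observation model the completeness offset
  inverts in expectation.

One global seed fans out to labelled sub-streams per operation, so each
stage is independently reproducible and bitwise-stable.

What the generator does *not* emulate: age-specific covariate effects,
registration that varies by region or by cancer stage, migration between
censuses, boundary changes (the emulated panel keeps 31 regions
throughout), missing-year masks in the count panel, and real geography.
Passing tests therefore demonstrate that the machinery is correct under
the stated generative assumptions — they cannot certify the
substantive findings one would obtain from real registry data, which are
not distributable with the package.

## Conventions and open choices

Where the problem admitted more than one defensible convention, the
package fixes one and documents it:

* **Standard population** for the reference ASR is the national female
  population of the reference year — consistent with building expected
  counts from the same year's national rates, and avoiding an arbitrary
  external standard.
* **Region ASRs** are `theta ×` reference ASR (linear scaling), not a
  re-aggregation of smoothed age-specific rates; the model smooths a
  single relative risk per region × period, so the scaling convention is
  the faithful readout.
* **Percentage change** between periods is computed draw-wise and then
  summarised; ratio-of-means intervals would be symmetric in a way
  published change intervals visibly are not. Point mode applies the
  same formula to point estimates and is what reproduces printed-table
  arithmetic exactly.
* **Quintiles**: regions sorted by wealth index (ties broken by region
  identifier), remainder regions allocated to the poorest quintiles
  first — 31 regions split (7, 6, 6, 6, 6). Quintile rates average
  member regions unweighted per draw; population weighting is an option.
* **Rankings** are dense ranks of posterior mean rates, with a
  tie-broken `display_rank` that is a true permutation for table
  layout.
* **Percentile rule** throughout is linear interpolation between order
  statistics (quantile type 7), stated because credible bounds at small
  draw counts are sensitive to it.

## Known limitations

Pure-R MCMC is fast enough for tens to a few hundreds of regions but not
for thousands; the ICAR update cost grows with the colour count of the
graph. DIC is reported because it is the conventional companion of this
model family, with its known tendency to under-penalise when the focus
is latent; WAIC/LOO are deliberately not implemented. The independent
per-period fits cannot pool information over time, so period-on-period
changes inherit the full posterior uncertainty of both endpoints. And
the completeness offset corrects expected counts in mean only — it
cannot recover information destroyed by severe thinning, which is why
early-period estimates carry visibly wider intervals.
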