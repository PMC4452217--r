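---
title: "Methods: joint occupancy-abundance modelling for possum monitoring"
author: "possumOccAb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: joint occupancy-abundance modelling for possum monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(possumOccAb)
```

## The monitoring problem

Brushtail possums are monitored on a national 8-km grid. Each sampling
location carries eight detection units: four 200-m leg-hold trap-lines
(AA, DD, MM, PP; 10 traps each, run for up to two nights) and four 150-m
faecal-pellet transects (A, D, M, P; 30 circular plots each). Two
quantities are reported: *occupancy* — the proportion of locations used by
possums — and *relative abundance* via the Trap Catch Index (TCI), possums
caught per 100 corrected trap-nights, where each non-target capture and
each sprung-but-empty trap subtracts half a trap-night from the effort
denominator.

Both quantities are corrupted by imperfect detection: an occupied location
can yield no captures and no pellets, and naive summaries confound absence
with non-detection. This package estimates both jointly in a hierarchical
model, and evaluates how much survey effort (nights, trap-lines) can be
dropped before estimates degrade — together with what the effort costs.

## The model

For location $i$ and detection unit $j$ ($j = 1\ldots4$ trap-lines,
$j = 5\ldots8$ pellet transects):

$$z_i \sim \mathrm{Bernoulli}(\psi), \qquad
  X_{ij} \sim \mathrm{Bernoulli}(z_i\,p_j), \qquad
  Y_{ij} \sim \mathrm{Poisson}(z_i\,\lambda),$$

where $z_i$ is latent occupancy, $\psi$ the occupancy probability, $p_j$
the per-unit detection probability (constant within the trap method and
within the pellet method, shared across habitats), $Y_{ij}$ the trap-line
TCI, and $\lambda$ the mean TCI conditional on occupancy. The zero
inflation of the abundance index arises mechanically: unoccupied locations
contribute structural zeros through $z_i$. The derived quantity

$$z\lambda = \lambda \times \psi$$

is the mean TCI across *all* locations, occupied or not, and is the
headline abundance index. It is computed draw by draw from the joint
posterior, because the mean of a product is not the product of means.
When `strata = "by_habitat"`, $\psi$ and $\lambda$ take separate values
for forest and non-forest locations while $p_{\mathrm{trap}}$ and
$p_{\mathrm{pellet}}$ remain shared; the "pooled" analysis simply pools
locations.

Priors are deliberately diffuse: $\mathrm{Beta}(1,1)$ on $\psi$ and each
$p$, and $\mathrm{Normal}(0, \sigma^2 = 100)$ on $\log\lambda$. We read
"Normal(0, 100)" as a *variance* of 100 (sd 10) — a genuinely
uninformative prior spanning many orders of magnitude of $\lambda$ — not
as a BUGS-style precision of 100 (sd 0.1), which would be sharply
informative and contradict the stated intent; the sd is configurable
(`priorLogLambdaSd`).

Model assumptions worth stating explicitly:

* **No false positives.** A capture or a pellet forces $z_i = 1$. Pellets
  can in reality persist for months, so a transect may record possums that
  no longer use the location; this failure mode is *not* modelled (nor
  simulated — see below).
* **Closure** within a season: $z_i$ is constant across a location's
  units and nights.
* **Independence** across locations and across units given $z_i$.
* **Unsurveyed units are missing, not zero.** About 16% of locations lack
  some units (dangerous terrain); treating those as non-detections would
  bias $\psi$ and $p$ downward, so all likelihood terms simply skip
  missing entries.

## Two readings of the Poisson likelihood

After trap-night corrections the TCI is not an integer (1 capture over
19.5 trap-nights gives 5.128...), so a Poisson likelihood on $Y$ is not
literally well defined. Both defensible readings are implemented and the
choice is recorded in the configuration:

* **`count_offset` (default).** Model the raw capture count with effort as
  an offset: $C_{ij} \sim \mathrm{Poisson}(z_i\,E_{ij}\,\lambda/100)$,
  where $E_{ij}$ is the line's corrected trap-nights. This keeps integer
  support and makes $\mathrm{E}[\mathrm{TCI}] = \lambda$ exactly; it is
  the statistically coherent reading.
* **`tci_rounded`.** Round $Y$ to the nearest integer (ties to even, R's
  `round()`) and model it as $\mathrm{Poisson}(z_i\lambda)$ directly. This
  replicates the behaviour of fitting the index itself and is retained for
  comparability with analyses that did so.

At protocol effort the two modes give nearly identical inferences; they
differ when corrected trap-nights vary strongly across lines.

The trap-line detection indicators $X_{ij}$ are retained in the likelihood
alongside $Y_{ij}$ even though $X = \mathbf{1}(Y > 0)$ makes them
partially redundant — the joint formulation above is the model being
reproduced, and dropping the $X$ trap columns would change the posterior
of $z$ at all-zero locations.

## The sampler

All parameters except $\lambda$ have conjugate full conditionals, so the
fit is Gibbs-within-Metropolis, written in vectorised R with per-location
sufficient statistics precomputed once (each sweep is O(n)):

* $z_i$ is forced to 1 by any detection; otherwise
  $\Pr(z_i = 1 \mid \cdot) = \psi A_i / (\psi A_i + 1 - \psi)$ with
  $A_i = \prod_{j \in \mathrm{obs}} (1 - p_j) \times
  \Pr(\text{all } Y = 0 \mid z_i = 1)$.
* $\psi \mid z \sim \mathrm{Beta}(1 + \sum z, 1 + n - \sum z)$ per
  stratum; $p \mid z$ likewise, over observed units at occupied locations
  only (unoccupied locations carry no information about $p$).
* $\log\lambda$ takes a Gaussian random-walk Metropolis step per stratum.
  The proposal scale adapts towards an acceptance rate of 0.44 in batches
  of 50 during burn-in only and is frozen afterwards, so the kept chain is
  a genuine Markov chain.

Defaults mirror the headline analysis: 2 chains, 10,000 burn-in and
50,000 kept iterations each, i.e. 100,000 posterior draws. Chains start
from a common centre ($\psi = p = 0.5$, $\lambda$ = mean positive TCI,
$z$ = detection indicator) perturbed by a deterministic chain-indexed
offset, satisfying the requirement of distinct initial values while
keeping results bit-reproducible from the seed. Convergence is summarised
by the Gelman–Rubin statistic in its between/within-chain variance form;
a fit is flagged `converged` when every R-hat is below 1.1. Non-convergence
is a flag on the result, never an exception — a replicate fit inside the
effort grid must not abort the grid.

### Verification strategy

The sampler is cross-validated against a brute-force oracle
(`bruteForcePosterior()`): with $p$ and $\lambda$ fixed, the marginal
posterior of $\psi$ is computed exactly by enumerating all $2^n$ latent
configurations on a grid (capped at 12 locations). The test suite compares
the enumeration against a Rao-Blackwellised density from the MCMC draws
(averaging the Beta full conditional over the sampled occupied counts) on
a 3-location fixture built so that two locations have genuinely uncertain
occupancy, at total-variation distance below 0.01. Parameter recovery is
checked end to end on synthetic data at 500 locations per habitat, with
every generator parameter recovered within three posterior standard
deviations. Test fits use shortened chains (hundreds to thousands of
iterations); these sizes are ample for the fixture posteriors involved and
keep the default suite quick, while headline settings remain the defaults
for real analyses.

## Effort evaluation

The effort analysis asks what happens to $\psi$ and $z\lambda$ when only
the first trap night is used, and when only $k \in \{1,2,3,4\}$ trap-lines
per location are used. Following the original design, trap-lines are
subsampled *without replacement, independently at each location*, 100
times per design cell; pellet transects are never subsampled (they are
collected alongside ungulate monitoring at no extra cost, and their
information is what keeps occupancy stable under reduced trapping).
Locations with fewer surveyed lines than requested keep all their lines,
with a warning.

Relative bias is computed per replicate against the full-effort baseline
(four lines, both nights). The baseline is fitted **with the same
configuration and seed as the replicate fits**. One could instead fit the
baseline once at headline chain lengths while shortening replicate fits,
but then the 4-line/2-night cell would not reproduce the baseline exactly
and "zero bias at full effort" — a structural identity, not a statistical
statement — would hold only approximately. Keeping one configuration per
grid preserves the identity bit-for-bit; for headline runs the defaults
are the full 10,000/50,000 settings anyway. Per-replicate subsampling
streams are split deterministically from the master seed.

One open point in the original description is whether the 100 subsampling
replicates re-ran the full MCMC; we re-fit the model for every replicate,
with chain lengths under the caller's control.

The night comparison treats $p_j$ as the per-line detection probability
*over whatever nights are included* — under one-night data, $p_j$ is
simply the single-night detection probability. No per-night sub-model is
introduced.

## Power analysis

Change in mean TCI between two survey rounds is assessed with a two-sided,
equal-variance, equal-n two-sample t-test — the documented behaviour of
`stats::power.t.test`, which is called directly rather than reimplemented
(an independent noncentral-t implementation backs it in the tests). The
per-location SD of TCI underlying the published planning numbers is not
itself published; `sdFromAnchor()` recovers it by inverting the power
function at an anchoring statement ("225 locations give 80% power to
detect a change from TCI 5.0 to 5.5"), giving sd $\approx 1.889$, a CV of
about 38% of the baseline TCI of 5.0. From that anchor the two-night
detectable-change table at $n = 786$ follows: 0.267 (5.34% of baseline)
at 80% power, 0.309 (6.18%) at 90%, 0.344 (6.87%) at 95%.

Two presentation notes. First, published tables of this kind sometimes
derive the percent column from the *rounded* absolute change
(100 × 0.27 / 5 = 5.4) and sometimes from the unrounded value (6.87 →
6.9); no single rounding convention reproduces such a mixed column, so
`powerTable()` reports full-precision values and leaves rounding to report
time. Second, the corresponding one-night planning numbers require the
one-night CV, which was estimated from data that are not published;
a single SD cannot reproduce both columns, so the one-night SD is left as
a free input rather than silently anchored. We also read "n locations"
as a per-group sample size (each survey round measures n locations), the
reading consistent with the two-sample formulation and the anchored
numbers.

## The cost model

Costs split into fixed per-location components (transport — vehicle plus
helicopter — and equipment), which do not depend on nights on site, and
variable components (labour, field allowance, food) that scale with
person-days. Two-night trapping keeps a two-person team on site 3 days at
8 h/day; one-night trapping, 2 days at 10 h/day. Money is handled in
integer cents, so totals are exact, and display rounding is half-up. The
annual plan multiplies by 271 locations per year, computes field days per
regime, applies a 172-day season with 30% weather loss
(`floor(172 × 0.7) = 120` workable days per team) and a ceiling on team
counts. The per-location saving is by construction a difference of
variable costs only — the tests assert it is invariant to the transport
and equipment rates.

## The synthetic-data generator

`simulateSurvey()` draws data from exactly the process the model assumes,
plus the survey geometry: per-habitat occupancy, per-line-per-night
capture counts that are Poisson with the line's realised corrected
trap-nights as offset (non-target captures and sprung traps are Binomial
events that both reduce the effort denominator and occupy traps), and
pellet-transect presence as the union of 30 per-plot Bernoulli draws,
forced to zero at unoccupied locations. Trap-line detection is therefore
*emergent from captures* rather than an independent coin flip, so
$X = \mathbf{1}(C > 0)$ holds by construction, as it does in real data.
`impliedDetection()` maps generator rates to the model's $p$ scale
($p_\mathrm{trap} = 1 - e^{-\bar e \lambda / 100}$,
$p_\mathrm{pellet} = 1 - (1 - q)^{30}$) for recovery assertions.

Defaults emulate the phased-implementation seasons: 85 forest and 79
non-forest locations, with 16% of locations missing one or two units
completely at random. Where the generating rates are not pinned down by
the study design, the package fixes them once at realistic values and
documents them as its own choices:

* $\psi$ = 0.8 (forest) / 0.4 (non-forest) and $\lambda$ = 4.5 / 2.0 —
  chosen so the pooled occupancy (~0.61) and forest mean TCI sit at the
  magnitudes the programme reports;
* per-plot pellet detection 0.05, giving per-transect detection ~0.79;
* non-target and sprung-trap rates of 2% per trap-night each — arbitrary
  but of the right order for leg-hold trapping; they matter only through
  the 0.5 trap-night corrections.

Captures are truncated at the traps still available on the line (traps
minus non-target and sprung events), since a trap holds one animal; at
realistic $\lambda$ this truncation is numerically negligible, and it is
what keeps every simulated record satisfying the survey-sheet invariant
`captures + non-target + sprung ≤ traps set`.

What the generator deliberately does **not** emulate: pellet persistence
and decay (so simulated pellets never produce false positives — a real
failure mode the model itself also excludes), spatial autocorrelation
between neighbouring grid vertices, weather interruptions (weather enters
the cost model only), covariate-driven heterogeneity in $\psi$ or $p$,
and any within-season dynamics. Passing recovery tests on these
simulations therefore demonstrates internal consistency of model and
sampler — not robustness to the ways real field data violate the model.

## Numerical choices and degenerate inputs

* Impossible states contribute $-\infty$ log-likelihood as a value, not an
  error; the enumeration oracle substitutes a large negative constant so
  that `0 × (-Inf)` cannot poison its matrix products.
* R-hat on a degenerate (constant) chain is defined as 1 when the chains
  agree and `Inf` when they do not.
* Identical chains give R-hat $\sqrt{(n-1)/n} < 1$, a property of the
  classic estimator, not a bug.
* All seeds are split from a single master seed via a draw of sub-seeds
  (each below $2^{31}$), so chains, replicates and pipeline stages are
  independently reproducible.
* Partially surveyed trap-lines (fewer than 10 traps set) are
  representable — `traps_set` is a per-record field — though the standard
  protocol always sets 10.
* A corrected trap-night total of zero or less (e.g. 10 non-target
  captures and 10 sprung traps on a 10-trap single-night line) signals a
  malformed record and raises an error naming the record.

## Known limitations

* Detection probabilities are constant within method: no covariates, no
  habitat-specific $p$, no per-night sub-model. When the generating
  process has habitat-specific trap detection (as the generator's
  emergent detection does when $\lambda$ differs by habitat), the fitted
  shared $p_\mathrm{trap}$ is a weighted compromise.
* No spatial structure: each grid vertex is exchangeable given its
  habitat.
* The abundance index is the TCI, an index — the model says nothing about
  absolute density.
* The enumeration oracle is exponential in locations and is intentionally
  capped at 12.
* Effort-grid runs re-fit the model per replicate; at headline chain
  lengths a full 8-cell, 100-replicate grid is an overnight desk job, not
  an interactive one. Shortened chains are the intended desk-scale mode.
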