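---
title: "Coalescent model selection for the origin of a range-restricted lineage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coalescent model selection for the origin of a range-restricted lineage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangecoal)
```

## The problem

`rangecoal` asks how a range-restricted plant lineage came into being when it
lives in sympatry with a widespread close relative: by a clean dichotomous
split from its sister species, or as a hybrid between two parental lineages
(with some admixture proportion $\alpha$), and in either case how long ago.
The motivating system is *Phyteuma gallicum*, an endemic of the French Massif
Central nested inside the range of *Ph. spicatum* and closely related to the
Central European *Ph. nigrum*; the same machinery applies to any small set of
demes sampled for RADseq SNPs.

The data are biallelic RAD SNPs for a few dozen diploids assigned to
sampling sites and demes (gene pools). The summary statistic is the set of
**folded pairwise two-dimensional site frequency spectra** (2D SFS): for each
unordered deme pair, a matrix counting SNPs by their joint minor-allele
counts. Competing demographic models are scored against these spectra by a
**composite multinomial likelihood** estimated with coalescent simulation,
compared by **AIC**, and the winning model's age parameters are bounded by a
**parametric bootstrap**.

## Pipeline overview

1. **`variant_filtering`** — from VCF + popmap to the analysis dataset:
   at most 10 SNPs per RAD locus, then one random SNP per locus that has
   $\le 50\%$ missingness, observed heterozygosity $\le 50\%$ and a minor
   allele carried by $\ge 2$ individuals ("complete" dataset); for the
   coalescent-modelling ("reduced") dataset additionally per-genotype read
   depth $\ge 6$, presence in $\ge 2$ individuals per sampling site, and
   removal of SNPs whose overall alternate-allele frequency is exactly 0.5
   (their minor allele is undefined; the test is `2 * alt == total` on
   integer counts, never on floats).
2. **`sfs_builder`** — per sampling site and SNP, four present haploid
   alleles are drawn without replacement (so the spectra contain no missing
   data), derived counts are summed per deme, and each pattern is folded on
   the deme pair's pooled minor allele.
3. **`demography` + `coalescent_engine`** — thirteen typed model
   specifications (three 3-deme, ten 4-deme) are simulated backwards in time
   under the structured coalescent.
4. **`inference`** — composite-likelihood fitting, AIC ranking, parametric
   bootstrap.
5. **`calibration`** — genetic distances to generations
   ($t = d / 2\mu$ with $\mu = 5.9\times10^{-9}$ substitutions/site/
   generation) and generations to years (3 years/generation).
6. **`synthetic_data`** — a generator with known truth emulating the study
   design, so every stage is testable without sequencing data.

## The coalescent engine

Within deme $d$ of diploid size $N_d$, each lineage pair coalesces at rate
$1/(2N_d)$ per generation; lineages migrate backwards at per-generation
rates $m_{ij}$; scheduled events implement divergence (all lineages of the
source deme move to the destination), hybrid founding (each lineage moves to
parent A with probability $\alpha$, else parent B) and instantaneous size
changes. Every hybrid founding carries a post-hybridisation bottleneck — the
hybrid deme is held at 0.5% of its present size for the 50 generations after
its origin — encoded as an ordinary size-change event so the engine needs no
special bottleneck logic. Migration is active only while both demes are
extant; whether background gene flow should extend into ancestral epochs is
not determined by the data design, and restricting it to coexisting demes is
the less-assuming default.

Site patterns are SNP-conditioned: exactly one mutation falls uniformly on
the genealogy's total branch length, so monomorphic patterns are never
produced and the likelihood ignores them by construction (together with
pair singletons, which the filtering removes from observed data).

One subtlety matters for correctness. A random segregating SNP hits a
*genealogy* with probability proportional to that genealogy's total branch
length, so pattern frequencies follow $E[L_i]/E[L_{tot}]$ — the classical
neutral spectrum $\xi_i \propto 1/i$ — not the unweighted per-genealogy
average $E[L_i/L_{tot}]$. For $n = 4$ the two differ by about one percent
(0.738 vs the exact $8/11 = 0.727$ for the folded singleton class), which is
far larger than Monte Carlo error at the simulation sizes used here.
`rangecoal` therefore (i) estimates expected spectra by accumulating every
branch's length into the folded cell of its subtree pattern
(a Rao–Blackwellised estimator with the correct expectation and lower
variance), and (ii) draws synthetic SNPs by resampling genealogies with
weights proportional to their total length.

## Model catalogue

Three-deme models treat *Ph. spicatum* as one gene pool (`Pspi`); four-deme
models split it into eastern (`PspE`) and western (`PspW`) lineages. All
models share background `Pnig`–`Pspi` gene flow (4-deme: `Pnig`–`PspE` only,
because the ranges of `Pnig` and `PspW` do not overlap) and, in 4-deme
models, `PspW`–`PspE` gene flow; `+mig` variants add focal `Pgal`–`Pspi(W)`
gene flow. The dichotomous 4-deme models come in two divergence-order
submodels (`-a`: the `Pgal`/`Pnig` split is older; `-b`: the `PspE`/`PspW`
split is older), because the branching order must be fixed before fitting.

```{r catalogue}
model_catalogue()
```

Free parameters and their default search ranges:

| parameter | default range | scale | meaning |
|---|---|---|---|
| `N_*` | [100, 200,000] | log | diploid effective sizes (present and ancestral; ancestral sizes are free, not tied to descendants) |
| `MIG_*` | [1e-8, 1e-3] | log | backward per-generation migration probabilities |
| `ALPHA_*` | [0.01, 0.99] | linear | admixture proportion from parent A |
| `TDIV_GAL`, `TDIV_SPW` | [100, 139,000] | linear | divergence/founding times (generations), constrained younger than `TDIV_ANC` |
| `TDIV_ANC` | [42,000, 139,000] | linear | root divergence, bounds from the genetic-distance calibration |

The migration upper bound is $10^{-3}$: with deme sizes up to $2\times10^5$
this already allows $Nm \gg 100$ (effectively panmictic demes), and larger
per-generation rates describe no biologically distinct scenario for
long-lived forbs with localised seed dispersal. All ranges are overridable
per parameter.

The `TDIV_ANC` bounds come from `prior_bounds_from_distances()`: the minimum
and maximum pairwise genetic distances between the two non-admixed species
(0.00049 and 0.00163 substitutions/site) divided by $2\mu$ and rounded *up*
to the next thousand generations. Rounding up, rather than outward, is what
maps both published conversions onto the published bounds; note that the
printed distances are themselves rounded, so re-deriving the generation
values from them reproduces the bounds only under this rule.

## Composite likelihood and masking

For each pair spectrum, unmasked cells are treated as independent
multinomial categories:
$\log_{10} CL = \sum_{\text{pairs}} \sum_{\text{cells}} m_c \log_{10} p_c$,
with expected probabilities renormalised over unmasked cells and floored at
$1/(10\,n_{sims})$ so unobserved cells never produce $-\infty$. Masked
cells are the pair-monomorphic corners, pair singletons ($i + j = 1$), and
everything unreachable after folding (including the lexicographically larger
image of exact-50% ties, which are stored at the smaller image — upstream
filtering makes global ties rare by removing exact-0.5 MAF SNPs).
`MaxObsLhood`, the ceiling attained when expected proportions equal observed
proportions (Gibbs' inequality), is reported with every fit; AIC is
$2k - 2\ln(10)\,\widehat{\log_{10} CL}$.

Because the composite likelihood conditions on segregating sites, it is
exactly invariant under rescaling $(N, t, m) \to (cN, ct, m/c)$: absolute
times are identified *only* through the calibrated `TDIV_ANC` range. Even
with the root age fixed, a classical divergence-versus-migration ridge
remains: at a few thousand SNPs, a regime with smaller sizes, younger
splits and stronger gene flow fits within a couple of log-likelihood units
of the generating parameters — less than one simulation-based evaluation's
Monte Carlo noise. The packaged recovery and bootstrap-coverage
experiments therefore anchor what the likelihood cannot identify, fixing
`TDIV_ANC` (as the distance calibration does in the real analysis) and the
migration rates at their generating values, and test recovery of the focal
divergence time with the deme sizes free. Reported ages inherit the
calibration's assumptions; gene-flow rates and ages should not be read as
jointly resolved quantities at this data size.

## Optimisation

`fit_model()` runs independent replicates. Each replicate draws a handful
of random start candidates (log-uniform for log-scale parameters,
rejection-sampled against the order constraints), scores each once and
starts from the best — simulated-likelihood surfaces punish hopeless
starts far more than the few extra evaluations cost — followed by
optimisation cycles. A cycle fixes one simulation
seed (shared by all replicates — common random numbers, so within-cycle
comparisons are not dominated by Monte Carlo noise) and performs one
coordinate-wise pass: each free parameter tries a step of shrinking relative
size (25% of the transformed range in the first cycle down to 2% in the
last) in both directions and continues in an improving direction for up to
four further steps. Accepted moves never decrease the cycle's estimated
likelihood; the likelihood can still drift between cycles when the seed
changes, which is the expected behaviour of any simulated-likelihood
optimiser. All replicates are finally re-scored under one common seed and
the best replicate wins, with ties broken by the lower replicate index so
results are independent of execution order.

## The synthetic generator

`generate_dataset()` emulates the reduced study dataset: 12,486 unlinked
SNPs by default, the field sampling design (Pgal 3 sites with 3/4/4
diploids; Pnig 4 × 4; PspE 3/4/4/4/4/4; PspW 3/4; pooled `Pspi` for 3-deme
models), per-genotype Bernoulli missingness (default 15%, a typical RAD
post-filter rate) and negative-binomial read depth (mean 20, dispersion 5,
chosen so the depth-6 filter is actually exercised — no empirical
read-depth distribution is assumed, so these are generator conventions,
not estimates). What it deliberately does *not* emulate: linkage between SNPs of
one RAD locus (SNPs are independent even when grouped under a locus ID),
genotyping error, allele-balance bias, and locus dropout correlated within
sites (an optional stress mode for the presence filter aside). Passing tests
therefore demonstrate correctness of the inference machinery under the
model's own assumptions, not robustness to real-data artefacts.

## Numerical choices and degenerate inputs

* Exact-50% MAF removal and fold ties are decided on integer counts.
* `downsample_site()` returns the identity block when the pool is exactly
  four and `NULL` below four; the vectorised path draws the equivalent
  hypergeometric count directly.
* Admixture with $\alpha \in \{0, 1\}$ consumes no randomness and is
  bit-identical to a merge, which keeps degenerate hybrid models comparable
  to their dichotomous limits.
* A genealogy that cannot finish (disconnected demes without gene flow, or
  $t > 10^9$ generations) is a hard error, not a silent hang.
* Bootstrap intervals are type-7 percentile intervals of the
  per-pseudoreplicate best estimates.
* The simulator uses its own deterministic xoshiro256** stream seeded from
  the user's integer seed, independent of R's RNG state; R-side draws
  (downsampling, starts, multinomials) use locally seeded R streams that are
  restored afterwards.

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script run the full pipeline at
reduced, single-CPU scales chosen as the smallest sizes at which each
property is statistically decisive: spectra from ~5,000 SNPs fitted with
20,000 simulations per evaluation, 20 cycles and 10 replicates for parameter
recovery; 10 repetitions of a two-model comparison (3,000 SNPs; 6,000
simulations, 8 cycles, 3 replicates per fit) for the model-selection
direction check, both competitors sharing the anchored root age and
background gene-flow rates; 20 pseudoreplicates for bootstrap coverage;
200,000 simulations for the analytic single-deme spectrum and $10^5$ for the
two-deme oracle comparison. The study-scale settings (100 replicates, 60
cycles, $10^5$ simulations, 100 pseudoreplicates) are the documented
defaults of `fit_model()` and `parametric_bootstrap()`.

## Known limitations

* Composite-likelihood AICs treat SFS cells as independent; with linked or
  ascertained SNPs the effective number of independent cells is smaller and
  the ΔAIC ≥ 10 rule is a convention, not a calibrated error rate.
* Absolute dates rest entirely on the borrowed mutation rate and the
  3-year generation time; both enter linearly.
* The expected-SFS estimator is Monte Carlo; likelihood differences well
  inside one evaluation's noise band cannot be resolved regardless of the
  optimiser.
* Only pairwise (not higher-dimensional joint) spectra are used, matching
  standard observed-SFS practice for small deme counts; information in
  three-way sharing patterns is ignored.
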