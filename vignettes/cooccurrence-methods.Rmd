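---
title: "Co-occurrence null models for root-associated fungal communities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence null models for root-associated fungal communities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctscore)
```

## Scope and model

`ctscore` analyzes spatial segregation and aggregation of taxon pairs in
binary community matrices, the situation that arises when hundreds of
host-plant individuals (here: oak seedlings) are screened for
root-associated fungal OTUs by amplicon sequencing. The observational
unit is the host individual; the data are a samples × OTUs
presence/absence matrix; the inferential target is whether specific OTU
pairs share host individuals more or less often than expected under a
null model that preserves the marginal structure of the data.

### From reads to presence/absence

Read-count tables are reduced to presence/absence in three steps, in
this order: samples with fewer than 20 total reads are removed
(sequencing-depth floor), then within each sample OTUs contributing
strictly less than 5% of that sample's reads are zeroed (damping
α-diversity inflation from uneven sequencing effort and removing
error-dominated rare calls), then samples flagged as contaminated
(non-host plant DNA) are dropped. Both thresholds are strict
inequalities: a sample with exactly 20 reads and an OTU at exactly 5%
are retained. Order matters because the 5% rule depends on per-sample
totals; the chosen order applies the depth floor to the raw totals. The
filters are set operations, so a sample failing several rules is removed
once. All-zero OTU columns are dropped afterwards so that "number of
OTUs" always refers to the retained community.

### Pair scores

For OTUs *i*, *j* with occurrences $R_i$, $R_j$ in $N$ samples and $S$
co-occurrences, the checkerboard score is $C = (R_i - S)(R_j - S)$ and
the togetherness score is $T = S(N + S - R_i - R_j)$. At fixed margins,
$C$ is strictly decreasing and $T$ strictly increasing in $S$, which
runs over the Fréchet-feasible range $[\max(0, R_i + R_j - N),
\min(R_i, R_j)]$.

Scores are standardized to $[0, 1]$ by dividing by the maximum over that
feasible range: $C_{std} = C / [(R_i - S_{min})(R_j - S_{min})]$ and
$T_{std} = T / [S_{max}(N + S_{max} - R_i - R_j)]$. This is the only
normalization for which 0 and 1 are the attainable extremes for *every*
margin configuration, which is what "lowest/highest possible level of
segregation (aggregation)" should mean; because the minimum score is 0
at the opposite extreme of the range, range-standardization coincides
with division by the maximum. Degenerate margins ($R = 0$ or $R = N$,
where the maximum is 0) are defined to give standardized score 0 rather
than NaN; such OTUs never pass screening anyway. The alternative
normalization $C / (R_i R_j)$, $T / (R_i R_j)$ used by some software is
available via `normalize = "product"`; for pairs with
$R_i + R_j \le N$ (the common case in sparse matrices) the two agree
for $C$ but not for $T$.

### Screening

Randomization tests on pairs with small counts are nearly powerless —
their null score distributions pile up on the extremes — so pairs are
screened before testing: per-host analyses use OTUs in ≥ 5 samples and
pair occurrence sums ≥ 25; pooled analyses use ≥ 10 and ≥ 50. Both
thresholds are arguments, not constants.

## Null models and testing

The default null is **fixed-fixed**: uniform over binary matrices with
the observed row sums (per-sample richness) and column sums (per-OTU
occupancy). It is the conservative standard for C-score analyses
because it tests association *given* both richness differences among
samples and occupancy differences among taxa. Sampling uses the
curveball trade algorithm: repeatedly pick two rows and uniformly
reshuffle the columns held by exactly one of them. The chain runs with
burn-in $5 \times \mathrm{fill}$ and thinning $\mathrm{fill}$ trades
between saved states (fill = number of ones), defaults chosen because
curveball mixing time scales with fill; at these defaults the lag-1
autocorrelation of the community mean standardized score is
indistinguishable from zero in the suite's diagnostics. Alternative
nulls (`fixed_fill_equiprobable`, `fixed_rows`) are available for
sensitivity analysis. The sampler has its own xoshiro256++ RNG stream,
so ensembles are bit-reproducible from an integer seed regardless of
R's RNG state, and the streaming and materialized code paths traverse
the identical chain.

Correctness is verified against an exact oracle:
`enumerate_margin_space()` lists every matrix with a given margin
signature (with a hard cap), and the test suite checks both that
curveball draw frequencies are uniform over enumerable supports
(chi-square, α = 0.01) and that Monte-Carlo pair P values track exact
enumeration probabilities within ±0.02 at M = 10,000.

### Tests

- **Per-pair tests** are one-sided in the upper tail — large $C_{std}$
  means segregation, large $T_{std}$ aggregation — matching the
  interpretation of each score; $P = (1 + b)/(1 + M)$ includes the
  observed matrix, guaranteeing a valid positive P. Ties are counted on
  the raw integer scores, which is exact. Benjamini–Hochberg FDR
  adjustment is applied separately within each (dataset, score-type)
  family.
- **Community tests** average the standardized score over all unordered
  pairs of OTUs present in a subset (a phylum, a guild, or everything),
  without per-pair screening — these are whole-community descriptions,
  not per-pair inferences — and report the one-sided P and
  $SES = (\mathrm{obs} - \mu_{null})/\sigma_{null}$. Screened-pair
  subsets can be passed explicitly for sensitivity.
- **Host-contrast test**: for each pair eligible (per-host screening)
  in both host datasets, $\Delta = score_{A} - score_{B}$ of the
  standardized scores, tested two-sided against the null obtained by
  permuting host labels over samples with group sizes preserved — the
  minimal exchangeability assumption, since no more specific
  randomization scheme is implied by the analysis design. One-sided
  variants were considered and rejected: the question is whether hosts
  differ, not in which direction.

P values below the permutation floor $1/(M+1)$ are impossible by
construction; with the default $M = 10^4$ (configurable to $10^5$) the
resolution is stated in the output's `M_used`.

## Supporting statistics

The diversity/spatial layer delegates to the field-standard
implementations and keeps a uniform interface: sample-based rarefaction
(Mao Tau, exact hypergeometric form; checked against a random-subset
resampling oracle), Raup–Crick dissimilarity (occupancy-weighted,
richness-preserving "r1" null communities simulated through vegan, with
the tie-split probability \eqn{D = [\#\{S_{null} > S_{obs}\} +
0.5\,ties]/reps} computed in-package — splitting ties is what makes 0.5
the exact chance level in sparse matrices, where tied shared counts are
common; verified on data assembled by the null process itself), Mantel
correlograms in 2 m distance classes
with progressive Holm correction, Moran's I with inverse-distance
weights and exact expectation $-1/(n-1)$, PERMANOVA (pseudo-F, $R^2$),
PERMDISP on distances to group centroids with the negative-eigenvalue
correction, the CLAM multinomial specialist/generalist classification
(supermajority 2/3, α = 0.001, coverage limit 10), and the Welch
richness t-test. CLAM operates on occurrence counts (samples occupied)
rather than reads, consistent with a presence/absence analysis;
read-count mode is an argument. Moran's I weights are not
row-standardized (the conventional default of the implementation the
field uses); coincident sampling points are an error with advice rather
than a silent adjustment.

## The synthetic generator

`simulate_community()` emulates the features of such surveys that the
analysis is sensitive to, with ground truth recorded exactly:

- **Occupancy**: per-OTU occurrence probabilities drawn from a beta law
  (long-tailed by default) or fixed; empirical occupancies calibrate
  within binomial bounds.
- **Couplings**: designated OTU pairs are drawn from the exact bivariate
  Bernoulli law with given marginals and presence odds ratio ψ (the
  closed-form root of the standard quadratic, verified against an
  independent root-finder). Pairs are disjoint so the joint law stays
  exact without a full graphical model; ψ > 1 plants aggregation,
  ψ < 1 segregation, and a coupling can be restricted to one host.
- **Host effects**: per-OTU log-odds shifts by host group.
- **Spatial structure**: a latent Gaussian field with exponential
  distance-decaying correlation added on the log-odds scale, one range
  and one scale parameter — enough to produce short-range Mantel /
  Moran's I autocorrelation.
- **Reads**: present OTUs receive $1 + \mathrm{NB}(\mu, k)$ reads, so
  the 20-read and 5% filters have non-trivial effects.
- **Placement**: samples sit on a jittered 2 m grid in a 300 m × 200 m
  rectangle, guaranteeing the ≥ 1 m minimum spacing of a field survey.

`emulate_study_shape()` is a preset with the shape of the motivating
survey — 249 + 188 samples, 319 OTUs, occupancy beta(3.2, 250), spatial
range 6 m — chosen so that after filtering, mean per-sample richness is
near 3.5 and roughly 34 OTUs occur in ≥ 10 samples. What the generator
does **not** emulate: phylogenetic structure, taxonomic identity
(guild labels are arbitrary), read-depth covariance with richness,
chimeras/contamination beyond a boolean flag, and OTU-clustering
artifacts. Passing tests on this generator therefore validate the
statistical machinery, not any claim about real fungal biology.

## Validation design and problem sizes

The acceptance suite exercises, at desk scale: the exhaustive score
grid ($N \le 12$); sampler-vs-enumeration uniformity and P-value
agreement; type-I error of the pair tests on 500 independent-OTU
matrices (200 samples × 30 OTUs, M = 2,000) with the rejection rate at
α = 0.05 required ≤ 0.07 for both scores; recovery of planted ψ = 8
(aggregation) and ψ = 1/8 (segregation) pairs as top-ranked hits in
≥ 80% of 200 replicates (400 samples, 30 OTUs, planted occupancy 0.2);
host-contrast validity (nominal rejection under shared couplings) and
detection of a host-specific ψ = 8 coupling (200 replicates, 200
samples per host); and the diversity-layer oracles. The acceptance
script reruns scaled versions of the same simulations (60–120
replicates, M = 1,000) so a full pass stays inexpensive; replicate
counts, not thresholds, are what scale.

Detection is defined as the planted pair's P being ≤ every other
pair's P for the corresponding score (ties at the permutation floor
count as detection, since rank among tied minima is arbitrary).

## Known limitations

- The host-contrast (Δ-score) test has limited power at realistic
  occupancies: with ~400 screened competitor pairs the smallest
  competing P is typically ≈ 1/400, so the planted pair must reach the
  permutation floor to rank first, and the binomial sampling noise of
  its realized co-occurrence count leaves a substantial fraction of
  replicates short of that even for ψ = 8 at occupancy 0.2 and 200
  samples per host. The test itself is valid (nominal under the null);
  it is rank-1 detection that is fragile. This mirrors the motivating
  analysis, which found no significant host effects.
- Community-level mean scores weight every pair equally; a few
  high-occupancy pairs can dominate SES.
- The curveball chain is a heuristic MCMC: uniformity is proven
  asymptotically and verified empirically on enumerable supports, but
  thinning adequacy on much denser matrices than tested here should be
  re-checked via the lag-1 autocorrelation diagnostic.
- Raup–Crick, PERMANOVA and PERMDISP inherit the behaviors of their
  vegan implementations (e.g. tie splitting, permutation schemes).
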