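---
title: "Models and methods in ssrdiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in ssrdiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The inference problem

`ssrdiverge` implements a complete inference stack for studying
ecological speciation between two closely related plant species from
diploid microsatellite (SSR) genotypes. The study design it targets is
two recently diverged, partly sympatric island endemics sampled at
five sites (two populations of one species, three of the other; 10,
19, 22, 15 and 15 diploids) and genotyped at 19 SSR loci. The
questions the stack answers, in order:

1. Which loci behave neutrally and which are selection outliers?
2. How is genetic variance partitioned within and between the species
   (diversity statistics, hierarchical AMOVA)?
3. How many genetic clusters are there and do they coincide with the
   species (admixture clustering, Evanno's delta-K, DAPC)?
4. Which divergence scenario — complete isolation (CI), ancestral
   migration (AM), secondary contact (SC) or continuous migration
   (CM) — best explains the neutral loci (coalescent simulation +
   ABC model choice)?
5. Do environmental variables explain the genetic structure
   (PCA / Kruskal-Wallis / logistic regression / dbRDA / Mantel)?

Every stage is exercised end-to-end on synthetic data with known
ground truth; no stage requires the original (undeposited) genotypes.

# Data model

Allele states are stored as small positive integers in repeat-count
units (`NA` = missing gene copy). All statistics depend only on
identities and differences of states, so importers may subtract a
per-locus fragment-length offset without changing any result. GenePop
(3-digit diploid codes, `000` missing) and STRUCTURE matrices (1- or
2-row per individual, `-9` missing) are supported; the
population-to-species mapping comes from a sidecar grouping CSV
because GenePop has no species level.

Missing data policy: statistics use pairwise-complete gene copies per
locus; AMOVA drops copies, not individuals.

# Diversity statistics and AMOVA

Per population and locus: `Na` (allele count), `Ne = 1 / sum(p^2)`,
Shannon `I = -sum(p log p)`, observed heterozygosity `Ho`, expected
`He = 1 - sum(p^2)`, unbiased `uHe = 2N/(2N-1) He` with the locus's
non-missing sample size, and the fixation index `F = 1 - Ho/He`.
Loci are averaged with equal weight; the reported SE is the
across-locus standard deviation over the square root of the locus
count. `F` is averaged over polymorphic loci only — a monomorphic
locus carries no information about inbreeding, and the across-locus
mean of per-locus ratios is not the ratio of means.

The AMOVA is a gene-copy-level, two-level nested variance partition
computed from pairwise copy distances (identity distance by default;
squared allele-size distance as an option). Identity distance is the
default because the target design's printed degrees of freedom
(1 / 3 / 157 / 161 for 81 diploids in 5 populations and 2 species)
correspond to copy-level identity AMOVA. Sums of squares use the
frequency shortcut `SS_g = (N^2 - sum(c_a^2)) / (2N)`; variance
components follow the standard unequal-sample-size expected mean
squares. Degrees of freedom and the size coefficients come from the
design copy counts (2 per individual), while per-locus sums of
squares use the actually scored copies — with little missing data
this matches the usual average-over-loci treatment. Negative variance
components are reported raw and flagged, never truncated, so that
arithmetic on published component tables stays exact. When every
species holds a single population the middle level vanishes and its
component is fixed at zero.

Permutation tests permute (a) populations among species (`F_CT`), (b)
individuals among populations within species (`F_SC`), and (c)
individuals among all populations (`F_ST`); p-values are
`(1 + #{F_perm >= F_obs}) / (n_perm + 1)` and reproducible under a
seed. With only five populations the `F_CT` permutation space is
small, which is exactly why the species-level test tends to be
non-significant in this design.

Pairwise population FST uses the same identity partition per pair;
negative pair estimates are truncated to zero (the conventional
reading "no differentiation"), unlike the full AMOVA components.

# FST outlier scan

The outlier model is the multinomial-Dirichlet decomposition of
locus-by-population differentiation: allele counts `n_ij` for locus
`i` in population `j` are multinomial-Dirichlet with parameters
`theta_ij p_i`, where `p_i` are ancestral frequencies,
`theta_ij = 1/F_ij - 1` and `logit(F_ij) = alpha_i + beta_j`. The
locus effect `alpha_i` (selection) is toggled in and out of the model
by a reversible jump against prior odds of 10 for neutrality, which
calibrates the "posterior odds > 10" decision rule; `beta_j` absorbs
demography. Priors: uniform Dirichlet on ancestral frequencies,
Normal(0, 1) on `alpha` and `beta`. Proposals are fixed-scale random
walks (frequencies move by two-allele mass transfer); the
reversible-jump insertion draws `alpha*` from a Normal(0, 1)
independence proposal. A locus monomorphic across all populations is
excluded with a warning.

Per locus the report gives the posterior inclusion probability, the
posterior odds `PO = P(incl)/(1 - P(incl))` (capped at 9999 when the
chain never excludes the locus), the posterior mean `alpha`, and a
q-value computed as the cumulative mean of the sorted posterior
neutrality probabilities. A locus is classified `positive`
(`alpha > 0`, elevated differentiation) or `balancing` (`alpha < 0`)
when `PO > 10` and `q < 0.05`. Default run length is 1e5 iterations
with thinning 1000 after 5e4 burn-in; tests and the validation runs
use 2e4 + 1e4 with thinning 20, which is ample at 50 loci.

# Admixture clustering, delta-K, DAPC

The clustering model is the admixture model with correlated allele
frequencies: cluster frequencies are Dirichlet around ancestral
frequencies with per-cluster drift `F_k`. A Gibbs sweep assigns every
gene copy given `Q` and the frequencies, redraws frequencies from
their Dirichlet full conditional, and redraws `Q` rows from
`Dirichlet(alpha + counts)`; `alpha` gets a Metropolis step with a
uniform prior on (0, 10), the frequency prior `lambda` is fixed at 1,
ancestral frequencies move by Metropolis mass transfer and `F_k` by a
logit random walk with a uniform prior. `lnP(K)` is estimated as the
posterior mean log-likelihood minus half its variance — the estimator
the Evanno delta-K consumes. Default test-scale MCMC is 2e4 sweeps
after 5e3 burn-in (the study scale of 1e6 + 1e5 and 10 replicate runs
is available through the arguments); at the fixture's differentiation
level the chains lock onto the species split within a few hundred
sweeps.

Evanno's table is computed exactly as
`ln'(K) = mean lnP(K) - mean lnP(K-1)`,
`|ln''(K)| = |ln'(K+1) - ln'(K)|`, `deltaK = |ln''(K)| / sd(lnP(K))`,
defined for interior K of a consecutive range with >= 2 runs per K.
If `sd(lnP) = 0`, delta-K is 0 when `|ln''|` is also 0 and infinite
(with a warning) otherwise. Replicate runs are aligned by greedy
column matching that maximizes summed matched-column dot products
before averaging — the small-K regime of CLUMPP-style alignment.

DAPC centers the one-hot allele-count matrix, retains the leading
principal components (2 by default, as in the target design), and
runs linear discriminant analysis on the group labels; group
membership probabilities come from the LDA posterior. A group with a
single individual is rejected because within-group scatter is
undefined.

# The coalescent simulator

Two present demes plus one ancestral deme; time in generations
backwards from the present (the target species are annual herbs, so
generations equal years and no conversion is applied). Within a deme,
lineage pairs coalesce at rate `1/(2N)`; backward lineage migration
runs at the forward immigrant fraction (the standard low-migration
identification) inside the scenario's window: none for CI,
`[t1, t2]` for AM, `[0, t1]` for SC, `[0, t2]` for CM; past `t2` all
lineages share the ancestral deme. Mutations are Poisson on branches;
each moves the allele state by a geometric number of repeat units
(strict stepwise at `p_geom = 0`) in a random direction from
ancestral state 100. There is no allele-range boundary (unbounded
ladder) — a deliberate simplification flagged as a fidelity caveat;
if a walk reaches zero the whole locus is shifted up, which no
statistic can detect. Diploids are formed by pairing copies within a
deme; with probability `f_is` an individual's second copy duplicates
its first, emulating inbreeding with a single parameter (chosen so a
single knob reproduces the high fixation indices of the target
design; it is not a partial-selfing coalescent).

The implementation maintains deme counts incrementally and
precomputes rate-change boundaries, so a locus costs O(events); all
randomness flows through R's RNG, making every simulation
bit-reproducible from `set.seed()`. Calibration anchors: under a
single deme and strict SMM the expected allele-size variance is
`theta/2 = 2 N mu`; between isolated demes the expected
`(delta mu)^2` grows as `2 mu t`; the boundary settings
`AM(t1 = t2)`, `SC(t1 = 0)` and `CM(m = 0)` are distributionally
identical to CI. The test suite checks all of these.

# ABC model choice

Summary statistics per population: mean allele count, mean expected
heterozygosity, mean allele-size variance, mean Garza-Williamson
`M = alleles / (range + 1)`; per population pair: identity FST,
squared difference of mean allele sizes, and the Jaccard proportion
of shared alleles — each averaged over loci (the arlsumstat-style
set; the exact published list lives in an inaccessible supplement, so
this set is declared and configurable). Undefined pairwise FST on
monomorphic comparisons becomes 0 with a warning.

Priors (declared, configurable; the published ones are not
available): `N1, N2, Nanc ~ U(100, 1000)` diploids;
`t2 ~ logU(1e4, 5e5)` generations; `t1 = f t2` with
`f ~ logU(1e-3, 1)`, which enforces `t1 <= t2`;
`m12, m21 ~ U(0, 0.2)`; one `mu ~ logU(1e-4, 1e-3)` shared across
loci. Time scales are scanned on the log scale because what the data
can resolve is the ratio of an epoch boundary to the coalescent
timescale (about `4N` generations), and that ratio spans orders of
magnitude across the prior box: a linear prior on `t1` puts almost
all SC mass on windows longer than the coalescent timescale, making
SC indistinguishable from CM by construction. The log-scale prior is
what gives the four scenarios usable contrast at this design size.

The reference table is Box-Cox transformed per statistic (profile
likelihood on a shifted positive variable), standardized, and reduced
to five partial-least-squares components fitted on the pooled
all-model reference — model choice needs one common projection;
per-model PLS can be used for parameter estimation. Rejection keeps
the `n_keep` nearest simulations per model (Euclidean distance in
component space, ties by row order). The marginal density follows the
ABC-GLM contract: a multivariate linear model
`stats = c + B theta + eps` fitted on the retained rows, residual
covariance `Sigma` (ridge-jittered if singular, with a message), and
`MD = mean_i Normal(obs; c + B theta_i, Sigma)` over the retained
prior draws. The same per-draw likelihoods act as importance weights
for posterior summaries: KDE-argmax mode on a 512-point grid,
weighted median, and shortest-interval HPDs at 50% and 95%. Relative
densities normalize the per-model MDs to percentages; Bayes factors
are their ratios.

Scale choices: the validation runs use 5,000 simulations per model
with the best 1,000 retained (20%, the scaled-down analogue of a
best-5,000-of-a-million analysis); `n_keep = 5000` is the function
default for larger references.

# Environment association

`vif_prune` iteratively drops the variable with the largest variance
inflation factor until all are below 10 (exact collinearity gives an
infinite VIF and goes first; ties break by column order).
Environmental PCA standardizes the variables (correlation-matrix
PCA). Species differences along axes use the Kruskal-Wallis rank test
with tie correction; per-variable axis regressions are ordinary least
squares of each variable on the two leading ordination axes, with
the model-level adjusted R², F and p. The multivariate logistic
regression is a maximum-likelihood IRLS fit; perfect separation is
detected (vanishing deviance or non-convergence) and flagged rather
than silently returned.

The constrained ordination is dbRDA: Euclidean distances on the
genetic response (the two leading principal components of the one-hot
allele-count matrix), principal-coordinate decomposition, and
redundancy analysis on the standardized predictors. For Euclidean
distances this is exactly an RDA on the response matrix — the
published phrase about "transforming the constrained variables to
Euclidean distance" is internally ambiguous, and this is the coherent
reading that reproduces the named method (vegan's `dbrda` supplies
the decomposition and the marginal — type II — permutation tests;
Ezekiel's formula gives the adjusted R²). Individuals inherit their
population's environmental values through an explicit join, because
environment is measured per site. With five sites the predictor
matrix has rank at most four, which is why the pipeline drops one of
the five variables (the design's rain-season precipitation variable)
— the same constraint that forced the original design to discard a
predictor. Mantel tests correlate off-diagonal distances with
row/column permutations of one matrix.

# Synthetic data: what it emulates, and what not

`make_genotype_fixture` simulates the 15 neutral loci under an AM
scenario with `t2 = 1.1e5` generations, `t1 = t2/2`,
`m12 = m21 = 0.1`, `N = 300` per deme, `mu = 5e-4`, strict SMM and
`f_is = 0.6`, mapped onto the five named populations. These settings
put the realized per-population expected heterozygosity inside the
target band 0.23–0.37 (theta = 4 N mu = 0.6 gives He around 0.33
under SMM) and the fixation index inside 0.39–0.73 (dominated by the
duplication probability); the generator re-simulates up to five times
and raises an error with the realized values if a band stays
unreachable (e.g. at `mu = 0`). Point estimates reported for designs
of this kind can place the mode of `t1` above that of `t2` even
though the scenario itself requires `t1 <= t2` (medians typically
respect it); the fixture stays on the `t2` scale of the emulated
design and sets `t1 = t2/2`.

Planted outliers are frequency-shift constructions, not selection
simulations: three fully homozygous, group-diagnostic loci (two
split by species, one also splitting the first species' populations,
mirroring the reported outlier pattern) and one balancing-type locus
with identical intermediate frequencies everywhere. The labels
describe what the scan should find, not a biological mechanism.

`make_env_fixture` draws the five named variables (alt, AET, bio3,
bio13, bio14) from a multivariate Gaussian with a compound-symmetric
correlation of 0.25 and shifts the species means by 2.2 SD units
along the equal-loadings combination, so that no single variable
separates the species but the leading principal component does — the
qualitative pattern the logistic-regression table of the target
study shows. Occurrence counts default to 23 + 16, the study's
retained record counts. `make_occurrence_fixture` plants in-cell
duplicate records for the grid-deduplication step.

What the fixtures do **not** emulate: real SSR allele-range limits,
null alleles and genotyping dropout, linkage, population-specific
inbreeding, spatially structured environments, and selection as a
process. Passing tests therefore demonstrate internal correctness
and statistical behaviour at the study's design size, not field
realism.

# Numerical and scale choices

- Every stochastic routine takes a `seed` and draws exclusively from
  R's RNG (including the C++ cores), so results are bit-reproducible.
- Validation problem sizes, chosen to probe the study scale while
  staying light: ABC recovery uses 5,000 reference simulations per
  model and 10 pseudo-observed datasets per scenario; the SMM
  calibration uses several thousand replicate loci (Monte Carlo SE
  about 1–2%); the outlier calibration uses 50 neutral island-model
  loci at FST 0.05 with a 2e4-iteration chain; delta-K uses 10 runs
  per K over K = 1..4 at 1e3 + 4e3 sweeps.
- The q-value construction guarantees monotonicity in the posterior
  odds ranking; the PO cap (9999) marks loci the chain never
  excluded.
- Permutation p-values are lower-bounded by `1/(n_perm + 1)`.
- The Box-Cox shift guard maps non-positive observed values slightly
  inside the support rather than failing on out-of-range pseudo-data.

# Known limitations

- The two-deme simulator treats populations within a species as
  samples from one deme; within-species population structure in the
  fixture therefore comes only from sampling noise.
- Backward migration equals the forward immigrant fraction; at the
  top of the migration prior (0.2 per generation) this
  identification is rough.
- CM and SC (and CI and AM) overlap by construction; model choice
  between them rests on prior mass, so recovery rates depend on the
  declared priors — see the prior discussion above.
- The admixture sampler does not correct for within-chain label
  switching; at the differentiation levels tested the chains do not
  switch, but close to `F_ST = 0` the posterior mean Q is attracted
  to uniform.
- The marginal and relative densities and posterior modes reported
  for the emulated study require its original (undeposited) genotypes
  and a reference table of millions of rows; they are design anchors
  here, not reproduction targets.
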