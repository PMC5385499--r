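---
title: "Methods: population genetics of partially clonal, subdivided populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: population genetics of partially clonal, subdivided populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

clonepop analyses diploid microsatellite genotypes from organisms that mix
sexual and asexual reproduction and live in subdivided habitats — the
motivating case is deep-sea corals sampled across seamounts, where a sled
sample can contain many fragments of one clonal colony and where populations
a few hundred metres apart can be genetically isolated. This vignette
records the models the package implements, the tunable parameters and their
defaults, the numerical choices made where the design was genuinely open,
and what the synthetic-data tests do and do not demonstrate about real data.

## Data model

A `genotype_table` holds unordered diploid allele calls (integer fragment
sizes, bp) for individuals at microsatellite loci, plus a site assignment
per individual. Missing data are per individual and locus (the GenePop
all-zero convention); half-calls are not representable. GenePop 2- and
3-digit codings are auto-detected on read; 3-digit is written by default
because fragment sizes run to several hundred bp. Pop blocks are anonymous
in GenePop, so a sidecar CSV supplies site names, seamount and region
membership, coordinates, depth, depth stratum and a fished/unfished flag.
Depth strata are carried as metadata rather than derived from depth,
because survey strata typically have gaps between them.

Fragment-size binning (`bin_alleles`) snaps every allele to the lattice
anchored at the locus's modal raw size with spacing equal to the repeat
unit; ties round toward the anchor. This reduces a fragment-binning program
to a deterministic rounding rule: adequate for jitter of up to half a
repeat unit, not for stutter or dye-shift artefacts.

## Clonality

Two individuals share a multilocus genotype (MLG) iff they agree at every
locus scored in both, each has at most `max_missing = 1` missing loci, and
matching is closed transitively. The wildcard tolerates the dropout typical
of sled-collected material; transitive closure means an individual missing
one locus can bridge two complete profiles. Individuals with more missing
loci are kept as flagged singletons rather than guessed.

For a repeated MLG, `P_gen` is the random-mating probability of its
genotype from the site's allele frequencies computed on the full,
unclone-corrected sample (frequencies before condensation are the relevant
reference, since the question is whether the repeats could be independent
sexual recruits); `P_sex` is the binomial tail
`Pr[X >= k - 1], X ~ Bin(N - 1, P_gen)` for an MLG of `k` copies in a
sample of `N` — the tail form generalises to the 10–15-member clones seen
in heavily clonal corals. Genotypic richness is `R = (G - 1)/(N - 1)`.
Clone condensation keeps, per site, the lexicographically smallest
individual id of each MLG, a deterministic choice that makes downstream
permutation tests reproducible.

## Diversity and Hardy–Weinberg testing

Per site and locus the package reports observed heterozygosity, Nei's
unbiased expected heterozygosity `(2n/(2n-1))(1 - sum p^2)`, Weir &
Cockerham's f (F_IS) from the b and c variance components, rarefied
allelic richness `A_r(g) = sum_i [1 - C(2n - N_i, g)/C(2n, g)]` (the
FSTAT-style estimator; `g` defaults to the smallest per-site gene count in
the comparison), and private-allele counts.

The exact HWE test is the probability-test variant: conditional on allele
counts, the p-value is the total Levene probability of genotype tables no
more probable than the observed one. It is estimated with a
Guo–Thompson-style Markov chain whose proposal re-pairs the four alleles of
two randomly chosen individuals. Because several proposal routes can merge
on the same table when genotypes repeat, the sampler uses the full
Metropolis–Hastings correction with explicit proposal multiplicities; the
chain was validated against full enumeration, which is also exported
(`exact_hwe_enumerate`) for biallelic loci. Defaults: 10,000 estimation
steps after 1,000 dememorization steps, seeded; the Monte-Carlo standard
error is reported from batch means. Bonferroni correction uses one family
per dataset (all defined locus-by-site tests); undefined (monomorphic)
tests are flagged and excluded from the family count, which is why a
survey's reported test count can be smaller than sites times loci.
Fished-versus-unfished diversity comparisons are one-way fixed-effects
ANOVA on per-site rarefied richness and expected heterozygosity.

## Null alleles

The per-site, per-locus null frequency estimate is
`r = (He - Ho)/(1 + He)`, truncated at zero. Under the masking model the
simulator (and, we assume, nature) applies — null/visible heterozygotes
read as visible homozygotes, null/null as missing — this estimator's
large-sample value is `2 r He /((1 + r)(1 + He))`, a mild underestimate
(about 0.15–0.16 when the true frequency is 0.2 at He near 0.9); the
Chakraborty variant `(He - Ho)/(He + Ho)`, exact under that masking model,
is available via `method = "chakraborty"`. A locus is flagged when `r`
exceeds 0.05 in a majority of the sites where it is polymorphic. The
correction recodes, per site and visible allele, the expected fraction
`2r/(p_a + 2r)` of apparent homozygotes as heterozygous for a synthetic
null allele labelled one repeat unit above the largest observed allele
(shifting further on collision). Which individuals are recoded is chosen
deterministically under a seed; the exact recoding rule of the original
desktop program is not documented at this granularity, so this
reconstruction is our own and is labelled as such. Downstream analyses are
run on both raw and adjusted data whenever a locus is flagged.

## Differentiation

Weir & Cockerham's theta is computed from the a, b, c variance components
per allele and locus and combined by summing components. Hedrick's G'_ST
and Jost's D use Nei–Chesser sample-size-corrected H_S and H_T; G'_ST
combines loci by averaging H_S and H_T, D by the harmonic mean of
per-locus values (falling back to the arithmetic mean, and saying so, when
some per-locus D are non-positive, where the harmonic mean is undefined).
Raw, possibly negative estimates are stored; display tables floor at 0.000
and star permutation significance. Significance permutes individuals among
groups with sizes fixed, `p = (1 + #{perm >= obs})/(1 + n_perm)`, default
9,999 permutations for pairwise tables.

AMOVA uses allele-mismatch distances (0/1/2 per locus) in an
Excoffier-style two-level design (seamounts / sites / individuals), with
level-appropriate permutation schemes: whole sites among groups for
Phi_CT, individuals among sites within groups for Phi_SC. A degenerate
hierarchy (one site per group) collapses to the single-level model, with
Phi_SC flagged undefined. Stepwise-weighted distances (R_ST-style) are
deliberately out of scope. PCoA is Gower double-centering with a
deterministic sign convention (first nonzero loading of each axis
positive). The Mantel test of isolation by distance uses haversine
great-circle distances (Earth radius 6371 km) and vegan's one-tailed
matrix permutation; Rousset's `F_ST/(1 - F_ST)` linearization is an
option, off by default because the emulated study's wording implies raw
F_ST.

## Gene flow and effective size

`nem_wright` implements `N_e m = 1/F_ST - 1` verbatim as the headline
form, with the textbook island-model rearrangement
`(1 - F_ST)/(4 F_ST)` behind `form = "island"`. The two differ by about a
factor of four at small F_ST, and published summaries are not always
consistent with either exactly; the package therefore reports the formula
it used and leaves reconciliation to the analyst. The private-allele
method inverts Slatkin's log-log regression of mean private-allele
frequency on `N_e m`, using the published coefficients for reference
sample sizes 10, 25 and 50 with log-linear interpolation at the data's
mean sample size.

LD-Ne follows Waples & Do: Burrows' composite disequilibrium over all
locus and allele pairs (alleles below frequency 0.02 excluded, the common
desktop default), the Waples small-sample expectation
`E[r^2] = 1/S + 3.19/S^2` (S >= 30) or `0.0018 + 0.907/S + 4.44/S^2`
(S < 30), and the matching quadratic inversion to N_e, with non-positive
drift components reported as infinite — the expected behaviour for very
large populations, which is a finding, not a failure. The confidence
interval is parametric (chi-square on the number of allele-pair
comparisons, which overstates independence and so narrows the interval;
jackknife alternatives are out of scope).

## Clustering

`fit_admixture` is a Gibbs sampler for the admixture mixture model:
independent Dirichlet(1) priors on per-cluster allele frequencies, latent
cluster assignments per allele copy, per-individual ancestry
q ~ Dirichlet(alpha) with alpha learned by a Metropolis random walk
(uniform(0,10) prior), and a no-admixture variant assigning whole
individuals. The correlated-allele-frequencies prior of the classic
desktop program is deliberately not reproduced: the package's accuracy
surface is recovery on simulated data, not replication of that program's
runs. L(K) is reported as the posterior mean data log-likelihood (no
harmonic-mean correction). Replicate runs are label-aligned by greedy
column matching of Q to the first replicate; Evanno's
`deltaK = |L(K+1) - 2L(K) + L(K-1)|/sd(L(K))` and the L(K) maximum are
both reported and no single K is auto-selected, because the two criteria
can legitimately disagree (they did in the emulated study, K = 2 vs
K = 3). Desk-scale MCMC defaults are burn-in 5,000 and 50,000 iterations;
the tests use shorter, validated settings (hundreds of burn-in sweeps
suffice for the clean two-deme recovery cases).

## The simulator

`simulate_population` is a forward-time model with non-overlapping
generations and constant deme sizes. Each offspring is, with probability
`c`, an exact clonal copy of a uniform resident (lineage id inherited, no
somatic mutation, so MLG ground truth is exact); otherwise two parents are
drawn independently through the column-stochastic migration kernel
(gametic migration, which gives the standard island-model calibration) and
contribute one gamete each with symmetric stepwise mutation at rate `mu`,
bounded so fragment sizes stay within 3-digit GenePop coding. Null alleles
are heritable allelic states seeded at a configured founder frequency, so
their realised population frequency is well defined for recovery tests;
masking happens only at emission. Everything is deterministic given the
seed.

Two presets bracket the study system the package emulates: a strongly
clonal, differentiated species (9 demes, c = 0.5, one null-prone locus,
kernel migration 0.06 — calibrated so that equilibrium pairwise theta
spans roughly 0.04–0.23; clonality suppresses effective gene flow, so the
kernel rate sits well above the sexual-only island-model value) and an
essentially sexual, depth-stratified one (three stratum blocks with free
within-stratum and near-zero between-stratum migration, c = 0.005).

One structural consequence of non-overlapping generations deserves
emphasis: clone families are short-lived (a lineage shrinks by the factor
`c` per generation in expectation), so the probability two sampled
individuals are clonemates is approximately `c^2 /((1 - c^2) N)` and
genotypic richness at c = 0.5 cannot drop much below ~0.85 however the
other parameters are set. Real coral surveys report far lower R because
colonies persist across many reproductive seasons and fragment; emulating
that would require overlapping generations, which this simulator
deliberately omits. Tests on the clonal preset therefore assert
directionality and bounds, not the survey's absolute R level — the
absolute level is exercised through the published count table instead.

What the simulator does not emulate: overlapping generations, selection,
scoring error other than null alleles (no stutter or dropout), somatic
mutation within clones, and hydrodynamically structured dispersal. Passing
recovery tests therefore shows the estimators are correct under the
stated model, not that real coral data meet that model.

## Study conditions used by the verification suites

These problem sizes were chosen once, as the package's desk-scale
emulation of the relevant theory, and the tests assert against them:

* Island-model calibration: 16 demes of N_e = 50 (the `1/(1 + 4N_e m)`
  target assumes the many-island limit; with d demes the equilibrium is
  depressed by roughly `(d/(d-1))^2`, so few-deme designs fail the target
  for reasons that have nothing to do with the estimator), mutation
  5e-4, 10 N_e generations from a common founder pool, 25 sampled per
  deme, 20 replicates per migration level.
* LD-Ne recovery: true N_e = 50 sampled exhaustively (n = 50), 9 loci at
  mutation 5e-3 — the upper end of published microsatellite stepwise
  rates, chosen so desk-scale loci carry allele numbers comparable to
  highly polymorphic survey loci; replicate estimates are combined by the
  harmonic mean with infinite estimates contributing zero, the standard
  convention for this estimator.
* Clustering recovery: two demes of N_e = 100 at migration 0.005, which
  equilibrates near theta = 0.15; four replicate runs per K over
  K = 1..4.
* Null-allele recovery: a 15-allele visible spectrum (He near 0.9,
  matching highly polymorphic survey loci) with a true null frequency of
  0.2 at one locus of nine, n = 200.
* Permutation calibration: 1,000 panmictic datasets of n = 100 at 5 loci,
  199 permutations each; the rejection rate at 0.05 is checked within
  plus or minus 0.015.

## Numerical choices and degenerate inputs

Monomorphic loci make HWE tests, F_IS denominators and null estimates
undefined; they are flagged, never zero-filled. Theta on a dataset with no
variation anywhere is an error. Negative variance components are retained
in stored estimates (they carry information about sampling noise) and
floored only in display. Permutation p-values use +1 smoothing so p = 0
never occurs. The Evanno statistic is undefined wherever the replicate
standard deviation is zero (e.g. identical seeds), and is reported as such
rather than patched.

## Known limitations

The admixture sampler can label-switch within a single long run at very
weak structure (alignment happens only across replicates). The chi-square
LD-Ne interval is anti-conservative. The Oosterhout-style null adjustment
is a reconstruction, not a byte-level reimplementation of the original
desktop tool. P_gen uses uncorrected HWE frequencies, so it overstates
sexual probability in inbred populations — conservative for declaring
clones, which is the direction a cautious analyst wants.
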