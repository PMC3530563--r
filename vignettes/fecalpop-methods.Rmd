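---
title: "Non-invasive population genetics with fecalpop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-invasive population genetics with fecalpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fecalpop` implements the inference chain of a non-invasive (faecal
DNA) population-genetic survey of a subdivided large-mammal
population: replicate microsatellite genotypes are collapsed to
reliable consensus genotypes, samples are matched into unique
individuals, and the resulting individual-level data feed diversity
and differentiation statistics, a haplotype phylogeny, model-based
clustering, and source-population assignment for a recently founded
(colonist) group. This vignette documents the models, the parameters
that matter, the synthetic-data generator used to validate every
stage, and the design decisions taken where the design was genuinely
open.

## 1. The error model for faecal genotypes

Faecal DNA is degraded and dilute, so a single PCR is untrustworthy.
The package uses the standard two-parameter error model for
non-invasive genotyping. In each replicate amplification of a true
genotype $(g_1, g_2)$:

* each allele copy *drops out* independently with probability $d$
  (a heterozygote then appears homozygous, or as a half-call);
* with probability $f$ one surviving call is replaced by a uniformly
  chosen *false allele* from the locus's allele ladder;
* if both copies drop, the reaction fails.

Defaults are $d = 0.2$ and $f = 0.05$ per replicate. Field studies of
this kind rarely publish their realised error rates, so these defaults
are conventions chosen at the upper-middle of the range reported for
faecal microsatellite work; both are configuration values
(`sim_config()`), and `estimate_error_rates()` recovers them from
replicate data, so no downstream result depends on the defaults being
correct.

### Consensus calling (multiple-tubes rule)

`call_consensus()` applies the multiple-tubes acceptance thresholds: a
heterozygote is accepted once both alleles are observed *together* in
at least `het_threshold = 2` replicates; a homozygote once its single
allele is observed in at least `hom_threshold = 5` replicates *and is
never contradicted* by any other allele. Alleles seen only once are
putative false alleles: they can never enter a call, but a singleton
does contradict a homozygote — the conservative reading, since a
contradicted homozygote is exactly the configuration dropout plus a
false allele produces. Samples whose loci all fail are discarded and
reported.

### Genotype reliability

`genotype_reliability()` scores each called locus by the posterior
probability that the call is the true genotype, given every replicate
outcome under the error model. The candidate truth set is restricted
to genotypes composed of the alleles observed at that sample-locus
plus one "unseen allele" pseudo-candidate: a full allele-space
enumeration adds only candidates whose likelihood is dominated by the
dropout-driven ones, and is numerically unstable for ladders with many
alleles. The prior over candidates is uniform; a frequency-weighted
prior would require population allele frequencies, which are not yet
estimable at this stage of the pipeline (individuals are not yet
identified). A sample's reliability is the product over its called
loci, and samples below 0.99 are flagged for further replication.
Reliability is applied per locus and multiplied per multilocus
genotype; the per-locus posteriors are exposed so users can audit the
calibration (the test suite checks that among loci with posterior
$\approx r$ the empirical accuracy is $\approx r$).

### Error-rate estimation

`estimate_error_rates()` fits $d$ and $f$ by maximum likelihood to the
*full* replicate data, marginalising the unknown truth of every
(sample, locus) over a candidate set built from its observed alleles,
with a jointly estimated heterozygosity nuisance parameter. An earlier
design conditioned on the consensus call and treated it as truth; that
is simpler but biased low (loci that suffered more dropout are more
likely to have failed the thresholds and be excluded — survivorship
bias of roughly $-0.04$ at $d = 0.2$), which is why the marginalised
form is used. The surface can be multimodal on very small inputs, so
the optimiser is multi-started. With simulation truth available the
function returns plug-in empirical rates instead.

## 2. Identity: from samples to individuals

`probability_of_identity()` evaluates, per locus and cumulatively, the
probability that two random individuals (under Hardy–Weinberg) or two
full siblings share a multilocus genotype:

$$P_{ID} = \sum_i p_i^4 + \sum_{i<j}(2p_ip_j)^2, \qquad
P_{IDsib} = 0.25 + 0.5\sum_i p_i^2 +
0.5\Bigl(\sum_i p_i^2\Bigr)^2 - 0.25\sum_i p_i^4.$$

With twelve loci of six to seven alleles each, the cumulative
$P_{IDsib}$ is well below $10^{-3}$, so identical genotypes can safely
be collapsed into recaptures.

`match_samples()` builds a graph over samples. An edge requires
genotypes identical at every mutually called locus, with at least
`min_shared_loci = 8` loci compared — the minimum bounds the
false-merge probability when some loci fail. For populations sampled
exhaustively (where recaptures are common and dropout-induced
one-allele differences are expected), a second rule merges samples
that differ by exactly one allele at exactly one locus *and* match in
sex. The mismatch is counted in alleles, not loci: $(a,b)$ vs $(a,a)$
and $(a,b)$ vs $(a,c)$ both qualify, because a single dropout (or a
single miscalled allele) produces either; the merge log records which
case occurred. Known-sex conflicts always block a merge, and by
default so do mtDNA haplotype conflicts — identical nuclear genotypes
with different maternal haplotypes indicate a coincidence or an error,
and are reported as QC conflicts rather than silently merged.
Individuals are connected components, and each individual's genotype
is re-called from its pooled replicates.

Molecular sex (`assign_sex()`) follows the asymmetry of Y-band
dropout: two two-band replicates confirm a male (dropout cannot create
a Y band), three one-band replicates with no two-band observation
confirm a female, anything else is unknown.

## 3. Diversity and differentiation

`diversity()` reports the mean number of alleles $A$, observed
heterozygosity $H_O$, unbiased expected heterozygosity
$H_E = \frac{2n}{2n-1}(1 - \sum_i p_i^2)$ averaged over loci, and
percent nucleotide diversity $\pi$ (mean pairwise sequence distance).

`hwe_test()` is the conditional exact test on the genotype table given
allele counts — complete enumeration for biallelic loci, Monte-Carlo
re-pairing of the allele vector otherwise; `ld_test()` is a G-test on
the two-locus composite-genotype table with a permutation null;
`bonferroni()` adjusts a p-value family.

Nuclear differentiation uses the Weir–Cockerham estimator $\theta$:
per-allele, per-locus variance components $a$ (among populations),
$b$ (among individuals within populations) and $c$ (within
individuals), combined as $\hat\theta = \sum a / \sum(a+b+c)$.
$R_{ST}$-type allele-size statistics are deliberately not offered.
Mitochondrial differentiation uses the AMOVA $\Phi_{ST}$: the
among-population share of molecular variance from the sum-of-squares
decomposition of squared inter-haplotype distances (Kimura
two-parameter by default). Both tests obtain significance by
permuting individuals between populations; the default is 10,000
permutations with seed-controlled reproducibility, and p-values carry
the $+1$ correction $(b+1)/(B+1)$. Negative estimates are reported as
computed, never truncated: a small negative value is the unbiased
estimator's way of saying "zero, within noise". Identical sequences
collapse to one haplotype after trimming to the common aligned window;
ambiguity codes do not create new haplotypes.

`regional_subdivision()` re-labels one population's individuals by
sampling region and re-runs the pairwise $\Phi_{ST}$ analysis against
the remaining populations — the design used to localise within-park
structure.

When many pairwise tests are reported together, significance should be
judged after Bonferroni correction across the whole reported family
(both marker matrices); the acceptance checks use
$\alpha = 0.05/20$ for the five-population design.

## 4. Haplotype phylogeny

`pairwise_distances()` implements the Kimura two-parameter closed form
$d = -\tfrac12\ln[(1-2P-Q)\sqrt{1-2Q}]$ (transitions $P$,
transversions $Q$), the uncorrected p-distance, and HKY
maximum-likelihood pairwise distances. "HKY distances" here means
HKY-corrected pairwise distances for neighbour joining — the usage of
desktop phylogenetics packages — not a full ML tree search: for each
pair the HKY likelihood (empirical base frequencies; $\kappa$ fixed or
moment-estimated from the alignment-wide transition/transversion
components) is maximised over the single branch length by
one-dimensional optimisation. With $\kappa = 1$ and equal base
frequencies this reduces to Jukes–Cantor, which the tests verify to
$10^{-6}$. Gaps and ambiguity codes are pairwise-deleted; saturated
pairs are capped at 10 substitutions per site with a warning.
Substitution-model selection is a configuration switch, not an
automated step.

`neighbour_joining()` (Saitou–Nei, exact on additive matrices) orders
labels lexicographically before clustering so ties break
deterministically, and clamps negative branch lengths to zero,
recording the clamped total. `bootstrap_support()` resamples alignment
columns, rebuilds the tree, and maps bipartition frequencies onto the
point estimate as percentages. `assign_clades()` gives each query leaf
the clade of its nearest reference by patristic distance — reference
haplotypes with known clade membership anchor new haplotypes into an
existing clade nomenclature — and reports ties rather than resolving
them.

## 5. Admixture clustering and source assignment

`run_admixture_sampler()` is an in-package Gibbs sampler for the
standard Bayesian admixture model (it re-implements the model, it does
not wrap the external program): allele-copy origins $z$ are sampled
from $\Pr(z = k) \propto q_{ik}\,p_{kla}$, cluster allele frequencies
and individual ancestries receive conjugate Dirichlet updates
($\lambda = 1$, $\alpha = 1$ fixed by default with an optional
Metropolis–Hastings update), and the run-level evidence is estimated
as $\ln P(D) \approx \bar L - \operatorname{var}(L)/2$ from the
post-burn-in log-likelihood trace. The optional location prior is a
simplified Dirichlet-mean parameterisation: each sampling location $g$
carries a mean-ancestry vector $\eta_g$ updated by
Metropolis–Hastings, and individuals from $g$ draw
$q_i \sim \mathrm{Dir}(\alpha K \eta_g)$. This is deliberately simpler
than the published location-prior model — its role here is only to
boost clustering power when structure is weak, which the
simplification preserves. Chains are bit-reproducible under a seed.

Documented defaults mirror common practice for weak-structure
microsatellite surveys — $K$ from 1 to 9, 20 replicates per $K$,
burn-in 100,000, run length 1,000,000. The test suite and acceptance
script run desk-scale chains (burn-in 5,000, length 20,000, $K \le 4$,
5 replicates, 100 individuals, 12 loci): at moderate differentiation
the posterior mean ancestries stabilise well before this length, and
the scaled runs keep the whole validation suite inside a desktop time
budget. Label switching across replicates is resolved post hoc by
greedy permutation alignment (`align_qmatrix()`) to the
highest-likelihood replicate.

`evanno_select()` computes
$\Delta K = |\bar L(K{+}1) - 2\bar L(K) + \bar L(K{-}1)| / s_{L(K)}$,
defined only for interior $K$ with at least two replicates; a flat
profile is flagged ambiguous rather than silently resolved.

`assign_source()` ranks candidate source populations per focal
individual by the HWE log-likelihood of the nuclear genotype under the
candidate's (leave-focal-out) allele frequencies, with a rare-allele
floor of $1/(2n+1)$ for unseen alleles, plus an mtDNA component
$\log \Pr(\text{haplotype})$ with a unit pseudocount. Per-marker and
combined rankings are reported. For *side-of-origin* questions under
strong female philopatry the mtDNA ranking is the appropriate
instrument: the maternal haplotype is inherited from the natal side
essentially deterministically, whereas at nuclear $F_{ST}$ near 0.01
the twelve-locus likelihood differences between candidates are smaller
than their sampling noise, so mixing the two markers lets nuclear
noise corrupt an almost-certain maternal signal. The combined ranking
remains the default report for settings where nuclear structure is
informative.

## 6. The synthetic-data generator

`simulate_metapopulation()` generates the study conditions the
analysis assumes: five demes (default sizes 47, 55, 112, 39, 59 —
a community conservation area plus four parks) split by a dispersal
barrier; twelve microsatellite loci with up to seven alleles; a 650 bp
mtDNA control-region fragment. Nuclear structure is parameterised
directly by a target $F_{ST}$ (default 0.01): gene-pool allele
frequencies are Dirichlet-distributed around ancestral frequencies
with concentration $(1-F_{ST})/F_{ST}$, the stationary island-model
approximation, with the $F_{ST} = 1/(1+4Nm)$ mapping available when a
migration rate is given instead. A generation-by-generation
Wright–Fisher run would add runtime without changing what the recovery
tests can detect, so the direct parameterisation is used; the test
suite confirms realised multi-locus $\theta$ is unbiased for the
target. Coalescent-exact microsatellite mutation (stepwise mutation)
is out of scope — frequency-parameterised simulation suffices for
recovery testing.

Mitochondrial structure encodes female philopatry: the two sides of
the barrier carry disjoint haplotype pools (six haplotypes each)
separated by 30 substitutions, with 3 substitutions of within-side
divergence — an order of magnitude apart, mirroring the deep
between-clade split such surveys observe; maternal lineages cross the
barrier with probability `female_migration_rate` (default 0). The
focal deme shares the western gene pool (its animals are recent
colonists from the west), so the generator's default regime exhibits
exactly the published signature: mtDNA $\Phi_{ST}$ one to two orders
of magnitude above nuclear $\theta$, no differentiation between the
two western parks, and focal individuals assignable to the west.

`sample_dung()` adds the observation layer: a shifted-Poisson number
of samples per individual (mean 1.15, raised to 2.8 in the focal deme
to emulate exhaustive sampling — roughly 317 samples for 112
individuals), four PCR replicates per sample per locus under the error
model, with the adaptive multiple-tubes top-up (an unresolved locus is
replicated up to `max_replicates = 8` — heterozygotes need two
concordant replicates, homozygotes five, so fixed four-replicate
designs could never accept a homozygote), and sexing replicates whose
Y band drops with the same $d$.

What the generator does *not* emulate — and hence what passing tests
do not show about real data: PCR stutter and size-shift artefacts,
cross-platform allele binning, null alleles, relatedness structure
within demes (all individuals are unrelated, so the false-merge test
bounds but does not measure sibling collisions), isolation by
distance, and selection. Conclusions about those features need real
calibration data.

## 7. Numerical choices and degenerate inputs

* Permutation p-values use $(b+1)/(B+1)$ and are exact under
  exchangeability; estimates are compared with a $10^{-12}$ slack so
  ties count as "as extreme".
* Monomorphic loci: HWE and LD tests return $p = 1$ with a note;
  loci monomorphic in a comparison contribute nothing to $\theta$; a
  fully monomorphic marker set is an error, not a zero.
* All sequences identical: $\Phi_{ST} = 0$, $p = 1$.
* NJ with one or two taxa returns labelled degenerate trees; equal
  distances resolve deterministically by label order.
* K2P log arguments $\le 0$ (saturation) cap the distance at 10 with
  a warning rather than returning `NaN`.
* The Gibbs sampler guards zero-probability corners (empty Dirichlet
  counts, missing alleles are skipped) and normalises posterior-mean
  ancestry rows exactly.
* Genepop export bins raw bp sizes to rank-ordered integer codes with
  a persisted allele map; half-calls, which Genepop cannot express,
  export as missing.

## 8. Pipeline and reproducibility

`run_pipeline()` executes simulate → consensus → individuals → stats →
phylo → structure → assign with a single global seed; each stochastic
stage derives `seed + offset`, so any stage re-runs in isolation with
identical output. Every stage writes its reports plus a manifest with
md5 checksums; a failing stage halts downstream stages and preserves
partial outputs. Problem sizes in the shipped tests are chosen so the
whole suite validates the full chain on a single CPU in minutes:
dozens-to-hundreds of individuals, hundreds of permutation and
bootstrap replicates, desk-scale MCMC — each scaled quantity is a
parameter, and the defaults for *scientific* quantities (error rates,
deme sizes, locus counts, target $F_{ST}$) are the study conditions,
not test conveniences.

## 9. Known limitations

* The reliability model ignores stutter and platform-specific binning
  error, which real faecal data do contain.
* The location-prior implementation is a simplified Dirichlet-mean
  form; it boosts weak-signal clustering but does not reproduce the
  published location-prior model's $r$ parameter or its
  uninformative-location safeguard.
* `estimate_error_rates()` assumes exchangeable replicates and a
  shared $(d, f)$ across loci and samples; per-locus heterogeneity is
  absorbed, not modelled.
* Hierarchical (multi-level) AMOVA, isolation-by-distance tests and
  migration-rate estimation are out of scope.
* The admixture model uses independent allele frequencies across
  clusters (no correlated-frequencies prior), which is conservative
  for very weak structure.
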