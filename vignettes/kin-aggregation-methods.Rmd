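---
title: "Diagnosing chaotic genetic patchiness through kin aggregation: models and methods"
author: "kinpatch"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing chaotic genetic patchiness through kin aggregation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kinpatch)
```

## The scientific problem

Marine species with pelagic larvae are expected to be genetically
well-mixed over large distances, yet many show *chaotic genetic
patchiness* (CGP): weak but statistically significant differentiation
between nearby samples, no isolation-by-distance structure, and frequent
within-sample departures from Hardy-Weinberg equilibrium (HWE).  One
candidate mechanism is the *kin-aggregation hypothesis*: shoals or
recruitment cohorts contain family groups (full- and half-sibs), so a
geographic sample is a mixture of a few large sibships rather than a
random draw from a panmictic pool.

kinpatch implements the complete chain of analyses used to test this
hypothesis on multilocus codominant (microsatellite) genotypes:

1. per-site, per-locus HWE exact tests and homozygote-excess (U-score)
   Monte Carlo tests, inbreeding coefficients, and a null-allele
   diagnostic regression;
2. pairwise between-site differentiation (the allele-sharing distance
   P\_D and Weir-Cockerham F\_ST) with permutation significance under
   sequential Bonferroni (Holm) correction, and Mantel tests against
   great-circle distances;
3. pairwise relatedness by maximum likelihood on the IBD-coefficient
   simplex, with group means and one-tailed permutation tests;
4. within-site genetic clustering (k-means on principal components of
   allele dosages, model choice by BIC) with discriminant projections;
5. full-sib/half-sib/unrelated dyad classification with an
   exclusion-probability power analysis of the marker panel;
6. sibship networks per cluster, with mean local transitivity tested
   against Erdős–Rényi G(n, m) nulls;
7. a pedigree-structured simulator that generates all of the above with
   known truth.

## Conditional Monte Carlo tests of HWE

Both HWE tests condition on the observed allele counts.  The null is
sampled exactly: the multiset of observed gene copies is shuffled and
re-paired into genotypes, which draws genotype tables uniformly from all
pairings consistent with the allele counts (the Levene distribution).
This is unbiased and, at the sample sizes involved here (tens of
individuals), faster and simpler than a Markov chain over tables.

* The **exact test** orders tables by their conditional probability; the
  p-value is the probability of a table no more probable than the one
  observed (lower tail).
* The **homozygote-excess test** uses U = the number of homozygous
  individuals, upper tail.  This count statistic is monotone-equivalent
  to per-allele weighted homozygote-excess scores for the common
  one-tailed decision; a weighted variant
  (\(\sum_a (O_{aa} - E_{aa})/p_a\)) is available via
  `weighted = TRUE` because the exact functional form of the original
  U-score is a design choice.

All Monte Carlo p-values use the add-one rule \((x+1)/(n_{mc}+1)\) and so
are never exactly zero.  The inner loop is implemented in C++ and driven
by R's RNG, so `set.seed()` governs every replicate.

The within-site inbreeding coefficient is \(F_{IS} = 1 - H_o/H_e\) with
\(H_e\) the plain gene diversity \(1 - \sum_a p_a^2\) from within-site
frequencies.  Its significance is a one-tailed allele-permutation test
(shuffle gene copies within the site-by-locus sample).  Because the
allele counts — and hence \(H_e\) — are invariant under that shuffle,
\(F_{IS}\) is a monotone function of the homozygote count, and the
permutation test coincides exactly with the U-count test's null; the
implementation exploits this identity rather than recomputing
\(F_{IS}\) per replicate.

`locusSummary()` reports Ho, He, allelic richness and missingness pooled
over all individuals by default (one row per locus); whether a published
summary pooled sites or applied a small-sample He correction is often
unstated, so a per-site grouping and an unbiased-He option
(\(2n/(2n-1)\) factor) are both exposed, with the plain pooled version
as default.

## Differentiation

P\_D is defined at the population-frequency level:
\[
P_D(A,B) = 1 - \frac{1}{L} \sum_{l} \sum_a \min(p_{a}^{A}, p_{a}^{B}),
\]
averaged over loci scored in both sites — 0 for identical frequency
distributions, 1 for disjoint allele sets.  The name "proportion of
different alleles" circulates without a standard formula, so the
definition is documented here and kept pluggable.

F\_ST defaults to Weir-Cockerham θ computed as a ratio of sums of
variance components across alleles and loci; a Nei G\_ST-style estimator
is available for sensitivity.  Negative estimates are reported as
computed.  Significance permutes individuals between the two sites of a
pair (preserving sample sizes — a conditional test), with Holm's
step-down across all pairs playing the role of sequential Bonferroni.

Geographic distances are haversine great circles with Earth radius
6371.0088 km.  The Mantel statistic is the Pearson correlation of
lower-triangle entries under simultaneous row/column permutation; 10000
permutations by default, matching the differentiation tests (the
original permutation count is unstated).

## Relatedness: likelihood on the IBD simplex

For a non-inbred dyad the genotype-pair distribution at a locus is a
mixture over IBD modes \(m \in \{0,1,2\}\) with weights
\((k_0, k_1, k_2)\) on the 2-simplex; relatedness is
\(r = k_2 + k_1/2\).  The genotyping-error model is class II: each
observed allele is the true allele with probability \(1-e\), otherwise a
random draw from the locus frequencies.  Because replacement draws come
from the same frequency distribution, an unshared gene copy keeps its
marginal law, and an IBD-linked pair of copies survives observation
jointly with probability \(q = (1-e)^2\), otherwise behaving as two
independent draws.  The likelihood with error is therefore the
error-free likelihood at mixed state probabilities

\[
Q_0 = P_0,\qquad
Q_1 = (1-q) P_0 + q P_1,\qquad
Q_2 = (1-q)^2 P_0 + 2q(1-q) P_1 + q^2 P_2,
\]

which is exact — no enumeration over true genotypes is needed.

**Triadic form.**  The estimator is specified as a triad likelihood
(focal pair plus a randomly drawn reference individual assumed unrelated
to both).  Under this 3-coefficient non-inbred parameterisation with
independent per-individual errors, the triad likelihood factorises: the
reference genotype term does not involve the pair's \((k_0,k_1,k_2)\),
so the triadic and dyadic maximisers coincide and the reference policy
(count, averaging, seed) has no numerical effect.  The implementation
computes the dyadic maximum and records the reference arguments for
interface compatibility.  This is a real difference from triadic
estimators that treat the pair-reference relationships as free nuisance
parameters; its practical consequence is discussed under *Limitations*.

**Optimisation.**  The log-likelihood
\(\sum_l \log(k_0 Q_{0l} + k_1 Q_{1l} + k_2 Q_{2l})\) is concave in
\(k\) (a sum of logs of linear functions), so the constrained maximiser
is unique.  It is found by a vectorised EM for mixture weights
(tolerance 1e-8, up to 2000 iterations, three interior starts retained
as a numerical safeguard; an active-set scheme freezes converged dyads
so slow boundary cases do not stall a batch).  Tests verify the EM
against a dense grid search of the simplex.

Allele frequencies for the estimator are pooled over the full sample by
default, because kin structure inflates within-site frequencies; this is
switchable.  Group mean relatedness \(\bar r\) is the arithmetic mean
over unordered within-group dyads.  The permutation test permutes whole
individuals among groups; since relatedness between two given
individuals does not depend on group labels, the permuted means are
recomputed from the same pairwise matrix — an exact computational
shortcut, not an approximation.

## Clustering

Genotypes are one-hot encoded as allele dosage counts (0/1/2), missing
dosages imputed by the column mean, centred, and projected onto
principal components.  All PCs with positive variance are retained by
default: unlike a discriminant projection, the k-means step does not
overfit with extra dimensions in a way that biases cluster membership,
though it does make the BIC comparison noisier (see *Limitations*).
k-means (50 restarts) is run for every candidate k and model choice uses

\[
BIC(k) = n \ln(W_k / n) + k \ln n,
\]

with \(W_k\) the total within-cluster sum of squares; the selected k is
the argmin.  The published analysis names only the method family
("all possible clustering solutions", minimum BIC), so maximum k
(default 10), retained PCs and scaling (off) are documented defaults
here.  Discriminant projections of the retained PCs on cluster labels
give up to k-1 axes with 67% inertia ellipses; with k = 2 there is a
single axis, suited to a density plot.

## Sibship and exclusion power

Dyads are classified by likelihood under three fixed hypotheses — FS
\((\tfrac14,\tfrac12,\tfrac14)\), HS \((\tfrac12,\tfrac12,0)\), U
\((1,0,0)\) — with the same error model as the relatedness module, a
uniform prior by default, and a 0.95 posterior threshold below which
dyads stay UNASSIGNED.  This is an explicit pairwise-likelihood
replacement for full-pedigree sibship reconstruction: it does not
enforce pedigree consistency across dyads, and avuncular or
grandparent-grandchild pairs share the HS k-vector and are reported as
HS.  Consequently the absolute dyad counts of a full-pedigree method are
not expected to be reproduced; the within-cluster *excess* of sib dyads
is the quantity the permutation test addresses (statistic: FS+HS dyads
fully inside a cluster; individuals permuted among clusters; two-tailed
p by doubling the smaller add-one tail, capped at 1).

The exclusion probability of the panel is the chance that
`groupSize` (default 3) unrelated individuals, drawn error-free from the
allele frequencies under HWE, are *excluded* from a joint full sibship:
a locus excludes the group when no ordered pair of parental genotypes
can produce all members as offspring.  Candidate parents are built from
the alleles observed in the group; this is sufficient because a parental
allele transmitted to some member is observed by definition, and one
transmitted to nobody can be replaced by any observed allele without
breaking compatibility.  Per-locus probabilities are estimated by Monte
Carlo (draws deduplicated up to allele relabelling, so each distinct
genotype pattern is checked once) and combined as
\(1 - \prod_l (1 - E_l)\); the random-subset variant reports the mean
and 2.5/97.5 percentiles over subsets, as used to quantify the power of
reduced panels.

## Networks

Each cluster's sibship graph has individuals as nodes and FS/HS dyads as
edges (the category is an edge attribute; topology does not distinguish
them).  The clustering coefficient is the *mean local transitivity*:
per node, the fraction of neighbour pairs that are themselves connected,
with nodes of degree < 2 contributing 0 — the only convention consistent
with dyad-only clusters reporting 0.000 ± 0.000.  The reported σ is the
standard deviation across nodes (an interpretation; the across-simulations
alternative is easily computed from the test object).  Significance
simulates G(n, m) uniform graphs with matching node and edge counts;
edgeless and complete graphs are degenerate (every replicate identical)
and return p = 1 with a flag.

## The synthetic-data generator

`simulateStudy()` emulates the study design: 9 sites of 34-85
individuals, 2-5 clusters per site of 8-36 individuals, 10 loci whose
allele counts follow the study's richness profile (7-50), per-locus
missingness drawn from 0.06-0.26, and a 1% per-allele genotyping error.
Frequencies are symmetric-Dirichlet per locus (uniform frequencies are
the concentration-to-infinity limit and can be supplied directly);
per-site frequencies are Dirichlet around the global pool with
concentration `siteTheta` (default 30, giving between-site F\_ST around
\(1/(\theta+1) \approx 0.03\), the order of the published pairwise
values).

Two structural choices deserve emphasis:

* **Half-sib predominance.**  Within a cluster, consecutive full-sib
  families share a father with probability `halfSibProb` (default 0.5),
  which reproduces the published predominance of half-sib over full-sib
  dyads.
* **Homozygote excess needs inbreeding, not just families.**  Full-sib
  families of outbred parents do *not* create homozygote excess: each
  offspring carries one independently drawn maternal and one paternal
  gene, so a family sample is marginally in HWE.  Two mechanisms are
  provided.  The default is individual inbreeding: with probability
  `inbreedingF` an offspring's paternal gene copy is identical by
  descent to the transmitted maternal copy, giving expected
  \(F_{IS} = \) `inbreedingF` at the site level with no effect on
  between-site differentiation; the default 0.33 is the median of the
  study-scale published inbreeding coefficients, and the published
  between-site F\_ST magnitude (~0.03) is then matched by `siteTheta`
  alone.  The alternative, `clusterTheta`, draws each cluster's parental
  pool from a Dirichlet around the site pool (a within-site Wahlund
  effect, \(F_{IS} \approx 1/(\theta_c+1)\)); it is off by default
  because, with only 2-5 clusters per site, the same pool variance
  inflates between-site F\_ST several-fold above the published scale.

What the generator does **not** emulate: coalescent history, mutation,
linkage, age structure, genuine consanguineous mating (inbred parents),
and oceanographic dispersal.  Passing tests on simulated data therefore
demonstrate correctness of the statistical machinery under the stated
generative model, not that real data will show the same effect sizes.

Null alleles are modelled as post-hoc masking: each gene copy turns null
independently with the configured frequency; null/null presents as
missing, null/visible as an apparent homozygote.  This reproduces the
diagnostic coupling of missingness and homozygote excess without
modelling null-allele inheritance.

## Numerical choices and degenerate inputs

* Monte Carlo and permutation p-values always use the add-one rule.
* Monomorphic loci: HWE tests return p = 1 flagged `degenerate`;
  \(F_{IS}\) is NA; exclusion probability is 0; such loci contribute
  nothing to F\_ST sums.
* Dyads with no shared scored locus get NA relatedness and are counted;
  dyads under the 3-locus overlap floor are UNASSIGNED in sibship calls.
* Two-tailed permutation p doubles the smaller add-one tail, capped
  at 1 — discrete and conservative when the statistic barely varies.
* Half-missing genotypes are treated as missing with a warning.
* Allele pairs are stored sorted, so genotype identity never depends on
  input order; all estimators are invariant to allele relabelling and
  locus order (tested).
* Per-stage pipeline sub-seeds are `seed * 100 + stage index`, so single
  stages can be rerun bit-for-bit.

## Problem sizes used in the test-suite simulations

Simulation-based checks are sized to make their Monte Carlo error small
relative to the tolerance being asserted while keeping the default test
run practical: 1000 HWE samples (n = 50, five equifrequent alleles) for
type-I calibration; 200 dyads per relationship class for bias recovery;
100 replicates for k-selection under panmixia; 50 replicates per
scenario (five sites of 24-40 individuals) for the end-to-end null
calibration and CGP-signature detection; and a 10^6-replicate
independent oracle for the Erdős–Rényi test comparison.  Binomial
3-standard-error bands around the nominal rate are used wherever a
rejection rate is asserted.

## Known limitations

* **Truncation bias at r = 0.**  Constrained maximum likelihood on the
  simplex cannot return negative relatedness, so unrelated dyads have a
  positive mean \(\hat r\) — about +0.04 with 10 loci at the study's
  richness profile (verified against a grid-search oracle; the effect
  shrinks with locus count and informativeness).  Triadic estimators
  that jointly model pair-reference relationships report smaller bias;
  under the factorised model implemented here (see above) that gain is
  structurally unavailable.  Group means of mostly-unrelated groups
  inherit a small positive offset; the permutation tests are unaffected
  because the offset is common to observed and permuted means.
* **BIC near-ties at small n.**  With ~20 individuals the
  \(n\ln(W_k/n)\) term is noisy and k can land on a neighbouring value
  in a small fraction of replicates even for well-separated families;
  at the study's site sizes this is rarely material, and the BIC curve
  is returned so borderline choices can be inspected.
* **Pairwise (not pedigree) sibship.**  Dyad calls are made
  independently; they can be mutually inconsistent as a pedigree, and
  HS is indistinguishable from avuncular/grandparent relationships.
* **He options.**  Whether to pool sites and whether to apply the
  small-sample He correction are exposed as options because the
  published table does not state them; defaults are pooled and
  uncorrected.
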