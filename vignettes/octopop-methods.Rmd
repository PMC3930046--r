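---
title: "Methods: octoploid SNP discovery and sturgeon population assignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: octoploid SNP discovery and sturgeon population assignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octopop)
```

## The problem

Ponto-Caspian sturgeons of the "high chromosome number" group are
functional octoploids: every nuclear locus exists as two paralogous
tetrasomic sets, eight similar genomic copies in all.  Pooled sequencing
reads from such a genome mix the two paralogs, so an apparently
heterozygous position in a read pileup can be two very different things:

* a **true SNP** segregating within one tetrasomic locus, usable for
  population genotyping; or
* a **paralogous sequence variant (PSV)** — a fixed difference between
  the two paralogs that every individual carries, which will never
  segregate in any population.

`octopop` implements the read-ratio logic that separates these cases, and
the downstream population-genetic pipeline that a genotyping panel built
from the surviving SNPs feeds: locus QC, Latter's $F_{ST}$ distances,
Weir–Cockerham $\theta$, UPGMA population trees with locus bootstrap, and
resampling-based selection of minimal assignment panels.

## The dosage model

Let $d \in \{0,\dots,8\}$ be the number of copies of allele B among the
eight copies at a site, and $e$ the symmetric per-read error rate.  The
expected B-read fraction is

$$p_d = \frac{d}{8}(1-e) + \Big(1-\frac{d}{8}\Big)e .$$

The biologically distinguished configurations are:

| total dosage $d$ | genotype of the two tetrasomic sets | expected ratio | class |
|---|---|---|---|
| 0 or 8 | AAAA+AAAA / BBBB+BBBB | all one allele | `monomorphic` |
| 2 or 6 | AAAA+AABB (or mirrored) | **3:1** | `candidate_snp` |
| 4 | AAAA+BBBB (fixed paralog difference) | **1:1** | `psv` |
| odd, or 4 split as AABB+AABB etc. | various | other | `other_heterozygous` |

`classify_sites()` evaluates the binomial log-likelihood of the observed
B count under all nine dosages and takes the maximum — a
maximum-likelihood reading of the "allele ratio close to 3:1" rule that
is principled at any depth and reduces to a simple ratio window as
coverage grows.  Sites below the coverage threshold (default 100 reads,
the panel-design setting) are set aside as `low_coverage`; likelihood
ties are resolved to the conservative `other_heterozygous` class so that
ambiguity never creates a panel candidate.  `call_candidates()` keeps the
`candidate_snp` class, ranks by coverage, then by likelihood margin
(best versus runner-up dosage — this package's deterministic secondary
key, alongside the classical sort-by-coverage criterion), then by site
id, and truncates to the panel size (default 384).

A note on operating characteristics: with nine dosage classes the exact
MLE dosage is a hard problem at moderate depth (adjacent dosages differ
by 12.5 percentage points of read fraction).  Enumeration shows
$P(\hat d = 6 \mid d = 6) \approx 0.86$ at depth 100 and $0.95$ at depth
200.  The *panel decision*, however — accept 3:1-like sites, reject
1:1-like sites — is much easier, because misreads of $d=4$ land almost
entirely in the adjacent odd classes, which are also rejected.  The
package's acceptance checks therefore test the filter as a call/no-call
decision at depth 200, where both the accept rate for $d=6$ sites and
the reject rate for $d=4$ sites exceed 95%.

## Genotype QC

A panel designed from a single discovery individual carries loci that
turn out uninformative in the population sample:

* loci *homozygous across all individuals* — monomorphic, fixed at the
  same allele (all calls 0 or all 2);
* loci *heterozygous across all individuals* — the signature of
  alternatively fixed paralogous copies leaking through the filter (all
  calls 1).

`filter_informative_loci()` drops both, reporting exact disjoint
categories.  Loci with every call missing get their own category rather
than being folded into either class — the classical exclusion rule says nothing
about missing data, and silent mislabeling would corrupt the category
arithmetic (categories always sum to the input locus count, and the
filter is idempotent).

## Population genetics

**Allele frequencies.** Panel calls are functionally diploid (0/1/2), so
the B frequency in a population is the B-dose fraction over non-missing
calls.  HWE-style diploid treatment of an octoploid is justified here
because the genotyping assay itself resolves only three intensity
clusters per locus.

**Latter's $F_{ST}$ distance.** For populations $x, y$ with per-locus
allele-frequency vectors $x_l, y_l$:

$$D(x,y) = \frac{\sum_l \sum_a (x_{la}-y_{la})^2 / 2}
                {\sum_l \big(1 - \sum_a x_{la} y_{la}\big)} ,$$

the form used by the POPTREE family of programs (summed squared
frequency differences over expected between-population heterozygosity).
Loci with an absent frequency in either population are excluded from
both sums.  No sample-size bias correction is applied — the distance is
computed exactly as above, the deliberate default for comparability
with POPTREE-style output.  When both populations are identically fixed
everywhere the
denominator vanishes and the distance is 0 by convention.

**Weir–Cockerham $\theta$.** The 1984 variance-components estimator,
per-locus and multilocus (ratio of summed components), with the
heterozygosity component from observed heterozygote proportions.  Loci
monomorphic overall are undefined and excluded from the multilocus sums.
There is no suitable estimator among the installed packages, so the
components are implemented directly; tests validate them against their
analytic anchors (alternative fixation $\to \theta \approx 1$, panmixia
$\to \theta \approx 0$) and by recovery of the Balding–Nichols
simulation parameter ($F = 0.2$ recovered within $0.03$ at 2,000 loci,
100 individuals per population).

**UPGMA.** Size-weighted average-linkage agglomeration; merge height is
half the merge distance, so the tree is rooted and ultrametric.  The
agglomeration loop is written out in the package rather than delegated
to `hclust` for one reason: a fixed, documented tie-break (merge the
pair whose sorted smallest-leaf labels are lexicographically smallest;
put the smaller-keyed child first) so that tied distance matrices give
bit-identical trees.  Tests verify exact agreement with
`stats::hclust(method = "average")` cophenetic distances on hundreds of
random (tie-free) matrices, and ultrametricity to $10^{-12}$.

**Bootstrap.** Loci — not individuals — are resampled with replacement,
the standard choice for frequency-based population trees built from a
fixed locus panel.  Each replicate reruns frequencies, distances and
UPGMA; support of a clade of the full-data tree is the percentage of
replicates containing it (counted with `ape::prop.clades`), written as
integer internal-node labels in the Newick output.

## Assignment and panel selection

**Likelihood.** An individual's assignment score for a population is the
sum over loci of the log HWE genotype probability under that
population's frequencies: $(1-p)^2$, $2p(1-p)$, $p^2$ for genotypes
0/1/2.  Zero (or unit) frequencies are corrected to $1/(2n+1)$ (resp.
$1-1/(2n+1)$) before taking logs — the standard assignment-test
convention — so a reference population that happens to be fixed is not
infinitely penalized.  Missing genotypes are skipped.

**Leave-one-out.** Each individual is assigned with its own
population's frequencies recomputed without it.  Ties count as
incorrect (unassigned), a conservative accuracy.  Per-population
accuracies and the confusion matrix are reported alongside the overall
rate, because a claim like "assignment with 80% accuracy" can be read
either way.

**Locus ranking.** Informative-locus selection follows the
resample-then-intersect scheme: several datasets are drawn by sampling
individuals per population (with replacement, Hardy–Weinberg, from the
observed population frequencies) up to total sizes 100, 100, 100 and
500 — sizes allocated proportionally to the observed population sizes,
at least two per population.  "Sample size" is read as individuals, not
loci: the locus count of the real panel is fixed, so resampling loci to
size 500 from 123 would be meaningless.  Within each dataset every locus
is scored by its mean single-locus leave-one-out log-likelihood ratio
(true population versus the best other) and ranked; the consensus set is
the intersection of the per-dataset top-$k$ lists (default $k = 12$, a
practical minimal-panel size), ordered by mean rank.  The scoring rule
inside the Whichloci program itself is not documented in enough detail
to reproduce; the log-likelihood-ratio score used here is stated
explicitly and deliberately kept behind a single function so it can be
swapped.  `select_min_panel()` then walks prefixes of the consensus
ranking until a target leave-one-out accuracy is met.

## The synthetic-data generator

Real sturgeon reads and panel genotypes are not redistributable (such
samples sit in national tissue collections), so the generator reproduces the
*statistical structure* of both pipeline inputs:

* **Read counts** (`sim_octoploid_sites`): Binomial(depth, $p_d$) draws
  with the true dosage attached, the exact generative model the
  classifier assumes, plus symmetric sequencing error.  It does not
  simulate reads, base qualities, mapping artifacts or allele-specific
  expression — so classifier tests demonstrate correctness under the
  model, not robustness to violations of it.
* **Genotypes** (`sim_population_frequencies` + `sim_genotypes`): the
  Balding–Nichols drift model — each population's allele frequency is a
  Beta draw around a shared ancestral frequency with drift parameter
  $F$ — chosen because its single parameter is exactly the $F_{ST}$ the
  downstream estimators measure, enabling parameter-recovery tests.
  Defaults mirror the study design: five populations of sizes 14, 14, 5,
  28 and 5 at 123 loci, with drift defaults (0.02, 0.02, 0.05, 0.15,
  0.30) chosen once to emulate two nearly indistinguishable river
  populations, a slightly drifted sea population, and two increasingly
  divergent outgroups.  The generator draws loci independently: no
  linkage, no selection, no ascertainment bias from panel design —
  passing tests therefore validate the estimators and the pipeline
  plumbing, not the demographic realism of any particular dataset.

All randomness flows from one explicit integer seed per call
(`withr::with_seed`, leaving the session RNG untouched), and every
stochastic operation is bit-reproducible under a fixed seed.

## Numerical choices and problem sizes

* Positions are 1-based throughout (marker names encode 1-based EST
  offsets).
* GenePop allele codes are fixed to 01/02 (00 missing) because the
  panel is strictly biallelic; richer codes are rejected, not coerced.
* Default error rate 0.01; default coverage threshold 100 reads.
* Likelihood ties (within $10^{-12}$) go to `other_heterozygous`; UPGMA
  distance ties break lexicographically; assignment ties (within
  $10^{-9}$) count as unassigned.
* Test problem sizes were chosen to make the statistical checks sharp
  but quick: 10,000 sites for the classifier operating characteristics,
  2,000 loci × 200 individuals for $\theta$ recovery, 500 random
  matrices for the UPGMA oracle, 100 bootstrap replicates for the
  clade-support check.

## Limitations

* The dosage classifier assumes exactly two tetrasomic paralog sets and
  symmetric errors; mapping bias between paralogs, copy-number
  variation, or partial tetrasomy would shift the expected fractions.
* Latter's distance and $\theta$ are computed from functionally diploid
  codes; true octoploid allele dosages are unobservable on this assay.
* Real sturgeon panel data (which loci survive QC, the exact
  population tree, the accuracy of any particular minimal panel) are
  not shipped with the package; it demonstrates the *methods* on
  synthetic data with known truth instead.
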