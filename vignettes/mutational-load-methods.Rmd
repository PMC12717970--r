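---
title: "Methods: quantifying mutational load through domestication"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying mutational load through domestication}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the model behind
each statistic, the parameters that matter and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where more than one defensible option existed. It
states no empirical result that the test suite does not itself compute.

## 1. The analysis model

The package addresses one question: how does the burden of deleterious
derived alleles carried by individual genomes change across populations
related by a domestication history (an outcrossing wild ancestor, partially
selfing semi-domesticated intermediates, and strongly bottlenecked, highly
selfing domesticates)?

The chain of inference is:

1. **Polarization.** Each biallelic SNP is oriented into ancestral/derived
   states using a single outgroup accession: the allele the outgroup
   carries homozygously is ancestral. This assumes no shared ancestral
   polymorphism and no outgroup-specific substitution at the site — both
   violated occasionally in real data, which is why sites with a
   heterozygous or missing outgroup call are *flagged and excluded* rather
   than guessed (the polarization rule only covers the homozygous case; the
   choice to exclude is ours, documented here, not prescribed by any
   source).
2. **Functional classification.** Sites are assigned to non-coding,
   synonymous, neutral-nonsynonymous or deleterious using two ingested
   effect annotations. Deleterious requires agreement of both: a
   deleterious-class SIFT-style label (the plain and the "low confidence"
   variants are pooled) *and* a PROVEAN-style score strictly below −2.5.
   The intersection is deliberately conservative; its complement within the
   nonsynonymous class ("neutral nonsynonymous") is therefore contaminated
   with weak-effect sites, which biases relative-load ratios toward zero
   but identically in all populations.
3. **Per-genome counts.** Load is a per-genome count, not a frequency:
   hom-derived sites count 1, heterozygous sites count ½ (a diploid carries
   half the dose). Zero-denominator ratios are `NA` and excluded from
   comparisons rather than set to 0 or Inf.
4. **Comparisons.** Rank-based tests throughout (Kruskal–Wallis, Dunn,
   Wilcoxon) because per-genome counts are heavy-tailed under bottlenecks;
   the deleterious-vs-neutral DAF comparison uses the asymptotic two-sample
   two-sided Kolmogorov–Smirnov test; private-vs-shared and
   inside-vs-outside-SV ratio comparisons use Welch t-tests. Multiple
   testing is Bonferroni-adjusted at α = 0.05.

## 2. Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| accession missingness cutoff | 0.25 | fraction | strictly-greater removal; an accession at exactly 25% is kept |
| site MAF filter | 0.001 | frequency | strictly-less removal, computed over non-missing ingroup dosages; guards against genotyping artefacts |
| PROVEAN cutoff | −2.5 | score | strict `<`; a score of exactly −2.5 is not deleterious |
| diversity window | 10 kb | bp | window for π and Tajima's D |
| correlate window | 100 kb | bp | window for relative load vs π / recombination / sweep statistic |
| SV merge distance | 100 | bp | start distance (both breakpoints for TRA) |
| SV length ratio | 0.9 | min/max | SURVIVOR-style similar-length criterion |
| SV minimum size | 30 | bp | non-TRA representative span |
| SV MAF filter | 0.01 | carrier frequency | presence/absence genotypes, not dosages |
| α | 0.05 | — | with Bonferroni across pairs/statistics |

All boundaries follow the wording of their definitions literally: removals
are strict inequalities, retentions include the boundary. This makes
boundary sites test-assertable.

## 3. The forward simulator: what it emulates

`simulate_populations()` is a discrete-generation forward Wright–Fisher
simulation of diploids with:

* **Four site categories** in configurable proportions; only the
  deleterious category has a fitness effect: multiplicative across loci
  with genotype factors {1, 1+hs, 1+s} (no epistasis — the simplest model
  consistent with purifying selection). Defaults s = −0.05, h = 0.5.
* **A population tree**: descendants are founded at their split generation
  by sampling founders with replacement from the source (a serial-founder
  model); sizes are piecewise-constant per population (bottlenecks are
  epoch changes). A population can be *sampled* at an earlier generation
  than the final one (`sample_gen`), which is how a pre-bottleneck snapshot
  of a lineage is taken.
* **Selfing**: each offspring is produced by self-fertilisation with the
  population's configured probability, otherwise by two fitness-weighted
  parent draws.
* **Recombination**: chromosomes assort freely; within a chromosome one
  crossover occurs per meiosis at a uniform site boundary (probability
  `xo_prob`, default 1). This is enough linkage for hitchhiking-flavoured
  experiments without a marker-level map.
* **Mutation**: one-way ancestral→derived at `mut_rate` per site per gamete
  per generation, recurrent but with no back-mutation.
* **Standing variation**: all sites start at `init_freq` (default 0.1) in
  the root founders. With the default mutation rate, deleterious sites sit
  near mutation–selection balance q ≈ u/(hs) ≈ 0.004 once the standing
  variation has been purged, so the deleterious class never empties.
* **The outgroup** is emitted homozygous ancestral at every site, so
  polarization is exactly the identity on simulator truth — every
  downstream count can be checked against truth. A configurable fraction of
  sites (default 10%) is *written to VCF with the derived allele as REF*,
  so the polarization code is genuinely exercised in both orientations.

What the generator does **not** emulate: realistic chromosome structure or
marker-level linkage maps, empirical mutation spectra, gene conversion,
shared ancestral polymorphism with the outgroup, genotyping error beyond
uniform missingness, and annotation-score realism (PROVEAN-like scores are
uniform on (−6, −2.6) / (−2.4, 2) for the two classes — only the decision
rule's inputs matter). A green simulation-based test therefore establishes
that the *pipeline logic* is correct and that the *statistical procedures*
have their nominal operating characteristics under the stated model; it
does not validate the model against real tomato data.

### Annotation-table emission

`emit_annotation_tables()` writes SIFT-style and PROVEAN-style TSVs from
truth. With misclassification rate m, exactly ⌊m · n⌋ of the n
nonsynonymous sites are emitted with the opposite deleterious/neutral
annotation (label and score move together); with m = 0 decoding recovers
truth at every site — both facts are forced by construction and asserted.

### SV fixtures

`generate_sv_fixtures()` plants truth SVs of the four retained types (DEL,
DUP, INV, TRA; insertions are excluded by contract) on a coarse genome grid
so that distinct truth SVs can never fall in one merge cluster. Caller
jitter is Gaussian but **truncated at ±50 bp**: with the 100 bp merge
distance, any two replicate calls of one truth SV then remain linkable *by
design*, which is the fixture's stated guarantee. Untruncated N(0, 33²)
jitter would put ~3% of call pairs beyond 100 bp and would let short SVs
fail the 90% length-ratio rule — so default truth lengths are 3–8 kb
(worst-case ratio with truncated jitter: 2900/3100 ≈ 0.935). False
positives are each given their own unused grid slot, making "appears in
exactly one caller" literal.

## 4. Numerical choices

* **π** is per-site 2j(n−j)/(n(n−1)) over non-missing allele calls (equals
  the mean pairwise haplotype difference), summed per window and divided by
  the *configured* window width; unobserved positions count as invariant.
  This reproduces the standard VCF-based estimator including its known
  downward bias in windows with structured missingness; windows with no
  called site report π = 0 with a `no_data` flag rather than `NA`, matching
  that estimator's behaviour.
* **Tajima's D** uses the textbook constants with
  n = 2 × (minimum per-site non-missing diploids in the window) —
  conservative and deterministic under missingness; D is `NA` (never 0)
  when S = 0 or n < 4.
* **High/low partition**: windows are ranked by the statistic; the top
  ⌊n/2⌋ form "high", ties at the cut go to "low", and odd counts give
  "low" the extra window — fully deterministic, order-invariant.
* **Dunn's test** uses the rank-sum z statistic with the standard tie
  correction Σ(t³−t)/(12(N−1)) and Bonferroni multiplication by the number
  of pairs. The compact letter display is built by insert-and-absorb over
  the adjusted significance matrix. Note a small-sample consequence of
  Bonferroni: with 3 groups of 3, a fully separated pair has adjusted
  p ≥ 0.05, so letters cannot separate any groups below n ≈ 4–5 per group.
* **SV clustering** is single-linkage (transitive closure), implemented as
  a sorted sweep with union-find and verified against a brute-force
  adjacency-closure oracle; representatives are member-wise median
  coordinates. Collapsing an already-collapsed catalogue is the identity.
* **Degenerate inputs** fail loudly and specifically: all-fitness-zero
  generations name the generation; all-missing sites name the site;
  non-monotone genetic maps name the chromosome; empty high/low groups,
  all-tied statistics and empty SFS classes return flagged verdicts
  (`"n"`, `"undefined"`) rather than numbers.

## 5. Open design choices (and why we chose as we did)

* **Outgroup het/missing sites**: flagged and excluded everywhere. The
  alternative (imputing the ancestral state from the major allele) injects
  frequency-dependent bias into exactly the quantity under study.
* **Imputation** is per-site modal dosage (ties to the lower dosage),
  deterministic, with imputed cells flagged. LD-based imputation is out of
  scope; downstream results must not depend on imputer stochasticity.
* **Per-accession private-allele proportions** are computed both ways the
  definition can be read — over the sites the accession itself carries and
  over the sites segregating in its population — and labelled
  (`prop_private_carried`, `prop_private_pop`).
* **Table-1-style Wilcoxon** is run on per-accession loads pooled within
  high/low groups (primary) *and* on per-window means (reported alongside,
  `p_window_means`), since the aggregation level admits both readings.
* **2-of-3 SV consensus before cross-accession collapsing** (not after):
  consensus is a per-sample evidence filter, collapsing a population-level
  identity operation; applying consensus first matches how the merging
  tools are used in practice.
* **Bottleneck direction checks** compare a lineage *pre vs post*
  bottleneck (snapshot sampling), restricted to sites segregating in each
  sample. Two facts force this reading: under pure drift the expected
  per-genome derived count over all sites is a martingale (so an all-sites
  before/after comparison has no expected direction), and in an
  ancestor-vs-descendant-branch comparison the large ancestor keeps
  purging (2Nhs ≈ 10) while selection is relaxed in the small descendant
  (2Nhs ≈ 1), which can *raise* the descendant's deleterious count — a
  real population-genetic effect, not a bug.

## 6. Known limitations

* The simulator's per-site one-way mutation model saturates at high θ (it
  is not infinite-sites); neutral-spectrum checks are run in the low-θ
  regime where the 1/i shape holds.
* SV genotypes are presence/absence; carrier frequency stands in for
  allele frequency, as short-read SV genotype dosages are unreliable.
* The KS test is asymptotic; with heavy ties at very small sample sizes
  its p-values are approximate (ties are rare for DAF lists of realistic
  size).
* The pipeline's sweep statistic is ingested, never computed; windows
  without a grid point carry `NA` and drop out of that partition test.
* Compact letters depend on the test's power: with fewer than ~5
  accessions per population no letters can separate (see §4).
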