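---
title: "Diagnosing nascent XY systems from microsatellites: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing nascent XY systems from microsatellites: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xylink)
```

## The problem

Many amphibians carry homomorphic sex chromosomes at an early stage of
differentiation: the X and Y look identical under the microscope, sex
linkage can be present in some populations and absent in others, and
chromosome rearrangements (here a reciprocal translocation segregating as
a stable polymorphism) may or may not be entangled with the
sex-determining region. `xylink` implements the inference chain used to
diagnose such a system from co-dominant microsatellite genotypes:

1. find **male-specific (Y-private) alleles** — under male heterogamety
   with suppressed X–Y recombination, Y-borne alleles occur in males and
   essentially never in females;
2. find **translocation-specific alleles** shared by translocated
   individuals of both sexes;
3. **score association** between classed alleles and their target class
   per population, to localise where recombination suppression holds;
4. **phase X and Y haplotypes** from the private alleles and split X
   copies into translocated (XT) and normal (XN) chromosomes;
5. compare per-class **gene diversity under the stepwise mutation model**
   with the neutral 4:3:1 autosome:X:Y expectation;
6. support the above with Weir–Cockerham F-statistics between sexes,
   Hardy–Weinberg and linkage-disequilibrium permutation tests, and a
   Mantel test of isolation by distance.

## Data model and conventions

Genotypes are unordered pairs of allele sizes (bp); Genepop files with 2-
or 3-digit encodings are read and written (`read_genepop()`,
`write_genepop()`). Missing calls are excluded **pairwise** per locus —
never imputed — and the reports carry per-locus missingness so the choice
is visible. An amplification-null allele that was scored as a sentinel
size (e.g. 499 where a translocated priming site fails) is declared in
`null_sentinels` and treated as an ordinary allele everywhere, because it
segregates like one.

Sample metadata normalises karyotype Types II–V to `TRANSLOCATED` and
Type I to `NORMAL`; populations map to `WEST`/`EAST` groups via a
user-overridable map (`default_group_map()`), the WEST group being the
translocation-polymorphic region where allele classification is scoped by
default.

## Allele classification thresholds

An allele is male-specific if carried by at least one male and at most
`max_female_carriers` females (default 2). The tolerance exists because
occasional **sex-reversed** individuals put Y alleles into phenotypic
females; such carriers are recorded as named exceptions, and
`flag_sex_discordant()` turns the same evidence into per-individual
verdicts (a phenotypic male with no private allele at every informative
fully linked locus, or a female carrying them, is a
`CANDIDATE_REVERSAL`). Flagged individuals are reported, never silently
removed. Translocation-specific alleles require carriers among
translocated individuals of both sexes and tolerate
`max_normal_carriers` (default 0) normal-karyotype carriers; because a
translocated haplotype can carry different alleles in different demes,
classification can be scoped per population.

The association score is \(D = 1 - N_{\mathrm{carriers}}/N_{\mathrm{target}}\):
0 under complete recombination suppression, rising toward 1 as
recombination decouples the classed alleles from sex or karyotype.
Carriers are counted per individual (at least one copy), since Y-linked
alleles are effectively hemizygous. An empty target class (a population
with no translocated individuals) yields a missing score, the "break in
the line" of a per-population profile.

## Phasing rules

For a male at a fully sex-linked locus, the copy matching a male-specific
allele is his Y and the other his X; female copies are X. Three male
configurations stay `UNPHASED`: no private allele (candidate reversal or
locally recombining locus), two different private alleles, and
homozygosity for a private allele — a truly Y-private allele cannot be
homozygous, so we treat that as a genotyping anomaly rather than invent a
Y+X reading. X copies matching a translocation-specific allele become XT
only in `TRANSLOCATED` (or, low-confidence, `UNKNOWN`) karyotypes; an
apparent translocation allele in a `NORMAL` individual stays XN and the
cell is logged against the karyotype expectation (MT: Y+XT, FT: XN+XT,
MN: Y+XN, FN: XN+XN). UNPHASED copies are excluded from diversity pools.

## Diversity under the stepwise mutation model

At mutation–drift equilibrium with single-step mutation, gene diversity
and the scaled diversity \(\theta = cN_e\mu\) are linked by

\[\theta = \frac{1/(1-H_E)^2 - 1}{2}, \qquad H_E = 1 - \frac{1}{\sqrt{2\theta+1}}.\]

With equal effective size and mutation rate in both sexes, autosomes, X
and Y are carried 4:3:1 per breeding pair, so
\(E(\theta_Y) = (\theta_Y + \theta_X)/4\),
\(E(\theta_X) = 3(\theta_Y + \theta_X)/4\), and the implied four-unit
total gives \(E(\theta_A) = \theta_Y + \theta_X\). A Y deficit relative
to \(E(\theta_Y)\) beyond the copy-number expectation indicates a
class-specific reduction of \(N_e\), e.g. from suppressed recombination.

`expected_heterozygosity()` uses Nei's unbiased estimator
\(\frac{n}{n-1}(1 - \sum p_u^2)\) on gene-copy pools, which applies
unchanged to haploid class pools (Y, XT, XN) with \(n\) the copy count;
the plain \(1-\sum p^2\) is available via a switch, and none of the
table-consistency checks depend on the choice.

**Combining loci.** Survey tables conventionally report a population's
class \(\theta\) as the arithmetic mean of per-locus \(\theta\)
estimates. That convention is kept as the default of
`class_diversity()`, but it is worth knowing that it is upward-biased as
an estimator of \(cN_e\mu\): \(\theta(H)\) is convex, so averaging
per-locus transforms inflates the mean (Jensen), substantially so when
per-locus \(H\) varies as much as coalescent theory says it must. The
alternative combiner `theta_of_mean_h` applies the transform to the mean
per-locus diversity and is the consistent choice for parameter recovery;
the package's simulator-recovery tests use it, while ratio comparisons
(where the convexity bias largely cancels) and report tables use the
table convention. Report tables round half-up to 2 decimals
(`round_half_up()`), the convention needed to reproduce printed tables
whose third decimal is a 5.

## F-statistics and permutation tests

`fstat_weir_cockerham()` implements the Weir & Cockerham (1984)
variance-component estimators (multi-allele, multi-locus, components
summed over alleles and loci), with the grouping free to be sexes,
populations or karyotypes. Negative estimates are reported as computed —
heterozygote excess at sex-linked loci makes strongly negative
\(F_{IS}\) the expected signature in both sexes. Per-group fixation
indices (\(F_{ISF}\), \(F_{ISM}\)) restrict the estimator to one group;
with a single group the among-group component drops and the within-group
f-hat remains, which the tests verify against an independent nested-ANOVA
oracle. Significance uses label permutations, defaulting to 5000
randomizations with Bonferroni correction across families — the
conventions of the surveys this package serves.

The Hardy–Weinberg test shuffles the 2n gene copies into random diploid
pairings, realising the Levene conditional distribution exactly in the
Monte-Carlo limit; the Markov-chain (Guo–Thompson) method is a noted
alternative but the shuffling estimator is simpler and seed-reproducible.
The LD test permutes one locus's genotypes and uses the genotypic G
statistic. Both include the observed array in the tail (+1 correction),
so p-values are valid at any permutation count; calibration tests check
5% nominal rejection within [0.03, 0.07] over 1000 null replicates.
`mantel_test()` correlates off-diagonal distances under joint row/column
permutation; geographic distance is the haversine on a 6371-km sphere
(the underlying surveys do not state their metric, so the simplest
defensible one is used and exposed).

## The generator

`simulate_xy()` exists so every stage is testable end to end without any
external download, and so parameter recovery can be demonstrated against
a known truth. It is a forward-time Wright–Fisher model of
chromosome-class gene-copy pools: with \(N\) breeding individuals
(`n_effective`, equal sex ratio) the pools hold \(N/2\) Y copies,
\(3N/2\) X copies and \(2N\) autosomal copies — 1:3:4 per breeding pair —
giving equilibrium \(\theta = cN_e\mu\) per class. Y haplotypes are
transmitted intact (no X–Y recombination); X copies recombine freely
except inside a configurable suppressed block that travels with the
translocation lineage tag; autosomal loci are unlinked. Mutation is
strict single-step (±1) at rate `mu` per copy per generation, floored at
a minimum size. Individuals are assembled by random union of copies at
sampling time, so genotype arrays are in Hardy–Weinberg proportions
within the class structure.

Two deliberate idealisations:

* **Pool sizes and the translocation-tagged copy count are conserved
  every generation.** A freely drifting neutral tag would fix or vanish
  over a 10N burn-in, leaving nothing to analyse; the study systems this
  emulates maintain the karyotype polymorphism over ecological time, so
  the generator holds the tagged fraction (`p_translocated`, default
  0.25 — roughly a third of individuals carrying a translocated
  karyotype) constant and lets alleles drift within lineages.
* **Sex reversal flips only the phenotypic label** of a sampled
  individual (rate `p_sex_reversal`), never the genotype — matching the
  interpretation of gonad-anomalous frogs as label/genotype mismatches.

Default study conditions are six sex-linked and five autosomal loci, the
locus counts of the motivating survey; founder X and Y alleles are offset
(200 vs 250 bp) so the pools stay disjoint over realistic burn-ins and
sex linkage is complete; the translocated founder haplotype carries a
+15 bp diagnostic allele inside the suppressed block; a designated locus
can emit its translocated copies as the 499 null sentinel. Burn-ins
shorter than \(10N\) generations warn. What the generator does **not**
emulate: genuine pedigree structure (random union replaces it), selection,
size homoplasy constraints beyond the size floor, allele-calling error,
and realistic missingness — so passing tests demonstrate the inference
chain's correctness under its own assumptions, not robustness to
real-world genotyping artefacts.

Recovery checks run at \(N = 500\), \(\mu = 10^{-3}\), 20 loci per
class, burn-in \(10N\), 50 sampled individuals of each sex, averaged
over 20 seeds — sizes chosen so the class pools are comfortably in the
diffusion regime while a full run stays in seconds; the mean recovered
\(\theta\) per class lands within 20% of \(cN_e\mu\) and the recovered
A:X:Y ratio within 20% of 4:3:1 per component.

## Orchestration

`run_all()` sequences the stages behind one configuration (R list or
YAML): validate → classify → flag → score → per-population F-statistics →
HWE/LD with Bonferroni → phase → partition → diversity table → Mantel
(with ≥3 populations), writing each table as TSV plus a run log recording
versions, seed and thresholds. One top-level seed is fanned out
deterministically to every randomized stage, so a rerun reproduces the
bundle exactly. Each module remains independently callable; the pipeline
is a convenience, not a cage.

## Known limitations

* Allele classification is threshold-based; no per-allele significance
  test is attached (the F-statistics and scores carry the inference).
* Phasing uses only the private-allele rule; no statistical (LD- or
  pedigree-based) phasing is attempted, and males without private alleles
  stay unphased rather than being probabilistically assigned.
* The \(\theta\) machinery assumes strict SMM at equilibrium; infinite-
  alleles or two-phase mutation would shift the \(H \leftrightarrow
  \theta\) mapping.
* Great-circle distance ignores topography; for frogs along basin edges
  the straight-line distance can understate effective isolation.
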