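---
title: "Chromosome-dosage sex genotyping by qPCR: models and methods"
author: "cephsex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosome-dosage sex genotyping by qPCR: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephsex)
```

## The dosage model

Coleoid cephalopods (cuttlefish, octopus, squid) carry a Z0/ZZ
sex-chromosome system: females have a single Z chromosome, males two. In
genomic DNA, a Z-linked locus is therefore present at half the copy
number of an autosomal locus in females, and at equal copy number in
males. Quantitative PCR resolves this because the quantification cycle
is logarithmic in starting template:

$$C_q(d) = C_q^{0} - \frac{\log d}{\log(1 + E)},$$

where $d$ is the template dose relative to the diploid autosomal
reference and $E$ is the per-cycle amplification efficiency. At $E = 1$
(perfect doubling), a two-fold dose step is exactly one cycle. Defining
$\Delta C_q = \bar C_q(\text{autosome}) - \bar C_q(\text{sex locus})$
per animal, males and females differ by
$\log 2 / \log(1+E)$ cycles — one cycle at full efficiency — and
normalizing by the male-cluster median ($\Delta\Delta C_q$) puts males
at 0 and females at $-1$, whatever the loci's amplification offsets or
the sample's DNA concentration (shared offsets cancel in the
difference, which is why no input normalization is needed beyond a
routine dilution).

`expectedCq()` implements the dose model; `simulateCqBatch()` builds
technical-replicate batches from it with Gaussian per-replicate noise
(`replicate_sd`), a Gaussian per-sample offset shared by both targets
(`sample_offset_sd`, modelling concentration scatter), and optional
symmetric outlier shifts to exercise the filter.

## The calling pipeline

`runBatch()` composes deterministic stages; nothing in the caller is
random.

1. **Replicate QC** (`filterReplicates`): within each (sample, target)
   group the mean over all replicates is computed once and values
   deviating by more than `max_dev` = 1 cycle are discarded. The pass is
   deliberately single-shot: iterative re-meaning can cascade on
   quadruplicates. Groups keeping fewer than two replicates are flagged
   unusable and excluded from clustering (never silently dropped).
2. **Summaries** (`summarizeGroup`): mean and SEM (sample SD / $\sqrt n$).
3. **Delta-Cq** (`deltaCq`): autosome minus sex-locus mean; the reported
   uncertainty is the *arithmetic sum* of the two SEMs. Quadrature
   ($\sqrt{s_a^2+s_s^2}$) is the statistically standard combination and
   is available via `quadrature = TRUE`, but the sum is the default to
   match the assay's established reporting convention.
4. **Clustering** (`splitClusters`): samples are sorted by delta-Cq and
   split at the contiguous boundary minimizing total within-cluster sum
   of squares (the exact 1-D two-class natural-breaks partition). On
   clean data this is the largest adjacent gap; unlike the raw largest
   gap it is not derailed by one extreme sample at a batch edge, which
   matters once batches reach tens of animals. The batch is declared
   single-cluster — all-male or all-female, requiring a `male_standard`
   reference — only when the boundary gap is below `min_gap` = 0.3
   cycles *and* the candidate clusters' medians are closer than
   `min_separation` = 0.5 cycles (half the dosage signature). The second
   condition exists because in large noisy batches the *local* gap
   between the nearest opposite-sex animals shrinks well below 0.3
   cycles long before the one-cycle separation between the cluster
   medians erodes; an absolute gap test alone would abort genuine mixed
   batches.
5. **Normalization** (`normalizeDdcq`): subtract the male (high) cluster
   median, or the supplied male standard. The male-cluster median maps
   to exactly 0 by construction.
6. **Calling**: every usable sample is assigned the nearer of the two
   expected values, 0 (male) or $-1$ (female). Values within
   `ambiguity_margin` = 0.25 cycles of the $-0.5$ midpoint keep their
   call but receive an `ambiguous-zone` QC flag (and the batch is
   flagged). The flag-not-abstain design is intentional: at realistic
   technical noise (replicate SD 0.2, quadruplicates; per-sample
   $\Delta C_q$ SD $\approx 0.14$) a few animals per hundred are
   *expected* to drift within 0.25 cycles of the midpoint while still
   being on the correct side of it, and the assay's decision rule is
   proximity. The exported `callSex()` primitive, by contrast, returns
   `"ambiguous"` inside the zone for callers that want abstention.
7. **Separation and validation** (`separationMetrics`,
   `exactBinomialP`): distance between cluster medians and the minimum
   between-cluster gap (negative when clusters overlap — reported
   as-is with a QC flag); with a truth table, a one-sided exact binomial
   test of the correct-call rate against chance (0.5), computed as the
   exact upper tail.

Amplification efficiency is assumed to be 100% in interpretation (one
cycle per two-fold); no efficiency correction is applied, so primer
pairs should be validated to near-complete efficiency. Estimating $E$
from dilution series is out of scope.

## Primer design

`enumerateCandidates()` emits every substring of the template within the
profile's size range on both strands and annotates GC content, melting
temperature, 3'-terminal GC run, longest homopolymer and self-dimer Tm,
recording every violated constraint. Two presets mirror the two design
routes the assay has been used with:

| parameter | `geneiousProfile()` | `pipelineProfile()` |
|---|---|---|
| optimal size | 20 nt | 20 nt |
| optimal Tm | 59 °C | 60 °C |
| optimal GC | 50% | 50% |
| product size | 100–200 bp | 150–300 bp |
| GC clamp | 1 | none |
| max poly-X | 3 | 5 |
| max dimer Tm | 30 °C | none |

The optima and the product/clamp/poly-X/dimer limits are the assay's
stated parameters; the min–max *ranges* (size 18–27 nt, GC 30–70%, Tm
52–62 °C and 52–63 °C) are package choices. The Tm band sits low
relative to the optimum deliberately: under the package's default
thermodynamic conditions (below) typical qPCR primers evaluate 3–4 °C
lower than under instrument-buffer conditions that fold divalent
cations into the salt term.

Melting temperatures use the unified nearest-neighbor
enthalpy/entropy table with duplex-initiation terms, a symmetry
correction for self-complementary oligos, and the entropic salt
correction $\Delta S + 0.368\,(N-1)\ln[\mathrm{Na^+}]$. Default
conditions are 50 mM monovalent salt, no divalents (a divalent
concentration, when supplied, is folded in as
$[\mathrm{Na^+}] + 120\sqrt{[\mathrm{Mg^{2+}}]}$), 250 nM total oligo
with the $C_T/4$ term for non-self-complementary duplexes. Against an
independent nearest-neighbor implementation these values agree within
2 °C for all bundled published primers (the tests assert 3 °C).

Dimer screening (`dimerTm`) scans all ungapped antiparallel alignments
of the two oligos, evaluates every contiguous complementary window of at
least 4 bp (including sub-windows of maximal runs, which can out-melt
the full run when short and GC-rich), and reports the most stable
window's Tm. This is a screening heuristic, not a hybridization
free-energy minimization: no loops, bulges or hairpins.

`pairPrimers()` combines passing forward/reverse candidates whose
product size is in range, rejects pairs whose cross-dimer Tm exceeds the
profile cutoff, and ranks by

$$|T_f - T_{opt}| + |T_r - T_{opt}| + |T_f - T_r|
  + 0.1(|G_f - G_{opt}| + |G_r - G_{opt}|)
  + |L_f - L_{opt}| + |L_r - L_{opt}|,$$

with ties broken by leftmost product start, then smallest product. The
penalty is this package's definition — only the ranking matters
downstream, not any external tool's score.

`scanSpecificity()` is an in-silico PCR check: a primer binds where its
`seed_len` = 12 3'-terminal bases match exactly and total mismatches
are at most `max_mismatch` = 3; convergent site pairs within
`max_amplicon` = 1000 bp predict amplicons; a pair is unique when it
predicts exactly one amplicon at the intended locus. The 3'-anchored
seed captures the biologically decisive criterion (polymerase extension
requires a matched 3' end) and makes the scan equivalent to an
exhaustive mismatch scan, which the tests assert on multi-10-kb
genomes.

`refineToSpecies()` ports a designed pair to a related species by
substituting consensus alleles at the primer coordinates (the consensus
must be positionally 1:1 with the template, e.g. a reference-guided
consensus). Pairs with an ambiguity code or alignment gap in either
primer's 3'-terminal 5 nt are rejected; other ambiguities are flagged.
Accepted refinements get recomputed thermodynamics and a fresh
constraint check. When male and female consensus sequences disagree, a
single consensus input is still expected — resolving heterozygous
design sites is left to the user.

## Z-contig assignment

For species without chromosome-level assemblies, Z-linked sequence is
located by aligning the assembly to a chromosome-level relative
(externally, e.g. minimap2 with an assembly-to-assembly preset) and
interpreting the PAF: `aggregateAlignments()` sums matching bases per
(contig, chromosome) after discarding alignments below `min_mapq` = 10
or `min_block` = 1000 bp, and `assignContigs()` assigns each contig by
majority vote — the best chromosome must hold more than
`min_fraction` = 0.6 of the contig's aligned bases (a fraction of
exactly 1 always qualifies) with at least `min_bases` = 5000 total.
Boundary ties are left unassigned: for primer design, a false Z label
is the costly error. Matching bases, not block length, are the evidence
measure — the conservative reading when alignments contain large
indels. All thresholds are package defaults; alignment-based Z
assignment has no established cutoffs, so they are deliberately
surfaced as arguments.

## What the simulators do and do not emulate

`simulateCqBatch()` reproduces the *structure* of a qPCR plate — known
genotypes, dosage-derived expected Cq, shared concentration offsets,
independent replicate noise, optional outliers — with Gaussian noise on
the Cq scale. Replicate SD defaults to 0.1 (a clean assay; 0.2 is a
realistic setting), chosen as plausible magnitudes for SYBR
quadruplicates since no per-replicate dispersion is published for the
assay. Real data add what the simulator does not model: melt-curve
failures, template degradation, pipetting dropouts, inhibitors,
between-run drift, and amplification efficiencies below 1 that differ
*between the two loci* (which would shift the female target away from
exactly $-1$). Passing the simulated checks therefore demonstrates the
pipeline's arithmetic and decision logic, not wet-lab performance.
`simulateGenome()` builds uniform-random chromosomes with verbatim
planted primer sites and exact-match contig/PAF fixtures; it has no
repeat structure, GC heterogeneity or indel noise, so it exercises
coordinate bookkeeping and detection logic, not aligner behavior.

Problem sizes used by the test suite (a few kb to a few tens of kb of
genome, batches of 8–81 animals, hundreds of simulated batches for the
recovery curve) were chosen so the full suite runs in well under a
minute while still covering the regimes where the decision rules can
fail — batch edges, midpoint values, single-sex batches, overlapping
clusters.

## Numerical and degenerate-input choices

- Coordinates are 0-based half-open internally; GFF3 (1-based
  inclusive) and PAF (0-based half-open) are converted only at the
  parser boundary.
- Lowercase (soft-masked) bases are uppercased on read; masking is not
  used downstream. `U` is accepted on input and stored as `T`.
- The replicate filter errors below two replicates; a filtered group
  keeping fewer than two is unusable, and a sample missing either
  target is flagged and excluded from clustering.
- `min_gap` may legitimately be negative in `separationMetrics()`
  (overlapping clusters); it is reported unclamped with a QC flag.
- Exactly tied candidate splits resolve to the smaller split index;
  exactly midpoint $\Delta\Delta C_q = -0.5$ is reported ambiguous.
- The exact binomial tail is computed in double precision; $2^{-81}$
  (the 81-animal perfect-validation p-value) is far above underflow.

## Known limitations

- Tm values are condition-dependent; comparisons against tools that
  default to different salt/oligo assumptions shift by a few degrees.
  Use `thermoConditions()` to match a target convention.
- Dimer and specificity models are ungapped; primers with strong
  hairpin propensity or indel-mediated off-targets are not flagged.
- The caller assumes exactly two dosage classes. Aneuploidies, somatic
  mosaicism or sex-chromosome systems other than Z0/ZZ violate the
  model.
- With very small batches (e.g. 4 + 4), cluster medians are noisy:
  at replicate SD 0.1 the female-cluster median has a Monte Carlo SD
  near 0.06, so single-batch summaries should be read with that
  uncertainty in mind.
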