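# cephsex

Sex genotyping of cephalopods by qPCR chromosome dosage.

Coleoid cephalopods (cuttlefish, octopus, squid) carry a Z0/ZZ
sex-chromosome system: females have one Z chromosome, males two. A
Z-linked locus is therefore present in genomic DNA at half the copy
number of an autosomal locus in females and at equal copy number in
males. Quantitative PCR resolves this two-fold dosage difference,
because Cq is logarithmic in template:

    Cq(d) = Cq0 − log(d) / log(1 + E)

so at 100% amplification efficiency (E = 1) a two-fold dose step is
exactly one cycle. Per animal, ΔCq = mean Cq(autosome) − mean Cq(sex
locus); after normalizing to the male-cluster median, ΔΔCq clusters at
0 for ZZ males and −1 for Z0 females. Shared concentration offsets
cancel in the difference, so the assay needs no input normalization —
which is what makes it work from non-invasive skin swabs of hatchlings
as well as from tissue.

The package implements the complete in-silico side of the assay, for
anyone setting up dosage-based sexing in cephalopods (or other
X0/Z0-type systems):

- **IO** — validating readers/writers for FASTA, GFF3, minimap2 PAF and
  technical-replicate Cq tables (`readFasta`, `readGff3`, `readPaf`,
  `readCqTable`, `extractFeatures`).
- **Z assignment** — majority-vote assignment of assembly contigs to
  reference chromosomes from whole-genome alignments, flagging putative
  Z-linked contigs for species without chromosome-level assemblies
  (`aggregateAlignments`, `assignContigs`).
- **Primer design** — candidate enumeration under Primer3-style
  constraint profiles, nearest-neighbor melting temperatures, dimer
  screening, pairing and penalty ranking, in-silico PCR specificity
  scanning, and refinement of a designed pair to a related species'
  consensus (`enumerateCandidates`, `nnTm`, `dimerTm`, `pairPrimers`,
  `scanSpecificity`, `refineToSpecies`). The validated published primer
  pairs for six cephalopod taxa ship with the package
  (`cephalopodPrimers()`).
- **Sex calling** — replicate outlier filtering, ΔCq/ΔΔCq computation,
  natural-breaks clustering, male-median normalization, SEM
  propagation, separation statistics and exact binomial validation
  (`runBatch` and its stage functions).
- **Simulation** — Cq batches with known genotypes and synthetic
  genomes with planted primer sites, so every stage is testable with no
  external data (`simulateCqBatch`, `simulateGenome`).

## Worked example

Simulate a blinded batch of eight animals (four ZZ, four Z0) with
quadruplicate reactions and realistic technical noise, then call sex:

```r
library(cephsex)

sim <- simulateCqBatch(n_male = 4, n_female = 4, replicate_sd = 0.1,
                       seed = 7)
res <- runBatch(sim$measurements, truth = sim$truth)
res
#> SexCallBatch: 8 sample(s) — 4 male, 4 female
#>   cluster medians (ddCq): male 0.000, female -0.943; distance 0.943; min gap 0.733
#>   validation: 8/8 correct, one-sided exact binomial p = 0.00391

head(sexCalls(res)[, c("sample_id", "delta_cq", "ddcq", "sem",
                       "cluster", "predicted_sex")], 4)
#>   sample_id delta_cq    ddcq    sem cluster predicted_sex
#> 1      s001 -0.19272 -0.1641 0.0875    high          male
#> 2      s002  0.00696  0.0356 0.0887    high          male
#> 3      s003  0.03378  0.0624 0.1028    high          male
#> 4      s004 -1.00635 -0.9778 0.0687     low        female
```

Reading the output: the male cluster is pinned at ΔΔCq = 0 by
construction, the female cluster sits near −1 (one cycle later at the
sex locus — half the Z dose), `min gap` is the distance between the
nearest animals of opposite clusters, and the validation line is the
one-sided exact binomial test of 8/8 correct calls against chance
(0.5⁸ ≈ 0.0039). Per-sample `sem` is the sum of the autosome and
sex-locus replicate-group SEMs.

Primer-level functions work on plain strings:

```r
nnTm("GGTGTTGTTCGCTCAGTTATC")   # 53.66 °C at 50 mM Na+, 250 nM oligo
gcContent("GGTGTTGTTCGCTCAGTTATC")  # 47.62
```

A thin command-line wrapper for the batch operations is installed at
`system.file("scripts", "cephsex.R", package = "cephsex")` with
`simulate-cq`, `call` and `assign-z` subcommands.

See the vignette (`vignettes/sex-genotyping-methods.Rmd`) for the dosage
model, the design-profile parameters, the clustering and ambiguity
rules, and what the simulators do and do not emulate.

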