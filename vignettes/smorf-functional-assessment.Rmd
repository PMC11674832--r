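---
title: "Assessing smORF function: models, statistics and design choices"
author: "smorfkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing smORF function: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smorfkit)
```

# Scope

Small open reading frames (smORFs, fewer than 100 codons) and in particular
short coding sequences (sCDS) — annotated smORFs translated from their own
mRNAs into peptides and microproteins — are systematically under-studied
because their size defeats both homology search and conventional genetic
screens. `smorfkit` implements the computational side of a combined
assessment: cataloguing smORFs from genome annotation, scoring their coding
potential by GC composition, quantifying mutant viability and fitness from
fly crosses and balancer-competition populations, accounting for proteomic
detection evidence, and merging everything into per-gene indicator tables.
A synthetic-data module generates all inputs with known truth so that every
stage is testable offline.

# The ORF catalogue

`find_orfs()` enumerates ATG-initiated ORFs under the standard genetic code
in all six frames. One record is emitted per (frame, stop codon): the
5'-most ATG, matching annotation practice; alternative in-frame starts are
suppressed. Near-cognate starts are out of scope. Coordinates are 0-based
half-open on the forward strand, so `end - start = 3 * (aa_length + 1)`
with `aa_length` counting codons without the stop. The smORF limit
"fewer than 100 codons" is `aa_length <= 99`.

Class assignment (`classify_catalog()`) consults a transcript annotation
read from GFF3: an ORF that coincides with an annotated CDS is `sCDS`
(CDS of at most 99 codons) or `canonical`; containment in an annotated
5'UTR, 3'UTR, pseudogene exon, or noncoding transcript gives `uORF`,
`dORF`, `pseudogene` or `lncORF`; ORFs overlapping no transcript are
`intergenic`. Where rules conflict, precedence is CDS evidence > uORF >
dORF > pseudogene > lncORF > intergenic — CDS evidence is strongest, and
the rest follows positional specificity. Two choices were genuinely open:

* ORFs nested inside (but not equal to) a CDS inherit the host CDS's
  class, since the CDS context dominates any other reading of those bases.
* ORFs that overlap a transcript without satisfying any containment rule
  (feature-straddling ORFs, antisense ORFs) are resolved by any-overlap in
  the same precedence order, strand-blind as a last resort. This keeps
  classification a partition: every ORF gets exactly one class.

Curation (`curate_catalog()`) applies three published-style filters in a
fixed order: sCDS on genes that also encode a protein isoform longer than
100 aa are dropped; redundant peptide isoforms (identical, or spans
overlapping at least 80% of the shorter record) are collapsed to the
longest (ties to the 5'-most start); and noncoding RNAs are capped at five
lncORFs each (longest five). The removals are disjoint and reported, and
curation is idempotent.

# GC ratio as a coding-potential statistic

`gc_ratio()` is (G+C)/(G+C+A+T); characters outside A/C/G/T are excluded
from numerator and denominator, softmasked bases count as uppercase
(composition is not repeat status), and an all-ambiguous sequence is an
error rather than a silent zero. GC is computed over the full ORF span
including the stop codon; published class references in *Drosophila* range
from 0.40 (untranscribed intergenic ORFs) through 0.47 (lncORFs) and 0.48
(pseudogenes) to 0.51 (sCDS) and 0.54 (canonical proteins). Those averages
derive from an external genome catalogue, so the package treats them only
as planting constants for synthetic data and qualitative ordering checks,
never as test oracles on real data. `class_summary()`,
`fraction_above()` and `length_gc_profile()` provide the per-class and
length-binned summaries; empty bins are flagged `NA`, never zero.

# Viability and fitness genetics

## Hemizygous crosses

A mutant insertion is scored over a deficiency: the ratio of Insertion/Df
offspring to their Insertion/Balancer siblings (`hemizygous_ratio()`;
balancer trans-heterozygotes are excluded). `classify_viability()` applies
the published thresholds literally: exactly 0 is `lethal`, below 0.1
`semi_lethal`, below 0.7 `low_viability`, otherwise `viable`; the "below"
boundaries are strict. An optional exact binomial test against 1:1
segregation (`hemizygous_test()`) is provided as annotation only.

## Balancer competition

The competition test starts a small population at 1:1 insertion:balancer
allele frequencies and lets it breed. Writing q for the balancer allele
frequency among surviving adults, with balancer homozygotes dead and no
other selection, random mating gives q <- q/(1+q) per generation, closed
form q0/(1 + t q0): from 0.5, q drops to 1/3, 1/4, 1/5 over three
generations, and the survivor genotype ratio II/IB rises 0.5, 1.0, 1.5.
That neutral decay is the null against which a fitness deficit shows.

The selection model weights zygotes II, IB, BB by 1-s, 1-h·s, 0. One
parameter default here deliberately departs from a first reading of the
genetics: **h defaults to 0, not 1**. With h = 1 the two surviving
genotypes share the factor (1-s), so the survivor composition — and with
it every statistic computable from counted flies — is algebraically
invariant in s: a "fully dominant" insertion cost is invisible to this
assay and s is unidentifiable. The informative regime is h < 1; h = 0
(insertion cost recessive, with the balancer heterozygote buffered) is the
natural default and is what the genotype-ratio logic of the test assumes.

`simulate_kr_population()` is the finite-N counterpart: each generation
draws N surviving offspring multinomially from the post-selection genotype
frequencies of the parental gamete pool; populations in which all
insertion-bearing zygotes die are truncated and flagged extinct.

`estimate_selection()` profiles s on a grid (default step 0.001) against
binomial likelihoods of the II count among II+IB survivors, with a 95%
profile-likelihood CI (1.92 log-units). Its default **conditional**
likelihood takes each generation's success probability from the observed
parental counts of the previous generation — the breeding scheme is
Markov, so conditioning removes genetic drift from the sampling model and
the CI holds near-nominal coverage (~95% at N = 500 in the package's own
recovery experiments). The alternative `method = "marginal"` uses the
deterministic trajectory instead; it ignores drift and measurably
undercovers (~80-90% at N = 500), and is retained for comparison.

`classify_fitness()` interprets a ratio statistic at generation 2-3
against 1: below 1 - tolerance the insertion is more deleterious than a
balancer (`lower_fitness`); within the band, `equilibrated`; above,
`higher_fitness`. The default tolerance 0.15 is a pragmatic band around
the published interpretation ("a ratio of 1 indicates the insertion is as
deleterious as a balancer"); note the *neutral* expectation at generation
3 is 1.5, which the reporting surfaces alongside. The default statistic is
the genotype ratio n_II/n_IB — the published description of the ratio
involves a genotype (Bal/Bal) that cannot be observed alive, and n_II/n_IB
is the only Insertion-homozygote ratio computable from surviving flies.
The allele-frequency ratio (1-q)/q is available as an alternative.

# Proteomic detection accounting

All proteomics reports are pure set/count arithmetic at gene level:
`overlap_report()` (shared vs exclusive detections), `detection_rate()`
(against a Ribo-seq-translated reference), `false_positive_analysis()`
(detections outside the Ribo-seq set, minus those explained by prior
proteomics, ambiguous Ribo-seq signal or RNA-seq support, over all
detections in the study — the only denominator consistent with the
published rate), `experiment_yield()` (per-method mean distinct sCDS
detections per experiment and sCDS:canonical ratio) and
`hit_count_distribution()`. Percentages are returned at full precision and
rounded to one decimal only for display (`pct1()`); the source tables'
own printed roundings are not all mutually consistent, so every report
carries its numerator and denominator. When the canonical-count table
carries a method column it defines the experiment roster, so experiments
with zero sCDS detections still count in the per-experiment mean.

# Indicator integration

`build_indicator_table()` outer-joins per-gene sequence features, a
proteomic detection flag, conservation/RNAi annotation flags (consumed as
given, never computed — homology search is out of scope) and phenotype
calls; genes with phenotype calls but no catalogue entry are retained with
missing sequence fields. `group_summary()` reports per-phenotype-group
percentages and means with missing values excluded per column and all
denominators emitted. `functional_fraction()` is the headline statistic:
mutant calls over non-untested genes. `association_tests()` (odds ratio,
exact test, Benjamini-Hochberg) is an added analysis beyond the
descriptive published comparison and defaults to off in reports.

The packaged per-gene fixture transcribes the published 46-gene
insertional screen (21 mutant, 25 wild-type). The hemizygous-stage (20 of
43) and pooled-comparison (47 of 76) tables were published only as
margins; their per-gene stand-ins are synthetic, constructed to realise
those margins, and are named and documented as such.

# The synthetic-data generator

`gen_genome()` plants ORFs of every class on one contig per class, each
inside an annotation cassette consistent with its class (mRNA with the ORF
as CDS; a 120-aa host CDS with the ORF in the 5' or 3'UTR; noncoding RNA;
pseudogene exon; bare spacer). Spacer and flank sequence is generated at
GC 0.40, scrubbed of ATG and CAT so it can neither seed nor extend an ORF,
and seeded with a 12-mer carrying stop codons in all three frames (its own
reverse complement) at least every 48 nt, so planted ORF boundaries are
exactly recoverable by the 5'-most-ATG rule. ORF bodies are drawn from the
61 sense codons with a per-base G+C probability calibrated by root-finding
so that the expected GC of the whole span — fixed ATG, uniform stop —
equals the planted class mean exactly; without that calibration the
ATG/stop composition bias (~0.007) would exceed the 3-standard-error band
(~0.004) at 500 ORFs per class. Class length distributions are truncated
normals chosen to mimic the field's catalogues (sCDS mean 73 aa on
[20, 99]; lncORFs mean 30 aa; UTR ORFs mean 25 aa; canonical 120-400 aa).
UTR ORF classes have no published GC reference and are planted at
0.45-0.46, between intergenic and lncORF.

What the generator does *not* emulate: multi-exon transcripts, isoform
complexity, codon-usage structure beyond composition, chromatin context,
and mass-spectrometry peptide chemistry. A green test on synthetic data
therefore establishes the correctness of the arithmetic and the
statistical machinery, not the biological fidelity of any particular
genome.

`gen_cross_counts()` draws Insertion/Df counts binomially with success
probability v/(1+v) for true relative viability v. `gen_kr_counts()`
wraps the stochastic competition simulator. `gen_detection_tables()`
gives each gene a lognormal translation covariate and makes per-experiment
detection Bernoulli with logistic probability in the log covariate
(calibrated per method so the expected distinct detections per experiment
match the configured means, 2.55 for PunchP-style and 23.7 for
gel-fractionation-style experiments); false detections outside the
reference set are planted at a configured share (default 7.1%) of
detected genes. The logistic form is the generator's choice — the source
observation is only a qualitative covariate difference between detected
and undetected genes.

# Numerical and testing conventions

All randomness flows through R's RNG under caller-supplied seeds; the
generators contain no time-based entropy, so equal seeds give byte-equal
outputs. Percentages are full precision internally. The acceptance tests
freeze expected values as exact fractions (e.g. 100·21/46) or derive them
from independent oracles written against the enumerative definitions: a
brute-force six-frame ORF scan and an explicit Punnett-square iteration,
neither sharing code with the implementation. Monte-Carlo checks use
3-standard-error bands around planted values at fixed seeds.

# Known limitations

* Classification assumes the single-exon transcript models the generator
  emits; multi-exon CDS spans are reduced to their genomic range, which
  can over-claim "coincidence" for spliced CDS.
* The selection model is a single per-genotype viability weight: no
  fecundity component, sex chromosomes, maternal effects or linked
  modifiers, and recombination is irrelevant only because balancers
  suppress it.
* The catalogue is per-ORF; whether a published catalogue of 887 sCDS
  counts genes or transcripts is unstated, so gene-level rollup is left to
  reporting.
* Conservation and RNAi-hit columns are annotation inputs; the package
  deliberately implements no homology pipeline.
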