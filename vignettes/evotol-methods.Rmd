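---
title: "Methods behind evotol: screening, enrichment, variant triage and backcross simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind evotol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evotol)
```

evotol implements the desk-scale statistical and combinatorial machinery of
a reverse-engineering workflow for microbial stress tolerance: a
plate-based deletion-collection screen scored by a sensitivity index, GO
term enrichment of the hit set, a whole-genome variant filter and
codon-level annotation for evolved strains, and a Monte Carlo backcross
simulator for allele-attrition expectations. This vignette explains each
model, its assumptions, the tunable parameters, and the numerical and
design choices made where the design was open.

## The growth model and the butanol sensitivity index

Synthetic plate assays are generated from a logistic growth model in which
one Hill-type inhibition factor

$$f(c) = \max\left(0,\; 1 - (c/c_{\max})^h\right)$$

scales both the specific growth rate, $\mu(c) = \mu_0 f(c)$, and the
carrying capacity, $K(c) = K_0 f(c)$, at butanol concentration $c$ (% v/v).
The OD660 trajectory is the exact logistic solution from inoculum `od0`;
above $c_{\max}$ (or when $K(c)$ falls to the inoculum) the culture cannot
grow and the curve stays flat. Optional measurement noise is multiplicative
lognormal, i.i.d. per reading.

Defaults describe a laboratory yeast strain in a sealed microtitre plate:
$\mu_0 = 0.40\ \mathrm{h^{-1}}$, $K_0 = 1.2$ OD660, `od0` $= 0.05$,
$c_{\max} = 1.45$ % v/v, `noise_sd = 0` unless asked for. Because a single
factor scales rate and plateau alike, calibrating the model to a target
stationary-phase OD ratio $\rho$ at 1% butanol has a closed form,

$$h = \frac{\log(1 - 1/\rho)}{\log(1/c_{\max})},$$

implemented in `calibrate_reference()`. The reference calibration
($\rho = 2$ at 1%, no growth above 1.45%) gives $h \approx 1.865$.

The butanol sensitivity index (BSI) is the 48-h OD660 ratio between the
unstressed and the 1%-butanol condition. `compute_bsi()` floors the
denominator at 0.01 OD so that non-growing cultures yield a large finite
index rather than infinity, and rejects control ODs at or below 0.02 as
failed assays. One numerical consequence of finite incubation is worth
stating: at 48 h a culture with the default $\mu_0$ has not saturated with
infinite-time precision, so the BSI of the calibrated reference strain is
about 2.0015 rather than 2 exactly. The package treats this as a property
of the assay, not an error; tests that verify the closed-form calibration
identity to high precision do so on long-duration curves where saturation
is complete.

## Screen scoring, classification bands and triage

`summarize_screen()` aggregates replicate wells by averaging the 48-h ODs
per condition first and taking the ratio of the means — not the mean of
per-well ratios, which is biased upward for noisy denominators. Failed
control wells are dropped before averaging.

`classify_strain()` bins a strain by its BSI and its 48-h OD in butanol:
`tolerant` for BSI in $[1, 2)$, `reference_like` within $2 \pm 0.25$,
`sensitive` for BSI in $(2, 10]$ with OD $> 0.1$, `hypersensitive` for
BSI $> 10$ with OD $< 0.08$, and `indeterminate` otherwise. These bands
overlap by construction (the reference band straddles 2), so a precedence
order is needed; the package applies hypersensitive → reference-like →
sensitive → tolerant → indeterminate. Putting the reference band ahead of
`sensitive`/`tolerant` means a strain indistinguishable from the reference
is never binned as a marginal hit merely because its index landed at
2.0001. The OD gap between 0.08 and 0.1 for high-BSI strains is left
`indeterminate` deliberately: calls in that window are ambiguous between a
weak grower and a noisy blank.

`triage_screen()` is pure bookkeeping with validation: hits minus dubious
ORFs plus extra picks gives the tested set; minus transformation failures,
the viable set; intersected with confirmation, the confirmed set. Overlap
and subset violations are errors, not warnings.

## GO enrichment

Enrichment of a study set of $n$ genes against a population of $N$ genes
uses the hypergeometric upper tail: for a term annotating $K$ population
genes of which $k$ are in the study,

$$p = \sum_{i=k}^{\min(K,n)}
  \frac{\binom{K}{i}\binom{N-K}{n-i}}{\binom{N}{n}}.$$

The tail is computed in log space via `lchoose()` and log-sum-exp, which
is stable for the $N \approx 5000$, deep-tail regime the workflow needs.
Annotations are first closed over the `is_a` ontology graph
(`propagate_annotations()`): a gene annotated to a term is annotated to
every ancestor, with set semantics so diamond-shaped paths count once.
Cycles in the parent graph are rejected at construction. Multiple testing
uses Benjamini–Hochberg step-up (`bh_fdr()`); terms with adjusted value
below `alpha` (default 0.05) are flagged. Terms annotating fewer than
`min_population_count = 2` population genes are not tested — singleton
terms cannot be enriched and only dilute the correction. Both the tail and
the FDR are hand-authored because they are the analytical core of this
stage; the test suite cross-checks them against `stats::phyper` and
`stats::p.adjust` as independent oracles, exhaustively for all population
sizes up to 30.

## Variant filtering

`run_filter_chain()` reduces an evolved strain's SNV calls against its
parent with five rules, applied as one pass with first-failing-rule
provenance: (1) indels (multi-base REF or ALT) are set aside; (2) ALT
alleles outside A/C/G/T (IUPAC ambiguity codes) are removed; (3) Phred
quality below 20; (4) read depth outside $[10, 400]$, both bounds
inclusive — too shallow is unreliable, too deep marks repeats and
mitochondrial bleed-through; (5) allele-aware parental subtraction: a call
is removed only when chromosome, position, REF and ALT all match a
parental call, so a different substitution at a shared site survives.
Multi-allelic records are split into one call per ALT before any rule
runs. The rules are logically independent, so the survivor set is
invariant to their order; "first failing rule" affects only the provenance
label on removed calls. Survivors are sorted by chromosome and position,
and a report object carries per-rule removal counts that always sum to the
input size.

## Codon arithmetic and consistency checking

For an intronless CDS, coding-nucleotide position $p$ (1-based) lies in
codon $\lceil p/3 \rceil$ at within-codon offset $((p-1) \bmod 3) + 1$.
`consistency_check()` asks whether a reported amino-acid change is
*possible* given a nucleotide substitution: it first compares the reported
residue number against the codon number computed from $p$
(`position_mismatch` if they differ), then enumerates all 64 codons and
keeps those that encode the reported reference residue and carry the
reference base at the computed offset; if substituting the alternate base
in any of them yields the reported alternate residue, the verdict is
`consistent`, otherwise `inconsistent`. These are existence semantics —
without the actual gene sequence the check can refute a report but cannot
confirm which codon the gene uses. The genetic code table is written out
by hand and verified in tests against an independently packaged copy.

`classify_location()` places genomic calls on intronless gene models as
coding, upstream (within a configurable promoter-proximal window, default
1000 bp, measured to the translation start on the correct strand) or
intergenic; minus-strand calls are converted to CDS coordinates from the
3' end with reverse-complemented alleles. A call covered by more than one
model is annotated against each and flagged ambiguous rather than
resolved silently.

## Backcross simulation

Meiosis of an evolved × naive diploid is simulated at the gamete level:
for each of two independent strands, the chain of loci along a chromosome
is walked with crossover probability between adjacent loci given by the
Haldane map function $r = \tfrac12(1 - e^{-2d/100})$ ($d$ in cM); loci on
different chromosomes assort independently. A tetrad consists of the two
simulated spores plus their allelic complements, which enforces exact 2:2
segregation at every heterozygous locus — a structural property of
meiosis, not an asymptotic one. Spore selection mimics the laboratory
protocol: a spore must carry the required marker state (e.g. the native
URA3 allele) and reproduce the evolved phenotype, either by carrying every
causal allele (`all_causal_required`) or by reaching an additive score
within `epsilon` of the full evolved score (`additive_threshold`). Each
backcross cycle mates the selected spore to the naive parent again;
a configuration whose phenotype rule no spore can satisfy is reported as
an error after `max_tetrads` attempts.

`estimate_retention()` repeats the whole series and reports per-locus
retention frequencies with exact binomial confidence intervals
(`stats::binom.test`). The Mendelian closed forms — $(1/2)^n$ for an
unselected unlinked locus after $n$ cycles, $(1-r)^n$ for a locus linked
at recombination fraction $r$ to a selected one, and retention 1 for the
selected loci themselves — are the oracles the test suite checks against,
at $10^4$ replicates within three Monte Carlo standard errors.

## What the synthetic generators do and do not emulate

`generate_screen()` plants a sensitivity class per strain (largest-
remainder apportionment of the requested proportions, so counts always sum
to the collection size) and draws replicate noisy curves from the class
dose-response. It emulates plateau-level differences and multiplicative
reader noise; it does not emulate spatial plate effects, evaporation
gradients, lag-phase heterogeneity, cross-well contamination, or the
correlated replicate structure of real pinned plates. A high recovery rate
on synthetic screens therefore demonstrates correctness of the scoring and
banding logic, not robustness to every plate artefact.

`generate_variants()` plants clean strain-specific calls, parental-shared
calls, and noise calls that each violate exactly one filter rule while
passing the others, cycling through the rules. It does not emulate
alignment artefacts, strand bias, or clustered mutations; it is a
specification oracle for the filter, not a sequencing simulator.
`generate_go_annotations()` plants enriched terms of known size under a
single root plus random background terms; real ontologies are deeper and
their annotation sizes heavy-tailed.

## Problem sizes and reproducibility

All stochastic functions take explicit integer seeds and restore the
caller's random-number state, so identical seeds give byte-identical
output. The default end-to-end replay (`run_replay()`) uses a 300-strain
screen at 4-h sampling, a population of 5154 genes for enrichment, and
2000 backcross replicates; the test suite uses screens of 40–5154 strains
(the largest noise-free and sparsely sampled), an exhaustive enrichment
oracle up to $N = 30$, 1000 random call sets for filter properties, and
$10^4$ replicates for the backcross null. These sizes are the package's
own choices, made so that the full suite runs in a few minutes on one CPU
while keeping every Monte Carlo tolerance at three standard errors.

## Known limitations

- The growth model has no lag phase and no death phase; the BSI of real
  cultures sampled before saturation will differ from the plateau ratio.
- The consistency check cannot confirm a reported substitution, only
  refute one; confirming requires the gene sequence, which the annotation
  module deliberately does not ingest.
- The backcross simulator assumes full spore viability, no gene
  conversion, no chromatid interference (implied by Haldane), and
  unstructured tetrad sampling.
- The minimal VCF reader handles the eight fixed columns and `DP=` depth
  only; genotype fields, phasing and structural variants are out of scope.
- Enrichment treats annotations as certain and genes as exchangeable; no
  gene-length or expression bias correction is applied.
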