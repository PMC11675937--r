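---
title: "Linking tRNA abundance to mRNA stability and translation efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking tRNA abundance to mRNA stability and translation efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnadapt)
```

## The analysis in one paragraph

Synonymous codons are not equivalent: codons decoded by abundant tRNAs are
translated efficiently and stabilize their mRNAs, while codons decoded by
rare tRNAs slow elongation and trigger codon optimality-mediated decay.
`trnadapt` takes measured tRNA abundances (tRNA-seq count tables) for two
cell states — for instance neural progenitor-biased versus neuron-biased
brain tissue — together with a coding transcriptome, per-gene mRNA
half-lives and mRNA abundances, and computes the standard family of codon
optimality and translation-adaptation metrics in both states: the codon
stabilization coefficient (CSC), the tRNA adaptation index (tAI and its
gene-level geometric mean tAI_gene), the codon adaptation index (CAI), and
the supply/demand ratio (SDR, with its cross-state difference ΔSDR). A
synthetic-data module generates all inputs with planted ground truth so
that every stage is testable end to end.

## Pipeline stages and their models

### 1. Isodecoder reference and isoacceptor pools

tRNA genes sharing an anticodon (isoacceptors) often differ in body
sequence (isodecoders), and some isodecoders are byte-identical at the
mature-sequence level. `build_isodecoder_reference()` collapses identical
mature sequences into one reference entry, appends the universal
post-transcriptional `CCA` 3' end, and names merged groups with an `-X`
suffix (with an ordinal, ordered by sequence, if several merged groups
share an anticodon family). Quantification happens at the isodecoder level;
`aggregate_isoacceptors()` then averages member isodecoders into the
anticodon-level pool, which is the quantity that matters for decoding:
one anticodon pool serves all cognate codons.

Selenocysteine, pseudogene and mitochondrial records are parsed but
excluded from isoacceptor pools and all downstream metrics — the analysis
targets cytosolic decoding of the standard 20 amino acids. Initiator Met is
kept as its own isoacceptor but excluded from tAI supply, since tAI models
elongation.

Because tRNA references always get a `CCA` appended, genomes that encode a
CCA genomically would end up with a doubled `CCA`; inputs are assumed to be
gtRNAdb-style mature sequences without it.

### 2. TMM normalization and fold changes

Between-sample normalization uses the trimmed mean of M-values: for each
sample against a reference sample, log ratios (M) and average log
abundances (A) of library-scaled counts are computed over features nonzero
in both samples, doubly trimmed (30% on M, 5% on A by default), combined as
a precision-weighted mean, and the resulting factors rescaled to geometric
mean 1. The reference sample is the one whose upper quartile is closest to
the mean upper quartile. These are the de facto published defaults; all are
arguments. The implementation is validated against an independent
brute-force oracle and against `edgeR::calcNormFactors` in the test suite.

Condition fold changes are `log2(mean_a / mean_b)` of normalized replicate
means, flagged at `|log2FC| >= 0.5` (boundary inclusive). When either mean
is zero, a pseudocount of 0.5 normalized units is added to both to avoid
infinities. Differential-expression *significance* is deliberately out of
scope: the package emits fold changes and threshold flags and can join an
externally computed q-value column (filtering at q <= 0.1) rather than
re-implementing a Bayesian count model.

One open choice is whether isoacceptor aggregation should weight multi-copy
(`-X`) isodecoder groups by gene copy number. The default is the unweighted
mean of isodecoder-group values; `copy_weights` enables the weighted
variant.

### 3. Codon usage matrices

For each CDS the 61 sense codons are counted (a single terminal stop is
stripped silently; an internal stop is an error by default because
half-life/CDS tables should be clean, with a documented truncating lenient
mode; codons containing ambiguous bases are skipped and logged). The
length-normalized frequency of codon *i* is its count divided by the total
sense codons in the CDS, so each gene's frequency row sums to 1.

For multivariate analysis the frequencies are additionally normalized
*within* synonymous families: each codon's value is its count over its
amino-acid family total, removing amino-acid-usage and gene-length effects
so that only synonymous choice remains. The two single-codon families (ATG,
TGG) carry no within-family variance and are dropped, which is what makes
the representation 59-dimensional. Families absent from a gene get 0 for
all members by default (a uniform 1/k option exists); PCA centering absorbs
the offset.

### 4. Optimality and translation-efficiency metrics

**CSC.** The codon stabilization coefficient of codon *c* is the Pearson
correlation, across genes, between the codon's frequency and mRNA
half-life. Half-lives are used in hours on their natural scale (a log
option exists). Codons are classed as optimal (CSC >= 0.01), non-optimal
(CSC <= -0.01) or neutral (strictly between); both boundaries are
inclusive of their class.

**tAI.** The raw decoding weight of a codon is

$$W_c = \sum_j (1 - s_{cj})\, \mathrm{TMM}_{cj}$$

summing over cognate anticodons *j*: the Watson-Crick anticodon (the
reverse complement of the codon) plus wobble-readable anticodons. The
penalties follow the dos Reis constrained values — s = 0 for all
Watson-Crick pairings, s(G:U) = 0.41, s(I:C) = 0.28, s(I:A) = 0.9999,
s(U:G) = 0.68 — with a genomically encoded anticodon A treated as inosine,
and the bacterial lysidine rule (s = 0.89) carried but disabled in the
default eukaryote mode. Measured abundances (mean TMM per condition)
replace the gene copy numbers of the classical formulation. Two codons need
special handling: ATG is restricted to the elongator-Met anticodon CAT
(a generic U:G rule would count Ile tRNAs as Met cognates) and TGG to CCA
(excluding the selenocysteine anticodon). tAI is then normalized within
each synonymous family by the family maximum, so the best-decoded codon of
every family scores exactly 1; `tAI_gene` is the geometric mean of tAI over
a gene's codon positions, computed as the exponential of the mean log for
numerical safety. A codon with zero weight occurring in a scored gene is an
error by default; the lenient mode substitutes the smallest positive tAI
(the dos Reis geometric-mean substitution is a documented alternative via
the `floor` argument).

**CAI.** Relative adaptiveness *w* of a codon is its count in a pooled
reference set (classically ribosomal protein genes; the pipeline falls back
to the top 5% of genes by mean expression when no reference is supplied)
divided by the count of its family's most-used codon — equivalently RSCU
over the family-maximal RSCU. Codons unused in the reference get a 0.5
pseudo-count. CAI is the geometric mean of *w* over the gene's codons,
excluding ATG and TGG per the standard formulation.

**SDR.** Demand for codon *c* is the expression-weighted average of its
frequency across the transcriptome, renormalized to sum 1 over sense codons
— the renormalization makes SDR dimensionless and invariant to expression
units, which the classical formula leaves open. Then SDR_c = tAI_c /
demand_c, gene-level SDR is the geometric mean over codon positions, and
ΔSDR = SDR(condition B) − SDR(condition A), with top/bottom 10% tail
selection on the ranking. Because the demand scale is a normalization
choice, absolute SDR and ΔSDR values are comparable within an analysis but
not across differently normalized ones.

**Cross-state comparisons.** `tai_csc_effect()` quantifies the separation
in tAI between stabilizing and destabilizing codons with a pooled-SD
Cohen's d and Welch's t-test; grouping by CSC sign is the default, with the
±0.01 classes as an option (both groupings are defensible and the choice is
exposed). `differential_tai_csc()` labels each codon by whether tAI changed
(|ΔtAI| >= 0.2) and whether the CSC class changed, in the same or opposite
direction: `concordant`, `discordant`, `tai_only`, `csc_only`,
`no_difference`. The `discordant` label is an addition — a label set
without it cannot represent both-changed-but-opposite codons.

### 5. Multivariate structure

PCA runs on the centered (unscaled) 59-dimensional amino-acid-normalized
matrix; values already live on comparable [0, 1] scales, and a z-score
option exists. Component signs follow a fixed convention (largest-magnitude
loading positive) so results are deterministic. k-means runs on the
59-dimensional matrix itself rather than on retained PC scores — clustering
the full matrix avoids making the result depend on how many components are
kept; PCA provides the visualization coordinates. "Elbow method" alone is
not an algorithm, so the rule is made explicit: k is chosen at the maximal
second difference of the inertia curve over the candidate range, and the
full inertia trace is returned so the choice can be overridden. All
stochastic steps take explicit seeds and are bit-reproducible.
`tai_gene_groups()` assigns the shared-high / shared-low / neuron-up
patterns either from hierarchical-cluster blocks of the two-column
tAI_gene matrix (default) or from explicit quantile thresholds.

## The synthetic-data generators

The generators emit exactly the file formats the pipeline consumes, and
every one is a pure function of (parameters, seed):

- `gen_trna_set()` — gtRNAdb-style named genes; a deterministic *covering*
  anticodon set option guarantees every sense codon is decodable; selected
  families receive byte-identical duplicate sequences to exercise
  collapsing.
- `gen_counts()` — negative-binomial replicate counts (dispersion 0.05 by
  default, Poisson at 0) around log-uniform baseline means, with condition
  B means shifted by planted log2 fold changes and library sizes jittered
  ±20%, emulating a triplicate-per-condition design at a depth of 10^6.
- `gen_transcriptome()` — per-profile synonymous-codon preferences built as
  a divergence-weighted mixture of a shared Dirichlet draw and
  profile-specific Dirichlet draws, so divergence 0 yields identical
  profiles; amino-acid composition is held fixed across profiles, isolating
  exactly the signal the amino-acid normalization is designed to retain.
  Genes are sampled codon by codon, so internal stops cannot occur.
- `gen_halflives()` — half-life = baseline + Σ β_c · freq + Gaussian noise,
  floored at 0.1 h. When no noise SD is given it defaults to 25% of the
  noiseless signal range, a regime in which planted stabilizing and
  destabilizing codons remain recoverable by CSC.
- `gen_expression()` — log-uniform expression over a configurable dynamic
  range, optionally up-weighting one profile's genes in one condition to
  move codon demand.

`simulate_study()` composes these into a two-condition scenario: condition
B's tRNA pool up-weights (log2 fold change +2) the anticodons decoding the
codons preferred by profile 2 and down-weights those preferred only by
profile 1; planted half-life coefficients are coupled to decoding supply
(scaled log Watson-Crick cognate abundance), so abundant tRNAs correspond
to stabilizing codons as they do in real data. Profile 2 is a 20% minority
class: codon-usage programs identified in real transcriptomes are small
minorities, and enrichment statistics over a 50/50 split would be
uninformative (a top decile can be at most 2-fold enriched over a 50%
baseline). Default problem sizes (600 genes in the study scenario, 2000 for
the dedicated recovery analyses, 80 isodecoders for fold-change recovery)
were chosen so that each planted signal is comfortably above its sampling
noise while a full run remains interactive.

What the generators deliberately do **not** emulate: multimapping and
alignment artefacts of real tRNA-seq (the pipeline starts at count
tables), tRNA modifications and charging state, batch effects,
length-dependent or UTR-mediated decay, and any coupling between codon
usage and amino-acid composition. Passing recovery tests therefore
demonstrates that the estimators recover the signals they model, under the
noise structure they assume — not that those signals dominate real tissue
data.

## Numerical and degenerate-input choices

- Geometric means are computed as `exp(mean(log(x)))`; zero factors are
  errors (strict) or floored (lenient, logged).
- CSC is undefined (NA, logged) for codons with zero frequency variance; a
  constant half-life vector is an error.
- An amino-acid family with zero total decoding weight is an error naming
  the family, as is zero demand for a codon that occurs in a scored gene.
- Ranking ties (content ranking, ΔSDR) break by gene id, so outputs are
  deterministic.
- Genes missing a half-life or expression value are dropped from the
  affected metric with a logged count, mirroring analyses restricted to the
  transcripts detected in both states.
- Fold-change, CSC-class, ΔtAI and content thresholds are all boundary
  inclusive.

## Limitations

- hydro-tRNAseq-style counts do not distinguish charged from uncharged
  tRNAs; tAI built on them assumes total abundance is a fair proxy for
  usable supply.
- CSC is a marginal correlation: frequency covariance between codons (via
  amino-acid composition and usage profiles) contaminates individual
  coefficients, which is visible even on synthetic data as attenuated
  recovery for weakly planted codons.
- The absolute SDR scale depends on the demand normalization; only
  within-analysis comparisons (rankings, differences, correlations) are
  meaningful.
- Isodecoder-level differential calls here are threshold flags on
  normalized fold changes, not significance tests.
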