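---
title: "Promoter, expression and composition analysis of bacterial sHSP genes"
author: "sHSPpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter, expression and composition analysis of bacterial sHSP genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sHSPpipe)
```

# Scope

Small heat-shock proteins (sHSPs, the HSP20 family: 12–43 kDa,
ATP-independent chaperones built around an α-crystallin domain) are a
core part of the bacterial heat-shock response. In many bacteria their
transcription is driven by the alternative sigma factor σ32, which
recognises a bipartite promoter: a 6-bp −35 element and an 8-bp −10
element separated by a spacer of variable length. A typical sHSP study
in an organism such as *Acidithiobacillus ferrooxidans* combines four
computational strands, and this package implements all of them as one
tested pipeline:

1. **σ32 promoter discovery** — positional weight matrices (PWMs)
   built from an aligned promoter training set, scanned over the 200
   bases upstream of each start codon, with scores and information
   content reported in bits;
2. **qRT-PCR relative expression** — the comparative threshold-cycle
   (ΔΔCt) method with an endogenous-control gene, replicate
   statistics, Student's t-test and a joint significance rule;
3. **GC-composition screening** — a Pearson χ² comparison of each
   gene's GC content against the genome-average coding GC, flagging
   candidate horizontal acquisitions;
4. **protein characterisation** — length, average molecular weight,
   theoretical pI, and global pairwise identity/similarity;

plus in-silico PCR for primer verification and a synthetic-data
generator that emulates the whole experimental design with known
ground truth.

Out of scope by design: phylogenetic tree inference, transcription
start-site prediction, homology modelling, and any structure-based
analysis. Multiple-alignment display, Gibbs-sampling motif discovery
and efficiency-corrected qPCR models are also not goals.

# The promoter model

## Construction

From a training set of aligned sites — 6-nt −35 elements, observed
spacer lengths, 8-nt −10 elements, one row per promoter — each element
gets its own PWM. With $n_{l,b}$ the count of base $b$ at position
$l$, $N$ sites, and pseudocount $c$:

$$p_{l,b} = \frac{n_{l,b} + c}{N + 4c}.$$

The default pseudocount is $c = 0.5$ per base. Curated σ32 training
sets are small (18 sites is typical), so unsmoothed matrices contain
zero-probability bases whose log-odds is $-\infty$; half a count is
the smallest conventional smoothing that keeps every score finite
without visibly distorting the observed frequencies.

The admissible spacer range is taken from the training set (observed
minimum to observed maximum), and the spacer contributes **no score
penalty**: a candidate site is scored purely as the sum of its two
block scores. With nothing known about the spacer-length energetics
beyond "variable", a flat profile over the observed range is the
assumption that adds no invented structure.

## Scoring and information content

All scores are in bits. For a site $s$ under background composition
$q$ (equiprobable by default),

$$R_i(s) = \sum_l \log_2 \frac{p_{l,s_l}}{q_{s_l}}, \qquad
R_{sequence} = \sum_l \sum_b p_{l,b} \log_2 \frac{p_{l,b}}{q_b}.$$

$R_i$ is the individual information of one site (identical to its
log-odds score in bits); $R_{sequence}$ is the expected per-site
information of the model, 0 for a uniform matrix and 2 bits per
position for a one-hot matrix. The consensus site maximises $R_i$ —
the test suite asserts this on random matrices. Because a bipartite
hit's "total bits" can mean either the model's $R_{sequence}$ or the
per-site $R_i$ of the highlighted boxes, the scan reports per-site
values (`bits35`, `bits10`, `total_bits`) and the model's
$R_{sequence}$ is available separately via `informationContent()`;
figure-style displays in the literature are ambiguous between the
two, so both are exposed and neither is treated as a reference value.

A GC-parameterised background (`gcBackground(gc)`, $P(G)=P(C)=gc/2$)
can replace the equiprobable default: *A. ferrooxidans* coding
sequences average ~59% GC, which penalises GC-rich chance matches.
The default stays equiprobable because bits reported against a
uniform background are the standard Schneider-style convention.

## Scanning

`scanUpstream()` enumerates **every** placement of the two blocks
with a spacer in the admissible range (no heuristics, no early
termination) and returns all of them, best first. Ties are broken by
smaller distance to the start codon, then by leftmost −35 position:
biologically, promoters closer to the gene are preferred, and a
deterministic order makes outputs reproducible to the byte. The
window is the 200 bases immediately 5′ of the start codon, in coding
orientation (minus-strand genes are reverse-complemented), and is
**not** clipped at upstream gene boundaries — the scan is a fixed
window, operon context deliberately ignored. An exhaustive scan of a
200-nt window against a 6+8 model costs under a millisecond, so
nothing faster is warranted.

```{r promoter-demo}
ts <- simulateTrainingSet(seed = 42)
model <- fitSigma32Model(ts)
model
u <- simulateUpstream(planted = TRUE, seed = 11)
head(scanUpstream(model, u$seq), 3)
u$truth
```

# Relative expression (ΔΔCt)

Per replicate, $\Delta Ct = Ct_{target} - Ct_{reference}$ cancels
sample-loading differences through an endogenous control (the alanyl-
tRNA synthetase gene *alaS* in the default design — assumed constant
across conditions). Then
$\Delta\Delta Ct = \overline{\Delta Ct}_{treat} -
\overline{\Delta Ct}_{control}$ and the fold change is
$2^{-\Delta\Delta Ct}$, assuming doubling per cycle (efficiency 2.0,
the Livak assumption; efficiency correction is out of scope). The
p-value is a two-sided two-sample Student's t-test on the replicate
$\Delta Ct$ sets; equal-variance by default ("Student's t-test" read
literally), Welch by flag. Significance requires **both** $p <
\alpha$ (strict inequality, $\alpha = 0.05$) and fold change $\geq
2$ — the fold floor guards against statistically detectable but
biologically trivial shifts.

Replicate structure: with a `technical` column present, technical
replicates are averaged within each biological replicate before
testing (`replicateModel = "biological"`, the default), so the t-test
sees biological variation only; `"pooled"` treats every measurement
as independent, which overstates precision but is offered for
comparison because the error model behind published triplicate
designs is often unstated.

```{r expression-demo}
ct <- simulateCtTable(noiseSd = 0, seed = 5)
relativeExpressionTable(ct, "alaS", "control_30C")[, c(
  "gene", "condition", "fold_change", "significant")]
```

# GC-composition screen

For a gene of $n$ unambiguous bases with $g$ G+C, tested against an
expected fraction $p$ (default 0.59, a typical genome-average coding
GC for *A. ferrooxidans*; `codingGC()` recomputes it from a CDS
collection):

$$\chi^2 = \frac{(g - np)^2}{np(1-p)},$$

the Pearson one-degree-of-freedom statistic on the observed (GC, AT)
split. Genes with $p\text{-value} < 0.01$ are flagged as candidate
horizontal acquisitions. GC is computed on the annotated CDS from
start through stop codon inclusive — reproducible from annotation
alone. `N` bases are excluded from numerator and denominator. The
test is asymptotic; a warning fires when an expected count drops
below 1. Composition is a deliberately coarse HGT signal: amelioration
erodes it over time and codon-level metrics are out of scope here.

# Protein characterisation

Molecular weight is the sum of average (isotope-weighted) residue
masses plus one water (18.0153 Da); average rather than monoisotopic
masses because that is the convention under which ~16-kDa chaperone
masses are reported. The theoretical pI solves net charge = 0 by
bisection on pH ∈ [0, 14] to $10^{-4}$; charge is Henderson–
Hasselbalch over the termini and the D, E, C, Y, H, K, R side chains
with the Bjellqvist pKa set (the ProtParam convention, including its
residue-specific terminal corrections). The charge function is
strictly monotone in pH, so the root is unique; the suite checks the
returned pH has |charge| < 10⁻³ and cross-checks frozen values from
an independent implementation of the same convention.

Pairwise identity and similarity come from a Needleman–Wunsch global
alignment (BLOSUM62, gap opening 10, gap extension 0.5 — alignment
parameters in published tables are rarely stated, so agreement with
any external value is only ever asserted within a band). Identity is
the fraction of alignment columns (gaps in the denominator) with
identical residues; similarity additionally counts positive-score
residue pairs.

# The synthetic-data generator

The generator exists so that every stage runs end-to-end with known
ground truth and no downloads. It emulates the design of a three-gene
bacterial sHSP heat-shock study:

* **Training sets**: 18 sites, consensus −35/−10 pair mutated per
  base at rate 0.1 (a mutation always changes the base), spacers
  uniform on 11–15 nt. These defaults give models of ~15 bits, the
  regime where planted-site recovery is expected to be essentially
  perfect.
* **Upstream windows**: 200 nt, i.i.d. background at configurable GC
  (default 0.5), consensus boxes planted at a recorded position.
* **Genes**: i.i.d. bases at a target GC. The null-calibration
  simulations use 450-nt genes — the length scale of sHSP CDSs
  (405–447 nt for the three-study-gene design) — where the discrete
  χ² test's exact size at α = 0.01 stays well inside the binomial
  99% interval used by the calibration check.
* **Ct tables**: the Livak model inverted — $Ct = Ct_{base} -
  \log_2(\text{fold}) + \mathcal{N}(0, \sigma)$, reference gene held
  at fold 1, default noise σ = 0.2 cycles and 3 replicates, matching
  a clean triplicate qPCR run. The default time course
  (`defaultHeatShockDesign()`) rises to folds (3.48, 40, 2) at 60
  min, placing the strongest responder 20-fold above the weakest and
  11.5-fold above the intermediate gene — the between-gene contrast
  structure reported for the *A. ferrooxidans* sHSP trio; absolute
  folds are not published, so 40 for the top responder is a choice,
  made once, at the scale typical of strong heat-shock induction.

What the generator does **not** emulate: amplification-efficiency
drift, probe chemistry artefacts, operon structure, codon usage,
compositional autocorrelation along real chromosomes, or sequence
evolution. Passing tests on synthetic data therefore demonstrate the
correctness of the computations and the calibration of the tests
under the stated error model — not robustness to real-data artefacts
outside that model.

Each generator draws from its own named PRNG stream derived from
(seed, generator name), and restores the caller's RNG state, so
workflows are bit-reproducible and adding one more simulated object
never perturbs existing draws.

# Numerical and design choices

* Coordinates are 1-based inclusive everywhere a position is read or
  reported (GenBank convention).
* Primer matching is exact — no mismatches, no ambiguity codes —
  because verification primers are designed for perfect template
  match; more than one productive amplicon is an error, not a
  warning, since it signals non-specific primers.
* Translation uses the bacterial/archaeal code (table 11); GTG/TTG
  initiators are reported as M at position 1 (with a message), and a
  non-initiator first codon is a warning, not an error, so partial
  CDSs remain translatable.
* The scan orders hits by (score, proximity to start, leftmost) —
  every key deterministic.
* Reports print GC% and pI to 2 decimals and molecular weight to the
  nearest Da, matching how such tables are conventionally printed;
  underlying functions return full precision.
* Pipeline runs write a parameter/log line per stage and no
  timestamps into result files, so identical config + seed gives
  byte-identical output.
* Printed χ² statistics in published composition tables are often not
  recoverable from the printed GC%, lengths and background (the exact
  formulation goes unstated); this package implements the standard
  Pearson test and treats published significance *patterns*, not
  statistic values, as the reproducible quantity.

# Problem sizes

The bundled checks run: brute-force scan equivalence on 100 random
model/window pairs (windows ≤ 60 nt); planted-site recovery on 200
windows of 200 nt; ΔΔCt recovery and null calibration on 500
simulated experiments each; GC null calibration on 10,000 genes of
450 nt. These sizes put the Monte-Carlo standard errors comfortably
inside the asserted bands while keeping a full run in well under a
minute per check.

# Limitations

* The σ32 model is strictly the 6+8 two-block form; extended −10
  elements or UP-elements are not modelled.
* The spacer is unscored; if real spacer-length preferences matter
  for ranking closely scoring sites, this model cannot express them.
* The HGT screen is composition-only and inherits all caveats of
  GC-based detection.
* pI and MW assume unmodified, fully denatured chains (no disulfides,
  no PTMs) — the standard caveat of ProtParam-style calculations.
* ΔΔCt assumes perfect doubling and a truly stable reference gene;
  violations bias folds multiplicatively.
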