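---
title: "Methods: piRNA discovery, differential expression, targets and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: piRNA discovery, differential expression, targets and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beepiR)
```

## Scope and model

beepiR implements a complete desk-scale analysis of Piwi-interacting RNAs
(piRNAs) from grouped small RNA-seq libraries, of the kind used to study
developmental stages of the honey-bee (*Apis mellifera*) larval gut: three
ordered groups (`Am4`, `Am5`, `Am6`, for 4-, 5- and 6-day-old guts) with
three biological replicates each. The pipeline has five cooperating parts:

1. **Discovery.** Reads are collapsed to unique-sequence *tags* with exact
   per-replicate counts, mapped to the reference genome, and filtered
   sequentially: tags overlapping annotated rRNA/tRNA/snRNA/snoRNA/scRNA
   features are subtracted first, then tags exactly matching known
   miRNAs; of the remainder, a tag is called a candidate piRNA when its
   length is 24–33 nt (inclusive) *and* its best-stratum alignment occurs
   at exactly one genomic position across both strands.
2. **Differential expression.** Counts are normalized to tags per million,
   `TPM = T * 1e6 / N`, with `N` the library's *total* clean small-RNA
   tags. Fold changes are ratios of replicate-pooled group TPMs (later
   stage over earlier stage), and significance comes from an
   Audic–Claverie exact conditional test on pooled counts. A piRNA is
   differentially expressed (DE) when `p <= 0.05` and `|log2FC| >= 1`,
   both boundaries inclusive.
3. **Target prediction.** Each DE piRNA is aligned antisense against every
   transcript window with a banded alignment (at most 2 gaps) and a
   plant-miRNA-style penalty score: mismatch 1, G:U wobble 0.5, gap 1,
   all doubled at piRNA positions 2–13 (the core), sites kept at total
   penalty ≤ 4. Each site's duplex free energy is estimated with a
   simplified nearest-neighbor model, and binding relationships are kept
   only when ΔG is *strictly below* −15 kcal/mol.
4. **Enrichment.** GO/KEGG-style term enrichment of the target genes uses
   a two-sided exact hypergeometric (Fisher) test against a configurable
   background (all supplied transcripts by default); significance is
   `p < 0.05`, strict, with no multiple-testing correction by default
   (Benjamini–Hochberg is available behind a flag).
5. **Network.** A bipartite regulatory network connects DE piRNAs to
   energy-gated target genes annotated to configured pathway categories
   (development, immune, energy metabolism), plus category nodes; hubs
   are ranked by distinct-gene degree, and the network exports to SIF and
   GraphML for Cytoscape-style viewers.

## Statistical choices

**Audic–Claverie test.** Conditional on a tag's total pooled count
`x + y`, the null law of the library-2 count `y` is binomial with
success probability `n2 / (n1 + n2)`. We report a two-sided p-value by
doubling the smaller *inclusive* tail and capping at 1; this conditional
formulation is exactly symmetric under swapping the libraries (so
reversing a comparison preserves every p-value bit for bit), and it
gives exactly `p = 1` at the
symmetric center (e.g. 5 vs 5 in equal libraries) and agrees with
brute-force enumeration of the conditional pmf to 10 decimal places in
the test suite. The test is exact under within-library (binomial/Poisson)
sampling but, like every pooled-count test, it is **anticonservative when
replicates are biologically overdispersed**: pooling discards the
replicate-to-replicate variance. At the simulated dispersion (0.1) and
depths around 10^5 this inflates the raw-p positive rate well above the
nominal level; the *joint* DE criterion (p together with `|log2FC| >= 1`)
keeps the realized false-positive rate of DE calling on null loci near
1–2%. This is documented rather than hidden: the fold-change gate, not
the p-value alone, carries most of the specificity, exactly as in the
two-threshold screening rule the pipeline implements. A Welch t-test on
replicate TPMs is available (`test = "welch-t"`) when replicate-aware
inference is preferred.

**Zero handling.** Fold changes floor both TPMs at 0.01 (configurable)
before taking the ratio, so a tag absent from one condition yields a
large finite `log2FC` rather than ±Inf. A tag absent from both groups
gets `p = 1` with a warning flag.

**Enrichment.** The two-sided Fisher p is computed in-package by
enumerating the hypergeometric support and summing probabilities no
larger than the observed table's (with a 1e-9 relative tie tolerance);
`stats::fisher.test` serves as an independent cross-check in the tests.

## Target scoring and the energy model

The complementarity scorer follows the published TargetFinder scheme
(penalties 1 / 0.5 / 1 with core doubling and cutoff 4); the tool itself
names no parameters in typical reports, so these constants are fixed here
and exposed via `scoring_params()`. The scan is a banded dynamic program
over *duplex space*: piRNA 5'→3' against the transcript read 3'→5' from
each candidate anchor, at most two gaps, with deterministic tie-breaking
(lowest penalty, then leftmost site). Both transcript orientations are
scanned and recorded by default, which makes the scan exactly symmetric
under reverse-complementing a transcript; biologically meaningful hits
are the sense-orientation ones, and score-4 hits on the reverse
orientation of random sequence are vanishingly rare.

The free-energy estimate is a deliberately simple nearest-neighbor sum:
standard Watson–Crick dinucleotide stack energies at 37 °C, flat values
for wobble-containing stacks (−1.3 kcal/mol with one G:U, −0.5 with two),
a fixed initiation term of +4.09 kcal/mol, and a fixed +2.0 kcal/mol per
*internal* unpaired position (terminal overhangs are free, so a duplex
with no pairs costs only the initiation term). The table ships with the
package (`nn_params()`, version `beepiR-nn-1.0`). This is not
ViennaRNA-grade thermodynamics — loop entropies, dangling ends and
temperature dependence are out of scope — but it preserves the
properties the screening step needs: perfect complementary duplexes of
≥ 24 nt always clear the −15 kcal/mol gate, and any single internal
mismatch strictly destabilizes a perfect duplex.

## The synthetic-study generator

`simulate_study()` produces a complete study with known truth: a random
single-chromosome genome with non-overlapping piRNA, ncRNA and miRNA
loci; per-replicate FASTQ libraries; target transcripts with planted
binding sites; and gene→term maps with a designed enriched pathway term.
Defaults are the study conditions the validation targets assume:

| parameter | default | rationale |
|---|---|---|
| groups × replicates | 3 × 3 | the emulated design |
| reads per replicate | 10^5 | desk-scale yet deep enough for DE power |
| piRNA loci | 500 | catalog of the right order of magnitude |
| piRNA length | uniform 24–33 nt | the defining length window |
| first base | C with weight 0.55 | reproduces the reported 1C bias |
| NB dispersion | 0.1 | typical small-RNA biological overdispersion |
| DE fraction / effect | 10% at \|log2FC\| = 2 | planted truth for power checks |
| contamination | 10% ncRNA + 5% miRNA | plausible post-QC residual |
| abundance spread | log-normal, sdlog 1 | realistic dynamic range |

Counts are negative binomial per replicate
(`variance = mu + 0.1 * mu^2`); reads are exact locus copies because the
pipeline starts from quality-filtered "clean tags" (an optional uniform
substitution rate exists for robustness experiments). A planted effect
multiplies a locus's mean by `2^log2FC` from the affected comparison's
second group *onward* — a sustained developmental shift — so each planted
effect is non-null in exactly one consecutive-group comparison.
Contaminant ncRNA reads are drawn from a small per-locus catalog of
stereotyped 20–35 nt degradation fragments (rather than uniformly random
windows), which mirrors the stereotyped fragment pools of real rRNA/tRNA
contamination and keeps the unique-tag space bounded; because
contaminants are emitted from their annotated loci, annotation-driven
subtraction can be validated exactly. The first DE piRNA receives three
times the Poisson target-site rate and serves as the designed network
hub.

What the generator does **not** emulate: sequencing error profiles and
base qualities, adapter artifacts, genome repeat structure and piRNA
clusters, ping-pong amplification beyond an optional 10A flag, multi-hit
mapping ambiguity, and database-driven (Rfam/BLAST) contaminant calls —
subtraction here is interval-based against supplied annotations. Passing
the end-to-end checks therefore demonstrates that the pipeline's logic is
sound under its stated model, not that it is robust to every artifact of
real libraries.

## Numerical and design decisions

* Coordinates are 0-based half-open internally; GFF3 I/O converts to
  1-based closed via `rtracklayer`.
* "Unique position" is read strictly: exactly one best-stratum alignment
  across both strands. The built-in mapper is exact-match and index-based
  (adequate at desk scale); a mismatch-tolerant scan and a BAM ingest
  path (with coordinate re-verification) are provided.
* ncRNA subtraction removes a tag when any hit overlaps a listed-class
  feature by ≥ 50% of the tag length (configurable), strand-agnostic;
  miRNA subtraction is exact sequence match, with an optional locus rule.
* Subtraction order is fixed: ncRNA classes → miRNA → length →
  uniqueness.
* piRNA identity is the tag sequence, not the locus; identifiers are
  FNV-1a hashes of the sequence (`piR-ame-<digits>`), stable across runs.
* Tag collapsing sorts by sequence, so FASTQ record order cannot affect
  any downstream result; the whole pipeline is deterministic given the
  generator seed.
* Degenerate inputs are defined, not accidental: empty FASTQ collapses to
  an empty tag table; zero library size is an error for TPM; both-zero
  counts give p = 1 with a warning; an empty category list yields an
  empty network.

## Validation problem sizes

The shipped tests validate formulas against hand arithmetic and
brute-force oracles (enumeration of the Audic–Claverie pmf, of the
hypergeometric support, and of all banded antisense alignments on ≤ 60 nt
transcripts), and run the full pipeline end-to-end at the default
conditions above (500 loci, 9 × 10^5 reads) plus a smaller 60-locus study
for order-invariance and byte-level determinism checks. These sizes were
chosen to exercise every code path at meaningful depth while keeping a
complete run in the low minutes on a single core; `scripts/acceptance.R`
re-runs the default-condition study from scratch and reports recovery,
DE sensitivity and specificity, first-base composition, planted-site
recovery, enrichment strength and hub agreement.

## Known limitations

* The pooled-count test's raw p-values are anticonservative under
  replicate overdispersion (see above); interpret them jointly with the
  fold-change gate, or use the Welch option.
* The energy model is a screening heuristic; absolute ΔG values are not
  comparable with full thermodynamic folding tools, only the relative
  ordering and the −15 kcal/mol gate semantics are meaningful.
* The exact-match mapper is not a general-purpose aligner; for large
  genomes, align externally and use the BAM ingest path.
* Enrichment uses raw p < 0.05 by default to match the screening
  convention it implements; switch on BH adjustment for inferential use.
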