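---
title: "Prioritizing transcription factors from concordant chromatin and expression changes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Prioritizing transcription factors from concordant chromatin and expression changes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(concordTF)
```

## The analysis

concordTF implements a cis-regulatory strategy for nominating candidate
transcription factors (TFs) from paired RNA-seq and ATAC-seq profiles
collected across three physiological states — fed, fasted, and leptin-treated
in the fasted state. The motivating biology is the hunger circuitry of AgRP
neurons: fasting and leptin push these neurons in opposite directions, and a
TF that promotes the hungry state should leave a mirrored footprint in the
chromatin — its motif over-represented in regions that open with fasting and
close with leptin, near genes regulated the same way — while a
hunger-suppressing TF should show the reciprocal pattern.

The pipeline has four stages.

1. **Differential classification.** Two contrasts are formed along the
   physiological chain: fasted vs. fed and leptin vs. fasted. Genes are
   called induced/repressed at |log2FC| > 0.5 (strict), FDR < 0.05, and mean
   CPM above 1 in at least one compared group; peaks are called
   opened/closed at |log2FC| >= 0.5 (inclusive), FDR < 0.05 and CPM >= 1.
   The strict-vs-inclusive asymmetry mirrors the conventional phrasing of
   the two assays' thresholds and is configurable
   (`threshold_config()`). Genes induced by fasting and repressed by leptin
   (and vice versa) form the *bidirectional* sets, the strongest candidates
   for leptin-dependent regulation.
2. **Concordant peak assignment.** A differential peak is *concordant* when
   its interval overlaps the closed window ±200 kb around the TSS of at
   least one gene regulated in the matched direction (fasted-opened with
   fasting-induced, fasted-closed with fasting-repressed, leptin-opened
   with leptin-induced, leptin-closed with leptin-repressed). Any
   overlapping base qualifies — assignment is by interval overlap, not peak
   center — and the window is strand-independent, unlike the promoter
   definition used for feature annotation (the 1 kb immediately upstream of
   the TSS, strand-aware). Peaks on chromosomes outside the allow-list
   (scaffolds) are kept for enrichment but can never be concordant.
3. **Motif enrichment.** Each concordant peak set is scored against a PWM
   library and tested for enrichment against **six** background sets:
   (1) all neutral peaks; (2) neutral peaks near neutral genes; (3) neutral
   peaks near significant genes; (4) neutral peaks near any TSS; (5) all
   peaks not concordant for the condition; (6) dinucleotide-preserving
   shuffles of the concordant sequences themselves. Backgrounds 2–4 use the
   same ±200 kb window as stage 2. "Neutral" peaks are those significant in
   neither direction of the condition's contrast; "neutral" genes are genes
   significant in neither contrast, so backgrounds 2 and 3 partition the
   near-gene neutral peaks cleanly.
4. **Prioritization.** A motif counts as *enriched* in a peak set when its
   adjusted enrichment p-value clears alpha in at least 5 of the 6
   background analyses. Enriched motifs take as representative p-value the
   most significant of their significant results; non-enriched motifs take
   the most significant of their non-significant results. Motifs are then
   classified by the four enrichment flags: enriched in fasted-opened and
   leptin-closed but neither of the other two is *hunger-pair-exclusive*
   (candidate hunger-promoting TF); the mirrored pattern is
   *satiety-pair-exclusive*; enrichment in exactly one of fasted-opened or
   leptin-opened gives the single-exclusive categories; anything else
   enriched somewhere is *mixed*, otherwise *none*. Pair-exclusive motifs
   are ranked by the sum of the two representative −log2(p) scores, with
   lexicographic motif-id tie-breaks; a summed score is defined only when
   both pair members are enriched and is reported as missing (never 0)
   otherwise.

## The enrichment statistic

Scanning uses the standard log2-odds model. A PWM row \(p_i\) is smoothed as
\(p_i' = p_i(1-4\varepsilon) + \varepsilon\) (default
\(\varepsilon = 0.01\)) and divided by the background base frequencies
(genome-wide mononucleotide frequencies by default, configurable to uniform
or the motif file's own background). A sequence's score is the **maximum**
log2-odds over all windows of the sequence and its reverse complement;
windows containing N are skipped, and a sequence with no valid window is
excluded. Maximum scoring was chosen over average-odds because it has a
direct brute-force oracle (the test suite compares it window by window) and
an interpretable "best site" semantics.

Enrichment of a motif in foreground vs. background is the
optimal-score-threshold Fisher test: for every candidate threshold *t*,
sequences scoring \(\ge t\) are hits, and a one-tailed Fisher exact test
(hypergeometric upper tail) is computed on the 2×2 table; the reported
p-value is the minimum over thresholds, Bonferroni-corrected by the number
of candidate thresholds, and then by the number of motifs in the library.
Candidate thresholds are restricted to the distinct observed foreground
scores: for the upper-tail statistic, any threshold strictly between two
foreground values is dominated by the next foreground value (same
foreground hits, no more background hits), so the restriction loses
nothing; the test suite verifies this against an exhaustive scan that
includes background score values.

All p-values are carried in natural-log space end to end, built from
`lchoose` terms with log-sum-exp. A table like 667/667 foreground hits vs.
0/667 background hits has \(p \approx 10^{-400}\) — far below double
underflow — yet its \(-\log_2 p \approx 1329\) is computed exactly; no
imputation or clamping is needed. For comparability with tools that cap
p-values at \(e^{-300}\) before log-transforming, `consensus_call(...,
clamp_log = TRUE)` reproduces that behavior behind a flag.

The sixth background uses the Altschul–Erickson dinucleotide-preserving
shuffle: a random Eulerian path through the dinucleotide transition
multigraph, preserving the exact dinucleotide count multiset and both
terminal residues. It is seeded and reproducible; the seed is recorded with
the background suite.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `gene_lfc_min` | 0.5 | strict lower bound on gene \|log2FC\| |
| `peak_lfc_min` | 0.5 | inclusive lower bound on peak \|log2FC\| |
| `fdr_max` | 0.05 | BH-FDR cutoff for both assays |
| `gene_cpm_min`, `peak_cpm_min` | 1 | mean-CPM expression/accessibility filter |
| `cpm_rule` | "any" | CPM filter satisfied in any vs. both compared groups |
| `window_bp` | 200000 | TSS window half-width for concordance (bp) |
| `alpha` | 0.05 | significance cutoff in the 5-of-6 consensus rule |
| `pseudocount` | 0.01 | PWM smoothing for the log-odds model |

Two readings in the pipeline are interpretations of ambiguous conventions
and are therefore configurable and documented here: the CPM filter is
"passes in at least one compared group" (switchable to "both"); background
set 5 is *all* peaks minus the condition's concordant set (the literal "all
non-concordant peaks" reading). The significance test behind the
gene–peak association statistics (the fraction of regulated genes with a
concordant peak vs. the neutral-gene baseline) is a one-tailed Fisher exact
test; no particular test is canonical for that comparison, and the p-values
should be read as descriptive.

## The synthetic study

`sim_config()` / `simulate_hunger_study()` generate a fully self-contained
study: an i.i.d. random genome (default four 3 Mb chromosomes plus a 50 kb
scaffold carrying a few neutral peaks, to exercise scaffold filtering),
gene models with guaranteed TSS spacing, and three peak groups per
condition — designed concordant peaks within 190 kb of a matched regulated
gene's TSS, designed non-concordant regulated peaks farther than 210 kb
from every matched gene, and neutral peaks everywhere. Counts are negative
binomial (Var = μ + αμ², α = 0.05) with log-normal base means, ±2 log2
effects on regulated features composed along the fed → fasted → leptin
chain, and log-normal library-size factors. Two causal 10-bp motifs (≈14
bits of information content, typical of a laboratory TF PWM) are planted by
overwriting genome bases — coordinates stay stable — with probability 0.8
in their designated concordant peaks (hunger motif: fasted-opened and
leptin-closed; satiety motif: the reciprocal pair) and 0.05 anywhere else;
six decoys are column-shuffled copies of the causal PWMs, matching
information content but not sequence. Every artifact is a pure function of
the config, and the ground truth (classes, designed links, planted
instances) is serialized next to the data.

The generator emulates the statistical structure the pipeline consumes —
sparse condition-specific effects, concordant peak–gene geometry, planted
motif excess — and deliberately not the things upstream of it: real genome
composition and repeat structure, read-level noise, fragment-size and Tn5
bias, TMM-style compositional normalization, dispersion sharing across
features, or correlated TF-family motifs. Passing tests on synthetic data
therefore validate the pipeline's logic and statistics, not the biology of
any particular dataset; for real data, externally computed differential
tables (e.g. from a count-based GLM framework) are the recommended input,
and the built-in Welch-t-on-log2-CPM stand-in (`simple_de_test()`) exists
so fully synthetic runs are self-contained — it is documented as a
stand-in, not a reimplementation of any GLM machinery.

## Numerical choices and degenerate inputs

* Thresholds in the enrichment scan are exact observed score values;
  tie-breaks for the optimal threshold take the smallest threshold
  attaining the minimal p-value.
* Ranking ties break lexicographically on motif id.
* A sequence whose every window contains N scores −Inf and is dropped from
  both foreground and background totals.
* An all-zero count feature has log2FC exactly 0 (the pseudo-offset is a
  0.5-count-equivalent CPM at the mean library size) and p = 1.
* `window_bp = 0` degenerates to overlap with the single-base TSS window;
  negative windows are rejected.
* Background sets must be non-empty; an empty set aborts the enrichment
  stage with the set's name in the message.
* The representative-score monotonicity ("if every p shrinks, the score
  does not drop") holds whenever the significance pattern is stable; an
  entry crossing alpha can move the representative between the significant
  and non-significant subsets, which is inherent to the consensus rule.

## Problem sizes in the test suite

The default synthetic study uses 228 genes, 848 peaks, 12 Mb of genome,
n = 4 replicates per condition and 8 motifs; the end-to-end recovery check
runs it across 20 seeds and requires the planted hunger motif to be
classified hunger-pair-exclusive and ranked first in ≥ 90% of them. The
statistical primitives are checked against exhaustive oracles (all 2×2
tables with total ≤ 12; all 64 consensus patterns; all 16 exclusivity
patterns; brute-force threshold scans and all-pairs window overlap up to
5000 peaks × 1000 genes). These sizes were chosen so the designed
concordant sets (~60 peaks per condition) sit well above the enrichment
test's detection floor while chance concordance stays limited.

## Known limitations

* The consensus and exclusivity logic operate on motifs, not TFs; paralogs
  with near-identical PWMs will co-rank and need downstream expression
  filtering, which is out of scope here.
* Background sets 1–5 are used at full size (no subsampling); with very
  large peak atlases the optimal-threshold scan is O(foreground thresholds
  × Fisher evaluations) per motif and background.
* The association statistics are descriptive; their Fisher p-values ignore
  gene–gene dependence from shared windows.
* `simple_de_test()` is intentionally simple: no dispersion moderation, no
  compositional normalization. Use a dedicated differential framework for
  real data and feed the tables in.
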