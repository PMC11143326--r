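# concordTF

Prioritize candidate transcription factors (TFs) from paired differential
RNA-seq and ATAC-seq profiles across three physiological states — fed,
fasted, and leptin-treated. The package is written for regulatory genomics
of hunger circuits (AgRP-neuron-style designs), but the machinery is
generic: two contrasts, four regulated peak sets, and a motif-enrichment
consensus that asks which TF motifs track one state pair and not the other.

## What it computes

Given gene models, peaks, a genome, a PWM library and differential tables
for the contrasts fasted-vs-fed and leptin-vs-fasted:

1. **Regulated sets** — genes at |log2FC| > 0.5 (strict), FDR < 0.05, mean
   CPM > 1; peaks at |log2FC| ≥ 0.5 (inclusive), FDR < 0.05, CPM ≥ 1;
   plus bidirectional genes (fasting-induced ∩ leptin-repressed and the
   reverse).
2. **Concordant peaks** — differential peaks whose interval overlaps the
   closed ±200 kb window around the TSS of a gene regulated in the matched
   direction (fasted-opened ↔ fasting-induced, fasted-closed ↔
   fasting-repressed, leptin-opened ↔ leptin-induced, leptin-closed ↔
   leptin-repressed), with association statistics against neutral genes.
3. **Motif enrichment** — each motif's maximum log2-odds score per sequence
   (both strands), then an optimal-score-threshold one-tailed Fisher exact
   test of each concordant set against **six** backgrounds: neutral peaks
   genome-wide, neutral peaks near neutral genes, near significant genes,
   near any TSS, all non-concordant peaks, and dinucleotide-preserving
   shuffles of the foreground itself. P-values are Bonferroni-adjusted
   (thresholds, then motif count) and carried in log space, so
   p ≈ 1e-400 still yields an exact −log2(p) ≈ 1329.
4. **Prioritization** — a motif is *enriched* in a peak set if adjusted
   p < α in ≥ 5 of the 6 backgrounds; its representative score is
   −log2 of the best significant p (or best non-significant p if not
   enriched). Motifs enriched in fasted-opened + leptin-closed but not the
   reciprocal pair are candidate **hunger-promoting** TFs; the mirrored
   pattern gives **hunger-suppressing** candidates; both are ranked by the
   summed pair score.

A fully synthetic study generator (`simulate_hunger_study()`) produces a
random genome, annotation, negative-binomial count matrices and a motif
library with causal motifs planted into condition-concordant peaks, so the
entire pipeline is testable offline with known ground truth.

## Worked example

```r
library(concordTF)

sim <- simulate_hunger_study(sim_config(seed = 1))
de <- function(m) list(
  fasted_vs_fed    = simple_de_test(m, sim$counts$groups, c("fasted", "fed")),
  leptin_vs_fasted = simple_de_test(m, sim$counts$groups, c("leptin", "fasted")))

report <- run_hunger_tf(sim$genes, sim$peaks,
                        de(sim$counts$gene_counts),
                        de(sim$counts$peak_counts),
                        sim$motifs, sim$genome, seed = 1)
summary(report)
```

```
TF prioritization report
  window: +/-200 kb; alpha = 0.05
  genes: 26 fasting-induced, 29 fasting-repressed, 22 leptin-induced, 30 leptin-repressed
  bidirectional: 12 fast-up/leptin-down, 8 fast-down/leptin-up
  peaks: 82 fasted-opened, 105 fasted-closed, 82 leptin-opened, 103 leptin-closed
  concordant peaks: fasted_opened=57, fasted_closed=80, leptin_opened=56, leptin_closed=74
  motif categories:

 hunger_pair_exclusive                   none satiety_pair_exclusive
                     1                      6                      1

Top hunger_pair motifs:
 rank  motif_id summed_score_hunger summed_score_satiety
    1 HUNGER_TF             88.0015                   NA

Top satiety_pair motifs:
 rank   motif_id summed_score_hunger summed_score_satiety
    1 SATIETY_TF                  NA             76.69008
```

The simulator planted `HUNGER_TF` instances in 80% of the designed
fasted-opened and leptin-closed concordant peaks (5% elsewhere) and
`SATIETY_TF` in the reciprocal pair; both are recovered as the sole
pair-exclusive motifs of their categories, the six information-content-
matched decoys land in `none`, and the summed scores (88.0 and 76.7) are
the paired −log2(p) evidence used for ranking. `report$concordant`,
`report$enrichment` and `report$priority` hold the per-stage tables;
`plot(report)` draws the four-axis radar of representative scores.

File-based runs use `run_config()` + `run_pipeline()`, which write
per-condition concordant-peak TSVs, the enrichment matrix, the priority
table, radar-plot JSON and a seed/config manifest. A thin CLI with
`simulate | classify | concord | enrich | prioritize | run-all`
subcommands is installed at `inst/cli/concordtf.R`.

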