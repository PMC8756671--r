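# bglccr

Differential expression of glucose-tolerant β-glucosidase genes under
carbon catabolite repression (CCR).

β-Glucosidase performs the rate-limiting final step of microbial cellulose
degradation, hydrolysing cellobiose to glucose. Accumulating glucose
represses cellulase expression (CCR), but some GH1 family β-glucosidases are
*glucose tolerant* — and in GH1 enzymes that phenotype tracks two conserved
residues, Trp168 and Leu173 (reference numbering), so tolerance can be
called from sequence alone. `bglccr` is for microbiome researchers who want
to test whether a community differentially regulates its glucose-tolerant
versus non-tolerant β-glucosidase genes under CCR, using paired DNA/RNA
abundance data (metagenome + metatranscriptome, or qPCR on DNA and cDNA).

The core statistic is per-gene **transcription efficiency**,
TE(g, t) = RNA_rel(g, t) / DNA_rel(g, t) (transcripts per gene copy), and its
change against the untreated control CK:

    relative TE(g, t) = (TE(g, t) − TE(g, CK)) / TE(g, CK)

Group averages of relative TE over glucose-tolerant and non-tolerant genes
describe the community's transcriptional regulation trend: under high
glucose, up-regulation of the tolerant group and repression of the rest.

The package provides, as pipe-friendly functions over tibbles:

* `classify_genes()` / `classify_fasta()` — six-frame translation, anchoring
  to a (configurable) reference GH1 protein by pairwise alignment, and the
  W168/L173 residue rule with explicit quality gates;
* `relative_abundance()`, `transcription_efficiency()`, `relative_te()`,
  `group_summary()`, `tolerant_ratio()`, `relative_activity()` — the
  abundance/TE pipeline;
* `reciprocal_match()` — metagenome ↔ metatranscriptome gene matching by
  reciprocal best hits at ≥ 95% identity;
* `build_network()` with `tidy()`/`glance()`/`autoplot()` — signed taxon
  co-occurrence networks (correlation threshold + permutation test);
* `sim_sequences()`, `sim_abundance()`, `sim_qpcr()`,
  `sim_block_profiles()` — a synthetic-data generator with planted ground
  truth;
* `run_pipeline()` — classify → TE → relative TE → summaries as one
  reproducible run with a JSON report.

## Worked example

Simulate a 40-gene community (half glucose tolerant), classify it, and run
the qPCR-style TE analysis:

```r
library(bglccr)
library(dplyr)

ref <- gh1_reference()
sim <- sim_sequences(n_genes = 40, seed = 1)
calls <- classify_genes(sim$genes, ref)
table(calls$call)
#> glucose_tolerant     non_tolerant
#>               20               20

ab <- sim_qpcr(sim$truth, noise_cv = 0.2, seed = 2)   # triplicate copy numbers
te  <- transcription_efficiency(aggregate_replicates(ab$dna),
                                aggregate_replicates(ab$rna),
                                value_col = "abundance")
rel <- relative_te(te, ck = "CK")
group_summary(rel, calls) |> filter(treatment %in% c("G_H_C_H", "C_H"))
#>   treatment            group n_genes    mean    sd gt_minus_nongt
#> 1       C_H glucose_tolerant      20  0.1071 0.245         0.0705
#> 2       C_H     non_tolerant      20  0.0365 0.248         0.0705
#> 3   G_H_C_H glucose_tolerant      20  1.0983 0.520         1.5997
#> 4   G_H_C_H     non_tolerant      20 -0.5013 0.108         1.5997
```

Reading the numbers: in the high-glucose arm `G_H_C_H` the glucose-tolerant
group's mean relative TE is ≈ 1.10 — its transcription efficiency roughly
doubled versus CK (the planted multiplier was 2, i.e. true value 1.0) —
while the non-tolerant group sits at ≈ −0.50, halved transcription (planted
0.5). In the glucose-free arm `C_H` both groups are near zero: no CCR, no
differential regulation. `plot_relative_te(rel, calls)` draws the per-gene
bars with the red (tolerant) and black (non-tolerant) group-average lines;
`autoplot(group_summary(rel, calls))` shows the group means per treatment.

The seven treatments (`treatment_design()`) encode the incubation design:
high-glucose arms `G_H_C_L`, `G_H_C_H`, `G_H_C_H_D` (200 mmol/L glucose with
low/high cellobiose ± gluconolactone), glucose-free counterparts `C_L`,
`C_H`, `C_H_D`, and the control `CK`.

See `vignettes/bglccr-methods.Rmd` for the model, parameter choices, noise
assumptions and known limitations.

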