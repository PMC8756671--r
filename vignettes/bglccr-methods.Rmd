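---
title: "Methods: differential expression of glucose-tolerant beta-glucosidase genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential expression of glucose-tolerant beta-glucosidase genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bglccr)
library(dplyr)
```

## The scientific question

beta-Glucosidase (EC 3.2.1.21) catalyses the final, rate-limiting step of
microbial cellulose degradation: hydrolysis of cellobiose to glucose. When
glucose accumulates, carbon catabolite repression (CCR) shuts down cellulase
expression — yet some GH1 family beta-glucosidases are *glucose tolerant*:
their activity, and apparently their transcription, persists under high
glucose. In GH1 enzymes this phenotype tracks two conserved residues, a
tryptophan at reference position 168 and a leucine at position 173, which
makes tolerance callable directly from sequence.

`bglccr` implements the quantitative machinery needed to ask whether a
microbial community *differentially regulates* its glucose-tolerant versus
non-tolerant beta-glucosidase genes under CCR:

1. residue-based tolerance classification of gene sequences
   (`classify_genes()`),
2. per-gene relative abundance at DNA and RNA level, transcription
   efficiency, and the relative-TE statistic against a control treatment
   (`relative_abundance()`, `transcription_efficiency()`, `relative_te()`,
   `group_summary()`),
3. cross-mapping of metagenome- and metatranscriptome-derived gene sets by
   reciprocal best hits at a percent-identity threshold
   (`reciprocal_match()`),
4. signed co-occurrence networks of the functional community
   (`build_network()`), and
5. a synthetic-data generator with planted ground truth that makes the whole
   pipeline testable end to end (`sim_sequences()`, `sim_abundance()`,
   `sim_qpcr()`, `sim_block_profiles()`).

## Tolerance classification

### Model

A gene is glucose tolerant iff the residues aligned to reference positions
168 and 173 are W and L. Nucleotide inputs are translated in all six frames;
each translation is split at stop codons and segments of at least 100 aa are
kept as candidate open reading frames (the targeted amplicons are
1100–1200 bp, about 370 aa, so one clean frame is expected). Candidates are
anchored to the reference by an end-gap-free global (overlap) alignment with
BLOSUM62 and affine gaps (open 10, extend 1); the highest-scoring candidate
wins, and walking the aligned columns yields a map from reference positions
to query residues.

### Quality gates and degenerate inputs

A residue read is only trusted when the winning alignment has at least 30%
identity over at least 150 aligned columns; otherwise the call is
`indeterminate`. The same holds when a discriminating position falls in a
gap column, outside the aligned region, or carries an ambiguity letter
(X/B/Z/J). The gates prevent reading residues off non-homologous frames: an
unrelated random protein aligns at roughly 10–20% identity and is rejected.
Genes with `indeterminate` calls are excluded from both the numerator and
denominator of tolerant-gene ratios and from group summaries, rather than
being lumped with the non-tolerant class — coercing them would bias group
means with alignment artefacts.

### The bundled reference

The residue numbering requires a concrete reference protein. The package
bundles a *synthetic* GH1-like protein (447 aa,
`inst/extdata/gh1_reference_synthetic.faa`) that carries W168/L173 in the
canonical acid/base (TFNEP) motif context plus an ITENG nucleophile motif.
It is a stand-in that makes the rule concrete and testable offline; for work
on real data both the reference FASTA and the discriminating positions are
arguments (`gh1_reference(path, positions)`), so a curated glucose-tolerant
GH1 protein can be dropped in without code changes.

## Transcription efficiency and the relative-TE statistic

Relative abundance of gene $g$ in sample $s$ is its abundance divided by the
sample's total over the *gene universe* — the classifiable genes (decided
calls). Transcription efficiency is

$$\mathrm{TE}(g,t) = \frac{\mathrm{RNA}_{rel}(g,t)}{\mathrm{DNA}_{rel}(g,t)},$$

transcripts per gene copy, and the treatment effect on a gene's
transcription is measured against the untreated control CK:

$$\mathrm{relative\ TE}(g,t) =
  \frac{\mathrm{TE}(g,t) - \mathrm{TE}(g,\mathrm{CK})}{\mathrm{TE}(g,\mathrm{CK})}.$$

Design choices that matter:

* **Direction.** TE is RNA/DNA by default so that larger TE means higher
  expression, consistent with how the statistic is interpreted; the
  direction is a switch (`direction = "dna_rna"`) for users who prefer the
  reciprocal.
* **Replicates.** qPCR triplicates are averaged arithmetically *before*
  ratio-taking (ratio of means, not mean of ratios), which is stable against
  near-zero replicate denominators; `aggregate_replicates()` reports the
  per-gene CV alongside.
* **Zeros.** TE is undefined where the DNA denominator is zero, and genes
  whose control TE is zero or undefined are excluded from relative-TE tables
  with their ids logged (attribute `excluded`). No pseudo-count is added by
  default; sparse count tables can opt in by adding one upstream.
* **Group means.** `group_summary()` averages unweighted across genes (each
  gene one vote), mirroring per-gene bar plots with a group-average line,
  and reports the signed gap mean(GT) − mean(non-GT) per treatment.
* **Compositionality.** When TE is computed from *relative* abundances, the
  per-sample normalisation sums do not cancel in the CK ratio: every gene's
  relative TE in treatment $t$ is multiplied by a common compositional
  factor. Group *differences* and orderings are unaffected, but exact
  per-gene effect recovery holds on absolute scales (qPCR copy numbers, or
  simulated tables without depth scaling). The validation suite therefore
  checks exact algebra on the copy-number route and orderings on both.

## Treatments

`treatment_design()` encodes the seven incubation treatments: three
high-glucose (200 mmol/L glucose) arms `G_H_C_L`, `G_H_C_H`, `G_H_C_H_D`
with 0.8 or 8 mmol/L cellobiose and optionally 20 mmol/L
D-glucono-1,5-lactone, their glucose-free counterparts `C_L`, `C_H`,
`C_H_D`, and the untreated control `CK`. `is_high_glucose` marks the arms
where CCR is expected; all planted effects in the simulator key off this
flag.

## Cross-mapping gene sets

To compare DNA- and RNA-level abundances gene by gene, metagenome and
metatranscriptome sequence sets are matched by reciprocal best hits at a
percent-identity threshold (default 95%). Identity is computed on a global
nucleotide alignment (match +2, mismatch −3, gap open 5, extend 2) as
identical columns over aligned columns, with terminal-gap columns excluded
from both counts. The end-gap exclusion deliberately lives in the *metric*,
not the alignment scoring: an alignment with fully free end gaps
degenerates, for unrelated sequences, to a few perfectly matching terminal
residues and would report 100% identity. Reciprocal-best-hit filtering (ties
broken by identity, then aligned columns, then lexicographic id) guarantees
each gene joins at most one retained pair. Protein-level matching is
available via `moltype = "aa"`.

## Co-occurrence networks

Signed networks are built from taxon abundance profiles: pairwise Spearman
(default; Pearson available) correlations, an edge kept when $|r| \ge
r_{min}$ (default 0.8) *and* a permutation test passes ($p \le 0.05$,
default 1000 permutations). The permutation null shuffles one profile over
samples; a single fixed permutation set (given `seed`) is shared across all
pairs, making the edge set reproducible and the gates monotone. Edge sign is
the correlation sign; `network_stats()`/`glance()` report edge counts by
sign, positive fraction, mean degree and the sign-blind global clustering
coefficient. This is a deliberately explicit, reproducible replacement for
platform-specific threshold-selection pipelines; module detection and
topological-role classification are out of scope.

## The synthetic-data generator

The generator is first-class, tested code: it emulates the statistical
structure the analysis assumes, with exported truth.

* **Sequences** (`sim_sequences()`): genes derive from the reference
  protein with i.i.d. substitutions at non-discriminating positions
  (default rate 0.05 per site, about the divergence where family membership
  is still unambiguous); glucose-tolerant genes keep W168/L173, non-tolerant
  genes have one or both ablated; uniform-codon reverse translation and
  random strand placement. Rates ≥ 0.5 are refused — they would destroy the
  homology the identity gate requires, by construction.
* **Abundances** (`sim_abundance()`): per-gene lognormal DNA baseline
  (meanlog log 100, sdlog 1) and base TE (meanlog 0, sdlog 0.5); expected
  RNA = DNA × baseTE × effect, where the effect is `f_up` (default 2) for
  tolerant genes under high glucose, `f_down` (default 0.5) for
  non-tolerant genes there, 1 otherwise — up-regulation of the tolerant
  group and repression of the rest under CCR. Observations multiply the
  expectation by mean-one lognormal noise (default CV 0.2, a typical qPCR
  replicate spread). The defaults make recovery decisive at 100 genes while
  leaving visible noise. With `depth` set, samples are scaled and rounded to
  counts (compositional, sequencing-like); without it values behave as
  absolute copy numbers (`sim_qpcr()` adds triplicates).
* **Taxa profiles** (`sim_block_profiles()`): a latent factor per sample,
  followed by odd blocks and opposed by even blocks, plus Gaussian noise —
  planted sign structure for network recovery.
* **Noise model choice.** Multiplicative lognormal keeps TE ratios
  analytically tractable: on the log scale the TE ratio against CK is
  exactly Gaussian, $\log(1+\mathrm{rel\,TE}) \sim N(\log f,\,4\sigma^2)$
  with $\sigma^2 = \log(1+\mathrm{CV}^2)$. Two consequences are worth
  knowing. First, the raw-scale group-mean estimator has a predictable
  multiplicative bias $e^{2\sigma^2}$ (about 8% at CV 0.2) — the validation
  suite checks unbiasedness within three standard errors of the estimator,
  and median/log-scale recovery is exact. Second, group comparisons are
  calibrated on the log scale, so the null-calibration check runs the
  two-sample t-test on $\log(1+\mathrm{rel\,TE})$.
* **Reproducibility.** All generators take a `seed` and restore the caller's
  RNG state. `seed = NULL` draws from the ambient stream instead: long
  Monte-Carlo designs seed once and draw replicates from one continuous
  stream, because re-seeding every replicate with consecutive integers
  leaves detectable structure in the generator's first draws (a known
  weakness of Mersenne–Twister initialisation that visibly distorts
  type-I-error estimates).

What the generator does *not* emulate: taxonomic composition, chimeras and
PCR bias, read-level error profiles, overdispersed count noise beyond the
lognormal, or genuine indels within genes. Passing tests therefore
demonstrate correctness of the statistical machinery under its stated
assumptions, not robustness to every artefact of real amplicon or shotgun
data.

## Validation problem sizes

The test suite runs the full analysis at desk scale: 200 genes for
classifier fidelity; 40 genes for the exact noiseless algebra; 1000
Monte-Carlo replicates of 100 genes (50 per group, CK plus one high-glucose
and one glucose-free arm) for effect recovery; 500 replicates for null
calibration; 50-gene sets of 400-nt sequences for cross-mapping against a
brute-force Hamming oracle; and a 10-taxon, 20-sample two-block design with
1000 permutations for network recovery. These sizes make the checks
decisive (the planted effects are many standard errors wide) while keeping
a full run in minutes.

## Worked example

```{r example}
ref <- gh1_reference()
sim <- sim_sequences(n_genes = 40, seed = 1)
calls <- classify_genes(sim$genes, ref)
table(calls$call)

ab <- sim_qpcr(sim$truth, noise_cv = 0.2, seed = 2)
te <- transcription_efficiency(aggregate_replicates(ab$dna),
                               aggregate_replicates(ab$rna),
                               value_col = "abundance")
rel <- relative_te(te, ck = "CK")
gs <- group_summary(rel, calls)
gs |> filter(treatment %in% c("G_H_C_H", "C_H"))
```

Under the high-glucose arm the glucose-tolerant group mean sits near
`f_up − 1 = 1` and the non-tolerant group near `f_down − 1 = −0.5`; in the
glucose-free arm both are near zero.

## Known limitations

* The residue rule is exactly two positions; no profile/HMM search, no
  discovery of additional discriminating residues, and no structural
  modelling. Genes too diverged to pass the identity gate are reported
  `indeterminate`, never guessed.
* Relative-TE on compositional (relative-abundance) inputs carries a
  per-treatment compositional factor; see above.
* The network stage reports marginal correlation structure only; it does not
  attempt direct-interaction inference, module detection or cross-network
  significance testing.
* The bundled reference is synthetic; numbering-faithful work on real data
  should supply a curated reference protein.
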