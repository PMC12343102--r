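---
title: "Ratiometric contaminant filtering: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ratiometric contaminant filtering: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ratiocut)
```

## The model

Proximity-labeling proteomics quantifies each detected protein as one or
more labeled-to-control ratios. The working assumption of the whole method
is ordinal, not parametric: *genuine residents of the target compartment
tend to carry larger ratios than contaminants*. Everything downstream —
TPR/FPR scanning, the cutoff, the ROC and its AUC — depends on the ratio
values only through their ranking, which is why no normalization of the
ratios is performed or required (any strictly increasing transform of a
column leaves every result unchanged; this is tested as an invariant).

Ground truth is anchored by two curated accession lists: true positives
(TP, known residents of the target compartment) and false positives (FP,
known residents of a contaminant compartment). For one ratio column, after
dropping cells missing in that column and sorting the remaining proteins by
ratio in descending order,

$$\mathrm{TPR}(k) = \frac{\#\{\mathrm{TP\ in\ top\ }k\}}{n_{TP}}, \qquad
  \mathrm{FPR}(k) = \frac{\#\{\mathrm{FP\ in\ top\ }k\}}{n_{FP}},$$

and the cutoff is the rank maximizing $\mathrm{TPR}(k)-\mathrm{FPR}(k)$
(the Youden criterion applied to a ranking). Proteins at ranks
$1..k^\*$ are retained *regardless of annotation*: unannotated proteins —
and proteins whose database annotation is intracellular but which genuinely
reach the target compartment — survive if they rank highly. With several
ratio columns, each column gets its own cutoff and the final proteome is
the intersection of the per-column retained sets.

The ROC curve over $(\mathrm{FPR}, \mathrm{TPR})$ summarizes enrichment
quality; its area (AUC) equals the Mann–Whitney probability
$P(r_{TP} > r_{FP}) + \tfrac12 P(r_{TP} = r_{FP})$ over all TP×FP pairs.
An AUC above roughly 0.7 indicates acceptable enrichment; an AUC near 0.5
means the labeling or enrichment failed. `ratiocut` treats that threshold
as a *warning tier* in the pipeline summary, never as an automatic abort:
it is interpretation guidance, not a gate, and the appropriate response to
a low AUC is experimental troubleshooting, not silent data deletion.

## Tunable parameters that matter

| parameter | default | meaning |
|---|---|---|
| `tie_policy` | `"last"` | when TPR−FPR attains its maximum at several ranks, take the deepest one (retain more proteins at identical criterion value); `"first"` is the conservative alternative |
| `missing_policy` | `"exclude"` | a protein not quantified in a column cannot pass that column's cutoff, hence drops out of the final intersection; `"pass"` is the anti-conservative sensitivity check |
| `top_n` | 100 | rows in the per-column most-enriched tables |
| `correlation_method` | `"pearson_log2"` | replicate QC estimator (see below) |
| `auc_warn` | 0.7 | AUC below this flags a column as questionable in the run summary |
| accession policy | strip isoforms, parse FASTA headers, uppercase | reference lists are gene-level; isoform suffixes or `sp|ACC|NAME` tokens would silently zero the TP/FP hit counts |

## Numerical choices

* **Cutoff inclusivity.** "Retained above the cutoff position" is read as
  ranks $1..k^\*$ *inclusive*: the maximal position is where the last
  informative TP gain occurs, and excluding it would drop a reference TP
  sitting exactly at the peak. Both the inclusivity convention and the tie
  policy are deliberate choices exposed as flags, since either convention
  is defensible.
* **Argmax robustness.** Inside `compute_curve()` the argmax of TPR−FPR is
  taken on the integer score $c_{TP}(k)\,n_{FP} - c_{FP}(k)\,n_{TP}$, which
  is exact; the standalone `find_cutoff()` accepts a plain numeric `diff`
  vector and therefore uses a small absolute tolerance (`1e-9`) so that
  equal rationals reached by different floating-point routes still tie.
* **Ties in ratio values.** Display ranking uses a stable sort (ties keep
  input-row order), but the ROC processes all entries sharing one ratio
  value as a single block (one segment), making the AUC independent of tie
  order and exactly equal to the Mann–Whitney statistic with half-credit
  for ties. The per-rank cutoff, by contrast, operates on the displayed
  ranking; a cutoff falling inside a tie block is therefore
  order-dependent in principle, which is the price of reporting a single
  rank.
* **Missingness.** Missing cells are handled per column (a row stays
  usable in its other columns), and QC correlations use pairwise-complete
  observations with the per-pair count reported; a pair with fewer than 3
  complete observations is reported `NA` rather than fabricated.
* **Duplicate accessions** after normalization keep the *first* occurrence
  (each drop logged): deterministic and order-preserving, whereas
  aggregating duplicate rows would silently mix evidence.
* **Text output precision** is 6 significant digits, so re-written tables
  are byte-stable and round-trip exactly at that precision.

## Replicate QC

Ratios are multiplicative, so the default estimator is Pearson correlation
of log2 ratios (`pearson_log2`); it is invariant to positive rescaling of a
column. Spearman is available when outlier ratios dominate. The estimator
and transform are recorded in the output metadata because the choice is a
package decision, not something the underlying method prescribes.

## Over-representation analysis

The final proteome is tested term-by-term against user-supplied flat
annotation sets (2-column TSV or GMT) with the upper-tail hypergeometric
probability and Benjamini–Hochberg FDR across the term collection —
matching the FDR-controlled reporting convention of the standard annotation
servers while staying fully offline. The default background is the set of
*detected* proteins (post-normalization), not a whole proteome: detection
bias would otherwise inflate every term tied to abundant compartments. A
user background file can override this. No ontology-graph propagation is
performed; terms are taken as flat sets, so results are not numerically
comparable to servers that propagate.

## What the synthetic generator emulates — and what it does not

`synth_generate()` draws a latent log2 ratio per protein — TP from
$\mathcal N(\mu_{TP}, \sigma)$, FP from $\mathcal N(\mu_{FP}, \sigma)$,
unannotated rows from a 50:50 mixture so the "retain regardless of
annotation" behavior is exercised — adds independent
$\mathcal N(0, \texttt{replicate\_sd})$ noise per ratio column, and emits
$2^{\text{latent}+\text{noise}}$, guaranteeing positive ratios. In failed
mode every protein draws from the FP component regardless of label, which
is the appropriate negative control: labels carry no information, so
TPR/FPR track the diagonal and the AUC concentrates at 0.5.

Defaults state one realistic experiment and are not revisited: four ratio
columns (two labeled × two control channels, the common TMT design);
500 TP + 500 FP + 1000 unannotated detected proteins; $\sigma = 1$ log2
unit; `replicate_sd = 0.25`; and $\mu_{TP}-\mu_{FP} = 1.15$, chosen a
priori from the normal-overlap relation
$\mathrm{AUC} = \Phi\!\big(\Delta / (\sigma_c\sqrt{2})\big)$ (with
per-column spread $\sigma_c = \sqrt{\sigma^2 + \texttt{replicate\_sd}^2}$)
so that a default run lands near AUC ≈ 0.79 — the quality level of a good
published cell-surface labeling experiment.

The generator does **not** simulate peptide-level quantification,
missingness mechanisms, or TMT ratio compression. A green test on
synthetic data therefore establishes that the algorithmic pipeline is
correct under the method's own ordinal assumptions — not that any
particular real dataset satisfies those assumptions, and not that the
package reproduces a specific published figure. Reference-subsampling
robustness (10-fold reduction leaving the retained set nearly unchanged,
Jaccard > 0.9 on well-separated data) is likewise demonstrated at
synthetic scale only.

## Worked example

```{r example}
sim <- synth_generate(synth_config(n_tp = 100, n_fp = 100, n_unannotated = 50,
                                   n_columns = 2, seed = 7))
curve <- analyze_column(sim$table, "R1", sim$reference)
curve
retained <- apply_cutoff(curve$ranked, curve$cutoff_rank)
length(retained)
```

```{r plots, fig.width = 6, fig.height = 4}
plot_enrichment_curves(curve)
plot_roc(curve)
```

## Known limitations

* The method stands or falls with reference quality. It is robust to
  reduced reference *coverage*, but systematically wrong references bias
  both the cutoff and the AUC; when no references exist, conventional
  statistical enrichment testing is the fallback, and that is out of scope
  here.
* A single cutoff per column cannot represent a mixture of two genuine
  sub-compartments with different enrichment strengths.
* The per-rank cutoff is order-dependent inside blocks of exactly tied
  ratios (see above).
* ORA treats annotation terms as flat sets; no term-term dependency or
  graph structure is modeled, and FDR control is across the supplied
  collection only.
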