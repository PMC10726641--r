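---
title: "Detecting expressed somatic SNVs from single-cell RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting expressed somatic SNVs from single-cell RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scresa)
library(dplyr)
```

## The problem

Full-length scRNA-seq protocols (SMART-seq2 and relatives) cover enough of
each transcript that somatic single-nucleotide variants on expressed alleles
are directly visible in the reads. The obstacle is noise: cell lysis, reverse
transcription, pre-amplification and alignment each inject artefactual
variants, and on a single cell a standard caller happily reports all of them.
Germline polymorphisms and RNA-editing events add two further confounders
that are not sequencing errors at all, but are not somatic either. Any method
that reports somatic SNVs from such data must therefore be engineered around
*precision*: a small trustworthy call set is worth more downstream than a
large contaminated one.

`scresa` attacks the problem with one biological assumption and two
engineering devices. The assumption: tumors grow clonally, so a real somatic
SNV is carried by a clone and recurs across cells, while artefacts are
approximately uniform over the (large) exonic space and essentially never
recur. The devices: (i) two independent caller pipelines per cell, whose
per-cell intersection (set A) is far cleaner than either alone, and whose
primary-only remainder (set B) is where artefacts concentrate; (ii) a
three-way partition — confident positives, confident negatives, and an
*unsure* remainder — so that borderline candidates are neither trusted nor
discarded but handed to a classifier trained on the confident sets.

## The labeling engine

For a cohort of $n$ cells the recurrence bounds are
$L = \max(3, \lceil 0.10\,n \rceil)$ and $U = \lfloor 0.80\,n \rfloor$:
"at least" semantics for the lower bound (ceiling), "more than" for the upper
(floor). A key seen in more than $U$ cells is removed as a putative germline
polymorphism or systematic artefact even if no germline list catches it.
A key is **positive** when at least one cell supports it with a
quality-passing set-A call and its recurrence lies in $[L, U]$; **negative**
when it is set-B-only, never quality-passing, and shows no cross-cell
recurrence; otherwise **unsure**. Per-call quality means depth $\ge 3$,
quality-by-depth $\ge 2$, Phred strand bias $\le 30$, and $\ge 1$
alt-supporting read. All thresholds are `resa_config()` knobs with these
defaults.

Three choices here were genuinely open and deserve a record:

* **Recurrence is counted on post-annotation, pre-quality calls** of the
  primary caller (a pseudo-bulk detection count). Counting after quality
  filtering would make the negative-set criterion ("no cross-cell
  recurrence") circular, since quality failures are exactly what defines
  negatives.
* **"No cross-cell recurrence" means recurrence = 1** (the strictest
  reading), exposed as `negative_max_recurrence`.
* **A missing FS or QD field passes its threshold.** Absence of evidence of
  bias is not evidence of bias; a secondary caller that never emits FS
  should not have all its calls fail the strand-bias test.

Keys on a germline list (population and matched-normal lists are cumulative,
not alternatives) are removed by exact key match; RNA-editing databases are
site-level resources, so editing removal matches on position only. When a
key is hit by several removal rules, the first in the order
non-exonic → editing → germline wins — the order in which the filters are
described and applied.

## The joint classifier

The unsure set is refined by two penalized logistic submodels trained on the
positive (label 1) and negative (label 0) keys, split 3:1 into train and
test. The split is stratified by class — plain random splitting can produce
a single-class test set at realistic set sizes — and the training minority
class is rebalanced by random oversampling with replacement.

The **quality submodel** (L1) sees per-key means of QUAL, depth, VAF, the
min-normalized genotype-likelihood triple and the two allele depths,
z-scored with training-set statistics (a mixed-penalty model needs
comparable scales; one-hot columns are left unscaled). The mean is used to
aggregate a key's supporting calls because it is symmetric in the cells —
`aggregate = "max_qual"` is available as an alternative. The **sequence
submodel** (L2) sees the 6-way mutation-type and 96-way SBS96 context
one-hots, plus, when a reference signature matrix is supplied, each
signature's probability mass at the variant's context class — the only
per-variant quantity derivable from a signature catalog without fitting
exposures, which is a stated interpretation rather than the only possible
one. Penalty strength is parameterized liblinear-style
($\lambda = 1/(nC)$, default $C = 1$ for both submodels) and fitted with
`glmnet`.

The submodel probabilities are combined by the thresholded weighted mean

$$P(\mathrm{pos}) = \tfrac{1}{2}\sum_{P \in \{P_{seq},\,P_{pos}\}} wP,
\qquad w = \mathbf{1}[P \ge 0.5],$$

whose attainable range is $\{0\} \cup [0.25, 1]$: a submodel below the
cutoff contributes nothing, and a single confident submodel can clear the
default 0.5 decision threshold only at $P = 1$. Ties at the threshold count
as positive (the rule is written with $\ge$). Both the inside cutoff
(`w_cutoff`) and the final threshold are separately tunable, defaulting to
0.5. Model performance is reported as the rank-based AUC of the *joint*
probability on the held-out keys — the joint classifier is the model, not
either submodel. Keys whose trinucleotide context is undefined (an N flank)
cannot be scored by the sequence submodel; because the combination rule
needs both probabilities, such keys are excluded from refinement and
reported, rather than silently scored by the quality submodel alone.
Refinement is additive by construction: the final set is the core positives
plus promoted unsure keys, never fewer.

## What the simulator emulates — and what it does not

`simulate_cohort()` generates the package's study conditions at the variant
level: calls are planted directly into per-cell VCF pairs, not into reads.
The defaults define the standard cohort (the `default` preset): 50 cells;
200 clonal somatic SNVs at prevalence 0.4 with dropout 0.2 (expected
recurrence $50 \times 0.4 \times 0.8 = 16$, comfortably inside $[5, 40]$);
100 germline SNVs at prevalence 0.95 (expected recurrence ≈ 47, above
$U = 40$, and also carried on the germline list); 50 editing sites at
prevalence 0.3; and Poisson(20) artefacts per cell at uniform exonic
positions, which makes artefact recurrence ≥ 2 a rare birthday-collision
event. Depth is negative-binomial per (cell, site) and alt reads are
binomial in the variant's Beta-distributed VAF, so allelic dropout emerges
both from the explicit dropout parameter and from zero-alt-read draws, the
way coverage limits detectability in real cells.

Quality values are class-conditional: true variants draw QUAL ~ N(150, 40),
QD ~ N(15, 5), FS ~ Exp(mean 3); artefacts draw QUAL ~ N(35, 15),
QD ~ N(1.8, 1.2), FS ~ N(25, 15) — i.e. artefacts sit mostly, but not
entirely, on the failing side of the QD ≥ 2 and FS ≤ 30 filters, so the
negative set is large and the unsure set is non-empty. Two secondary-caller
parameters shape the consensus sets: a per-call sensitivity of 0.9, and a
per-variant systematic miss probability of 0.12 — some variants a given
caller simply never emits. The systematic component is what routes genuinely
recurrent somatic variants into set B and hence the unsure set, the
population refinement exists to recover; with purely per-call misses a
16-cell variant would almost surely have at least one dual-caller cell.
Somatic contexts are drawn C>T-biased by default (60% of mass on C>T
classes, cancer-like) because the data this method targets carry strong
mutational signatures, and an informative sequence submodel is part of
realistic conditions; `spectrum_bias = "uniform"` switches this off.

Passing tests on these cohorts therefore demonstrates the pipeline's logic
— filtering, recurrence arithmetic, set algebra, learnability, determinism —
under a faithful statistical cartoon. They do not demonstrate robustness to
what the simulator omits: alignment-induced position-correlated artefacts,
expression-dependent (gene-correlated) dropout, caller-specific field
quirks, UMI chemistries, or subclonal structure beyond independent
per-clone prevalences.

## Numerical choices and degenerate inputs

* Ratios with zero denominators (precision of an empty prediction set,
  overlap of an empty set, cosine of a zero spectrum, AUC of a single-class
  test set) are reported as `NA` with a warning — undefined is not zero.
* The stratified split keeps at least one test row per class; splitting
  fewer than 8 labeled rows, or a class with fewer than 2 members, is an
  error rather than a silent degenerate fit.
* The hypergeometric stage test is upper-tail *inclusive*
  ($P[X \ge k]$), the standard over-representation form; the enriched flag
  uses the raw $p < 0.05$ threshold, with Benjamini–Hochberg values reported
  alongside for transparency, not for the flag.
* Gene assignment for enrichment takes the first overlapping gene span,
  alphabetical on ties; a cell counts once per gene regardless of how many
  of that gene's variants it carries.
* Determinism is treated as a contract: inputs are sorted (cells by id,
  keys by coordinates) on ingest, every stochastic step derives from the
  configured seed, and reruns — including with permuted manifest rows —
  produce byte-identical outputs.

## Problem sizes used in the test suite

The shipped tests run the full pipeline on the `default` preset (50 cells,
200 somatic SNVs) and the `high_burden` preset (50 cells, 2,000 somatic
SNVs on a 200 kb genome), chosen so a complete suite run stays comfortably
interactive; oracle-equivalence checks use 200 randomized small instances
per operation (≤ 20 cells, ≤ 100 keys, hypergeometric cohorts of $N \le
12$), where brute-force reimplementations are exact. The classifier's
parameter-recovery checks use 2,000-row synthetic logistic cohorts whose
generating coefficients are known.

## Known limitations

Precision comes at the price of sensitivity to rare subclones: a variant
expressed in fewer than $L$ cells cannot enter the core positive set, and
can be recovered only via the unsure route. The method presumes two caller
pipelines; with a single caller every key is set B and the positive rule
never fires. Evaluation against WES-style truth inherits that truth set's
blind spots — single-cell-private mutations absent from bulk truth depress
measured precision without being errors. Finally, the signature-component
features are a lookup interpretation of "signature components"; packages
wanting fitted per-sample exposures should compute them upstream and pass
them as additional columns.

## A compact session

```{r example, eval = FALSE}
dir <- tempfile()
sim <- simulate_preset("tiny", dir, seed = 1)   # 12 cells, 20 somatic SNVs
lab <- resa_run(sim$paths$manifest, sim$paths$exons, sim$paths$editing,
                sim$paths$germline, cfg = resa_config(seed = 1))
glance(lab)
model <- resa_refine(lab, sim$paths$ref)
glance(model)
autoplot(model)                                  # held-out ROC
autoplot(mutation_spectrum(model$final_positive, sim$paths$ref))
```
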