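---
title: "afpred: methods and design notes"
author: "afpred maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{afpred: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Antifreeze proteins (AFPs) adsorb onto growing ice crystals and depress
the freezing point of body fluids (thermal hysteresis). They are
sequence- and structure-diverse, which makes them hard to recognise by
homology alone, and annotated AFPs are vastly outnumbered by non-AFPs —
in the reference setting roughly 1 positive to 20 negatives. `afpred`
implements a sequence-only classifier for this situation: a hybrid
329-dimensional descriptor, an undersampling random-forest ensemble with
majority voting, and ANOVA-ranked incremental feature selection, with
balanced accuracy as the headline metric.

## The descriptor space

Each protein is represented by five concatenated feature families,
always in this order:

| block | width | contents |
|---|---|---|
| composition | 110 | amino-acid (10) and dipeptide (100) composition over a 10-group reduced alphabet |
| physicochemical | 76 | 6 ProtParam-style global parameters + 70 auto-covariance features |
| disorder | 28 | summaries of a per-residue disorder score track |
| domain | 15 | binary InterPro entry indicators |
| evolutionary | 100 | functional-group-reduced PSSM features |

**Reduced alphabet.** The 20 residues are partitioned by side-chain
chemistry into phenyl (F/W/Y), carboxyl (D/E), imidazole (H), primary
amine (K), guanidino (R), thiol (C), sulfur (M), amido (Q/N), hydroxyl
(S/T) and non-polar (A/G/I/L/V/P). Functional groups positioned to match
the ice lattice are implicated in ice binding, so composition is taken
over groups rather than raw residues. AAC is `N(g)/L`; DPC counts the
`L−1` overlapping dipeptides over ordered group pairs, `N(g_i g_j)/(L−1)`.

**Global physicochemical parameters.** Theoretical pI (bisection on the
Henderson–Hasselbalch net-charge curve with the Bjellqvist/Expasy pKa
set, including ProtParam's residue-specific terminal pKas), counts of
D+E and R+K, the Guruprasad instability index (`10/L` times the summed
dipeptide instability weights; the published 400-entry weight table
ships as `inst/extdata/diwv.csv`), the Ikai aliphatic index and
Kyte–Doolittle GRAVY.

**Auto-covariance (AC) encoding.** For property *j* and lag λ,

$$AC(j,\lambda) = \frac{1}{L-\lambda} \sum_{i=1}^{L-\lambda}
  (P_i^j - \bar P^j)(P_{i+\lambda}^j - \bar P^j)$$

over seven residue properties (hydrophobicity, hydrophilicity, net
charge, van der Waals volume, free energy of solution in water,
side-chain interaction parameter, accessible surface area) and
λ = 1…10, giving 70 features. Two choices here were genuinely open:

* *Which AAindex scales.* The seven property names do not pin down
  AAindex accessions. We ship ARGP820101, HOPT810101, KLEP840101,
  FAUJ880103, CHAM820102, KRIW790103 and CHOC760101 as
  `inst/extdata/aaindex_properties.csv`; `propertyTable(path)` and the
  `propertyTab` argument of `assembleFeatures()` accept a replacement
  table of the same shape.
* *Standardisation.* The AC definition centres each property but does
  not rescale it, so a property measured in large units would dominate
  any distance-based treatment of the block. We standardise each scale
  to zero mean / unit variance over the 20 residues before encoding
  (`standardize = TRUE`, the default); tests pin both the standardised
  default and the raw closed forms.

**Disorder block.** From a per-residue score track in [0, 1] (VSL2-style
output is the expected source; running a disorder predictor is out of
scope): mean and population standard deviation; counts and min/max
lengths of disordered and ordered segments; and per-residue-type mean
scores. The disorder call is `score ≥ 0.5` — 0.5 because that is VSL2's
own decision boundary; a segment is a maximal run of same-call residues;
an absent segment class reports min = max = 0 and an absent residue type
reports 0 (a sentinel, kept numeric so matrices stay complete).

**Domain block.** Binary indicators over a fixed 15-entry InterPro
panel. The shipped panel (`defaultDomainPanel()`) is the set of entries
observed in at least 10 training AFPs, in rank order, so prediction
works without re-deriving it; `derivePanel()` rebuilds a panel from new
annotations, ordering by descending positive count with lexicographic
tie-breaks (the tie rule is ours — determinism — as no rule is implied
by the panel's provenance).

**PSSM block.** Each element of the L×20 PSI-BLAST log-odds matrix is
sigmoid-scaled, `f(x) = 1/(1+e^{-x})`; rows are grouped by the sequence
residue's functional group, columns by the target residue's group, and
each of the 10×10 group-pair sums is divided by L. Scaling precedes
aggregation (the presentation order of the method); `scaled = FALSE`
exposes the other order for comparison. The 10×10 pair reading is the
only one consistent with the stated 100-dimensional output.

## The imbalance-handling ensemble

With positives P and a ratio parameter G (default 9, the value found
optimal in the reference study's sweep), training samples exactly G·P
negatives without replacement, partitions them into G disjoint groups of
P, and joins each group with all P positives. One random forest is
trained per balanced subset, and prediction takes a majority vote:
positive iff votes > G/2. Odd G makes ties impossible; even G is
accepted only with `allowAnyG = TRUE`, and a tie then votes negative
(the majority-prior class). Undersampling is re-drawn inside every
cross-validation fold, matching a per-run reading of the procedure.

The base learner is `ranger` with 100 trees, `mtry = floor(sqrt(d))`,
unlimited depth, single-threaded and seeded — the original study used a
default-parameter WEKA random forest whose exact settings are
version-dependent and unrecoverable, so the learner is pluggable
(`fitFun`/`predictFun` in `ensembleConfig()`). Prediction passes a fixed
seed to `ranger` because tree-vote ties are otherwise broken with R's
global RNG, and model prediction must be a pure function of model and
data.

## Feature selection

`anovaRank()` scores every feature with the two-group one-way ANOVA F
statistic (between-group over within-group mean squares; for two groups
F = t² of the pooled-variance t statistic, which the tests exploit as an
oracle). Conventions for degenerate features: SSW = 0 with SSB > 0 gives
F = ∞ and ranks first (such a feature separates the groups perfectly);
SSB = SSW = 0 gives F = 0; ties break by ascending column index.

`incrementalSelection()` evaluates nested prefixes of the ranking with
the full ensemble pipeline under stratified K-fold cross-validation and
returns the smallest prefix attaining the maximum balanced accuracy
(parsimony as the tie rule). Cost is linear in the number of evaluated
prefixes; `stride` thins the evaluation grid without changing the
metric reported for any evaluated prefix.

## Evaluation

`computeMetrics()` evaluates Sn = TP/(TP+FN), Sp = TN/(TN+FP), Acc and
BAcc = (Sn+Sp)/2 exactly; a class absent from the truth vector makes the
corresponding rate (and BAcc) `NA` with `defined = FALSE`, never a
silent zero. Cross-validation is class-stratified; per-fold predictions
are pooled into a single confusion matrix before the formulas are
applied once (with ~37 positives per fold, fold-level sensitivity is too
noisy to average meaningfully), and per-fold reports are retained.

## The synthetic generator, and what it does not show

`generateSequences()` draws residues i.i.d. per position from
class-specific functional-group frequency profiles. The negative class
is uniform over the 20 residues; the positive class mixes in, with
weight `signal`, a profile that concentrates mass on the hydroxyl,
amido and non-polar groups. The signal is injected at the group level
deliberately: the reduced-alphabet composition features are then the
natural detectors, so descriptor bugs surface as balanced-accuracy loss
in end-to-end tests. `generatePSSM()` adds a class-dependent bias on the
columns of each residue's own group over integer noise;
`generateDisorder()` is a window-5 moving average of uniforms;
`generateDomains()` assigns panel entries to positives with probability
`enrichment` (default 0.6) and to negatives at `negRate` (default 0.02).

The generator emulates class-conditional composition shifts, enrichment
and profile biases — not real AFP biology: no phylogenetic correlation,
no sequence motifs or repeats, no realistic PSSM statistics from a real
database search, no length–class dependence. Passing trend tests on this
generator demonstrates that the pipeline's machinery behaves as designed
under a controlled signal; it does not certify real-data accuracy.

`runExperiment()` reproduces the qualitative designs: the
imbalance sweep (a single forest on 1:1…1:8 training sets; specificity
rises, sensitivity falls), ensemble-vs-none at 1:9 (the ensemble
recovers balanced accuracy), a G sweep, and a training-size sweep.
These evaluate on a balanced held-out set drawn from the same generator
rather than by cross-validation on the imbalanced training set: the
direction of every trend is the same and each replicate needs one
training pass instead of K. Default scales — 40 positives per replicate,
10 replicates, lengths 50–150, signal 0.6, composition features only —
were fixed once as a realistic small-data regime for this field and give
each trend comfortable Monte-Carlo margins.

## Numerical and interface decisions

* **Dataset filter.** Sequences shorter than 50 residues or containing
  B, J, O, U, X or Z are rejected (`too_short` takes precedence when
  both apply — the rule order is ours). Filtering is total and
  idempotent.
* **80/20 split.** Per class, the test set receives
  round-half-up(0.2 × class size) records: with 464/9083 inputs this
  yields the 93/1817 test and 371/7266 training sets of the reference
  setting; plain `round()` would give 92.8 → 93 but 1816.6 → 1817
  either way, and half-up is the rule that reproduces both printed
  counts in general.
* **Instability index scaling.** `10/L` times the dipeptide weight sum,
  the ProtParam/Guruprasad definition, verified against an independent
  implementation.
* **PSSM dialect.** The PSI-BLAST `-out_ascii_pssm` form is parsed
  (position, residue, first 20 log-odds columns); a bare
  whitespace-delimited L×20 matrix is auto-detected so fixtures need no
  header boilerplate. Column order "ARNDCQEGHILKMFPSTWYV" is recorded on
  the profile object.
* **Seeds.** Every stochastic function takes an explicit seed, restores
  the caller's RNG state, and derives member/fold sub-seeds
  deterministically; the command-line interface refuses to run
  stochastic subcommands without `--seed`.
* **No scaling at assembly.** Random forests are split-point invariant
  to monotone transforms and the ANOVA F ranking is location/scale
  equivariant, so the assembled matrix is left on natural scales.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run the trend experiments at
30 positives per replicate, 10 replicates, 60-tree forests and
composition-only features, and the selection-recovery check at
30 positives / 150 negatives with 5 informative + 45 noise features —
sizes chosen so the whole battery completes in a few minutes on one CPU
while leaving each directional check at least one replicate-SD of
margin.

## Known limitations

* The shipped AAindex accessions and the standardisation choice are
  plausible defaults, not recovered facts; results on real data will
  shift slightly under other property tables.
* VSL2, InterProScan and PSI-BLAST are not run; their outputs are
  consumed as inputs, and prediction quality on real data inherits
  whatever those upstream tools produce.
* The 25%-identity redundancy reduction used to build the original
  benchmark is out of scope; users assembling their own datasets should
  de-duplicate before splitting.
* `incrementalSelection()` re-trains the full ensemble for every
  evaluated prefix; on hundreds of features with G = 9 and 10 folds this
  is thousands of forest fits — use `stride`, or a smaller G, for
  exploratory passes.
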