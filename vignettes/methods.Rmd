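---
title: "Methods: overlap significance and rank-based tumour-signature scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: overlap significance and rank-based tumour-signature scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dystroscore)
```

# The scientific problem

Muscular-dystrophy transcriptome studies publish lists of differentially
expressed genes in heterogeneous identifier spaces (Affymetrix probes,
Ensembl IDs, gene symbols), and so do cancer meta-analyses. Two questions
can be asked of such lists without access to any raw data:

1. Do a dystrophy list and a cancer list share more genes than chance
   would allow, given a finite gene universe?
2. Does a ternary up/down/unchanged expression profile of a tumour
   classifier panel resemble one specific tumour category?

`dystroscore` implements both, plus the stages that produce their inputs.

# Models and procedures

## Overlap significance

With list sizes $n_1$ and $n_2$ drawn from a universe of $N$ genes, the
intersection size under the null of independent uniform draws is
hypergeometric, and the reported $P$-value is the inclusive upper tail
$P(X \ge k)$. We interpret "an intersection larger than the given one"
inclusively: this is the conventional enrichment tail and the only reading
that yields $P = 1$ at $k = 0$; a strict-tail mode ($P(X > k)$, `strict =
TRUE`) is available. Point masses are assembled from log-binomial
coefficients (`lchoose`) so genome-scale universes neither overflow nor
underflow.

**The universe is an explicit input.** The statistic is undefined without
$N$, yet published overlap tables rarely state it. `gene_universe()`
accepts either a bare size or an explicit member set (then every tested
list must be a subset); every result records which mode was used. No
default $N$ is supplied on purpose — silently assuming one would make
cross-study $P$-values incomparable.

**Direction handling.** Intersections are direction-agnostic by default
(published overlap tables intersect whole lists; direction-resolved
analysis was reported inconclusive), with an optional stratified mode
(`direction = "up"` or `"down"`) that intersects and sizes the lists
within one direction stratum.

**Multiple testing.** The many-vs-many matrix reports raw stars, as
published overlap tables do; Benjamini–Hochberg adjusted $p$-values can be
added (`adjust = "BH"`) and are reported alongside, never replacing, the
raw grades.

## Rank-based tumour-signature scoring

A scoring table assigns each classifier gene, per category, a sign
$\pm 1$ and a rank $R \ge 1$. With $HR$ the category's highest rank and
$C = 1/HR$:

$$B = \begin{cases} 1 - C R & \text{observed direction matches the sign} \\
0 & \text{otherwise} \end{cases}$$

The category score $S$ sums $B$ over its entries; the ideal score
$S_{ideal}$ is the same sum with every gene matching; the relative score
is $S / S_{ideal} \in [0, 1]$.

**Complement ("not X") semantics.** The source procedure defines
contributions only via sign correspondence but reports the ideal scores of
a category and its complement as equal. The only reading under which that
equality is an identity is: an entry contributes $B$ to "not X" exactly
when the observed direction is the *strict opposite* of its sign;
unchanged genes contribute to neither side. That is what `score_profile()`
implements, and the equality $S_{ideal}(X) = S_{ideal}(\neg X)$ holds by
construction (tested).

**Precision.** Category coefficients are conventionally printed at 6
decimals; the engine keeps $C$ at full precision so the ideal profile
normalizes to exactly 1 (a rounded $C$ would not), rounding only in
reports. `"HS"` in the printed coefficient definition is read as a typo
for $HR$.

**Edge rules.** Profile genes absent from the table are ignored and
listed; table genes absent from the profile contribute 0; tied ranks are
permitted; a single-entry category has $S_{ideal} = 0$ (its only gene sits
at $HR$) and its relative score is defined as 0.

**Category specificity.** A gene can carry ranks in all categories, so
"specific to EWS" cannot be derived from the rank columns;
`count_category_hits()` reads a dedicated `specific_category` column and
counts unknown genes under `unassigned`.

**Diagnosability.** Relative scores of at least 0.4 were reported
sufficient for a correct tumour diagnosis by the source classifier; 0.4 is
therefore the default `classify()` threshold.

## List standardization

Source identifiers are expanded to *all* GeneIDs they map to (fan-out —
this is why a standardized list can exceed its probe count), via an
offline many-to-many mapping table; the original web services are neither
available nor reproducible. Unmapped identifiers are dropped, never
guessed (synonym heuristics are irreproducible offline), and every run
emits a report (input, mapped, fan-out, dropped). When one GeneID arrives
with conflicting directions, it is kept with direction `unspecified` and a
warning: excluding it silently would bias overlap counts downward.
Detection-call aggregation sums the call scores (I +1.1, MI +1.0, NC 0,
MD −1.0, D −1.1) per probe across comparisons and applies *strict*
inequalities at ±5.5, exactly as printed.

## ΔΔCt relative quantification

$\Delta Ct = Ct_{target} - Ct_{ref}$ (arithmetic mean of reference-gene
Ct values when there are several — the geometric mean on the expression
scale; the source study names no reference gene, so the choice is echoed
in every report). The calibrator is the **mean ΔCt of the calibrator
group** rather than a single sample — the source does not say which, and
the group mean is the stabler choice. $RQ = 2^{-\Delta\Delta Ct}$,
reported per gene as $2^{-\overline{\Delta\Delta Ct}}$ (the geometric mean
of per-sample fold changes, natural on the cycle scale). Significance is
classical one-way ANOVA **on ΔCt values** (standard for qPCR; RQ is
log-normal there), and a gene is called up when $RQ \ge$ `fc_threshold`
(default 2) with $p <$ `alpha` (default 0.05), down at the reciprocal
threshold. Undetermined Ct values are missing; genes with more than
`max_missing` (default 0.2) missing wells are excluded and listed.
Efficiency correction (non-2 amplification base) and multiple-testing
across panel genes are deliberately out of scope, matching the source
analysis.

# Tunable parameters

| parameter | default | units | where | why |
|---|---|---|---|---|
| `universe_size` N | required | genes | overlap | unstated in published tables; must be explicit |
| `strict` | `FALSE` | — | overlap | inclusive tail is the standard enrichment reading |
| star cutoffs | 0.05/0.01/0.001 | prob. | overlap | published footnote convention |
| `up/down_threshold` | +5.5 / −5.5 | call score | genelists | printed strict cutoffs |
| `fc_threshold` | 2 | fold | ddct | printed DE criterion |
| `alpha` | 0.05 | prob. | ddct | printed significance level |
| `max_missing` | 0.2 | fraction | ddct | tolerate 1 in 5 failed wells, typical for TLDA panels |
| score `threshold` | 0.4 | relative score | tumor_score | published diagnosability limit |

# The synthetic-data generator

The generators state a world and hold it fixed:

* `gen_list_pair()` — lists drawn uniformly without replacement from
  `g1..gN`; that *is* the hypergeometric null, so the overlap test is
  calibrated against it by construction, or with a forced intersection of
  exactly `k` genes.
* `gen_scoring_table()` — defaults to the published panel shape, 4
  categories × 24 genes (96 entries), distinct per-category ranks with
  the maximum always present so $HR$ is pinned; signs are fair coins.
  `max_rank = 100` is a scale choice only; scores are invariant to rank
  scale through $C = 1/HR$.
* `gen_profile_with_match()` — a fraction $f$ of a category's entries
  match their signs, the rest oppose them, other categories' genes are
  unchanged; $f \cdot n$ is rounded to nearest with ties toward more
  matches.
* `gen_ct_dataset()` — reference Ct $\sim N(20, sd)$, gene-specific
  baseline ΔCt uniform on 2–8 cycles, a planted per-gene group shift on
  the ΔCt scale (−1 cycle ⇔ twofold up), Gaussian well noise with
  `sd = 0.3` cycles — a typical technical spread for TaqMan arrays;
  group sizes default to 10 per group, a realistic patient-cell study
  size (recovery tests use 20 where ±10% accuracy is asserted).

Every generator takes an explicit integer seed and restores the caller's
RNG state; equal seeds give byte-identical files.

**What a green test does not establish.** The generator plants clean,
independent Gaussian shifts: no probe-level artefacts, batch effects,
amplification-efficiency drift, or correlated genes. Passing the recovery
and calibration suites shows the *computations* are correct and
calibrated under their own null — not that any particular biological
dataset meets those assumptions.

# Numerical and design notes

* Hypergeometric tails: log-space summation; the test suite checks exact
  agreement with exhaustive enumeration of all draws for every
  $N \le 12$ and with `phyper` across random parameters — the
  implementation itself never calls the stats-package distribution.
* One-way ANOVA is computed from the sums-of-squares decomposition and
  cross-checked against `oneway.test(var.equal = TRUE)`; zero
  within-group variance is a hard error rather than an infinite $F$.
* Direction conflicts, unmapped probes, ignored profile genes and
  excluded high-missingness genes are all *reported*, never silent.
* Known limitation: published analyses whose inputs are no longer
  downloadable (the original 96-gene rank table, several third-party
  supplements) cannot be regenerated; their code paths are exercised by
  constructed tables with hand-computed expectations instead.

# A note on printed inconsistencies

The source material reports one muscle-biopsy list as both 529 and 539
GeneIDs and a myoblast list as both 296 and 297; its myotube marker
arithmetic (5 shared + 20 specific printed as 26) also does not add up,
and two genes appear in both a "myoblast-specific" and a myotube list.
The package takes no side: fixtures mimic each printed number only where
that specific table is mimicked, and the discrepancies are documented
here rather than resolved.
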