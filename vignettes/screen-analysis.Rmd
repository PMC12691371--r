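---
title: "Models and methods behind screenSL"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind screenSL}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenSL)
```

`screenSL` analyzes the two screen layers used for chemoresistance
target discovery in triple-negative breast cancer models — genome-wide
knockout screens for re-sensitizer genes and dual-knockout (CDKO)
screens for synthetic-lethal (SL) gene pairs — plus the transcriptome
framework that decides which cell line is worth screening in the first
place. This vignette explains the models, the defaults, and the design
choices that were genuinely open, in the package's own terms.

## Pooled-screen counts and quality control

All analyses start from integer count tables (guides or constructs ×
samples) held in a `ScreenCountSet`, a `SummarizedExperiment` whose
column data records timepoint (`T0`/`Tend`), condition and replicate.
Quality control mirrors the statistics screen studies print per sample:
mapping ratio, missed (zero-count) guides, guides above a read
threshold, replicate correlations on log2(count + 1), PCA, and the Gini
index

$$G = \frac{\sum_i \sum_j |x_i - x_j|}{2 n^2 \bar x},$$

computed on raw counts including zeros (the population form with the
$n^2$ denominator). Computing on raw rather than normalized counts is a
deliberate choice: dropout should *raise* the index, which is its whole
point as a screen-health metric. Reported percentages are half-up
rounded to two decimals, the convention of published screen QC tables;
the above-threshold read cutoff defaults to 10 (the sources that print
this column rarely state their cutoff, so it is a parameter).

## The synthetic-data generators

The generators define the study conditions every recovery test runs
under, so their defaults are fixed once and documented here.

**Genome screen.** Baseline guide abundance is log-normal with
$\sigma_{\log} = 0.07$; T0 counts are negative binomial around
`depth` = 500 reads per guide with dispersion (NB size) 1000, i.e.
$\mathrm{var} = \mu + \mu^2/1000$ (Poisson recovered as dispersion
$\to \infty$). The end-point mean is the T0 mean times
$2^{\beta(\mathrm{gene, condition}) + \eta}$ with guide-level jitter
$\eta \sim N(0, \tau)$, $\tau = 0.2$, representing heterogeneous guide
efficacy; safe (non-targeting) guides have effect exactly 0. The
abundance and noise defaults were set by a small-CV calculation: a
total coefficient of variation $c$ gives Gini $\approx c/\sqrt{\pi}$,
so $\sigma_{\log}^2 + 1/\mathrm{depth} + 1/\mathrm{dispersion} \approx
(0.05\sqrt{\pi})^2$ puts a null library's Gini near 0.05, the range
well-executed screens report. The acceptance script recomputes this:
null screens land in 0.04–0.06 at both timepoints.

**CDKO screen.** Per-guide fitness is gene fitness (drawn
$N(0, 0.3)$ unless supplied) plus $N(0, \tau)$ guide jitter; a
construct's expected LFC is $f_i + f_j + \gamma_{\mathrm{pair}} +
\varepsilon$ with construct noise $\varepsilon \sim N(0, 0.25)$ and
planted interactions $\gamma$ on unordered gene-pair labels (both
orientations are generated). Depth defaults to 200 reads per construct,
matching the coverage scale of the screens this models. Setting
$\tau = \sigma_\varepsilon = 0$ and `count_noise = FALSE` yields the
noiseless limit in which counts equal their real-valued expectations —
used by the exactness tests, where every delta-based SL score returns
$\gamma$ to machine precision.

**Transcriptome cohort.** Patients are baseline $N(7, 1)$ log2
expression plus a planted shift $\delta$ on DEG genes for
non-responders (default 150 genes at $|\delta| = 1.5$, alternating
sign), a batch offset, and $N(0, 0.5)$ noise; group sizes default to
the 29 non-responder : 15 responder baseline comparison. Cell line $c$
is $\lambda_c \cdot$ (non-responder centroid) $+ (1-\lambda_c) \cdot$
(its own independent centroid) $+$ noise, so $\lambda \in [0, 1]$ is a
planted representativeness dial.

What the generators deliberately do **not** model: PCR chimeras and
cassette recombination in dual libraries, copy-number-driven fitness
artifacts, probe-level microarray noise, and real pathway co-regulation
(planted DEGs are independent genes). Recovery results therefore show
the *estimators* behave as designed, not that real screens are this
clean.

## Gene essentiality and re-sensitizer selection

Counts are normalized by a median-of-ratios size factor computed on the
non-targeting control guides only (falling back to all guides with a
warning), then each Tend replicate is compared against the pooled mean
of the T0 replicates — a single baseline is appropriate because T0
precedes the branching into treatment arms. The β score of a gene is
the mean of its guides' replicate-averaged LFCs. This estimator shares
the sign convention and approximate log2 scale of the
maximum-likelihood scorers used on real screens, so the ±1 selection
cutoffs carry over; it is deterministic, transparent and fast, which is
what a simulation-validated pipeline needs.

Permutation p-values draw, per gene, `n_permutations` (default 10,000)
random same-size guide sets from all targeting guides of the condition.
Each gene gets its own draws: sharing one null sample across genes
looks cheaper but couples every p-value to the Monte-Carlo error of
that one sample and visibly distorts uniformity at a few thousand
genes. FDR is Benjamini–Hochberg within condition.

Re-sensitizers default to the literal rule β(control) > 1 and
β(drug) < −1. The alternative reading — control scores merely
*non-essential*, β(control) > −1 — is supported by changing
`thr_control`; the package does not guess which was meant, it exposes
both. For CDKO candidate selection the same tension appears
(candidates described both as "essential" and as "non-essential"); the
default follows the non-essential reading, $|\beta(\mathrm{control})|
\le 1$, the stated null band of the score.

## SL scores, consensus, and what consensus can and cannot do

Single-guide fitness $f$ comes from safe-harbor pairings: the mean LFC
of a guide's safe-paired constructs over both cassette positions, with
gene fitness the median over the gene's guides. The four scores are

* **Horlbeck**: mean of $\delta = \mathrm{LFC} - (f_{g_i} + f_{g_j})$
  (gene-level fitness) over up to 3 × 3 × 2 constructs;
* **median-B/NB**: median of the same deltas, optionally minus the
  median safe–safe delta (B), which makes the score invariant to global
  LFC shifts;
* **sgRNA-derived-B/NB**: deltas against *guide-level* fitness,
  averaged per orientation then across orientations — this corrects a
  guide-efficiency outlier that a gene-median fitness retains;
* **rank aggregation**: ascending percentile ranks of the guide-level
  deltas; per pair, $\rho = \min_k F_{\mathrm{Beta}(k,\,n-k+1)}(r_{(k)})$,
  small when the pair's constructs sit unusually low.

Negative score (or small ρ) = depletion beyond additivity = synthetic
lethal. Same-gene constructs are excluded from pair scoring (pairs have
two distinct genes), and pairs observed with fewer than 4 constructs
are flagged low-confidence rather than dropped. Per method the top 10%
most-SL pairs are flagged; consensus keeps pairs flagged by ≥ 3
methods. The B/NB variants differ from their counterparts by a
constant, so they rank pairs identically; counting them as separate
methods (as some published Venn diagrams do) only duplicates votes,
which is why the package treats each family as one method with a
variant switch.

One property deserves emphasis because it shapes expectations.
**Consensus over methods computed from the same data does not shrink
the false-positive set the way independent methods would.** If four
methods flagged independently at rate $q = 0.1$, a null pair would
reach a ≥ 3-method consensus with probability
$P(\mathrm{Bin}(4, 0.1) \ge 3) \approx 0.37\%$ — about 7.7 of 2,080
pairs, which the package's null calibration (independent random scores)
reproduces. But on a real or simulated screen all four scores aggregate
the *same* per-construct deltas, and their null rankings correlate
strongly (mean vs median of the same values alone correlate near 0.8–0.9).
In the desk-scale recovery scenario (40 genes, 20 pairs planted at
$\gamma = -2$) the consensus therefore recalls every planted pair but
also admits several-fold more null pairs than the independence
calculation suggests: the acceptance script reports recall 1.0 and
precision ≈ 0.4. This is a property of consensus-of-correlated-methods,
not of the noise level — score correlations are invariant to rescaling
the noise — and raising `min_methods` to 4 only helps marginally.
Practically: treat the consensus as a high-recall shortlist and rank
within it, rather than reading the top-decile consensus as a
false-discovery control.

The SL network is the undirected simple graph of consensus pairs; hub
genes are those with ≥ 10 partners.

## Cell-line representativeness

Probe preprocessing removes probes below background in ≥ 80% of samples
(boundary inclusive — a probe at exactly 80% is removed) and collapses
multi-probe genes by the median. Batch correction is per-gene,
per-batch mean centering with the grand mean added back: the
fixed-effect special case of linear-model batch removal, which leaves
group contrasts exactly unchanged for batch-balanced designs.
Differential expression is a Welch t-test per gene with BH adjustment
and a signed fold change $FC = 2^{\Delta}$ for $\Delta \ge 0$, else
$-2^{-\Delta}$, so the usual "FC ≥ 1.5 or ≤ −1.5, adjusted p < 0.01"
rule reads directly.

The three similarity labels are:

1. **DEG co-clustering** — hierarchical clustering of patients and cell
   lines on the DEG submatrix, average linkage on (1 − Pearson) sample
   distance, cut at k = 2; a cell line is labeled 1 iff its cluster
   holds the majority of the non-responder samples. Linkage, distance
   and k are parameters because the upstream literature rarely states
   them; "clustered together with non-responders" is operationalized as
   the majority rule.
2. **Spearman ranking** — the mean Spearman correlation with the
   non-responder samples over the top-variable genes (largest SD across
   the cell-line panel, deterministic name tie-break); label 1 iff the
   cell line ranks within `top_rank`. The full-scale analysis uses the
   top 2,000 genes and a top-100-of-916 cutoff; the desk-scale
   simulations use 1,000 genes and `top_rank = 1` of 5 lines, the
   closest scaled analogue.
3. **ssGSEA co-clustering** — the same clustering on the gene set ×
   sample matrix of single-sample enrichment scores
   $ES = \sum_i [P^w_{in}(i) - P_{out}(i)]$, with rank weight
   $r^{\alpha}$, $\alpha = 0.25$, and global max − min normalization.
   The implementation is verified against an explicit walk enumeration
   on every small case.

The overall score is the label sum (0–3), ranked descending with ties
broken by the average Spearman. In the planted-λ cohort
(λ ∈ {0.9, 0.7, 0.5, 0.2, 0.0}) the λ = 0.9 line ranks first in 10 of
10 seeds in the acceptance run.

## Numerical conventions and degenerate inputs

* Pseudocount 1 inside every log2 ratio and before correlation/PCA.
* Half-up rounding for reported percentages (with a tiny representation
  guard so values sitting exactly on .xx5 round up).
* Constant sample vectors give `NA` correlations, never a silent 0;
  constant genes give p = 1 in differential expression.
* An all-zero vector has no Gini index (error), and all control guides
  zero in a sample is a hard error naming the sample.
* Permutation p-values use the add-one estimator
  $(1 + \#\{|null| \ge |obs|\})/(B + 1)$, so p ∈ (0, 1].
* Ties: average ranks in Spearman/ssGSEA/rank-aggregation; gene-name
  tie-break in top-variable selection; ρ̄ tie-break in the overall
  ranking.

## Problem sizes

The test suite and acceptance script run at desk scale by design: 40
genes × 3 guides + 4 safe for the CDKO recovery (780 scored pairs),
2,000 genes × 3 guides + 100 controls for the genome screen, 2,000-gene
cohorts with 29 + 15 patients and 5 cell lines, and 100 repetitions for
the consensus null calibration. The estimators contain nothing that
scales worse than the full cross of the guide library, and the
full-size 230-guide design (52,900 constructs) is exercised in the
combinatorics and I/O tests.

## Limitations

The β estimator is a mean of normalized LFCs, not an NB maximum
likelihood fit: with very low counts or strong overdispersion the MLE's
variance weighting would differ. The SL consensus caveat above applies
to any same-data multi-method consensus, including published ones. The
representativeness framework inherits the arbitrariness of k = 2
tree-cutting when the non-responders do not form a clean cluster, and
the simulators' independence assumptions make its power estimates
optimistic relative to correlated real transcriptomes.
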