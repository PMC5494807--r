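---
title: "Methods: age-related stromal expression analysis with stromage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: age-related stromal expression analysis with stromage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stromage)
```

## The scientific setting

Cancer-associated stroma changes with patient age: senescent fibroblasts
accumulate and are suspected to remodel the tumour micro-environment through
the senescence-associated secretory profile (SASP) and through autophagy
activation in fibroblasts transitioning to senescence (AST, the "reverse
Warburg effect"). `stromage` implements the comparison of stromal expression
profiles between two extreme age groups — here 9 young (< 45 years) and 8
old (≥ 80 years) patients with triple-negative breast cancer — as three
inferential stages: per-gene signed fold-change differential expression,
gene set enrichment over four small curated programmes (senescence, DNA
damage response, SASP, AST), and cross-dataset overlap validation.

The input is assumed to be an already normalized, log2-scale probe- or
gene-level matrix (e.g. fRMA output); normalization itself is out of scope.
When several probes map to one symbol, `collapse_probes()` averages their
log2 values per sample — averaging on the log2 scale, the scale the
normalized values live on, not after linearisation — and drops probes
without a symbol, since all downstream matching is symbol-based.

## Differential expression

For gene $g$ with young-group values $y$ and old-group values $o$ (log2),
the default statistic linearises first and forms the ratio of arithmetic
group means:

$$ r_g = \frac{\operatorname{mean}(2^{y})}{\operatorname{mean}(2^{o})},
\qquad
\mathrm{FC}_g = \begin{cases} r_g & r_g \ge 1 \\ -1/r_g & r_g < 1 \end{cases} $$

so $|\mathrm{FC}| \ge 1$ always and a **negative** value means higher
expression in **old** stroma. A fold change is a ratio of expression levels,
not of their logarithms, which is why linearisation comes first; because
"average expression" could also be read as the log-scale mean, the
geometric-mean variant $2^{\bar y - \bar o}$ is available as
`fc_mode = "diff_of_log_means"`. The two agree in sign and are close for the
within-group spreads typical of normalized arrays; the mode used is logged
by the pipeline so any reproduction states which variant ran.

Genes with $|\mathrm{FC}| \ge 1.5$ are called differentially expressed. The
call uses the fold-change rule **only**; a two-sided Wilcoxon rank-sum
p-value is computed per gene and reported alongside (exact enumeration for
small samples without ties, normal approximation with tie correction
otherwise), and an optional `p_threshold` can additionally gate the call but
defaults off. No multiple-testing correction is applied at this stage, and
none is implied by the DE call: the per-gene p-values are descriptive. When
every value in both groups is identical the ranking is degenerate and
$p = 1$ is returned by convention. DE tables are sorted by signed fold
change ascending with lexicographic tie-break, so output order is
deterministic.

## Gene set enrichment

Genes are ranked by descending signed fold change (ties broken by symbol):
the top of the list is most up-in-young, the bottom most up-in-old. For a
set with $N_{hit}$ members inside the $N$-gene universe, a running sum
increases by $w_i / \sum w$ at members and decreases by $1/(N - N_{hit})$
elsewhere. The enrichment score is the **signed maximum-magnitude
deviation** of that walk (first occurrence on exact ties), a single number
in $[-1, 1]$: negative ES means the programme concentrates among genes
up-regulated in old stroma.

Design choices that were genuinely open, and how they were fixed:

* **Weighting.** The default is the unweighted (classic Kolmogorov–Smirnov)
  statistic, $w_i = 1$, because it admits an exact brute-force oracle and an
  exhaustively enumerable permutation null — both exploited by the test
  suite. The score-weighted variant ($w_i = |score_i|$, exponent 1, the
  common default of weighted GSEA implementations) is available as
  `weight_mode = "weighted"` and is cross-checked against `fgsea`'s
  statistic in the tests. The choice matters when comparing printed ES
  values across implementations, which is why both modes are first-class and
  logged.
* **ES extraction.** One signed maximum-magnitude deviation rather than a
  (max-positive, min-negative) pair, because a single ES per set spanning
  $[-1, 1]$ is what the analysis reports and plots.
* **Permutation scheme.** `gene_label` by default: the ranking is computed
  once and null sets of size $N_{hit}$ are drawn from the universe. It is
  cheap, well-defined for any ranking, and exhaustively enumerable on small
  universes (`exact = TRUE`). Phenotype permutation — reshuffling the 9/8
  group labels and re-deriving the whole ranking — is implemented
  (`scheme = "phenotype"`) and is the stricter null when fold changes are
  correlated across genes, but with $\binom{17}{8} = 24310$ distinct splits
  its resolution is limited and only sampled permutations are offered.
* **p-value.** Two-sided on $|ES|$, with the add-one correction
  $p = (1 + \#\{|ES_{perm}| \ge |ES_{obs}|\})/(1 + n_{perm})$ so $p > 0$
  always. Across the batch of tested sets, Benjamini–Hochberg gives
  `q_fdr`.
* **Small sets.** `min_hits = 3` by default, so the 3-gene DNA damage
  response programme remains testable; sets below it are skipped and
  reported. With such tiny sets the permutation p is necessarily coarse —
  a singleton, for instance, can only take $N$ distinct ES values — which
  is the price of scoring literature-curated programmes as printed.
* **Determinism.** Seeds are mandatory and each set gets a sub-seed
  (`seed + position`), so adding a set never changes the others' p-values,
  and no function touches the caller's RNG state.

## The curated programmes and fixtures

The four programmes ship as a GMT fixture: senescence effectors (CDKN1A,
CDKN2A, TP53, RB1, GLB1), the DNA damage response axis (ATM, NBN, CHEK2),
a 43-gene SASP panel, and the 15-gene AST panel. Symbols are used exactly
as printed in the source tables (e.g. `IL8`, not `CXCL8`): the analysis
matches on the array's symbol annotation and silent alias resolution would
change set membership. `CCL3` appears in the source SASP table
parenthesised — a typographic signal of doubt whose meaning (exclusion?
alias uncertainty? partial detection?) is not stated — so it is carried as
a *provisional* member: excluded from the default SASP membership,
re-included with `load_curated_sets(include_provisional = TRUE)`. In GMT
files provisional members are written back parenthesised, making the
round-trip exact.

The published 227-gene DE table ships as a TSV fixture (120 negative,
107 positive signed fold changes, strongest `SPP1` at −4.79; where the
running text and the table disagree on a sign, the table's convention was
kept). The patient metadata table (9 young, 8 old) ships likewise. The
external validation lists do **not**: the external datasets' DE lists were
never published as tables, and this package does not reprocess the public
accessions. Instead `external_de_lists_synthetic.tsv` is a clearly labelled
synthetic stand-in — built from the ten published overlap genes plus
invented decoys and not-significant universe padding — sufficient to
exercise and test the validation machinery. Deriving real external lists is
a manual recipe (below), not code.

## Overlap validation

`intersect_lists()` intersects the study's DE lists with external lists per
direction, restricted to a common universe: by default the intersection of
the measured-symbol universes of the two sides (the most conservative
well-defined choice), with the external datasets pooled first
(`union_of_external`) or kept separate (`per_dataset`). Significance is the
one-sided hypergeometric tail $P(X \ge k)$ — the standard test for gene-list
intersection — computed exactly. Both the universe choice and the pooling
mode change the p-value, so both are explicit parameters and part of the
output.

## The synthetic-data generator

`simulate_expression()` emulates the statistical structure the analysis
assumes, with known ground truth: gene baselines
$\mu_g \sim N(7, 1)$ (log2), within-gene residual noise
$N(0, 0.3)$, two groups of 9 and 8 samples, a sparse 1% of genes with
strong effects ($\pm$`de_log2fc`, default 1.5 log2 units ≈ 2.8-fold, inside
the 1.5–5-fold range the DE stage targets), optional coordinated module
shifts, and optional many-probes-per-gene redundancy (probe jitter
$N(0, noise\_sd/2)$ around the gene profile). Module shifts are
*sub-threshold* by design — each member below the 1.5-fold cut-off — so
that set enrichment, not single-gene DE, is what detects them; this
reproduces the qualitative mechanism of interest, where SASP and AST
emerged only when their genes were compiled into sets.

What the generator does **not** model: probe-level microarray noise and
background, LCM sampling artefacts, RNA degradation or amplification bias,
gene–gene correlation beyond the injected modules, and batch structure.
Green tests therefore certify the inferential machinery under a clean
Gaussian log-intensity model, not robustness to real-array pathologies.

`null_battery()` runs the no-effect configuration repeatedly and reports
observed type-I rates for the DE call, the Wilcoxon step and set
enrichment. Note the exact Wilcoxon null for a 9-vs-8 design is discrete:
the attainable rate just below $\alpha = 0.05$ is slightly under 0.05, and
the test suite compares against that exact attainable rate, not 0.05
itself.

## Problem sizes and numerical tolerances

The test suite pins the implementation to independent oracles at sizes
where exhaustive enumeration is feasible: every ES instance with
$N \le 12$ and set size $\le 4$ against a plain running-sum walk; every
two-group split of $\le 8$ distinct values against full-enumeration
Wilcoxon; the 15-outcome exhaustive permutation null for a pair in a
6-gene universe; hypergeometric tails against explicit `choose()` sums
(tolerance $10^{-12}$ on all closed-form comparisons). Stochastic checks
use fixed seeds: 500 null permutation p-values against uniformity
(Kolmogorov–Smirnov, $\alpha = 0.01$), a 2000-gene background with a
20-gene +0.6 log2 module at $n_{perm} = 10^4$, and simulation batches of
150–2000 genes chosen so the full suite runs in well under a minute —
sizes at which the measured rates are stable, not a constraint of the
method.

## Reproducing the published array-wide enrichment scores

The shipped fixtures allow replaying the published DE table (the pipeline's
`de_table` replay mode reproduces its 120/107 partition), but the published
*array-wide* ES values for the four programmes were computed on the full
~20k-symbol ranking, which only exists after reprocessing the deposited
raw data. The recipe: download the study's GEO series matrix
(accession GSE90521) or CEL files, fRMA-normalize, map probe sets to
symbols, then

```r
m  <- read_expression_matrix("GSE90521_series_matrix.txt", group_map)
m  <- collapse_probes(m, probe_symbol_map)
de <- run_diffexp(m)                       # fc_mode as discussed above
res <- run_gsea(de, load_curated_sets(), n_perm = 10000, seed = 1)
```

Two caveats make this a reproduction *attempt* rather than a mechanical
check: the original analysis's GSEA variant (weighting exponent,
permutation scheme, sidedness) is not fully specified, so both weight modes
should be tried; and the probe→symbol annotation version affects the
universe. The pipeline logs both knobs precisely so that any reproduction
states what was run.

## Known limitations

* Tiny curated sets give coarse permutation p-values; interpret DDR/
  senescence scores accordingly.
* The gene-label null treats genes as exchangeable within the fixed
  ranking; correlated expression (co-regulated neighbours of a programme)
  makes it anti-conservative relative to phenotype permutation.
* The hypergeometric overlap test conditions on list sizes and universe;
  with universes as small as the shipped synthetic stand-in, p-values are
  illustrative, not comparable to array-wide analyses.
* The fold-change-only DE rule has no error-rate control; it mirrors the
  published procedure rather than current best practice (moderated
  statistics with FDR would be the modern choice).
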