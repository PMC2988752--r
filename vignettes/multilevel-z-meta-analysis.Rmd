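---
title: "Multilevel signed Z-score meta-analysis: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel signed Z-score meta-analysis: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zmeta)
```

## The model

Many differential-expression studies publish only a per-gene p-value and
the direction of change, not the underlying expression values.  `zmeta`
combines evidence at exactly that granularity.  For gene $i$ in study
$j$ with p-value $p_{ij}$:

$$
z_{ij} = \begin{cases}
\Phi^{-1}(1 - p_{ij}) & \text{up-regulated in the adverse phenotype}\\
\Phi^{-1}(p_{ij})     & \text{down-regulated,}
\end{cases}
$$

so the sign encodes direction and the magnitude the strength of
evidence.  Across the $N_i$ studies whose platform measured gene $i$,

$$
Z_i = \frac{\sum_j z_{ij}}{\sqrt{N_i}}
$$

(Stouffer's method in Rosenthal's extension).  Under the per-study null
the $z_{ij}$ are standard normal, and the $\sqrt{N}$ denominator keeps
$Z_i$ standard normal regardless of how many platforms carried the
gene.  The assumptions are the usual ones for p-value combination:
studies are independent, each p-value is valid (uniform under its
null), and a common direction convention exists across studies.

Because study counts differ between cancer types — with four breast
studies against nine lung studies, the lung evidence would otherwise
dominate any aggregate — per-type tables are rescaled before they are
compared.  With per-type mean absolute scores $m_g$, the common target
is the unweighted mean $\bar m$ and every score in type $g$ is
multiplied by $\bar m / m_g$.  For two groups with $m = 1.87$ and
$2.85$ this gives a target of $2.36$ and factors $1.26$ and $0.83$:

```{r}
breast <- signed_z_table(c("A", "B"), c(1.0, 2.74), label = "breast")
lung   <- signed_z_table(c("A", "B"), c(2.0, 3.7),  label = "lung")
bal <- balance_groups(list(breast = breast, lung = lung))
round(c(target = bal$target, bal$factors), 2)
```

Balancing multiplies each group by one positive scalar, so it never
reorders genes within a type, and the post-adjustment mean $|Z|$ of
every group equals the target to $10^{-9}$ (asserted in the tests).

## The three levels

1. **Level 1 — bone vs non-bone.** Within each cancer type the
   normal-vs-tumor studies are Stouffer-combined; all types are
   balanced jointly; the bone-metastasizing side (breast, lung) and the
   non-bone side (colon, ovarian) are each summarized as the unweighted
   mean of their adjusted per-type tables; the sides are subtracted.
   The subtraction cancels the generic carcinoma signature and keeps
   what is specific to bone-metastasizing cancers.
2. **Level 2** averages the level-1 contrast gene-wise with the
   combined prostate normal-vs-localized table.
3. **Level 3** averages the level-2 table with the combined
   localized-vs-metastatic table.

Averaging pairwise and in this order is deliberate: for a gene present
at every stage,

$$
Z^{(3)} = \tfrac14 Z_{\text{bone contrast}} + \tfrac14 Z_{\text{prostate NT}}
        + \tfrac12 Z_{\text{loc vs met}},
$$

so the most progression-specific comparison carries half the final
weight.  The property suite verifies this weight law symbolically on
random tables.

### Design choices that were genuinely open

* **Within-side aggregation at level 1** is the unweighted mean of the
  adjusted per-type tables, not a further Stouffer combination: a
  second $\sqrt{N}$ combination would re-inflate whichever side has
  more types and defeat the purpose of balancing.  Balancing itself is
  run across all four types jointly (one common target), and is *not*
  applied at levels 2–3, which involve a single tissue.
* **Missing-gene policy.** Platforms overlap only partially, so per-gene
  study counts differ.  A contrast needs both sides, so `contrast_tables`
  drops one-sided genes by default (the count is logged; a `zero_fill`
  alternative exists).  An average can tolerate one side, so
  `average_tables` carries the available value by default, which is how
  genes measured on only some platforms stay in the final ranking.
* **Sidedness.** Source studies rarely state whether their p-values are
  one- or two-sided; the conversion applies $\Phi^{-1}(1-p)$ to the
  supplied value without halving, and the synthetic generator emits
  two-sided p-values for symmetry with the equal-variance t-test used
  on expression matrices.
* **Stouffer denominator.** $\sqrt{N}$, the standard form of the named
  method; it is isolated in `combine_stouffer()` so the plain-$N$
  variant would be a one-line change.

## Numerical choices

* P-values are clamped into $[10^{-15}, 1 - 10^{-15}]$ on ingest;
  this keeps $\Phi^{-1}$ finite without materially moving any p-value a
  DE tool realistically reports.
* A simulated t-statistic of exactly 0 is reported as direction "up"
  (a deterministic tie-break; the event has probability 0 for
  continuous draws).
* Candidate ranking breaks z ties lexicographically by gene symbol, so
  `rank_candidates()` output is reproducible across platforms.
* Genes with zero pooled variance in `per_gene_ttest()` get p = 1 with
  a warning rather than NaN; `enrichment_ttest()` on a zero-variance
  split with separated means returns an infinite statistic, which is
  what the pooled formula yields.
* Gene symbols are uppercased at every boundary; balancing refuses a
  group whose mean $|Z|$ is 0 (a degenerate table rather than a
  recoverable state).

## What the synthetic generator emulates — and what it does not

`generate_truth()` plants three disjoint effect components on a gene
universe: a shared *tumor* signature (all normal-vs-tumor studies), a
*bone* signature (normal-vs-tumor studies of breast, lung, prostate),
and a *metastasis* signature (localized-vs-metastatic studies).  Within
each component half the planted genes go up and half down (odd counts
resolve toward up).  Defaults — 10,000 genes, 100 planted genes per
component at standardized effect 1.0, 10 hubs — describe a moderately
strong signature in a genome-scale universe and are the conditions
under which the package's recovery behavior is assessed.

`simulate_study()` draws each on-platform gene's t-statistic from the
noncentral t distribution with noncentrality
$\delta\sqrt{n_1 n_2/(n_1+n_2)}$ and $n_1+n_2-2$ degrees of freedom —
the exact sampling distribution of a two-sample t under normality — and
reports the two-sided p with the statistic's sign.  Simulating at the
p/direction granularity matches what the meta-analysis actually
consumes, and reproduces the two structural nuisances that matter:
larger studies yield sharper p-values for the same effect, and each
study measures only a seeded uniform subsample of genes
(`platform_fraction`), so contributing-study counts vary per gene.

The default study collection mirrors a realistic multi-study corpus:
4 breast + 9 lung normal-vs-tumor studies on the bone side, 5 colon +
5 ovarian on the non-bone side, 11 prostate normal-vs-localized and 7
localized-vs-metastatic studies.  The prostate group sizes follow a
published study roster for those two comparisons (e.g. 22 vs 59, 3 vs
22, 59 vs 20, 27 vs 5); the non-prostate sample sizes are invented but
typical of early microarray cohorts (4–86 per arm).  Platform fractions
cycle through 0.7–1.0.

`generate_interactome()` wires each planted hub to at least
`hub_degree_min` partners (default 10) drawn preferentially from the
planted-effect genes — the picture of a driver regulating the members
of its signature — plus 20,000 uniform background edges over the
10,000-gene universe, a sparse density typical of curated direct-interaction
networks.  This wiring is what makes hub recovery from the
*candidate-induced* subnetwork a fair benchmark: a hub's neighborhood
is largely inside the top candidates, while its overall connectivity is
diluted by the full network.

What the generator does **not** emulate: probe-level structure and
probe-to-gene collapsing, normalization artifacts, batch effects,
correlated genes (all draws are independent given the planted effect),
heterogeneous true effects across studies of the same phenotype, and
any dependence between the interactome and expression noise.  Passing
tests therefore demonstrate that the pipeline's mathematics recovers
planted signal under its own assumptions — not that any particular real
dataset satisfies those assumptions.

## Hub selection

`select_hubs()` nominates gene $g$ from candidate subnetwork $S$ of full
interactome $F$ when

$$
\deg_S(g) \ge 5 \quad\text{and}\quad
\frac{\deg_S(g)/(|S|-1)}{\deg_F(g)/(|F|-1)} \ge 2 .
$$

"Connectivity" is operationalized as degree normalized by the number of
possible partners, so the local and overall quantities are comparable
densities; a raw degree ratio is available via
`normalization = "degree"`.  The degree threshold refers to the
subnetwork ("interacts with at least 5 other genes *from the
network*"), and interactions are collapsed to undirected edges since
the criterion does not use direction.  Both thresholds are monotone
filters: raising either can only shrink the hub list.

## Validation statistics

`relative_z()` is the ratio of a set's mean $|Z|$ to the
transcriptome-wide mean $|Z|$; for a sound pipeline, the ratio for
genes genuinely tied to progression should exceed 1 and rise from
level 1 to level 3 (the acceptance suite checks this trend across 50
replicate simulations).  `enrichment_ttest()` formalizes the same
comparison as a pooled-variance t-test on $|Z|$ with $df =$ genes $- 2$.
`compare_correlations()` implements the independent-samples Fisher
r-to-z test; when the two correlations share a vector (as
tissue-vs-prostate comparisons do) the test is approximate, since the
cross-correlation needed for the dependent version is generally not
recoverable from published summaries.  `set_mean_z()` uses *signed*
means — concordance with an external up/down split shows as
mean(up) > mean(all) > mean(down) — while enrichment uses $|Z|$.

## Problem sizes

The shipped test-suite and acceptance script exercise the defaults the
generator is calibrated to: single runs and 50-replicate trend checks
at 10,000 genes with 41 studies across the four roles, plus smaller
universes (200–3,000 genes) for unit-level properties.  These sizes
were chosen as the package's reference conditions; all stages are
vectorized, and one full replicate completes in a few seconds.

## Known limitations

* Evidence enters only through p-values and directions; no
  effect-size or random-effects meta-analysis, and no modeling of
  between-study heterogeneity beyond the |Z| balancing.
* Balancing couples groups globally: adding or removing any study
  shifts every type's adjustment factor slightly, so only the
  pre-balancing Stouffer stage is strictly local to a study's platform.
* The carry-available averaging policy means a gene measured at only
  one level is scored by that level alone, with no penalty for reduced
  evidence beyond its smaller `n_studies` count.
* The hub rule is a fixed threshold pair, not a statistical test; it
  inherits the arbitrariness of "at least 5" and "twice the overall
  connectivity".
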