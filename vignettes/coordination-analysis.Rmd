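---
title: "Coordination analysis: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coordination analysis: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coordinatr)
```

## The statistic and its assumptions

`coordinatr` compares, between a reference and a condition group of
expression samples, not the *level* of each gene but its *coordination*:
the vector of Pearson correlations it exhibits with every other gene
across a group's samples. For a seed gene $s$ and group $g$ the profile is

$$ R^{(g)}(s) = \big(\, r(x_s^{(g)}, x_t^{(g)}) \,\big)_{t \neq s}, $$

and the composite correlation is the correlation of the two profiles,

$$ \mathrm{Pc}(s) = \mathrm{cor}\!\left( R^{(\mathrm{ref})}(s),\,
   R^{(\mathrm{cond})}(s) \right). $$

A gene with high Pc keeps the same "correlation fingerprint" in both
groups; a gene with low Pc has been decoupled from (or re-coupled to) the
transcriptome when the condition emerges. The statistic assumes:

* samples within a group are exchangeable replicates of one biological
  state (no batch or time structure);
* Pearson correlation is meaningful on the supplied values — for raw
  counts this is the analysis convention adopted here (the pipeline
  correlates the matrix as provided by default), but library-size
  gradients can masquerade as global co-expression, which is why
  `transform = "cpm_log1p"` is offered;
* the two profiles are comparable position by position. This drives the
  shared-background rule below.

No significance is attached to a single Pc value: the published analysis
reports none, and with 8 samples per group a profile entry has a standard
error of roughly $1/\sqrt{n-3} \approx 0.45$ z-units, so Pc is a ranking
statistic, not a test statistic. Calibration is instead demonstrated on
synthetic data: under the null (no rewiring, no amplification) the
recovery AUC of a pseudo-rewired label set is 0.5 within ±0.05 (asserted
by the acceptance suite over 1,000 label permutations).

## Parameters that matter

| parameter | default | units / range | rationale |
|---|---|---|---|
| `min_reads` | 70 | reads, inclusive | the published high-expression cut-off ("at least 70 reads"); applied to reference-group aggregates only, so the gene set is fixed before the condition group is examined |
| `read_aggregation` | `mean` | mean / min / sum | the source analysis does not state how 8 samples are aggregated; mean is least sensitive to single-sample dropouts; `min` gives the strictest reading of "at least 70 reads", `sum` suits pooled counting |
| `r_cutoff` | 0.5 | Pearson R, strict `>` | the published correlated-set rule is "R>0.5"; the boundary value itself is excluded, and the strictness is covered by a unit test |
| `pc_method` | `pearson` | pearson / spearman | the source uses Pearson for R; Spearman is offered because profiles are bounded and can be heavy-tailed near ±1 |
| `transform` | `none` | none / log1p / cpm_log1p | correlate values as deposited (the convention reproduced here); CPM+log1p available when library sizes differ materially |
| `bottom_k`, `top_k` | 3 | genes | the published workflow carries the 3 lowest-Pc genes (and a high-Pc control) into the functional comparison |
| `fdr_alpha` | 0.05 | BH q | conventional FDR level defining a set's "functions" |
| `min_term_size` | 5 | genes, after background intersection | singleton/tiny terms produce noise-dominated hypergeometric tails |

## Numerical and degenerate-input choices

* **Undefined is a flag, not a NaN.** A constant vector has no defined
  correlation; `pearson_r()` returns `NA_real_` deliberately, profiles
  mark such entries, and `composite_correlation()` computes Pc over
  positions where both profiles are defined, requiring at least 3 and
  non-constant sub-vectors. Undefined Pc records sort last and are never
  selected.
* **Shared background.** For each seed, the profile background excludes
  the seed itself (its self-correlation of 1 in both groups would inflate
  every Pc identically) and every gene with zero variance in *either*
  group, so the two profiles are index-aligned. Removals are logged with
  counts.
* **Ties.** Ranking ties break lexicographically by gene identifier
  (radix/C collation), making outputs byte-stable across reruns.
* **Round-off.** Correlations are clamped to $[-1, 1]$; identity checks
  in tests use a $10^{-12}$ tolerance; the scalar `pearson_r()` is checked
  against a brute-force product-moment oracle and the matrix route
  (`stats::cor`) is cross-checked against the scalar route.
* **Boundary config.** `r_cutoff` is constrained to the open interval
  (0, 1): a cutoff of exactly 1 would make every correlated set empty by
  construction (correlations are clamped to 1), so it is rejected at
  configuration time rather than silently producing empty output. The
  "cutoff excludes everything" behaviour is still exercised in tests with
  a cutoff of 0.99.
* **Duplicates and gaps at I/O.** Duplicate gene rows are *summed* (read
  counts are additive), missing cells become 0 with a warning (sparse
  exports omit zeros), and both events are surfaced to the user rather
  than hidden.

## The enrichment stand-in

The original analysis delegates "GO analysis" to an external web platform
whose test and versioned annotation are not reproducible offline. The
package substitutes the simplest defensible equivalent: a one-sided
hypergeometric over-representation test of each GMT term against the
shared profile background, with Benjamini–Hochberg adjustment, and
"functions" defined as terms with $q < \alpha$. FRI and FAI are then
exactly the published index definitions:

$$ \mathrm{FRI} = \frac{|\text{common terms}|}{|\text{condition terms}|},
   \qquad
   \mathrm{FAI} = \frac{|\text{new terms}|}{|\text{condition terms}|}, $$

with FRI + FAI = 1 whenever the condition term set is nonempty and both
undefined when it is empty (a seed whose condition-group correlated set
has no significant term has no denominator; reporting 0/0 as 0 would
fabricate "full loss"). Because the platform's significance criterion is
unknowable, absolute term counts (such as the published count of shared
terms) are not comparable and are not asserted anywhere; only the index
algebra and the intersection machinery are.

## What the simulator emulates — and what it does not

Each sample draws one standard-normal factor per module plus per-gene
noise; a gene in module $m$ has latent value
$\sqrt{\rho}\, f_m + \sqrt{1-\rho}\,\varepsilon$, which makes the
within-module latent correlation exactly $\rho$ and between-module
correlation zero. Latents become counts via the Gaussian copula: the
negative-binomial quantile of the latent's normal CDF value, with
per-gene means drawn log-uniformly and a shared dispersion. The copula
decouples the correlation target (what coordination analysis measures)
from the marginal count distribution (what RNA-seq produces); the
marginal-fidelity test checks simulated means against their NB targets at
$n = 10{,}000$.

Design choices made once, and why:

* **Rewiring = module reassignment**, not noise injection: a rewired gene
  keeps its marginal distribution and high expression, isolating loss of
  coordination from differential expression.
* **Coherence amplification is one multiplicative knob**
  ($\rho \mapsto \min(1.15\rho, 0.99)$ by default) because the source's
  directional claim — correlation increases in the condition group — is
  qualitative, not quantitative.
* **Defaults are the recovery-scale world**: 2,000 genes, 50+50 samples,
  10 modules × 50 genes, $\rho = 0.7$, 100 seeds, 10 rewired. Profiles
  over 8+8 samples (the real cohort's size) are far too noisy for stable
  unit assertions; the identity-pipeline acceptance test runs at 8+8 where
  exactness is guaranteed by construction.
* **Unstated marginals chosen once as realistic bulk values**: NB
  dispersion 0.2 (variance $\mu + 0.2\mu^2$, typical of human bulk
  cohorts) and log-means uniform on $\log 5$–$\log 500$ reads. Seed genes
  draw from the top quarter of that range so they clear the 70-read
  filter by construction rather than by luck.

The simulator does **not** model batch effects, library-size gradients,
differential expression, or single-cell dropout. Consequently a green
recovery test establishes that the statistic recovers planted profile
rewiring under clean exchangeable sampling — not that it is robust to
confounding, normalization error, or the 8-sample noise regime of real
cohort data. One honest subtlety the simulation itself exposes: genes
*outside* any module have pure-noise profiles whose Pc is low and
unstable, so in a world with many unco-ordinated genes the global bottom
of the ranking mixes genuinely rewired genes with noise genes. Recovery
is therefore always evaluated among the designated seed set, and real
analyses should read the bottom of the ranking alongside the size of each
gene's correlated set.

## Known limitations

* Pc carries no p-value or permutation null by design (out of scope); the
  ranking is descriptive.
* The ≥ 70-read aggregation across reference samples is a documented
  guess (`mean`, selectable) — the source text does not specify it.
* Reproducing the published per-gene Pc values exactly would require the
  accession's processed matrix and knowledge of its preprocessing, which
  the source does not document; the reproduction script states this.
* The enrichment stage tests the supplied GMT as a flat collection: no
  ontology-graph propagation, so parent terms are only found if
  explicitly present in the GMT.
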