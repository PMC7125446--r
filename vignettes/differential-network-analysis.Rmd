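---
title: "Differential network-structure analysis with mdgnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential network-structure analysis with mdgnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdgnet)
```

`mdgnet` compares the *structure* of gene co-expression networks between two
cohorts. The working hypothesis is that disease can manifest as rewiring:
a gene keeps its expression level but changes which partners it co-varies
with. The package operationalizes this with one structural parameter — node
degree in a thresholded Spearman correlation network — and ranks genes by
how much their degree differs between cohorts.

# The model and its assumptions

Let $X_g^C$ and $X_g^E$ denote gene $g$'s expression across the control and
experimental samples. Three ingredients define the analysis:

1. **Correlation networks.** For each cohort, compute all pairwise Spearman
   coefficients $\mathrm{SCC}(A,B)$. Spearman is used because microarray-scale
   expression is monotone-but-not-linearly related across genes and is robust
   to heavy tails; only the rank structure of each profile matters. At a
   threshold $\alpha \in (0,1]$, genes $A \ne B$ are joined iff
   $|\mathrm{SCC}(A,B)| \ge \alpha$ (inclusive; sign is ignored, since
   strongly negative dependence is dependence).
2. **Average degree.** The sole structural parameter compared is the mean
   degree $2m/n$ of each cohort's network, traced over the grid
   $\alpha \in \{0.1, \dots, 0.9\}$. The cohorts are *separable* when one
   average-degree curve strictly exceeds the other at **every** grid point;
   any tie or crossing counts as not separable. The strictness is
   deliberate: average degrees are noisy summaries, and a claim of global
   structural difference should not survive a single tied threshold.
3. **MD-G score.** Gene $g$'s score is
   $\frac{1}{|\mathcal A|}\sum_{\alpha \in \mathcal A}
   |\deg_C(g,\alpha) - \deg_E(g,\alpha)|$ — the *absolute* degree
   difference averaged over the grid. The absolute (rather than relative)
   difference is used on purpose: a relative change $|E-C|/C$ depends on the
   baseline $C$, so hub genes and periphery genes would be scored on
   different scales. Ties in the ranking break by ascending gene identifier,
   making every reported list deterministic.

The analysis presumes expression has already been preprocessed and collapsed
to one value per gene per sample; no normalization is performed here.

# The screening cascade

Structural comparison is preceded by a per-gene differential screen, built
as a decision tree so that each gene receives exactly one location test,
chosen by the evidence about its distribution:

| stage | test | question | default FDR cutoff |
|---|---|---|---|
| 1 | two-sample KS | same distribution at all? | 0.0005 |
| 2 | one-sample KS per cohort | is each cohort normal? | 0.001 |
| 3 | two-sided variance-ratio F | equal variances? | 0.001 |
| 4 | pooled t / Welch / Mann–Whitney | equal location? | 0.001 |

A gene whose two-sample KS q-value passes stage 1 is flagged outright
(route `ks2_different`). Otherwise, if both cohorts pass the normality
check, the F test routes the gene to the pooled `t` (variances homogeneous)
or `welch` test; if either cohort fails normality the gene goes to
`mann_whitney` — justified because stage 1 already found the two
distribution *shapes* consistent. A gene is flagged iff it exits at stage 1
or its final location q-value passes the stage-4 cutoff.

Several points were genuinely open and are resolved as follows:

* **FDR families.** One cutoff per stage is interpreted as one
  Benjamini–Hochberg family per stage, computed across the genes that reach
  that stage, with the two cohorts' normality p-values adjusted as two
  separate families. `fdr_scope = "global"` instead computes every stage for
  every gene and adjusts each stage across all genes; on strong signals the
  two scopes agree (tested), and staged is the default because each stage
  then remains a well-defined multiple-testing family.
* **Normality with estimated parameters.** The one-sample KS is applied to
  the sample standardized by its own mean and SD. The classical p-value is
  then conservatively biased (the Lilliefors problem); this is accepted as
  the default because the plain KS is the stated procedure, and
  `normality = "lilliefors"` provides the corrected test (used in the test
  suite to verify that heavy-tailed genes reach the Mann–Whitney route once
  the normality stage has power).
* **Two-sided F test.** $p = \min(1,\, 2\min(P(F \le f), P(F \ge f)))$, so
  the result is symmetric in the cohorts (tested).
* **Degenerate genes.** A cohort with zero variance cannot satisfy the
  parametric preconditions: the normality check returns $p = 0$ and the gene
  is routed to Mann–Whitney. If *all* values across both cohorts are tied,
  the location p-value is 1 by convention.
* **Mann–Whitney.** Exact enumeration when both samples have at most 8
  untied values, otherwise the normal approximation with continuity and tie
  correction.

A practical consequence worth knowing: a large location shift is itself a
gross distribution difference, so strongly shifted genes exit at stage 1
rather than reaching "their" location test. The cascade's routes therefore
describe how *evidence* was weighed, not which generative family a gene came
from; what is guaranteed (and tested, at a 3-SD effect) is the final
decision — differential genes flagged, null genes passed through.

# The Monte Carlo null experiment

Observed separability is calibrated against the probability that two
datasets drawn from the *same* distribution separate by chance, in either
direction. Two null models are exposed:

* `iid_normal` (default): every entry of both replicate matrices is standard
  normal at the analysis dimensions.
* `label_permutation`: pools the user's two cohorts and reassigns sample
  labels at random, preserving the real gene–gene correlation structure.

The estimate is a binomial fraction over `B` replicates with standard error
$\sqrt{\hat p(1-\hat p)/B}$, and `confidence = 1 - estimate`.

`scripts/acceptance.R` runs the `iid_normal` model at 244 genes and 64/82
samples with $B = 200$, the dimensions of the motivating case-control
design. The estimate there is **0%**: with $n \ge 64$ samples the null
Spearman coefficient has standard deviation $1/\sqrt{n-1} \approx 0.11$, so
$P(|\mathrm{SCC}| \ge 0.8)$ is astronomically small, both cohorts' average
degrees are exactly zero at $\alpha = 0.8$ and $0.9$ in essentially every
replicate, and the strict tie rule then forbids separability. In other
words, the i.i.d. null's correlation tails are far thinner than real
expression data's (real cohorts retain nonzero degrees at $\alpha = 0.9$).
A null calibrated on data of realistic dependence — the
`label_permutation` model — is therefore the recommended reference for real
analyses; the i.i.d. model remains the reproducible, data-free default for
the reported calibration quantity. This model-dependence is intrinsic to any
"random network" calibration whose generator is not pinned down.

# The synthetic-data generators

`sim_config()` defaults emulate a peripheral-blood case-control expression
design: 64 control and 82 experimental samples, gene panels in the
thousands, and a standardized effect size of $\delta = 3$ for planted
differential genes.

* **Cascade branches** (`gen_de_dataset()`): shape-shift genes are standard
  normal in C and a two-component normal mixture with means $\pm 0.989$ and
  component SD 0.15 in E — first two moments matched, strongly bimodal, so
  only the two-sample KS can see the difference. The values were chosen so
  that KS power at $q \le 0.0005$ is reached around 150 samples per cohort
  (the sup-distance to the normal CDF is $\approx 0.22$). The heavy-tailed
  family is Student $t_3/\sqrt 3$ (unit variance, same shape in both
  cohorts, location shifted by $\delta$), giving a branch where the
  two-sample KS passes under $\delta = 0$ while normality genuinely fails.
  The unequal-variance branch uses a variance ratio of 4.
* **Connectivity modules** (`gen_connectivity_dataset()`): module genes
  follow the single-factor model $x_g = \lambda_g f + \sqrt{1-\lambda_g^2}\,
  \varepsilon$ with one factor draw per sample; planted genes have
  $\lambda = \rho_C$ in C and $\rho_E$ in E, peers $\rho_C$ in both,
  background genes pure noise. Marginals stay standard normal, so the planted
  signal is invisible to the screen by construction — which is exactly what
  makes it a clean test of the degree-difference ranking.
* **Gene sets** (`gen_gene_sets()`): random terms over the universe plus one
  deliberately planted term, written and re-read as plain GMT.

All randomness flows from the single config seed through `withr::with_seed`,
so every dataset, test and acceptance experiment is reproducible bit for
bit.

What the generators do **not** emulate: probe-level noise, normalization
artifacts, batch effects, correlated null genes outside planted modules, or
realistic (heavy-tailed, blockwise) background dependence. Passing tests
demonstrate that the pipeline recovers the planted structure under clean
conditions; they do not certify power or calibration on real microarray
data, where background correlation alone will inflate degrees at low
thresholds.

# Numerical choices

* Threshold comparisons use |SCC| rounded to 12 decimal places, so ties at
  the cutoff resolve identically across platforms; the comparison itself is
  inclusive (`>= alpha`).
* Correlation against a constant gene is undefined; it is set to 0 with a
  warning (no edge at any positive threshold) rather than propagating `NA`.
* The two-sample KS in the screen defaults to the asymptotic p-value
  (`ks2_exact = FALSE`): it is fast at thousands of genes and handles ties
  uniformly; the exact small-sample computation remains available through
  `two_sample_ks()`.
* Kappa similarity is computed over the query gene list (the convention of
  the enrichment tools this mirrors), with the degenerate case (expected
  agreement 1) defined as 1 when observed agreement is 1 and 0 otherwise.
* Term clusters are the maximal average-linkage subtrees whose merges all
  exceed kappa 0.3; the dendrogram cut at height $1 - 0.3$ is taken with a
  small epsilon so that the cut is strict at exactly 0.3. Linkage is
  exposed (`linkage =`) since no particular agglomeration rule is canonical.
  Cluster representatives are smallest-p members (ties by term id) and
  clusters are renumbered by representative significance.
* The enrichment universe defaults to the union of all GMT genes —
  "the whole genome" is not reproducible without fixing an annotation
  release — and can be overridden.
* `diff_stats()` uses the population variance by default (divisor $n$); the
  choice is configurable since the difference is not identifiable from
  reported magnitudes alone, and its default gene list is the MD-G set.

# Problem sizes

The test suite and acceptance experiments run at deliberately modest sizes
chosen as the smallest that leave the statistical questions meaningful:
null-calibration screens at 2,000 genes x 20 seeds, branch-resolution at 500
genes with 300 samples per cohort, connectivity recovery at 230 genes
(30-gene module, 5 planted, 60 samples per cohort) x 20 seeds, and the null
separability experiment at the full 244 x 64/82 dimensions with $B = 200$.
The complete suite runs in about a minute on one core.

# Known limitations

* **Screen-first design.** Restricting the network stages to
  differentially expressed genes (the default) means genes whose *only*
  change is connectivity are never examined; `pipeline_config(screen =
  FALSE)` analyzes all genes when rewiring is the object of interest.
* **Degree only.** No other structural parameters (path length, betweenness,
  clustering coefficient) are computed; the method's premise is that average
  degree already separates the cohorts.
* **Unequal cohort sizes bias degrees.** The smaller cohort's correlation
  null is wider, inflating its degrees at every threshold; the comparison is
  of raw degrees, as defined, and users should keep cohort sizes in mind
  when interpreting direction.
* **Enrichment needs user-supplied GMTs.** No ontology databases ship with
  the package, so term-level results depend entirely on the annotation file
  provided.
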