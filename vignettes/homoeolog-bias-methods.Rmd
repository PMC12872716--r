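---
title: "Methods: homoeolog expression bias, hotspot scanning and biomarker selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homoeolog expression bias, hotspot scanning and biomarker selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

hexbias analyses subgenome expression dynamics in hexaploid wheat RNA-seq
experiments: which of the three homoeologous copies (A, B, D) of a gene triad
carries the expression, how that balance moves across developmental stages and
between genotypes, where differential expression clusters along the genome,
and which genes discriminate genotype classes. This vignette documents the
models and the numerical choices; the README shows the user-facing workflow.

```{r setup, eval = FALSE}
library(hexbias)
```

## Triad bias classification

For a triad with replicate-averaged homoeolog expression
$(t_A, t_B, t_D)$ in TPM, the relative expression of each homoeolog is its
share of the triad total, e.g. $r_A = t_A / (t_A + t_B + t_D)$. Shares are
undefined when the triad total is zero in a condition; such cells are
reported as `undefined` and excluded from proportion denominators.

Triads enter the analysis when their summed TPM reaches 5 in at least one
condition (a genotype × stage combination), with the boundary included
(`>= 5`). Replicates are collapsed by the arithmetic mean before the filter
and the shares; the median is available as an option because the aggregation
statistic is a genuine free choice with skewed expression distributions.

Each (triad, condition) cell is assigned one of seven categories from its
shares, with thresholds read on the fraction scale:

* `X_dominant`: $r_X > 0.60$ and both other shares $\le 0.20$;
* `X_suppressed`: $r_X < 0.20$ and both other shares $< 0.80$
  (each other share individually below 0.80);
* `balanced`: everything else.

The boundary semantics are taken literally from the rule statement: a share
of exactly 0.20 is neither dominant-compatible nor suppressed. The dominant
and suppressed regions overlap — $(0.15, 0.65, 0.20)$ satisfies both
`B_dominant` and `A_suppressed` — and the rules as stated do not order
themselves. hexbias evaluates dominant rules first, because single-homoeolog
dominance is the stronger and more specific signal; cells where both rule
families fire carry `rule_conflict = TRUE` so the choice is auditable. Two
dominant rules can never fire together (two shares cannot both exceed 0.6),
and whenever two suppressed rules fire a dominant rule fires as well, so the
precedence rule resolves every conflict. The partition of the simplex is
verified in the test suite against an independently coded rule table on a
grid of step 0.001.

Ternary coordinates for plotting use the standard barycentric embedding with
the A vertex at the origin, B at $(1, 0)$ and D at $(1/2, \sqrt3/2)$:
$x = r_B + r_D/2$, $y = (\sqrt3/2)\, r_D$.

## Stability across stages

A triad is *stable* in a genotype when its category is defined and identical
at all stages; the overall unchanged fraction divides the stable triads by
the triads with a defined category at every stage (a category cannot be
"unchanged" where it does not exist). The per-category, per-stage stability
of category $c$ at stage $d$ is the fraction of triads assigned $c$ at $d$
(again restricted to all-stages-defined triads) that are stable in $c$; the
per-category average is the unweighted mean over stages. Per-transition
persistence is also available through the stage-pair transition matrices
(`transition_counts()`), which conserve the number of doubly-defined triads.

Genotype-specific stable sets are compared by set difference
(`unique_stable_biased()`), attaching the focal-subgenome gene of each triad
(the B homoeolog for `B_suppressed`, and so on). Their overlap with
differential-expression calls uses the union of the supplied contrasts at
the conventional thresholds $|\log_2 FC| \ge 1$ and adjusted $p < 0.01$,
with a gene-level direction tally (`up`, `down`, `mixed`).

## Genomic hotspot scan

Per-gene $\log_2$ fold changes of a genotype contrast are smoothed along
each chromosome with a Nadaraya–Watson local-constant regression using a
Gaussian kernel in base-pair space, evaluated at gene midpoints. Genes
annotated but absent from the contrast table enter with fold change 0, so
the whole annotated gene set forms the background. Tied midpoints are
separated by a deterministic sub-basepair jitter derived from a gene-id
hash, keeping runs reproducible and input-order independent.

The default bandwidth is 10 Mbp: wheat chromosomes span hundreds of Mbp and
reported enrichment blocks extend over tens to hundreds of Mbp, so a 10 Mbp
kernel resolves such blocks while averaging over enough genes (roughly 10–40
at typical densities) to be stable. It is exposed as a parameter everywhere.

Significance is positional and two one-sided:

* **Permutation mode (default).** Fold changes are permuted over the
  chromosome's gene positions (10,000 times by default) and the observed
  smoothed value is ranked in its positional null with add-one continuity,
  flooring p at $1/(n_{perm}+1)$. This null conditions on the chromosome's
  own fold-change distribution, which makes it calibrated without
  distributional assumptions.
* **t mode.** A one-sample t-statistic of the kernel-weighted values against
  zero, with a Satterthwaite-style effective sample size
  $n_{\mathrm{eff}} = (\sum_j w_j)^2 / \sum_j w_j^2$ per position. This
  mirrors the analytic convention of positional-enrichment tools and can
  produce arbitrarily small p-values.

P-values are Benjamini–Hochberg corrected across all gene positions
genome-wide, separately per direction, and maximal runs of consecutive
significant same-direction genes become regions whose bounds are the member
genes' outermost coordinates.

Two numerical consequences deserve emphasis. First, the discrete permutation
p-value floor means BH-adjusted values cannot fall below roughly
$(1/(n_{perm}+1)) \cdot N/k$ for $N$ positions and $k$ floor-level
positions; the conventional FDR cutoff of $10^{-5}$ is therefore only
meaningful in t mode, and permutation-mode analyses should use an achievable
level (0.05 in the package's own permutation-mode runs). The default
`q_cutoff = 1e-5` is kept for t-mode fidelity to the field convention.
Second, because the permutation null is centred on the chromosome-wide mean
fold change, a chromosome dominated by one strong up-block can show nominal
"down" calls in its flanks — positions significantly below a null inflated
by the block. Down-calls on a chromosome with a large opposite-direction
block should be read with that in mind.

## Nearest shrunken centroids

Counts are prepared as $\log_2((c_{gs} + 1)/\hat{s}_s + 0.5)$ where
$\hat{s}_s$ is the DESeq median-ratio size factor of sample $s$ (median over
reference genes of the ratio to the per-gene geometric mean; genes with any
zero count are excluded from the reference — vacuous after the +1
pseudocount, but enforced for arbitrary input). Voom-style precision weights
(inverse fourth power of a lowess fit of $\sqrt{sd}$ against the mean) can
be computed and used in the centroid means, but are off by default: the
unweighted form is fully specified and auditable, and the weighted variant's
exact placement inside shrinkage differs between implementations, so both
exist behind a flag (`use_weights`).

The classifier is the canonical nearest-shrunken-centroids rule: per-gene
standardized contrasts
$d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))$ with
$m_k = \sqrt{1/n_k - 1/n}$, pooled within-class standard deviation $s_i$
(df $n - K$) and fudge constant $s_0 = \mathrm{median}(s_i)$, soft
thresholded at $\Delta$: $d'_{ik} = \mathrm{sign}(d_{ik})(|d_{ik}| -
\Delta)_+$. Shrunken centroids are $\bar x_i + m_k (s_i + s_0) d'_{ik}$ and
prediction minimizes the standardized squared distance minus
$2 \log \pi_k$. At $\Delta = 0$ this reduces to plain nearest centroids with
pooled standardization (cross-checked against an independent implementation
in the tests); at large $\Delta$ all genes drop and prediction falls back to
class priors.

$\Delta$ is chosen from a 30-point grid between 0 and $\max |d_{ik}|$ by
repeated stratified k-fold cross-validation on the training split (5-fold,
repeated 2 or 10 times), maximizing mean CV accuracy with ties broken toward
the largest threshold — the sparsest model among equally accurate ones,
which is the point of the method when used for biomarker discovery. The
train/test split is stratified 60/40 with per-class training size
`round(0.6 * n_class)`; metrics treat a designated reference class (the
low-responsive genotype) as the negative class for
sensitivity/specificity. All randomness (split, folds) sits behind integer
seeds.

## The synthetic hexaploid generator

The generator emulates the design of a two-genotype (high- vs
low-embryogenic), three-stage, three-replicate hexaploid experiment with
known truth at every level.

* **Layout.** Triad homoeologs are placed on cognate chromosomes (group
  1–7 × subgenome A/B/D, all 600 Mbp) in non-overlapping slots; non-triad
  genes are spread round-robin. Gene lengths are uniform on 1–5 kb.
* **Categories.** Each triad draws a starting category per genotype from a
  mixture (defaults: balanced 0.878; suppressed 0.030/0.045/0.020 for
  A/B/D — B-suppression most common, D least; dominants 0.009 each —
  matching the field observation that suppression outnumbers dominance
  several-fold), then evolves by a keep/redraw Markov rule: keep with
  probability `stability` (default 0.73), otherwise redraw from the
  mixture. The expected all-stages-unchanged fraction is analytic,
  $\sum_c \pi_c (s + (1-s)\pi_c)^{K-1}$, and the generator is tested
  against it. Note the redraw-from-marginal rule lower-bounds the
  attainable churn when one category dominates the mixture: with 88%
  balanced triads the unchanged fraction cannot fall below ~0.68 however
  small `stability` is. Real time courses report lower unchanged fractions
  than this bound, i.e. their transitions are less "sticky" than a marginal
  redraw; the generator's stability estimand is self-consistent but is not
  a fit to any particular dataset.
* **Shares.** Given a category, subgenome shares are Dirichlet with
  concentration 200 around archetypes chosen strictly inside the rule
  regions — dominant $(0.8, 0.1, 0.1)$, suppressed $(0.05, 0.475, 0.475)$,
  balanced $(1/3, 1/3, 1/3)$ — so planted categories are recoverable: the
  thresholds define regions, not generative centres.
* **Expression and noise.** Triad totals are log-normal (meanlog 4, sdlog
  1, TPM-scale) and shared between genotypes, so between-genotype fold
  changes come only from category differences and planted effects. Counts
  are negative binomial with common dispersion 0.05 around
  expression × length(kb) × depth; depth 5 puts typical per-gene counts in
  the low hundreds, as in a bulk library spread over tens of thousands of
  genes. Dispersion 0 switches to the deterministic rounded-mean limit.
  TPM is recomputed from counts and lengths and column-normalized to 1e6.
* **Planted effects.** A hotspot block multiplies expression by
  $2^{\pm\text{effect}}$ in the first genotype at all stages. By default
  only non-triad genes in the block are shifted (`hotspot_scope =
  "nontriad"`), because shifting a single homoeolog would silently change
  the realized bias category of its triad and break the planted truth; the
  `"all"` scope implements the dense structural-variant-like block and is
  what the hotspot-recovery study uses. Biomarker genes (default two,
  alternating sign, effect 4 log2 units) and a fraction of planted DE
  genes get analogous between-genotype shifts. DEG tables report the true
  log2 fold change of expected expression, with `padj` assigned below 0.01
  exactly for genes at $|\log_2 FC| \ge 1$ — differential-expression
  testing itself is out of scope, and downstream stages consume only
  (gene, log2fc, padj, contrast).

What the generator does **not** emulate: batch and replicate-level library
effects, gene-length or GC bias in counting, correlated dispersion,
stage-dependent expression trends within a genotype, unbalanced designs, or
real wheat triad structure (paralog families, homoeolog-specific mapping
error). Passing recovery tests therefore demonstrates the pipeline's
correctness on its stated model, not robustness to those artefacts.

## Problem sizes and runtimes

The package's own studies are sized for interactive use: the demo runs 300
triads + 900 background genes with 2,000 permutations; the reproduction
study 3,000 triads; the category/stability recovery study 5,000 triads; the
hotspot study 500 triads + 5,500 background genes (placing ~100 genes in a
180 Mbp block on chromosome 1B) with 10,000 permutations; the null
calibration 200 chromosomes of 150 genes at 1,000 permutations each. All
complete in seconds to tens of seconds on one core.

## Known limitations

* The classification is threshold-based as specified; the
  centroid-distance assignment variant used elsewhere in the literature is
  intentionally not implemented.
* Permutation q-values are bounded below by the permutation count (see
  above); genome-wide scans needing $q < 10^{-5}$ must use t mode.
* The per-category stability estimand follows the all-stages-unchanged
  definition; per-transition persistence is computed but secondary.
* `evaluate_nsc()` sensitivity/specificity are defined against a single
  reference class and are most meaningful for two-class problems.
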