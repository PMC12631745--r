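---
title: "Methods: phenotype-based drug-sensitivity signature discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phenotype-based drug-sensitivity signature discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sensig` builds a transcriptomic predictor of drug sensitivity in three
movements: derive a phenotype from drug-response data, rank genes along
two complementary axes (effect size and predictive attribution), and
distill a compact logistic signature whose score can be carried to
external cohorts. This vignette explains the model underlying each
stage, the parameters that matter, the synthetic study conditions used
to test the pipeline, and the design choices made where the procedure
was genuinely open.

## Phenotype from two response sources

The unit of analysis is a cell line with two independent IC50
measurements (call them sources A and B, e.g. a pooled-barcode screen
and a viability-assay screen) and RNA-seq. Only complete cases enter the
analysis; the merge is deterministic (lexicographic id order) so reruns
are reproducible regardless of input file order.

Labels come from unsupervised structure in the 2-D IC50 profile.
Agglomerative clustering with Ward linkage on Euclidean distances
(`ward.D2`) is the primary method; the number of clusters is chosen by
the mean silhouette score
\[ s_i = \frac{b_i - a_i}{\max(a_i, b_i)}, \]
with $a_i$ the mean within-cluster distance and $b_i$ the smallest mean
distance to another cluster (singletons contribute 0). k-means (10
seeded restarts) is evaluated as a comparator over the same $k$ range;
hierarchical clustering wins ties because its dendrogram is
interpretable and a fixed cut height (default 8, retained via
`cut_distance`) can reproduce the clustering on new data. Clustering is
done on raw micromolar values by default — the measurement scale on
which the profiles are plotted and on which the clinically meaningful
separation (tens of micromolar) lives — with `log_transform = TRUE`
available when one source spans orders of magnitude.

The consistency rule then converts clusters to labels: per cluster,
compute the mean IC50 *rank* within each source; the cluster ranked
highest in both sources is resistant, lowest in both is sensitive, all
others are excluded. Ranks make the rule scale-free, so it is unaffected
by the two sources' different units or dynamic ranges. If no cluster is
consistently extreme the function refuses with the per-cluster rank
table rather than guessing. A one-way ANOVA with Tukey HSD confirms that
clusters differ in each source separately; the degenerate all-equal,
zero-variance case returns $p = 1$ rather than dividing by zero.

## Two ranking axes

**Effect size.** Differential expression between the resistant and
sensitive groups uses a deliberately transparent negative-binomial Wald
test: median-of-ratios size factors $f_j$ (normalized to geometric mean
one), pooled within-group method-of-moments dispersion
$\hat\alpha = \max\{(s^2 - \bar\mu)/\bar\mu^2,\ 10^{-8}\}$ on normalized
counts, a log2 fold change from the ratio of normalized group means with
a 0.5 pseudo-count when a mean is zero, a delta-method standard error
from the NB variance $\mu + \alpha\mu^2$, and a two-sided normal p.
There is no shrinkage, outlier refitting or independent filtering; the
gates are BH-adjusted $p < 0.05$ and $|\log_2 FC| > 1$, both strict. The
test is a pipeline component, not a contribution: when a full
shrinkage-based estimator is preferred, its up/down sets can be slotted
into `sign_intersection()` unchanged. All-zero genes are defined (not
errors): $\log_2 FC = 0$, $p = 1$. Type-I error of the Wald path is
checked by simulation in the test suite (a 2,000-gene null cohort,
50 lines per class, raw $p < 0.05$ at $0.05 \pm 0.02$).

**Attribution.** A gradient-boosted tree ensemble (binary logistic
objective, AUC metric) is trained on $\log_{10}(\mathrm{TPM}+1)$
features and explained with exact per-tree SHAP attributions, whose sum
over features equals the model margin for every sample (the additivity
property asserted to $10^{-6}$ in the tests). To keep the ranking
honest, attributions are aggregated inside cross-validation:
12 repeats of stratified 5-fold CV, attribution computed only for
held-out-fold samples, summarised as mean |SHAP| per gene per repeat and
averaged over repeats. Repeats are seeded `base_seed + r` from
`base_seed = 42`; samples are sorted by id before fold assignment, so
the summary is invariant to column order.

Booster settings: depth 8, learning rate 0.1, L1 = L2 = 0.1, round cap
150 with 50-round patience against a 20% stratified early-stopping
slice, single-threaded histogram trees, and per-tree feature subsampling
`colsample_bytree = 0.3` (seeded, hence deterministic). The subsampling
is the package's overfitting control of choice and serves a second
purpose specific to attribution: with many informative, partially
redundant genes, greedy boosting on the full feature set repeatedly
splits on whichever gene is in-sample best and the rest receive zero
attribution; forcing each tree to work with a random 30% of genes makes
the ensemble survey the redundant signal so mean |SHAP| reflects all
informative genes rather than the argmax. "Contributing" genes are
those with mean |SHAP| strictly above `epsilon` (default 0).

## From candidate panel to signature

The candidate panel is the sign-partitioned intersection: up-regulated
DEGs that contribute attribution, and down-regulated DEGs likewise.
Recursive elimination then scores each panel size by 5-fold
cross-validated **specificity** — the fraction of truly sensitive lines
predicted sensitive — because the clinically costly error is calling a
sensitive tumor resistant and withholding effective therapy. At each
step an L2-logistic model ($C = 1$, features standardized on the fitting
data) is fitted on all samples and the gene with the smallest absolute
standardized coefficient is dropped; coefficient ties break toward the
lexicographically smallest gene id for determinism. The fold partition
is drawn once per elimination run and reused across panel sizes, so the
specificity curve is comparable along the path; standardization is
refitted inside every training fold to avoid leakage. "Standardized
coefficient" is read as z-scored inputs (not post-hoc coefficient
rescaling): it is the form in which the coefficient is the model's
actual decision weight.

The optimal panel maximizes mean CV specificity, with ties broken
**toward the larger panel**. This reverses the more common parsimony
default, deliberately. With ~50 sensitive training lines, CV specificity
is granular (steps of ~1/48) and saturates at exactly 1.0 over long
stretches of the elimination path whenever the panel's aggregate signal
is strong; breaking ties toward fewer genes then collapses the panel to
the smallest subset that happens to clear the ceiling, discarding genes
that carry independent differential-expression and attribution evidence.
Since the signature is deployed as a fixed assay, retaining redundant
evidence-backed genes costs nothing and hedges estimation noise on
external data, where aggregate effects are weaker. The correlation check
(`panel_correlation()`) reports the maximum off-diagonal |r| so heavily
redundant panels are visible.

The final model is an L2-logistic fit on the optimal panel ($C = 1$,
Newton solver minimizing $\sum_i \ell_i + \lVert w\rVert^2/2C$ with
unpenalized intercept, iteration cap 1000, objective tolerance
$10^{-10}$ with step halving). The fitted object stores per-gene
centers, scales and coefficients plus the intercept, so the plain-text
descriptor is sufficient for any implementation to rescore. Scores are
$P(\text{resistant})$; the operating cutoff defaults to 0.5 and the
cutoff sweep (0.1–0.9 by 0.1) reports accuracy, recall, precision, NPV,
specificity and F1, with 0/0 ratios reported as missing rather than
silently zero.

## Validation statistics

Survival stratification of the score uses the standard toolkit, wrapped
to fix conventions: Kaplan–Meier product-limit curves with the median as
the earliest time the curve reaches 0.5; the two-group log-rank test
with hypergeometric variance; Cox proportional hazards with Breslow tie
handling and Wald 95% CIs, where covariates observed at a single level
are excluded and flagged `estimable = FALSE` rather than fabricated.
Landmark ROC at horizon $t$ defines positives as events by $t$,
negatives as lines followed event-free beyond $t$, and excludes patients
censored before $t$ — the simplest censoring-aware definition; no
inverse-probability weighting is attempted. The cross-drug panel
compares predicted classes per drug with Welch's t on natural-log IC50;
the fold change is the exponentiated difference of log means
(a geometric-mean ratio) with its CI built on the log scale using the
Welch degrees of freedom, because an arithmetic-scale CI could cover
negative concentrations. BH correction across drugs is available and
shares the single BH implementation used by the DEG stage.

## The synthetic study conditions

The generator's defaults are the package's fixed study conditions,
chosen once to mirror a mid-sized two-source screen:

| parameter | default | rationale |
|---|---|---|
| class sizes | 60 / 55 / 35 | sensitive / resistant / discordant lines, the scale of a two-source pan-cancer overlap |
| genes | 2,000 | desk-scale transcriptome surrogate |
| planted signature | 15 up + 15 down, $\log_2 FC = 2$ | sign-split effects clearing the DEG gate with margin |
| NB dispersion | 0.8 | biological CV ≈ 0.9, typical of expression variance across heterogeneous cancer cell lines; see below |
| library-size log-SD | 0.2 | moderate depth variation |
| IC50 class means | ln 8 / ln 60 μM | a clinically meaningful boundary in the tens of μM |
| IC50 log-SD / source noise | 0.18 / 0.12 | clearly separated clusters with correlated sources |
| discordant shrink | 0.25 ln-units | inconsistent clusters sit slightly inward of the concordant extremes |

Two structural choices deserve explanation. First, the discordant pool
is split between *both* off-diagonal patterns (sensitive-like in A /
resistant-like in B and the reverse), so the 2-D profile has four modes
and silhouette selection faces the same four-cluster geometry the
consistency rule is designed for; a single discordant direction would
produce only three modes. Their per-source class means sit 0.25 ln-units
inward of the concordant extremes: with identical extreme means, the
concordant-resistant and discordant clusters would have statistically
indistinguishable mean ranks within one source and the consistency rule
would (correctly) refuse on most cohorts — the intermediate position is
also the more faithful geometry for lines whose two assays disagree.

Second, the dispersion default places the generator in the
weak-per-gene, strong-in-aggregate regime: at $\alpha = 0.8$ a single
planted gene separates the classes at ~1.5 SD on the log-TPM scale —
individually informative but far from sufficient — while the 30-gene
aggregate separates them essentially perfectly. This is the regime the
discovery procedure is built for (a phenotype classifier that is fair
but not perfect on held-out lines, improved by pooling a panel), and it
is what makes the attribution stage meaningful: with near-zero
within-class variance any one planted gene would saturate the
classifier and absorb all attribution.

Exponential survival (group hazard $\lambda$ and $\lambda\cdot HR$,
independent exponential censoring tuned to the requested censored
fraction) and the log-normal drug panel (per-drug class shift of
$\log_2 FC$) complete the validation inputs. Every generator is a pure
function of (config, seed): the caller's RNG state is saved and
restored, and identical inputs give bit-identical outputs.

What the synthetic conditions do *not* emulate: gene–gene correlation
and pathway structure, dispersion–mean trends, batch effects, realistic
missingness mechanisms (missingness is uniform at random), non-
exponential hazards, and any connection between expression and the
drug-panel effects beyond the class labels. Passing tests therefore
demonstrate that the machinery recovers planted structure under the
stated statistical model — not that the pipeline's discoveries on real
screens are correct, which depends on database versions and biology
outside the package's control.

## Numerical choices and degenerate inputs

- Newton ridge-logistic: gradient max-norm tolerance $10^{-10}$,
  backtracking line search, iteration cap 1000 (reported, not silent);
  zero-variance features get coefficient 0 with a warning.
- Silhouette: singleton clusters contribute 0; all-identical points are
  rejected (zero distances).
- ROC/PR AUC: trapezoidal over distinct thresholds; tied scores yield
  diagonal segments, so constant scores give AUC 0.5.
- BH: `p.adjust` step-up, checked against a hand-rolled oracle.
- Confusion ratios with zero denominators are `NA`, never 0.
- All-zero genes, all-censored survival tables, single-class test sets,
  single-level Cox covariates and under-populated drug arms are defined,
  flagged outcomes rather than errors; empty source intersections and
  inconsistent cluster orderings are hard errors with diagnostics.

## Problem sizes in the test suite

The suite exercises the full default cohort (150 lines × 2,000 genes)
for the seed-swept recovery properties — phenotype ARI, DEG
recall/type-I, SHAP enrichment over 12×5 CV, end-to-end recovery over
10 seeds — and smaller fixtures (tens of samples, tens to hundreds of
genes) for oracle equivalences and structural checks, keeping the whole
suite in the minutes range on a single core. Survival recovery uses
n = 1000 (Cox, ±0.15 on log HR at HR = 2) and 40 log-rank simulations at
n = 200/arm.

## Known limitations

- The NB Wald test is anti-conservative-free only in the moderate-
  dispersion regime it is tested in; very heavy-tailed counts
  (dispersion ≫ 1) degrade mean-ratio testing and would warrant an
  external shrinkage estimator.
- The signature's probability scores are not calibrated (no Platt or
  isotonic step); only the ranking and the cutoff-based calls are used.
- Landmark ROC discards patients censored before the horizon, which is
  biased when censoring is informative.
- The cut-height clustering path (`cut_distance = 8`) is retained for
  fidelity with fixed-cut workflows but is secondary to silhouette
  selection and is sensitive to the IC50 scale.
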