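---
title: "Methods: manifold detection and diffusion pseudo-time for vaginal microbiome dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: manifold detection and diffusion pseudo-time for vaginal microbiome dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

The vaginal microbiome occupies a handful of canonical community state
types (CSTs): four *Lactobacillus*-dominated, generally healthy states
(CST I, *L. crispatus*; II, *L. gasseri*; III, *L. iners*; V,
*L. jensenii*) and a diverse, non-*Lactobacillus* state (CST IV)
corresponding to bacterial vaginosis (BV). Transitions between these
states are continuous rather than discrete: large collections of
cross-sectional samples can be read as snapshots of a dynamical process
unfolding along low-dimensional trajectories in the high-dimensional
composition space. `bvmanifold` recovers those trajectories with the
machinery of single-cell trajectory inference — a k-nearest-neighbor graph
over samples, a random-walk (diffusion) operator on that graph, and a
pseudo-time that orders samples by their diffusion distance from a
clinically defined BV "root" region — and then runs the downstream analyses
a microbiome study needs: CST arm partitioning, indicator ROC analysis
with a permutation null, sliding-window taxa profiles, and per-subject
longitudinal dynamics.

## The model, step by step

**Filtering.** Count tables are filtered to samples with strictly more
than 1000 reads and taxa with strictly more than 100 reads, transformed to
relative abundances, then stripped of rare taxa whose prevalence is not
above $10^{-4}$ or whose mean relative abundance is not above
$5\times10^{-5}$ (both conditions required; an OR variant is a flag).
Boundary cases are resolved strictly — a sample with exactly 1000 reads is
dropped. Filtering runs in this order: depth, taxon reads, relative
transform, rarity.

**CST assignment.** Each sample is scored against reference centroids with
the Yue–Clayton similarity
$\theta = \sum a_ib_i / (\sum a_i^2 + \sum b_i^2 - \sum a_ib_i)$
and assigned the argmax label; subCSTs merge deterministically into arms
(I-A/I-B $\to$ I, III-A/III-B $\to$ III, IV-C0..4 $\to$ IV-C). Centroids can
be loaded from a published reference file or fit as renormalized per-label
means of a labeled cohort. Taxa absent from the reference are dropped with
renormalization so both vectors live on a shared simplex; this convention
is ours, as reference implementations do not document one.

**Graph.** PCA (centered, no scaling, no log-ratio transform by default —
a CLR option exists behind a flag) reduces the composition matrix to at
most 50 components. A kNN graph (k = 15, Euclidean on PC scores,
symmetrized by union) receives adaptive Gaussian weights
$w_{ij} = \exp(-d_{ij}^2/\sigma_i\sigma_j)$ with $\sigma_i$ the distance
to the k-th neighbor. Disconnected components are bridged through their
single closest cross-component pair (repeated until connected, every added
edge logged) rather than failing: the method computes one global manifold
over all CSTs. Finally the kernel is density-normalized
($w_{ij} \leftarrow w_{ij}/q_iq_j$ with $q_i$ the degree), the standard
anisotropic ($\alpha=1$) correction of diffusion maps. Without it the
diffusion operator depends on sampling density, which matters here because
daily longitudinal series contribute dense clumps of near-identical
samples alongside sparser cross-sectional ones; with it, pseudo-time
recovery on mixed cohorts improved materially while purely cross-sectional
results were unchanged.

**Roots.** The BV anchor is the set of samples with a positive Amsel's
test and Shannon diversity strictly above 3.5 (natural log). An empty root
set is an error instructing threshold review, never a silent fallback.

**Diffusion pseudo-time.** The kernel is row-normalized into a transition
matrix $T$; its top $m$ eigenpairs ($m = 15$ by default) are obtained
through the symmetric conjugate $D^{-1/2}WD^{-1/2}$. The DPT distance is

$$\mathrm{dpt}(x,y)^2 \;=\; \sum_{i\ge2}
\left(\frac{\lambda_i}{1-\lambda_i}\right)^2
\bigl(\psi_i(x)-\psi_i(y)\bigr)^2,$$

with right eigenvectors $\psi_i$ normalized to unit Euclidean norm and
signs fixed by forcing each vector's largest-magnitude entry positive, so
results are reproducible across linear-algebra backends. A sample's raw
pseudo-time is its minimum DPT distance to the root set (mean aggregation
is a config option; minimum is the natural set distance when the root is a
group rather than a single sample). The final label is
$1 - \mathrm{dpt}/\max(\mathrm{dpt})$: roots sit at 1 (BV), the farthest
sample at 0 (healthiest), normalized globally rather than per component.
The test suite pins this implementation against an independent dense
oracle that eigendecomposes $T$ directly and applies the formula from
scratch; the two agree to $10^{-8}$.

**Layout.** Two-dimensional coordinates (spectral by default — the second
and third transition-operator eigenvectors — or an external UMAP embedding
passed through) exist for visualization only. Pseudo-time never reads
them, and the tests assert that perturbing the layout leaves pseudo-time
untouched.

**Projection.** Held-out samples map to their single Bray-Curtis nearest
neighbor on the full relative-abundance vectors (not PC scores) and
inherit its pseudo-time, arm and layout. Ties break by reference order and
are reported; a k > 1 averaged variant exists behind a flag.

**Evaluation.** Indicators binarize as: Nugent > 7 (strict, with a
conventional $\ge 7$ flag), pH > 5.5, stored booleans otherwise; missing
values are excluded, never imputed. ROC curves sweep thresholds over
observed pseudo-time values; the AUC uses the Mann–Whitney rank form with
ties counted one half, and the swept curve's trapezoid area is checked
against it internally. The permutation null shuffles labels 100 times;
the empirical p-value carries the +1 correction so it is never zero. Root
samples are excluded from ROC analyses (they define the anchor) but kept
in window profiles. Per-arm statistics use Spearman correlations for
continuous variables and two-sided Wilcoxon rank-sum tests for binary
ones, BH-corrected across the whole table, with small arms reported as
excluded rather than tested. Amine contrasts split at pseudo-time > 0.9.
Sliding windows are 0.2 wide with 0.01 steps — starts 0.00 through 0.80,
81 windows — half-open on the right except the last, which closes so a
sample at exactly 1 belongs somewhere.

**Longitudinal dynamics.** Per-subject trajectories order samples by study
day (pseudo-time computation itself never sees subject identity or time).
Deltas are sample-to-sample differences, not per-day rates (a rate variant
is a flag): the menses test compares deltas whose sample day falls within
[menses start − 2, menses end] against all others with a one-sided
Wilcoxon rank-sum test (window membership uses the sample's own day).
Medication episodes are maximal runs of flagged days, analyzed over
[first − 1, last + 1]; "consistent decrease" is net change < 0 (the
stricter every-step-decreasing call is also reported), and windows with
fewer than two samples are unevaluable rather than silently dropped.

## The synthetic cohort generator

Because the study's clinical cohorts require controlled-access downloads,
the package ships a generator that emulates their structure with a known
latent progression parameter $b \in [0,1]$ per sample (0 healthiest, 1
BV):

* **Compositions.** Each sample draws a healthy source arm (priors
  0.45/0.15/0.30/0.10 for I/II/III/V, approximating Lactobacillus-CST
  prevalence in reproductive-age cohorts) and a subCST (A/B split for I
  and III). Its expected profile is $(1-b)\cdot\text{arm centroid} +
  b\cdot\text{BV profile}$, realized as a Dirichlet draw with total
  concentration 300. The BV endpoint is drawn once per cohort: a
  near-uniform mixture over the anaerobe taxa with a six-fold elevated
  *G. vaginalis*-like weight, shared across arms so all routes converge on
  one root region.
* **Taxon panel.** 100 taxa by default: the four *Lactobacillus* species,
  a *G. vaginalis* analogue, and the remainder split 65/35 between further
  anaerobes and low-abundance commensals. The anaerobe block is sized so
  the BV endpoint's Shannon entropy clears the 3.5 root threshold with
  margin ($\ln 66 \approx 4.2$ before concentration loss), which a
  smaller panel would not.
* **Latent distribution.** Cross-sectional $b \sim \mathrm{Beta}(1.2,
  1.8)$, a healthy-skewed cohort in line with the observed predominance of
  *Lactobacillus* samples.
* **Metadata.** Nugent is $\mathrm{round}(10b)$ plus $\pm 1$ integer noise
  clipped to [0, 10]; pH is $4.0 + 2.5b$ plus Gaussian noise (sd 0.3);
  each Amsel criterion is Bernoulli with a logistic link on $b$ (slopes
  8–10, midpoints 0.65–0.80) and the test is positive iff at least three
  criteria are; amines are log-normal with a +1.5 natural-log location
  shift for cadaverine, putrescine and tyramine when $b > 0.9$ and no
  shift for spermine and spermidine, mirroring which amines track BV.
* **Trajectories.** Longitudinal subjects (default 20 × 70 daily samples,
  the daily-cohort shape) follow archetypes weighted 0.5/0.3/0.2: stable
  (mean-reverting noise at low $b$), cyclic (a +0.35 bump spanning two
  days before each menses interval through its end; menses every 28 days
  for 5 days), and erratic (a jump process across arms). Medication
  episodes (5 days, started at a small per-day rate) force $b$ to decay
  geometrically — strictly decreasing across the episode.
* **Determinism.** One pseudo-random stream per logical component
  (latents/trajectories, compositions, metadata), each sub-seeded from the
  master seed; a fixed seed fixes every emitted table byte-for-byte.

What the generator does *not* emulate: sequencing error and read-level
noise, strain structure within *G. vaginalis*, covariation between
subjects, and realistic day-to-day fluctuation magnitudes in healthy
states (no published estimate exists; noise scales were chosen once for
testability). Passing tests therefore demonstrate that the pipeline
recovers a planted low-dimensional progression under realistic
compositional noise — not that it resolves every ambiguity of clinical
data.

## Numerical choices and degenerate inputs

* Identical samples get kernel weight 1 (the $0/0$ kernel limit), and the
  adaptive width product is floored at the smallest normal double to avoid
  division by zero.
* Bridging edges receive their kernel weight floored at $10^{-6}$ so an
  extremely remote component cannot re-disconnect the operator
  numerically; $\lambda_2 \ge 1 - 10^{-12}$ after bridging is an error.
* Assignment and projection ties break deterministically by label or
  reference order, with a message.
* Constant pseudo-time within an arm yields NA correlations, reported as
  such; arms below the size threshold are excluded, mirroring how small
  arms are handled in practice.
* Projection renormalizes only queries that actually lost mass during
  taxon alignment, so a query identical to a reference sample keeps an
  exactly zero Bray-Curtis distance.
* The noiseless generator limit (concentration $\to \infty$) reproduces
  arm centroids exactly, which the tests exercise at concentration $10^8$.

## Problem sizes

Tests and the acceptance script run the full pipeline at the package's
default study conditions: 1200 cross-sectional samples over 100 taxa,
20 × 70 longitudinal cohorts for the menses and medication analyses, and a
demo fixture of ~400 cross-sectional plus 10 × 40 longitudinal samples.
These sizes keep every eigendecomposition dense and exact (the operator
never exceeds ~1500 × 1500) while preserving the structural features the
method must handle: four arms of unequal density, a shared diverse root
region, and clumped daily sampling.

## Known limitations

* DPT's scale across arms depends on arm sampling density and tip
  connectivity; with max-normalization a single nearly-disconnected clump
  (e.g. a very stable subject sampled daily) can stretch the global scale
  and compress gradients elsewhere. Density normalization mitigates but
  does not eliminate this; at small cohort sizes the pooled recovery of
  the latent progression is noticeably split-sensitive even when
  within-arm ordering stays excellent.
* Pseudo-time is composition-driven: correlations with composition-derived
  quantities (Shannon diversity, Nugent score) are partly built in, and
  the package makes no causal claims about BV development.
* The root definition inherits the ambiguity of clinical BV diagnosis; the
  Shannon threshold is configurable and results should be checked for
  robustness to it.
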