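---
title: "regpot: methods and design notes"
author: "regpot authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{regpot: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the statistical machinery it
implements: the models and their assumptions, the tunable parameters and
why their defaults are what they are, the numerical choices that are easy
to miss when reading the code, and what the synthetic fixtures do and do
not establish about behaviour on real data.

## 1. The context-dependent model

The unit of analysis is a (variant, cell type) pair. For each of 12
chromatin marks — DNase I hypersensitivity and 11 histone modifications —
three features summarize the variant's position relative to that mark's
narrow peak calls in that cell type:

* **Hit** — 1 if the variant lies inside a peak, 0 otherwise. A variant at
  1-based position $p$ overlaps a BED-style half-open interval
  $[\mathrm{start}, \mathrm{end})$ iff
  $\mathrm{start} < p \le \mathrm{end}$. This conversion lives in exactly
  one function (`pos_overlaps_interval()`); every overlap in the package,
  including the GRanges-based bulk path, reduces to it, and it is
  property-tested against a per-base brute-force scan.
* **Intensity** — the signalValue of the overlapping peak, 0 without an
  overlap. When several peaks overlap (possible when a track is read with
  `merge = FALSE`), the maximum signal is taken: the strongest local
  evidence, and deterministic. Intensity is used in its native
  signalValue units; peak calls from a uniformly processed consolidated
  epigenome are comparable across tracks by construction, so the extractor
  does not renormalize (an optional `log1p` transform exists, off by
  default).
* **Centrality** — the distance in bp from the variant to the overlapping
  peak's summit (nearest summit if several). Without an overlap it is set
  to a fixed sentinel of 10,000 bp rather than a missing value, so the
  logistic design matrix stays numeric; the constant is configurable and
  far exceeds any within-peak distance. narrowPeak summits of $-1$
  (unknown) are replaced by the interval midpoint.

Overlapping intervals within one track are merged by default when a file
is read; whether peak callers ever emit such overlaps varies, and merging
makes the non-overlap invariant of a track explicit. The reader exposes
`merge` as an option.

With the full panel this yields 36 features per variant per cell type,
in a fixed column order (marks alphabetical, then Hit/Intensity/
Centrality) so that design matrices are reproducible across runs and
platforms. Marks without a supplied track are omitted from the layout by
default (an 11-mark run has 33 columns); when a layout including them is
requested explicitly they appear as flagged missing triples, or as
non-overlap encodings under `zero_fill = TRUE`.

The **regulatory potential** is a logistic regression of case (fine-mapped
eQTL) versus matched control status on these features,
$P(\mathrm{causal}\mid X) = 1/(1+e^{-(\alpha+\beta X)})$, fitted by
maximum likelihood through `stats::glm`. Features enter unstandardized —
Hit is binary and the other features are interpretable in their own units
— with an optional z-scaling flag. Two numerical safeguards:

* Exactly collinear columns are detected by a QR factorization and dropped
  with a message (all-NA and constant columns likewise), so rank-deficient
  designs never reach the optimizer.
* Perfect or quasi-separation — detected either from the optimizer's
  warnings or from exploding Wald standard errors — triggers a refit by
  ridge-penalized IRLS with $\lambda = 10^{-6}$ (intercept unpenalized,
  penalty applied on an internally standardized scale so it is
  scale-free). The model is flagged, the estimates are finite, and small
  fixtures never abort a pipeline.

**Feature selection** is pure backward stepwise AIC, with
$\mathrm{AIC} = 2k - 2\ln L$ and $k$ counting the intercept: at each step
the removal that most decreases AIC is applied, stopping when no removal
decreases it. Removed features are not allowed to re-enter; backward-only
is the simplest procedure consistent with starting from the full model,
and it is cross-checked against `stats::step` in the tests. Ties between
candidate removals are broken by alphabetical feature name so the selected
set is deterministic. A candidate refit that fails is skipped with a
warning. One consequence worth stating plainly: a pure-noise feature
survives backward AIC selection whenever its final likelihood-ratio
statistic exceeds 2, which under the null happens with probability
$P(\chi^2_1 \ge 2) \approx 0.157$ — AIC selection keeps roughly one in six
null features by design, and the tests around the selector are written
with that property in mind.

Per-study selected features are combined by **occurrence**: a feature is
shared when selected in strictly more than half of the studies, and the
generalized model is a single logistic fit on the row-wise pooled study
matrices restricted to the shared set. Marks absent from a study's cell
type are not imputed; their columns are dropped for that study's fit.

## 2. Matched controls

Two sampling schemes build control SNP panels against a candidate pool,
both seeded, both drawing without replacement across cases within one draw
(preventing degenerate duplicated controls), and both reporting — rather
than silently relaxing — cases with an empty eligible set:

* **random_tss**: the control must deviate from the case allele frequency
  by less than 0.05 and lie within 10 kb of some annotated TSS.
* **strict**: additionally, the control's distance to its nearest TSS must
  match the case's within 1,000 bp; the control must not be in high LD
  ($r^2 > 0.8$) with the case nor with any of the case's high-LD partners
  (pairs absent from the LD table count as $r^2 = 0$); and the GC content
  of the 101-bp window centred on the control must match the case's
  within 0.05. The GC tolerance is a package choice (the matching
  criterion does not fix one); 0.05 on a [0,1] scale is roughly half the
  between-locus standard deviation of window GC in the synthetic genomes
  and is configurable.

One control is drawn per case; a 1:1 design keeps the case and control
totals balanced for the logistic fit, and multiple draws can be made by
reseeding. An independent verifier (`verify_controls()`) re-derives every
constraint from the raw inputs, and the test suite runs it over sampler
output.

## 3. Score combination

External predictor scores are summarized per predictor by empirical
class-conditional histogram densities on 20 equal-width bins spanning the
pooled training range, with a Laplace pseudocount of 1 per bin — so no
occupied-range bin has zero density and likelihood ratios stay finite.
Scores outside the training range clamp to the edge bins. Twenty bins is
a deliberate middle ground at the training sizes the package targets
(hundreds of labeled variants): fine enough to capture the score
distributions' shape, coarse enough that bins do not run empty.

The composite probability multiplies per-score two-class posteriors in the
product form stated above. With more than one predictor this product is
itself a score in $(0,1)$ rather than a normalized posterior — the
per-factor normalization does not distribute over the product — and the
package implements the product form as printed and treats it exactly as a
score. The combined probability then fuses composite probability $p_S$
and regulatory potential $p_X$ under an independence assumption. The
proportionality constant in
$P(\mathrm{causal}\mid S,X) \propto p_S\, p_X / \pi$ is not identifiable
from the two inputs alone, so the package normalizes over the two
hypotheses:

$$
P = \frac{q}{q+\bar q},\qquad
q = \frac{p_S p_X}{\pi},\qquad
\bar q = \frac{(1-p_S)(1-p_X)}{1-\pi}.
$$

This is the standard naive-Bayes resolution: it yields a proper
probability, preserves ranking in each argument, has the flat-prior fixed
point $P(0.5, 0.5) = 0.5$, leaves $p_S$ unchanged when the context is
uninformative ($p_X = \pi$), and cancels symmetric evidence
($P(p, 1-p) = 0.5$). Inputs of exactly 0 or 1 are clamped to
$[10^{-12}, 1-10^{-12}]$ with a warning. The prior defaults to
$\pi = 0.5$ everywhere.

## 4. Weighted gene-based association (GATES)

For a gene with $m$ SNPs sorted by ascending GWAS P value (ties broken by
SNP id), the effective number of independent P values among the top $j$ is
$m_e(j) = j - \sum_{\lambda_i > 1} (\lambda_i - 1)$ over the eigenvalues
of the leading $j \times j$ block of the P-value correlation matrix, with
$m_e(0) = 0$. The P-value correlation is derived from genotype LD as
$\rho_p = r^2$ by default; the transform is an explicit function argument,
since finer polynomial approximations exist and users may prefer them.
A correlation matrix that fails positive semidefiniteness after clipping
is projected to the nearest PSD correlation (eigenvalue clipping plus
unit-diagonal rescale) with a warning.

Prior weights (combined probabilities) are affinely rescaled to
$[1, 10]$ — a fixed max/min ratio of ten, so even a badly wrong weight
changes a SNP's contribution by at most an order of magnitude; constant
input maps to unit weights. The per-SNP weights
$w_{(i)} = c\,(m_e(i)-m_e(i-1))\,r_{(i)}$ with $c$ chosen so that
$\sum_i w_{(i)} = m_e$, and $P_G = \min_j m_e\, p_{(j)} / \sum_{k\le j}
w_{(k)}$, capped at 1. The weights never enter $m_e$ itself. With
independent SNPs and unit weights this reduces exactly to the Simes test,
which the suite verifies against a brute-force oracle at $10^{-12}$ over
1000 random blocks.

Comparing weighted and unweighted runs, a gene is **improved** when it
crosses the significance threshold $\alpha = 10^{-5}$, or was already
significant and its P value fell below $0.8 \times$ the unweighted value
("decreased by over 0.8-fold" is read as $p_w < 0.8\, p_{unw}$ — the
natural reading for a quantity that decreases); **worsened** when it was
significant and the weighted P value is larger; otherwise unchanged.

## 5. Enrichment analyses

GWAS signal enrichment of the top fraction (default 5%) of prioritized
SNPs uses Fisher's statistic $-2\sum \ln p$ against $B$ permuted draws of
equally many SNPs, drawn uniformly from all SNPs or allele-frequency
matched (deviation < 0.05) to each top SNP. The empirical P value uses
the add-one estimator $(1 + \#\{T_{perm} \ge T_{obs}\})/(B+1)$ — at
desk-scale $B$ a raw estimator can return an exact zero, which is both
misleading and breaks downstream log transforms; ties count toward the
permutations ($\ge$, the conservative direction). An optional pruning of
SNPs with GWAS P above a floor (0.001 in genome-scale practice) applies
identically to the observed and every permuted draw. $B$ defaults to
10,000 and is configurable to $10^6$.

The genomic inflation factor is the median-based genomic-control
convention, $\lambda = \mathrm{median}(\chi^2_{obs}) /
\mathrm{qchisq}(0.5, 1)$, with the observed 1-df statistics implied by the
P values. Per-chromosome effective-marker ratios divide $M_e$ of the
sub-genome-wide subset by $M_e$ of the top set, both via the eigenvalue
construction above. Coverage curves rank all scored variants
(descending, ties by id) and report the benchmark fraction recovered at
each top fraction. Q-Q summaries are emitted as tables (expected and
observed $-\log_{10} P$ with optional permutation envelopes), not images;
plotting is a thin optional layer left to the user.

## 6. Tissue mapping

For disease SNP sets scored across cell types, the specificity matrix
holds the mean predicted potential per (disease, cell type). "Centred at
1" normalization is multiplicative — each row is divided by its mean
across cell types — because that is the only reading under which values
scatter around 1; a subtractive centring would scatter around 0. The
most relevant tissue is the row argmax (ties: lexicographically first
cell type, flagged), which the normalization leaves identical to the raw
argmax. Cell types are clustered by average-linkage hierarchical
clustering on the Euclidean distance between normalized columns — the
least committal of the common linkages given that nothing stronger is
specified — with columns pre-sorted by name so identical profiles merge
deterministically.

## 7. The synthetic fixture generator

`generate_fixture()` builds a coupled bundle with known ground truth: a
single-chromosome genome with GC drifting per kb (uniform in [0.3, 0.7]),
SNPs at a regular spacing (default 1 kb) with uniform allele frequencies
in [0.05, 0.95], TSSs at every $n/n_{genes}$-th SNP so every SNP is
TSS-proximal, block LD with $r = \rho^{d}$ at rank distance $d$
($\rho = 0.9$, blocks of 10, independence across blocks — PSD by
construction), per-mark/per-cell-type peaks, a 3-predictor score panel
with causal scores shifted by 1 SD, and gene-structured GWAS P values.
Causal SNPs (fraction 0.1) overlap the informative marks (DHS, H3K4me1,
H3K4me3, H3K27ac — active-chromatin marks) of the first, "matched" cell
type with an odds multiplier of 5 over the 0.2 baseline hit rate; other
marks and cell types stay at baseline. The planted causal SNP of each
causal gene carries the gene's strictly smallest GWAS P value (drawn from
a non-central 1-df chi-square, ncp = 25), so the gene-test power property
is testable. Everything is a pure function of the seed; the bundle is
byte-identical across runs.

These defaults are the study conditions under which the test suite runs:
case/control discrimination is decidedly easier than on real epigenomes
(no confounding between marks, no population structure, uniform allele
frequencies, literal conditional-independence of scores given the label).
Passing tests therefore establish the correctness and calibration of the
*procedures* — overlap arithmetic, estimator recovery, test validity,
determinism — not the attainable accuracy on real consortium data, which
depends on data properties the generator deliberately does not emulate
(realistic allele-frequency spectra, chromosome-scale genomes,
imputed epigenomes, inter-mark correlation).

## 8. Problem sizes and runtime choices

The test suite and acceptance checks run at desk scale by choice:
logistic recovery and stepwise behaviour at $n = 5000$; permutation
calibration over 200 replicates at $B = 999$; the inflation factor on
$10^5$ uniform P values; Simes-oracle agreement over 1000 random blocks;
control-matching bounds on panels of 1000–21,000 SNPs. These sizes are
large enough for the asymptotics each check relies on and small enough to
re-run routinely.

## 9. Known limitations

* The composite product over several predictors assumes conditional
  independence of scores given causal status; correlated predictors will
  make it overconfident, as in any naive-Bayes combination.
* $\rho_p = r^2$ is a first-order approximation to the correlation of
  association P values; the hook accepts finer transforms.
* The ridge fallback under separation gives finite but penalized
  estimates; their Wald P values are approximations.
* Gene-SNP assignment is taken as given (explicit map); no windowing
  heuristics are built in.
* The tissue-mapping and clustering outputs are descriptive; no inference
  is attached to the normalized means.
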