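---
title: "Moment-based sequence encodings and ensemble classification of 6mA sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Moment-based sequence encodings and ensemble classification of 6mA sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sixmA)
```

## The problem and the data model

N6-methyladenosine (6mA) is a common internal RNA modification whose
dysregulation is implicated in a range of diseases. Experimental mapping of
6mA sites is laborious, so sequence-based classifiers are used to triage
candidate adenosines. sixmA frames the task as binary classification of a
fixed-length window

$$ R_{-20} R_{-19} \ldots R_{-1}\, A\, R_{+1} \ldots R_{+20}, $$

a 41-nt RNA fragment (length $2L+1$ with $L = 20$) whose central position 21
is the candidate adenosine; label 1 marks a true 6mA site. Input may be RNA
or DNA alphabet (T is coerced to U), and records violating the window
invariants (length, central A, unambiguous bases) are skipped with a logged
reason rather than aborting a whole file: public supplementary datasets are
frequently messy, and a loader that dies on the first malformed record is
useless for them.

Duplicate handling is deliberately minimal: exact (sequence, label)
duplicates are removed, and the same sequence appearing under both labels is
kept but flagged. Sequence-identity clustering (CD-HIT style) is out of
scope — it requires an external tool and an arbitrary identity threshold,
and the package's statistical claims do not depend on it.

## The feature vector

Each window is mapped to a 522-dimensional descriptor composed of six
blocks. Throughout, k-mers (k = 1, 2, 3) are overlapping and ordered
lexicographically over (A, C, G, U); positions are 1-based.

| block | size | content |
|---|---|---|
| PRIM moments | 90 | 30 moments of each of the mono/di/tri PRIM matrices |
| RPRIM moments | 90 | the same on the reversed sequence |
| frequency vector | 84 | overlapping k-mer counts (4 + 16 + 64) |
| AAPIV | 84 | per-k-mer sums of occurrence start positions |
| RAAPIV | 84 | AAPIV of the reversed sequence |
| 2D-matrix moments | 90 | 30 moments of each integer-encoded sequence matrix |

**Frequency vector.** Composition only: the counts of all mono-, di- and
tri-nucleotides. For a 41-nt window the blocks sum to 41, 40 and 39 — a
conservation law the tests exploit.

**AAPIV / RAAPIV.** Position-weighted composition: for each k-mer, the sum
of the 1-based start positions of its occurrences. The mono block always
sums to $41 \cdot 42 / 2 = 861$. The reverse variant re-anchors positions at
the 3' end, exposing asymmetries the forward scan cannot.

**PRIM / RPRIM.** The position-relative incidence matrix is a
$4^k \times 4^k$ summary of where each k-mer sits relative to every other.
The literature describing these matrices presents their layout but not the
entry computation, so the package fixes a convention and documents it:

$$ W_{i \to j} = \sum_{q \,\in\, \mathrm{occ}(j)} (q - f_i), $$

where $f_i$ is the position of the first occurrence of k-mer $i$, the sum
runs over all occurrences of k-mer $j$, occurrences preceding $f_i$
contribute negatively, and the entry is 0 when either k-mer is absent. This
choice is deterministic, testable by brute force, and position-relative in
the intended sense; it is a convention, and the brute-force oracle in the
test suite is the normative statement of it.

**2D sequence matrices.** The overlapping k-mer stream (length 41, 40, 39)
is integer-encoded as 1..$4^k$ and written row-major into a 7 × 7 matrix,
zero-padded at the tail — a positional image of the window that the moment
transforms below can summarize.

## Statistical moments

Matrices are reduced to moments of order $j + k \le 3$, ten index pairs per
family, three families per matrix:

- **raw**: $E_{jk} = \sum_c \sum_d c^j d^k \beta_{cd}$ (1-based indices);
- **central**: the same sums about the mass centroid
  $(\bar x, \bar y) = (E_{10}/E_{00},\, E_{01}/E_{00})$, so first-order
  central moments vanish identically;
- **Hahn**: projections onto discrete orthogonal Hahn polynomials.

The order set (all $j + k \le 3$) is the only reading consistent with the
522 total: 30 moments per matrix × 3 matrices = 90 per matrix family.

Because PRIM entries are signed, a matrix can have zero total mass, making
the centroid undefined. Feature assembly substitutes zeros for the central
block of such a degenerate matrix (with a warning when the moment function
is called directly) instead of failing: a rare pathological window should
not abort the encoding of a dataset.

### Hahn polynomial convention

The Hahn family used here is the classical discrete orthogonal family
$Q_n(r;\, u, v, N{-}1)$ (terminating $_3F_2$ sum with rising-factorial
Pochhammer symbols), scaled by the prefactor $(N{+}v{-}1)_n (N{-}1)_n$
conventional in the moment-feature literature, and evaluated on the support
$r = 0, \ldots, N-1$. Several mutually inconsistent renderings of the "Hahn
polynomial" circulate in the sequence-feature literature; most are not
orthogonal families at all (easily checked by computing a Gram matrix), so
they forfeit exactly the property — invertibility of the moment transform —
that motivates Hahn moments. The convention here agrees with the common
rendering at orders 0 and 1 and restores orthogonality at all orders:
under the weight
$\rho(r) = \binom{u+r}{r}\binom{v+N-1-r}{N-1-r}$ (uniform at $u = v = 0$)
the family is orthogonal, which the test suite verifies along with exact
reconstruction of a matrix from its full-order moments.

Shape parameters default to $u = v = 0$; no published value exists for this
application, the uniform-weight member is the symmetric default, and both
parameters are exposed for sensitivity analysis. Polynomials are
orthonormalized (weight-absorbed, unit norm) before use so that moments of
the 64 × 64 tri-nucleotide matrices stay well-scaled; the raw prefactor
grows like $N^{2n}$ and would otherwise dominate the feature scale.

Features are emitted unscaled: the encoder is a pure function of the
sequence, and any standardization belongs to the model pipeline where it can
be fit on training folds only.

## Ensemble models

Three ensemble families are provided, mirroring standard practice:

- **stacking**: four base learners — KNN ($k = 5$), a decision tree, a
  single-hidden-layer neural network, an RBF SVM — whose out-of-fold
  predictions (internal stratified 5-fold) train a gradient-boost
  meta-learner. Out-of-fold generation is the standard leakage guard: the
  meta-learner never sees a base prediction produced by a model that was
  trained on that row.
- **bagging**: a bootstrap bag of deep decision trees, random forest,
  extremely randomized trees, and a single decision tree as reference.
- **boosting**: gradient boosting (exact splits, depth 3, learning rate 0.1,
  200 rounds) and histogram-binned gradient boosting (depth 6, 256 bins).
  Gradient boosting is the headline variant: it is the configuration the
  approach is typically reported with.

Feature standardization (zero mean, unit variance, fit on the training data
only) is applied for the stacking family, whose base learners are
distance/margin/gradient-descent based; tree ensembles are scale-invariant
and receive raw features. All fitting is deterministic given the config
seed, single-threaded, with no subsampling in the boosting variants.

Hyperparameter tuning is off by default and, when enabled, searches small
fixed grids (KNN neighbours {3, 5, 7, 9}; SVM cost {0.1, 1, 10}; tree depth
{3, 5, 10, 30}; boosting learning rate {0.05, 0.1, 0.2} × {100, 300}
rounds) by internal stratified 5-fold cross-validation. No published grids
exist for this setting; small documented grids keep runs reproducible and
cheap, which we value over speculative fidelity.

## Evaluation protocols

Two protocols are provided: an independent stratified train/test split
(default 70/30) and stratified k-fold cross-validation (default k = 10).
Metrics are Sn, Sp, ACC, MCC, F1 from the confusion table and AUROC from
continuous scores (rank/Mann–Whitney form, ties counted one half). For
k-fold, the headline numbers are computed from pooled (micro-averaged)
counts — every sample is scored exactly once — with per-fold metrics
retained for dispersion; pooling is the aggregation that keeps the
confusion-count invariant $TP+TN+FP+FN = n$ interpretable. A metric with a
zero denominator is reported as an explicit NA with a reason, never silently
coerced to 0, because silent zeros corrupt cross-model comparisons.

## The synthetic generator and what passing tests mean

`generate_synthetic()` emulates a balanced benchmark of labeled windows:
positives drawn from a per-position nucleotide probability profile,
negatives from the uniform background, central A forced in both classes.
`planted_profile(strength)` raises the probability of a consensus base (G)
at twelve flanking positions (15–20 and 22–27) from 0.25 to
$0.25 + 0.75 \cdot \mathrm{strength}$: strength 0 is the exact null
(classes identically distributed), strength 1 plants a deterministic
consensus and makes the classes separable. The default sizes used in the
package's end-to-end checks are 1000 windows per class — comparable to the
per-class sizes of real 6mA benchmarks (roughly 900–1800 per class) while
keeping a full encode–train–test cycle around a minute on one CPU; the
no-signal cross-validation check uses 100 per class, and the
signal-strength sweep uses 100 per class over strengths
{0, 0.25, 0.5, 0.75, 1} across 5 seeds.

The generator emulates positional composition bias only. Real 6mA data
additionally carry motif context (e.g. GAC/AGG enrichment around true
sites), species-specific background composition, and sequence homology
between records; none of these are modeled. Passing the behavioral tests
therefore demonstrates that the pipeline extracts planted positional signal
and is honest under the null — it does not certify the headline accuracies
achievable on any real benchmark, which depend on dataset composition and
curation.

## Numerical choices and limitations

- Moment indices are 1-based in raw/central sums and 0-based on the Hahn
  support; both conventions are fixed and documented.
- Rectangular matrices are zero-padded (bottom/right) to square before Hahn
  moments; all matrices produced by the encoder are already square.
- Class calls use a fixed 0.5 score threshold; AUROC is threshold-free.
- Ties in KNN voting and SVM probability calibration are resolved under the
  config seed; reruns with the same seed are bit-identical.
- The PRIM entry convention (signed offsets relative to the first
  occurrence) is one of several defensible readings; switching conventions
  changes feature values but not the pipeline contract.
- The 522-feature encoder is $O(4^3)$ per window in its largest block;
  encoding costs roughly 10 ms per window, so datasets of a few thousand
  windows encode in seconds.
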