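---
title: "Nearest-profile collaborative matrix factorization: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nearest-profile collaborative matrix factorization: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npcmf)
```

## The prediction problem

Experimentally confirming that a miRNA regulates a disease process is slow
and expensive, so curated association catalogues are sparse: a zero in the
miRNA × disease adjacency matrix $Y \in \{0,1\}^{n \times m}$ mostly means
*not yet tested*, not *not associated*. The task is to rank the unknown pairs
so that genuinely associated ones surface at the top. The guiding biological
assumption is that functionally similar miRNAs tend to associate with
phenotypically similar diseases, which motivates models that couple a
low-rank factorization of $Y$ to side similarity information.

## Similarity layers

**Functional / semantic similarity.** A miRNA functional similarity matrix
$S_m$ (e.g. MISIM scores) is consumed as an input. Disease semantic
similarity $S_d$ can be computed from a MeSH-style DAG of child $\to$ parent
links: for a query disease $D$, every ancestor $t$ receives a semantic
contribution
$$D1_D(t) = \begin{cases} 1 & t = D\\
\max\{\Delta \cdot D1_D(t') : t' \text{ child of } t\} & t \neq D,\end{cases}$$
with decay $\Delta = 0.5$ by default, and
$$S_d(i,j) = \frac{\sum_{t \in T(i) \cap T(j)} \big(D1_i(t) + D1_j(t)\big)}
                 {DV1(i) + DV1(j)}, \qquad DV1(i) = \sum_{t \in T(i)} D1_i(t),$$
where $T(i)$ is the ancestor closure of disease $i$. Taking the **max** over
children (rather than summing over paths) makes the contribution of a
multi-parent ancestor $\Delta^{\text{shortest path}}$; summing over paths is
a conceivable variant but would let densely connected regions of the
hierarchy dominate, so the max form is used.

**GIP kernels.** The network topology of the known associations enters
through Gaussian interaction profile kernels,
$GIP(i,j) = \exp(-\gamma\,\lVert y_i - y_j\rVert^2)$ over rows (miRNAs) or
columns (diseases) of $Y$. The bandwidth is used literally with default
$\gamma = 1$ — no per-profile normalization — the conventional simplification
for this kernel in association prediction.

**Fusion.** Both layers combine linearly,
$K_m = \alpha S_m + (1-\alpha)\,GIP_m$ (and likewise $K_d$), with
$\alpha = 0.5$ by default, giving equal weight to curated similarity and
network evidence. $\alpha$ is exposed and can be swept with
`sensitivity_sweep()`.

## WKNKN pre-imputation

Because most zeros are unobserved rather than negative, the factorization is
fitted to a pre-imputed matrix. For each miRNA $i$, the $K$ most similar
miRNAs *with at least one known association* (ranked by $K_m$, ties to the
smaller index) contribute their profiles with weights $p^{t-1} K_m(i, i_t)$,
normalized by $\sum_t K_m(i, i_t)$; the disease side is analogous. The two
per-side estimates are averaged — keeping the result a convex-like
combination inside $[0,1]$, whereas taking a max would systematically inflate
the imputation — and combined with $Y$ by an elementwise maximum, so known
1-entries are never altered. Defaults $K = 5$, $p = 0.7$ are the values at
which cross-validated AUC is empirically stable; both can be swept. WKNKN is
always applied *after* cross-validation masking, never before, so held-out
pairs cannot leak into the training matrix.

## The factorization model

The score matrix is $\hat Y = AB^\top$ with $A \in \mathbb{R}^{n\times k}$,
$B \in \mathbb{R}^{m\times k}$, fitted by minimizing
$$\lVert Y - AB^\top\rVert_F^2
 + \lambda_l\big(\lVert A\rVert_F^2 + \lVert B\rVert_F^2\big)
 + \lambda_d\lVert R_m - AA^\top\rVert_F^2
 + \lambda_t\lVert R_d - BB^\top\rVert_F^2.$$

The side targets $R_m, R_d$ define three nested model flavours:

* `mode = "semantic"` — $R_m = S_m$, $R_d = S_d$: classic collaborative
  matrix factorization with dense similarity regularizers;
* `mode = "fused"` — the fused kernels $K_m, K_d$, adding network topology;
* `mode = "nearest_profile"` (default, the full model) — sparsified kernels
  $N_m, N_d$ that keep, per entity, only its single most similar other
  entity, storing the kernel value itself. Nearest-profile prediction for a
  new entity is exactly its neighbour's profile scaled by that similarity,
  so the regularizer pulls each entity's latent Gram row towards the one
  neighbour that carries real signal instead of towards a dense average that
  can drown it.

The nearest-neighbour matrices are used asymmetric, exactly as the per-row
construction produces them; `nearest_profile(K, symmetrize = TRUE)` offers
the symmetrized $(N + N^\top)/2$ variant but it is off by default.

## Optimization

Factors are initialized from the rank-$k$ truncated SVD,
$A = U_k S_k^{1/2}$, $B = V_k S_k^{1/2}$, with a deterministic sign
convention (largest-magnitude component of each left singular vector made
positive) so fits are bit-reproducible without any seed. Updates are
alternating least squares in closed form:
$$A \leftarrow (YB + \lambda_d R_m A)\,(B^\top B + \lambda_l I_k + \lambda_d A^\top A)^{-1},$$
$$B \leftarrow (Y^\top A + \lambda_t R_d B)\,(A^\top A + \lambda_l I_k + \lambda_t B^\top B)^{-1},$$
where every Gram term is the $k \times k$ matrix $A^\top A$ (resp.
$B^\top B$), as the dimensions of the normal equations require. The $B$
update uses the freshly updated $A$ (Gauss–Seidel sequencing) — standard ALS
practice that converges faster than simultaneous Jacobi updates — while each
update's own regularizer Gram uses the pre-update factor, consistent with
the fixed-point reading of the stationarity conditions. Because the updates
are fixed-point maps rather than exact blockwise minimizers, the objective
trace is only *empirically* near-monotone: after the initial descent it may
creep upward by tiny relative amounts while settling, which the test suite
asserts as a soft property (no increase beyond 0.1% after burn-in) rather
than strict monotonicity.

Numerical details: iteration stops when the relative objective change falls
below `tol = 1e-6` or after `max_iter = 100` updates (the trace always
includes the initial objective, so it has `iterations + 1` entries); a
singular $k\times k$ system is retried once with a $10^{-10}$ diagonal
jitter and only then raises an error; an all-zero $Y$ yields all-zero
factors; argmax ties anywhere (nearest neighbours, WKNKN ranking, ranking
tables) break towards the smallest index for reproducibility.

## Hyperparameters

| parameter | default | meaning |
|---|---|---|
| `k` | `min(50, n, m)` | latent rank; dimensionless. Not dictated by the model — at the ~500×400 scale of curated catalogues 50 is a conservative ceiling, and synthetic studies here use `k = 10` (twice the planted rank) |
| `lambda_l` | 1 | Tikhonov weight; mid-point of the $\{2^{-2},...,2^{1}\}$ search grid |
| `lambda_d`, `lambda_t` | 0.01 | side-regularizer weights; the mid-ratio ($10^{-2}\lambda_l$) of the ratio grid, applied symmetrically to both sides |
| `alpha` | 0.5 | similarity/GIP fusion weight |
| `gamma` | 1 | GIP bandwidth |
| `wknkn_k`, `wknkn_p` | 5, 0.7 | WKNKN neighbours and decay |
| `delta` | 0.5 | semantic decay in the DAG recursion |

`grid_search()` evaluates $\lambda_l \in \{2^{-2},2^{-1},2^0,2^1\}$ crossed
with ratio grids $\lambda_d/\lambda_l,\ \lambda_t/\lambda_l \in
\{0,10^{-4},10^{-3},10^{-2},10^{-1}\}$ (100 combinations) by
cross-validation on identical fold assignments, with lexicographic
tie-breaking.

## Evaluation protocol

Cross-validation masks association *pairs* (CV-p): the 1-entries are
partitioned into five near-equal folds, each fold is zeroed in turn, and the
entire pipeline — GIP kernels, fusion, WKNKN, nearest profiles, fitting — is
recomputed from the masked training matrix, since GIP kernels change
whenever $Y$ does. Held-out positives are scored against all pairs that are
zero in the *full* matrix (the unknowns — the standard negative set in this
literature, as true negatives are not curated). AUC is computed per fold as
the tie-aware rank statistic (identical to the trapezoidal ROC area),
averaged per repeat, and reported as mean ± sd over repeats; pooling fold
scores before computing a single AUC is a defensible alternative, but
per-fold averaging keeps folds exchangeable units and yields the spread.
Repeats default to a single round here; large-scale studies conventionally
use 100.

## The synthetic benchmark

`simulate_mda()` generates the study conditions used throughout validation:
100 miRNAs × 80 diseases, 5 latent clusters per side with Gaussian
prototypes in 5 dimensions (noise sd 0.1), the top 10% of the latent score
matrix planted as true associations, and 10% of those hidden from the
observed matrix. Side similarities are cluster-consistent (≈0.8 within,
≈0.2 between, symmetric noise, clipped to $[0,1]$, unit diagonal), so the
"similar entities share associations" assumption holds by construction and
the regularizers have genuine signal to exploit; the disease DAG hangs each
disease under its cluster node beneath a common root. These sizes keep a
full repeated-CV study under a few minutes on one CPU while leaving every
pipeline stage non-trivial.

What the generator does *not* emulate: the heavy-tailed degree
distributions of curated catalogues (a few diseases with hundreds of
associations, many with one), annotation biases that correlate with study
popularity rather than biology, a real multi-level ontology, or similarity
matrices estimated with noise correlated to the associations themselves.
Passing the synthetic suite therefore demonstrates correctness of the
machinery and the expected ordering of model variants under the model's own
assumptions — not clinical-grade accuracy on real catalogues.

On these conditions the acceptance suite checks that 5-fold CV-p AUC of the
full model exceeds 0.85 and that it beats both the classic-CMF ablation
(dense similarity regularizers, no WKNKN — the original form of the method
it extends) and the no-WKNKN ablation in at least 4 of 5 generator seeds;
`scripts/acceptance.R` recomputes the same quantities from scratch.

## Known limitations

* Dense algebra throughout: fine to a few thousand entities per side,
  wasteful beyond.
* The nearest-profile regularizer keeps exactly one neighbour; in very
  noisy similarity matrices that single neighbour can be wrong, and there is
  no fallback weighting (an acknowledged trade-off of the approach — excess
  neighbour information adds noise, too little loses robustness).
* Scores are unnormalized inner products: useful for ranking, not
  calibrated probabilities.
* The AUC negative set treats all unknown pairs as negatives, so reported
  AUCs are conservative when many unknowns are true associations.
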