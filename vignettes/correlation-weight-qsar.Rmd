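---
title: "Correlation-weight QSAR from SMILES attributes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-weight QSAR from SMILES attributes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cwqsar)
```

## The model and its assumptions

`cwqsar` fits endpoint models of the optimal-descriptor form

$$\log(S) = C_0 + C_1 \cdot DCW(T, N), \qquad
DCW = \sum_k CW(S_k) + \sum_k CW(SS_k) + \sum_k CW(NNC_k).$$

The structural vocabulary is deliberately minimal. $S_k$ are single
SMILES-atoms — a token is one character unless it cannot be read
separately: bracket atoms (`[C@@]`), and the two-letter organic-subset
elements `Cl` and `Br`. $SS_k$ are ordered pairs of adjacent tokens;
order is kept because `N(` (nitrogen at a branch point) and `(N`
(nitrogen opening a branch) are different structural facts. $NNC_k$ are
nearest-neighbor codes of the hydrogen-suppressed molecular graph,
$100 N_T + 10 N_C + N_X$ per vertex, so the code digits read as (total,
carbon, non-carbon) heavy-atom neighbor counts. Bond order is ignored in
the graph — only adjacency enters the codes — while bond *symbols* still
contribute as tokens, so double bonds are represented where they are
informative.

Attribute identity is a fixed-width 12-character dot-padded code
(`C...1.......`, `NNC-O...220.`), which makes weight tables and reports
diff cleanly. All featurization is lossless: no token class is discarded;
whether an attribute influences the model is decided solely by the rarity
threshold below.

The model family assumes the endpoint is (approximately) additive in
attribute counts. That is a strong assumption; its payoff is
interpretability — each weight is one attribute's marginal pull on the
endpoint — and immunity to descriptor-calculation failures, since any
parseable SMILES featurizes.

## The four-way split and the target functions

Data are partitioned into active training (A), passive training (P),
calibration (C) and validation (V) sets of near-equal size (a remainder
goes to P first, then A, then C; 289 compounds split 72/73/72/72). Each
set has one job:

* **A** — the only set the least-squares line $C_0, C_1$ and the weight
  updates are fit to;
* **P** — enters the target function only through $R^2_P$, penalizing
  weight tables that fit A idiosyncratically;
* **C** — supplies the correlation-quality index (IIC or CII) inside the
  target function and the model-selection score;
* **V** — appears in no objective anywhere; the optimizer receives its
  SMILES (for featurization of the attribute universe) but never its
  endpoints, which the test suite enforces by permuting them.

The Monte Carlo objective is
$TF = R^2_A + R^2_P - |R^2_A - R^2_P| + \lambda \cdot \mathrm{index}_C$
with $\lambda = 0.3$ by default. The index is either the **IIC** — the
Pearson correlation scaled by $\min(MAE^-, MAE^+)/\max(MAE^-, MAE^+)$,
where the two MAEs average the negative- and non-negative-side residuals
(observed − calculated) — or the **CII** — one minus the summed
"protests", a protest being the increase in $R^2$ obtained by deleting
one point. The IIC pushes the regression toward the diagonal of the
observed-vs-calculated plot; the CII reduces the number of points that
oppose the correlation.

Splits are chosen by a Las Vegas search (`las_vegas()`): split at random,
train fully, score on the calibration set (R², ties broken by lower MAE,
then lower seed), repeat, keep the best. The same engine with a distinct
seed stream provides the best-of-k run selection inside
`run_experiment()`; the two loops compose but stay independent.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `threshold_T` | 3 | An attribute is active when at least T active-training compounds contain it (count of compounds, not occurrences; `count_mode` switches this). Rare attributes are blocked: weight pinned to 0. |
| `epochs_N` | 15 | Optimization epochs; one epoch is a full pass over the active attributes in fresh random order. |
| `tf_kind` | `"CII"` | Which calibration index enters TF. |
| `tf_coefficient` | 0.3 | Weight $\lambda$ of the index; dimensionless. |
| `step` | 0.1 | Coordinate-move magnitude in weight units. |
| `init_low`, `init_high` | 0.5, 1.5 | Range of the seeded uniform weight initialization. Runs differ only through the seed, which the multi-run promoter interpretation requires. |

The move scheme is symmetric greedy coordinate ascent: at each visit the
weight is tried at $w \pm step$, $(C_0, C_1)$ are refit on A for every
candidate, and the best of the three states is kept. The returned model
is the best-TF state seen anywhere along the trajectory (snapshotting),
not the final state, and the per-epoch trace of that running best is
stored in `tf_trace`. Greedy ascent with per-evaluation refit is the
simplest faithful maximizer of this TF; the step stays configurable
because the planted-signal recovery rate is sensitive to it at small N.

## Sign canonicalization

$(C_1, \{CW\}) \mapsto (-C_1, \{-CW\})$ leaves every prediction
unchanged, so the sign of an individual weight is meaningless without a
convention. Trained models are canonicalized to $C_1 \ge 0$; under that
convention a positive weight reads directly as an endpoint-increasing
attribute. Without canonicalization, runs that converge to the mirrored
solution flip every promoter sign and cross-run sign stability is noise.

## Model selection, promoters, applicability

`run_experiment()` reproduces the full design: for each split and each
target function, k independent runs; the best model by calibration R²
(ties: lower MAE, then seed) is evaluated on all four sets; per-TF
summaries report mean ± sd of validation R²; identity-percentage matrices
(share of compounds with the same role in two splits, denominated by the
first split's role set — hence asymmetric) document split diversity.

Promoters: over ≥ 2 runs sharing the split, an attribute is classified
*increase* when its weight is strictly positive in every run, *decrease*
when strictly negative, *undefined* otherwise; a configurable minimum
|weight| (default 0) guards against counting near-zero weights as signs.
Reports are sorted by active-training frequency and carry the statistical
defect per attribute.

The applicability domain is statistical: for each attribute,
$d_k = |P-P'|/(N+N') + |P-P''|/(N+N'') + |P'-P''|/(N'+N'')$ over the
A/P/C probabilities (compound frequency / set size; terms with zero
frequency sum contribute 0); a compound's defect $D_j$ sums $d_k$ over
its *distinct* non-blocked attributes; the domain cutoff is twice the
mean defect of the A∪P∪C reference population. By Markov's inequality at
least half of any reference population is always in-domain. Filtering to
the domain changes which compounds are reported, never their
predictions. Compounds consisting solely of blocked attributes get
$D_j = 0$ with an explicit flag rather than an error.

## The synthetic-data generator

No public, license-free sweetness table accompanies the method, so the
generator is a first-class module rather than a fixture. It emits valid
small-organic SMILES — carbon-dominated draws from a C/N/O/S/Cl/Br
palette, chains up to 12 heavy atoms, one-level branches (probability
0.3), single rings of size 3–6 with closure digits 1–3 (probability
0.3), double bonds (0.25) and stereo bracket atoms (0.08) — and an
endpoint

$$y = c_0 + c_1 \sum_k w_k \, n_k + \varepsilon, \qquad
\varepsilon \sim N(0, \sigma).$$

Defaults plant positive effects on `N`, `=` and `NNC-C...220.` and a
negative effect on `O` ($c_0 = 0.5$, $c_1 = 0.4$, $\sigma = 0.1$),
chosen so the fixed-seed 289-compound benchmark
(`benchmark_corpus()`) spans ≈ 4.9 log units, the order of magnitude
over which relative sweetness varies. Because the endpoint is exactly
additive in attribute counts, the model family can represent it
perfectly: at $\sigma = 0$ the line fit recovers $(c_0, c_1)$ to
numerical precision, and at $\sigma = 0.1$ best-of-3 CII optimization
reaches validation R² ≥ 0.8 in the test suite's seeded repetitions.

What the generator does *not* emulate — and hence what passing tests do
not show about real data: real sweetener chemistry (sugars,
sulfonamides, peptides), fused rings, charges, tautomers, non-additive
structure–activity effects, measurement error structure beyond i.i.d.
Gaussian noise, and the near-duplicate clusters of curated literature
data. Results on the benchmark certify the machinery, not the chemistry.

## Numerical choices and degenerate inputs

* R² is the squared Pearson correlation throughout, matching its use on
  validation sets; the $1 - SSE/SST$ determination form appears only
  inside the Q2F family and the Q²(LOO) definition.
* IIC edge cases: one residual side empty with the other non-zero gives
  ratio 0 (hence IIC 0 — maximally one-sided errors); both sides zero
  (perfect fit) gives ratio 1, IIC = r. IIC keeps the sign of r; negative
  values are reported as-is.
* CII uses centered incremental sums, O(n) per evaluation, and is tested
  to agree with a naive leave-one-out loop to 1e-12; a leave-one-out
  subset with zero variance contributes no protest. CII of a degenerate
  (zero-variance) prediction vector scores 0 inside TF rather than
  erroring mid-search, as does R²; a candidate weight state with zero
  descriptor variance scores −Inf and is simply never accepted.
* Q²(LOO) uses the univariate hat-matrix identity $e_i/(1-h_i)$, tested
  against explicit refitting.
* $\langle r_m^2\rangle$ averages both regression directions; the
  $|r^2 - r_0^2|$ radicand is clamped to 0 below 1e-14 because the
  square root amplifies float noise at perfect fits.
* Model JSON uses 17 significant digits, the shortest width that
  round-trips IEEE doubles bit-exactly.
* Every random draw (splits, initialization, visit order, generator,
  experiment) runs under `withr::with_seed` with seeds derived from the
  user's seed, so nothing touches or depends on the global RNG state.

## Problem sizes

Examples and tests run at desk scale by choice: corpora of 40–80
compounds for unit tests, the 289-compound benchmark with 5 repetitions
× 3 runs for end-to-end recovery, 2 splits × 2 runs for the experiment
harness. The full design (7 splits × 10 runs) is a configuration change
(`experiment_config(n_splits = 7, n_runs_per_split = 10)`), not a code
change.

## Known limitations

* The tokenizer covers the organic subset plus bracket atoms; exotic
  SMILES (multi-digit `%nn` ring closures, disconnected `.` components)
  are rejected rather than silently mangled.
* Duplicate detection is exact string equality after whitespace
  stripping, not canonical-structure identity; two spellings of one
  molecule pass as distinct. Chemical-identity deduplication would need a
  canonicalizing toolkit and is out of scope.
* Greedy ±step ascent has no annealing; it can stall on plateaus. The
  Las Vegas and multi-run layers are the intended remedy — restart
  diversity substitutes for acceptance schedules.
* Q² is computed per reported set on its own pairs; whether a pooled
  training-set Q² is preferable is a design choice documented here, not
  a settled convention.
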