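---
title: "Canonical Autocorrelation Embeddings: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical Autocorrelation Embeddings: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In highly monitored clinical settings — the motivating case is quantitative
EEG (qEEG) of comatose post-cardiac-arrest patients, summarized at 1 Hz into
66 derived features — the unit of analysis is not a single observation but a
*dataset*: a couple of hours of multivariate recordings per subject. Clinical
experience suggests that what carries prognostic information in such data is
not only the level of individual features but the *correlation structure*
among them: strong, widespread correlation in cortical activity is an ominous
sign, and subtle multi-feature couplings may be invisible to a human reader.

This package implements a pipeline for that setting:

1. **CAA** (Canonical Autocorrelation Analysis) discovers sparse
   multiple-to-multiple linear correlations *within* a single feature set;
2. **CAE** (Canonical Autocorrelation Embeddings) represents every subject by
   the set of its discovered correlation structures, equipped with a metric;
3. **k-nearest correlations** classifies subjects by letting each of their
   structures vote through its nearest labeled structures, aggregated as
   thresholded log-odds, with an explicit *defer-when-uncertain* policy aimed
   at operating points with a very low false-positive rate.

## The CAA model

For a standardized data block $X \in \mathbb{R}^{n\times m}$ (columns centred,
unit sample variance), CAA solves

$$\max_{u,v}\; u^\top G v \quad \text{s.t.}\quad
\|u\|_2^2 \le 1,\; \|v\|_2^2 \le 1,\;
\|u\|_1 \le c_1,\; \|v\|_1 \le c_2,\;
\sum_{i}\sum_{j \in S_i} |u_i v_j| = 0,$$

where $G = X^\top X/(n-1)$ is the sample correlation matrix and $S_i$ is the
set of forbidden correlates of feature $i$ (by default $S_i = \{i\}$: a
feature may not "correlate with itself"; after polynomial expansion, a
feature and its powers form one mutual group). The disjoint-support
constraint is what distinguishes CAA from Sparse PCA: without it, the
one-matrix problem collapses to $u = v$ and maximizes *variance*; with it,
the solution is a genuine two-sided *correlation* between disjoint groups of
features.

Each solution $(u, v)$ is a *canonical pair*: a two-dimensional projection
$(Xu, Xv)$ in which the data are maximally linearly correlated. Pairs are
extracted sequentially: after each pair the gram matrix is deflated,
$G \leftarrow G - d\,(uv^\top + vu^\top)$ with $d = u^\top G v$, which
annihilates exactly the discovered correlation ($u^\top G' v = 0$ for
unit-norm disjoint pairs).

### Solving one half-step by KKT conditions

With $v$ fixed the problem in $u$ is convex, and its solution is a
soft-thresholded, renormalized gradient,

$$u \propto \mathcal{S}\big(Gv,\; \lambda_1 w + \lambda_2\big),
\qquad w_i = \sum_{j\in S_i} |v_j|,$$

where $\mathcal{S}(g,\theta)_i = \mathrm{sign}(g_i)\max(|g_i|-\theta_i, 0)$.
$\lambda_1 = \max_{i: w_i>0} |g_i|/w_i$ is the smallest multiplier that
zeroes every coordinate forbidden by $v$'s support (computed in closed
form); $\lambda_2 = 0$ when the $\ell_1$ constraint is slack, otherwise it is
found by bisection on $\|u\|_1 = c_1$.

Numerical choices that matter here:

- **Bisection depth.** The $\ell_1$ norm of the normalized thresholded
  gradient is continuous and non-increasing in $\lambda_2$; we bisect to
  machine precision (bracket below $10^{-15}$, max 200 halvings) rather than
  stopping at a loose tolerance, because each half-step must solve its
  subproblem essentially exactly for the alternating search to be provably
  monotone. The per-pair objective trace is checked to be non-decreasing
  with an absolute slack of $10^{-10}$ (on correlation scale).
- **Tied gradients.** When the largest free gradient entries are exactly
  tied, the soft-threshold family's $\ell_1$ norm plateaus at $\sqrt{k}$ and
  can jump over the budget $c$. The optimum then sits at a corner of the
  constraint set; we place mass $(a, b, \dots, b)$ on the tied coordinates
  with $a + (k-1)b = c$ and $a^2 + (k-1)b^2 = 1$ (deterministically, larger
  weight on the lowest index), which attains the optimal value
  $c\cdot g_{\max}$. Ties occur in practice after deflation, which zeroes
  parts of $G$ exactly.
- **Degenerate steps.** A free gradient at floating-point-residue level
  (below $10^{-12}$ relative to the gradient's magnitude) signals that
  nothing correlates with $v$'s support — typically an exactly deflated
  column — and is treated as "no structure found" rather than as signal.
- **Initialization.** A fully dense start is useless: $\lambda_1$ zeroes the
  entire support of a dense $v$ by construction, so the first half-step
  returns $u = 0$. We therefore start from single-coordinate vectors: the
  dominant coordinates of the leading eigenvectors of $G$ (a deterministic
  strong start), topped up with seeded random coordinates
  (`n_restarts = 8` by default) to escape local optima of the biconvex
  problem; the best restart by $d$ wins.
- **Sign canonicalization.** $(-u,-v)$ is objective-equivalent to $(u,v)$;
  pairs are flipped so the largest-magnitude coordinate of $u$ is positive
  (ties to the lowest index), stabilizing both the convergence check and
  the embedding metric.
- **Convergence.** Maximum coordinate change of the canonicalized pair below
  `tol = 1e-6`, capped at `max_iter = 500`.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `c1`, `c2` | 1.5 | $\ell_1$ budgets; must lie in $[1, \sqrt m]$ (below 1 the constraint set is empty given $\|u\|_2 = 1$). 1.5 targets small, readable supports of roughly 2–3 features per axis; budgets that leave the constraint slack keep small noise loadings in the support. |
| `max_pairs` | 5 | extraction cap per subject |
| `r2_min` | 0.25 | strict retention filter on the squared Pearson correlation of the projection scores; applied at extraction time, so the first sub-threshold pair terminates extraction (deflating past noise-level structure is meaningless) |
| `n_restarts` | 8 | initializations per pair |
| `seed` | 1 | controls the random restarts (per-pair substreams derive from it) |

Whether budgets should be tuned per subject is an open design question; the
package fixes them globally in the configuration, which keeps embeddings of
different subjects comparable.

## The embedding and its metric

A subject's model is the *set* of its retained canonical pairs. The distance
between two structures $C_1 = (u_1, v_1)$ and $C_2 = (u_2, v_2)$ is the
swap-minimized chord distance

$$d(C_1, C_2) = \min\big(\|u_1-u_2\| + \|v_1-v_2\|,\;
\|u_1-v_2\| + \|v_1-u_2\|\big),$$

additionally minimized over the joint sign flip of one argument. A canonical
pair is only defined up to the axis swap and the joint flip — both encode
the same correlation — so the metric is taken over the four-element group
they generate. The group acts by isometries, hence the triangle inequality
survives and distances are well-defined on equivalence classes (the package
verifies the metric axioms over a thousand random triples in its tests).
Distances are bounded by 4 for unit vectors.

Neighbor queries are exact brute-force scans (cohort scale is at most a few
thousand points) pruned at `prune_radius = 2`; ties are broken by
`(subject_id, pair_index)` for determinism. Note the radius is kept at the
conventional value 2 even though the geometric gloss sometimes attached to
it (a quarter-turn of one axis) corresponds to a chord of $\sqrt 2$; nothing
downstream relies on the geometric reading.

Only pairs with $R^2$ strictly above `r2_min` are admitted. Subjects with no
admissible pair are recorded in a deferral list — downstream classification
defers on them; no point is fabricated.

## k-nearest correlations and deferral

Each query structure receives a class probability $q$ = mean label of its up
to $k$ nearest labeled structures inside the pruning radius (own-subject
points are excluded — a structure never votes on its own subject). A subject
aggregates only its *discriminative* votes, $|q - 0.5| > t$:

$$\hat y_p = \sum_{i:\,|q_i - 0.5| > t} \log\frac{\tilde q_i}{1 - \tilde q_i},$$

with $\tilde q$ clipped to $[\varepsilon, 1-\varepsilon]$,
$\varepsilon = 1/(2k)$ by default (capped at $1/4$ so $k=1$ still yields
finite, non-degenerate odds) — a Laplace-style stabilization that preserves
vote ordering while keeping log-odds finite when $q \in \{0, 1\}$. Shared
structures that occur in both classes produce $q \approx 0.5$ and are
silenced by the threshold; the classifier's decisions rest on the
discriminative ones, which also keeps the evidence inspectable.

A subject with zero admissible pairs, zero neighbors, or zero discriminative
votes is **deferred**: it receives no recommendation at any operating
threshold (in ROC computations deferred subjects are placed at $-\infty$).
The decision rule is `recommend_positive` iff not deferred and the score
exceeds the operating threshold; everything else defers to the clinician.

The literal reading of the thresholded aggregation — a product over
indicator-weighted odds — would be zero as soon as any vote is
non-discriminative; consistent with its surrounding description, the package
reads it as a product over the discriminative votes only.

$(k, t)$ are tuned by subject-stratified inner cross-validation. The
selection criterion is deployment-aligned: TPR at FPR $\le$ 0.025, with
ties broken by AUC, then smaller $k$, then smaller $t$. With cohorts of this
size a per-inner-fold TPR is extremely coarse (a handful of validation
subjects per fold), so the criterion is computed on the pooled inner
out-of-fold scores — same expectation, far lower variance.

## The synthetic cohort generator

No clinical recordings ship with the package; the generator emulates the
*statistical* object the method consumes — a per-subject matrix with sparse
latent cross-correlations — not the physiology of qEEG features. Defaults
mirror the motivating study design: 40 subjects per class, 66 features,
7200 rows (two hours at 1 Hz), one structure shared by both classes and one
specific to class 1, both with target $R^2 = 0.8$.

A planted structure draws a latent series $z_t \sim N(0,1)$ i.i.d. and sets
block features to $x_j = w_j z + \sigma \epsilon_j$ on both blocks. The
noise variance is solved in closed form so the *population* $R^2$ between
the weighted block sums hits the target: with $\alpha = \sum w_{a}^2$,
$\beta = \sum w_b^2$, $\sigma^2$ is the positive root of
$(\alpha+\sigma^2)(\beta+\sigma^2) = \alpha\beta / R^2$. Closed-form
calibration (rather than rejection sampling) keeps generation deterministic
and fast; the realized per-subject $R^2$ is recorded in the manifest, and
across seeds its mean lands within a few hundredths of the target.

Two switches exist for experiment design rather than realism:
`equalize_variance` tops up every feature with independent noise to the
maximum marginal variance across classes, producing cohorts whose classes
differ *only* in correlation structure (the regime the embedding targets,
and one in which marginal-feature baselines are blind by construction);
`class1_shift` adds a mean offset to chosen features, producing the opposite
regime where baselines should win and the embedding has nothing to find. An
optional AR(1) latent switch exists (default off) to probe robustness to
temporal autocorrelation; the method itself treats rows as exchangeable.

**What passing tests do and do not show.** The generator's latents are
Gaussian, i.i.d. in time, with linear couplings and homogeneous noise. Real
qEEG is none of these things — non-stationary, heavy-tailed, temporally
autocorrelated, with feature semantics that the generator does not model.
Success on synthetic cohorts demonstrates that the implementation recovers
what it is designed to recover under its own assumptions; it is not evidence
of clinical performance.

### Identifiability of planted supports

Under a single-latent-factor construction, all structural features of one
planted structure form an exchangeable correlation clique: within-block and
cross-block correlations are equal, so which features land on the $u$ side
versus the $v$ side is not identifiable — any balanced split of the clique
is an equivalent optimum. Support recovery is therefore asserted on the
union $\mathrm{supp}(u) \cup \mathrm{supp}(v)$ against the planted union.
For the same reason, rank-2 deflation of one split leaves within-clique
correlation behind, so a single planted structure legitimately yields more
than one retained pair (different splits of the same clique); tests assert
that the first pairs match the planted structures in order of strength and
that no retained pair mixes two structures, not that the pair count equals
the structure count.

## Evaluation harness

The study design is reproduced at desk scale: stratified subject-level
10-fold outer cross-validation; $(k,t)$ tuned in an inner 10-fold loop
inside each training fold; the training embedding built from training
subjects only (CAA fits themselves are per-subject and unsupervised, so
models are fitted once). Baselines — lasso-regularized logistic regression
(glmnet) and Euclidean k-nn (class) on either the per-feature quartiles of
the window ("sets"; Q1/Q2/Q3, linear-interpolation convention, i.e. three
values per feature) or the final row ("points") — run on the *identical*
fold plan for paired comparison, with their hyperparameters tuned in the
inner loop. Baselines consume the raw, unstandardized matrices: marginal
location/scale information is part of their signal, and per-subject
standardization upstream would remove exactly what they are entitled to use.

ROC curves use the conservative step-function convention (positive iff
score strictly above threshold), so a reported operating point's empirical
FPR never exceeds its target; `tpr_at_fpr` returns the largest TPR whose
FPR respects the bound, with the largest realizing threshold. Confidence
intervals are percentile intervals from a subject-level bootstrap stratified
by class (1000 replicates by default) — the CI method is a package choice,
recorded in the output metadata. The AUC is reported but the quantity of
interest is TPR at a low FPR bound: with deferral, the system is evaluated
where it would actually operate.

Problem sizes used by the shipped verification runs: the end-to-end checks
run the full default cohort (80 subjects, 66 × 7200) with a reduced inner
grid ($k \in \{1,3,5,9\}$, $t \in \{0, 0.1, \dots, 0.4\}$); the regime
contrast (correlation-only vs mean-shift-only signal) uses 40-subject
cohorts with 20 features × 2000 rows and 5×5-fold nested CV — sizes chosen
to exercise the complete design while keeping a laptop run comfortable.
The property checks (KKT optimality vs an independent general-purpose
solver, ascent/feasibility over hundreds of random fits, metric axioms over
a thousand triples) run at small dimensions where oracles are exact.

## Known limitations

- The alternating search solves a biconvex, not convex, problem; restarts
  mitigate but do not eliminate local optima.
- With slack $\ell_1$ budgets (small $m$, strong signal), supports carry
  small noise loadings; interpretation should weight loadings, not just
  support membership.
- The embedding compares structures by their loading vectors, not by the
  subspaces they span; strongly correlated but differently weighted
  structures are distant by design.
- Scores are log-odds sums, not calibrated probabilities; the deferral
  threshold is set from training operating points, not from a probability
  model.
- Selective-label bias (outcomes censored by historical treatment
  decisions) is acknowledged but out of scope; the generator does not
  model it.
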