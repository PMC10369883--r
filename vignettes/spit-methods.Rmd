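---
title: "Detecting heterogeneous differential transcript usage with spit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting heterogeneous differential transcript usage with spit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Differential transcript usage (DTU) is a change in the relative proportions
of a gene's isoforms between conditions, independent of the gene's total
expression. Standard DTU tools assume the case group is homogeneous: every
case sample carries the same shift in isoform proportions. In complex
diseases that assumption routinely fails — distinct subgroups of patients
("splicotypes") may carry distinct sets of isoform switches, and averaging
over the whole case group dilutes each subgroup's signal below detectability.

`spit` detects DTU without assuming homogeneity. Per transcript it looks for
subgroup structure among the case samples, tests the subgroups separately
against matched control tails, judges significance against an empirical null
distribution estimated from the control group itself, removes candidates
explainable by recorded covariates, and finally clusters the case samples on
their shared events.

## The model, stage by stage

### Isoform fractions

Counts are converted to isoform fractions
$IF_{i,j} = t_{i,j} / \sum_{k \in G_j} t_{i,k}$, where $t_{i,j}$ is the
count of transcript $j$ in sample $i$ and $G_j$ is the set of transcripts of
$j$'s gene. Within a gene the fractions of a sample sum to one, so the
statistic is invariant to overall expression changes. Genes with zero total
count in a sample are assigned all-zero fractions; such genes cannot survive
the gene-count filter, so the convention has no downstream effect.

### Pre-filtering

Six stringent filters (all optional, applied in order) remove transcripts
that cannot support a reliable call: CPM $\ge 10$ in at least `n_small`
samples; positive counts in at least a fraction `pr` = 0.2 of each group;
gene counts $\ge$ `gc` = 10 in $\ge$ `gn` = 10 samples; $IF >$ `f` = 0.1 in
at least `n_small` samples; at least two surviving transcripts per gene; and
a consistently dominant isoform in at least `pd` = 0.75 of control samples.
Two choices the filter description leaves open are resolved as follows: the
CPM denominator is the per-sample total over the *input* transcript set,
fixed before any removal, so the step-1 outcome does not depend on removal
order; and isoform fractions are recomputed over the surviving transcripts
after every removal, which keeps the within-gene sum-to-one invariant true
for steps 4–6. Dominance ties in a control sample (two isoforms sharing the
maximal IF) count toward neither isoform, the conservative reading.

### Partitioning case samples

For each transcript a Gaussian KDE with bandwidth `h` (default 0.09, in IF
units) is fitted to the case-group fractions. The KDE is evaluated on a
fixed 512-point uniform grid over $[0,1]$: a fixed grid makes minimum
locations deterministic and comparable across bandwidths. A transcript is
treated as bimodal when the density has an interior local minimum flanked by
an interior local maximum on each side; the deepest such minimum $m$ splits
case and control samples into left tails ($IF \le m$) and right tails
($IF > m$). Requiring *interior* flanking maxima means a lone outlier at the
support boundary (whose density bump peaks on the boundary grid point) never
creates a partition — consistent with the intent that outliers should not
drive subgroup detection as long as smoothing is adequate. If two minima tie
at grid resolution the one closer to the data median is taken. No boundary
correction is applied to the KDE; oversmoothing through a generous `h` is
the intended mitigation, and `h` is deliberately larger than
histogram-fidelity bandwidth selectors would choose, because overdispersed
RNA-Seq fractions produce erratic histograms whose spurious modes must be
smoothed away.

Control tails smaller than `n_small` are expanded across $m$ (nearest
samples first) until they hold `n_small` samples, so a tail comparison is
never starved of controls. Case tails are *not* expanded — they are the
biological stratification being claimed — and if either case tail holds
fewer than `n_small` samples the partition is rejected and the transcript is
tested whole-group. With a valid partition, the left tails of case and
control are compared by a two-sided Mann-Whitney U test, as are the right
tails; otherwise a single whole-group test is used.

### The Mann-Whitney engine

To damp meaningless differences, fractions are rounded to two decimals
before ranking. Group sizes up to 8 without ties use the exact U
distribution; everything else uses the tie-corrected normal approximation
with continuity correction (ties are the norm after rounding). Small groups
*with* ties also fall back to the corrected approximation — refusing to test
would silently drop transcripts. Tests are two-sided throughout since
dominance can shift in either direction.

### The empirical null and the threshold

Instead of estimating dispersion per transcript, the package estimates one
null distribution of *minimal* p-values. Each of `n_iter` (default 1000)
iterations splits the control group into two random halves (odd counts give
the extra sample to a random half), draws a split point $o$ uniformly on
$[0,1]$ — the least-informative choice, and logged for reproducibility —
defines left/right tails of each half at $o$, runs the tail-wise U tests for
every transcript, and records the minimum p-value over transcripts together
with its source transcript. A transcript may contribute this minimum only
once across all iterations, so a single outlier transcript cannot dominate
the null; if every transcript has been consumed the process stops early and
the null shrinks with a warning. Inside these iterations a tail with fewer
than two samples on either side skips that side's test, and if both sides
are skipped the whole halves are compared, so every transcript receives a
p-value in every iteration.

The significance threshold is the $\lceil \kappa N \rceil$-th smallest of
the $N$ recorded minima (with $\kappa = 0.1$ and 1000 iterations, the 100th
smallest). `ceiling` generalizes the worked example conservatively to
non-integer products. Significance is strict (`p < threshold`), which makes
$\kappa \to 0$ degenerate rather than silently permissive. Case samples are
never permuted into the null: unknown case subgroups are exactly what must
not be absorbed into the noise estimate.

### Confounding control

Every significant transcript defines a binary vector $v$ over all samples
(1 = the sample carries the event; controls are all 0). A depth-one random
forest (100 bootstrap stumps by default) regresses the transcript's IF
values on $v$ plus the covariates, minimizing L2 loss on leaf means, with at
least `n_small` samples required to split a root. Each feature's permutation
importance is the drop in the forest's $R^2$ over `n_perm` = 100 column
permutations ($R^2$ is computed on the training samples — deterministic
given the forest; out-of-bag scoring would add sampling noise without
changing the comparison). The transcript is kept only when the first
quartile of $v$'s importance strictly exceeds every covariate's third
quartile (quartiles by linear interpolation); with no covariates the
transcript is trivially kept.

Two design points matter here. First, split-loss ties are broken in favour
of the covariate, not $v$: a covariate that partitions the samples exactly
as well as the DTU indicator takes the split, so $v$ accumulates only the
importance it strictly earns. With a random tie-break the duplicate-covariate
case degenerates into a coin flip on the binomial tree-share imbalance; the
conservative rule makes the decision deterministic — a covariate duplicating
$v$ always forces a drop, while an independent covariate never wins a split
and the candidate is kept. Second, categorical covariates are coded as
integers in lexicographic level order before stump fitting; binary
categoricals are unaffected by the order, and the arbitrary ordering of
multi-level categoricals is a documented limitation.

### The DTU matrix and splicotype clustering

Calls are assembled into a binary gene × case-sample matrix: tail-wise
transcripts mark the members of each individually significant tail,
whole-group transcripts mark every case sample, and a gene row is the OR
over its transcripts. When both tails of a transcript are significant, only
tail members are marked (marking all case samples would erase the subgroup
structure the tails just established). Case samples are then clustered
hierarchically under the distance
$d(a,b) = |a \triangle b| / (\text{number of DTU genes})$ — the proportion
of events unique to either sample. Average linkage is the default: on a
bounded set-difference metric it avoids single-linkage chaining. No
automatic cluster count is chosen; the dendrogram is always emitted and a
flat cut at a user-chosen $k$ is optional, because the subgroup count is a
judgement read off the dendrogram.

## The simulator

`generate_base_counts()` emulates a healthy bulk RNA-Seq population rather
than replicating any particular dataset. Per-gene totals are negative
binomial with variance $\mu + \mu^2 \cdot \mathrm{disp}$; per-sample isoform
fractions are Dirichlet draws centred on a gene profile whose dominant
isoform mean IF is uniform on $[0.65, 0.85]$ (centred on the 0.75 dominance
default); isoform counts are multinomial. The Dirichlet concentration is
tied to the same dispersion parameter ($\theta = 10/\mathrm{disp}$) so a
single knob controls overdispersion of totals and of fractions coherently,
and the Poisson limit is exact as $\mathrm{disp} \to 0$. Defaults
(`dispersion = 0.3`, gene means log-uniform on 300–3000, 2–4 isoforms per
gene) were chosen once as a realistic bulk profile: transcript mean–SD
clouds sit clearly above the Poisson line while the dominant isoform remains
consistently dominant in controls.

`inject_dtu()` plants ground truth: case samples are divided as evenly as
possible into splicotypes; each splicotype draws its gene set *with
replacement* from a common DTU superset, so some events are shared between
splicotypes and some are exclusive; and for each affected gene the dominant
(mean control IF $u$) and least dominant ($v$) isoforms swap fractions,
$u \leftrightarrow v$, with uniform noise on $[-\epsilon, \epsilon]$
(the noise law is unspecified in principle; uniform is used and logged).
Remaining isoforms are rescaled to preserve the within-gene sum, fractions
are clipped to $[0,1]$ and renormalized if noise escapes the simplex, counts
are rewritten as gene total × fraction rounded half-to-even, and the gene
total becomes the sum of the rounded counts. For scoring, the "true" gene
set is the union of the per-splicotype sets — with-replacement draws leave
roughly a fifth of the superset unused, and an uninjected gene carries no
signal.

What the simulator does *not* emulate: read-level artifacts (positional
bias, multimapping), per-transcript dispersion heterogeneity, correlated
covariates, or library-size imbalance. Passing tests on these simulations
therefore demonstrates the pipeline's statistical behavior under controlled
heterogeneity, not performance on any particular real dataset.

## Parameter fitting

`h` and `kappa` are the two hyperparameters that matter. `loocv_fit()`
estimates them per dataset: the control group is repeatedly split in half,
DTU is injected into one half (`n_g` splicotypes; the dominance filter step
is skipped during these constructions since it would bias the filtered set
toward the genes about to be modified), and every $(h, \kappa)$ pair on the
grid ($h \in \{0.02, \dots, 0.20\}$ by 0.01, $\kappa \in \{0.1, \dots, 1\}$)
is scored by gene-level F-score. Leave-one-out cross-validation selects, for
each held-out experiment, the pair maximizing the *mean* F over the training
experiments (the aggregation over training experiments is a deliberate
choice — it is robust to a single unlucky simulation), and the consensus
pair is the most frequently selected one, ties preferring smaller $\kappa$
then smaller $h$ (the more conservative setting). F-scores are gene-level,
matching how DTU performance is conventionally reported. The null
distribution does not depend on $h$ or $\kappa$, so the implementation
evaluates one null and one partition pass per $h$ per experiment and reuses
them across the whole grid and all folds; this is algebraically identical to
re-running the pipeline per fold. Fitting is worthwhile for control groups
of at least 32 samples; below that a warning is emitted and the defaults
$(0.09, 0.6)$ are a sensible fallback.

## Numerical and reproducibility choices

* One seed drives the whole pipeline; each stochastic stage (null building,
  confounding permutations, simulation, fitting) re-seeds from a sub-seed
  derived from the seed and the stage name, so disabling one stage never
  shifts another stage's stream, and a run is a pure function of
  (inputs, parameters).
* Fractional counts from quantifiers are rounded half-to-even at read time;
  the CPM and count filters presume integer counts.
* `n_small` defaults to 12, the smallest subgroup size at which the tail
  comparisons are considered interpretable; every guard (filters, tail
  sizes, stump roots) shares it.
* Minimum group size for any U test is 2 per side; smaller tails inherit the
  whole-group fallback.
* The problem sizes used throughout the test suite (300 genes, 60 vs 60
  samples, 5 splicotypes, 1000 null iterations; 500-transcript null
  experiments) are reduced-scale study conditions chosen so a full pipeline
  run completes in seconds while all size guards (`n_small` = 12,
  splicotypes of 12 samples) remain at their defaults.

## Known limitations

* Strictly two modes per transcript: the partition is a single split point;
  three or more splicotypes at one locus are found only through the gene
  union and clustering, not within one transcript's density.
* With fewer transcripts than null iterations the null exhausts early and
  its tail quantiles become conservative (the eligible set shrinks as
  transcripts are consumed), which inflates the threshold at small scale;
  family-wise error control at small $\kappa$ is an asymptotic property of
  transcriptome-scale inputs.
* Multi-level categorical covariates are ordered arbitrarily for stump
  splits; a level order correlated with the response can understate a
  confounder.
* The simulator's homogeneous dispersion is harsher than real data for
  null-calibration properties and gentler for robustness ones.
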