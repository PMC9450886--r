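---
title: "Methods: exploratory feature extraction, behavioral clustering, and permutation inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploratory feature extraction, behavioral clustering, and permutation inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishclust)
```

`fishclust` analyzes novel-tank exploration of zebrafish: it reduces each
fish-session 3D swim trace to four exploratory parameters, clusters fish into
behavioral types with a similarity-weighted k-nearest-neighbor (k-NN) graph
and Louvain community detection, assigns later sessions to the reference
clusters, and quantifies group structure and longitudinal consistency with
permutation tests. This vignette documents the models, the tunable
parameters, the numerical choices, and what the synthetic-data generator can
and cannot tell you about real recordings.

## The four exploratory parameters

A trace is a time-ordered table of `(t, x, y, z)` in seconds and centimetres
inside a square tank (default 15 cm side, 11.1 cm water depth — 2.5 L over a
225 cm² footprint). Feature extraction composes, in order:

1. **Diffraction correction.** Depth cameras under-range points viewed
   through water. `fit_depth_correction()` fits the ordinary least-squares
   line mapping in-water readings to true depth from paired calibration
   measurements (`z_true = slope · z_water + intercept`). The regression
   direction (true depth on measured depth) is a package choice; with a
   near-linear map and low noise the reverse fit differs negligibly.
2. **Interpolation.** Missing depth readings (typically a small fraction of
   frames) are filled linearly in time; runs at either end of the trace take
   the nearest available value, since extrapolating a fish's depth has no
   support in the data.
3. **Smoothing.** A Savitzky–Golay filter, window 7 frames and polynomial
   order 3, is applied to each coordinate channel before computing bottom
   distance, center distance, and distance travelled. This filter preserves
   cubic trends exactly while attenuating tracker jitter, which otherwise
   inflates path length. Percent explored is computed on the *unsmoothed*
   trace by default (`smooth_explored = FALSE`): voxel occupancy is a
   counting measure and smoothing would erase genuine excursions.

The parameters themselves:

- **Bottom distance** `B` (cm): trial mean of the unsigned distance to the
  tank's bottom plane. The plane is fitted by least squares (`z` on `x, y`)
  from points sampled on the floor (`fit_bottom_plane()`), normalized to a
  unit normal oriented toward the water, so `B` is `|ax + by + cz + d|`
  averaged over frames. Low `B` is bottom dwelling (geotaxis).
- **Center distance** `C` (cm): trial mean of the perpendicular distance to
  the vertical line joining the center top and center bottom of the tank.
  High `C` is wall proximity (thigmotaxis).
- **Distance travelled** `L` (cm): sum of Euclidean distances between
  successive smoothed frames.
- **Percent explored** `E` (%): the tank cube is divided into 10 × 10 × 10 =
  1000 evenly spaced voxels and `E` is the percentage visited at least once.
  The grid spans the full tank rather than the water volume, so voxels above
  the waterline are simply unreachable; both choices are supported through
  `voxel_counts` and the tank geometry. Voxel membership uses half-open
  boxes `[lo, hi)` with the last box closed; frames outside the tank bounds
  are clamped to boundary voxels with a warning rather than dropped, since
  they are tracker artifacts of real positions.

Whether `B` and `C` summarize frames by mean or median is an open choice; the
package uses the arithmetic mean, which matches the variance-based
standardization downstream. `binned_features()` computes the same four
parameters over contiguous time bins (default 6, i.e. 60-s bins of a 6-min
trial) for habituation analyses; the step joining two bins is credited to the
later bin so per-bin `L` sums exactly to the whole-trial value.

## Behavioral clustering

Features of a reference cohort are standardized per feature
(`(x − μ)/σ`), and similarity between fish `i` and `j` is

```
S_ij = 1 / (1 + D_ij)
```

with `D_ij` the Euclidean distance in standardized 4-D space. Any bounded,
strictly decreasing map with `S(0) = 1` serves; `exp(−D)` is available via
`method = "exponential"`. Each fish is linked to its `k` most similar fish
and the edge set is symmetrized by union (an edge exists if either endpoint
selects the other), guaranteeing minimum degree `k`; mutual symmetrization
is stricter and can disconnect sparse regions. Similarity ties are broken
toward the lower node index in sorted-id order, and the Louvain node-visit
order is randomized from a fixed seed, so a fitted model is reproducible
bit-for-bit and invariant to the row order of the input table. Louvain's
resolution parameter is fixed at 1; communities are relabeled 1, 2, … by
decreasing size so "cluster 1" is stable across runs.

**Choosing k.** `scan_k()` refits the graph and partition over a range of k
and scores each partition on the standardized point cloud with
Calinski–Harabasz (higher better), mean Silhouette width (higher better) and
Davies–Bouldin (lower better) — point-cloud indices, not graph quantities,
because they are defined for partitions of a metric space. `select_k()`
operationalizes "the middle of a good, stable regime": it ranks every k by
the mean rank of the three indices, keeps the best 1/`window` quantile
(default the top 20%), finds the longest contiguous run of kept ks whose
community count is constant, and returns that run's midpoint. Small k
fragments genuine clusters (Louvain's resolution limit: a 60-fish cluster
can split in two when `k = 20`); k near n merges everything. The plateau
rule lands between those regimes and is deterministic.

**Out-of-sample assignment.** A new fish-session is standardized with the
*reference* parameters (never re-estimated, so day-2 data live in the day-1
space), its `m_assign` most similar reference fish are found, and it takes
the community holding the largest share of those neighbors. `m_assign` is
half the size of the smallest reference community — large enough to be
stable, small enough that the smallest cluster can still win a vote. Ties go
to the tied community with the larger total similarity, then to the lower
community id; both rules are deterministic.

When exactly four communities are found, `name_clusters()` attaches the
archetype names by feature signature: lowest `B + E` → shy; highest `C`
among the rest → wall-hugger; highest `L + E` → active explorer; the
remainder → bold.

## Permutation inference

All tests share one convention: `p = (b + 1) / (m + 1)`, where `b` counts
permutation statistics at least as extreme as the observed one and `m` is
the number of resamples (default 10,000). The add-one form never returns 0;
the resolution floor `1/10001` prints as 0.0001 at four decimals. Two-sided
p-values double the smaller tail, capped at 1.

- **Representation tests** (`representation_test()`): are strain × sex
  groups over- or under-represented in a cluster? The null permutes the
  cluster-label vector across all fish with group sizes fixed; per-cell
  two-sided p-values are BH-FDR-corrected across all cells.
- **Overlap scores** (`overlap_score()`, `overlap_test()`): a fish observed
  over `E` exposures scores one point per unordered pair of exposures with
  the same cluster. All pairs are counted, not only consecutive ones — with
  5 exposures and 4 clusters the attainable range is 1–10, with 6 exposures
  2–15 (the minima are pigeonhole-forced), which only the all-pairs reading
  produces. The cohort statistic is the mean score; the null permutes every
  exposure column except the first independently across fish.
- **Two-session overlap** (`two_day_overlap()`): percent of fish in the same
  cluster on both days against a null permuting the second day's labels; the
  null mean is reported as the chance level (~25% for four balanced
  clusters, Σ pᵢ qᵢ in general).
- **Permutation t-tests** (`perm_t_test()`): Welch t with group-label
  shuffling (unpaired) or one-sample t of differences with sign flipping
  (paired).
- **Permutation ANOVAs** (`perm_anova()`): F statistics from the classical
  least-squares decomposition (Type II for two crossed between factors;
  split-plot ratios for one between and one within factor — both verified
  against `car::Anova` and `aov` with an `Error()` stratum in the test
  suite). Nulls: between main effects permute rows (or subject labels)
  unrestrictedly; the between-factor interaction permutes residuals of the
  additive model (the Freedman–Lane idea); within effects and mixed
  interactions permute each subject's level order independently. This is an
  approximation to full Freedman–Lane residualization for every term, chosen
  for transparency; under exchangeable nulls each scheme is exact, which the
  suite checks by type-I calibration (rates within [0.03, 0.07] at α = 0.05
  over 200 null simulations with m = 999).
- **FDR** (`fdr_adjust()`): step-up Benjamini–Hochberg via `p.adjust`,
  with input validation. Note that BH is not idempotent as an operator —
  re-adjusting adjusted values inflates them — so the package never
  double-adjusts.
- **Spearman correlations** (`spearman_ci()`): ρ on ranks with a percentile
  bootstrap CI over paired resamples (10,000 by default); the bootstrap
  method is a package choice, made explicit rather than delegated.

## The synthetic cohort generator

`generate_trace()` is a correlated random walk inside the water volume: the
heading is an AR(1) unit vector with persistence `turn_persistence`, speed
is truncated-normal `(speed_mean, speed_sd)`, and two deterministic drifts
act on position — a vertical restoring drift toward `depth_pref` (gain 1.5/s)
and a horizontal radial drift of strength `wall_affinity` (positive toward
the walls, negative toward the center; 2 cm/s per unit). Boundaries reflect.
This is the minimal mechanism that spans the four archetypes:

| archetype | depth_pref (cm) | wall_affinity | speed (cm/s) | persistence |
|---|---|---|---|---|
| shy | 0.8 | 0.2 | 1.2 ± 0.4 | 0.5 |
| wall_hugger | 5.55 | 2.0 | 4.0 ± 1.0 | 0.6 |
| active_explorer | 6.1 | 0.0 | 8.0 ± 2.0 | 0.8 |
| bold | 10.2 | −1.0 | 2.2 ± 0.8 | 0.5 |

These defaults are calibrated so extracted features reproduce the expected
qualitative profile — shy lowest in `B` and `E`, wall-huggers highest in
`C`, active explorers highest in `L` and `E`, bold highest in `B`, lowest in
`C` and below average in `L` — not any absolute values, which are not
available to calibrate against. Defaults: 6-min trials at 30 frames/s (a
native depth-camera mode), 15 cm tank, 11.1 cm water.

`generate_cohort()` draws each fish's session-1 archetype from its
(strain, sex) mixture and evolves it across sessions as a first-order Markov
chain: keep with probability `persistence`, else redraw from the mixture.
Under a uniform 4-archetype mixture the expected session-to-session
agreement is `persistence + (1 − persistence)/4`; the default
`persistence = 0.39` makes this ≈ 0.54, matching the two-day consistency
the assay is expected to show. The default cohort composition is 426 fish
(AB 58F/52M, TL 54F/50M, TU 58F/50M, WIK 51F/53M) with mild strain and sex
tilts in the archetype mixtures (TL shifted toward shy, males toward active
explorer); the within-group variances and tilt magnitudes are package
choices stated in `default_archetype_probs()`, not measured quantities.

`generate_feature_cohort()` skips trace simulation and draws features
directly from per-archetype Gaussians (`default_archetype_means()`), whose
centers are at least 5.5 within-archetype standard deviations apart. It is
the fast path for planted-cluster recovery tests. Exact recovery (ARI = 1
at n = 426) additionally requires that no fish is drawn nearer a wrong
archetype center, which at 5.5 sd still happens for a few fish per cohort;
recovery tests that demand exactness therefore widen the same geometry to a
12-sd minimum separation, and tests at the default separation assert
high-but-inexact agreement (≥95%) instead.

**What the generator does not emulate:** tracker dropout bursts, body-pose
ambiguity near the water surface, reflections at the glass, wall-following
with corner-cutting kinematics, habituation drift within a session, or any
strain-specific locomotor signature beyond the archetype mixtures. Passing
tests therefore demonstrate that the *analysis* is correct and calibrated
under its own assumptions, not that those assumptions hold for a given rig.

## Numerical choices and degenerate inputs

- Standardization refuses zero-variance features unless reference
  parameters are supplied.
- `perm_p` errors on non-finite observed statistics; t statistics are
  defined as 0 when the mean difference is 0 even with zero spread, and
  ±Inf for a nonzero difference with zero spread.
- Internal validity indices are `NA` for single-community partitions;
  `select_k` skips undefined rows and falls back (with a warning) to the
  single best-ranked k when no stable run of length ≥ 2 exists.
- All randomness is seeded: generators take explicit seeds, the pipeline
  fans one root seed out by fixed per-stage offsets (+1 simulate, +2
  cluster, +3 stats), and every seeded call restores the caller's RNG
  state.
- Problem sizes in the test suite are chosen to keep the full run
  desk-scale: planted-recovery cohorts of 426 fish, calibration experiments
  of 200 null simulations with m = 999 resamples, trace-level property
  checks at 15–30 fps and 20–120 s trials.

## Known limitations

- The mixed-ANOVA split-plot statistic uses subject-weighted level means;
  with strongly unbalanced between-groups it is a valid permutation
  statistic but not the textbook unweighted-means F.
- Louvain is greedy; on adversarial graphs it can return a locally optimal
  partition. The suite checks it attains the exact modularity optimum on
  small fixtures (brute-force enumeration over all partitions) and recovers
  planted structure at realistic sizes, which is the regime the analysis
  uses.
- Assignment near community boundaries is inherently unstable: fish whose
  neighborhoods mix labels can legitimately flip between sessions; the
  package reports labels, not posterior probabilities.
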