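---
title: "Small-world brain network analysis of EEG mental fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Small-world brain network analysis of EEG mental fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Prolonged cognitive work degrades alertness and performance. Two
complementary EEG signatures of this state are well established: spectral
slowing — the power of the slow rhythms (theta, alpha) rises relative to the
fast beta rhythm — and a reorganization of *functional connectivity*, the
statistical dependence between the signals recorded at different scalp
electrodes. `fatiguenet` implements a complete analysis chain for the second
signature, anchored by the first: multichannel EEG recorded repeatedly over
a fatiguing session (five time points T0–T4, each in a resting and a task
condition) is decomposed into the classical rhythms, pairwise dependence is
quantified by mutual information (MI), the resulting weighted graphs are
binarized, and their *small-world* organization is tracked over time.

Because the kind of recordings this design needs are rarely shareable, the
package also contains a synthetic multichannel EEG generator whose fatigue
course is fully controlled. Every stage of the pipeline can therefore be
exercised against known ground truth, at desk scale, with deterministic
seeds.

## The measures

**Fatigue ratio.** For each epoch and channel the band powers are the mean
squared samples of the band-filtered trace, and the fatigue index is
\[(P_\theta + P_{\alpha 1} + P_{\alpha 2}) / P_\beta,\]
averaged over epochs and over the nine middle-scalp channels (F3, C3, P3,
F4, C4, P4, Fz, Cz, Pz). Delta is excluded: it mainly reflects sleep and
overlaps with artifacts. The ratio is computed *per epoch-channel first* and
then averaged — the alternative (ratio of averaged powers) is more sensitive
to single-epoch outliers. The ratio is invariant to a global rescaling of
the signal, so the arbitrary amplitude units of the generator are harmless.

**Mutual information.** For channels \(x, y\), MI is estimated from a 2-D
equal-width histogram spanning each vector's own range:
\[\hat I(x,y) = \sum_{ij} \hat p_{ij} \ln
\frac{\hat p_{ij}}{\hat p_{i\cdot}\hat p_{\cdot j}},\]
in nats, with the Miller–Madow correction
\((K_{xy} - K_x - K_y + 1)/(2N)\) subtracted (\(K\) = occupied cells/bins)
and the result clamped at zero. The default bin count per axis is
\(\lceil\sqrt{N/5}\rceil\) — 16 bins for the standard 5-s, 256-Hz epoch
(\(N = 1280\)) — a compromise between resolution and occupancy that keeps
the independence floor of the corrected estimator below 0.05 nats at this
\(N\). Per 19-channel epoch set this yields a symmetric \(19\times 19\)
matrix with zero diagonal; the per-epoch matrices of a cell are averaged.
Note two practical properties verified in the test suite: the estimator
reaches the Gaussian closed form \(-\tfrac12\ln(1-\rho^2)\) within 15 % at
large \(N\), and band-limited signals carry a *positive bias floor*
(autocorrelation reduces the effective sample count), so MI thresholds are
meaningful only relative to this estimator — not transferable across
estimators.

**Networks.** Weighted matrices are binarized two ways:

* *weight threshold* — edge iff \(w_{ij} \ge T\) (ties at the threshold
  survive), swept over \(T = 0.15, 0.16, \dots, 0.35\). Thresholds that
  leave any node isolated are flagged and excluded from comparison rather
  than repaired.
* *fixed mean degree* — the \(m = \mathrm{round}(nK/2)\) strongest weights
  become edges (half-up rounding resolves \(n = 19, K = 5\);
  lexicographic node order breaks exact ties deterministically), so that
  compared networks differ only in edge placement, not in edge count.

For a binary graph, \(C_i = 2E_i / (K_i(K_i-1))\) (zero when \(K_i < 2\)),
\(C\) is the node average, and \(L\) is the mean shortest-path length over
ordered pairs (breadth-first search; unit-weight Dijkstra is identical). If
a graph is disconnected but isolate-free, \(L\) is averaged over reachable
pairs and flagged — leaving infinite distances undefined is the only
alternative the construction principle permits.

**Small-world index.** Against an ensemble of degree-preserving random
graphs (default 250),
\[\sigma = \frac{C / \bar C_{\mathrm{rand}}}{L / \bar L_{\mathrm{rand}}},\]
using the ensemble *means* as references (not per-null ratios).
\(\sigma > 1\) marks small-world organization. Nulls are produced by
Maslov–Sneppen double-edge swaps: edges \((a,b), (c,d)\) become
\((a,d), (c,b)\) unless a self-loop or duplicate would arise. Each accepted
swap relocates two edges *and two non-edges*, so the mixing budget is
\(10 \times \min(|E|, |\bar E|)\) accepted swaps, and proposals are drawn
from whichever side is sparser — at high density the classical
10 × |E| budget is unreachable (there is nothing left to move) while the
complement formulation mixes the few vacant slots quickly. A complete
graph, or one with a single non-edge, admits no move at all and is returned
unchanged, which makes \(\sigma = 1\) exact for complete graphs. Null seeds
are `seed + null index`; every run is reproducible.

**Statistics.** Group contrasts across the five time points use one-way
ANOVA with subjects as the unit of analysis, computed directly from sums of
squares so that degenerate inputs (zero within-group variance) are flagged
rather than silently propagated; the implementation is cross-checked
against base R's `oneway.test`/`aov` in the tests. Rhythm selection runs
this ANOVA on the per-subject mean MI (the average of the 171
upper-triangle weights) for every rhythm × condition and keeps those with
\(p < 0.05\); the network stage then analyses the most significant
combination. Pairwise tables (T0–T1, T1–T2, ...) are realized as two-group
ANOVAs. Deliberately, no multiple-testing correction is applied and
repeated measures are treated as independent groups — both choices mirror
the classical analysis this package operationalizes, and both are caveats
to keep in mind when interpreting p values.

## The synthetic generator

Each channel is a sum over the five rhythms of band-limited Gaussian noise:
white noise filtered with a 4th-order Butterworth band-pass applied
forward–backward (zero phase), with one second of padding absorbing the
transients. Base amplitudes (SD, arbitrary microvolt-like units) are
delta 12, theta 8, alpha1 10, alpha2 7, beta 5 — the usual dominance of slow
over fast rhythms at rest. The trajectory multiplies the theta/alpha
amplitudes by `slow_fast_gain` (default 1.00, 1.25, 1.50, 1.45, 1.40 across
T0–T4: the power ratio rises while fatigue builds and eases once subjects
disengage near the end).

Inter-channel dependence lives in the alpha1 band, where fatigue effects on
connectivity are expressed:

* a *spatial base*: channel noise is mixed by the Cholesky factor of a
  distance-decay correlation matrix \(\exp(-d_{ij}/\lambda)\) over schematic
  10–20 grid positions (\(\lambda = 1.5\) grid units), off-diagonals scaled
  by the trajectory's `alpha1_structure` weight
  (default 1.00, 0.60, 0.35, 0.00, 0.55);
* a *global shared source*: \(y = \sqrt{1-c}\,x + \sqrt{c}\,s\) with
  \(c =\) `alpha1_coupling` (default 0.10, 0.26, 0.37, 0.48, 0.30), a
  variance-preserving convex mixture.

Why both knobs? The global mixture alone raises every pairwise MI but —
because MI is convex in correlation — it *preserves the rank order* of the
pairs, so a fixed-degree network built from the top-\(m\) weights would
never change shape. What makes real fatigued connectivity "more random" is
that its spatial organization flattens: near and far pairs become alike. The
structure weight models exactly that. At baseline the strongest pairs are
the spatially close ones and the fixed-degree network is lattice-like
(\(\sigma\) well above 1); as structure fades the ranking is increasingly
decided by estimator noise and the network drifts towards a degree-matched
random graph (\(\sigma \to 1\)); at T4 both knobs partially recover. The
coupling dominates the *mean* MI (and hence threshold-network density),
reproducing the rise-to-T3-dip-at-T4 course, while the structure weight
governs fixed-degree topology. Both default courses were fixed once, from
pilot calibration of the generator against the estimator's scale, to
reproduce the qualitative orderings described above; they are packaged in
`inst/extdata/default_trajectory.yaml` and fully overridable.

The coupling/structure trajectory acts only in the task condition (the rest
condition keeps baseline values), while the power-ratio gain acts in both —
fatigue raises spectral slowing in rest and task alike, but the
connectivity reorganization is expressed under load. Other rhythms carry
the fixed spatial correlation at all times, so their mean-MI time courses
are flat by construction and the selection step has true nulls to reject.

What the generator does **not** emulate: ocular/cardiac artifacts, 1/f
background spectra, volume-conduction forward models, nonstationarity
within epochs, or between-subject heterogeneity (subjects differ only by
noise realization). Passing tests therefore demonstrate the correctness and
calibration of the *analysis*, not robustness to the full messiness of
recorded EEG.

Seeds: a master seed spawns per-(subject, time, condition) child seeds via
a fixed linear counter scheme (`child_seed()`), so cells are independent
yet individually reproducible, and any single cell can be regenerated
without running the others.

## Numerical and design choices

* Band edges are half-open \([lo, hi)\): 4 Hz belongs to theta, 10 Hz to
  alpha2. Adjacent bands never share an FFT bin, so disjoint band powers
  never exceed the total.
* Brick-wall FFT filtering is applied per epoch; the edge ringing of a
  5-s window is accepted in exchange for exact band separation and
  idempotence (refiltering changes nothing beyond rounding).
* Resampling is polyphase rational (1000 → 256 Hz uses 32/125) with
  anti-alias filtering, via the `signal` package.
* Constant traces have undefined histograms; their MI is defined as 0 with
  a warning.
* `sigma` is reported as `NA` when the null ensemble is triangle-free
  (\(\bar C_{\mathrm{rand}} = 0\)).
* Default problem sizes: the full design is 18 subjects × 10 epochs as in
  the classical protocol; the packaged analyses in the tests and the
  acceptance script use 6 subjects × 5 epochs × 50–250 nulls, which keeps a
  complete run within a few minutes while leaving every group contrast
  well-powered under the default trajectory.

## Limitations

The selection step inherits the classical analysis' uncorrected multiple
comparisons, so with nine true-null rhythm × condition combinations an
occasional false positive alongside alpha1/task is expected (the network
stage takes the *most significant* combination, which is robust to this).
Histogram MI values, and therefore the absolute threshold window, are
estimator-specific. And the synthetic trajectory encodes the *qualitative*
fatigue course — monotone rise of coupling to T3 with a T4 reversal — not
effect sizes measured on any real cohort.
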