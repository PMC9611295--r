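---
title: "Methods: phase-lag-index brain networks for task-switching EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-lag-index brain networks for task-switching EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

`plinet` implements a complete functional-connectivity analysis of
multichannel EEG recorded around a task switch, of the kind used to ask
whether mental fatigue changes how the brain reorganises between
cognitive tasks. Two labelled conditions (for example, a working-memory
block versus the mental-arithmetic block that follows it) are compared
through five stages:

1. **Preprocessing** — common average reference, zero-phase band-pass
   decomposition into the four classical rhythms (delta 0.5–4, theta
   4–8, alpha 8–13, beta 13–30 Hz).
2. **Connectivity** — sliding-window phase lag index (PLI) between all
   channel pairs, per band, averaged over windows.
3. **Network metrics** — proportional sparsity thresholding of the mean
   PLI matrix and four weighted graph metrics, swept over sparsity
   15–30 % and aggregated by the area under the curve (AUC).
4. **Statistics and ranking** — one-way ANOVA on AUC features and on
   every edge's PLI; edges with p < 0.05 feed a consensus SVM-RFE
   ranking whose top 20 connections are reported with scalp-region
   categories.
5. **Classification** — stratified 10-fold cross-validated SVM, random
   forest and k-nearest-neighbour classification from the concatenated
   four-band PLI feature vector (7080 features for 60 channels).

Because task-state EEG of this kind is rarely shared, the package ships
a synthetic cohort generator with *planted*, band-specific phase
coupling, so that every stage is testable against a known ground truth.

## Phase lag index

For two band-limited signals, the analytic-signal (Hilbert) phase is
extracted within each window independently and

$$\mathrm{PLI} = \left| \frac{1}{T}\sum_t \operatorname{sign}
\big(\Delta\phi(t)\big) \right|, $$

with $\Delta\phi$ wrapped to $(-\pi, \pi]$ and $\operatorname{sign}(0)$
contributing zero. PLI is 0 for identical or zero-lag-coupled signals —
which is why it is favoured when volume conduction is a concern — and 1
for any consistently lagged pair. Windows default to 4 s with a 2-s
step, so a 400-s recording yields 199 windows; with 60 channels there
are 1770 pairs per band per window and 7080 across the four rhythms.
Phase is deliberately computed per window rather than once over the full
record: windowed estimation is the unit of analysis, and the two choices
differ slightly at window edges.

## Weighted graph metrics

The window-averaged PLI matrix is proportionally thresholded: at
sparsity $s$ the $k = \operatorname{round}(s \cdot 1770)$ strongest
edges keep their weights and all others become zero (ties at the cutoff
resolve to the smaller canonical edge index so results are
deterministic). On the resulting weighted network with path lengths
$l^w_{ij}$ defined over reciprocal weights:

* characteristic path length $L^w = \frac{1}{n(n-1)}\sum_{i \ne j} l^w_{ij}$;
* clustering coefficient $C^w = \frac{1}{n}\sum_i \frac{2 t_i^w}{k_i (k_i - 1)}$
  with $t_i^w = \tfrac12 \sum_{j,h} (w_{ij} w_{ih} w_{jh})^{1/3}$;
* global efficiency $E^w_{glob} = \frac{1}{n(n-1)}\sum_{i \ne j} 1 / l^w_{ij}$;
* local efficiency $E^w_{loc}$, the same quantity computed inside each
  node's neighbour subgraph and weighted by the connecting edges,
  $\frac{1}{k_i(k_i-1)} \sum_{j \ne h \in N_i} (w_{ij} w_{ih} /
  l^w_{jh}(N_i))^{1/3}$, averaged over nodes.

Each metric is computed at sparsity 0.15, 0.16, …, 0.30 and aggregated
by the trapezoidal AUC, which removes the arbitrary choice of a single
threshold. Shortest paths use Dijkstra's algorithm on reciprocal
weights (via igraph); the metric implementations are validated against
exhaustive brute-force evaluation (Floyd–Warshall plus direct
triple-loop formulas) on random small graphs to 1e-10.

**Disconnection.** Thresholded graphs can disconnect. The efficiency
metrics handle this naturally ($1/\infty = 0$), but the mean path length
diverges. `characteristic_path_length()` therefore computes $L^w$ on the
largest connected component and raises a `disconnected` attribute, which
the sparsity sweep records per level. This is an explicit convention,
not an estimate of the diverging quantity.

## Condition comparison and consensus SVM-RFE

AUC features (4 bands × 4 metrics) and all 1770 edge PLIs per band are
compared between conditions by classical one-way ANOVA with the
window-averaged, per-subject value as the unit of analysis. Edge
selection keeps p < 0.05 **uncorrected** — selection here is a filter
before multivariate ranking, not an inferential endpoint; a
Benjamini–Hochberg option exists (`fdr = TRUE`) but is off by default.
Conditions are treated as independent groups even when subjects repeat
across conditions; a paired design would be more sensitive, and this
divergence is deliberate so that the two-sample contract stays simple.

Significant edges are ranked by SVM recursive feature elimination with
an RBF kernel ($C = 1$, $\gamma = 1/p$ on standardised columns, both
configurable). Features are scored by the change in the dual margin
term when a feature is struck from the kernel matrix with the support
vector coefficients frozen:
$\Delta J_j = \tfrac12\big[W^2(\alpha) - W^2_{(-j)}(\alpha)\big]$, with
$W^2(\alpha) = \sum_{a,b} \alpha_a \alpha_b y_a y_b K(x_a, x_b)$. The
score is kept **signed**: in the linear limit it reduces exactly to
$w_j^2/2 \ge 0$, whereas under an RBF kernel the removal of an
uninformative feature shrinks pairwise distances and *inflates* every
kernel entry, producing a large spurious magnitude; taking the absolute
value would therefore protect noise features, which we verified
empirically on two-feature constructions (the informative feature wins
rank 1 in essentially all seeds with the signed score and almost never
with the absolute one). A `kernel = "linear"` switch gives the literal
$w_j^2$ criterion.

Robustness comes from consensus: the elimination is repeated on
class-stratified 90 % subsamples (1000 runs by default) and the run
rankings are aggregated by positional vote counting — the consensus
rank-1 feature is the most frequent rank-1 feature across runs, the
consensus rank-r feature is the most frequent within positions 1..r
among features not yet chosen, and vote ties break toward the lower
column index. Stratification guarantees both classes survive every
subsample; whether the original protocol stratified is unknown, and the
choice is recorded here as ours.

## The synthetic cohort generator

`synthetic_config()` defaults describe the acquisition the package
targets: 20 subjects per condition, 60 channels, 400-s recordings at
200 Hz, four rhythms. Each channel carries unit-variance 1/f-amplitude
background noise (power slope −2), produced by spectral shaping of
white noise — realistic broadband EEG spectra with no fitted
parameters. A planted edge in band $b$ with coupling $c$ adds to its
two channels `osc_amplitude` (default 2, in units of the background SD)
times `c * shared + (1 - c) * own`, where `shared` is one narrowband
Gaussian source whose second copy is delayed by a constant π/4 phase and
`own` is independent narrowband noise. The constant nonzero lag makes
the phase-difference sign consistent, so PLI increases monotonically
with $c$ — and because PLI is blind to zero-lag coupling, a zero-lag
shared source would be invisible by construction, which is why the lag
is fixed away from 0 and π. Per-subject couplings are jittered by a
clipped Gaussian (SD 0.05 by default) to create between-subject
variance for the ANOVA and classification stages. Everything is
deterministic given the master seed; per-recording seeds are derived
from (seed, condition, subject).

What the generator does **not** emulate: ocular and muscle artifacts
(the ICA stage standard for recorded EEG is out of scope here), volume
conduction through a head model, non-stationarity across a session, and
spatially correlated background activity. One consequence worth knowing:
the common average reference mixes a small copy of every planted source
into all channels, so channels of a strongly coupled pair acquire weak
but real lagged coupling with the rest of the montage. This is a
realistic reference effect, and it means edge-wise selection on a
planted cohort legitimately retains more than the nominal 5 % of null
edges. Passing tests on this generator demonstrates the pipeline's
mechanics and calibration, not performance on recorded EEG.

## Numerical choices

* Band-pass filters are 4th-order Butterworth applied forward–backward
  (zero phase, effective 8th order) — the standard realisation of
  zero-phase digital filtering; transition widths are not specified by
  the design, so the Butterworth default is documented rather than
  tuned. Odd-reflection padding of about three periods of the low band
  edge suppresses edge transients.
* Edge-count rounding at a sparsity level is half-away-from-zero; at
  15 % sparsity a 60-node network keeps round(0.15 × 1770) = 266 edges.
* `sign(0) = 0` in the PLI sum, so identical signals give exactly 0.
* Degenerate ANOVA input (zero total variance) returns F = 0, p = 1
  with a `degenerate` flag instead of failing inside a 1770-edge scan.
* All stochastic stages (generator, subsampling, folds) take explicit
  integer seeds and restore the caller's RNG state.

## Scales used by the heavy validation checks

The package's end-to-end checks (in `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`) run a deliberately scaled-down study: 20
cohorts of 20 subjects per condition with 60-s recordings, one planted
beta edge at coupling 0.2 vs 0.8, beta-band connectivity, and a
20-subsample consensus ranking; classification uses the full four-band
7080-feature vector of the first cohort. These sizes keep a full
verification run in the tens of minutes on one core while leaving the
planted effect large enough that recovery and classification are
decisively testable; the 1000-run consensus default remains the
recommended setting for real analyses.

## Known limitations

* PLI cannot see zero-lag interactions by design; the generator
  consequently never plants them.
* $L^w$ on disconnected graphs is a convention (largest component), and
  values across sparsity levels with different disconnection flags are
  not strictly comparable.
* The edge-selection step is uncorrected by default and will pass ~5 %
  of null edges; downstream consensus ranking is designed to absorb
  this, but the selected-edge count should not be read as an inference.
* The cross-validation unit is the recording (subject × condition);
  window-level classification is possible through the feature matrices
  but leaks within-recording dependence and is not a default anywhere.
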