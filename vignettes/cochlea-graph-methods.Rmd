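---
title: "Cochlea graphs from sound-evoked signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cochlea graphs from sound-evoked signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cochleagraph)
```

# The model

`cochleagraph` treats the cochlea as a weighted, undirected functional
graph. The nodes are 100 tonotopically mapped inner hair cells (IHCs); a
*graph signal* is one scalar per node — the time-averaged simulated IHC
response to one acoustic stimulus. A corpus of 1,000 varied stimuli yields
a 100 x 1,000 signal matrix from which functional links between nodes are
inferred. Structure (modularity, clustering, global efficiency, density)
and function (graph-Fourier-transform denoising) of the resulting graphs
can then be compared across construction methods and across degrees of
hearing loss.

## Tonotopic scaffold

Node positions follow the Greenwood human place–frequency map
$f = A\,(10^{a x} - k)$ with $A = 165.4$, $a = 2.1$, $k = 0.88$ and $x$ the
normalized distance from the apex. Nodes sit at equally spaced places;
the place domain is rescaled so the endpoint characteristic frequencies
(CFs) are exactly `f_min = 20` Hz and `f_max = 20` kHz. Node 1 is the base
(highest CF), matching the usual high-to-low labeling of cochlear
connectivity matrices. 3D coordinates on a 2.75-turn conical helix (basal
radius 5 mm, apical radius 1 mm, height 5 mm) are attached for
visualization and export only — they never influence graph construction,
and they are a parametric stand-in, not an anatomical reconstruction.

## The periphery simulator

The simulator is deliberately minimal: it preserves the two response
properties the graphs depend on — tonotopic tuning and level dependence —
and nothing else. Per node, the chain is

1. 4th-order gammatone band-pass at the node's CF, bandwidth
   $1.019 \cdot \mathrm{ERB}(f)$ with the human
   $\mathrm{ERB}(f) = 24.7\,(4.37 f/1000 + 1)$ Hz, peak gain normalized
   to 1;
2. multiplication by the node's performance factor $p \in [0, 1]$;
3. half-wave rectification;
4. first-order low-pass at 1 kHz (membrane smoothing);
5. compressive nonlinearity $y \mapsto y^{0.6}$.

The scalar graph signal is the arithmetic time-mean of this nonnegative
series. Stimuli (100 ms at 44.1 kHz, raised-cosine 5-ms ramps) are drawn
with equal probability from pure tones, 2–5-partial tone complexes
(harmonic or inharmonic) and 1/3-octave noise bands, with log-uniform
frequencies on 50 Hz–16 kHz and levels uniform on 40–90 dB (100 dB
corresponds to unit amplitude). Every draw is seeded; a stimulus set is a
pure function of its configuration.

This chain is *not* a biophysical IHC model: there is no middle ear, no
spiking, no adaptation, no efferents. Tests that pass on these signals
demonstrate properties of the framework, not of any particular cochlea.

## Hearing loss

Audiograms (dB HL at standard clinical frequencies) are interpolated to
node CFs linearly in log-frequency, held flat beyond the measured range,
and mapped to performance factors $p = 10^{-\mathrm{HL}/40}$ clipped to
$[0, 1]$. The compressive exponent ($-\mathrm{HL}/40$ rather than the
physical $-\mathrm{HL}/20$) keeps moderate-to-profound losses
distinguishable: $-\mathrm{HL}/20$ collapses everything beyond ~40 dB to
numerically dead nodes. Severity is graded by the WHO 2021 bands on the
0.5/1/2/4 kHz pure-tone average.

A subtlety motivates the structure of the impairment model. The
transduction chain above is *homogeneous* in its gain: scaling the
gammatone output by $p$ scales the scalar signal by exactly $p^{0.6}$.
Because graph learning standardizes each node's row, a gain-only
impairment would leave every patient's learned graph identical — an
audiogram would change nothing. Real sensorineural loss does more than
attenuate, and `impair_signal_matrix()` models its three canonical
consequences on the clean signal matrix:

* **sensitivity loss** — the exact $p^{0.6}$ row scaling;
* **loss of frequency selectivity** — Gaussian smearing of the matrix
  across tonotopically neighboring nodes, kernel SD
  $0.10 \cdot \mathrm{HL}/120$ in place units. At total loss this spreads
  excitation over roughly plus/minus ten of 100 nodes, consistent with the
  2–4x auditory-filter broadening reported in sensorineural impairment;
* **elevated internal noise** — seeded additive Gaussian noise with
  per-node SD $1.3 \cdot (\mathrm{HL}/120) \cdot \mathrm{RMS(row)}$,
  truncated at zero. The 1.3 factor makes a total-loss node's signals
  carry about $-2.3$ dB internal signal-to-noise ratio, the baseline noise
  level reported for profound-loss cochlear signals relative to their
  normal-hearing counterparts.

These three strengths are model constants, not fitting dials; they were
fixed during model design and all reported experiments use them
unchanged. With them, severity reshapes the learned graphs the way the
clinical analysis expects: graphs densify while modularity, module count,
efficiency and clustering decline.

The synthetic cohort generator draws, per patient, a severity grade
uniform over the six WHO bands, a target PTA uniform within the band
(profound capped at 110 dB so the 5-dB per-frequency jitter stays inside
the clinical $[-10, 120]$ range), and one of four audiogram shapes (flat,
gently sloping, steeply sloping, 4-kHz notched). Demographics (age 1–18,
sex, race, ethnicity) are sampled independently of severity, so every
demographic–metric association in a synthetic cohort is a true null.

## Graph construction

Four methods, sharing the `cochlea_graph` contract (symmetric, nonnegative,
zero-diagonal weights; cached combinatorial Laplacian $L = D - W$):

1. **Smooth-signal learning** (`learn_graph_smooth`). With $z$ the vector
   of pairwise squared Euclidean distances between standardized node rows
   and $w$ the upper-triangular weights, solve
   $$\min_{w \ge 0}\; 2 z^\top w - \alpha\, \mathbf{1}^\top \log(S w)
     + \beta \lVert w \rVert^2,$$
   where $S w$ is the weighted degree vector. The log barrier keeps every
   node connected; the linear term links nodes whose signals co-vary. The
   solver is a forward–backward–forward primal–dual scheme whose two
   proximal maps are closed-form (a shifted nonnegative clip, and the
   positive root of a quadratic for the degree barrier); step size
   $0.9 / (2\beta + \sqrt{2(n-1)})$. Distances are z-scored per row
   (amplitude differs enormously across CF; without standardization the
   graph would encode loudness, not co-variation) and divided by their
   off-diagonal mean, which makes $\alpha = 1$ scale-free. Default
   $\beta = 0.5$: at $\beta = 0$ the solution on these signals collapses
   to a near-path graph (no triangles, clustering pinned at zero) and the
   objective is unbounded whenever two rows coincide; a modest Frobenius
   ridge spreads weight over near-tied candidate edges. Convergence is
   declared at relative iterate change below `tol` (default 1e-8 for
   analysis, 1e-6 in the orchestrated experiments); non-convergence
   returns the last feasible proximal point with a warning, never an
   invalid matrix.
2. **Correlation** — Pearson correlation between node rows, negatives
   clipped to zero (Laplacian filtering needs nonnegative weights; the
   absolute-value variant is deliberately not the default).
3. **Frequency** — $1/|f_i - f_j|$, max-normalized to 1.
4. **Linear** — the traditional tonotopic path, unit weights.

`threshold_to_density()` keeps the top `floor(d * n(n-1)/2)` edges (ties
broken toward lower node indices, so thresholding is deterministic); by
default it is used for display at density 0.25 only, and all metrics are
computed on the full weighted graphs (a config switch thresholds first).

## Metrics

Communities come from seeded weighted Louvain; modularity is the standard
weighted $Q$. Global efficiency uses shortest paths with edge length
$1/\text{weight}$ — weights are similarities, so strong edges are short —
and unreachable pairs contribute zero. Average clustering is the
geometric-mean (Onnela-type) weighted coefficient on max-normalized
weights; the Barrat alternative, which is insensitive to weight
dispersion, is intentionally not used. Density counts strictly positive
edges. Severity associations are Pearson correlations against PTA;
categorical demographics use one-way ANOVA instead (no r is defined).

## Denoising

Graph-Fourier-transform filtering uses the Tikhonov kernel
$h(\lambda) = 1/(1 + \tau \lambda)$, i.e.
$\hat{x} = \arg\min_x \lVert x - y \rVert^2 + \tau\, x^\top L x$ — the
canonical low-pass consistent with the smoothness assumption under which
the graph was learned. The benchmark adds seeded white noise at controlled
SNR to each scalar graph signal (noise is added to the length-100 graph
signals, not to the audio, because filtering happens on the graph), filters
with every graph, and scores per-signal RMSE against the clean signal;
noise realizations are shared across graphs so comparisons are paired, and
Welch (unequal-variance) two-sample t-tests compare RMSE distributions per
method pair and SNR — the RMSE spreads of different graphs differ too much
for a pooled-variance test.

The default is one *shared* $\tau = 1$ for all graphs. An oracle mode
(per graph and SNR, pick the $\tau$ minimizing held-out RMSE on 10% of the
signals, then score on the rest) is available for fairness when weight
scales differ; note that under oracle selection every connected graph
converges to the same large-$\tau$ limit — projection onto its Laplacian
kernel, i.e. the signal mean — so the cross-method contrast at very low
SNR is intrinsically a shared-$\tau$ phenomenon.

Eigendecomposition is dense (`eigen(symmetric = TRUE)`) — exact and cheap
at $n = 100$; eigenvalues are clipped at zero from below to absorb
round-off on the PSD cone.

# Problem sizes and numerical choices

The packaged experiments run at 100 nodes with 200-stimulus signal
matrices, SNRs $\{-15, -10, -5, 0, 5\}$ dB with 3 noise replicates, and
100-patient cohorts over 10 cohort seeds; the acceptance script uses the
full 1,000-stimulus corpus. These sizes were chosen so that the full
analysis suite completes comfortably on a single CPU while leaving the
statistical conclusions unambiguous. Degenerate inputs fail loudly:
zero-variance signal rows, duplicate CFs, zero-power signals for SNR,
edgeless graphs for community detection, and identical-row instances with
$\beta = 0$ (where the learning objective is unbounded) are all rejected
with named errors. The cohort pipeline excludes and reports patients whose
graph learning fails rather than dropping them silently.

# What the synthetic data can and cannot show

The generator emulates the *study conditions* — tonotopically tuned,
level-dependent responses from 100 nodes to a varied seeded corpus, and a
cohort spanning normal hearing to profound loss — not any particular
cochlea. Known divergences from real data, beyond those noted above: the
simulated signals are considerably smoother along the tonotopic axis than
phenomenological IHC models produce, which flatters local (path-based)
smoothing in the denoising benchmark; audiogram-independent mechanisms of
real hearing loss (dead regions, neural pathology) are absent; and the
cohort's audiogram shapes and demographics are stylized. Sign patterns and
ordering results transfer; absolute RMSE values and correlation magnitudes
should not be expected to.

# Known limitations

* The periphery has no spiking stage, no adaptation and no efferent
  feedback; graph signals are time-means, so all temporal fine structure
  is discarded by design.
* Graphs are static; time-varying graph learning is out of scope.
* The frequency graph's $1/|\Delta f|$ weights span three decades on a
  log-spaced CF grid, so under a shared $\tau$ its basal half is
  effectively unfiltered — a structural property of that construction, not
  a solver artifact.
* Louvain is greedy; modularity values are lower bounds on the optimum,
  made reproducible by seeding rather than exhaustive search.
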