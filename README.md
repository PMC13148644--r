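# cochleagraph

Graph signal processing of cochlear sound encoding.

The cochlea performs a time–frequency decomposition of sound: thousands of
inner hair cells (IHCs), laid out tonotopically from high-frequency base to
low-frequency apex, each transduce one band of an incoming waveform.
Classical models simulate those responses one cell at a time; they say
nothing about the *functional relationships between cells* across many
stimuli. `cochleagraph` closes that gap for auditory and network
neuroscientists: it represents the cochlea as a weighted functional graph
whose nodes are tonotopically mapped IHCs and whose **graph signals** are
sound-evoked scalar responses, then asks what the graph's structure does
for hearing — and what hearing loss does to the graph.

## The core model

Given a node × stimulus signal matrix, functional links are inferred four
ways:

1. **Smooth-signal graph learning** — with `z` the pairwise squared
   distances between standardized node responses and `w` the edge weights,
   solve the log-degree-barrier problem

   ```
   min_{w ≥ 0}  2 zᵀw − α 1ᵀ log(Sw) + β‖w‖²
   ```

   (`Sw` = weighted degrees) by a forward–backward–forward primal–dual
   scheme with closed-form proximal maps;
2. **Correlation** — Pearson correlation between node responses, negatives
   clipped;
3. **Frequency** — inverse characteristic-frequency difference `1/|Δf|`,
   max-normalized;
4. **Linear** — the traditional tonotopic path.

Graphs are compared by weighted modularity (seeded Louvain), number of
modules, Onnela weighted clustering, global efficiency (`1/weight` edge
lengths), and edge density, and by how well each graph denoises cochlear
signals with the Tikhonov graph filter `h(λ) = 1/(1 + τλ)` in the
Laplacian eigenbasis (RMSE against the clean signal; Welch t-tests between
methods). Clinical audiograms map to per-node performance factors
(`10^(−HL/40)`), and a synthetic audiogram cohort generator supports
severity-versus-graph-structure studies in the style of a 224-patient
clinical analysis. A lightweight gammatone-based periphery simulator
(tonotopic tuning + rectification + membrane low-pass + compression)
stands in for heavyweight phenomenological models.

## Worked example

```r
library(cochleagraph)

map <- build_tonotopic_map(100)                 # 20 Hz (apex) to 20 kHz (base)
set <- generate_stimulus_set(200, seed = 101)   # tones, complexes, noise bands
X   <- build_signal_matrix(set, map)            # 100 x 200 graph signals
g   <- learn_graph_smooth(X, map = map)
g
#> Cochlea graph [gsp_learned]: 100 nodes, 320 edges (density 0.065), total weight 135

graph_metrics(g, seed = 404)
#>      density modularity n_modules global_efficiency avg_clustering
#> 1 0.06464646  0.7952552        10        0.07151416      0.3572013
```

The learned graph links each IHC to tonotopic neighbors plus cross-cochlea
partners that co-vary across stimuli, organized into 10 frequency modules
with high modularity (Q = 0.80). How much does that mesh structure help
against noise, compared with the traditional linear chain?

```r
graphs <- list(gsp_learned = g, linear = linear_graph(map))
res <- snr_sweep_experiment(graphs, X, snrs = c(-10, 0), tau = 1, seed = 202)
res
#> Denoising result: 2 methods x 2 SNRs (fixed tau)
#>       method snr_db   mean_rmse     sd_rmse
#>  gsp_learned    -10 0.015143115 0.014270500
#>  gsp_learned      0 0.005579280 0.005369335
#>       linear    -10 0.019161550 0.017845050
#>       linear      0 0.006267107 0.005959424
```

At −10 dB SNR the learned mesh filters the same noisy signals to a 21%
lower error than the linear path (0.0151 vs 0.0192), and the advantage
shrinks as the noise does — mesh topology matters most when hearing is
hard. `res$tests` holds the per-SNR Welch p-values.

For hearing loss, `performance_profile()` converts any audiogram to
per-node factors, `run_cohort_analysis()` runs the full synthetic-cohort
study (audiograms → impaired signal matrices → learned graphs → metric ~
severity correlations), and `run_denoising_benchmark()` orchestrates the
four-graph SNR sweep. A command-line front end with `simulate`,
`build-graph`, `analyze`, `denoise` and `cohort` subcommands is installed
at `inst/cli/cochleagraph.R`.

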