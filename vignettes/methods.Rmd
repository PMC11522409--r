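---
title: "Methods: from raw MEA voltages to feedforward propagation statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from raw MEA voltages to feedforward propagation statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meacircuit)
```

# The experimental system

`meacircuit` analyses extracellular recordings from *engineered multinodal
cultures*: four neural populations — one cortical node (`C`) and three
hippocampal nodes (`H1`, `H2`, `H3`) — grown in separate compartments of a
microfluidic chip on top of a microelectrode array (MEA), connected in a chain
by microtunnels that admit axons predominantly in one direction. The design
imposes a *feedforward* anatomy, `C → H1 → H2 → H3`, and the central
scientific question is whether spontaneous and evoked activity actually
propagates along it, how reliably, and how perturbations (such as amyloid-β
exposure of the cortical node) change that propagation.

The package covers the full chain from raw voltages to summary statistics:

1. filtering and artifact handling (`bandpass_notch_filter`,
   `salpa_subtract`, `blank_after_stimulus`);
2. spike detection (`detect_spikes`, PTSD);
3. burst and network-burst detection (`detect_bursts_table`,
   `detect_network_bursts`);
4. propagation classification (`classify_propagation`,
   `propagation_summary`);
5. synchrony and evoked dynamics (`coherence_index`, `compute_psth`);
6. functional connectivity and graph metrics (`correlation_matrices`,
   `graph_summary`);
7. fluorescent particle quantification for the perturbation assay
   (`quantify_particles`);
8. statistics (`exact_ranksum_p`, `group_summary`);
9. a ground-truth generator (`simulate_spike_trains`,
   `render_raw_signal`, `make_particle_phantom`) used to validate all of the
   above.

# Preprocessing

Signals are sampled at 25 kHz (microvolts). Each channel is band-pass
filtered with a 4th-order Butterworth design at 300–3000 Hz plus a 50 Hz
biquad notch (Q = 30), both applied forward–backward so the filter is
zero-phase and spike times are not displaced. Edge transients are controlled
by odd-reflection padding (up to 1 s). The quoted corner frequencies are the
single-pass −3 dB points; the two-pass application squares the magnitude
response.

For stimulation recordings, each stimulus is followed by a large, slow
saturating transient. `salpa_subtract` implements the local-polynomial
artifact suppression idea: within a 300 ms post-stimulus epoch, a cubic is
fitted in a sliding 6 ms window (a Savitzky–Golay filter, which *is* the
sliding local least-squares polynomial fit) and subtracted; subtraction stops
once the fitted artifact has remained inside a noise band for a full window
(the fit-and-test rule), so late spikes ride on an untouched trace. Samples
pegged at the amplifier rails are bridged by linear interpolation before
fitting. The first 15 ms after every stimulus are blanked (spikes removed,
samples zeroed) and the blanks recorded as masked intervals, which all
firing-rate denominators respect.

# Spike detection (PTSD)

The *precise timing spike detection* algorithm scans the filtered trace for
pairs of opposite-sign local extrema separated by at most the *peak lifetime*
(1 ms) whose peak-to-peak excursion reaches `k` noise standard deviations
(`k = 9` for embryonic cultures; 7.5 is the usual choice for adult tissue).
The spike is timestamped at the larger-magnitude extremum, both polarities are
admitted, and a 1.6 ms refractory period suppresses double counts. The noise
SD is the scaled median absolute deviation, which is nearly unaffected by the
spikes themselves. The scan is implemented in C++ (`src/ptsd.cpp`) and is
exact — no windowed approximations.

# Bursts, network bursts and propagation

Single-electrode bursts use the *logISI* method: the histogram of
log10(inter-spike intervals) at 10 bins per decade is smoothed with a 3-bin
moving average; the tallest peak below 100 ms is the intra-burst peak, and the
first histogram minimum after it whose *void parameter*
\(1 - h_{min}/\sqrt{h_{p1} h_{p2}}\) reaches 0.7 sets the ISI threshold,
capped at 100 ms (unimodal histograms fall back to the cap). A burst is a
maximal run of at least 4 spikes with all ISIs at or below the threshold.

Network bursts pool all electrode-burst onsets and apply the same histogram
machinery to the inter-onset intervals (*logIBEI*), grouping contiguous
bursts. A group qualifies when it involves at least
`ceiling(0.10 × n_active)` distinct electrodes, where an electrode is active
at ≥ 0.1 Hz; qualifying groups with overlapping spans are merged so network
bursts never overlap.

Each network burst gets a per-node onset (earliest burst start among the
node's electrodes; microtunnel electrodes are never part of node aggregates).
The *initiation node* is the earliest node (sub-sample ties resolve upstream),
and the *span* is the length of the longest chain of consecutive downstream
nodes with strictly increasing onsets. A burst that initiates in `C` and
spans all four nodes is *feedforward*; the fraction of such events is the
headline propagation statistic.

# Synchrony, connectivity and evoked responses

The *coherence index* is the sample SD over mean of the pooled spike counts in
50 ms bins — 0 for perfectly steady firing and \(\sqrt{M}\) when all spikes
fall into one of `M` bins, with no dependence on overall rate.

Functional connectivity bins each train at 50 ms and takes, for each pair,
the maximum over lags up to ±10 bins of
\(r(l) = \sum_t x_t y_{t+l} / \sqrt{\sum x^2 \sum y^2}\). No mean is
subtracted, so autocorrelations are exactly 1 at lag 0 and ties are broken
toward the smallest |lag|, then the negative lag. The node-level 4×4 matrix
holds mean within-node pairwise coefficients on the diagonal and the
pooled-train maxima off it. Coefficients below 0.1 are discarded; the
surviving weighted graph is summarised by Louvain communities (best of 100
seeded restarts, reported with the weighted modularity `Q`) and weighted
pagerank (damping 0.85).

Evoked activity is summarised as a per-node PSTH: spike counts in 20 ms bins
over 300 ms after each of the stimuli, with across-trial mean and SD per bin.

# Particle quantification

Fluorescence micrographs of labelled aggregates are thresholded with Kapur's
maximum-entropy criterion over the 256-level histogram (16-bit inputs are
min–max rescaled to 8-bit first), touching blobs are split with a
distance-transform watershed, and regions are converted to equivalent
circular diameters \(2\sqrt{A/\pi}\) at 2803/2046 ≈ 1.37 µm/px. Particles
are retained only if strictly larger than 5 µm, the cut used to reject
antibody precipitate. One geometric caveat: disks smaller than ~10 µm that
touch rasterise with a *flat* distance-transform ridge at this calibration,
so no watershed — including the original ImageJ one — can split them; the
shipped fixtures use 16 µm disks for the splitting behaviour.

# The synthetic generator

`simulate_spike_trains` is the package's ground-truth engine, and its
defaults are the reference operating point of every seeded experiment in the
test-suite:

| parameter | default | rationale |
|---|---|---|
| `nb_rate` | 6 /min/node | spontaneous network-burst rate of a mature culture |
| `p_tx` | 0.62 | per-hop transmission; 0.62³ ≈ 0.24 of cortical events span all four nodes, the proportion typical of mature controls |
| `hop_delay`, `hop_jitter` | 20 ms, 5 ms | node-to-node onset delay through a microtunnel |
| `participation_prob` | 0.75 | electrodes of a reached node joining the event |
| `spikes_per_burst_mean` | 8 | spikes per electrode burst (≥ 4 always) |
| `intra_burst_isi_mean`, `intra_burst_isi_min` | 10 ms, 2 ms | intra-burst ISIs; the 2 ms floor reflects neuronal refractoriness and keeps ground-truth trains resolvable by a detector with a 1.6 ms dead time |
| `onset_jitter` | 5 ms | per-electrode burst-onset scatter within a node |
| `tonic_rate` | 1 Hz | asynchronous background firing |
| `init_nodes` | all four | which nodes spontaneously initiate events |
| `perturbation = "abeta"` | rate ×2 in `C`, `p_tx` ×0.6 | reproduces the two reported perturbation effects; any synchrony change is emergent, not injected |

Events are Poisson per initiating node, hop downstream with probability
`p_tx` per tunnel, recruit a Bernoulli subset of each reached node's
electrodes into short bursts, and ride on top of tonic background spikes
(thinned within 0.5 ms of burst spikes so ground truth stays unambiguous).
The generator returns the complete truth — event records with per-node
onsets, burst intervals and per-electrode spike times — so every analysis
stage can be scored exactly. `render_raw_signal` turns any spike table into a
raw voltage recording (biphasic 0.6 ms trough-to-peak templates on Gaussian
noise, optional exponential stimulation artifacts) for testing the
filtering/detection front end.

The generator emulates the *statistical structure* of multinodal bursting; it
does not model subthreshold dynamics, electrode drift, waveform diversity, or
bursting-rate non-stationarity over development.

## Interactions worth knowing about

Two method properties surfaced while validating parameter recovery, and both
are inherent to the published definitions rather than implementation choices:

- **Pre-burst background spikes extend bursts.** A tonic spike within one ISI
  threshold (up to 100 ms) before a burst's first spike is absorbed into the
  burst by the maximal-run rule, pulling the burst onset — and hence the node
  onset of a network burst — earlier. With appreciable background rates this
  occasionally breaks the strictly-increasing onset chain and downgrades the
  measured span.
- **Nearby events merge.** Network bursts are non-overlapping by definition,
  so independent events closer than their own duration are merged and
  classified as one event.

Propagation studies that need a clean estimate of `p_tx` should therefore
simulate with `init_nodes = "C"` and low (or zero) `tonic_rate`, which is
exactly what the package's own acceptance fixtures do.

# Numerical conventions

- Time is seconds everywhere; sample indices are 0-based, so sample `i`
  covers `[i/fs, (i+1)/fs)`; all binning is half-open `[t, t + bin)`.
- Every stochastic routine (simulator, renderer, Louvain restarts) draws from
  a private RNG stream seeded by an explicit argument and restores the
  caller's RNG state, so `run_pipeline` output is byte-identical across runs
  at a fixed seed.
- The exact rank-sum p-value is the enumeration tail probability
  `P(|W − μ| ≥ observed)` over all `choose(na + nb, na)` rank assignments,
  which matches `wilcox.test(exact = TRUE)` for tie-free data; ties fall back
  to a flagged normal approximation with tie and continuity corrections.

# A complete run

```{r pipeline, eval = FALSE}
sim <- simulate_spike_trains(network_sim_config(seed = 1), duration = 120)
bundle <- run_pipeline(sim$table, analysis_config(), seed = 1)
bundle
write_results_bundle(bundle, "results.json")
```

The same chain is available from the shell:

```sh
meacircuit simulate --duration 120 --seed 1 --out spikes.csv
meacircuit run --spikes spikes.csv --seed 1 --out results.json
```
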