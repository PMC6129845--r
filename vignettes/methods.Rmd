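---
title: "Methods: cell-type-resolved activation sequences in preBötzinger complex imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-resolved activation sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

In transverse brainstem slices, the preBötzinger complex (preBötC) produces
rhythmic inspiratory bursts that can be recorded simultaneously as a local
field potential (LFP) and, with a bulk-loaded calcium indicator (OGB-1), as
somatic fluorescence transients of dozens of neurons at ~10 Hz frame rate.
Glycinergic and GABAergic identities are read out from genetically encoded
reporters (EGFP under the GlyT2 promoter, tdTomato under the GAD65
promoter), which spectrally overlap with the indicator and one another.
`prebotseq` implements the full analysis chain from raw movie + LFP to
per-cycle activation orders and cell-type-level timing statistics:

1. spectral unmixing of a 3-excitation x 3-emission reference stack into
   OGB-1 / EGFP / tdTomato abundance maps (non-negative factorization);
2. LFP conditioning: full-wave rectification, leaky integration
   (tau = 150 ms by default, the midpoint of the conventional 100–200 ms
   range), and anti-aliased resampling onto imaging frame times;
3. movie conditioning: per-pixel zero-phase Butterworth band-pass
   (0.025–1.5 Hz, order 3) plus a 3 x 3 spatial mean;
4. a per-pixel map of the maximum normalized cross-correlation (maxCC)
   against the integrated LFP over lags 0–40 frames, thresholded at 0.2 to
   place non-overlapping 7 x 7-pixel ROIs on inspiratory cells;
5. regular/irregular classification of each cell at a maxCC cutoff
   (automatic Otsu suggestion, manual override), combined with the marker
   flags into five types: R-Ex, R-Gly, Irr-Ex, Irr-Gly, Irr-Cotrans;
6. burst detection on the integrated LFP (amplitude and prominence above
   0.8 x the SD of the detrended trace), sigh exclusion;
7. per-(cell, cycle) activation timing (fluorescence peak within +/- 24
   frames of the LFP peak, above a noise criterion), the >= 50% cycle
   inclusion rule, activation orders and percent ranks (10% bins);
8. across-slice summaries (occupancy, cumulative curves, leader and early
   fractions, mean timings) with one-way ANOVA + Tukey HSD on per-slice
   values and pairwise two-sample KS tests.

Because no raw recordings of this kind are publicly deposited, the package
ships a first-class synthetic-recording generator with complete ground
truth; every stage is validated by parameter recovery against it.

# The synthetic generator and its defaults

`default_paper_like_config()` encodes the study conditions the analysis
assumes. These values were chosen once, from the published phenomenology,
and are not tuned per run:

* **Cells.** 30 rhythmic cells proportioned like the pooled composition of
  the five published slices (10 R-Ex, 4 R-Gly, 10 Irr-Ex, 4 Irr-Gly,
  2 Irr-Cotrans) plus 6 non-rhythmic OGB-1-only distractors, placed
  uniformly at random with a minimum Chebyshev separation of 8 px in an
  80 x 80 px field (1 µm/px). Somata are disks of radius 3 px with a
  Gaussian shoulder, matching the 7 x 7 ROI scale.
* **Rhythm.** 120 bursts at 5 ± 0.8 s intervals (~10-minute recording);
  each burst is a Gaussian envelope (SD 150 ms) carrying broadband noise in
  the 10 kHz LFP channel. A sigh occurs with probability 1/20 per burst:
  its LFP envelope and calcium amplitudes scale by 2.5 and a second calcium
  peak follows 600 ms later (doublet).
* **Timing.** Per-type calcium-peak offsets relative to the burst envelope
  center are Gaussian with means 225 / 170 / 102 / 81 / 290 ms
  (R-Ex / R-Gly / Irr-Ex / Irr-Gly / Irr-Cotrans) and SDs 350 / 350 / 450 /
  450 / 400 ms. The means follow the reported per-type averages; R-Gly, for
  which no average is reported, is placed between the irregular types and
  R-Ex because regular glycinergic cells are described as recruited before
  R-Ex. The cycle-to-cycle SDs are back-solved from the reported fractions of
  activations occurring at or before the LFP peak (e.g. ~42% for Irr-Ex
  with a +102 ms mean implies a SD near 0.5 s).
* **Reliability and amplitude.** Regular types activate with p = 0.95 per
  cycle at amplitude 8 ± 1.5 (a.u.); irregular types with p = 0.6 at
  3.5 ± 0.8, on imaging noise of SD 1 — irregular cells are therefore
  detectable at the 0.2 maxCC threshold but fall below the
  regular/irregular cutoff, reproducing the reported dichotomy between
  large reliable transients and small, brief, cycle-skipping ones.
* **Calcium kernel.** Double exponential, 80 ms rise / 1000 ms decay,
  typical of OGB-1 somatic transients at this frame rate.
* **Spectra.** A fixed 9 x 3 mixing matrix (channels = 3 excitations x 3
  emission bands) with spectroscopically sensible entries: OGB-1 and EGFP
  emit in the green bands with different optimal excitation wavelengths;
  tdTomato emits only in the red band but has appreciable short-wavelength
  (S0→S2) two-photon excitation. EGFP is painted on glycinergic and
  co-transmitting cells, tdTomato on co-transmitting cells, OGB-1
  everywhere (plus a 0.05 neuropil background). Stack noise is a folded
  Gaussian of SD 0.02.

What the generator does **not** emulate: motion artifacts, photon-physics
noise (noise is Gaussian per pixel), neuropil contamination of ROI traces,
slow photobleaching, burstlets as distinct low-amplitude LFP events, and
any network mechanism behind the timing differences (offsets are drawn
independently per cycle). Passing recovery tests therefore demonstrates
that the analysis correctly measures what the generator encodes — not that
it is robust to every artifact of real two-photon data.

## Timing conventions

Ground-truth burst times are the centers of the LFP burst envelopes, and
each active cell's kernel peaks at `center + offset`. Rectify-integrate
delays the measured LFP peak by roughly the integrator time constant
(~1 frame), while the zero-phase band-pass shifts the asymmetric calcium
transient's sampled peak by a similar amount; the two delays largely cancel
in the reported timing difference, which is why recovered timings are
nearly unbiased (mean absolute error well under one frame at 10 Hz). This
cancellation was verified numerically before the conventions were frozen.

# Numerical choices

* **Zero-phase movie filter.** The band-pass is applied as the exact
  squared-magnitude response of the order-3 Butterworth high-pass/low-pass
  cascade in the frequency domain, after odd-symmetric reflective padding
  of one low-cut period per end (padded length rounded up to a 2-3-5-smooth
  FFT size). At a 0.025 Hz band edge the equivalent recursion has a memory
  comparable to the whole recording, so forward–backward filtering cannot
  be made acceptably edge-clean by padding; the spectral form is strictly
  zero-phase, exactly linear and exactly time-reversal symmetric, which the
  test suite asserts to machine precision. The per-pixel temporal mean is
  subtracted so the output is exactly DC-free.
* **Resampling the integrated LFP.** A zero-phase Chebyshev Type I
  low-pass of order 8 (0.05 dB ripple, DC gain normalized to exactly 1) at
  0.8 x (frame rate / 2), applied as staged decimation with per-stage ratio
  <= 10 — a single stage at a 1000x ratio is numerically unstable (poles
  collapse onto the unit circle). Frame samples are linearly interpolated
  at the recorded trigger times.
* **Detrending.** A 10 s moving median is subtracted before the burst SD
  is computed; the median preserves burst peaks while tracking drift.
* **Burst peaks.** Local maxima must exceed 0.8 x SD(detrended) in both
  amplitude and topographic prominence; the prominence requirement rejects
  noise ripples riding on burst shoulders, standing in for the visual
  confirmation used with real data. Peaks closer than 1 s keep the larger.
* **Sighs.** Flagged at amplitude > 2 x the median burst amplitude (the
  source describes sighs qualitatively; the factor is configurable), and
  excluded from sequence analysis rather than silently dropped.
* **ROI splitting.** Candidate centers are all regional maxCC maxima
  inside suprathreshold 8-connected components of area >= 9 px — adjacent
  cells merge into one component at threshold 0.2, so one-peak-per-
  component undercounts. Each candidate is re-centered on the
  suprathreshold-weighted centroid of its plateau (the maxCC blob is flat
  across a soma). Greedy acceptance by descending maxCC with a 7 px
  Chebyshev exclusion radius then guarantees non-overlapping 7 x 7 windows.
* **Cutoff suggestion.** Otsu's between-class variance maximization on the
  detected cells' maxCC sample, clamped to [0.40, 0.70] with a warning
  (empirical cutoffs are expected around 0.47–0.64 and depend on burst
  count and noise); a manual override is first-class. With fewer than 6
  cells the function refuses and asks for a manual value.
* **Activation noise rule.** "Above noise" is operationalized as
  3 x 1.4826 x MAD of the cell's inter-burst samples (frames farther than
  24 from every accepted burst peak). Ties in timing break by cell id; tie
  counts are recorded.
* **Percent-rank denominator.** Ranks are normalized by the number of
  cells activated in that cycle (position i of N activated gets 100·i/N),
  the reading that makes cycles with different numbers of active cells
  comparable. Normalizing by the slice's total cell count is a defensible
  alternative convention; it changes only the scale of the bins and can be
  obtained by rescaling `rank` in the `ranked` table.
* **Unmixing.** Matrix NMF (multiplicative updates, Frobenius objective,
  five seeded restarts, the first warm-started at the expected signatures)
  on the 9 x pixels unfolding — with three fluorophores and nine channels
  this flattening loses nothing relative to a multi-way decomposition. A
  per-channel dark level (the channel median) is subtracted first; without
  it the nonnegative noise floor is absorbed by the sparsest component
  (tdTomato) and corrupts its abundance map. Components are assigned to
  fluorophores by greedy cosine matching, resolving NMF's permutation
  ambiguity. Marker flags compare the mean abundance in a 7 x 7 ROI with
  the background mean + 2 SD (background = pixels outside all ROIs); the
  original cells were classified visually, so this numeric rule is the
  package's own.
* **ANOVA unit of analysis.** Tests across cell types run on per-slice
  summary values (n = number of slices), not pooled activations, matching
  how such data are summarized as mean ± SE across slices. The KS family
  is reported without multiple-testing correction by default (raw pairwise
  p-values), with Holm available.

# Problem sizes

Unit tests run on compact recordings (56 px field, ~13 cells, 24 bursts,
~130 s) that preserve every structural property of the full configuration.
The acceptance suite and `scripts/acceptance.R` run five full-scale slices
(80 px, 36 cells, 120 bursts, ~10 min of simulated time each, seeds 1–5 by
default); this batch completes in roughly 7 minutes on one CPU and is the
package's reference problem size. The ANOVA type-I rate is estimated from
1000 null replicates of five groups x five slices.

# Known limitations

* At ~10 Hz the fluorescence peak is a coarse proxy for spike timing —
  far too slow to resolve transient onsets — so onset detection is
  deliberately out of scope and no sub-frame interpolation is attempted.
* The Otsu cutoff assumes the maxCC sample is roughly bimodal; short
  recordings (few bursts) shrink the regular/irregular gap and lower
  classification accuracy, which the compact test fixture makes visible.
* Percent-rank occupancy in sparsely populated bins is noisy for rare
  types (Irr-Cotrans contributes two cells per synthetic slice).
* The generator's independence assumptions (offsets independent across
  cells and cycles) make the sequence statistics better-behaved than real
  data, where correlated network state could widen the across-slice SE.
* The small mean-timing gap between Irr-Gly and Irr-Ex (21 ms at
  cycle-to-cycle SDs of ~0.45 s) is near the resolution limit of a
  five-slice batch; its recovered ordering is reproducible under the
  default seeds but is the least robust of the ordering relations.
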