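---
title: "NMF-based front-ends for acoustic bird species classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NMF-based front-ends for acoustic bird species classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(birdnmf)
```

## The problem

Acoustic bird species classification (ABSC) assigns a species label to a
field recording of bird vocalizations. Conventional front-ends borrow
mel-frequency cepstral coefficients (MFCC) from speech processing, but the
mel scale encodes the human auditory system: bird vocalizations concentrate
their energy between roughly 1 and 10.5 kHz, with narrow, species-specific
spectral structure that mel filters average away. This package implements
two front-ends that adapt the spectral analysis to the birds themselves by
non-negative decomposition of their spectrograms, plus everything around
them: syllable segmentation, temporal feature integration, and an SVM
evaluation harness with per-recording majority voting.

## KL-NMF

Both front-ends rest on non-negative matrix factorization. A magnitude
spectrogram $V \in \mathbb{R}_+^{F \times T}$ is approximated as $V \approx
W H$ with $W \in \mathbb{R}_+^{F \times K}$ (spectral basis vectors, SBVs)
and $H \in \mathbb{R}_+^{K \times T}$ (activations), by minimizing the
generalized Kullback-Leibler divergence

$$D_{KL}(V \| WH) = \sum_{ij} \Big( V_{ij} \log \frac{V_{ij}}{(WH)_{ij}}
  - V_{ij} + (WH)_{ij} \Big),$$

with the convention $0 \log (0/x) = 0$. Optimization uses the classical
multiplicative updates

$$W \leftarrow W \otimes \frac{(V \oslash WH) H^T}{\mathbf{1} H^T},
  \qquad
  H \leftarrow H \otimes \frac{W^T (V \oslash WH)}{W^T \mathbf{1}},$$

which preserve non-negativity and never increase the divergence — a
property the test suite asserts on every step of randomly generated
problems. Initialization follows a multi-restart protocol: 10 random
non-negative $(W, H)$ pairs are drawn, the pair with the smallest
*Euclidean* (Frobenius) distance to $V$ is kept, and that pair is refined
by at most 200 KL update sweeps. The restart selection metric differs
deliberately from the optimized cost; it is part of the prescribed
protocol.

`nmfDecompose()` implements the full factorization, `inferActivations()`
the activation-only variant (fixed $W$, update $H$ only) used at feature
extraction time.

## The two front-ends

**NMF_CC (learned filter bank).** All training spectrograms are
concatenated column-wise and factorized with $K = 40$; the resulting basis
vectors, L1-normalized and sorted by peak frequency, replace the 40
triangular mel filters. Cepstral extraction is otherwise identical to
MFCC: filter-bank outputs, floored log, orthonormal DCT-II, coefficients
$C_1..C_{12}$ plus the frame log-energy — 13 features per frame, 26 with
deltas.

**H_CC + G_NMF (activation features).** Per species $i$, NMF with $K = 4$
learns class bases $W_i$; their concatenation $W_{bs}$ ($F \times KC$)
stays fixed while the activations $H_{bs}$ of a test spectrogram are
inferred. The features are the DCT of $H\_Log = \log(H_{bs} + 10^{-10})$,
keeping $C_1..C_{13}$, plus the maximum-gain term
$G\_NMF_t = \arg\max_k H_{bs}[k, t]$ — the 1-based index of the most
active SBV, stored as a real-valued feature — for 14 per frame. With 12
species the $H\_Log$ vector has $4 \times 12 = 48$ entries. The index
reading of $G\_NMF$ is implemented (ties resolve to the first index); the
"maximum value" reading is a plausible alternative but the index is what
carries class identity, since column blocks of $W_{bs}$ map to species.

Front-ends combine by frame-wise concatenation (e.g. NMF_CC + H_CC +
G_NMF = 27 features, 54 with deltas).

## Segmentation and temporal integration

Syllables — the fundamental vocalization units — are detected on the
per-frame maximum of the dB spectrogram by iterative peak-stripping: the
loudest remaining frame seeds a segment that extends while the trace stays
within 20 dB of its peak; detection stops when the loudest remaining frame
falls 20 dB below the global maximum. The 20 dB threshold is read relative
to the global spectrogram peak (the plausible alternative, a per-recording
noise floor, would require a noise estimator the procedure does not
define). Segments shorter than 3 frames (30 ms of analysis support) are
discarded as too short for stable statistics.

Each syllable's frame features are collapsed into one segmental vector by
computing the mean, standard deviation and skewness of every feature
column — population ($1/N$) variance and uncorrected moment skewness
$g_1 = m_3 / m_2^{3/2}$ (0 when $m_2 = 0$), the simplest conventions and
stable for short segments. The vector is statistic-major: all means, all
standard deviations, all skewnesses ($3 \times D$ values).

## Classification and evaluation

Segmental vectors are z-score normalized with training statistics and fed
to a one-vs-one RBF SVM (libsvm via e1071). The kernel parameters are
selected on a log2 grid ($C \in 2^{-3..7}$, $\gamma \in 2^{-7..3}$, steps
of 2) by stratified 5-fold inner cross-validation, ties going to the
smaller $C$ then the smaller $\gamma$. Decisions are made per syllable; a
recording receives the most frequent syllable label, ties going to the
class earliest in sorted order.

`kfoldEvaluate()` runs the stratified 6-fold outer protocol. Everything
learned — NMF filter bank, SBV models, feature normalizer, SVM
hyperparameters — is computed from the training folds only; the report
retains the fold index sets so leakage is checkable after the fact. Folds
are stratified by species: the reference protocol's "balanced groups"
reading. The confusion matrix has true classes in columns, normalized to
100% per column and averaged over folds.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `audio.rate` | 22050 Hz | analysis sampling rate |
| `audio.low/high` | 1000 / 10500 Hz | Butterworth band-pass edges |
| `audio.order` | 4 | Butterworth prototype order, applied forward-backward |
| `spectrogram.window/shift` | 20 / 10 ms | Hamming window and hop |
| `spectrogram.nFFT` | 512 | F = 257 bins at 22.05 kHz |
| `segmentation.thresholdDb` | 20 dB | pulse-detection threshold |
| `segmentation.minFrames` | 3 | minimum syllable length |
| `frontend.KFilterbank` | 40 | filters / SBVs in the learned bank |
| `frontend.KPerClass` | 4 | SBVs per species in the H_CC model |
| `nmf.nRestarts/maxIter/tol` | 10 / 200 / 1e-6 | NMF protocol |
| `nmf.maxFrames` | 4000 | training-frame cap for dictionary learning |
| `classifier.innerFolds` | 5 | SVM model-selection folds |
| `evaluation.folds` | 6 | outer cross-validation folds |

The spectrogram uses `nFFT = 512` (next power of two above the 441-sample
window, zero-padded). The NMF tolerance `1e-6` (relative KL change between
sweeps) supplies the early-stopping rule the 200-sweep cap implies but
does not fix. Dictionary learning subsamples at most `maxFrames = 4000`
training columns (seeded): a 40-atom dictionary is heavily overdetermined
by thousands of frames, and the cap keeps per-fold learning affordable
without affecting the learned filters materially.

## Numerical choices

- An epsilon floor of `1e-12` inside every division of the multiplicative
  updates prevents 0/0; a floor of `1e-10` before every log (filter-bank
  energies, H_Log) keeps silent frames finite. Zeros in $W$ or $H$ are
  structural: multiplicative updates cannot resurrect them.
- The DCT is the orthonormal type-II; $C_0$ (the overall level) is
  discarded for cepstra, which is why doubling the signal amplitude
  changes only the log-energy term.
- Random NMF initializations are scale-matched: entries in $(0, 1]$ scaled
  so $E[(WH)_{ij}]$ matches $\bar V$, which shortens burn-in.
- Deltas use the standard regression estimator over ±2 frames with edge
  replication.
- All randomness flows from a single integer seed through named child
  streams, so every stage is independently reproducible.
- The activation-only update is column-separable, so the evaluation
  harness infers the activations of all recordings in a fold in one
  batched call on their concatenated spectrograms (equivalent to
  per-recording inference up to the random start, and much faster); in
  the batched path the divergence is evaluated every 5 sweeps for the
  trace and the stopping rule, which leaves the updates untouched.

## The synthetic generator

`makeSyntheticDataset()` stands in for a curated field-recording
database. Each species is a chirp complex: syllables are linear chirps at
2 species-specific centre frequencies in the 1.5–10 kHz band (primary
centres evenly spaced, hence pairwise separated by ≥ 500 Hz), with
raised-cosine onset/offset ramps (15 ms), randomized durations
(80–180 ms), randomized inter-syllable gaps, and white noise at 30 dB
SNR. The default verification fixture is 4 species × 30 recordings × 3 s.
Difficulty is controllable: shrinking the inter-species frequency
separation provably degrades cross-validated accuracy (a test covers
separations of 2400, 300 and 80 Hz).

The generator emulates the features the pipeline depends on — repeated
in-band syllables, low-rank species signatures, silent gaps, broadband
noise — but not reverberation, overlapping soundscapes, other animals, or
recording-channel variation. Passing tests therefore demonstrate the
machinery is correct and discriminative where species differ spectrally;
they do not quantify robustness to real field conditions.

## Verification scale

The test suite and `scripts/acceptance.R` run the full 6-fold evaluation
on the default fixture (120 recordings, two NMF front-ends) plus
unit-scale NMF problems (e.g. planted dictionaries at F = 60, K = 5,
T = 150 over 10 seeds); these sizes give stable accuracies in minutes on
a single core. Accuracies on this clean, well-separated fixture sit near
the ceiling (≥ 90%) by design; they are a correctness check of the
pipeline, not an estimate of field performance.

## Known limitations

- The segmenter is a threshold model of "syllables as spectral pulses";
  it has no insertion/deletion guarantees on noisy recordings, and no
  gold-standard boundaries exist to tune it against.
- mp3 decoding is out of scope; the I/O contract is WAV (PCM 16/24/32-bit
  or float) plus a manifest CSV.
- Statistical comparison of front-ends (mixed-effects modeling of
  accuracies) is out of scope; the reports expose raw per-fold accuracies
  and confusion matrices for downstream analysis.
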