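---
title: "Detecting mouse song syllables and testing their syntax"
author: "usvsyntax"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mouse song syllables and testing their syntax}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usvsyntax)
```

Adult male mice produce ultrasonic vocalizations (USVs, roughly 35–125 kHz)
organized into song-like sequences whose composition and ordering change with
social context. This package implements the full analysis chain for such
recordings: syllable detection and classification from the waveform,
segmentation into song bouts, sequence summary statistics, and a two-stage
statistical comparison of first-order transition dynamics between groups of
animals or between contexts. A synthetic generator produces both symbolic
corpora and audio with exact ground truth, so that every stage is testable
without recordings.

## Syllable detection and classification

The acoustics stage mirrors the classic spectrogram-based pipeline for mouse
song. The waveform (sampling rate at least 250 kHz) is transformed in blocks
of 256 samples with half overlap, giving a frequency resolution of ~977 Hz
and a frame step of 0.512 ms. The sonogram is truncated to the 35–125 kHz
song band, a noise floor is estimated and zeroed, and runs of voiced frames
become syllables:

* frames with any surviving in-band power are *voiced*;
* voiced runs separated by silence shorter than 10 ms are merged (a syllable
  may contain brief amplitude dips);
* merged runs shorter than 3 ms are discarded.

Each syllable's per-frame peak frequency forms its *pitch track*. An
instantaneous *pitch jump* is a step of at least 10 kHz between consecutive
defined frames (runs of up to 3 missing frames are bridged, because jumps
often co-occur with brief amplitude dips; longer missing runs split the
syllable into notes across which no jump is scored). Syllables are labelled
**s** (no jumps), **u** (one upward jump), **d** (one downward jump), or
**m** (two or more jumps). Syllables with under half their frames defined, or
with spectral purity below 0.1 (broadband mechanical noise — scratching,
cage sounds), are labelled *unclassified* and removed from sequence analyses.

### Numerical choices

**Noise thresholding.** The threshold is per frequency row and robust:
on the log-power scale, cells below `median + 5 * MAD` of their row are
zeroed. Two details matter. First, the rule works on *log* power because
spectrogram noise power is approximately exponential; on the linear scale a
median+MAD rule leaves several percent of noise cells standing, which would
make "any surviving power" detection useless. Second, the MAD is one-sided —
estimated from deviations *below* the row median — so syllable energy in a
row cannot inflate that row's own threshold. A dynamic-range floor 80 dB
below the sonogram peak (with a 10 dB guard above it) suppresses numerical
residue in quiet recordings. The rule assumes that voicing occupies a
minority of each row's frames, which holds for real sessions (mostly
silence); a recording that is one wall-to-wall tone defeats any row-wise
noise estimate.

**Window.** The transform uses a rectangular window by default (Hann is
available in the configuration). The reason is the spectral-purity
definition below: a tapered window spreads even a perfectly bin-centred
tone's power across three bins, capping measured purity near 0.67, whereas
the field's convention is that a pure tone has purity 1. The cost of the
rectangular window is slower sidelobe decay for off-grid tones, which is why
the noise rule above must be robust to cross-row leakage.

**Spectral purity** is the per-frame power in the peak lobe (the peak bin
and its two neighbours — a tone's footprint at the transform's resolution)
divided by the total in-band power, averaged over the syllable's defined
frames; 1 for a pure tone, near 0 for broadband noise. Peak and total power
come from the *raw* band-limited power, not the thresholded power —
thresholding a noise burst leaves only its outlier cells, which would push
its purity toward 1 and invert the statistic's meaning. Purity of very short
syllables is slightly diluted by the two boundary frames whose blocks
straddle the syllable edge; a 100 ms pure tone measures ~0.995.

**Timing.** Reported onsets and offsets are the centres of the first and
last voiced frames. Voicing spreads about half a frame beyond the true
edges of a sound (a block partially overlapping the syllable is already
voiced), so frame centres are the unbiased boundary estimate; on synthetic
audio at SNR 30 dB boundaries are recovered well within one frame step.

**Amplitude** is mean in-band power in dB relative to a full-scale
bin-centred sine, since WAV amplitude is dimensionless.
**Frequency modulation** is the range (max − min) of the pitch track.

## Sequences and summary statistics

Classified syllables are segmented into song bouts: a new sequence starts at
every inter-syllable interval of 250 ms or more (a gap exactly at the
threshold splits). Unclassified syllables are deleted *before* gap
computation, so a removed noise event cannot break an otherwise continuous
bout. Sequences of one or two syllables are kept everywhere except the
complex/simple ratio, which by definition counts, among sequences of three
or more syllables, those with at least two "m" syllables against those with
at most one. Summaries per session: syllable rate (syllables/min),
repertoire proportions over s/d/u/m, syllables per sequence, and the
complex/simple ratio; across animals, sequence length and rate are
correlated by Spearman's rank correlation with mid-ranks.

## Transition statistics and the two-stage test

Every sequence `a1...aL` is bracketed by silence (state `X`), contributing
transitions `X→a1`, the internal pairs, and `aL→X` — L+1 in total. Over the
five states {s, d, u, m, X} this yields 24 observable transition types
(silence-to-silence cannot occur). Conditional probabilities are
row-normalized counts: the probability of a transition given its starting
state. Group-level matrices average animals cellwise, excluding per row the
animals that never produced that start state.

Whether transition dynamics differ between two groups (or two contexts of
the same animals) is tested in two stages:

1. **Local tests.** For each of the 24 transition types, a two-sided rank
   test on the per-animal probabilities: Wilcoxon-Mann-Whitney between
   groups, Wilcoxon signed-rank between contexts (zero differences dropped).
   Tests are exact by enumeration — with mid-ranks under ties — up to a
   combined sample size of 12, and use the normal approximation with tie and
   continuity correction beyond. Types with fewer than two usable values are
   marked missing.

2. **Combination and permutation null.** Local p-values are combined by the
   truncated product method: `W` is the product of the p-values at or below
   `tau` (default 0.05, the canonical truncation point; `tau = 1` recovers
   Fisher's method). `W` is computed for eleven targets: transitions *to*
   each state (columns), *from* each state (rows), and all 24 globally.
   Because the 24 local tests share animals, `W`'s null distribution is not
   the independence one; it is estimated by Monte Carlo permutation with the
   *animal* as the unit — all 24 of an animal's probabilities move together
   under a group-label shuffle (two-sample) or an independent within-animal
   context swap (paired). The reported p-value is `(1 + #{W_perm ≤ W_obs}) /
   (1 + B)` with `B` = 10,000 by default, so p can never be zero. Transition
   types missing in the observed data are excluded from observed and
   permuted statistics alike, keeping the null aligned with the statistic
   actually computed. The ten margin p-values are Benjamini-Hochberg
   adjusted as one family; the single global p is reported unadjusted.

Under effect-free synthetic cohorts (8 animals/group, 200 sequences each)
the global test's empirical size at the 5% level is indistinguishable from
nominal, and a planted absolute shift of +0.25 toward silence is detected
essentially always, loading on the to-silence margin — the signature of a
group producing shorter sequences.

With `tau = 1` and genuinely independent local tests, the permutation p
converges to the closed-form Fisher (chi-square) p. The convergence is a
large-sample statement: at 8–10 animals per group the local p-values are
discrete and continuity-corrected, and the product's null is visibly off
chi-square; with 25 animals per group of independent values the two agree to
better than 0.02 on average. This is worth remembering when comparing the
permutation output against textbook combined tests.

## Syntax diagrams

Group-context probability matrices export to Graphviz DOT: nodes are the
four syllable types plus silence, edges are transitions with probability
*strictly above* 0.05 (common transitions, not rare events), pen width
proportional to probability. The statistics above always use all
transitions, including rare ones; the cutoff is purely presentational.
Whether published diagrams draw silence as one node or as separate
begin/end nodes varies, so both renderings are available
(`splitSilence = TRUE`).

## The synthetic generator

`sampleCohort()` emulates a two-group, multi-context study. Each group has a
first-order chain over the five states; per animal and context, every row is
drawn from a Dirichlet centred on the group row with concentration 50, which
gives per-animal standard deviations of a few percentage points — comparable
to animal-to-animal variability in real cohorts. Sequences are emitted by
Markov walks from silence to silence, so the L+1 transition identity holds
by construction (walks are capped at 200 syllables with a warning). Planted
effects act on the probability scale with proportional renormalization:
an additive shift toward silence (shorter sequences) and a multiplicative
suppression of transitions into "m" (less complex sequencing). The default
baseline chain has the topology commonly seen in wildtype males — sequences
start with "s"; "s", "d", "m" self-loop; "u" does not — but its values are
invented synthetic defaults, not measurements from any animal.

`synthWaveform()` renders note plans (constant-frequency plateaus with
raised-cosine ramps) into waveforms with additive white noise at a stated
SNR, returning exact onset/offset/label ground truth. What the synthetic
audio does *not* emulate: frequency sweeps within notes, harmonics,
amplitude modulation, reverberation, or competing vocalizers. Passing the
audio round-trip suite therefore demonstrates correctness of the detection
logic and its bookkeeping, not robustness to every property of real
recordings.

## Problem sizes used in the test suite

The shipped tests exercise the pipeline at sizes chosen to make their
statistical assertions sound: 500 effect-free replicates at 500 permutations
for the size check, 100 replicates for the power check, 20 cases at 10,000
permutations for the Fisher limit, 100 syllables of synthetic audio for the
round trip, and ~5×10^5 generated transitions for the law-of-large-numbers
check (enough that even the rarely visited "u" start state gets tens of
thousands of draws). Audio suites use 150 ms inter-syllable gaps, keeping
the voiced duty cycle realistic for a recording session and within the
stated assumption of the row-wise noise rule.

## Known limitations

* The first-order (Markov) transition model ignores longer-range structure;
  higher-order or hidden-state models are out of scope.
* The detector assumes a single vocalizer; overlapping animals produce
  merged or unclassified syllables.
* Row-wise noise estimation assumes syllables are sparse in time within
  each frequency row.
* The truncated product with `tau = 0.05` cannot register evidence from
  paired designs with fewer than ~6 animals, where the exact signed-rank
  test's smallest attainable p exceeds `tau`.

## A worked example

```{r example}
spec <- cohortSpec(nAnimals = 8, seqPerAnimal = 100,
                   toSilenceShift = c(wt = 0, het = 0.2))
cohort <- sampleCohort(spec, seed = 1)
mats <- lapply(cohort$corpora, function(g)
  lapply(g, function(a) conditionalProbabilities(transitionCounts(a$LF))))
result <- syntaxTest(mats$wt, mats$het, nPerm = 1000, seed = 2)
result
heatmapTable(result)
```
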