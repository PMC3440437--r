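---
title: "Counting-only neural decoding: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting-only neural decoding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikedecoder)
```

# The decoding problem

An implanted brain–machine interface must infer a behavioral state from
the spiking of a recorded neuronal population while dissipating almost no
power. `spikedecoder` models a two-unit architecture that splits the work:
an *internal* unit that reduces N spiking channels to K bits per time
window using nothing but counters and comparators, and an *external* unit
that learns the internal unit's program and cleans up its output with a
hidden-Markov smoother. The reference application is position decoding
from hippocampal place cells on a linear track, where each unit's roughly
Gaussian, unimodal receptive field makes a simple threshold rule a good
detector of "the animal is in my field".

# Internal unit: windowed counts and threshold templates

Spikes on each channel are counted in consecutive half-open windows
$[tW, (t+1)W)$ by saturating $b$-bit counters (counts clamp at $2^b - 1$;
they never wrap). A spike landing exactly on a boundary belongs to the
later window, matching the semantics of counters that reset synchronously
at the window edge.

The decoder's program is a set of templates, at most one per state by
default. Template $T_j$ stores up to $M$ (channel, threshold) pairs and
fires when **all** of its comparisons succeed:
$Y_j(t) = \prod_{(c,\theta)\in T_j} [x_c(t) \ge \theta]$. States may own
several templates (OR-combined), and a state whose template is empty
simply never fires — the smoother recovers such states through the
transition prior. The comparison is *attain-or-exceed* ($\ge$), used
identically during learning and decoding.

The same program is exactly a two-layer integrate-and-fire network: one
second-layer unit per template, wired to its channels with synaptic
weight $1/\theta$, integrating over the window and resetting at each
boundary. For the equivalence to be exact each synapse's contribution is
capped at 1 (`min(count/θ, 1)`), and the unit fires when the capped sum
reaches its synapse count — an uncapped weighted sum would let one very
active channel compensate for a silent one and would not implement
conjunction. Units with no synapses never fire, mirroring the empty
template rule. `emulate_if_network()` implements this construction and
the test suite holds it bit-identical to `decode()`.

# Learning the program

During a labeled training period the package accumulates, for each
(state $k$, channel $i$), histograms of window counts in-state
($H_{k,i}$) and out-of-state ($\bar H_{k,i}$); unlabeled windows are
excluded. For a candidate threshold $\theta$:

* sensitivity $= P(x_i \ge \theta \mid k)$, from $H$;
* specificity $= P(x_i < \theta \mid \neg k)$, from $\bar H$;
* PPV $=$ in-state mass $\ge\theta$ divided by total mass $\ge\theta$,
  under the empirical training occupancies (so PPV — unlike sensitivity
  and specificity — depends on how the training period sampled the
  states).

The selected threshold is the *lowest* $\theta \in 1..2^b-1$ with
sensitivity $\ge \sigma_{\min}$ and PPV $\ge \rho_{\min}$; if none
qualifies the channel contributes no rule. When no training mass reaches
$\theta$ on either side the PPV is undefined (NaN); the PPV constraint is
treated as vacuous only when $\rho_{\min} = 0$, so degenerate minima
behave as expected without ever letting an undefined PPV qualify under a
real constraint.

**Ranking the M channels.** Which qualifying channels are "most
informative" is genuinely open; the package ranks by PPV at the selected
threshold, breaking ties by sensitivity and then by lower channel index.
PPV is the quantity that directly limits the false-positive bits the
smoother must clean up, and the full ordering is deterministic. The
minima can be overridden per state (`per_state=`), supporting the usual
practice of tightening them until no template exceeds $M$ rules.

# External unit: confusion-matrix emissions and a diffusion prior

The smoother treats the discretized positions as hidden states of a
discrete-time Markov model observed through the decoder's K-bit output.

**Emissions.** $Q(j,k)$ is the fraction of training windows with bit $k$
set whose true state was $j$ (column-stochastic, Laplace pseudocount
$\varepsilon = 1$ by default so every emission is positive even for bits
that never fired in training). The emission probability of output row
$\mathbf y$ in state $j$ multiplies $Q(j,k)$ over the set bits,
treating bits as conditionally independent; an all-zero row has an empty
product, probability 1 for every state — silent windows are carried
entirely by the prior. Note that $Q(j,k)$ is a posterior
$P(j \mid y_k = 1)$ used as a per-bit likelihood factor; this
posterior-as-likelihood approximation is deliberate and keeps the
emission model estimable from a short training record.

**Transitions.** $P(j \to j') \propto \exp(-d(j,j')^2 / (2\kappa\tau))$,
row-normalized, with $d$ the physical distance between segment centers.
The package adopts the Gaussian kernel as the canonical diffusion form
(the config accepts an explicit distance matrix for other geometries).
$\tau$ is the elapsed time since the decoder last emitted a nonzero
word: it resets to one window at every informative window and grows by
$W$ per silent window, so uncertainty spreads while the decoder is
silent. $\tau$ enters in whole windows with minimum one.

Broadening here means exactly: the self-transition mass is non-increasing
in $\tau$, every row's entropy is non-decreasing, and far states gain
probability — not that every off-diagonal entry grows monotonically. A
nearest neighbor in fact *overshoots*: its probability rises while the
kernel width is below one segment, peaks, and then relaxes down toward
the uniform limit $1/K$. The tests assert the former, correct, set of
properties.

**Viterbi.** Standard log-space dynamic programming with backtracking,
uniform initial distribution (nothing is known about the starting
state), and argmax ties broken toward the smaller state index for
determinism. Per-step transition kernels are cached by their $\tau$
value. The suite checks optimality against exhaustive path enumeration
(all $K^T$ paths for $K \le 4$, $T \le 6$) and agreement between log and
probability domain scores to $10^{-10}$.

# Spike detection

For raw-waveform input the package provides single-threshold detection:
one event per upward crossing of the effective threshold, per polarity,
with refractory suppression (`dead_time`, default 1 ms). The per-channel
noise scale is the median absolute deviation scaled to Gaussian sigma —
a robust estimator unaffected by the sparse large deflections the spikes
themselves contribute. The default threshold is 4 times the noise scale
(a conventional confidence multiple; exposed in `detection_params()`),
and default polarity is negative, the extracellular convention.

# The synthetic place-cell scenario

Real tetrode recordings of the kind this decoder was demonstrated on are
not available, so the generator builds a controlled stand-in:

* 32 cells with Gaussian tuning curves (SD 0.15 m, peak 20 Hz, baseline
  0.5 Hz) tiling a 3.5 m track at segment midpoints — field widths and
  rates in the range typical of dorsal CA1 place fields;
* six constant-speed traversals (three per direction, the session
  structure of the original experiment) at 0.2 m/s mean speed with 10%
  per-traversal jitter, positions sampled at 100 Hz;
* inhomogeneous-Poisson spiking by thinning against each cell's peak
  rate;
* W = 250 ms, b = 3, M = 2, $\sigma_{\min} = 0.3$, $\rho_{\min} = 0.5$,
  $\kappa = 0.01\ \mathrm{m^2/s}$ (of order speed² × W for this
  locomotion), $\varepsilon = 1$.

Training uses the first traversal pair — one sweep in each direction, so
every state is visited from both sides — and evaluation uses the
remaining, strictly later, traversals (chronological split; templates
and $Q$ never see test data). For the leave-one-out robustness harness
each channel is replaced in turn by a rate-matched channel with uniform
random event times, the decoder is re-applied unchanged, and the
held-out correlation is recorded per channel.

What the generator does **not** emulate: theta-phase precession,
bursting and refractory structure, cross-channel noise correlations,
multi-unit contamination, field remapping between directions, and
nonstationary running speed within a traversal. Passing tests on this
fixture therefore demonstrate the correctness of the algorithmic chain
and realistic end-to-end behavior under Poisson place-field coding — not
performance on any particular animal's data.

A deliberate property of the default protocol is how *little* training
data it provides: about 145 windows across 32 states (≈4–5 in-state
windows per state). Threshold learning from such thin histograms is
noisy, and the held-out correlation varies substantially across random
realizations of the scenario; at the package's default seed the pipeline
decodes the held-out traversals at r ≈ 0.99, but individual seeds can do
considerably worse. Lengthening the training period (more traversals, or
slower traversals) stabilizes learning quickly; the default is kept
short because it mirrors the session structure the method was originally
demonstrated on.

# Resource models

Two closed-form models quantify why this architecture suits implants.
The compression factor is the raw acquisition bit rate over the decoded
bit rate, $N B f_s W / K$. The operation-rate model charges each of the
$K_T M$ threshold comparisons per frame one memory access, one
multiplexer selection, one comparison, $b_{\text{logic}}$ binary-logic
operations and one shift-register update, plus two fixed per-frame
operations (window clock and output latch):
$\Theta = K_T M (4 + b_{\text{logic}}) + 2$ per frame, times the frame
rate $1/W$. With 32 templates, $M = 2$, single-comparison logic and
10 frames/s this is 3220 operations per second.

# Problem sizes and numerical tolerances in the test suite

Exhaustive oracles keep the expensive checks exact but small: path
enumeration at $K \le 4, T \le 6$; decode-vs-full-conjunction sweeps at
$N, K \le 8$ over hundreds of random instances; threshold-selection
scans over random 3-bit histogram banks of 20–60 windows. The end-to-end
scenario runs at its natural scale (32 × 32, ~420 windows) and completes
in seconds. Row-stochasticity is checked to $10^{-12}$, path-score
agreement to $10^{-10}$ relative, and the hand-computed K = 3 transition
row to $10^{-4}$.

# Known limitations

* Emissions use a posterior-as-likelihood approximation and assume
  conditional independence of output bits; both are pragmatic, not
  principled, and are the first thing to revisit for correlated
  populations.
* The conjunction operation suits unimodal receptive fields; multimodal
  or multi-unit channels need the level-band / sum-of-products logic for
  which the operation registry is only a hook.
* PPV-based channel ranking inherits the training period's occupancy; a
  strongly non-uniform training trajectory biases which channels are
  kept.
* The generator's simplifications listed above bound what synthetic
  results can claim about in vivo performance.
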