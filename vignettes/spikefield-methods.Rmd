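---
title: "Methods: a spiking neural field with short-range Mexican-hat connectivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a spiking neural field with short-range Mexican-hat connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikefield)
```

## The model

`spikefield` simulates a topographic sheet of 100 x 100 conductance-based
integrate-and-fire neurons, the standard abstraction for winner-take-all
target selection in retinotopic structures such as the superficial
superior colliculus. Each cell's membrane potential obeys

$$\tau_m \frac{\partial V}{\partial t}
   = -(V - V_0) - g_e (V - V_e) - g_i (V - V_i),$$

with a spike emitted and $V$ reset to $V_r$ when $V$ crosses the threshold
$V_t$, followed by a 1.5 ms absolute refractory period during which the
cell is clamped at $V_r$ and ignores all drive (capping the firing rate
near 600 Hz). The gating variables $g_e, g_i \ge 0$ are dimensionless
channel-opening counts that decay exponentially with time constants
$\tau_e = 3$ ms and $\tau_i = 10$ ms and receive instantaneous increments
from presynaptic spikes. The slower inhibitory synapse is what produces
the delayed inhibition wave underlying all the suppression phenomenology.

Defaults (`neuron_params()`, `sim_config()`): $\tau_m = 10$ ms,
$V_t = -50$, $V_r = -80$, $V_0 = -70$, $V_e = 0$, $V_i = -80$ mV; grid
100 x 100 cells, simulation clock 0.01 ms, recording clock 1 ms, 200 ms
per run.

## Lateral connectivity and the weight-splitting convention

Lateral weights come from an isotropic difference of Gaussians

$$f(d) = (1+\beta)\, e^{-d^2/2\sigma^2} - \beta\, e^{-d^2/2K^2\sigma^2},$$

with $K$ the inhibition/excitation extent ratio and $\beta$ the depth of
inhibition. Three presets are built in: the reference hat `s1`
($K = 1.2$, $\beta = 6$), the wide hat `s2` ($K = 2$, $\beta = 1.43$,
chosen so its minimum matches s1's within 1% -- verified by
`kernel_minimum()`), and the deep hat `s3` ($K = 1.2$, $\beta = 8$).

Two readings of how $f$ feeds the two conductances are implemented in
`build_kernel()`:

* **`"net"` (default, used by every protocol driver).** $f$ is evaluated
  first and split by sign: $w_e = \max(f, 0)$ is the central excitatory
  lobe (maximum exactly 1 at the origin, so $f$ is naturally normalized
  to $(-1, 1]$), $w_i = \max(-f, 0)$ the magnitude of the inhibitory
  annulus. With gains $\alpha_e = \alpha_i = 200$ the net weight peaks at
  200 at the origin and bottoms near $-113$ (about half), i.e. the
  excitatory weight is roughly twice the inhibitory depth. Excitation is
  purely local, inhibition purely annular.
* **`"terms"`.** The two raw Gaussian terms are used directly, so every
  spike deposits $(1+\beta)$-scaled and $\beta$-scaled increments on both
  conductances at every offset.

The net kernel $\alpha_e w_e - \alpha_i w_i$ is identical under both
conventions; the dynamics are not, because the two conductances have
different reversal potentials and decay times. Under `"terms"` the
deposits nearly cancel pointwise while $\tau_i > \tau_e$ makes the
time-integrated inhibition dominate everywhere ($\alpha_i \beta \tau_i
\gg \alpha_e (1+\beta) \tau_e$ at the origin), so no localized
self-maintained activity exists at any overall gain: the lattice either
stays input-locked or fires in global waves. Under `"net"` a local bump
recruits its neighborhood through the pure-excitation core while the
annulus builds a standing inhibitory moat, which is the classic dynamic
neural field mechanism, and the full selection phenomenology appears. We
therefore fixed `"net"` as the default. Together with the gain units
below and a 1-cell stimulus line width, this choice was calibrated once
against a single anchor -- a line stimulus on the reference kernel selects
a single cluster up to length 18 and is completely suppressed from length
20 -- after which every other protocol outcome is validation, untouched.

**Gain units.** All gains are quoted in mV as in the standard parameter
table ($\alpha_e = \alpha_i = 200$ mV, stimulus gain
$\alpha_s = 4000$ mV). Since $g_e, g_i$ are dimensionless, the engine
converts a gain to a conductance increment at 1 V per unit:
$\Delta g = \alpha w / 1000$. An input spike thus opens $\Delta g_e = 4$
on each stimulated cell -- strong enough that one or two input spikes
bring a resting cell to threshold -- while a single lateral spike opens at
most $0.2$, so recruitment requires cooperative firing.

## Stimuli

External inputs are experimenter-controlled spiking units, not Poisson
processes: `rate_to_spike_train()` integrates the prescribed rate curve
on the simulation clock and emits a spike whenever the running integral
crosses an integer. A sustained 400 Hz profile over 200 ms yields exactly
80 spikes at 2.5 ms spacing; the default transient profile (a Gaussian
peaking at 400 Hz at 25 ms with sd 80 ms) yields 48 spikes, the floor of
its rate integral (about 48.8). Each input spike increments $g_e$ of
every mask cell by $\alpha_s w_s / 1000$ with $w_s \in [0, 1]$.

Geometries: 1-cell-wide vertical lines at column $x = 50$, vertically
centered (lengths 2-42); filled squares and rasterized disks centered on
the map (a disk holds exactly the cells whose centers lie within half the
diameter of the stimulus center, placed on the half-cell point for even
diameters so that the disk is contained in the same-size square); and two
2 x 2 blocks, A anchored at $(31, 51)$ and B displaced along $+x$ by
2-40 cells. Coordinates are 0-based throughout.

## Integration scheme

The membrane equation is advanced by exponential Euler: with the
conductances frozen over one step,
$V \leftarrow V_\infty + (V - V_\infty)\, e^{-\Delta t\, g_{tot}/\tau_m}$
where $g_{tot} = 1 + g_e + g_i$ and $V_\infty$ is the conductance-weighted
balance point. This is exact for the frozen-conductance problem and
unconditionally stable. Stability matters: during cluster volleys the
summed conductances reach $O(10$-$100)$, the effective membrane time
constant $\tau_m / g_{tot}$ drops below the 0.01 ms step, and a forward
Euler update (multiplier $1 - \Delta t\, g_{tot} / \tau_m < -1$) would
diverge. Conductances decay exactly ($e^{-\Delta t/\tau}$ factors);
increments from spikes in one step are delivered at the start of the next
(one-step synaptic latency). All cells crossing threshold in the same
step spike together -- no serialization, so lattice symmetries are
preserved exactly, which the mirror-symmetry test exploits. The
relaxation exponential is evaluated by a degree-6 Taylor tail for
arguments below $1/64$ (truncation error $< 10^{-16}$, i.e. exact in
double precision) and `exp` otherwise; the brute-force reference
simulator mirrors the evaluation verbatim so the two engines produce
bit-identical spike sets on small lattices.

Boundaries are open: kernel contributions falling off the grid are
dropped, which is why the protocols keep stimuli below half the grid
extent. Initial state is rest ($V = V_0$, $g = 0$).

## What counts as a spiking cluster

A *spiking cluster* is a self-maintained group: it persists near the
refractory-limited rate after the transient input has decayed.
`detect_clusters()` finds 8-connected components of spiking cells
(8-connectivity keeps a rasterized disk's diagonal rim in one piece);
components below `min_size = 3` cells are discarded as specks. For
protocol classification the drivers detect over the final 50 ms with a
150 Hz per-cell rate floor: input-locked firing cannot exceed the
instantaneous input rate there (under 100 Hz for the transient profile),
while self-maintained clusters run at 280-600 Hz, so any floor between
100 and 300 Hz yields identical classifications -- the value is not a
tuned quantity. Under sustained drive that gap closes, and the drivers
additionally require a cluster to contain at least one non-stimulated
cell: external input can only drive mask cells directly, so lateral
recruitment is the unambiguous signature of self-maintenance there. The
rule is not applied under transient drive, where a genuine cluster may
lie wholly inside a large 2D mask.

Cluster statistics (spike counts, spike-count-weighted centers of
gravity, first-spike and recruitment times) are computed over the full
run on the member cells. The per-cluster steady rate divides terminal
spikes by the number of members active in the terminal window, so
late-onset clusters are not diluted by silent members. In the
two-stimulus protocol the cluster nearest B is reported with its signed
x-deviation, negative toward A.

Note one consequence of the model's structure: per-cell input drive is
independent of stimulus size, so stimulated cells always fire a few
transient, input-locked spikes even at sizes where selection fails
completely. "Complete suppression" therefore means no self-maintained
cluster -- the network's total spike count is small but not zero, and the
relative-activity ratio of a suppressed run sits near 0.3 rather than
exactly 0. Both the ratio and the discrete cluster count are reported.

## Membrane noise

The optional noise is additive on the membrane potential of
non-refractory cells. The stated amplitude (4 mV, a fifth of the
rest-to-threshold distance) is interpreted as the sd of the stationary
fluctuation of $V$: per-step draws are scaled by
$\sqrt{2\,\Delta t/\tau_m}$ so that the Ornstein-Uhlenbeck balance under
the membrane leak has the stated sd. Interpreting the amplitude instead
as an independent 4 mV kick per millisecond accumulates to a ~9 mV
stationary fluctuation, which spontaneously ignites clusters all over a
bistable field and contradicts the observation the noise control is
meant to reproduce -- that moderate noise leaves the selection outcomes
essentially unchanged. Noise runs are seeded and reproducible;
deterministic runs are bit-reproducible and seed-independent.

## Protocol drivers and problem sizes

`run_size_sweep()` (line lengths 2-42 by 2, kernels s1/s2/s3 at
$\sigma = 5$, transient or sustained drive), `run_shape_sweep()` (squares
and disks, even sizes, reference kernel) and `run_two_stimulus_sweep()`
(A-B separations 2-40 by 2 at $\sigma = 8.5$, weight ratios 1333-4000 mV,
optional noise, optional B-alone border control) reproduce the study
protocols end to end; every condition is a full 10,000-cell, 200 ms
simulation (a few seconds each on one CPU with the compiled engine). The
test suite exercises the same protocols at a subset of the condition
grids, plus reduced 10 ms runs for the initial rise-speed curves, whose
0-6 ms measurement window does not depend on the later dynamics.

The summary of each sweep records cluster counts and classification
(`single` / `suppressed` / `double` / `multiple`), total spikes, relative
activity against the smallest condition, first-spike and
cluster-recruitment latencies, probe-line rise speeds over 0-6 ms and
30-90 ms (the probe is the column two cells from the stimulus line,
tracked at the recording clock; the speed is the mean derivative of the
maximum potential over the line), and terminal cluster rates.

## What passing tests do and do not show

The deterministic engine checks (analytic membrane decay, refractory
contract, conductance positivity, quiescence, mirror symmetry,
translation equivariance, equivalence with a brute-force per-pair
simulator) validate the integrator exactly. The protocol-level checks
validate emergent phenomenology: single-cluster selection for small
stimuli, complete suppression over an intermediate size band, delayed
multi-locus selection for large stimuli, and attraction/fusion,
suppression and repulsion between two stimuli, including the ordinal
shape of the rise-speed and deviation curves. They do not certify exact
agreement with any particular reference implementation's floating-point
trajectory: regime *boundaries* sit on knife edges of the dynamics, and
two of them (the largest suppressed separation in the equal-weight
two-stimulus protocol and the largest suppressed disk) land one 2-cell
protocol step away from their published positions in this implementation,
with the neighbouring steps and all other boundaries agreeing exactly.
Nothing here says anything about real collicular tissue: inputs are
deterministic, the lattice is uniform and unmapped (no logarithmic
magnification), and all parameters are the study's constants.

## Known limitations

* No synaptic transmission delays beyond the one-step latency; no
  distance-dependent conduction delays.
* The steady cluster rates of the wide and deep kernel variants
  (430-440 Hz and 280-300 Hz here) fall below the 550-600 Hz and
  350-400 Hz bands reported for the original implementation, consistent
  with an integrator difference at the volley scale; the refractory
  ceiling and the ordering of variants are respected.
* Weights are static: no plasticity, no learning.
* Serialization is plain text (CSV summaries, CSV/JSON kernel export,
  YAML configs).
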