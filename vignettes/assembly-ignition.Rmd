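---
title: "Hebbian cell assemblies and their spontaneous ignition: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hebbian cell assemblies and their spontaneous ignition: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`hebbca` simulates six cortical areas arranged as a chain of primary
perceptual (P1), higher perceptual (HP), perceptual association (PA),
prefrontal (PF), premotor (PM) and primary motor (M1) areas.  Each area is a
pair of 25 x 25 grids (12 x 12 in the reduced preset) of excitatory and
inhibitory graded-response cells; each excitatory cell stands for a cluster
of pyramidal neurons within one cortical column, and the inhibitory cell
beneath it for that column's interneurons.

The state of every cell is its membrane potential `V(x, t)`, integrated with
the Euler scheme (`dt = 0.5`, arbitrary time units) from

```
tau dV/dt = -V + k1 (V_in + k2 * eta),
```

where `V_in` sums all excitatory and inhibitory postsynaptic potentials plus
a constant baseline `Vb`, and `eta` is uniform white noise on
`[-0.5, 0.5]`, drawn independently per cell and step — the model correlate
of spontaneous neuronal firing.  Excitatory output is a piecewise-linear
sigmoid clipped to `[0, 1]` with an adaptive threshold `phi = alpha * omega`,
where `omega` low-pass filters the cell's own output with time constant
`tauA` (neuronal adaptation: recent activity raises the threshold).
Inhibitory output is rectified-linear.  Each area additionally carries one
low-pass average `omegaS` of its total excitatory output (time constant
`tauS`); `kS * omegaS` is subtracted from every excitatory cell's input of
that area.  Local and area-global inhibition together implement competition
and keep activity physiological.

Within-area excitatory links are sampled in a 19 x 19 neighbourhood, the
excitatory drive onto the inhibitory layer in a 5 x 5 neighbourhood, both
with a Gaussian distance fall-off clipped to zero outside the
neighbourhood; neighbourhoods are clipped, not wrapped, at area borders
(edge cells simply have fewer neighbours — there is no evidence for a torus
in this system).  Between-area links are topographic and follow the
six-area adjacency: chain links P1-HP, HP-PA, PA-PF, PF-PM, PM-M1 plus the
four "jumping" links P1-PA, HP-PF, PA-PM, PF-M1 in the full variant.  This
gives between-area partner counts of 4 (central areas PA, PF), 3 (secondary
HP, PM) and 2 (primary P1, M1); the serial variant (jumping links removed)
gives 2:2:1.  All initial weights are uniform on `]0, 0.1]`, and the two
directions of every reciprocal projection are sampled independently —
reciprocity holds at area level, not per cell pair.  Self-links are
excluded within the excitatory layer.

Learning is the discretised Artola-Bröcher-Singer rule applied to every
excitatory-to-excitatory weight at every training step: with presynaptic
output at least `theta_pre`, a strongly depolarised postsynaptic cell
(`V >= theta_plus`) gives `+delta_w` (LTP) and a moderately depolarised one
(`theta_minus <= V < theta_plus`) gives `-delta_w` (homosynaptic LTD);
a strongly depolarised cell with an inactive presynaptic link also gives
`-delta_w` (heterosynaptic LTD).  The postsynaptic variable is the membrane
potential, as the rule is stated, not the output.  Weights are clipped to
`[0, w_max]`: the rule alone is unbounded, and stable two-state (on/off)
assemblies require saturation.  Plasticity runs only during training;
probing and the spontaneous phase operate on frozen weights, which is what
makes the cell-assembly definition below well defined.

## Training, membership, ignition, analysis

Training presents sensorimotor pattern pairs — sets of cells in P1 (the
"sensory" pattern) and M1 (the "motor" pattern), 20 cells each at reference
scale, i.e. 3.2% of an area — in random order, each for 16 steps with an
additive drive strong enough to saturate the driven cells, separated by
inter-stimulus intervals drawn uniformly from a configured range.  Patterns
overlap partially: each shares a small fixed number of cells with one
ring-neighbouring pattern (4 of 20 at reference scale), standing in for the
overlap between motor and perceptual features of real action schemata.

After training, each pattern is probed (plasticity frozen, noise on, 12
repetitions by default) and every excitatory cell's output is averaged over
the 15 steps following stimulus onset; the window starts at onset + 1
because outputs lag the stimulus by one synchronous update.  Each probe is
preceded by a short noise-only settle period from the zero state; because
every adaptation threshold starts at zero, the settle triggers one rebound
ignition, and the default settle length (20 steps) delivers the probe in a
recent-activity context comparable to training, where each stimulus follows
earlier network activity within a few tens of steps.  The probe gain
depends on that context — long settles (past full recovery of adaptation
and global inhibition) let the whole coupled assembly system co-ignite and
blur membership, while the training-matched context yields the most
informative relative response profiles; thresholds are in any case relative
per pattern and area.  For pattern
`w` and area `A` the threshold is `theta_w(A) = gamma * max` of that
pattern's average response in `A`, with `gamma = 0.5` for all statistics;
cells at or above threshold are the CA members.  A CA is *active* at a step
when at least 50% of its member cells (union across all six areas) have
output at or above their area's `theta_w(A)`; ignition events are maximal
runs of active steps in a stimulus-free, noise-driven recording (20000
steps at reference scale).  Event-aligned 40-step trials starting 10 steps
before onset are averaged into per-area ASI traces, normalised by per-area
CA size; the critical 6-step window starts at the last pre-onset step at
which the average number of active CA cells is zero in all areas for all
CAs.  Per step, a two-way repeated-measures ANOVA (centrality x frontality,
CAs as subjects) is computed from textbook sums of squares, each main
effect tested against its own subject-by-factor interaction, without
sphericity correction.  Planned comparisons (each centrality level against
the zero baseline, and the pairwise differences) are tested on per-subject
contrast scores with `n - 1` error degrees of freedom, matching the
`F(1, n - 1)` statistics this design reports; a pooled-error alternative
would use the omnibus error stratum, but the per-contrast form is what the
reported degrees of freedom imply.  Significance is `p < 0.05`,
uncorrected, as usual for planned comparisons.

## Calibrated defaults and why

The exact constants behind the published simulations are not part of the
text this implementation works from, so every constant is a configuration
field and the shipped defaults were calibrated, by grid searches over the
reduced preset summarised below, to satisfy, in order:

1. *Rest stability*: an untrained network driven only by noise settles into
   sparse, low-rate background activity without runaway (mean output
   ~0.005-0.02, no locked-on cells).
2. *Assembly formation*: training must grow pattern-specific,
   *distributed* assemblies — strong within- and between-area weights among
   pattern-driven and recruited cells, while background and cross-pattern
   weights are pruned.  The failure modes on either side are total weight
   collapse (background LTD outruns pattern LTP) and epileptic merging
   (all patterns associate into one global attractor).  The decisive
   quantities are the probability that a postsynaptic cell crosses
   `theta_plus` during its pattern's stimulation versus at rest, the ISI
   (long enough that one presentation's reverberation dies before the
   next), and the strength/speed of area-global inhibition, which enforces
   competition between assemblies.
3. *Bistability*: after training, assemblies must ignite spontaneously
   under the same noise (rare, noise-triggered transitions to full
   activation) and self-terminate through adaptation and global inhibition.

The calibrated dynamics defaults are `tau = 2.5`, `k1 = 3`, `k2 = 0.85`,
`Vb = 0`, `alpha = 5`, `tauA = 10`, `kS = 0.2`, `tauS = 7.5`,
`g_inh = 0.4`, `dt = 0.5`; plasticity defaults `delta_w = 0.002`,
`theta_pre = 0.15`, `theta_plus = 0.5`, `theta_minus = 0.2`,
`w_max = 0.25`.  Noise reaches inhibitory as well as excitatory cells (the
membrane equation is stated for every cell), and the baseline term is
likewise applied to both; with `Vb = 0` the no-noise network has an exact
resting fixed point, which the no-noise control exploits.  The rectified
noise in the inhibitory layer produces a tonic hyperpolarisation of the
excitatory layer that scales with `k1 * k2 * g_inh`, so the LTP threshold
`theta_plus` sits deliberately in the far upper tail of the rest
distribution of `V` — background activity must essentially never potentiate
or depress a link, both because heterosynaptic LTD would otherwise erode
pattern pathways between their presentations and because the baseline
alignment of the critical window requires rest activity to stay below the
membership thresholds.  The weight ceiling `w_max = 0.25` is what makes
assemblies terminate: with at most a few tens of potentiated in-links per
member cell, the recurrent drive during ignition exceeds the rising
adaptation threshold `alpha * omega` plus the global-inhibition term for
only a bounded time.

Three further calibration findings shaped the reduced preset.  First,
pattern geometry: on a 12 x 12 grid with full-size (19 x 19)
neighbourhoods, topography is effectively lost — every cell receives
comparable expected input from every pattern, so the structurally
best-connected cells are recruited by *all* patterns and the assemblies
merge into one global attractor.  The pattern generator therefore defaults
to compact, tile-centred blobs (`layout = "clustered"`), which concentrate
each pattern's topographic projection onto its own region of every
downstream area; the shared (overlap) cells sit on the boundary between
ring-neighbouring blobs.  Second, kernel scaling: the reduced preset
shrinks the within-area kernel (7 x 7) more than the between-area kernel
(13 x 13), keeping within-area recurrence blob-local (so that
ring-neighbouring assemblies are not bridged by lateral links) while
between-area projections stay broad enough to drive recruitment.  Third,
inter-stimulus intervals of 10-25 steps keep the interval between two
presentations of the same pattern short enough that background
heterosynaptic depression does not erode its pathway, while area-global
inhibition and adaptation extinguish each presentation's reverberation
within the interval.

## Scale presets

The reference ("full") preset matches the published conditions: 25 x 25
areas, 12 patterns of 20 cells (overlap 4), 15000 presentations per
pattern, ISIs of 30-80 steps, 20000 recorded steps.  The default
("reduced") preset preserves the architecture, the degree ratios and the
qualitative dynamics at a size chosen to run in minutes on one CPU:
12 x 12 areas, 6 patterns of 10 cells (overlap 2), 1000 presentations per
pattern, ISIs of 20-50 steps, 4000 recorded steps.  The reduced preset's ISI range, kernel sizes and connection probabilities
are part of the calibration described above.  Absolute published event counts and F values are single
stochastic realisations under unavailable constants and are not
reproduction targets; the structural ratios, the noise-necessity control
and the centrality ordering of ignition onsets are.

## What the synthetic data do and do not show

All inputs are synthetic by design: the pattern generator *is* the
experimental material (there is no external data set).  Passing tests show
that the implemented mechanisms — sparse topographic wiring, the learning
rule, competition, noise — produce distributed assemblies whose spontaneous
ignition starts in the most richly connected areas.  They do not show
anything about real cortical tissue beyond the model's assumptions: cells
are rate-coded cluster averages with no spike timing or conduction delays,
areas are identical in size and parameters, and "anatomy" enters only
through the between-area adjacency.

## Numerical choices and degenerate inputs

Synchronous updates: all outputs are computed from the state at step t,
then inputs, then the plasticity step (using outputs and potentials at t),
then one Euler step of every state variable.  The noise stream is drawn
from R's RNG in a fixed order (excitatory cells, then inhibitory), so a
single `set.seed()` reproduces entire experiments bit for bit.  Non-finite
inputs abort with the offending cell's area and grid coordinates.
Event detection uses strict maximal runs (merge gap 0) by default; a
configurable merge gap exists because self-deactivation can in principle
chatter at the 50% boundary.  Ignition events whose 40-step trial window
does not fit in the recording are dropped; CAs that never ignite are
excluded from the ASI analysis (and from the subject pool of the ANOVA).
An all-zero probe profile in an area yields an empty, flagged membership.
If no all-zero pre-onset step exists the critical window cannot be
anchored and the analysis stops with an explicit error rather than
guessing an origin.  Zero-variance contrasts are reported as `F = 0,
p = 1` when the mean is also zero and as `F = Inf, p = 0` otherwise.

## Known limitations

* The published constants are unavailable; the calibrated defaults
  reproduce the qualitative regime (bistable assemblies, centrality-ordered
  ignition) but not the exact published event counts or F values.
* At the reduced scale the subject pool is 6 CAs, so the per-step ANOVAs
  have few error degrees of freedom and onset steps vary more between
  seeds than in the reference-scale design; the onset analysis is therefore
  reported as a majority vote over several seeds.
* At the reduced scale the six assemblies share a substantial fraction of
  their higher-area member cells and their spontaneous ignitions tend to
  co-occur, so the assemblies behave less independently than the
  reference-scale design implies; the area-level cascade (central before
  secondary before primary) is unaffected, but per-assembly statistics are
  strongly correlated across assemblies.
* Training sits between two failure regimes (weight collapse and epileptic
  merging), and individual network realisations occasionally land outside
  the bistable regime — a seed can produce an ignition that never
  self-terminates or a network that never ignites.  The analysis code
  reports these honestly (no aligned window, no onsets) rather than
  papering over them.
* Only independent per-CA detection is implemented; simultaneous ignitions
  of overlapping CAs are not disambiguated.
* At the reduced scale the serial (jumping-links-removed) variant trains and
  analyses cleanly but its weaker assemblies did not ignite spontaneously
  within the 4000-step recordings in any calibration run, so the serial
  onset comparison is not reproduced at this scale; the variant's wiring
  (2:2:1 partner counts) and pipeline behaviour are still exercised.
* Associative recall from the sensory component alone (stimulating only a
  pattern's P1 cells) reactivates higher areas but, because the reduced-scale
  assemblies share many higher-area cells, the reactivation is not reliably
  pattern-specific; specificity holds for the paired probe used to define
  membership.
* Memory: recordings are dense `steps x cells` matrices; a reference-scale
  20000-step recording of 3750 cells occupies ~600 MB.
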