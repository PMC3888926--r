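# hebbca

Spontaneous ignition of Hebbian cell assemblies in a six-area model of
fronto-temporal cortex.

## The problem

Voluntary, stimulus-independent actions are preceded by a stereotyped
cascade of cortical activations: prefrontal and higher-association areas
light up first, then premotor/secondary areas, and primary sensorimotor
cortices last.  `hebbca` implements a mechanistic account of that cascade:
six cortical areas — primary perceptual (P1), higher perceptual (HP),
perceptual association (PA), prefrontal (PF), premotor (PM) and primary
motor (M1) — are modelled as grids of excitatory/inhibitory
graded-response leaky-integrator cells with neuronal adaptation, uniform
membrane noise, local lateral inhibition and area-global inhibition, wired
by sparse, patchy, topographic projections.  Next-neighbour links form a
chain P1-HP-PA-PF-PM-M1; "jumping" links (P1-PA, HP-PF, PA-PM, PF-M1) give
the central areas PA and PF four between-area partners, secondary areas
three and primary areas two.

Repeated paired stimulation of sensory (P1) and motor (M1) patterns under
the discretised Artola-Bröcher-Singer LTP/LTD rule

```
w <- w + dw   if O_pre >= theta_pre and V_post >= theta_plus        (LTP)
w <- w - dw   if O_pre >= theta_pre and theta_minus <= V_post < theta_plus
w <- w - dw   if O_pre <  theta_pre and V_post >= theta_plus
w <- w        otherwise,    clipped to [0, w_max]
```

grows distributed sensorimotor **cell assemblies** (CAs) — two-state
circuits binding each sensory pattern to its motor partner.  With no input
at all, membrane noise occasionally accumulates inside an assembly's
positive-feedback loops and the assembly **ignites**, then self-terminates
through adaptation and global inhibition.  The package detects these
ignition events (a CA is active when ≥ 50% of its member cells fire above
the pattern- and area-specific threshold `theta_w(A) = gamma * max` average
probe response, `gamma = 0.5`), builds event-aligned average spontaneous
ignition (ASI) traces, and tests — with per-time-step repeated-measures
ANOVAs and planned comparisons over a 6-step critical window — whether
ignition reaches significance first in central, then secondary, then
primary areas.

## Worked example

```r
library(hebbca)

# end-to-end: build -> train -> probe -> record -> detect -> ASI -> ANOVA
cfg <- experiment_config("full", scale = "reduced", seed = 1)
run <- run_experiment(cfg)
run
summary(run)

# the wiring audit shows the 4:3:2 partner structure
audit_graph(run$net)

# per-area CA sizes across the gamma grid
run$ca_sizes

# per-step ANOVA and planned comparisons on the aligned critical window
tidy(run$anova)
glance(run$anova)

# plots
autoplot(run$events)
autoplot(run$asi)
```

```
#> <ca_run> variant full (reduced scale), seed 1
#>   ignition events: 222 over 6 CAs
#>   first significant step: central 1, secondary 2, primary 3

#> # A tibble: 6 x 8   (audit_graph)
#>   area  centrality frontality n_partners between_in between_out mean_in_per_cell
#> 1 P1    primary    posterior           2       7872        7753             54.7
#> 2 HP    secondary  posterior           3      11889       11982             82.6
#> 3 PA    central    posterior           4      15860       15872            110.
#> 4 PF    central    anterior            4      16029       15842            111.
#> 5 PM    secondary  anterior            3      11778       12005             81.8
#> 6 M1    primary    anterior            2       7930        7904             55.1

#> # ca_sizes at gamma = 0.5
#>   area  centrality mean_size
#> 1 P1    primary         30.5
#> 2 HP    secondary       46.3
#> 3 PA    central         57.5
#> 4 PF    central         59
#> 5 PM    secondary       46.3
#> 6 M1    primary         31.8

#> # glance(run$anova)
#>   n_subjects n_steps first_step_central first_step_secondary first_step_primary
#> 1          6       6                  1                    2                  3
```

What the numbers mean: the trained network spontaneously ignited 222 times
across all six learnt assemblies within the 4000 recorded noise-driven
steps; the between-area audit shows the 4:3:2 partner structure; mean CA
size per area is largest in the central areas (PA, PF), then secondary
(HP, PM), then primary (P1, M1); and in the aligned critical window the
central areas reach significant above-baseline activation at time-step 1,
secondary at step 2 and primary at step 3 — the cascade of a voluntary
"action thought" emerging in higher-association cortex and spreading
outwards to the primary sensorimotor areas.


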