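---
title: "A coupled PRE/TRE-promoter model of epigenetic memory and dynamic regulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A coupled PRE/TRE-promoter model of epigenetic memory and dynamic regulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pretre)
```

## The model

`pretre` simulates two coupled stochastic units over developmental time.

The **PRE/TRE** is an ordered array of `S` nucleosomes, each in one of
three configurations: active (A), neutral/unmodified (U) or silent (M).
Each configuration aggregates every histone modification and bound
factor of that valence, so the model is agnostic about the molecular
carrier of memory. One *update attempt* picks a target nucleosome
uniformly at random and then, with probability 0.5, performs a
*feedback* conversion — a mediator is drawn uniformly from the other
`S − 1` nucleosomes and, if modified, converts the target one step
toward its own configuration with probability `p3` (toward M) or `p4`
(toward A) — and otherwise a *feedback-independent* transition: with
probability `p5` the target moves one step (A→U, M→U, or U→A/M with
equal probability). Conversions are strictly stepwise (A↔U↔M, never
A↔M directly) and feedback has unbounded range, the published default
of this model class. The positive feedback destabilises U and makes the
array bistable; its state is summarised as `E = (N_A − N_M)/S`.

The **promoter** is an array of `s` binding sites, free (F) or bound
(B). Per sweep each site independently binds with probability `p1` and
unbinds with probability `p2`; sites are exchangeable and there is no
cooperativity. Activity is `a = N_B/s`, with uncoupled stationary value
`p1/(p1 + p2)`.

**Coupling.** Every simulated minute the four rate parameters are
re-derived from the scenario's base values — never compounded on
previous adjustments — using the current states. Writing `x` for the
signal favouring a parameter `q` (`x = E` for `p1`, `−E` for `p2`,
`P = 2a − 1` for `p4`, `−P` for `p3`), the default form (model 1) is

q′ = q·(1 + C·x) if x ≥ 0, else q/(1 + C·|x|),

clamped to \[0, 1\]; model 2 is the signed-linear `q·(1 + C·x)`,
clamped. `p5` is never adjusted, and `C = 0` is an exact pass-through.
Both forms satisfy the qualitative contract — the more active or silent
the PRE/TRE, the more active or silent the promoter, and vice versa —
but the exact published relationships are not available, so these are
documented reconstructions; quantitative tolerances elsewhere in the
package account for that.

**Development.** A cell-cycle schedule drives division events: at the
end of a dividing cycle the promoter is reset to all-F (transcription
factors leave mitotic chromatin) and each nucleosome is independently
wiped to U with probability 0.5 (random partitioning of parental
histones at replication). The default embryonic schedule has 13 rapid
cycles ending at 130 min (durations 8×8, 9, 10, 11, 14, 22 min — chosen
to sum to exactly 2h10 so that cycle 14 starts on the observed
initiation boundary), a 160-min cycle-14 initiation phase ending at
4h50, maintenance cycles dividing at 6h20 and 7h30, and optional
600-min larval cycles out to 100 h for eye-disc scenarios. All
durations are TSV-overridable (`read_schedule()` / `write_schedule()`).

## Time calibration

One engine step is one simulated minute: one promoter sweep plus
`attempts_per_minute` chromatin update attempts (default
`round(0.23 · S)`, i.e. 14 for `S = 60`). This constant is the single
mapping between model iterations and wall-clock developmental time, and
it was calibrated once, jointly with the scenario `p1` defaults, against
two quantitative anchors of the modelled biology: the uncoupled array
should hold roughly 90% of nucleosomes in U through the rapid pre-MBT
cycles, and the silenced anterior promoter should derepress about six
hours into development when `p3` collapses at maintenance onset. Faster
chromatin kinetics let random A/M domains survive the rapid early
cycles (naivety is lost); slower kinetics make the mutant derepression
unrealistically late. The default sits where both anchors hold.

## Scenario defaults

`p2 = 0.1` everywhere (transcription-factor dissociation). The `p1`
regimes, chosen so the uncoupled stationary activities
`p1/(p1 + p2)` give clearly separated regimes, are:

| regime | p1 | uncoupled activity | used in |
|---|---|---|---|
| repressed | 0.01 | 0.09 | anterior initiation, disc before activation |
| active | 0.19 | 0.66 | posterior; anterior after repressors vanish |
| silent baseline | 0.05 | 0.33 | activation assay outside heat shock |
| heat shock | 0.8 | 0.89 | 1-h heat-shock windows |

Two of these deserve comment. The active-regime value 0.19 deepens the
coupled silent state (the maintained anterior activity sits near 0.09,
memory score ≈ 0.91) without delaying mutant derepression. The silent
baseline 0.05 is higher than a naive choice because of the mitotic
reset: immediately after each division the promoter restarts from
all-F, so for a few minutes the PRE/TRE sees a fully silent promoter
regardless of its own state. With a very small baseline `p1` a
reactivated promoter recovers too slowly from each reset, and the
active state erodes over the ~9 larval divisions; at 0.05 the memory of
activation survives to 100 h while the unshocked baseline still
silences reliably.

For the same reason the default *early* heat-shock window is
\[135, 195\] min — at the start of the cycle-14 initiation phase. Under
the reconstructed coupling the silent baseline locks the PRE/TRE into M
within roughly 40 min of initiation onset, after which a 1-h shock can
no longer flip it; a shock at the onset itself both activates the
promoter and converts the still-naive PRE/TRE. The *late* window
(\[300, 360\] min, after the initiation phase ends) produces only
transient activation followed by re-silencing, as required.

Coupling is `C_e = 0` during cycles 1-13 (decoupled early development)
and `C_im = 4` from initiation onward in the memory scenarios; the
eye-disc scenarios couple only from each position's activation onset,
with `C = 2.5`.

## The eye-disc scenario

The disc is a row of independent lineages indexed by the
anterior-posterior coordinate `x ∈ [0, 1]`. Zone 1 (`x < 0.3`) never
activates. In zones 2-3 an activation front sweeps from posterior to
anterior during third instar (onset 60 h at `x = 1` to 80 h at
`x = 0.3`); from its onset a position's `p1` follows a piecewise-linear
enhancer gradient — rising across zone 2 to a peak at the morphogenetic
furrow (`x = 0.6`), declining across zone 3 to a posterior plateau —
and coupling switches from 0 to `C = 2.5`. The gradient is
parameterised in *activity* units and converted to `p1` through the
uncoupled stationary relation; the posterior plateau default (0.45) is
deliberately near the coupling-neutral activity 0.5, so the posterior
disc is only mildly repressed by the element. Promoter activity
averaged over 90-100 h proxies adult reporter expression.

With flexible chromatin (`p3 = p4 = 0.2`, `p5 = 0.17`; the *eya*-like
element) the response tracks the gradient position-for-position
(Spearman correlation ≈ 0.97 with the target profile), giving a smooth,
unimodal, sharpened gradient. With strongly bistable chromatin
(`p3 = p4 = 0.25`, `p5 = 0.04`; *bxd*-like), random A/M states adopted
before coupling are perpetuated, and the disc variegates — with a
residual positional trend at `C = 2.5` that disappears at high `C`.

A known limitation of the reconstructed coupling matters here: model 1
adjusts `p1` up and `p2` down simultaneously, so the promoter odds are
amplified by `(1 + C·|E|)²`. At `C = 2.5` the closed loop is bistable
for any target activity except 0.5, and the realised profile is a
steep, essentially deterministic amplification of the target gradient
rather than a gently compressed one. Spatial smoothness and the
eya-versus-bxd contrast are robust, but tail-based bimodality summaries
of the eya profile (the variegation index over positions) remain larger
than a gentler coupling form would produce. The index is still sharply
discriminating: it is consistently lower for eya than for bxd discs.

## Statistics

- `memory_score(traj, target, window)`: mean over the window of the
  activity (target "active") or one minus it ("repressed"); equals 1
  exactly for perfect memory and degrades smoothly. Chosen because the
  published anchor fixes only the perfect-memory value; the active and
  repressed scores of one trajectory sum to 1.
- `derepression_time(ensemble)`: first sampled time at which the
  per-time median activity exceeds 0.5 and stays above it to the
  horizon — defined on the median so single-replicate flicker cannot
  register. Engine samples are taken before the division event of a
  minute; sampling after divisions would zero the median at every
  division and make persistent crossings undefined.
- `variegation_index(values)`: `2·min(frac < 0.25, frac > 0.75)` over
  per-replicate (or per-position) window means — bounded, symmetric,
  zero for mid-centred unimodal ensembles.
- `accumulation_curves()`, `gradient_profile()` (optionally
  max-normalised, mirroring per-disc image normalisation),
  `window_mean_activity()` over 90-100 h.

## Validation against an exact chain

For `S ≤ 4` the chromatin update rule defines a finite Markov chain on
`3^S` configurations. `build_exact_chain()` enumerates the per-attempt
kernel directly from the stated rules and composes one sweep;
`compare_to_oracle()` measures the total-variation distance between the
empirical distribution of simulated replicates and the exact k-step
distribution (typically ≈ 0.004 at `S = 3`, `k = 5`, `n = 10^5`,
against a 0.02 gate, with a deliberate parameter mismatch as negative
control). The chain shares no code with the simulation path and gates
the compiled kernel used everywhere.

## Problem sizes and reproducibility

Ensemble sizes follow the assay designs: 50 replicates for kymograph
displays, 400 for outcome distributions, 1000 for accumulation curves
and pre-MBT composition, 100 positions × 1 replicate for discs. With
the compiled kernel a 400-replicate, 100-h scenario runs in a few
seconds on one CPU. Replicate `i` of an ensemble uses seed
`base_seed + i − 1`; replicates are fully isolated, so results are
independent of execution order and replicate count, and identical
(configuration, seed) pairs give bit-identical trajectories on any
host.

## What the synthetic scenarios do and do not show

The scenarios emulate the *logic* of the reporter assays: compartmental
enhancer regimes, heat-shock pulses, lineage-specific cycle schedules
and an activation front, all as piecewise-constant `p1`/`C` programs.
They do not model transcription or mRNA explicitly (activity stands in
for expression), TF concentrations (absorbed into `p1`), asynchronous
division across an ensemble, sequence-driven recruitment, or
distance-dependent feedback. Passing tests therefore show that the
coupled bistable-array mechanism reproduces the observed regulatory
phenomenology under these idealised programs — not that real loci use
these particular parameter values.

## Numerical notes and degenerate inputs

Probabilities are validated to \[0, 1\] and coupling-adjusted values
clamped there; `C = 0` and `(E, P) = (0, 0)` are bit-exact identities.
Schedules must tile the horizon exactly in integer minutes and are
validated on construction (positive durations, ordered phase bounds).
An all-U array with `p5 = 0` is absorbing; an undriven promoter
(`p1 = 0`) stays silent. Division events falling on the final minute
are applied after that minute's sample. U-noise splits exactly 50/50
between A and M, keeping the A/M label symmetry exact when `p3 = p4`.
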