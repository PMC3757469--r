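---
title: "Screening combinatorial enzyme mutants by reaction barriers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening combinatorial enzyme mutants by reaction barriers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscreen)
library(dplyr)
```

## The screening model

The package operationalizes a qualitative screen for enzyme activity built
on one physical assumption: for serine-hydrolase chemistry, formation of the
tetrahedral intermediate (TI) is rate-determining, so a mutant whose
computed barrier for that step is lower than another's is more likely — not
guaranteed — to be more active. Everything downstream treats the barrier as
a ranking and classification statistic, never as a quantitative rate
prediction: no transition-state-theory conversion to k~cat~ is attempted,
and none should be read into the outputs.

Barriers come from adiabatic mapping. The O^γ^–C distance between the
catalytic serine and the substrate carbonyl carbon is fixed at

$$d_i = d_\mathrm{ini} - i\,\frac{d_\mathrm{ini} - d_\mathrm{fin}}{n},
\qquad i = 0, \dots, n,$$

where $d_\mathrm{ini}$ and $d_\mathrm{fin}$ are the distances in the
enzyme–substrate complex (ES) and the TI. Each frame is geometry-optimized
by an external semi-empirical program under that constraint, with a set of
surface residues frozen (they otherwise form spurious hydrogen bonds during
optimization and corrupt the profile shape), a gradient criterion of
0.5 kcal/(mol·Å) and a 15 Å locality cutoff for the linear-scaling
wavefunction. The package generates these job descriptions
(`render_job()`, `render_backend_deck()`) and consumes the resulting
energies; it never computes energies itself. We index frames 0..$n$
inclusive, with frame 0 the ES reference — the barrier definition needs the
ES energy, so the reference frame is part of every profile. The default
$n = 10$ gives the conventional 11-point profile.

The barrier of a profile is
$\Delta E^\ddagger = \max_i E(i) - E(0)$, with ties for the maximum resolved
to the lowest frame index. The definition is deliberately insensitive to
where the maximum sits and needs no smoothing or spline fit; profiles with
any number of frames ≥ 3 are accepted.

## Combinatorics of the mutant space

Given a library assigning each mutable position $i$ a set of $g_i$ allowed
substitutions, the number of order-$o$ mutants (one substitution at each of
$o$ distinct positions) is the elementary symmetric polynomial
$e_o(g_1, \dots, g_N)$. `count_by_order()` evaluates it with the standard
recurrence (exact for integer $g_i$); `enumerate_mutants()` materializes
the mutants and is tested against both the closed form and an independent
brute-force oracle.

Steric exclusions are input data, not something the package decides: pairs
of substitutions whose side chains cannot be placed in the same structure
are listed in a two-column table, and a mutant is discarded exactly when it
contains both members of some pair. Exclusions are applied to complete
mutants, never to partial search branches, so the result set is independent
of enumeration order. Mutant identity is the unordered substitution set;
the canonical text form sorts tokens by ascending position, and the wild
type (order 0) is a reference, never an enumeration result. The default
`max_order` is 4: the shipped combinatorial study stops at four-fold
mutants, and the parameter is exposed for anything deeper.

## Profile filters

Two filters remove unusable screening candidates, in a fixed order:

1. **Regularity.** A profile showing several peaks of comparable height is
   inconclusive — the mapping has probably slipped into a different
   conformational valley — and is discarded. The original workflow judged
   this visually; the package formalizes it: a profile is irregular when at
   least two *interior* local maxima lie within `peak_similarity_window`
   (default 2.0 kcal/mol) of the global maximum. An interior maximum is a
   frame strictly inside the profile whose energy exceeds both neighbours;
   a plateau counts once, at its first frame. The 2.0 kcal/mol window is a
   design choice, not a published value: it is of the order of the method's
   own energy noise, and narrowing the window provably never makes more
   profiles irregular (a monotonicity the tests assert). Because the
   threshold formalizes a visual judgement, the discard counts it produces
   on real screening data are expected to track, but not exactly match, a
   human count; `plot_profiles()` annotates each profile with its verdict
   so the visual criterion stays recoverable.
2. **Barrier cap.** Among regular profiles, barriers strictly above
   `barrier_max` (default 19.0 kcal/mol, the largest barrier retained in
   the benchmark set) are discarded as non-promising. The boundary is
   strict: a barrier of exactly 19.0 is kept. Irregularity takes
   precedence, so the two discard classes are disjoint and the partition
   is exhaustive — an irregular profile with a high barrier counts once,
   as irregular.

## Classification and the benchmark

Experimentally, a mutant at `improve_min` (default 1.2) fold-wild-type
activity or above is improving (+1); at `degrade_max` (default 0.8) or
below, degrading (−1). Activities strictly between the two fall in a
neutral band, map to factor 0 and are excluded from agreement counting —
the defining rule names only the outer regions, so scoring a ±1 prediction
against a neutral observation would be arbitrary; such records are logged
instead. Both boundaries are inclusive, per the "or higher / or lower"
phrasing of the rule.

Computationally, a barrier at or above the cutoff $c_S$ (default
12.5 kcal/mol) predicts degrading, below it improving; the cutoff boundary
is inclusive on the degrading side. `optimize_cutoff()` scans every
observed barrier value plus every midpoint between adjacent distinct
values — between two such candidates no record changes side, so the scan is
exhaustive for this rule family — and reports *all* cutoffs achieving the
maximum agreement rather than electing one. On the shipped benchmark set
the maximum is 15 of 22 and the optimal set contains 12.5 among four
values; the package reports the exact fraction (15/22 = 68.18%) and the
rounded percent. Subgroup summaries at ≥ 3.0 and ≤ 0.5 fold-WT are fixed
defaults matching the headline claims, and configurable.

For prospective use the cutoff is irrelevant: `rank_candidates()` simply
returns the $N$ kept candidates with the lowest barriers, ties broken by
the mutant identifier string so reruns are reproducible.

## The synthetic generator

`generate_profile()` and `generate_screening_set()` stand in for backend
output so the analysis chain is testable end to end. A profile is a
piecewise-linear bump through three anchors — (0, baseline),
(`peak_frame`, baseline + barrier), ($n$, baseline + `ti_delta`) — with
optional single-frame secondary peaks at a stated height below the global
maximum, and independent per-frame Gaussian noise (frame 0 included, so
extraction must tolerate a noisy reference). The construction guarantees
that at zero noise the extracted barrier and peak frame equal the
generator's labels exactly, and that a secondary peak within the
regularity window makes the profile irregular by the package's own
definition. All generation is seeded; no unseeded path exists.

Screening-set defaults — barriers from a Normal(13, 3.5²) kcal/mol
truncated below at 1, an irregular fraction of 0.15, 11-frame profiles —
mirror the barrier range and inconclusive share observed in the shipped
combinatorial amidase screen. What the generator does *not* emulate:
correlated noise along a profile, systematic shifts between related
mutants, or any physical relation between a mutant's composition and its
barrier. Passing tests therefore demonstrate that the bookkeeping,
extraction and filtering are correct, not that the semi-empirical energies
themselves are accurate for any real enzyme.

## Numerical and degenerate-input choices

- Energies and thresholds in kcal/mol, distances in Å throughout; no unit
  conversion layer.
- Barrier extraction is invariant under adding a constant to all energies;
  global-maximum ties resolve to the lowest frame.
- An order above the number of library positions counts 0 rather than
  erroring; requesting more ranked candidates than exist returns the full
  pool with a message.
- A degenerate schedule ($d_\mathrm{ini} = d_\mathrm{fin}$) is legal and
  constant; reversing the endpoints reverses the distance sequence.
- Table readers reject missing columns and non-numeric cells with the
  offending row numbers; the YAML pipeline configuration rejects unknown
  keys by name.
- Reports contain no timestamps, so reruns are byte-identical.

## Test problem sizes

The suite checks barrier recovery on 1000 zero-noise synthetic profiles,
filter-label recovery on 400 profiles, enumeration against a brute-force
oracle on 100 random libraries of up to six positions with up to five
substitutions each, and schedule affinity on dozens of random endpoint
pairs — sizes chosen so the whole suite runs in about a minute on a laptop
while still exercising every order of the combinatorial space the shipped
library spans.

## Limitations

The screen is qualitative by design. Known failure modes inherited from
the underlying method: barriers near the cutoff classify unreliably (the
benchmark's misclassifications concentrate there), organism- and
expression-level effects on measured activity are outside the model, and
the steric-exclusion list is only as good as the upstream structural
modelling that produced it.
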