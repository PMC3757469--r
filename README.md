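# mutscreen

Desk-scale tooling for *in silico* screening of combinatorial enzyme mutants
by estimated reaction barriers.

## The problem

Enzyme engineering campaigns routinely need to decide which of hundreds of
candidate multi-mutants are worth expressing and assaying. For serine
hydrolases such as *Candida antarctica* lipase B (CalB), formation of the
tetrahedral intermediate (TI) by nucleophilic attack of the catalytic serine
O<sup>γ</sup> on the substrate carbonyl carbon is assumed rate-determining, so a
lower computed barrier for this step is taken as a proxy for higher overall
activity. Barriers are estimated by adiabatic mapping: the O<sup>γ</sup>–C
distance is interpolated in equal steps between its value in the
enzyme–substrate complex (ES, frame 0) and in the TI (frame *n*),

d<sub>i</sub> = d<sub>ini</sub> − i·(d<sub>ini</sub> − d<sub>fin</sub>)/n,  i = 0…n (default n = 10),

each frame is geometry-optimized with the distance constrained by an external
semi-empirical program, and the barrier is

ΔE<sup>‡</sup> = max<sub>i</sub> E(i) − E(0)  (kcal/mol).

`mutscreen` implements everything *around* the quantum-chemistry step, which
stays behind a backend contract:

- **Combinatorics** — enumerate and count all single- to *k*-fold mutants
  from a per-position substitution library with multiplicities g<sub>i</sub>
  (counts are the elementary symmetric polynomials e<sub>o</sub>(g)), under
  steric exclusion constraints given as forbidden mutation pairs.
- **Scheduling** — render per-frame constrained-optimization job descriptions
  (fixed distance, frozen surface residues, gradient criterion, locality
  cutoff) for the external backend.
- **Profile analysis** — extract barriers and peak positions from energy
  profiles, flag irregular (multi-peaked, inconclusive) profiles, and filter
  out irregular or high-barrier candidates.
- **Classification & benchmark** — convert experimental fold-wild-type
  activities and computed barriers into qualitative ±1 activity factors,
  count agreement, scan the barrier cutoff c<sub>S</sub> for maximum
  agreement, rank surviving candidates by barrier, and summarize the
  composition of a candidate list.
- **Synthetic profiles** — a seeded generator of labelled energy profiles so
  the whole analysis chain is testable without any quantum-chemistry
  program.

The published CalB amidase benchmark tables ship as packaged fixtures: the
22-mutant benchmark set S (with the WT reference), the six-position
substitution library (g = 1, 1, 3, 2, 5, 1), the two forbidden pairs
(A141N–I189Y, A141Q–I189Y) and the 20 lowest-barrier candidates from the
combinatorial set L.

## Worked example

```r
library(mutscreen)
library(dplyr)

lib <- calb_mutation_library()
count_by_order(lib, 1:4)
#> [1]  13  64 154 193

enum <- enumerate_mutants(lib, max_order = 4, exclusions = calb_exclusions())
nrow(enum)
#> [1] 386

set_s <- filter(calb_set_s(), mutant != "WT")
bench <- benchmark(set_s)          # cutoff c_S = 12.5 kcal/mol by default
bench
#> Activity benchmark: 15/22 correct (68%) at cutoff 12.5 kcal/mol
#>   high_activity (>= 3.0 fold-WT): 4/6 correct
#>   low_activity (<= 0.5 fold-WT): 7/8 correct

optimize_cutoff(set_s)
#> Cutoff scan: max agreement 15/22 (68%) at cutoff(s) 12.25, 12.50, 12.85, 12.90 kcal/mol

rank_candidates(calb_set_l_top20(), n = 3)
#> # A tibble: 3 × 3
#>    rank mutant                 barrier
#>   <int> <chr>                    <dbl>
#> 1     1 G39A-T103G-I189Y           5.7
#> 2     2 G39A-I189Y                 6.2
#> 3     3 G39A-A141Q-I189G-L278A     6.3
```

Of the 424 hypothetical single- to four-fold mutants, 38 contain a forbidden
pair, leaving 386 sterically possible candidates; 15 of those also appear in
the benchmark set. At the 12.5 kcal/mol cutoff the qualitative activity of
15 of the 22 benchmark mutants is predicted correctly (68%), including four
of the six most active (≥3-fold WT) and seven of the eight least active
(≤0.5-fold WT) mutants. The ranked list returns the screening candidates
with the lowest barriers; three lie below the predicted wild-type barrier of
7.5 kcal/mol.

`run_screening()` chains all stages (enumerate → analyze → filter → rank →
benchmark) and writes a report bundle; `inst/cli/mutscreen.R` exposes the
same stages as shell subcommands (`enumerate`, `schedule`, `analyze`,
`classify`, `benchmark`, `rank`, `simulate`).

Plots: `autoplot()` on benchmark and cutoff-scan objects, and
`plot_profiles()` for faceted energy profiles annotated with their filter
disposition.

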