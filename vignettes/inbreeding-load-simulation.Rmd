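---
title: "Simulating inbreeding load from dominant and overdominant mutations"
author: "odload"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating inbreeding load from dominant and overdominant mutations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Inbreeding depression — the fitness decline of inbred relative to outbred
individuals — is fed by the *inbreeding load* `B`: deleterious effects hidden
in heterozygotes that inbreeding exposes in homozygotes.  Two genetic
architectures produce such a load.  Under the **dominance model**, partially
or fully recessive deleterious alleles segregate at mutation–selection–drift
balance; inbreeding exposes them, and selection against the exposed
homozygotes *purges* them.  Under the **overdominance model**, heterozygotes
are fitter than both homozygotes, so Mendelian segregation itself maintains a
load that selection cannot purge: the polymorphism *is* the optimum.  The two
architectures predict different dynamics in small or selfing populations, and
odload exists to simulate those dynamics jointly and to account for the load
the way empirical studies do.

## The model

`evolve()` runs a discrete-generation Wright–Fisher life cycle for `n`
diploids.  Each offspring is produced by self-fertilisation with probability
`S`, otherwise by two distinct parents.  Mutations are non-recurrent
(infinite sites): every event creates a fresh site, stored as an id in sparse
per-haplotype vectors, with a central registry of per-mutation parameters and
copy counts.  Four classes exist:

| class | genotype fitnesses | parameters |
|---|---|---|
| deleterious / lethal | `1, 1 - sh, 1 - s` | `s`, `h` |
| overdominant, classical | `1 - sW, 1, 1 - sM` | `sW`, `sM` (`= s_o` when symmetric) |
| overdominant, alternative | `1, 1 + s_o, 1` | `s_o` |
| neutral | `1, 1, 1` | — |

Fitness is multiplicative across loci.  Two traits are supported:
**viability** (a survival probability, capped at one, applied by rejection
sampling on candidate offspring) and **fecundity** (parents drawn with
probability proportional to fitness, offspring accepted unconditionally).
Under the classical overdominance scheme a segregating locus penalises
*every* wild-type homozygote — including individuals that never carried the
mutation — which is what makes the classical segregation load so large.

Recombination is either *free* (each heterozygous site transmits
independently, the default) or *mapped* (Poisson crossovers on a chromosome
of `totalLength` Morgans, no interference, uniform mutation positions).

### Load accounting

* **Inbreeding load** `B = sum over segregating loci of 2 d p q`, in lethal
  equivalents, with the dominance deviation `d = s (1/2 - h)` for
  dominance-type loci, `d = (sW + sM) / 2` for classical overdominance and
  `d = s_o / (1 + s_o)` for the alternative scheme.  One symmetric
  overdominant locus contributes at most `s_o / 2` (at `q = 1/2`), so `n_o`
  such loci are expected to hold `B_o = n_o s_o / 2` (`expectedBo()`).
  We use the sign convention `d = s (1/2 - h)` so that partially recessive
  deleterious alleles (`h < 1/2`) contribute positive load.
* **Maximum fitness** `W_max` is the fitness of the best genotype
  constructible from the alleles present: the fixed deleterious factor
  `wFixDel` times, under the classical scheme, `(1 - s_hom)` of the surviving
  allele for every overdominant locus that left polymorphism — or, under the
  alternative scheme, `(1 + s_o)` per segregating overdominant locus, capped
  at one for viability.
* **Expressed load** `L = (W_max - W) / W_max`.
* **Inbreeding depression** of selfed progeny `delta = log(W_O / W_S)` and
  its rate `delta* = delta / (F_S - F_O)`, with the progeny inbreeding
  coefficients estimated from segregating neutral markers by the SNP-based
  estimator implemented in `yangInbreeding()` (reference allele frequencies
  taken from the assayed parental population, which is the progeny's parent
  generation; monomorphic markers are excluded because the estimator is
  undefined at `p = 0` or `1`).

### Fixed-load bookkeeping

Mutations reaching copy number `0` or `2n` are pruned the same generation.
During a burn-in, load fixed before line foundation is excluded from
reported fitness: under viability selection a factor shared by every
individual cannot change survivor composition, and the bottleneck tables
report declines *within* lines.  For the same reason, classical overdominant
loci fixed or lost before foundation are dropped entirely — retaining them
would multiply every fitness by `(1 - s_o)` per event and drive reported
means toward zero without affecting any dynamics.  After `foundSample()`
(which restarts accounting at generation 0), `trackFixed = TRUE` folds fixed
deleterious mutations into `wFixDel` and counts overdominant loci leaving
polymorphism in `nOFixed` / `odFixFactor`, which is exactly what `W_max` and
the trajectory fitness need.  Under the alternative scheme a fixed
overdominant locus has homozygote fitness one, so dropping it at foundation
is arithmetically identical to retaining it.

## Parameters and defaults

Rates are genome-wide haploid rates per generation.

| parameter | default | meaning |
|---|---|---|
| `U` | 0.2 | deleterious (non-lethal) mutation rate |
| `ULet` | 0.02 | lethal/sterile rate (`s = 1`, `h = hLethal`) |
| `UO` | 0 | overdominant rate (studied levels: 1e-5 … 1e-4) |
| `UN` | 1.0 | neutral marker rate (only feeds the inbreeding estimator) |
| `sShape`, `sMean` | 0.33, 0.2 | gamma distribution of deleterious `s`, truncated to (0, 1] |
| `hMax`, `hRate` | 0.5, 7 | dominance rule `h = hMax exp(-hRate s)` |
| `hLethal` | 0.02 | dominance of lethals |
| `sOWild`, `sOMut` | 0.04 | overdominant homozygote disadvantages |

The deleterious/lethal parameters are a **calibration**, not a measurement:
the gamma shape follows the popular mutational models for fitness (an
L-shaped distribution with many nearly neutral and few large-effect
mutations; `h` decreasing in `s` so large-effect mutations are nearly
recessive), and `hRate`, `ULet` and `hLethal` were then fixed — once, before
any downstream experiment was run — so that a panmictic `n = 1000` population
at balance reproduces the canonical base-population anchors of this model
class: mean viability near 0.69 (close to the `exp(-2U)` prediction),
total inbreeding load near 2.3–2.5 lethal equivalents split roughly 1.5/0.85
between deleterious and lethal classes, and, in a 50-founder sample, about
1400–1550 segregating deleterious mutations at mean frequency ~0.09 and
60–75 lethals at mean frequency ~0.013.  Note that the segregating *counts*
are sample statistics: a sample of 100 gametes hides most of the large
low-frequency class present in the base population, while `B` and `W` are
essentially invariant to sampling (`E[B_sample] = (1 - 1/2k) B_base`).

For reporting, dominance-type mutations are split at `s = 0.9` into
"deleterious" and "lethal" classes, so the rare large-`s` gamma draws count
as lethals alongside the `ULet` class.

## The experimental designs

* `runBurnin()` — a base population of `nBase = 1000` evolved for
  `burninGens = 10000` generations at selfing rate `S`.  Deleterious and
  lethal classes reach mutation–selection–drift balance within a few thousand
  generations, but the number of segregating overdominant loci does *not*
  equilibrate: symmetric overdominant alleles with `2 N s_o >> 1` are almost
  never lost once established, so `n_o` grows roughly linearly at the rate
  (influx `2 N U_o`) × (establishment probability ≈ `2 s_o`).  The
  10 000-generation burn-in is therefore part of the study conditions — e.g.
  `U_o = 1e-4`, `s_o = 0.04` accumulates `~0.2 × 0.08 × 10^4 ≈ 150`
  overdominant loci — and shortening it proportionally lowers `n_o` and
  `B_o`.
* `selfingSweep()` — burn-ins at `S = 0, 0.25, 0.5, 0.75, 1`, each followed
  by a 50-founder sample and a `selfingAssay()`, aggregated over replicates,
  with the closed-form expectation columns `E_Bo = n_o d / 2` and
  `E_delta = (B/2)(1 + F)`, `F = S / (2 - S)`.
* `runBottleneckLines()` — lines of `n = 50` founded from an `S = 0` base and
  kept panmictic for 250 generations under continued mutation, selection and
  drift; per-generation trajectories of `W`, `W_max`, `L` and the partitioned
  `B`, plus the table of class counts, frequencies and `dW_pct` (the
  proportional fitness decline relative to each line's own generation-0 mean,
  averaged across lines) every `reportInterval = 50` generations.

The selfing assay computes *expected* genotypic fitness of each progeny (no
survival lottery, no new mutations) because the assay estimates expectations
and both choices only add noise that the progeny counts would have to buy
back; progeny genotypes are still randomly segregated gametes.

## Randomness, determinism and numerical choices

All stochastic draws — including the C++ engine's — flow from R's RNG, so
`set.seed()` before any call fully determines its result.  The orchestrators
use the documented derivation `set.seed(baseSeed + r)` for replicate `r`
(sweeps offset each selfing-rate level by `10000 (m - 1)`), which the JSON
run manifest records; `runReplicates()` from a `manifestConfig()` reproduces
every full-precision output byte for byte.  Per-site transmission coins are
served 24 to a `unif_rand()` draw; the bit cache is reset at every entry into
the engine so results never depend on call history.

Viability selection uses rejection against the running cohort maximum, which
is exact for survivor composition at fixed `n` (only relative viabilities
matter) while still reporting absolute mean viability.  A generation in
which every candidate has zero fitness (or `5e7` candidate draws are
exhausted) flags the run `extinct`; extinct replicates are excluded from
aggregation and counted.  The deterministic single-locus recursion iterates
to `1e-12` on genotype frequencies with an iteration cap; the exact chain
(`singleLocusChain()`) enumerates genotype-count states `(n_AA, n_Aa,
n_aa)` — allele counts alone are insufficient under selfing — and solves
absorption by dense linear algebra, refusing `N > 30`.

Display tables are rounded the way such tables are conventionally printed
(counts to 1 decimal, frequencies and loads to 2, fitness decline to 1); a
`*_full.tsv` companion written at `%.17g` round-trips exactly, so downstream
checks never fight display rounding.

## Problem sizes used by the test suite and acceptance script

The packaged checks run the full 10 000-generation, `n = 1000` burn-ins the
designs call for — the overdominant supply makes the burn-in length
substantive — but scale the replication down: 1–3 burn-in replicates per
scenario (5 000 generations for the dominance-only scenarios, whose mutation
classes are at balance well before that) and 10–12 bottleneck lines drawn
from them (the full design uses 200 independent replicates).  Against Monte-Carlo error of that size the
stochastic anchors are reproduced within a few percent; quantities dominated
by the overdominant-locus supply (`n_o`, `B_o`, and through them the late
fitness declines) inherit its replicate-to-replicate spread of roughly
±8–10%.  The neutral-marker rate is set to 0 in runs where no marker-based
estimate is computed; neutral sites are fitness-inert by construction (a
tested invariant), so this changes compute cost only.

## What the simulator does and does not emulate

The generator reproduces the study conditions of its model class: joint
dominance/overdominance architectures, partial selfing, drastic bottlenecks,
multiplicative fitness, infinite sites.  It does **not** emulate several
features of real data: linkage maps are a single chromosome (so no
chromosome-number effects and, under the default free recombination, no
pseudo-overdominance from repulsion linkage); `h` is a deterministic
function of `s` rather than a joint distribution; there is no epistasis,
environmental fitness variance, back-mutation, or separate sexes; and the
overdominant class has fixed effects per scenario rather than a distribution.
Passing tests therefore show that the implementation is a faithful engine
for this model family — not that the calibrated DFE is the truth about any
particular species' genome.

## Known limitations

* The exact chain is limited to one locus and small `N`; multi-locus
  validation is statistical (copy-count conservation, martingale checks,
  drift-decay rates), not exact.
* `meanFitness()`/`loadSummaryRow()` recompute fitness in R for
  transparency; for long runs use the engine trajectory, which logs the same
  quantities every generation at C++ speed.
* Snapshots serialise whole populations as text; they are meant for
  resuming runs and building fixtures, not as a compact archival format.
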