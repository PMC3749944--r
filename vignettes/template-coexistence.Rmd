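---
title: "Methods: resource competition of template replicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: resource competition of template replicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(replicoex)
```

This vignette documents the model, the analytic theory, the default
parameters and the numerical choices behind `replicoex`. Code chunks are
shown but not evaluated at build time; every quantitative statement made
here is computed by the package's test suite or by
`scripts/acceptance.R`, not asserted from memory.

## The model

The unit of competition is a *sequence pair*: a plus strand of length $L$
over a monomer alphabet and its pairing image. The pairing image is
determined by the **pairing scheme** (homologous: each base maps to
itself; complementary: each base maps to its complement) and the
**polarity** (parallel: same reading direction; antiparallel: reversed).
The four combinations give four strand maps — identity, complement,
reverse, and reverse-complement. When a strand equals its own image
(e.g. any strand under homologous–parallel pairing, or a reverse
palindrome under complementary–antiparallel pairing) the pair collapses
to a single self-paired strand.

Replication is stage-structured. A strand at stage $r$ carries a partial
copy of length $r$; stage $0$ is the free strand. With $x_r$ the
concentration at stage $r$, $m_j$ the concentration of monomer type $j$,
$k$ the elongation rate constant, $\delta_r$ the decay rate of the
replication intermediate occupying slot $r$, and $\mathrm{ins}(r)$ the
monomer type inserted at copy position $r$ (the pairing image of the
template base at position $r$):

$$
\dot x_r = k\, m_{\mathrm{ins}(r)} x_{r-1}
         - k\, m_{\mathrm{ins}(r+1)} x_r
         - \delta_r x_r, \qquad 0 < r < L,
$$

completion of the last step releases the free template (its own stage 0)
plus a free copy of the *partner* strand (the partner's stage 0); for a
self-paired strand both products are the same species, so the completion
flux enters its stage 0 twice. Monomers obey

$$
\dot m_j = f_j - g_j m_j
         - k\, m_j \sum_{\text{steps inserting } j} x_{r-1},
$$

with constant influx $f_j$ and first-order decay $g_j$. Decayed strands
and intermediates do **not** return monomers to the pool (no recycling).
Free strands themselves do not decay; turnover acts on intermediates and
monomers. The state space of a system with $P$ pairs is the union of all
stage variables of all (collapsed) strands plus the monomer pool; the
right-hand side and the analytic Jacobian are implemented in C
(`src/replicoex.c`) and verified in `tests/testthat/test-kinetics.R`
against an independent pure-R oracle and a hand-written explicit
two-strand model.

## Analytic theory (binary alphabet, homologous pairing, uniform rates)

At a coexistence steady state each persisting strand must exactly double
per pass through its cascade. With uniform intermediate decay $\delta$
this pins every monomer that limits some strand to

$$
\kappa = \frac{\delta}{2^{1/L} - 1},
$$

and intermediate concentrations decay geometrically along the cascade
with ratio $\rho = 2^{-1/L}$ per stage. A position $i$ of the sequence
therefore contributes weight $\rho^{\,i-1}$: early positions consume
monomer at higher intermediate concentrations and matter more (the *head
effect*). Summing weights by monomer type gives per-sequence weighted
compositions $\alpha_A, \alpha_B$ and the scalar statistic

$$
s = \alpha_A - r\,\alpha_B ,
$$

(with $r$ a ratio fixed by the symmetric monomer supply; $r = 1$ under
the package defaults). Two sequences coexist iff their statistics have
opposite signs — each is then limited by a different monomer once
position weights are accounted for. Sequences with *identical monomer
counts* are dynamically neutral: the system has a line of fixed points,
the leading eigenvalue is zero, and the attained state depends on the
initial conditions. Note neutrality is keyed to compositional identity,
not merely to equality of $s$: equal counts force equal statistics but
the converse is false, and simulation confirms that equal-$s$,
different-composition pairs are not neutral.

Because $\rho^{\,i-1}$ is decreasing, a head block of $h$ minority bases
can outweigh a majority tail when

$$
h \;\ge\; \lceil L \log_2 (4/3) \rceil ,
$$

with $\log_2(4/3) \approx 0.41504$ in the long-$L$ limit. The first
length at which two *same-majority* sequences can coexist is $L = 7$
(e.g. `BBBAAAA` vs `AAAAABB`, both A-majority). All of these statements
are enforced by `tests/testthat/test-analytic.R` and by the exhaustive
criterion–simulation equivalence check in `test-acceptance.R` (all
ordered binary pairs, $L \le 5$).

On two monomer types no three sequences coexist in a structurally stable
way: tuned three-way coexistence exists but is neutral and is destroyed
by an arbitrarily small generic perturbation of the decay rates
(`test-acceptance.R`). Under complementary pairing on four monomer
types, stage structure partitions the resources finely enough that up to
eight distinct strands (four pairs) coexist with a strictly negative
leading eigenvalue — twice the number of resources — while no sampled
group of five pairs coexists. The degenerate exception: with *exactly*
uniform decay the pooled monomer-consumption constraints of
complementary pairs have rank 2, so larger groups can rest on a neutral
manifold; any narrow jitter of the decay rates restores exclusion, which
is why the randomized-degradation protocol and the CLI examples draw or
jitter $\delta$.

## Parameter defaults and rationale

| Parameter | Default | Rationale |
|---|---|---|
| elongation $k$ | 1 | sets the time unit; only ratios matter |
| monomer influx $f_j$ | 1 | symmetric supply, order-1 scale |
| monomer decay $g_j$ | 1 | order-1 turnover; ceiling $f/g = 1$ |
| intermediate decay $\delta_r$ | 0.01 | slow relative to elongation so cascades complete; keeps $\kappa < f/g$ up to $L \approx 70$ |
| randomized draws | $\delta_r \sim U(0.009, 0.011)$ | ±10% narrow jitter: breaks degeneracies without leaving the slow-decay regime |

The survey protocols draw one fresh degradation-rate set per (cell,
replicate); elongation, influx and monomer decay stay at their symmetric
defaults so that coexistence differences are attributable to sequence
structure. The analytic theory additionally requires uniform $\delta$
and refuses non-uniform inputs rather than silently approximating.

## Generator realism

Scan cells are ordered pairs (or $N$-tuples) of sequences drawn from the
full combined sequence space. Exhaustive enumeration is used when the
space is small (e.g. all $8^2 = 64$ ordered binary pairs at $L = 3$);
larger spaces are sampled uniformly **with replacement**, duplicates are
logged, and the sample size is reported alongside the fraction.
Fractions are computed over converged runs only, with the unconverged
count reported. The constructive stable-set search
(`find_stable_set()`) draws each plus strand with probability mass
`bias` on a distinct focal monomer — mimicking the composition
partitioning that the theory predicts is necessary — then verifies each
candidate end to end by simulation; the returned result carries the
drawn rate set, because stability is a claim about that specific system.

## Numerical choices

- **Integration**: `deSolve::lsoda` in windows, with the C right-hand
  side and Jacobian. Convergence requires *both* a windowed
  rate-of-change test and a relative right-hand-side test
  $|\dot y| / \max(y, \epsilon_{\mathrm{ext}}) < \epsilon$; the windowed
  test alone mistakes slow transients near neutral manifolds for
  equilibria.
- **Extinction**: a species is extinct when its total concentration
  falls below `eps_ext` ($10^{-8}$); extinct blocks are clamped to zero
  so they cannot numerically resurrect.
- **Early solver returns**: lsoda's step-limit returns are accepted at
  the time actually reached and integration continues; only zero
  progress aborts. The solver's stdout notices are suppressed.
- **Stability**: eigenvalues of the analytic Jacobian at the attained
  steady state; `stable` / `neutral` / `unstable` classified with a
  $10^{-6}$ tolerance around zero. Neutral classifications are always
  reported as such, never folded into "stable".
- **Reproducibility**: every scan and search takes an integer seed;
  rerunning a CLI scan with the same config yields byte-identical CSVs.

## Problem sizes and cost

Exhaustive binary scans are cheap ($L = 3$: 64 cells in seconds); the
largest routine computations are the 2000-cell sample at $L = 9$ and the
5000-cell complementary sample, each well under a minute per thousand
cells on one core. The randomized-degradation grand mean (6400 runs)
completes in under a minute.

## Open questions and decisions taken

- *Neutrality condition*: implemented as compositional identity (see
  above), the strictly correct condition, rather than equality of the
  statistic.
- *Re-verification of found stable sets*: performed under the rate set
  the search drew, not a fresh draw — the claim is conditional on the
  rates, and a fresh draw is a different dynamical system.
- *Zero-pair systems* are permitted (monomer-only dynamics), keeping the
  model total on its input space.

## Limitations

Deterministic mass action in a well-mixed volume: no finite-population
stochasticity, spatial structure, mutation, sequence-length change, or
monomer recycling. Stability is local (linearization at the attained
fixed point); global basins are probed only indirectly through
initial-condition dependence tests on neutral systems. The closed-form
criterion covers the binary-alphabet, homologous, uniform-decay case;
all other regimes are handled by simulation.
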