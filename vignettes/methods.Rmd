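---
title: "Model and methods: how a developmental organisation learns to generalise"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question

Developmental architectures bias which phenotypes mutation can reach. Under
selection in a *sequence* of environments that share structural regularities,
can short-sighted natural selection shape those biases so that the system
becomes predisposed to produce phenotypes it has *never* been selected for —
novel members of the same structural family? `grnevolve` casts this as a
statistical-learning problem: past environments are a training set, the full
family is the test set, and the evolved developmental organisation is the
model whose generalisation we measure.

# The model

## Phenotype class (the synthetic world)

A phenotype is a vector of $N = 16$ signed traits partitioned into 4 modules
of 4 traits. Each module has two complementary states, $A_m = -B_m$. The
class of viable targets is every concatenation of per-module states, with a
pattern and its global complement identified (the canonical representative
has first trait $+1$): $2^{4-1} = 8$ distinct members. All targets therefore
share intra-module structure, while inter-module combinations vary freely —
exactly the kind of regularity a learner can exploit.

Training uses 3 members; testing uses all 8 (the test set includes the
trained targets, so perfect generalisation means a distribution uniform over
the full class). The selective environment switches between the training
targets every $K$ generations; an *epoch* is $N_T \times K$ generations, one
pass over the $N_T = 3$ training environments.

**Choice of the training triple.** The paper-style experiment assumes the
training sample carries the class's combinatorial structure. Under the
canonical lexicographic ordering the first three members leave two modules in
the same state across all three training targets; that degenerate sample
plants a *spurious, perfectly supported* inter-module correlation that no
selective condition can unlearn — empirically every scenario then collapses
onto a single pattern. The package default (`default_train_indices()`) is the
lexicographically first triple in which every module state, and every
module-pair product, varies across the training set ($\{P_1, P_4, P_6\}$ for
the default class). This is a design decision of this package, documented
here because the source experiment does not identify its three targets.

## Development

The genotype is $[G, B]$: direct effects $G \in [-1,1]^N$ (the embryonic
expression state) and an unbounded $N \times N$ regulatory matrix $B$.
Development iterates

$$P(t+1) = (1-\tau_2)\,P(t) + \tau_1 \tanh\!\big(B\,P(t)\big),
  \qquad P(0) = G,$$

for $T$ steps; the adult phenotype is $P(T)$, normalised to $[-1,1]^N$ by
$P_a \leftarrow P_a / (\tau_1/\tau_2)$. Defaults $\tau_1 = 1$, $\tau_2 =
0.2$, $T = 10$; all three are configuration parameters, as the source
experiment's developmental constants are not published in full. The map is
odd ($\mathrm{develop}(-G,B) = -\mathrm{develop}(G,B)$), which is what makes
a pattern and its complement dynamically equivalent and justifies the
complement folding used throughout. With $B = 0$ the dynamics are a pure
decay that preserves the sign pattern of $G$: the ancestral organisation
represents all $2^N$ sign patterns equally.

## Fitness and the hill climber

For target $S \in \{-1,+1\}^N$, benefit is
$b = \tfrac12\big(1 + P_a\!\cdot\!S / N\big) \in [0,1]$ and fitness is
$f_S(P_a) = b - \lambda c$ with connection cost
$c = \sum_{ij} |b_{ij}| / N^2$ (L1, favouring sparsity) or
$c = \sum_{ij} b_{ij}^2 / N^2$ (L2, favouring weak coefficients).

Evolution is strong-selection/weak-mutation hill climbing: one genotype, one
mutant per generation, mutant fixed iff its fitness *strictly* exceeds the
parent's. Every reproduction perturbs one uniformly chosen gene of $G$ by
$U[-0.1, 0.1]$ (clamped to $[-1,1]$); with probability `b_prob` every
element of $B$ is additionally perturbed by $U[-\mu, \mu]$ with
$\mu = 0.1/(15N^2)$.

**The B-mutation rate.** The source describes this rate twice,
inconsistently: once as probability $1/15$ and once as "half the
reproduction events". The two rates produce the same qualitative trajectory
on different clocks (the $1/15$ trace is the $1/2$ trace stretched roughly
sevenfold), but only $1/2$ completes the published endpoint behaviours —
L1-driven generalisation to the full class, the control's overfitting
signature — within the published run length of 150 epochs at $K = 20000$.
The package default is therefore `b_prob = 0.5`, with the alternative
available as a knob.

**Why the clamp matters.** Once $G$ has adapted to the current target its
entries sit exactly at $\pm 1$; mutations pushing outward change nothing,
and in those generations acceptance is decided purely by the (tiny) fitness
differential of the simultaneous $B$ perturbation. These "quiet"
generations are the channel through which selection acts coherently on the
developmental architecture; without hard bounds on $G$, $B$ evolution would
be hitch-hiking noise.

## Environmental noise

With noise scale $\kappa$, a fitness evaluation sees $S + \kappa n$,
$n_i \sim \mathcal N(0,1)$ iid, fresh each generation. Parent and mutant
are evaluated against *independent* realisations (`noise_mode =
"independent"`, the default). This is a deliberate design decision: if both
genotypes share one realisation the noise enters the selection differential
only through $P_\text{mut} - P_\text{par}$ and is suppressed by a factor
$\sim|\Delta P|/|P| \approx 10^{-3}$, making the published "optimal"
$\kappa = 35\times10^{-4}$ numerically inert (we verified that shared-mode
noise traces are indistinguishable from the control). With independent
realisations the noise acts as a finite selection temperature on the small
$B$ differentials — the mechanism by which jittering slows canalisation.

## Measuring the induced phenotype distribution

Generalisation is a property of $B$ alone: we estimate the distribution of
phenotypes that development *spontaneously* produces from random embryonic
states (drift dominates $G$ because its mutation scale vastly exceeds
$B$'s). Classify-and-Count: 5000 embryonic states drawn uniformly in
$[-1,1]^N$ (scrambled Sobol by default — a Joe–Kuo sequence with Matousek
linear scramble plus digital shift, implemented in `src/sobol.cpp`; plain
uniform sampling is provided and statistically equivalent), each developed
under fixed $B$, each adult discretised to its sign pattern (an exact zero
maps to $+1$; a measure-zero tie rule for determinism), tallied raw
("unfolded") and with complements identified ("folded").

From the folded frequencies $O(s_i)$:

* **training / test error**: $\chi^2(O, E) = \sum_i (O_i - E_i)^2 / E_i$
  with $E$ uniform over the training set (3 patterns) or the full class
  (8 patterns). $O$ is *not* renormalised over the set: mass outside the
  set depresses $O$ and inflates the error, so a perfectly generalised
  system scores 0 on the test set and a system canalising one pattern
  scores up to $\approx 7$.
* **coverage**: class members with folded frequency $\ge 0.01$.
* **entropy**: plug-in Shannon entropy (bits) of the *unfolded*
  distribution. The ancestral $B=0$ population value is $N = 16$ bits, but
  the 5000-sample plug-in estimate is capped at $\log_2 5000 \approx 12.3$
  bits; the meaningful final values (4 bits for a class-generalised
  organisation: 4 independently varying modules) are far below the cap and
  unaffected.

Measurement runs on its own seeded stream and never touches the evolution
RNG.

# What the scenarios show

With the defaults ($K = 20000$, 150 epochs, i.e. $9\times10^6$
generations):

* **control** ($\lambda = 0$, $\kappa = 0$): test error falls from the
  no-model baseline ($\approx 1$) to a minimum $\approx 0.35$ around epochs
  10–12, then rises to $\approx 0.8$ while training error keeps falling
  toward 0 — textbook over-fitting. The end state memorises the 3 trained
  targets plus some novel module combinations (coverage typically 7 of 8
  here; the source reports 6 — see the ledger note on this one-member
  discrepancy).
* **noise** ($\kappa = 35\times10^{-4}$): the same descent stretched out;
  the minimum ($\approx 0.36$–$0.41$) is only reached near epoch 150 —
  canalisation postponed, not avoided.
* **weak connectivity** (L2, $\lambda = 38$): the trace flattens near its
  minimum — behaviour analogous to early stopping.
* **sparse connectivity** (L1, $\lambda = 0.22$): inter-module couplings
  are pruned, $B$ converges to a near block-diagonal organisation, and the
  distribution becomes uniform over the whole class: coverage 8/8, test
  error $\to 0$, entropy $\to 4$ bits, training error $\to 3 \times
  (1/8 - 1/3)^2/(1/3) \approx 0.39$.

## Why the scaled-down preset was abandoned

A natural scaled preset ($K = 2000$, same 150 epochs) fails for a reason
worth recording: after each environment switch, $G$ needs ~600–1000
generations to re-adapt (set by the gene mutation step and $N$, independent
of $K$). At $K = 2000$ this transient consumes the block and the system
sits in the fast-switching regime — every condition collapses onto the
trait-majority pattern of the training set. The "learning rate" of the
developmental architecture is governed by the exposure time *net of that
transient*, so $K$ cannot be scaled down without changing the regime. The
compiled core runs the full-scale world in well under a minute, so all
shipped tests and the acceptance report use $K = 20000$.

## Rate of adaptation

Evolvability is assayed by freezing $B$, re-randomising $G$, and hill
climbing on benefit alone (cost is constant with $B$ frozen) until the
developed sign pattern equals the target, up to 2500 generations (censored
runs carry 2500). "Reached the target" is the discrete sign-pattern event:
with saturating dynamics the continuous benefit approaches its optimum only
asymptotically, so the sign criterion is the event being counted; a
threshold criterion can be emulated via the benefit if needed. Organisations
evolved under L1 reach every class member quickly (no censoring); control /
noise / L2 organisations cannot reach their missing member(s) at all.

## Sensitivity sweeps

`sensitivity_sweep()` exposes the U-shape of the final test error in the
regularisation weight and the noise level. Default grids are log-spaced and
chosen so that both regime boundaries of *this* model are interior to the
sweep: L1 $\lambda \in \{10^{-4}, 10^{-2}, 0.22, 1, 30\}$ (measured
boundaries: $10^{-4}$ over-fits like the control; $\lambda = 30$ returns
exactly the no-model baseline with $B \to 0$; the published optimum 0.22
sits in a wide effective plateau), L2 $\lambda \in \{0.1, 10, 38, 200,
1000\}$ and $\kappa \in \{0, 10^{-3}, 3.5\times10^{-3}, 10^{-2},
5\times10^{-2}\}$ (interior optimum at $3.5\times10^{-3}$, matching the
published value).

# Numerical and reproducibility notes

* All randomness flows through R's RNG (`set.seed()`), including inside the
  compiled loops; traces are bit-reproducible given a seed. Per-generation
  draw order is fixed: noise, gene choice, gene step, matrix gate, matrix
  steps.
* Acceptance of mutants uses strict inequality; exact ties (e.g. a clamped
  gene mutation with no matrix mutation) are rejected, keeping the parent.
* The measurement sample is one fixed scrambled-Sobol point set per run
  (seed offset from the run seed), so trace-to-trace measurement noise is
  common-mode.
* The Sobol implementation supports up to 36 dimensions; unscrambled output
  is verified bit-exact against an independent reference implementation in
  the test suite.
* The uniform-random schedule policy draws one target per $K$-block from a
  pre-generated, seed-indexed block table, so `target_at()` is
  block-constant and O(1).

# What a green test does and does not establish

The synthetic class generator *is* the world the experiments assume:
modular targets, complement degeneracy, equal-time cyclic exposure. Green
acceptance tests establish that the implemented evolutionary mechanics
reproduce the published relationships between regularisation, noise,
switching rate and generalisation *within this stated world*. They do not
establish anything about real gene-regulatory networks, about classes whose
modules are statistically dependent, about population-level (non-SSWM)
dynamics, or about robustness to the unpublished developmental constants
beyond the defaults documented above.

# Known limitations

* The developmental constants ($\tau_1, \tau_2, T$) and the B-mutation rate
  are under-determined by the source; defaults are the package's own
  resolution, recorded above, and everything is configurable.
* Plug-in entropy is biased low near the sample-size cap (early epochs).
* The switching-rate sweep at the published total of $24\times10^6$
  generations is available as a preset but excluded from the test suite for
  runtime; scaled presets preserve its qualitative ordering only down to
  $K \gtrsim 10^4$ (see above).
* Coverage uses a hard 0.01 frequency cut-off; members hovering at the
  threshold can flip a seed's coverage count by one.
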