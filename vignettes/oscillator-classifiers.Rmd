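---
title: "Classifying points with small networks of photosensitive chemical oscillators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying points with small networks of photosensitive chemical oscillators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oscnet)
```

## The model and its assumptions

`oscnet` simulates networks of identical chemical oscillators, each
described by the two-variable Oregonator reduction of photosensitive
Belousov–Zhabotinsky kinetics. For oscillator $j$ with activator $u_j$ and
inhibitor $v_j$:

$$\frac{du_j}{dt} = \frac{1}{\varepsilon}\Big[u_j - u_j^2 -
\big(f v_j + \phi_j(t)\big)\frac{u_j - q}{u_j + q}\Big] - \alpha u_j +
\beta \sum_{i \sim j} (u_i - u_j), \qquad \frac{dv_j}{dt} = u_j - v_j,$$

where $i \sim j$ runs over the coupled pairs of a symmetric adjacency
(all-to-all by default; for three all-to-all oscillators the coupling term
equals $-(\alpha + 3\beta)u_j + \beta\sum_i u_i$ because the self-exchange
contributions cancel). The assumptions inherited from the chemistry are:
all oscillators share the same kinetic constants; coupling is through
activator exchange only (no inhibitor transport); the species supplying the
extra decay and the exchange reactions are in excess, so $\alpha$ and
$\beta$ enter as constant first-order rates.

Illumination controls each oscillator individually:

$$\phi_j(t) = a\big(c + \tanh(-s\,(t - t_{\mathrm{ilum}}(j)))\big),$$

a smooth switch from $\approx 2a$ before the switch-off time to
$a(c - 1)$ afterwards. While $\phi \approx 0.2$ the oscillator has a stable
steady state at $u = v \approx 2\times 10^{-4}$ (`steady_state()` solves
the scalar fixed-point equation by bracketed root-finding on $(0,1)$ to a
tolerance of $10^{-14}$); once released, it fires large activator spikes.
`measure_period()` reports the free-running period at
$\phi = 10^{-4}$, $\alpha = 0.849$ as $\approx 10.8$ time units. The
parsing of the Oregonator nonlinearity as
$(fv + \phi)\,(u-q)/(u+q)$ is the standard photosensitive form and is the
only reading under which $u = v \approx 2\times10^{-4}$ is a fixed point at
$\phi \approx 0.2$; it is cross-checked by the steady-state, period and
stripe-counting tests.

## Parameters that matter

* $\varepsilon = 0.2$, $q = 2\times10^{-4}$, $f = 1.1$ (dimensionless):
  fixed kinetic constants of all oscillators; never optimized.
* $a = 0.1$, $c = 1.001$, $s = 10$ (illumination amplitude, offset, switch
  slope): fixed constants of $\phi_j$. The offset keeps $\phi$ strictly
  positive ($\phi \to 10^{-4}$, the oscillatory regime, rather than 0).
* $\alpha, \beta \ge 0$ (1/time): activator decay and coupling rates. The
  decay moderates spike amplitude so that the coupling is controllable;
  both are genome traits of the classifier.
* $t_{\mathrm{start}} < t_{\mathrm{end}}$, $t_{\mathrm{ilum}}(3)$,
  $t_{\max}$ (time units): input-encoding anchors, the normal oscillator's
  fixed inhibition time, and the observation window.
* $h = 10^{-4}$ (time units): RK4 step. Samples are stored every 0.01 time
  units regardless of $h$.
* Peak threshold 0.05 (activator units): a counted maximum must exceed it.
  Spikes are $O(0.1\!-\!1)$ and the inhibited baseline is
  $2\times10^{-4}$, so the threshold sits two decades above baseline and
  two-ish below the spikes; counts are insensitive to its exact value.

## Numerical choices

* **Integrator.** Classic fixed-step RK4 in compiled code, from $t = 0$ to
  $t_{\max}$, no burn-in. Fixed step keeps runs bit-reproducible and makes
  the batch driver trivially vectorizable over records. Refinement tests
  verify the nominal convergence order and that maxima counts are
  identical at $h = 10^{-3}$ and $10^{-4}$; the coarser step is used where
  only counts matter (e.g. inside the genetic algorithm).
* **Initial condition.** Each oscillator starts in the steady state of its
  own initial illumination $\phi_j(0)$ — the prepared state of a strongly
  illuminated BZ oscillator. For the free-running period measurement the
  illumination is *held* at $10^{-4}$ but the start is still the
  illuminated steady state: the fixed point at $\phi = 10^{-4}$ itself is
  unstable, and a trajectory started exactly on it never leaves it.
* **Peak detector.** Interior strict local maxima of the stored series
  (`u[i-1] < u[i] >= u[i+1]`) above the threshold; samples at $t = 0$ and
  $t = t_{\max}$ are never counted. This is deterministic and
  grid-convention-free; any detector with these properties gives the same
  counts at the stored sampling interval of 0.01.
* **Instability policy.** Activator values below $-10^{-6}$, non-finite
  states, or magnitudes above $10^3$ raise an error rather than being
  clamped. The batch driver can instead flag the failing record, which the
  GA uses to assign fitness 0 and continue.
* **Tie-breaks.** The majority rule maps ties and unseen counts to class 0
  (the background); MI ties across oscillators select the lowest index.
  Both are arbitrary but deterministic.

## The classifier and its fitness

A labeled record $(x, y, g)$ is encoded as switch-off times
$t_{\mathrm{ilum}}(1) = t_{\mathrm{start}} + (t_{\mathrm{end}} -
t_{\mathrm{start}})x$ (likewise $y$ for oscillator #2), simulated, and read
out as the maxima counts $(o_1, o_2, o_3)$. Over a dataset these become
random variables $O_j$, and the fitness is
$\max_j I(G; O_j) = \max_j [H(G) + H(O_j) - H(G, O_j)]$ in bits, with
plug-in entropies. No bias correction is applied: with $N = 800$ records
and at most a handful of observed count values the plug-in bias is
negligible compared with the binomial noise of the accuracy itself.
Using MI rather than accuracy to drive the optimization avoids committing
to a count-to-class mapping during the search; the mapping (the per-count
majority rule) is fitted on the training table afterwards and frozen for
test evaluation.

## The evolutionary optimizer

Generational GA over the 7 traits (role of oscillator #3,
$t_{\mathrm{ilum}}(3)$, $t_{\mathrm{start}}$, $t_{\mathrm{end}}$,
$t_{\max}$, $\alpha$, $\beta$): population $K = 200$, top 20% carried
unchanged (with cached fitness — evaluation is deterministic), offspring
from two distinct parents drawn uniformly from the top 50%, per-gene
uniform crossover, mutation hitting one gene per genome on average with a
uniform $\pm 10\%$ relative perturbation, 1,000 generations. Where the
procedure is under-specified the package chooses the simplest consistent
operator and documents it: uniform crossover; uniform mutation on the
capped interval; network-level (not gene-level) parent pooling; violations
of $t_{\mathrm{start}} < t_{\mathrm{end}}$ repaired by swapping the two
values; a gene at exactly 0 is immobile under relative mutation (the
initialization ranges avoid exact zeros). Initialization ranges —
$t_{\mathrm{start}} \in [0,10]$, $t_{\mathrm{end}} \in
[t_{\mathrm{start}}+0.5, 40]$, $t_{\mathrm{ilum}}(3) \in [0,30]$,
$t_{\max} \in [5,50]$, $\alpha \in [0,1.5]$, $\beta \in [0,1]$ — bracket
the $\approx 10.8$ oscillation period with margin and contain the
published optimum. A single seeded RNG stream drives initialization,
parent choice, crossover and mutation, so runs are exactly reproducible.

The full published optimization ($K = 200$, 1,000 generations, 800 records
at $h = 10^{-4}$) is deliberately not rerun in the test suite; the GA is
validated by a scaled-down recovery run ($K = 20$, 30 generations, 100
records, $h = 10^{-3}$) whose evolved mutual information must exceed the
95th percentile of 100 label-permutation baselines, together with direct
evaluation of the published optimum. These sizes keep the whole suite
within minutes while still exercising every operator.

## Synthetic data: what it emulates and what it does not

The three generators are pure functions of $(n, \mathrm{seed})$:

* `sample_flag()`: uniform points in $[0,1]^2$ labeled by the disk of
  radius $(2\pi)^{-1/2}$ centred at $(0.5, 0.5)$ — the radius that makes
  the two classes exactly equal in area, so chance performance is 50%.
  Boundary points count as "sun" (a measure-zero convention).
* `sample_horned()`: the same uniform points labeled by
  $F_D(x-y) \le x+y \le F_U(x-y)$ with the printed degree-14 even
  polynomials.
* `sample_french_flag()`: uniform $x$ labeled by thirds (half-open
  stripes, right edge closed).

These are exactly the study conditions of the benchmark problems, not
approximations of laboratory data: they contain no measurement noise, no
oscillator heterogeneity, and no drift in the kinetic constants. Passing
tests therefore demonstrate the computational claim — that the model
network separates these geometries — not robustness of a wet chemical
implementation.

A caveat discovered while validating the horned-region problem: the
printed boundary polynomials diverge outside their fitted support
($F_U(1) \approx 2740$, $F_D(1) \approx -49$), so for
$|x - y|$ beyond the minimum of $F_U - F_D$ (at $|p^*| \approx 0.65$) the
"between the curves" condition is satisfied by the entire corner wings of
the unit square. Agreement between the network's single-maximum region and
the polynomial label is $\approx 99\%$ on $|x - y| \le p^*$ and
$\approx 92\%$ over the whole square, with essentially all extra
disagreement contributed by those wings; `horned_label()` nevertheless
applies the printed polynomials verbatim on the whole square, and the
tests assert both numbers. In the containment direction the picture is
clean: $\ge 98\%$ of the points the network labels "red" lie between the
curves.

## Problem sizes used by the tests

Unit tests run single trajectories and small batches at $h = 10^{-3}$
(counts are verified step-size invariant); the end-to-end checks use a
fresh 800-point training sample and a 5,000-point test sample at
$h = 10^{-4}$, 2,000 points for the horned-region comparison, a 200-point
sample for the symmetry properties, and the scaled GA described above.

## Known limitations

* Fixed-step explicit RK4 only; no adaptive or implicit solvers. The
  spike fronts set the usable step ($h \le 10^{-3}$ in practice).
* No spatially extended (reaction–diffusion) media and no inhibitory
  (bromine-exchange) coupling; the coupling is activator exchange with a
  single shared rate.
* The decision rule is the per-count binary majority rule; the
  French-flag three-class example is handled as a direct count-to-class
  lookup, not by this rule type.
* The GA assigns fitness 0 to genomes whose simulation blows up; a region
  of genome space that is numerically fragile is thus implicitly
  penalized rather than explored with a smaller step.
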