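---
title: "Methods: stimulation-evoked synchronization patterns on aging connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stimulation-evoked synchronization patterns on aging connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`synchimera` implements a whole-brain modelling pipeline that asks a simple
question of a structural connectome: if one brain region is driven into
oscillation, which cognitive systems synchronize in response? The answer — a
binary pattern over nine cognitive systems, classified as synchronous,
asynchronous, or chimera (a coexistence of both) — is a dynamical fingerprint
of the balance between cognitive integration and segregation, and the package
tracks how that fingerprint changes across a cross-sectional age cohort.

## The network model

Each brain region $k$ carries a Wilson–Cowan neural mass: mean excitatory and
inhibitory population activities $E_k(t), I_k(t)$ obeying

$$\tau \dot E_k = -E_k + (S_{E,\max} - r_E E_k)\,
  S_E\!\Big(C_{EE}E_k - C_{EI}I_k + C_E \sum_j A_{jk} E_j(t - \tau^d_{jk}) + P_k\Big)
  + \sigma w_k(t),$$

with the symmetric equation for $I_k$ (couplings $C_{IE}, C_{II}$, global
coupling $C_I = C_E/4$, reflecting the roughly 4:1 excitatory-to-inhibitory
neuron ratio, and the same delays). The activation is the shifted logistic
$S(x) = [1+e^{-a(x-\theta)}]^{-1} - [1+e^{a\theta}]^{-1}$, so $S(0)=0$ and the
all-zero state is an exact fixed point of the unforced, noise-free network —
a property the test suite checks to machine precision.

Weights $A_{jk}$ are volume-normalized streamline counts; delays are
$\tau^d_{jk} = \lVert x_j - x_k \rVert / v_d$ with conduction velocity
$v_d = 10$ m/s, giving delays of roughly 1–17 ms across a head-sized layout.
Model time is milliseconds throughout, which makes the mm / (m/s) delay
arithmetic and the oscillation counts in a 500 ms window self-consistent.

The local parameter set defaults to the classical oscillation-capable
Wilson–Cowan values ($C_{EE}=16$, $C_{EI}=12$, $C_{IE}=15$, $C_{II}=3$,
$a_E=1.3$, $\theta_E=4$, $a_I=2$, $\theta_I=3.7$, $\tau=8$ ms,
$r_E=r_I=1$). Every parameter is overridable through `wc_params()`; all
package-level claims are properties that do not depend on this specific set.
With these defaults a single uncoupled region stimulated at $P = 1.15$
oscillates with a period near 55 ms, while $P = 0$ leaves it quiescent and a
much larger drive ($P \gtrsim 3$) parks it at a non-zero fixed point — the
stimulation amplitude sits inside the oscillatory window of a Hopf
bifurcation, which is why the protocol fixes $P_k = 1.15$ on exactly one
region per run.

### Integration and noise

The equations are integrated by Euler–Maruyama. The noise symbol $\sigma$ is
interpreted as the intensity of the white-noise drive: each step adds
$\tfrac{1}{\tau}\sqrt{\sigma\,\Delta t}\,\mathcal N(0,1)$ independently to $E$
and $I$ (default $\sigma = 10^{-5}$; with $\sigma = 0$ runs are
bit-reproducible). Pre-stimulus history for $t<0$ is pinned at the initial
value $E_k(0)=I_k(0)=0.1$. Per-edge delays are rounded to whole integration
steps and served from a ring buffer.

The reference step is $\Delta t = 10^{-3}$ ms. For the desk-scale cohort runs
(`demo_sim_config()`) we use $\Delta t = 0.02$ ms, a 150 ms transient, and the
standard 500 ms steady-state window: halving the step changes the stimulated
oscillation period by well under 1% (the suite enforces < 2%), and the tuned
critical coupling moves only in the fifth decimal. These sizes are the
package's own accuracy/cost choice for small synthetic cohorts; both are
plain `sim_config()` fields.

### Critical-coupling tuning

Whole-brain responsiveness requires the network to sit at the edge of
instability. `tune_global_coupling()` bisects $C_E$ between the quiescent
regime (the zero state attracts) and the departed regime, to a bracket width
of $10^{-6}$, and returns the midpoint on the quiescent side. Two practical
details matter:

* **Departure, not just oscillation.** The bisection predicate treats a run as
  "departed" when either the steady-window standard deviation of the mean
  excitatory activity exceeds $10^{-4}$ (sustained oscillation) or its mean
  exceeds $10^{-3}$ (a non-zero fixed point). On some strongly coupled toy
  networks the doubling search would otherwise jump straight over a narrow
  oscillatory window onto an elevated fixed point that a variance test alone
  calls "quiescent", and the bracket search would run away.
* **Finite-horizon threshold.** Near criticality the decay/growth rates
  vanish, so with a finite window the operational threshold sits slightly
  above the asymptotic bifurcation point. This is deterministic, monotone in
  $C_E$ on the networks we generate (verified by grid scan on a toy), and
  identical between tuning and the later classification runs.

Tuning runs use a 250 ms detection window rather than the full 500 ms; this
does not measurably move the returned $C_E$ and halves the cost of the
bisection, which dominates per-individual runtime.

## From trajectories to patterns

For each stimulated region the steady-state window yields phases
$\phi_k(t) = \operatorname{atan2}(I_k, E_k)$ (raw activities by default; mean
centering is an option). Samples with $E_k = I_k = 0$ exactly have no defined
angle; they are set to phase 0 with a warning — these are quiescent regions
whose contribution to any order parameter is then a constant unit vector, a
choice the upstream literature leaves open. For a pair of cognitive systems
the Kuramoto order parameter magnitude over the union of their regions is
averaged over the 500 ms window, giving the pairwise synchrony
$R \in [0,1]$ and a symmetric $9\times 9$ synchrony matrix per run. For the
diagonal we use the single system's own order parameter: the union
normalization would double-count members and cap within-system synchrony at
0.5, which contradicts its meaning.

Classification thresholds the matrix at $R \ge 0.65$ (inclusive; results are
reported in the field as robust over roughly 0.55–0.80), runs modularity-based
community detection over the binary system graph (self-loops excluded:
self-synchrony is not evidence of between-system structure), labels every
system in a multi-member community as part of the synchronous group — also
when several multi-member communities coexist — and classifies the pattern:
all nine synchronous, all nine asynchronous, or chimera otherwise. Over nine
systems the pattern space is $2^9 = 512$ with exactly one synchronous and one
asynchronous end member and 510 chimeras.

### Community detection details

igraph's Louvain implementation is deterministic for a fixed vertex order, so
"restarts" are realized as seeded random vertex permutations (50 by default);
greedy agglomeration and leading-eigenvector solutions seed two further
candidates. The best candidates are polished by a deterministic refinement:
strictly improving single-node moves, then modularity-neutral merges. The
merge step matters for the science, not just the optimizer: on random binary
system graphs roughly a fifth of instances have degenerate modularity optima
where the same maximal modularity is attained both with and without singleton
communities — i.e., with different three-way classes. We resolve the
degeneracy toward fewest communities, and apply the same convention in the
exhaustive Bell-enumeration oracle (`brute_force_partition()`), which the test
suite uses to check both the achieved modularity (≥ 99% of the optimum) and
the class agreement (≥ 98%) on 200 random graphs.

## The synthetic cohort generator

Real multi-site diffusion-MRI cohorts are out of scope; the generator
produces connectomes with the statistical structure the analysis relies on:

* 128 regions in 9 cognitive systems by default (ventral-temporal 10 and
  auditory 3 per hemisphere, subcortical 14 in total, the remaining cortical
  systems sharing the rest), with log-normal volumes and a mirrored
  two-hemisphere coordinate layout spanning 10–170 mm so delays span
  ~1–17 ms at 10 m/s;
* a weighted stochastic block model over the systems: dense, heavy
  within-system blocks (default edge probability 0.85, median streamline
  count 600) and sparse, light between-system connectivity (0.20, 90), with
  truncated log-normal counts (log-sd 0.7) reproducing heavy-tailed strength
  distributions;
* a planted rich club: a core of hub regions (drawn round-robin from the
  subcortical, default-mode and attention systems) whose mutual edges are
  always present with boosted weights and whose incident edges are
  strengthened. Core-core weights deliberately do not follow the age
  trajectories — hub wiring is treated as age-invariant, consistent with
  reports of preserved rich clubs across age;
* configurable age trajectories (constant, linear, decline, inverse-U) per
  parameter. The integration dial for the planted aging trend is the
  **between-system edge density**: after critical retuning, a uniform weight
  rescaling is exactly absorbed into $C_E$, and we found the between-system
  weight *scale* has no monotone effect on class proportions, whereas density
  does (sync proportion rising from 0 to ~0.75 as between-density grows from
  0.06 to 0.45). The demo cohort therefore plants "aging increases
  integration" as a linear density trajectory (factor 0.4 → 2.0 on a 0.20
  base).

The demo cohort (`demo_cohort_config()`) has 27 regions (3 per system) and 12
individuals (4 per coarse age bin), with one stimulated region per system per
individual — the same analysis shape as a full cohort at a small fraction of
the cost. Seeds derive from a single master seed by a documented counter
scheme (`individual_seed()`), so a whole cohort is reproducible from one
integer.

What passing tests on this generator do and do not show: they demonstrate
that the pipeline recovers structure that is genuinely present (planted
cores, planted age trends, strength-dependent classes) and that every
computational step matches closed forms or independent oracles. They do not
validate the neuroscience of any particular empirical cohort: synthetic
blocks have no spatial autocorrelation of weights, no measurement noise, no
site effects, and age acts through the generator's dials rather than biology.

## Aging statistics

Patterns pool into a table keyed by individual, age, stimulated region and
its cognitive system (the auditory system is reported split by hemisphere;
classification always runs on the nine canonical systems). On top of it:

* class proportions per group (exact counts, so each triple sums to 1) and
  net changes between age groups;
* coarse age bins young (< 30), middle (30–59), old (≥ 60); fine bins of 5
  years with 65–75 and 75–90 merged for sample size;
* prevalence tiers per pattern: low < 3%, medium 3–5% (both boundaries
  closed, matching the printed "3% – 5%" convention), high > 5%;
* pattern similarity: mean pairwise fraction of systems with equal labels,
  computed by an $O(N_p \cdot N_{CS})$ counting identity and tested against
  the $O(N_p^2)$ enumeration. Its decomposition averages similarity across
  individuals for a fixed stimulated region ("individual similarity") or
  across a system's regions for a fixed individual ("region similarity") —
  names follow the results-level usage (high individual similarity = patterns
  reproducible across people), the convention also implemented here;
* strength stratification: stimulated regions binned into equal-count deciles
  (heavy-tailed strengths make equal-width bins sparse), per-bin class
  proportions and dominant class, ties broken toward chimera as the
  intermediate state;
* confidence intervals as $\bar x \pm t_{0.975, n-1}\, \sigma/\sqrt n$.

## Structural measures

Strength ($S_k = \sum_j A_{jk}$), module strength ($S_{k,m}$, an exact
partition of $S_k$), and participation coefficient
($PC_k = 1 - \sum_m (S_{k,m}/S_k)^2$, defined as 0 for isolated regions) use
the cognitive parcellation as the default module partition and accept any
partition. The weighted rich-club coefficient $\phi(r)$ over strength-ranked
cutoffs divides the weight among the top-$r$ regions by the sum of the same
number of strongest weights anywhere; it is normalized by the mean of 100
randomized nulls that preserve the strength sequence (degree-preserving
rewiring followed by symmetric iterative proportional fitting back to the
original strengths). Members are read off at the upper end of the widest
contiguous run of cutoffs with normalized coefficient above 1: the club is
intentionally inclusive (it contains every cutoff set in the run), which is
the reading under which planted cores are recovered reliably; the peak-based
alternative collapses to unstable small-rank ratios. Distance to the rich
club is a hop count on the binary graph of nonzero edges by default
(`Inf` for disconnected regions), with an inverse-weight option.

## Degenerate inputs and numerical conventions

* Connectome matrices must be symmetric within `1e-12` (relative to the
  largest weight); anything within tolerance is symmetrized by averaging,
  anything worse is rejected with the offending index.
* A blown-up integration (non-finite state) aborts with the step and region.
* Empty groups in the statistics are skipped with warnings, not silently
  dropped; similarity is undefined (an error) for fewer than two patterns.
* All randomness flows through R's RNG: simulation noise via the config seed,
  per-region and per-individual seeds derived by the documented counter
  scheme, and community-detection restarts through seeded permutations, so
  every result in the package is reproducible from single integers.

## Known limitations

* Euler–Maruyama with fixed step: adequate at the validated step sizes, but
  stiff parameter sets would need smaller steps; no adaptive integrator is
  provided.
* The finite-horizon critical point is an operational threshold, not the
  asymptotic bifurcation value; both tuning and classification consistently
  use the same horizon.
* Louvain-with-refinement is a heuristic; on rare adversarial graphs it can
  remain below the true optimum (the suite bounds this at the 1% level on
  random instances).
* The generator's age dials are phenomenological. They emulate reported
  trends (inverse-U connectivity, rising integration, preserved hubs); they
  are not fitted to any dataset.
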