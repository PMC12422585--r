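# synchimera

Stimulation-evoked synchronization patterns and chimera states on aging
structural connectomes.

## What this package is for

The balance between **cognitive integration** (brain systems synchronizing,
supporting coordinated processing) and **cognitive segregation** (systems
operating independently, supporting specialized processing) shifts across the
lifespan. `synchimera` studies that balance *in silico*: it builds
personalized whole-brain network models on structural connectomes, perturbs
one brain region at a time, and records which cognitive systems synchronize in
response. It is intended for computational neuroscientists who want a tested,
reproducible implementation of this stimulation-and-classification pipeline
plus the age-stratified statistics on top of it.

The core objects and steps:

1. **Connectome** — a symmetric, volume-normalized weight matrix $A_{jk}$ over
   128 brain regions grouped into 9 cognitive systems (Att, Aud, FP, CO, MS,
   DM, V, VT, SC), with region volumes and coordinates. A seeded synthetic
   generator (`generate_cohort()`) produces cohorts with modular block
   structure, a rich-club core, heavy-tailed strengths, and configurable age
   trajectories.
2. **Dynamics** — each region is a Wilson–Cowan excitatory/inhibitory neural
   mass; regions couple through $A_{jk}$ with axonal conduction delays
   $\tau^d_{jk} = \lVert x_j - x_k\rVert / v_d$ and weak white noise,
   integrated by Euler–Maruyama. The global coupling $C_E$ (with
   $C_I = C_E/4$) is tuned per connectome to the **critical regime** by
   bisection to a $10^{-6}$ bracket, so the resting network is quiescent but a
   single stimulated region ($P_k = 1.15$) undergoes a Hopf bifurcation and
   oscillates.
3. **Synchrony** — phases $\phi_k = \operatorname{atan2}(I_k, E_k)$ over a
   500 ms steady-state window feed the pairwise Kuramoto order parameter;
   time-averaging gives a $9 \times 9$ synchrony matrix
   $R_{s_j,s_k} \in [0,1]$ per stimulated region.
4. **Classification** — the matrix is binarized at $R \ge 0.65$, communities
   of systems are found by seeded Louvain modularity maximization, systems in
   multi-member communities form the synchronous group, and each run is
   classified **synchronous / asynchronous / chimera**. Of the $2^9 = 512$
   possible patterns, 510 are chimeras.
5. **Aging statistics** — class proportions by age bin and system, pattern
   prevalence tiers (< 3% low, 3–5% medium, > 5% high), pattern similarity
   (mean pairwise label agreement) with its region/individual decomposition,
   t-based confidence intervals, and class-by-strength stratification.

## Worked example

```r
library(synchimera)

str(enumerate_pattern_space())
#> List of 4
#>  $ total       : int 512
#>  $ synchronous : int 1
#>  $ asynchronous: int 1
#>  $ chimera     : int 510

# one synthetic individual from the demo cohort (27 regions, 9 systems)
cc <- demo_cohort_config(master_seed = 42)
cn <- generate_connectome(age = 68, cc, seed = individual_seed(42, 1))
cn
#> <connectome> synthetic_104771: 27 regions, age 68
#>   systems: Att, Aud, CO, DM, FP, MS, SC, V, VT
#>   edges (nonzero upper triangle): 143

# tune the network to the critical regime
tuned <- tune_global_coupling(cn, wc_params(),
                              sim_config(dt = 0.02, transient = 150,
                                         record_window = 250, record_dt = 0.2))
sprintf("critical coupling C_E = %.6f (bracket width %.1e)", tuned$C_E, tuned$width)
#> "critical coupling C_E = 7.984628 (bracket width 9.5e-07)"

# stimulate one region, compute the synchrony matrix, classify
params <- set_global_coupling(wc_params(), tuned$C_E)
traj <- simulate_wc(cn, params, stimulus_spec(target_region = 5),
                    demo_sim_config(seed = 1))
R <- synchrony_matrix(phase_trajectory(traj),
                      cognitive_parcellation(cn$regions$system))
round(R[1:4, 1:4], 2)
#>      Att  Aud   FP   CO
#> Att 1.00 0.93 0.75 0.86
#> Aud 0.93 0.95 0.78 0.90
#> FP  0.75 0.78 0.70 0.76
#> CO  0.86 0.90 0.76 0.89
classify_synchrony_matrix(R)
#> <synchronization_pattern> class: synchronous
#>   Att=1 Aud=1 FP=1 CO=1 MS=1 DM=1 V=1 VT=1 SC=1
```

The synchrony values here are high and every system joins one community: this
68-year-old synthetic connectome (whose generator raises between-system
density with age) integrates globally when region 5 is stimulated. The same
protocol on a 12-year-old individual of the same cohort yields an
all-asynchronous pattern for region 5 and synchronous for region 20 —
stimulated-region identity and age both matter, which is exactly what the
cohort statistics quantify.

A full cohort analysis is one call:

```r
res <- run_pipeline(pipeline_config(master_seed = 7))
res$proportions_by_bin
#>   age_bin  n prop_async prop_chimera prop_sync
#> 1  middle 36  0.3888889   0.33333333 0.2777778
#> 2     old 36  0.4166667   0.02777778 0.5555556
#> 3   young 36  0.2777778   0.55555556 0.1666667
```

Each row sums to 1; the synchronous share rises young (0.17) → middle (0.28)
→ old (0.56) because the demo generator plants an age-increasing
between-system density. The
bundle also carries the full pattern table, prevalence tiers, pattern
similarity by system, strength stratification, and per-individual tuned
couplings. With `out_dir` set, intermediates are persisted and a rerun over a
completed directory reuses them.

A thin command-line wrapper with subcommands (`generate-cohort`, `tune`,
`stimulate`, `classify`, `analyze`, `enumerate-patterns`, `run-all`) lives at
`inst/cli/synchimera-cli.R`.

## Reading the methods

The model, tuning procedure, classification conventions, generator design and
numerical choices are documented in `vignettes/methods.Rmd`.
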