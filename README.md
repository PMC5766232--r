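# remyelin

Conduction velocity in segmentally remyelinated myelinated axons.

When a myelinated axon loses a segment of myelin and rebuilds it, the new
sheaths are shorter: one normal internode (nodal separation ℓ, here
1150 μm) is typically replaced by two internodes of ℓ/2. `remyelin` is a
toolkit for studying how an accumulating, randomly placed population of
such remyelinated segments slows saltatory conduction — and in particular
how much of the slowing is carried not by the *count* of short internodes
but by the *transitions* between long and short ones. It is aimed at
computational neuroscientists modelling demyelinating disease and
age-related conduction slowing.

The package provides:

* **Synthetic axon layouts** — uniform, semi-uniform (one transition), and
  binomially remyelinated ensembles with counter-based reproducible seeds
  (`make_uniform_layout()`, `make_semi_uniform()`, `remyelinate()`,
  `axon_ensemble()`).
* **A discrete-cable simulator** — isopotential Hodgkin–Huxley nodes of
  Ranvier coupled by ideal internodal resistances
  `g_n = πd²/(4 R_c ℓ_n)`, integrated semi-implicitly (Crank–Nicolson
  coupling, Rush–Larsen gates, compiled core), with threshold-crossing CV
  measurement between electrodes at fixed physical positions
  (`assemble_cable()`, `simulate_cv()`, `find_threshold()`).
* **Closed-form velocity theory** — the benchmark (travel-time harmonic
  mean) velocity

  `v̄(p) = v_ℓ v_{ℓ/2} / ((1−p) v_{ℓ/2} + p v_ℓ)`,

  √ℓ conduction-speed scaling, the perturbative transition-delay
  estimator

  `δτ_a/τ_a ≈ (v_a − v_b)/v_b · (1 − 2μR_cC_m v_a/d)⁻¹`,

  and composite travel-time estimates built from transition counts
  (`benchmark_velocity()`, `sqrt_scaling_ratio()`,
  `transition_delay_fraction()`, `semi_uniform_estimate()`,
  `composite_estimate()`, `implied_fraction_for_drop()`).
* **A study pipeline** — sweep the remyelination fraction `p`, simulate
  500-draw ensembles, and compare against the benchmark and a
  uniform-average control, with restricted-sample (fixed-composition)
  analyses (`run_study()`, `restricted_sample()`,
  `compare_to_benchmark()`, `autoplot()`).

## Worked example

The closed-form machinery, applied to the printed uniform-axon speeds of
a 10 μm motor fibre (40.44 m/s normal, 31.91 m/s fully remyelinated) with
nodal parameters d = 3.3 μm, μ = 1 μm, R_c = 70 Ω·cm, C_m = 2 μF/cm²:

```r
library(remyelin)

benchmark_velocity(40.44, 31.91, p = 0.5)
#> [1] 35.67216

transition_delay_fraction(40.44, 31.91)
#> # A tibble: 1 × 4
#>     v_a   v_b correction_factor fraction
#>   <dbl> <dbl>             <dbl>    <dbl>
#> 1  40.4  31.9             0.657    0.407

semi_uniform_estimate(40.44, 31.91, direction = "long_to_short")[,
  c("fraction", "tau_a_us", "delta_tau_us", "speed_m_per_s")]
#> # A tibble: 1 × 4
#>   fraction tau_a_us delta_tau_us speed_m_per_s
#>      <dbl>    <dbl>        <dbl>         <dbl>
#> 1    0.407     28.4         11.6          35.5

composite_estimate(17, 18, 10.2, 6.8, 40.44, 31.91)
#> [1] 34.8838

implied_fraction_for_drop(40.44, 31.91, 0.10)
#> [1] 0.4156572
```

Reading: a half-remyelinated axon "should" conduct at 35.67 m/s if every
internode kept its uniform-axon speed. Crossing from long into short
internodes costs an extra 41% of the incoming internode's transit time
(11.6 μs), pulling a semi-uniform axon down to 35.49 m/s; the reverse
crossing gives back less (−29%), so a random arrangement with 17
long→short and 18 short→long transitions lands at 34.88 m/s — below the
benchmark. A 10% CV drop needs ≈ 42% of the axon remyelinated.

Simulation uses the same protocol as the study design — stimulus at twice
the fully remyelinated model's threshold, electrodes at fixed physical
positions (base nodes 11 / 31 / 101), CV from interpolated −40 mV
crossings over the 80,500 μm span:

```r
base <- make_uniform_layout(120, 1150, 0.69)
amp  <- 2 * find_threshold(remyelinate(base, 1),
                           config = sim_config(t_total_ms = 12))
simulate_cv(base, amp, config = sim_config(t_total_ms = 12))
#> # A tibble: 1 × 7
#>   t1_ms t2_ms separation_um cv_m_per_s stim_node rec1_node rec2_node
#>   <dbl> <dbl>         <dbl>      <dbl>     <int>     <int>     <int>
#> 1  1.45  6.62         80500       15.6        11        31       101
```

(The Hodgkin–Huxley nodal membrane conducts at ≈ 10–16 m/s rather than
the motor fibre's 32–40 m/s; the qualitative structure — √ℓ scaling,
transition asymmetry, below-benchmark ensembles — is what the simulator
reproduces. See the methods vignette,
`vignettes/remyelinated-conduction.Rmd`.)

A command-line wrapper is included at `inst/cli/axon-remyelin`
(`theory`, `simulate` and `study` subcommands; `--show-config` dumps every
default).

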