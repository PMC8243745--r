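# limipv

Simulation and analysis of disturbance-driven cholangiocyte differentiation
through Delta-Notch signaling, for computational and developmental
biologists studying juxtacrine patterning.

During liver development, bile-duct epithelial cells (cholangiocytes)
differentiate from bipotent hepatoblasts specifically around portal veins,
whose smooth muscle cells express extremely high levels of the Notch ligand
Jagged1. `limipv` models this with the Lateral Inhibition with Mutual
Inactivation (LIMI) model on a 20 × 20 toroidal lattice: each cell carries
Delta (D), Notch (N) and a Notch-target reporter (R), coupled to its four
von Neumann neighbors,

    dN_i/dt = beta_N - gamma N_i - N_i <D_j>_i / k_t - N_i D_i / k_c
    dR_i/dt = beta_R (N_i <D_j>_i)^n / (k_RS + (N_i <D_j>_i)^n) - gamma_R R_i
    dD_i/dt = beta_D / (1 + R_i^m) - gamma D_i - D_i <N_j>_i / k_t - N_i D_i / k_c

where `<X_j>_i` is the neighbor mean, the `1/k_t` terms are trans-activation
(with mutual consumption), the `1/k_c` terms are cis-inactivation, and the
`1/(1 + R^m)` factor is lateral inhibition of ligand production. A
portal-vein (PV) cell is a lattice cell whose Delta is clamped at 1000,
overriding its Delta equation. The system is integrated by synchronous
explicit Euler steps (dt = 1e-4, negatives clipped to zero) until every
derivative of every non-PV cell falls below 1e-3.

At equilibrium, each of the four PV-adjacent cells is scored with a z-score
against the rest of the field ("diff"):

    diff = (R_neighbor - Ave) / SD

with Ave and SD taken over all cells except the PV cell and its neighbors.
A neighbor with diff > 2 is called a cholangiocyte. The four diffs are
averaged and log2-transformed for sweep heatmaps; non-positive averages and
zero-SD fields are sentinel ("cross") cells.

## Worked example

```r
library(limipv)

p <- simulation_params(beta_N = 100, beta_D = 10, m = 1, n = 3)
run <- simulate_pv_case(p, seed = 1)   # ~20 s: ~2.8M Euler steps
run$report
#> <diff_report>
#>   field: Ave = 1.07872, SD = 1.05341 over included cells
#>   neighbor diffs: 728200, 728200, 728200, 728200
#>   mean diff = 728205, log2 = 19.4740
#>   cholangiocyte calls: 4 of 4
```

With high Notch and low Delta production the field settles into an almost
flat reporter distribution (Ave ≈ 1.1, SD ≈ 1.1), and the clamped PV cell
drives the reporter of exactly its four neighbors to ~7 × 10^5 — a z-score
of ~7 × 10^5, log2 ≈ 19.5, far above the differentiation cutoff of 1 on the
log2 scale: spatially restricted cholangiocyte differentiation. Swapping the
production rates reverses the outcome:

```r
p2 <- update_params(p, beta_N = 10, beta_D = 100)
simulate_pv_case(p2, seed = 1)$report
#> <diff_report>
#>   field: Ave = 1750.88, SD = 1532.1 over included cells
#>   neighbor diffs: 1, 1, 1, 1
#>   mean diff = 1.00011, log2 = 0.0002
#>   cholangiocyte calls: 0 of 4
```

Here the undisturbed field is itself strongly patterned (SD ≈ 1500), the
disturbance disappears into that variability, and no neighbor stands out.

Production-rate maps and one-parameter sensitivity sweeps:

```r
g <- sweep_2d(log_axis(1, 1000, 10), log_axis(1, 1000, 10),
              m = 1, n = 3, simulation_params(), master_seed = 1)
plot(g)   # log2(diff) heatmap, crosses on sentinel cells

sweep_1d("beta_R", log_axis(1e4, 1e8, 5), simulation_params(), seeds = 1:3)
```

A command-line driver with `simulate`, `sweep` and `sensitivity` verbs is
installed at `inst/cli/limipv.R`; run configurations round-trip through
JSON (`read_run_config()` / `write_run_config()`), and `run_single()` /
`run_sweep()` write CSV fields, JSON summaries and PNG figures.

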