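# thermokin

Local-in-time kinetic analysis of vibrational energy transport in
biomolecules.

After a short, localized heat pulse — a photoexcited chromophore, a
transiently thermostatted residue in a simulation — excess vibrational energy
spreads through a peptide within picoseconds. `thermokin` is for the people
who measure or simulate that process and want mechanism out of it: it turns
per-residue kinetic-energy time series into **time-dependent
residue-to-residue transfer rates**, and from those into heat fluxes,
effective diffusivities, ballistic offsets, and activation barriers.

## The model

The per-residue kinetic energies $E_j(t)$ are described by a master equation
with backbone ($j,\,j\pm1$) and hydrogen-bond ($j,\,j+3$ or $j,\,j+4$)
coupling channels plus solvent relaxation:

$$
\dot E_j = \sum_i \left[k_{i\to j}E_i - k_{j\to i}E_j\right]
           - R_j k_s\,[E_j - E_{s,j}],
\qquad E_{s,j} = \tfrac{f_j}{2}k_B T_B .
$$

Reverse rates are fixed by detailed balance
($k_{\mathrm{rev}} = k_{\mathrm{fwd}} f_{\mathrm{don}}/f_{\mathrm{acc}}$), so
equipartition is exactly stationary. Per 0.1 ps analysis bin, the rate vector
$\mathbf{k} = (k_{1,2},\dots,k_{N-1,N},k_{\mathrm{HB}})$ is estimated by
non-negative least squares,

$$
\mathbf{k}(t_n) = \arg\min_{\mathbf{k}\ge0}\tfrac12\lVert G(t_n)\mathbf{k}-\mathbf{d}(t_n)\rVert^2 ,
$$

with the solvent rate identified independently from the total-energy budget.
Transport is then characterized through pairwise fluxes
$J_{ij} = k\,[E_i - (f_i/f_j)E_j]$ against effective temperature gradients
$\Delta_{ij}T_{\mathrm{eff}} = 2[E_i-(f_i/f_j)E_j]/3Nk_B$: linear (Fourier)
regime fits give per-link conductivities $\kappa_{\mathrm{eff}}$ and
diffusivities $D_{\mathrm{eff}} = \kappa_{\mathrm{eff}}\Delta x^2/C$; the
zero-gradient intercept measures the ballistic channel; and the ratio of
high- to low-bath-temperature fluxes at matched gradients yields Arrhenius
barriers $\Delta F = \ln(J_H/J_L)/[1/k_BT_L - 1/k_BT_H]$.

Synthetic generators (a master-equation forward simulator with the transient
heater protocol and finite-ensemble noise, plus an FPU-β lattice surrogate)
make every stage testable by parameter recovery — no molecular dynamics
required. The methods vignette (`vignettes/methods.Rmd`) documents the
estimators, numerical choices, and their limits.

## A worked example

Simulate a 50-member ensemble of a ten-residue 3₁₀ helix at 300 K, heat
residue 1 by 670 K for 1 ps, release, then fit rates and regimes:

```r
library(thermokin)

topo  <- build_topology(10, helix = "310")
model <- kinetic_model(topo, bath_temperature = 300,
                       k_backbone = 1.5, k_hbond = 0.5, k_solvent = 0.05)
ens   <- simulate_master_equation(model, heater_protocol(), t_total = 8,
                                  n_members = 50, seed = 1, noise_scale = 0.35)

mean_tr <- ensemble_mean_trajectory(ens)
rates   <- fit_rates(mean_tr, topo)
fluxes  <- compute_fluxes(mean_tr, topo, rates)
bins    <- bin_by_gradient(fluxes)
segment_regimes(bins)
#> # A tibble: 4 × 8
#>   label range_lo range_hi kappa_eff   d_eff intercept n_bins converged
#>   <chr>    <dbl>    <dbl>     <dbl>   <dbl>     <dbl>  <int> <lgl>
#> 1 A            4       15   0.00308  0.0732   0.00548     11 TRUE
#> 2 B           15       30   0.00616  0.147   -0.0471       6 TRUE
#> 3 C           30       50  NA       NA       NA            0 FALSE
#> 4 D           50       77  NA       NA       NA            0 FALSE
```

Region A's slope is the per-link conductivity in eV K⁻¹ ps⁻¹; `d_eff`
converts it to nm² ps⁻¹ via the (configurable) per-link heat capacity and
0.2 nm spacing; regions C and D stay unconverged here because a 50-member
desk-scale ensemble leaves their high-gradient bins unreliable — exactly
what the `n_bins`/`converged` columns are for. The front detector on the
same ensemble reports

```r
front_velocity(ensemble_profile(ens), threshold = 5)
#> # A tibble: 1 × 5
#>   velocity velocity_sem n_arrivals ballistic curvature_p
#>      <dbl>        <dbl>      <int> <lgl>           <dbl>
#> 1     1.60        0.193          9 FALSE         0.00871
```

an apparent front speed of 1.6 nm ps⁻¹ whose positive arrival-time curvature
(`ballistic = FALSE`) correctly exposes this purely diffusive synthetic
ensemble as front-free. Results round-trip as plain text
(`write_results()` / `read_results()`), fitted objects have `tidy()` /
`glance()` methods, and `autoplot()` draws profiles, rate traces, and
flux–gradient characteristics. `run_pipeline(run_config(...))` (or the thin
CLI at `inst/cli/thermokin`) chains the stages and writes all tables, the
exact configuration, and a JSON summary.

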