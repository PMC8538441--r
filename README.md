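# gnrtherm

Simulation of gold-nanorod-assisted photothermal therapy of skin tumors, for
researchers planning laser heating protocols: which laser power, nanorod
loading and heating/cooling duty cycle keep a tumor inside the apoptosis
temperature window while sparing the surrounding tissue.

## The model

A cylindrical squamous-cell-carcinoma tumor (10 mm diameter, 3.5 mm long,
top at 0.1 mm depth) sits in a four-layer skin block (epidermis, papillary
dermis, reticular dermis, subcutaneous fat; 30 × 30 × 10 mm). A 1064 nm
top-hat laser beam of diameter 10 mm illuminates the surface. Three coupled
stages are simulated:

**Light transport.** Voxel-based Monte Carlo: photons hop a path length
*S* = −ln ξ / μ<sub>tot</sub> with μ<sub>tot</sub> = μ<sub>a</sub> + μ<sub>s</sub>,
drop the absorbed weight fraction ΔW = W μ<sub>a</sub>/μ<sub>tot</sub> into
the current voxel, and spin into a new direction with a Henyey–Greenstein
deflection cosine (anisotropy *g*) and uniform azimuth. Gold nanorods
(67 × 10 nm) loaded uniformly into the tumor at volume fraction
*f<sub>v</sub>* add

&nbsp;&nbsp;μ<sub>np</sub> = 0.75 *f<sub>v</sub>* *Q* / *r*<sub>eff</sub>,&nbsp;&nbsp;
*r*<sub>eff</sub> = (3*V*/4π)<sup>1/3</sup>,&nbsp;&nbsp;
μ = μ<sub>m</sub> + μ<sub>np</sub>

to the host tumor coefficients, where *Q* is the rod's absorption (or
scattering) efficiency, calibrated at load time from published
mixed-tissue anchor values.

**Heat conduction.** The normalized absorption grid drives an explicit
finite-difference solution of ρc<sub>v</sub> ∂T/∂τ = q + ∇·(k∇T) with
harmonic-mean interface conductivities 2kk′/(k+k′), under a pulsed schedule
(τ<sub>h</sub> on, τ<sub>c</sub> off, total τ<sub>tot</sub>).

**Dose metrics.** Per snapshot, the apoptosis ratio θ<sub>A</sub> is the
tumor volume fraction with 43 °C < T < 50 °C and the thermal hazard value
θ<sub>H,n</sub> is the band-weighted mean hazard over the normal-tissue
shell within half a tumor diameter of the tumor (weights 1–8 from
biostimulation to ablation). Their time-averages θ<sub>A</sub>\*,
θ<sub>H,n</sub>\* and the objective
θ<sub>A,eff</sub>\* = θ<sub>A</sub>\*/θ<sub>H,n</sub>\* score a treatment;
an exhaustive sweep maximizes θ<sub>A,eff</sub>\* over conditions.

## Worked example

```r
library(gnrtherm)

geom <- build_skin_stack(fv = 1e-6, voxel = 0.5, fine_surface = FALSE)
ag   <- run_monte_carlo(geom, n_photons = 2e4, seed = 1)
ag
#> absorption grid: 20000 photons, 0.9539 deposited + 0.0461 escaped (beam 10 mm top-hat)

ts  <- run_treatment(geom, ag, treatment_schedule(P_l = 500, tau_h = 30,
                     tau_c = 30, tau_tot = 120),
                     snapshot_interval = 2, record = "masks")
evaluate_treatment(ts)
#> dose report: apoptosis retention 0.6417, hazard retention 1.0491, effective ratio 0.6116 (61 snapshots)
```

At 500 mW with a 30 s/30 s duty cycle and a light nanorod loading
(f_v = 10⁻⁶), the tumor spends about 64 % of its volume-time inside the
apoptosis window while the surrounding shell accrues only ~5 % excess
hazard, giving an effective apoptosis retention ratio of 0.61.

A reduced condition sweep and per-treatment-time optimum:

```r
grid <- condition_grid(tau_tot = c(120, 960), P_l = seq(200, 800, 100),
                       fv = 1e-6, tau_hc = c(20, 60))
res  <- run_sweep(grid, voxel = 0.5, n_photons = 1e5, seed = 1)
select_optimum(res)
#>   tau_tot P_l    fv tau_hc theta_A_star theta_H_star theta_A_eff_star seed
#> 1     120 500 1e-06     60    0.7350286     1.078079        0.6817950    1
#> 2     960 200 1e-06     60    0.7394854     1.134189        0.6519947    1
```

The optimal laser power falls as the treatment lengthens (500 mW at 120 s
versus 200 mW at 960 s): longer irradiation accumulates more heat, so less
power is needed to hold the apoptosis band and more power only damages the
surrounding tissue.

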