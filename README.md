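# mcfrw — random-walk model of water diffusion in the mineralized collagen fibril

Bone's nanoscale building block, the mineralized collagen fibril (MCF,
~200 nm diameter, ~1000 nm long), packs plate-shaped apatite crystals in a
staggered arrangement within a matrix of tropocollagen molecules; water
moves through the remaining pore network. How strongly that collagen–apatite
architecture hinders water transport — and how the hindrance accumulates
along the fibril axis — matters for bone nutrition, mineralization and the
design of bone-mimicking scaffolds, but it is hard to measure directly at
this scale.

`mcfrw` is an R package (with a compiled core) for simulating that
transport. It is aimed at researchers in bone biomechanics and nanoscale
mass transport who want a reproducible, fully scriptable obstructed-random-
walk model:

* **geometry** — a staggered lattice of apatite platelets (Gaussian
  dimensions truncated to literature ranges, axial period
  `(ℓ + a_L)/2 = D_period = 67 nm`), relaxed by 6·10⁶ random
  displacement/rotation moves under a ±20° inclination bound and a
  no-overlap constraint, plus a hexagonal lattice of 1.23 nm collagen
  cylinders; calibrated to a configurable mineralization degree (32%
  default),
* **walker** — obstructed Gaussian random walks with per-coordinate step
  σ = √(2 D₀ Δt) (D₀ = 2.66·10⁻⁹ m²/s, Δt = 2·10⁻¹⁰ s), full-segment
  collision tests and the stay-and-resample collision rule,
* **analysis** — time-averaged mean squared displacement
  MSD(nτ) = 1/(N−n) Σⱼ |r((j+n)τ) − r(jτ)|², least-squares MSD fits with
  D = β₁/6 (Einstein relation, d_S = 3), path tortuosity
  τ* = effective length / Euclidean end-to-end distance, and first-passage
  sub-trajectory statistics at reference planes ("quotes") every 134 nm
  along the fibril, with Student-t 95% confidence intervals.

Analytic fixtures, brute-force oracles, a pipeline driver
(`run_pipeline()`) and a command-line interface (`inst/cli/mcfrw.R`) are
included.

## Worked example

```r
library(mcfrw)

axial_gap(94.51, 67)          # axial inter-platelet gap from the 67 nm period
#> [1] 39.49

geom <- build_mcf_geometry(seed = 1)   # ~1 min: lattice + 6e6-move relaxation
print(geom)
#> MCF obstacle geometry
#>   envelope: radius 100 nm, length 1000 nm
#>   platelets: 1032 (perturbed)
#>   max inclination: 19.92 deg
#>   collagen: hexagonal lattice, spacing 1.6 nm, radius 0.615 nm

est <- estimate_volume_fraction(geom, n_samples = 1e6, seed = 2)
sprintf("mineral volume fraction: %.3f +/- %.4f", est$fraction, est$se)
#> [1] "mineral volume fraction: 0.319 +/- 0.0005"

cfg <- walk_config(n_trajectories = 30, max_steps = 3e7, master_seed = 1)
report <- simulate_quote_stats(geom, cfg)   # ~1 min
print(report)
#> Per-quote sub-trajectory statistics
#>  quote_L_nm n_subtraj mean_tortuosity tort_ci_lo tort_ci_hi    mean_D   D_ci_lo   D_ci_hi
#>         134        30           173.2      113.3      233.0 9.333e-10 7.555e-10 1.111e-09
#>         268        30           340.6      231.6      449.6 8.793e-10 7.193e-10 1.039e-09
#>         402        30           525.8      377.0      674.7 8.393e-10 6.929e-10 9.856e-10
#>         536        30           679.1      505.8      852.5 7.287e-10 5.969e-10 8.606e-10
#>         670        30           759.4      568.9      950.0 7.209e-10 5.902e-10 8.517e-10
#>         804        30           934.5      605.6     1263.5 7.055e-10 5.791e-10 8.319e-10
#>         938        30          1051.2      745.8     1356.5 6.752e-10 5.481e-10 8.022e-10
```

Reading the table: every one of the 30 walkers contributes a first-passage
sub-trajectory at each quote plane. Mean tortuosity rises monotonically
along the fibril (here ~6× from the first to the last quote — the path a
water particle actually travels grows much faster than its net advance),
while the mean diffusion coefficient falls from 9.3·10⁻¹⁰ to 6.8·10⁻¹⁰ m²/s
(about 28% below the first-quote value), an order of magnitude below the
bulk-water D₀ and of order 10⁻¹⁰ m²/s, consistent with experimental bone
diffusivities. Note that absolute tortuosity values depend on the position
sampling interval (see the vignette); compare them only between runs with
the same `record_stride`.

`plot(report)` draws both profiles with their confidence bands;
`plot(geom)` renders an occupancy cross-section of the geometry.

## Reproducible pipelines

```sh
Rscript inst/cli/mcfrw.R pipeline --config run.yaml --out results/
```

runs build-geometry → simulate → analyze with a YAML configuration whose
defaults are the standard model conditions (every constant above is
overridable — e.g. the mineralization degree for low/high-mineral variants),
and writes the geometry, per-trajectory CSVs, per-quote summaries and a JSON
manifest that allows bit-identical replay. Subcommands `build-geometry`,
`make-fixture`, `simulate`, `analyze` and `report` expose the stages
individually.
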