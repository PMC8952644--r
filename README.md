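# fretsphere

Quantitative modelling of Förster resonance energy transfer (FRET) for
fluorophores covalently bound to the surface of spherical core–shell
nanoparticles (e.g. a TiO₂ core with a silica shell carrying rhodamine 110
donors and rhodamine 101 acceptors). The package is aimed at fluorescence
spectroscopists who record time-correlated single-photon counting (TCSPC)
donor decays of labelled particle suspensions and want to extract acceptor
numbers and particle-size information from them, or to predict decays and
energy-migration behaviour for a planned labelling design.

## The model

Fluorophores sit on a sphere of radius *R*; radii vary across the batch with
a positive-truncated Gaussian law *f_G(R) = exp(−(R−⟨R⟩)²/2σ²)/C*. A donor
excited at *t = 0* decays intrinsically with lifetime τ₀D and transfers
energy to every other fluorophore at the Förster rate

    w(r) = (1/τ₀X) (R₀XY / r)⁶,

with *r* the through-space (chord) distance and R₀XY the critical radius of
the pair type. Two regimes are covered:

* **Single-step transfer** (few donors, many acceptors): donor–donor
  migration is negligible and the ensemble donor decay has the closed form

      I(t) = I₀ e^(−t/τ₀D) ∫₀^∞ f_G(R) s(t,R)^(N_A) dR,
      s(t,R) = ½ ∫₀^π exp[ −(t/τ₀D) R₀DA⁶ / (2R²(1−cosθ))³ ] sinθ dθ,

  evaluated by `donor_decay()` via a universal one-argument integral
  (accurate to ~1e−12) and fixed-order Gauss–Legendre averaging over the
  size distribution.

* **Multistep migration** (many donors, few acceptors): no closed form
  exists; `simulate_decay()` and `migration_stats()` run a Gillespie
  ("step-by-step") kinetic Monte-Carlo simulation of the excitation hopping
  on explicit particle realizations, with acceptors as perfect traps, frozen
  (static) dipole orientations, and per-channel histograms
  *I(t_k) = 1 − Σ_{j≤k} n_j / Σ_j n_j* on a 4096-channel TCSPC grid.

`generate_tcspc()` turns model curves into Poisson-noised synthetic
measurements (optionally convolved with a Gaussian instrument response),
and `fit_monoexponential()` / `fit_decay_model()` recover lifetimes,
acceptor numbers and size parameters by bounded multi-start
Levenberg–Marquardt least squares. Everything is tibble-first and works
with `tidy()`, `glance()` and `autoplot()`.

## Worked example

Predict the decay of a particle batch (⟨R⟩ = 75 nm, σ = 5 nm) carrying 335
acceptors per particle, synthesize a measurement, and fit the acceptor
number back:

```r
library(fretsphere)
set.seed(42)

p  <- photophysics_params()        # tau0D = 3.82 ns, R0DD = 4.6, R0DA = 5 nm
sz <- size_distribution(75, 5)

model <- analytic_decay_curve(p, sz, n_acceptors = 335,
                              k_max = 1024, T_ns = 20)
meas  <- generate_tcspc(model, total_counts = 1e6)
fit   <- fit_decay_model(meas, p, sz, n_acceptors = 335,
                         free = c("n_acceptors", "amplitude"),
                         n_nodes = 48)
fit
#> <fret_fit: single_step_analytic> converged
#>   n_acceptors       340.791 +- 2.14  (rounded: 341)
#>   amplitude         8044.68 +- 23.3
#>   weighted RSS: 1027.46 over 1024 channels (5 starts)
```

The acceptor number comes back within ~2% of the generating value, and the
weighted residual sum of squares is close to the number of channels, as
expected for Poisson noise. Energy migration in the opposite
labelling regime (335 donors per acceptor):

```r
set.seed(42)
migration_stats(labeling_spec(335, 1, min_separation = 0.52), sz,
                photophysics_params(kappa2_mode = "explicit_static"),
                n_configs = 500, n_traj_per_config = 20)
#> # A tibble: 1 x 11
#>   mean_jumps se_jumps mean_sq_displacement se_sq_displacement rel_msd
#>        <dbl>    <dbl>                <dbl>              <dbl>   <dbl>
#> 1      1533.     342.                 7.50              0.363   0.355
#> # i 6 more variables: se_rel_msd <dbl>, rel_rms <dbl> (= 0.596),
#> #   se_rel_rms <dbl>, n_traj <int>, n_configs <int>, min_separation <dbl>
```

The excitation hops more than a thousand times yet ends, on average, only
~0.6 donor–donor critical radii from where it started (`rel_rms`) — energy
migration on the sphere is intense but spatially confined.

A thin command-line front end over the same functions ships in
`inst/cli/fretsphere.R` (subcommands `simulate`, `analytic`, `generate`,
`fit`, `stats` driven by a JSON config; see `run_pipeline()`).

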