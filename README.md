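# pcfret

Multiplexed FRET readout via donor photochromism.

## The problem

FRET biosensors report kinase activities, second messengers and molecular
associations in living cells, but most of them are built from the same
cyan/yellow fluorescent-protein pair. Two such sensors expressed in the same
cell produce emission spectra that are essentially indistinguishable, so
their responses cannot be separated by spectral unmixing. `pcfret`
implements an analysis that separates them anyway, using a different axis of
contrast: *photochromism* of the donor. If one donor is reversibly
switchable (its fluorescence is suppressed by an off-switching light dose
and restored by violet light) while the other is photostatic, the two
sensors respond differently to an off-switching pulse inserted between FRET
acquisitions — and that difference is enough to unmix them.

The package is aimed at quantitative-imaging groups running
sensitized-emission FRET experiments with photochromic donors (e.g. an
mTFP0.7-based PKA reporter combined with an ECFP-based ERK reporter), and
at anyone wanting to evaluate such designs in simulation first.

## The model

A sensitized-emission acquisition measures donor-excited donor emission
S_DD, donor-excited acceptor emission S_DA, and directly excited acceptor
emission S_AA. With bleed-through and cross-excitation factors α, δ and the
brightness factor γ:

    F_c = S_DA − α·S_DD − δ·S_AA          (sensitized emission)
    Θ   = 1 / (γ·S_DD / F_c + 1)          (FRET efficiency)

Off-switching suppresses each pair's signals by its photoswitching ratio ρ.
Energy transfer competes with photochromism, so ρ depends on Θ; for a
single well-behaved species with no-FRET ratio ρ₀:

    ρ(Θ) = ρ₀^(1 − Θ)

For a two-pair mixture, the measured on/off signals in each channel are

    S_on  = S_on,1 + S_on,2
    S_off = ρ₁(Θ₁)·S_on,1 + ρ₂(Θ₂)·S_on,2

four equations in four unknowns once the ρᵢ are known. Since the ρᵢ depend
on the sought-after efficiencies, `iterative_unmix()` solves the system by
fixed-point iteration: evaluate each pair's ρ from its calibration curve at
the current Θ guess, solve the linear system exactly, recompute Θ from the
recovered signals, repeat until convergence (tolerance 1e-6, typically a
handful of iterations). Calibration curves are fitted from pooled cell data
by orthogonal distance regression (`fit_calibration()`: straight line,
power law, or double exponential).

The package also contains the Poisson photon-budget Monte-Carlo study used
to validate the method (`run_study()`, `random_guess_control()`), a
synthetic imaging fixture generator (`generate_fixture()`), and the
downstream time-lapse analysis: photobleaching baseline fits
(`fit_baseline()`), percent-increase responses (`percent_increase()`),
onset times (`onset_time()`) and k-means response classification
(`cluster_responses()`).

## Worked example

Simulate one noiseless acquisition of a mixture of a photochromic pair
(ρ₀ = 0.3, Θ = 0.35) and a photostatic pair (ρ₀ = 1.0, Θ = 0.10), then
unmix it:

```r
library(pcfret)

pairs <- list(power_law_pair("rsAKARev", rho0 = 0.3),
              power_law_pair("EKARev",   rho0 = 1.0))
specs <- list(pair_sim_spec(brightness_n = 1e4, rho0 = 0.3),
              pair_sim_spec(brightness_n = 1e4, rho0 = 1.0))
acq <- simulate_acquisition(specs, thetas = c(0.35, 0.10), noise = FALSE)
iterative_unmix(acq$on, acq$off, pairs)
```

    pair_id s_dd_on s_da_on theta clipped
    rsAKARev    6500    3500  0.35   FALSE
    EKARev      9000    1000  0.10   FALSE

Both planted efficiencies are recovered exactly (converged in 3
iterations): the photochromic pair contributed 6500 donor-channel and 3500
acceptor-channel photons in the on state, consistent with Θ = 0.35 at
γ = 1. Under Poisson noise the same call returns estimates whose accuracy
depends on the photon budget; with 1000 detected photons per pair the
median mean-absolute deviation over random efficiency pairs in [0, 0.6] is
about 0.03, versus about 0.19 for guessing at random:

```r
study <- run_study(list(list(pairs = specs, n_sims = 500)), seed = 1)
study[[1]]$summary[["median"]]        # ~0.01 at brightness 1e4
random_guess_control(n_sims = 5000)$summary[["median"]]  # ~0.19
```

A command-line interface wrapping these functions (subcommands `simulate`,
`calibrate`, `unmix`, `analyze-traces`, `fixtures`) is installed at
`inst/cli/pcfret.R`:

    Rscript inst/cli/pcfret.R unmix --traces traces.csv --pairs pairs.json --out unmixed.csv

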