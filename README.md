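# lhcquench

Spectroscopic characterisation of light-harvesting complex (LHC) family
pigment–protein complexes, built around the in vitro analysis of the
stress-related LHCSR1 and LHCSR3 subunits of *Chlamydomonas reinhardtii*
that trigger non-photochemical quenching (NPQ) in green algae.

The package answers two linked questions for a refolded pigment–protein
complex:

* **Which carotenoids sit in which binding site?**  The Soret-region
  (400–520 nm) absorption spectrum is deconvolved into red-shifted
  pigment *spectral forms* by non-negative least squares under soft
  pigment-stoichiometry constraints, solved by variable projection:
  for trial shifts δ the amplitudes *a* minimise

  ‖y − X(δ)a‖² + w² Σₚ (Σ_{j∈p} aⱼ − Tₚ)²,  a ≥ 0,

  with per-pigment totals Tₚ from the HPLC stoichiometry normalised to
  8 Chl per apoprotein.  Fitted carotenoid components are assigned to
  the L1 (≈13 nm red shift), L2 (≈16–18 nm) or peripheral N1/V1-like
  site (≈8 nm) by their shift, and fractional site occupancies are
  reported.

* **How strongly does each condition quench?**  TCSPC fluorescence
  decays across a pH (7.5 / 5) × detergent (0.03% / 0.007% β-DM)
  condition matrix are fitted with two exponentials (Poisson-weighted
  variable projection); the amplitude-weighted average lifetime
  τ_avg = ΣAᵢτᵢ/ΣAᵢ quantifies quenching and conditions are compared as
  1 − τ_avg(quenched)/τ_avg(reference).

A synthetic-data module generates internally consistent pigment tables,
Soret spectra and decay histograms (with lognormal HPLC noise, additive
spectral noise and Poisson counting noise) including packaged
LHCSR1-like, LHCSR3-like and LHCII-like fixture scenarios, and
`run_pipeline()` chains all stages into a machine-readable report.

## Worked example

Generate the LHCSR3-like synthetic data set and run the analysis:

```r
library(lhcquench)

sc  <- lhcsr3_scenario()

## pigment stoichiometry, normalised to 8 Chl per apoprotein
tab <- scenario_to_pigment_table(sc, seed = 1)
normalize_to_chl(tab)
#> <stoich_summary: 8 Chl per apoprotein>
#> Chl a/b Chl/Car     Neo     Vio     Lut    Cars Lut/Vio
#>    6.31    3.01    0.03    1.20    1.43    2.66    1.19

## TCSPC decays: unquenched reference vs the most quenching condition
decays <- scenario_to_decays(sc, seed = 1)
ref <- fit_biexponential(decays[["pH 7.5 0.03% b-DM"]], seed = 1)
q   <- fit_biexponential(decays[["pH 5 0.007% b-DM"]],  seed = 1)
ref
#> <biexp_fit: tau=3.980 ns (A=0.493), tau=1.492 ns (A=0.507); tau_avg 2.718 ns; chi2_red 1.04>
q
#> <biexp_fit: tau=2.804 ns (A=0.167), tau=0.574 ns (A=0.833); tau_avg 0.947 ns; chi2_red 1.06>
lifetime_reduction(ref, q)
#> <quenching: tau_avg 2.718 -> 0.947 ns, reduction 65.2%>
```

The stoichiometry row reproduces the LHCSR3 characterisation (2.66
carotenoids per 8 Chl, Chl/Car 3.01, Lut/Vio 1.19), and the decay fits
recover the published bi-exponential parameters of the two conditions
(τ_avg 2.725 → 0.950 ns) from Poisson-sampled histograms of 2×10⁶
photons: acid pH plus aggregation shortens the average lifetime by ~65%,
the strongest quenching in the condition matrix.

Deconvolving the Soret spectrum and assigning binding sites:

```r
sp <- scenario_to_spectrum(sc, seed = 1)
st <- normalize_to_chl(scenario_true_pigment_table(sc))
targets <- c(chl_a = st$chl_a_n, chl_b = st$chl_b_n, lutein = st$lut_n,
             violaxanthin = st$vio_n, neoxanthin = st$neo_n)
fit <- fit_soret(sp, site_window_specs(), stoich_targets = targets,
                 options = soret_options(restarts = 2, seed = 1))
site_composition(fit)
#> N1V1  total 0.128  (neoxanthin 23%, violaxanthin 77%)
#> L1    total 1.214  (lutein 97%, violaxanthin 3%)
#> L2    total 1.318  (lutein 19%, violaxanthin 81%)
```

L1 is essentially a lutein site, L2 is dominated by violaxanthin in this
LHCSR3-like complex, and traces of neoxanthin plus weakly shifted
violaxanthin occupy the peripheral site — the occupancy pattern the
scenario encodes (96:4, 17:83), recovered end to end from the spectrum.

A thin command-line wrapper is installed at `inst/cli/lhcquench`
(subcommands `stoich`, `fit-decay`, `fit-soret`, `simulate`, `run`).

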