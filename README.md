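# anthokinetics

Thermal processing degrades anthocyanins — the red/purple flavonoid pigments
of crops like red cabbage (*Brassica oleracea* L. var. *capitata*) — and the
rate at which that happens governs how much colour and nutritional value a
dried product retains. `anthokinetics` is an R package for quantifying that
degradation from concentration–time measurements taken during drying: it fits
the integrated rate laws of reaction orders n ∈ {0, 0.5, 1, 1.5, 2}, selects
the order that best describes each compound, and derives the standard kinetic
and thermodynamic report — half-life, Q10, Arrhenius activation energy, and
Eyring activation enthalpy/free energy/entropy — plus a temperature-generalized
equation that predicts concentration at any drying temperature and time inside
the calibrated range.

It is aimed at food scientists and process engineers analysing drying (or any
isothermal heating) experiments where a labile compound is sampled over time
at several temperatures.

## The model

Degradation follows an n-th order rate law, dC/dt = −k·Cⁿ. Each candidate
order has a linearizing transform y(C₀, Cₜ) with y = k·t on a noiseless
trajectory:

| order n | transform y                  | half-life t½            |
|---------|------------------------------|-------------------------|
| 0       | C₀ − Cₜ                      | C₀ / 2k                 |
| 0.5     | 2(√C₀ − √Cₜ)                 | (2−√2)√C₀ / k           |
| 1       | ln(C₀ / Cₜ)                  | ln 2 / k                |
| 1.5     | 2(1/√Cₜ − 1/√C₀)             | 2(√2−1) / (k√C₀)        |
| 2       | 1/Cₜ − 1/C₀                  | 1 / (k·C₀)              |

Rate constants are the least-squares slopes of y against t; the order is
selected by the coefficient of determination on the transformed scale.
Across temperatures, ln k regressed on 1/T gives the activation energy
Ea = −slope·R (Arrhenius), and at each temperature the Eyring parameters are
ΔH = Ea − RT, ΔG = −RT·ln(k·h/(k_B·T)), ΔS = (ΔH − ΔG)/T. For prediction,
the per-temperature slope a(T) and intercept b(T) of the linearized fits are
themselves modelled as simple functions of temperature (constant / linear /
quadratic / log bases), giving a surface a(T)·t + b(T) that inverts back to a
concentration at any (T, t).

## Worked example

The built-in generator emulates the two dominant degraders of red cabbage
during air-impingement jet drying — a 1.5-order compound patterned on
cyanidin-3-diglucoside-5-glucoside (C3dG5G) and a 2-order compound patterned
on the cyanidin aglycone — at 50/60/70 °C on the drying-schedule sampling
grids:

```r
library(anthokinetics)

data <- generate_dataset(red_cabbage_config(noise_scale = 0, replicates = 1))
report <- run_pipeline(data[, setdiff(names(data), "concentration_true")])
report$selection
#> # A tibble: 2 × 3
#>   compound      best_order mean_r_squared
#>   <chr>              <dbl>          <dbl>
#> 1 C3dG5G-like          1.5              1
#> 2 cyanidin-like        2                1

report$thermo[report$thermo$compound == "cyanidin-like", ]
#> # A tibble: 3 × 10
#>   compound      temperature_C order      k t_half    ea delta_h delta_g delta_s q10_to_next
#>   <chr>                 <dbl> <dbl>  <dbl>  <dbl> <dbl>   <dbl>   <dbl>   <dbl>       <dbl>
#> 1 cyanidin-like            50     2 0.0094   74.5  41.2    38.5    91.9  -0.165        1.88
#> 2 cyanidin-like            60     2 0.0177   39.6  41.2    38.4    93.1  -0.164        1.29
#> 3 cyanidin-like            70     2 0.0229   30.6  41.2    38.4    95.2  -0.166       NA
```

Read the rows as: at 50 °C cyanidin degrades with rate constant
k = 0.0094 min⁻¹ and loses half its initial content in 74.5 min; the
activation energy across 50–70 °C is 41.2 kJ/mol; the positive ΔG
(~92 kJ/mol) marks degradation as non-spontaneous and the negative ΔS an
entropy barrier; Q10 = 1.88 means the rate nearly doubles from 50 to 60 °C.
`report$validation` holds the pooled predicted-vs-observed R² of the
temperature-generalized model (1.0 on this noiseless input; ≥ 0.8 is the
usual bar on real, noisy series).

A command-line wrapper with `simulate`, `fit`, `thermo`, `predict` and
`report` subcommands is installed at
`system.file("cli/anthokinetics.R", package = "anthokinetics")`.

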