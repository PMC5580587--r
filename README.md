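# tmcgm

Small-sample forecasting of positive annual indicators — the motivating
case is disease-specific two-week hospitalization rates (per mille) used to
plan medical-service capacity — with the T-MCGM(1,1) composite model:
a **GM(1,1) grey trend**, a **Markov chain over residual error states**,
and an interval correction whose **whitening coefficients are optimized by
a finite-difference Gauss–Newton iteration**.

## The model

For a positive series x⁽⁰⁾(1..n), the accumulated series
x⁽¹⁾(j) = Σᵢ≤ⱼ x⁽⁰⁾(i) and background sequence
z⁽¹⁾(k) = ½[x⁽¹⁾(k−1) + x⁽¹⁾(k)] define the grey difference equation

    x⁽⁰⁾(j) + a·z⁽¹⁾(j) = b,   j = 2..n,

solved for the developing coefficient *a* and grey action *b* by least
squares. Fitted values are restored through the exponential time response
x̂⁽⁰⁾(i+1) = [x⁽⁰⁾(1) − b/a](1 − eᵃ)e^(−ai). The signed residuals are
partitioned into *r* equal-width states [Lⱼ, Uⱼ]; a one-step transition
matrix P is counted from the state labels; and each fitted value is
corrected by the expected whitened interval value

    x̃⁽⁰⁾(t) = x̂⁽⁰⁾(t) + Σᵢ aᵢ(t−1)·[αᵢLᵢ + (1−αᵢ)Uᵢ],

where a(t−1) is the previous state's indicator propagated through P and
α ∈ [0,1]^r is chosen to minimize ‖x⁽⁰⁾ − x̃⁽⁰⁾‖² by a Gauss–Newton
iteration with finite-difference Jacobian (step ratio R = 200, start
α = 0.5), constrained to the unit box. Accuracy is reported as MAPE and
RMSE, side by side for the plain and the corrected model. See the methods
vignette (`vignettes/grey-markov-forecasting.Rmd`) for the full account,
including the convention choices and the optimizer's active-set step.

## Worked example

The package bundles urban two-week hospitalization rates for diabetes
(`DD`), heart disease (`HD`) and cerebrovascular disease (`CD`),
2006–2015, from the China Health Statistics Yearbook.

```r
library(tmcgm)

hd  <- example_series("HD")
fit <- tmcgm(hd, r = 3)
fit
#> T-MCGM(1,1) on 'HD' (n = 10, r = 3)
#>   GM(1,1): a = -0.0815417, b = 9.04886
#>   alpha: 1.0000 0.6476 0.2894
#>   MAPE: GM 3.23% -> corrected 2.81%;  RMSE: 0.5334 -> 0.4926

round(predict(fit, horizon = 7), 2)
#>  2016  2017  2018  2019  2020  2021  2022
#> 21.82 23.62 25.60 27.78 30.15 32.72 35.50
```

Reading the output: the negative developing coefficient `a` means the
restored trend grows by the factor e^(−a) ≈ 1.085 (about 8.5%) per year; `alpha` are the
optimized whitening coefficients of the three residual states (1.0 pins the
first state's correction at its lower bound, 0 would pin it at the upper);
the corrected model cuts the in-sample MAPE from 3.23% to 2.81%. The seven
forecasts continue the trend with the Markov state correction applied.
`sweep_states(hd, 3:5)` tabulates the same fit across state counts:

```r
sweep_states(hd, 3:5)
#>   r  mape_gm mape_tmcgm   rmse_gm rmse_tmcgm
#> 1 3 3.230234   2.813229 0.5334027  0.4926460
#> 2 4 3.230234   1.921251 0.5334027  0.3735724
#> 3 5 3.230234   1.456300 0.5334027  0.3398615
```

The same pipeline runs from a shell via the installed script
(`<library>/tmcgm/exec/tmcgm`):

```sh
tmcgm run --input rates.csv --column HD -r 3 --horizon 7 --output report.json
```

with subcommands `fit` (plain GM(1,1)), `run` (full pipeline + JSON
report) and `simulate` (synthetic grey series generator).

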