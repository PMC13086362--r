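# herdseason

Quantitative reconstruction of sheep/goat herding practices from
archaeological remains: birth seasonality from intra-tooth enamel
δ¹⁸O sequences, seasonal diet from paired δ¹³C, collagen quality control
and statistics, mortality profiles with Bayesian credibility intervals,
taphonomic indices, and Ovis/Capra identification from collagen
peptide-mass fingerprints (ZooMS). Every input has a seeded synthetic
generator, so the full pipeline is testable without any external data.

It is written for zooarchaeologists and stable-isotope palaeoecologists
who have per-tooth tables of sequential enamel samples, collagen
measurements, faunal element/wear records, and MALDI-ToF spectra, and who
want the published analysis chain as reproducible, tested code.

## The models

**Birth seasonality.** A sequence of enamel δ¹⁸O values at distances *x*
(mm from the enamel–root junction) is fitted with a cosine seasonality
model

δ¹⁸O(x) = A·cos(2π(x − x₀)/X) + M,

where A is the amplitude (‰ VPDB), X the period (mm of crown per annual
cycle), x₀ the position of the δ¹⁸O maximum (summer), and M the mean.
The normalised ratio **x₀/X ∈ [0, 1)** locates the summer peak within the
annual cycle and, compared against reference bands from modern caprines of
known birth date, estimates the season of birth. Optional damping and
linear-drift terms are available. Fitting profiles the period (the model
is linear in the remaining parameters at fixed X) and polishes with
trust-region nonlinear least squares.

**Phase shift.** Paired δ¹⁸O/δ¹³C series are fitted jointly with
sinusoids sharing one period; the shift (Ψ_C − Ψ_O) in degrees diagnoses
dietary timing — 180° means carbon maxima at oxygen minima, the signature
of a ¹³C-enriched winter diet. Pooled fits over pattern groups share the
period and phases with per-specimen means.

**Diet mixing.** Tissue δ¹³C is converted to % C₄ diet by two-end-member
interpolation (enamel −11.58 / +4.18 ‰; collagen −20.3 / −6.3 ‰ by
default, all configurable and derivable from modern plant values with
Suess and enrichment corrections).

**Mortality.** Payne age-class counts get a Dirichlet(counts + prior)
posterior with seeded Monte-Carlo credibility intervals, analytic Beta
marginals as cross-check, and per-draw survivorship curves.

**ZooMS.** Spectra are baseline-corrected, Savitzky–Golay smoothed and
peak-picked (S/N ≥ 3.5); Ovis vs Capra is called from the COL1α2 757(+16)
markers (3017.4/3033.4 vs 3077.4/3093.4 m/z).

## Worked example

```r
library(herdseason)

# a simulated tooth: A = 3.5, X = 24 mm, x0 = 9.6 mm, 10% winter C4 pulse
g <- gen_tooth_sequence(A = 3.5, X = 24, x0 = 9.6, M = -5, sigma = 0.2,
                        step = 1.2, crown_length = 30, c4_winter = 10,
                        sigma_c = 0.15, specimen_id = "MI42", seed = 20)

fit <- fit_seasonal_cosine(g$seq)
fit
#> Cosine seasonality fit (basic model): specimen MI42
#>         A         X        x0         M x0_over_X
#>     3.375    23.992     9.604    -5.036     0.400
#> rmse 0.177 permil on 26 samples; converged: TRUE
```

The fit recovers the generating truth (A = 3.5, X = 24, x₀/X = 0.4) to
within the 0.2 ‰ noise level. The x₀/X ratio of 0.400 falls in the spring
band of the shipped reference set:

```r
estimate_birth_season(fit)
#>   specimen_id x0_over_X angle_deg season_call ... tentative
#> 1        MI42 0.4003178  144.1144      spring ...     FALSE
```

The paired carbon series sits in opposition to oxygen (true offset 180°
from the winter C₄ pulse), and the per-season diet summary isolates that
pulse:

```r
fit_phase_shift(g$seq)$phase_shift_deg
#> [1] 177.5075

classify_seasonal_diet(fit, g$seq)$per_season
#>         season  n mean_pct_C4 min_pct_C4 max_pct_C4
#> 1       summer  5   0.7642246   0.000000   2.436016
#> 2 transitional 15   4.9448069   2.031648   8.778261
#> 3       winter  6   9.3526789   8.477674   9.884435
```

Winter increments average 9.4% C₄ against the 10% generating truth, while
summer stays near zero — the pattern read as seasonal movement between C₄-
bearing lowland winter pasture and pure-C₃ highland summer pasture.

A mortality profile with credibility intervals, from per-class counts:

```r
dirichlet_profile(mortality_counts(c(0, 0, 3, 2, 2, 3, 6, 5, 2)), seed = 1)
#> Dirichlet mortality profile (95% credibility, 10000 draws, seed 1)
#>  class count  prop lower upper  surv
#>      A     0 0.031 0.001 0.114 0.968
#>      B     0 0.031 0.001 0.111 0.937
#>      C     3 0.125 0.035 0.258 0.812
#>      ...
#>      I     2 0.094 0.021 0.215 0.000
```

And a ZooMS identification from a synthetic sheep fingerprint:

```r
sp <- gen_maldi_spectrum("Ovis", snr = 18, seed = 4, specimen_id = "MI42")
call_taxon(process_spectrum(sp$spectrum))
#> ZooMS call for MI42: Ovis
#>           marker    taxon     mz observed_mz      snr
#>  COL1a2 757(+16)     Ovis 3017.4    3017.312 14.87226
#>  COL1a2 757(+16)     Ovis 3033.4    3033.314 16.75715
#>  ...
```

`run_all(run_config(...))` chains the stages — ZooMS taxa feed the
sequence labels — and writes per-stage CSVs, a JSON summary, the config
copy and a log into one output directory; reruns with the same config are
bit-identical.

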