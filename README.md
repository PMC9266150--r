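# nirsize

Fruit-size correction of NIR transmission spectra for soluble solids
prediction.

## The problem

Transmission NIR spectra of intact fruit decay with the optical path
through the flesh: under Beer–Lambert attenuation,

    I(λ) = I0(λ) · exp(−u_e(λ) · d),

where `d` is the fruit's equatorial diameter (mm) and `u_e(λ)` the
effective extinction coefficient of the tissue (1/mm). Fruit of different
sizes therefore yield systematically shifted spectra at identical internal
quality, and a PLS calibration for soluble solids content (SSC, °Brix)
built on one size class transfers poorly to smaller or larger fruit.

`nirsize` corrects for this. Each sample's log-intensity gap to a
reference spectrum `I_R` at reference diameter `d_R`, divided by its
diameter gap, estimates `−u_e(λ)`; averaging over all samples with a
diameter gap of at least `minGap` mm gives the cohort's extinction curve,
and every spectrum is then rescaled to the reference diameter:

    I_i*(λ) = exp(−u_e(λ) · (d_R − d_i) + ln I_i(λ)).

Around the correction the package provides a complete, testable
chemometrics pipeline: wide-CSV spectra I/O, wavelength restriction,
SNV / MSC / Savitzky–Golay pretreatments, Kennard–Stone
calibration/prediction splitting, NIPALS PLS1 regression with
cross-validated latent-variable selection, Rc/RMSEC/Rp/RMSEP evaluation,
and a synthetic cohort generator with exact ground truth. It is aimed at
chemometricians and postharvest researchers working with transmission
spectra of fruit.

## Worked example

Simulate a three-size-group cohort (65–75, 75–85, 85–95 mm; 160 fruit
each; 350–850 nm), estimate the extinction curve against the medium group,
and compare cross-size SSC prediction with and without correction:

```r
library(nirsize)

cohort <- generateCohort(syntheticConfig(seed = 1))
cohort$set
#> SpectraSet: 480 samples x 501 wavelengths (350-850 nm)
#>   groups: 65-75 (n=160), 75-85 (n=160), 85-95 (n=160)
#>   diameter: 65.1-95.0 mm; SSC: 9.2-17.2 Brix

estimateExtinction(cohort$set, referenceGroup = "75-85")
#> CorrectionModel: d_R = 79.88 mm, 501 wavelengths
#>   extinction: 0.07478-0.09772 /mm (mean 0.08482)
#>   estimated from 456 samples (24 excluded for small gap)

report <- runExperiment(experimentPlan(cohort$set, cells = "cross-size"))
report[, c("prediction_set", "corrected", "n_lv", "r_p", "rmsep")]
#>   prediction_set corrected n_lv   r_p rmsep
#> 1          65-75     FALSE    3 0.791 3.352
#> 2          65-75      TRUE    5 0.980 0.531
#> 3          85-95     FALSE    3 0.733 1.228
#> 4          85-95      TRUE    5 0.985 0.551

compareCorrection(report)
#>   calibration_set prediction_set pretreatment delta_r_p delta_rmsep improved
#> 1           75-85          65-75     original     0.188      -2.821     TRUE
#> 2           75-85          85-95     original     0.252      -0.677     TRUE
```

Reading the output: a medium-group model predicting the small group raw
reaches Pearson Rp 0.791 with RMSEP 3.35 °Brix — the diameter shift pushes
predictions off scale. After transforming all spectra to the medium
group's mean diameter, the same experiment reaches Rp 0.980 / RMSEP 0.53
°Brix; `improved` flags that both metrics moved the right way, for both
the small and large target groups. The estimated extinction curve
(~0.075–0.098 /mm) carries the absorption structure of the simulated
tissue.

A thin command-line front end with the same capabilities ships in
`inst/scripts/nirsize.R` (subcommands `simulate`, `correct`, `split`,
`evaluate`, `reproduce`).

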