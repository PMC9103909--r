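# SERSelect

Variable-selection PLS calibration for quantitative surface-enhanced
Raman scattering (SERS) spectroscopy, with carbendazim residue
quantification as the worked case.

## What it does, and for whom

Quantifying a trace pesticide from SERS spectra of food extracts is a
chemometrics problem: of ~1400 wavenumber channels, only narrow regions
around the analyte's vibrational bands carry concentration information,
and the raw spectra are dominated by substrate background, multiplicative
scatter between replicate chips, and noise. `SERSelect` is for analytical
chemists and chemometricians who want a tested, reproducible
implementation of the standard workflow for this setting:

1. **MSC** — multiplicative scatter correction: each spectrum `x` is
   regressed on the calibration-mean reference `m`, `x ≈ a + b·m`, and
   replaced by `(x − a)/b`;
2. a **rank-stratified 2:1 split**: samples sorted by concentration,
   grouped into triplets, one of each triplet drawn into the prediction
   set;
3. **PLS1 regression** (NIPALS with X-deflation), latent-variable count
   chosen by 10-fold cross-validation with a 2% parsimony rule;
4. four **wavelength-selection** algorithms feeding the PLS model:
   a genetic algorithm (GA), the interval variable iterative space
   shrinkage approach (iVISSA), the LASSO (cyclic coordinate descent,
   1-SE rule), and bootstrapping soft shrinkage (BOSS);
5. **evaluation** in the field's standard figures: R_C/RMSEC on
   calibration, R_P/RMSEP on prediction, RPD = SD/RMSEP (RPD > 2 usable,
   > 3 a good quantitative model), plus spike-recovery statistics
   (recovery %, RSD %, relative error %) and a baseline-corrected
   peak-intensity specificity check at 1225 1/cm.

Because the emulated study design (7 levels × 36 replicates = 252 spectra
on a 1416-point grid, 400–2500 1/cm) has no public raw spectra, the
package ships a seeded synthetic-spectrum generator as a first-class,
tested module; the methods vignette
(`vignettes/SERSelect-methods.Rmd`) documents its model and why each
default is what it is.

## Worked example

```r
library(SERSelect)

cfg <- generatorConfig(seed = 1)        # the default study design
res <- runPipeline(cfg, methods = "boss", seed = 1)

res$reports
#>     method nComponents nSelected
#> 1 BOSS-PLS           1       118
#>                                                                 selectedWavelengths
#> 1 470; 565; 629; 735; 770; 845; 955; 1007; 1227; 1271; 1394; 1463; 1520; 1641; 2080
#>          rC      rmsec        rP      rmsep      rpd
#> 1 0.9999918 0.06785462 0.9999945 0.05536471 303.6548

res$recovery
#>   level  n    meanPred      sdPred recoveryMin recoveryMax       rsd
#> 1   0.1 10  0.09457145 0.002510851    90.22395    98.51887 2.6549775
#> 2   0.5 10  0.49441822 0.002076148    98.47271    99.74961 0.4199173
#> 3   1.0 10  0.99732602 0.003330143    99.10159   100.16691 0.3339071
#> 4   5.0 10  4.99625100 0.016021502    99.40846   100.43809 0.3206705
#> 5  10.0 10 10.00536978 0.030480299    99.40580   100.40600 0.3046394
```

Reading the output: the BOSS selection kept 118 of 1416 wavelength
variables, whose cluster representatives sit at the eight carbendazim
bands (629–1521 1/cm, each representative within one grid step of its
band center) and at the displaced surface-species bands the generator
defines; one latent variable suffices; the prediction-set correlation
(`rP`) and `rpd` indicate a quantitative calibration; and on the
synthetic spiked validation set (5 levels × 10 replicates) all
per-sample recoveries fall between 90% and 100% with per-level RSDs
below 3%. (Numbers above are the output of this exact call; other seeds
vary within the tested bounds.)

`runPipeline(cfg, methods = c("ivissa", "ga", "lasso", "boss"), ...)`
produces the four-row model-comparison report; `writeModelReport()`
writes it as CSV or an aligned text table, `writeSpectra()`/
`readSpectra()` round-trip spectra through a plain CSV dialect.

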