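# attrpk

Quality-attribute pharmacokinetics of therapeutic antibodies from
affinity-purification LC-MS peptide mapping.

## The problem

PK studies of protein therapeutics usually report one number per sample —
total drug concentration by ELISA. But a monoclonal antibody in
circulation is a mixture of molecular variants: deamidated forms
accumulate at physiological pH, high-mannose (Man5) glycoforms clear
faster through mannose-receptor pathways, N-terminal glutamines cyclize to
pyroglutamate. Whether such a quality attribute matters for patient
exposure depends on how it converts and clears *in vivo*, which is exactly
what a single total-concentration curve cannot show.

`attrpk` implements the full analysis that turns attribute-resolved LC-MS
peptide measurements into that answer:

1. **Quantitation.** From long-format peak-area tables (light peptides
   from circulating drug; heavy peptides from a stable-isotope-labeled
   internal calibrant spiked at a fixed amount into each serum aliquot):
   relative attribute levels `area(modified) / Σ area(all forms)`,
   absolute concentrations `ratio × calibrant / serum volume`, a
   20-peptide reference panel for total drug concentration, standard-curve
   QC, and a screen for peptides decaying faster than the whole molecule.
2. **Mechanistic PK model.** Each attribute splits the drug into an
   original and a modified form, each following a two-compartment model
   with shared distribution rates, first-order conversion
   (original → modified, rate `ktr`) in both compartments, and
   form-specific central clearance (`kcl0`, `kclmod`):

   ```
   dAC0/dt   = −(kCP + ktr + kcl0)·AC0 + kPC·AP0
   dAP0/dt   = −(kPC + ktr)·AP0 + kCP·AC0
   dACmod/dt = −(kCP + kclmod)·ACmod + ktr·AC0 + kPC·APmod
   dAPmod/dt = −kPC·APmod + ktr·AP0 + kCP·ACmod
   ```

   with IV-bolus initial conditions `AC0(0) = (1−f)·Dose`,
   `ACmod(0) = f·Dose` — `100·f` is the attribute's "initial level".
   Deamidation-like attributes assume `kclmod = kcl0`; Man5-like
   attributes assume `ktr = 0`.
3. **Estimation.** Maximum-likelihood fitting of the free rates and the
   central volume to total-concentration plus attribute-fraction time
   series, with seeded multi-start optimization in log space and
   per-parameter CVs from the observed information (or a parametric
   bootstrap).
4. **Exposure simulation.** Windowed AUCs of the modified and total drug
   by ODE-state augmentation, relative AUC (`attribute/total × 100%`), and
   sweeps over the initial level `f` — the "what if manufacturing shipped
   a batch with more of this attribute" question.
5. **Synthetic studies.** A ground-truth-known generator (3 subjects,
   single IV dose, 11 sampling times over 42 days, lognormal peak-area
   noise, heavy calibrant at a fixed spike) so every stage is testable
   end to end without clinical data.

## Worked example

Exposure impact of an Fc deamidation site at different initial levels,
using the reference deamidation parameter set
(`kCP = 0.17, kPC = 0.093, ktr = 0.01, kcl0 = kclmod = 0.13 d⁻¹,
V = 3.34 L`):

```r
library(attrpk)
p <- reference_params("deamidation")
sw <- relative_auc_sweep(p, f_values = c(0, 0.056, 0.112, 0.278))
round(sw[, 1:4], 1)
#>   initial_level_pct attribute_auc total_auc relative_auc_pct
#> 1               0.0           4.7      45.8             10.2
#> 2               5.6           7.0      45.8             15.3
#> 3              11.2           9.3      45.8             20.3
#> 4              27.8          16.1      45.8             35.2
```

Because deamidated and original forms clear at the same rate, total
exposure is identical at every initial level, and even a 0% batch reaches
~10% deamidation-specific exposure through in vivo conversion: a 2-fold
increase of the initial level (5.6 → 11.2%) raises the relative AUC by
only a third (15.3 → 20.3%). Deamidation exposure is conversion-driven,
not batch-driven. (Absolute AUC columns here are per unit dose; anchor
them to a measured exposure with `calibrate_scale()`.)

Fitting a Man5-like model to a noisy synthetic study recovers the
generating parameters, including the faster clearance of the glycoform:

```r
cfg <- study_config(noise_cv = 0.1, seed = 17,
                    attribute_specs = default_attribute_specs()[c("man5", "deamidation")])
st  <- generate_study(cfg)
q   <- quantify_study(st$peak_table, cfg)
d   <- fit_dataset(q$total, dplyr::filter(q$attributes, attribute == "man5"),
                   dose = 1, f = 0.03)
fit <- fit_attribute(d, "man5-like", n_starts = 8, seed = 17)
fit
#> <attr_fit> man5-like
#>   param      estimate          CV%
#>   kCP          0.1767          9.7
#>   kPC         0.09551         12.1
#>   ktr               0      (fixed)
#>   kcl0         0.1271          4.3
#>   kclmod       0.2871         29.1
#>   V             3.341          3.0
#>   -logLik -199.6286, converged, 60 obs
```

The generating values were `kCP = 0.18, kPC = 0.096, kcl0 = 0.127,
kclmod = 0.295, V = 3.32`: the modified form clears ~2.3× faster, so Man5
exposure is controlled by both the initial level and clearance.
`tidy(fit)` and `glance(fit)` return the same information as tibbles;
`run_pipeline(cfg)` chains all four stages and writes tidy CSVs plus a
reproducibility manifest.

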