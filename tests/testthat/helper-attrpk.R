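# Shared fixtures: reference truth vectors and small study builders.

deamidation_truth <- c(kCP = 0.17, kPC = 0.093, ktr = 0.01,
                       kcl0 = 0.13, V = 3.34)
man5_truth <- c(kCP = 0.18, kPC = 0.096, kcl0 = 0.127,
                kclmod = 0.295, V = 3.32)

# Study with the attribute of interest first, so that the clean-peptide
# total-concentration signal follows that attribute's own kinetics.
make_study_config <- function(attribute = "deamidation", noise_cv = 0,
                              seed = 1, ...) {
  order <- c(attribute, setdiff(c("deamidation", "man5"), attribute))
  study_config(attribute_specs = default_attribute_specs()[order],
               noise_cv = noise_cv, seed = seed, ...)
}

quantified_study <- function(attribute = "deamidation", noise_cv = 0,
                             seed = 1) {
  cfg <- make_study_config(attribute, noise_cv = noise_cv, seed = seed)
  st <- generate_study(cfg)
  list(config = cfg, study = st,
       quant = quantify_study(st$peak_table, cfg))
}

fit_data_for <- function(qs, attribute) {
  spec <- qs$config$attribute_specs[[attribute]]
  frac <- dplyr::filter(qs$quant$attributes, attribute == !!attribute)
  fit_dataset(qs$quant$total, frac, dose = qs$config$dose_amount,
              f = spec$params$f)
}
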