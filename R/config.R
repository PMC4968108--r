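#' Default clinical sampling schedule
#'
#' The single-ascending-dose schedule used throughout: pre-bleed, 10 min,
#' 1 h, 4 h, 12 h, day 2, day 4, and weeks 1, 2, 3 and 6, expressed in days.
#'
#' @return Numeric vector of 11 times in days, starting at 0.
#' @export
default_sample_times <- function() {
  c(0, 10 / 1440, 1 / 24, 4 / 24, 0.5, 2, 4, 7, 14, 21, 42)
}

#' Default attribute specifications
#'
#' Four attribute models emulating the in vivo behaviour commonly seen for
#' IgG quality attributes over six weeks: an Fc deamidation site rising from
#' ~5.6% towards ~38%, a Man5 glycoform falling from 3% to ~0.6% through
#' faster clearance, N-terminal pyroglutamate converting essentially to
#' completion from 96%, and a slowly declining Fc Met oxidation (~8.5% to
#' ~7%). Deamidation and Man5 use the reference best-fit rates; the other
#' two reuse the same distribution/clearance backbone with conversion or
#' clearance set to produce the qualitative trend.
#'
#' @return A named list of attribute specs, each a list with `name`, `kind`
#'   (`"deamidation-like"` or `"man5-like"`), `params`
#'   ([attribute_params()]), and `peptide` (reporter peptide id).
#' @export
default_attribute_specs <- function() {
  list(
    deamidation = list(
      name = "deamidation", kind = "deamidation-like",
      params = reference_params("deamidation", f = 0.056),
      peptide = "FC_DEAM_PEP"
    ),
    man5 = list(
      name = "man5", kind = "man5-like",
      params = reference_params("man5", f = 0.03),
      peptide = "FC_GLYC_PEP"
    ),
    pyroglu = list(
      name = "pyroglu", kind = "deamidation-like",
      params = attribute_params(kCP = 0.17, kPC = 0.093, ktr = 0.1,
                                kcl0 = 0.13, kclmod = 0.13, V = 3.34,
                                f = 0.96),
      peptide = "HC_NTERM_PEP"
    ),
    metox = list(
      name = "metox", kind = "man5-like",
      params = attribute_params(kCP = 0.18, kPC = 0.096, ktr = 0,
                                kcl0 = 0.127, kclmod = 0.148, V = 3.32,
                                f = 0.085),
      peptide = "FC_METOX_PEP"
    )
  )
}

#' Default peptide panel
#'
#' 24 clean (unmodifiable, carryover-free) LysC peptides with spread
#' ionization efficiencies, plus one reporter peptide per attribute in
#' `attribute_specs`, plus one N-terminal light-chain peptide subject to
#' extra in vivo degradation (for the terminal-degradation screen).
#'
#' @param attribute_specs Attribute spec list; reporter peptides are added
#'   for each entry.
#' @param n_clean Number of clean peptides.
#' @return A tibble with columns `peptide_id`, `ionization`,
#'   `is_modifiable`, `attribute` (NA for clean peptides), `extra_decay`
#'   (1/day, additional first-order loss relative to total drug).
#' @export
default_peptide_panel <- function(attribute_specs = default_attribute_specs(),
                                  n_clean = 24) {
  ids <- sprintf("PEP%02d", seq_len(n_clean))
  # deterministic, spread over ~1.5 orders of magnitude
  ion <- exp(1.5 * sin(seq_len(n_clean)) + 0.1 * seq_len(n_clean))
  clean <- tibble(
    peptide_id = ids, ionization = ion,
    is_modifiable = FALSE, attribute = NA_character_, extra_decay = 0
  )
  rep_pep <- purrr::map_dfr(attribute_specs, function(spec) {
    tibble(peptide_id = spec$peptide, ionization = 1,
           is_modifiable = TRUE, attribute = spec$name, extra_decay = 0)
  })
  nterm <- tibble(peptide_id = "LC_NTERM_PEP", ionization = 0.05,
                  is_modifiable = FALSE, attribute = NA_character_,
                  extra_decay = 0.05)
  bind_rows(clean, rep_pep, nterm)
}

#' Build a synthetic-study configuration
#'
#' Collects everything the generator needs: subjects, dose, sampling
#' schedule, attribute models, peptide panel, internal-calibrant spike and
#' serum aliquot, measurement noise, and the seed. Defaults emulate the
#' clinical design: 3 subjects, a single IV bolus, 11 sampling times over
#' 42 days, a 2.5 µg heavy-labeled calibrant in 12.5 µL serum, and 10%
#' proportional measurement noise on peak areas.
#'
#' @param n_subjects Number of subjects.
#' @param dose_amount Administered dose, mg. Defaults to a unit bolus: all
#'   downstream exposure quantities of interest are dose-invariant ratios.
#' @param sample_times Strictly increasing times in days; first must be 0
#'   (the pre-bleed).
#' @param attribute_specs See [default_attribute_specs()].
#' @param peptide_panel See [default_peptide_panel()].
#' @param calibrant_amount Heavy-calibrant spike per sample, µg.
#' @param serum_volume Serum aliquot per sample, µL.
#' @param noise_cv Proportional (lognormal) CV of peak-area noise; `0`
#'   disables noise.
#' @param seed Integer seed; mandatory for reproducibility.
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(noise_cv = 0, seed = 1)
#' cfg$sample_times
#' @export
study_config <- function(n_subjects = 3,
                         dose_amount = 1,
                         sample_times = default_sample_times(),
                         attribute_specs = default_attribute_specs(),
                         peptide_panel = NULL,
                         calibrant_amount = 2.5,
                         serum_volume = 12.5,
                         noise_cv = 0.10,
                         seed = 17) {
  if (is.null(peptide_panel))
    peptide_panel <- default_peptide_panel(attribute_specs)
  if (!is.numeric(n_subjects) || n_subjects < 1)
    abort("`n_subjects` must be a positive integer.")
  if (!is.numeric(dose_amount) || dose_amount <= 0)
    abort("`dose_amount` must be positive.")
  if (length(sample_times) < 2 || any(diff(sample_times) <= 0))
    abort("`sample_times` must be strictly increasing.")
  if (sample_times[[1]] != 0)
    abort("`sample_times` must start at 0 (the pre-bleed).")
  if (!is.numeric(noise_cv) || noise_cv < 0)
    abort("`noise_cv` must be >= 0.")
  if (!is.numeric(calibrant_amount) || calibrant_amount <= 0)
    abort("`calibrant_amount` must be positive.")
  if (!is.numeric(serum_volume) || serum_volume <= 0)
    abort("`serum_volume` must be positive.")
  if (any(peptide_panel$ionization <= 0))
    abort("`peptide_panel` ionization factors must be > 0.")
  if (is.null(seed) || !is.numeric(seed) || !is.finite(seed))
    abort("`seed` is mandatory and must be a finite integer.")
  for (spec in attribute_specs) {
    if (!inherits(spec$params, "attribute_params"))
      abort(paste0("attribute_specs entry `", spec$name,
                   "`: params must be an attribute_params object."))
    if (!spec$kind %in% c("deamidation-like", "man5-like"))
      abort(paste0("attribute_specs entry `", spec$name,
                   "`: unknown kind `", spec$kind, "`."))
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    dose_amount = dose_amount,
    sample_times = sample_times,
    attribute_specs = attribute_specs,
    peptide_panel = peptide_panel,
    calibrant_amount = calibrant_amount,
    serum_volume = serum_volume,
    noise_cv = noise_cv,
    seed = as.integer(seed)
  ), class = "study_config")
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  cat(sprintf("  %d subjects, dose %.3g mg, %d sample times (0-%.3g d)\n",
              x$n_subjects, x$dose_amount, length(x$sample_times),
              max(x$sample_times)))
  cat(sprintf("  attributes: %s\n",
              paste(names(x$attribute_specs), collapse = ", ")))
  cat(sprintf("  panel: %d peptides; calibrant %.3g ug / serum %.3g uL\n",
              nrow(x$peptide_panel), x$calibrant_amount, x$serum_volume))
  cat(sprintf("  noise CV %.3g, seed %d\n", x$noise_cv, x$seed))
  invisible(x)
}

#' Write / read a study configuration as YAML
#'
#' @param config A [study_config()] object.
#' @param path File path.
#' @return `write_study_config()` returns `path` invisibly;
#'   `read_study_config()` returns a `study_config`.
#' @export
write_study_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  x <- unclass(config)
  x$attribute_specs <- purrr::map(x$attribute_specs, function(spec) {
    list(name = spec$name, kind = spec$kind, peptide = spec$peptide,
         params = unclass(spec$params))
  })
  x$peptide_panel <- as.list(as.data.frame(x$peptide_panel))
  # precision 20 makes doubles (e.g. the 10-minute sample time) survive
  # the text round trip bit-exactly
  yaml::write_yaml(x, path, precision = 20)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$seed))
    abort("Config file must carry a `seed`.")
  specs <- purrr::map(x$attribute_specs, function(spec) {
    p <- spec$params
    list(name = spec$name, kind = spec$kind, peptide = spec$peptide,
         params = attribute_params(p$kCP, p$kPC, p$ktr, p$kcl0, p$kclmod,
                                   p$V, dose = p$dose, f = p$f))
  })
  names(specs) <- purrr::map_chr(specs, "name")
  panel <- as_tibble(x$peptide_panel)
  panel$attribute <- as.character(panel$attribute)
  study_config(
    n_subjects = x$n_subjects, dose_amount = x$dose_amount,
    sample_times = as.numeric(x$sample_times),
    attribute_specs = specs, peptide_panel = panel,
    calibrant_amount = x$calibrant_amount, serum_volume = x$serum_volume,
    noise_cv = x$noise_cv, seed = x$seed
  )
}
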