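# Lognormal multiplier with unit mean and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Heavy-calibrant concentration in the processed sample, ug/mL.
calibrant_concentration <- function(config) {
  config$calibrant_amount / config$serum_volume * 1000
}

#' Generate a synthetic quality-attribute PK study
#'
#' Produces a long-format peak-area table with known ground truth. For each
#' attribute the noise-free truth is the ODE solution of the two-compartment
#' original/modified-form model under the configured parameters; observed
#' light peak areas are form-specific central concentrations scaled by each
#' peptide's ionization factor and multiplied by lognormal noise at the
#' configured CV. Heavy areas correspond to the constant internal-calibrant
#' spike. The pre-bleed (time 0) sample carries zero drug signal.
#'
#' Clean (unmodifiable) peptides report the total drug concentration, taken
#' from the first attribute spec's trajectory, so a study intended for
#' fitting one attribute should list that attribute first.
#'
#' @param config A [study_config()].
#' @return An object of class `synthetic_study`: a list with `peak_table`
#'   (tibble: `subject`, `time_days`, `peptide_id`, `mod_form`,
#'   `light_area`, `heavy_area`), `truth` (noise-free trajectories,
#'   attribute fraction series and total-concentration series), and
#'   `config`.
#' @examples
#' study <- generate_study(study_config(noise_cv = 0, seed = 1))
#' head(study$peak_table)
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  times <- config$sample_times
  specs <- config$attribute_specs
  if (length(specs) == 0) abort("`config` must carry >= 1 attribute spec.")

  trajectories <- purrr::map(specs, function(spec) {
    p <- spec$params
    p$dose <- config$dose_amount
    simulate_attribute(p, times)
  })

  attribute_series <- purrr::imap_dfr(trajectories, function(traj, nm) {
    tibble(attribute = nm, time_days = traj$time_days,
           fraction = traj$ACmod / (traj$AC0 + traj$ACmod))
  })

  total_traj <- trajectories[[1]]
  total_concentration <- tibble(
    time_days = total_traj$time_days,
    concentration = total_traj$C0 + total_traj$Cmod
  )

  heavy_conc <- calibrant_concentration(config)
  panel <- config$peptide_panel

  one_peptide <- function(pep) {
    if (isTRUE(pep$is_modifiable)) {
      spec <- specs[[pep$attribute]]
      if (is.null(spec))
        abort(paste0("peptide_panel: peptide `", pep$peptide_id,
                     "` references unknown attribute `", pep$attribute, "`."))
      traj <- trajectories[[pep$attribute]]
      bind_rows(
        tibble(time_days = times, peptide_id = pep$peptide_id,
               mod_form = "none", true_light = traj$C0,
               true_heavy = heavy_conc),
        tibble(time_days = times, peptide_id = pep$peptide_id,
               mod_form = pep$attribute, true_light = traj$Cmod,
               true_heavy = 0)
      )
    } else {
      conc <- total_concentration$concentration *
        exp(-pep$extra_decay * times)
      tibble(time_days = times, peptide_id = pep$peptide_id,
             mod_form = "none", true_light = conc, true_heavy = heavy_conc)
    }
  }

  per_pep <- purrr::map_dfr(seq_len(nrow(panel)), function(i) {
    pep <- as.list(panel[i, ])
    one_peptide(pep) %>% mutate(ionization = pep$ionization)
  })

  # pre-bleed precedes the bolus: no drug signal (calibrant still spiked)
  per_pep$true_light[per_pep$time_days == 0] <- 0

  peak_table <- purrr::map_dfr(seq_len(config$n_subjects), function(s) {
    n <- nrow(per_pep)
    per_pep %>%
      mutate(
        subject = sprintf("S%02d", s),
        light_area = .data$true_light * .data$ionization *
          lognormal_noise(n, config$noise_cv),
        heavy_area = .data$true_heavy * .data$ionization
      )
  }) %>%
    select("subject", "time_days", "peptide_id", "mod_form",
           "light_area", "heavy_area") %>%
    arrange(.data$subject, .data$time_days, .data$peptide_id,
            .data$mod_form)

  structure(list(
    peak_table = peak_table,
    truth = list(
      trajectories = trajectories,
      attribute_series = attribute_series,
      total_concentration = total_concentration
    ),
    config = config
  ), class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("<synthetic_study>\n")
  cat(sprintf("  %d peak-area records, %d subjects, %d time points\n",
              nrow(x$peak_table), x$config$n_subjects,
              length(x$config$sample_times)))
  cat(sprintf("  attributes: %s\n",
              paste(names(x$config$attribute_specs), collapse = ", ")))
  invisible(x)
}

#' Generate a spike-in standard-curve peak table
#'
#' Emulates serial dilutions of the drug spiked into blank serum alongside
#' the constant heavy-calibrant amount: at each concentration level, every
#' clean peptide's light/heavy area ratio is proportional to the level
#' (exactly so at `noise_cv = 0`).
#'
#' @param levels Positive spike-in concentrations, µg/mL.
#' @param config A [study_config()]; supplies the panel, calibrant and
#'   noise settings.
#' @return A tibble with columns `level`, `peptide_id`, `mod_form`,
#'   `light_area`, `heavy_area`.
#' @export
generate_standard_curve <- function(levels, config) {
  stopifnot(inherits(config, "study_config"))
  if (length(levels) == 0) abort("`levels` must be non-empty.")
  if (any(levels <= 0)) abort("`levels` must be positive concentrations.")
  set.seed(config$seed + 1L)
  heavy_conc <- calibrant_concentration(config)
  panel <- config$peptide_panel %>% filter(!.data$is_modifiable)
  grid <- tidyr::expand_grid(level = levels,
                             peptide_id = panel$peptide_id) %>%
    left_join(panel %>% select("peptide_id", "ionization"),
              by = "peptide_id")
  n <- nrow(grid)
  grid %>%
    mutate(
      mod_form = "none",
      light_area = .data$level * .data$ionization *
        lognormal_noise(n, config$noise_cv),
      heavy_area = heavy_conc * .data$ionization
    ) %>%
    select("level", "peptide_id", "mod_form", "light_area", "heavy_area")
}

#' Write / read a long-format peak-area table
#'
#' CSV columns: `subject`, `time_days`, `peptide_id`, `mod_form`,
#' `light_area`, `heavy_area`.
#'
#' @param peak_table Tibble as produced by [generate_study()].
#' @param path File path.
#' @return `write_peak_table()` returns `path` invisibly;
#'   `read_peak_table()` returns a tibble.
#' @export
write_peak_table <- function(peak_table, path) {
  required <- c("subject", "time_days", "peptide_id", "mod_form",
                "light_area", "heavy_area")
  if (!all(required %in% names(peak_table)))
    abort(paste0("peak table must have columns: ",
                 paste(required, collapse = ", ")))
  readr::write_csv(peak_table[, required], path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject = readr::col_character(),
    time_days = readr::col_double(),
    peptide_id = readr::col_character(),
    mod_form = readr::col_character(),
    light_area = readr::col_double(),
    heavy_area = readr::col_double()
  ))
}
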