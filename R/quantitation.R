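#' Sum peak areas over charge states
#'
#' XIC peak areas of the same peptide observed at multiple charge states
#' are integrated separately and added together; this collapses a
#' per-charge table to one record per (subject, time, peptide, form).
#'
#' @param raw Tibble with columns `subject`, `time_days`, `peptide_id`,
#'   `mod_form`, `charge`, `light_area`, `heavy_area`.
#' @return A peak table with areas summed over charges.
#' @export
merge_charge_states <- function(raw) {
  required <- c("subject", "time_days", "peptide_id", "mod_form", "charge",
                "light_area", "heavy_area")
  if (!all(required %in% names(raw)))
    abort(paste0("`raw` must have columns: ",
                 paste(required, collapse = ", ")))
  dup <- raw %>%
    dplyr::count(.data$subject, .data$time_days, .data$peptide_id,
                 .data$mod_form, .data$charge) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0)
    abort(paste0("Conflicting duplicate rows for the same charge state, ",
                 "e.g. ", dup$peptide_id[[1]], " charge ", dup$charge[[1]],
                 " at t=", dup$time_days[[1]], "."))
  raw %>%
    group_by(.data$subject, .data$time_days, .data$peptide_id,
             .data$mod_form) %>%
    summarise(light_area = sum(.data$light_area),
              heavy_area = sum(.data$heavy_area), .groups = "drop") %>%
    arrange(.data$subject, .data$time_days, .data$peptide_id,
            .data$mod_form)
}

#' Relative level of a quality attribute
#'
#' The relative level of a modified form is its peak area divided by the
#' summed areas of all forms (modified and unmodified) of the same peptide,
#' per subject and time point. Time points where every form's area is zero
#' (e.g., the pre-bleed) are flagged missing (`NA`), never reported as 0.
#'
#' @param peak_table Long-format peak table (see [generate_study()]).
#' @param peptide Peptide id to evaluate.
#' @param mod_form Modified-form label whose share is reported.
#' @param attribute_name Name attached to the series; defaults to
#'   `mod_form`.
#' @return A tibble (`attribute`, `subject`, `time_days`, `fraction`)
#'   with `fraction` in `[0, 1]` or `NA`.
#' @export
relative_percent <- function(peak_table, peptide, mod_form,
                             attribute_name = mod_form) {
  tbl <- peak_table %>% filter(.data$peptide_id == peptide)
  if (nrow(tbl) == 0)
    abort(paste0("Peptide `", peptide, "` not present in the table."))
  if (!mod_form %in% tbl$mod_form)
    abort(paste0("Form `", mod_form, "` not observed for peptide `",
                 peptide, "`."))
  tbl %>%
    group_by(.data$subject, .data$time_days) %>%
    summarise(
      denom = sum(.data$light_area),
      num = sum(.data$light_area[.data$mod_form == !!mod_form]),
      .groups = "drop"
    ) %>%
    mutate(
      attribute = attribute_name,
      fraction = dplyr::if_else(.data$denom > 0,
                                .data$num / .data$denom, NA_real_)
    ) %>%
    select("attribute", "subject", "time_days", "fraction") %>%
    arrange(.data$subject, .data$time_days)
}

#' Absolute concentration from light/heavy peak-area ratios
#'
#' With a heavy-labeled internal calibrant spiked at a fixed amount into a
#' fixed serum aliquot, the light/heavy area ratio converts directly to an
#' absolute serum concentration:
#' `conc (ug/mL) = ratio * calibrant_ug / serum_ul * 1000`.
#' Points with zero heavy area are flagged missing; ratios below the
#' quantitation floor are retained but flagged `below_lloq`.
#'
#' @param peak_table Long-format peak table.
#' @param peptide Peptide id.
#' @param calibrant_ug Calibrant spike per sample, µg.
#' @param serum_ul Serum aliquot, µL.
#' @param mod_form Form to quantify (default the unmodified peptide).
#' @param lloq_ratio Light/heavy ratio below which a point is flagged as
#'   under the reliable quantitation range.
#' @return A tibble (`subject`, `time_days`, `concentration`,
#'   `below_lloq`); concentration in µg/mL, `NA` where heavy area is 0.
#' @examples
#' # ratio 1 with the 2.5 ug / 12.5 uL protocol corresponds to 200 ug/mL
#' @export
absolute_concentration <- function(peak_table, peptide,
                                   calibrant_ug = 2.5, serum_ul = 12.5,
                                   mod_form = "none", lloq_ratio = 1e-4) {
  tbl <- peak_table %>%
    filter(.data$peptide_id == peptide, .data$mod_form == !!mod_form)
  if (nrow(tbl) == 0)
    abort(paste0("Peptide `", peptide, "` / form `", mod_form,
                 "` not present in the table."))
  tbl %>%
    mutate(
      ratio = dplyr::if_else(.data$heavy_area > 0,
                             .data$light_area / .data$heavy_area, NA_real_),
      concentration = .data$ratio * calibrant_ug / serum_ul * 1000,
      below_lloq = !is.na(.data$ratio) & .data$ratio < lloq_ratio
    ) %>%
    select("subject", "time_days", "concentration", "below_lloq") %>%
    arrange(.data$subject, .data$time_days)
}

#' Fit a spike-in standard curve
#'
#' Ordinary least-squares line of the light/heavy area ratio against the
#' spiked concentration, pooling all peptides (the ionization factor
#' cancels in the ratio). Serves as a linearity QC: with an ideal internal
#' calibrant the slope is the unit conversion itself.
#'
#' @param curve_table Tibble with columns `level`, `light_area`,
#'   `heavy_area` (as from [generate_standard_curve()]).
#' @return An object of class `standard_curve`: `slope`, `intercept`,
#'   `r_squared`, `n_levels`, `degenerate`.
#' @export
fit_standard_curve <- function(curve_table) {
  required <- c("level", "light_area", "heavy_area")
  if (!all(required %in% names(curve_table)))
    abort("`curve_table` must have columns level, light_area, heavy_area.")
  n_levels <- length(unique(curve_table$level))
  if (n_levels < 3)
    abort("A standard curve needs >= 3 concentration levels.")
  d <- curve_table %>%
    mutate(ratio = .data$light_area / .data$heavy_area)
  fit <- lm(ratio ~ level, data = d)
  ss_tot <- sum((d$ratio - mean(d$ratio))^2)
  degenerate <- ss_tot < .Machine$double.eps * length(d$ratio)
  r2 <- if (degenerate) NA_real_ else
    suppressWarnings(summary(fit))$r.squared
  if (degenerate)
    warn("Constant ratios: zero-slope standard curve, R^2 undefined.")
  structure(list(
    slope = unname(coef(fit)[["level"]]),
    intercept = unname(coef(fit)[["(Intercept)"]]),
    r_squared = r2, n_levels = n_levels, degenerate = degenerate
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat("<standard_curve>\n")
  cat(sprintf("  ratio = %.6g + %.6g * conc, R^2 = %s (%d levels)%s\n",
              x$intercept, x$slope,
              ifelse(is.na(x$r_squared), "undefined",
                     sprintf("%.6f", x$r_squared)),
              x$n_levels, ifelse(x$degenerate, " [degenerate]", "")))
  invisible(x)
}

#' @export
tidy.standard_curve <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n_levels = x$n_levels,
         degenerate = x$degenerate)
}

#' Select reference peptides for total-concentration measurement
#'
#' Implements the two stated selection criteria — high intensity, and
#' absence of carryover and modifications: peptides with any modified form
#' in the table, or any nonzero pre-dose (time 0) light signal, are
#' excluded; the remainder are ranked by median light intensity across all
#' samples (descending, ties broken lexicographically by peptide id) and
#' the top `k` returned.
#'
#' @param peak_table Long-format peak table including the pre-dose sample.
#' @param k Number of reference peptides (default 20).
#' @return Character vector of peptide ids, highest-intensity first.
#' @export
select_reference_peptides <- function(peak_table, k = 20) {
  stats_tbl <- peak_table %>%
    group_by(.data$peptide_id) %>%
    summarise(
      has_mod = any(.data$mod_form != "none"),
      carryover = any(.data$light_area[.data$time_days == 0] > 0),
      median_intensity = median(
        .data$light_area[.data$mod_form == "none"]),
      .groups = "drop"
    )
  eligible <- stats_tbl %>%
    filter(!.data$has_mod, !.data$carryover) %>%
    arrange(desc(.data$median_intensity), .data$peptide_id)
  if (nrow(eligible) < k) {
    warn(sprintf("Only %d eligible peptides (requested %d); returning all.",
                 nrow(eligible), k))
    return(eligible$peptide_id)
  }
  eligible$peptide_id[seq_len(k)]
}

#' Total drug concentration from a reference-peptide panel
#'
#' Per subject and time point, the unweighted mean of the per-peptide
#' absolute concentrations over the reference panel. Points where more
#' than half the panel is missing are flagged.
#'
#' @param peak_table Long-format peak table.
#' @param reference_peptides Character vector of peptide ids
#'   (see [select_reference_peptides()]).
#' @param calibrant_ug,serum_ul,lloq_ratio As in
#'   [absolute_concentration()].
#' @return A tibble (`subject`, `time_days`, `concentration`,
#'   `n_peptides`, `n_missing`, `flagged`).
#' @export
total_concentration <- function(peak_table, reference_peptides,
                                calibrant_ug = 2.5, serum_ul = 12.5,
                                lloq_ratio = 1e-4) {
  if (length(reference_peptides) == 0)
    abort("`reference_peptides` must be non-empty.")
  per_pep <- purrr::map_dfr(reference_peptides, function(pep) {
    absolute_concentration(peak_table, pep, calibrant_ug, serum_ul,
                           lloq_ratio = lloq_ratio) %>%
      mutate(peptide_id = pep)
  })
  per_pep %>%
    group_by(.data$subject, .data$time_days) %>%
    summarise(
      n_peptides = dplyr::n(),
      n_missing = sum(is.na(.data$concentration)),
      concentration = mean(.data$concentration, na.rm = TRUE),
      .groups = "drop"
    ) %>%
    mutate(
      concentration = dplyr::if_else(is.nan(.data$concentration),
                                     NA_real_, .data$concentration),
      flagged = .data$n_missing > 0.5 * .data$n_peptides
    ) %>%
    arrange(.data$subject, .data$time_days)
}

#' Screen peptides for preferential in vivo degradation
#'
#' Compares each peptide's concentration curve against the total drug
#' curve: the slope of `log(peptide / total)` against time estimates any
#' extra first-order loss of that peptide's region of the molecule (e.g.,
#' terminal degradation). Peptides whose log-ratio slope is negative with
#' magnitude above `slope_threshold` and regression p-value below
#' `p_threshold` are flagged.
#'
#' @param peptide_series Tibble (`peptide_id`, `subject`, `time_days`,
#'   `concentration`) for the peptides under scrutiny.
#' @param total_series Tibble (`subject`, `time_days`, `concentration`)
#'   of total drug concentration on the same grid.
#' @param slope_threshold Flagging threshold on |slope|, 1/day.
#' @param p_threshold Two-sided regression p-value threshold.
#' @return A tibble (`peptide_id`, `slope`, `se`, `p_value`, `n_points`,
#'   `flagged`); slope in 1/day.
#' @export
terminal_degradation_screen <- function(peptide_series, total_series,
                                        slope_threshold = 0.01,
                                        p_threshold = 0.05) {
  joined <- peptide_series %>%
    dplyr::inner_join(
      total_series %>%
        rename(total = "concentration") %>%
        select("subject", "time_days", "total"),
      by = c("subject", "time_days")
    ) %>%
    filter(is.finite(.data$concentration), is.finite(.data$total),
           .data$concentration > 0, .data$total > 0) %>%
    mutate(log_ratio = log(.data$concentration / .data$total))
  joined %>%
    group_by(.data$peptide_id) %>%
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$time_days)) < 3)
        abort(paste0("Peptide `", key$peptide_id,
                     "`: fewer than 3 shared time points."))
      fit <- lm(log_ratio ~ time_days, data = d)
      # a peptide tracking the total exactly gives a zero-residual fit;
      # the perfect-fit warning from summary.lm is expected there
      sm <- suppressWarnings(summary(fit))$coefficients
      tibble(slope = sm["time_days", "Estimate"],
             se = sm["time_days", "Std. Error"],
             p_value = sm["time_days", "Pr(>|t|)"],
             n_points = nrow(d))
    }) %>%
    ungroup() %>%
    mutate(flagged = .data$slope < -slope_threshold &
             .data$p_value < p_threshold)
}

#' Quantify a whole study
#'
#' Convenience wrapper running the full quantitation stage: reference
#' peptide selection, the 20-peptide (by default) total-concentration
#' average, and relative-level series for every attribute reporter peptide
#' found in the table.
#'
#' @param peak_table Long-format peak table.
#' @param config The [study_config()] that produced it (supplies calibrant
#'   amount, serum volume, and the attribute-to-peptide map).
#' @param k Number of reference peptides.
#' @return A list with `reference_peptides`, `total` (concentration
#'   series), and `attributes` (bound tibble of attribute fraction series).
#' @export
quantify_study <- function(peak_table, config, k = 20) {
  stopifnot(inherits(config, "study_config"))
  refs <- select_reference_peptides(peak_table, k = k)
  total <- total_concentration(peak_table, refs,
                               calibrant_ug = config$calibrant_amount,
                               serum_ul = config$serum_volume)
  attributes <- purrr::map_dfr(config$attribute_specs, function(spec) {
    relative_percent(peak_table, spec$peptide, spec$name)
  })
  list(reference_peptides = refs, total = total, attributes = attributes)
}
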