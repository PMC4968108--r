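make_raw_charges <- function() {
  tibble::tibble(
    subject = "S01", time_days = c(1, 1, 1, 2),
    peptide_id = c("P1", "P1", "P2", "P1"),
    mod_form = "none", charge = c(2, 3, 2, 2),
    light_area = c(100, 50, 40, 80), heavy_area = c(10, 5, 4, 8)
  )
}

test_that("charge states are summed, order-invariantly", {
  merged <- merge_charge_states(make_raw_charges())
  expect_equal(nrow(merged), 3)
  p1 <- dplyr::filter(merged, peptide_id == "P1", time_days == 1)
  expect_equal(p1$light_area, 150)
  expect_equal(p1$heavy_area, 15)
  # single charge state passes through unchanged
  p2 <- dplyr::filter(merged, peptide_id == "P2")
  expect_equal(p2$light_area, 40)
  # permuting input rows changes nothing
  raw <- make_raw_charges()
  shuffled <- raw[c(4, 2, 3, 1), ]
  expect_identical(merge_charge_states(shuffled), merged)
  # duplicate (sample, peptide, form, charge) rows are a hard error
  expect_error(merge_charge_states(raw[c(1, 1, 2), ]), "duplicate")
})

test_that("relative levels divide a form by the sum over all forms", {
  tbl <- tibble::tibble(
    subject = "S01", time_days = c(1, 1, 2, 2, 2, 0, 0),
    peptide_id = "P1",
    mod_form = c("deam", "none", "deam", "none", "oxid", "deam", "none"),
    light_area = c(35, 65, 20, 50, 30, 0, 0),
    heavy_area = 1
  )
  s <- relative_percent(tbl, "P1", "deam")
  expect_equal(s$fraction[s$time_days == 1], 0.35)
  # fractions over all forms sum to 1 at each retained point
  forms <- unique(tbl$mod_form)
  tot <- rowSums(sapply(forms, function(fm)
    relative_percent(tbl, "P1", fm)$fraction))
  expect_equal(tot[!is.na(tot)], rep(1, sum(!is.na(tot))), tolerance = 1e-9)
  # all-zero denominator (pre-bleed) is missing, never 0
  expect_true(is.na(s$fraction[s$time_days == 0]))
  expect_error(relative_percent(tbl, "P9", "deam"), "not present")
})

test_that("light/heavy ratios convert to absolute concentrations", {
  tbl <- tibble::tibble(
    subject = "S01", time_days = c(0, 1, 2, 3),
    peptide_id = "P1", mod_form = "none",
    light_area = c(0, 10, 5, 3), heavy_area = c(10, 10, 10, 0)
  )
  conc <- absolute_concentration(tbl, "P1", calibrant_ug = 2.5,
                                 serum_ul = 12.5)
  expect_equal(conc$concentration[conc$time_days == 1], 200)  # ratio 1
  expect_equal(conc$concentration[conc$time_days == 2], 100)  # ratio 0.5
  expect_equal(conc$concentration[conc$time_days == 0], 0)    # pre-bleed
  expect_true(is.na(conc$concentration[conc$time_days == 3])) # heavy 0
  # linear in light, inverse-linear in heavy
  tbl2 <- tbl; tbl2$light_area <- tbl2$light_area * 3
  conc2 <- absolute_concentration(tbl2, "P1")
  expect_equal(conc2$concentration[2:3], 3 * conc$concentration[2:3])
  tbl3 <- tbl; tbl3$heavy_area <- tbl3$heavy_area * 2
  conc3 <- absolute_concentration(tbl3, "P1")
  expect_equal(conc3$concentration[2:3], conc$concentration[2:3] / 2)
})

test_that("standard-curve fitting reports slope, R2 and degeneracy", {
  exact <- tibble::tibble(level = c(1, 2, 4, 8),
                          light_area = c(2, 4, 8, 16), heavy_area = 4)
  sc <- fit_standard_curve(exact)
  expect_equal(sc$r_squared, 1, tolerance = 1e-12)
  expect_equal(sc$slope, 0.5 / 4 * 4)  # ratio = level / 2
  flat <- tibble::tibble(level = c(1, 2, 4), light_area = 5,
                         heavy_area = 5)
  expect_warning(scf <- fit_standard_curve(flat), "degenerate|Constant")
  expect_true(scf$degenerate)
  expect_true(is.na(scf$r_squared))
  expect_error(fit_standard_curve(exact[1:2, ]), "3 concentration levels")
  # noisy curve recovers the generator slope within 5%
  cfg <- study_config(noise_cv = 0.05, seed = 13)
  tbl <- generate_standard_curve(c(1, 2, 5, 10, 20, 50, 100, 200), cfg)
  scn <- fit_standard_curve(tbl)
  true_slope <- 1 / (cfg$calibrant_amount / cfg$serum_volume * 1000)
  expect_equal(scn$slope, true_slope, tolerance = 0.05)
})

test_that("reference-peptide selection matches a brute-force oracle", {
  set.seed(99)
  n_clean <- 25
  meds <- runif(n_clean, 1, 100)
  clean_ids <- sprintf("C%02d", seq_len(n_clean))
  rows <- purrr::map_dfr(seq_len(n_clean), function(i) {
    tibble::tibble(subject = "S01", time_days = c(0, 1, 2),
                   peptide_id = clean_ids[i], mod_form = "none",
                   light_area = c(0, meds[i], meds[i]), heavy_area = 1)
  })
  # five modifiable peptides, high intensity: excluded regardless
  mod_rows <- purrr::map_dfr(1:5, function(i) {
    tibble::tibble(subject = "S01", time_days = c(1, 1),
                   peptide_id = sprintf("M%02d", i),
                   mod_form = c("none", "deam"),
                   light_area = c(1000, 10), heavy_area = 1)
  })
  # carryover peptide: nonzero pre-dose signal, highest intensity
  carry <- tibble::tibble(subject = "S01", time_days = c(0, 1),
                          peptide_id = "CARRY", mod_form = "none",
                          light_area = c(5, 1e6), heavy_area = 1)
  tbl <- dplyr::bind_rows(rows, mod_rows, carry)
  sel <- select_reference_peptides(tbl, k = 20)
  # brute-force oracle: order clean peptides by median intensity
  oracle <- clean_ids[order(-meds, clean_ids)][1:20]
  expect_identical(sel, oracle)
  expect_identical(select_reference_peptides(tbl, k = 1), oracle[1])
  expect_false("CARRY" %in%
                 suppressWarnings(select_reference_peptides(tbl, k = 26)))
  # permutation invariance
  expect_identical(select_reference_peptides(tbl[sample(nrow(tbl)), ], 20),
                   sel)
  expect_warning(sel_all <- select_reference_peptides(tbl, k = 30),
                 "eligible")
  expect_equal(length(sel_all), n_clean)
})

test_that("total concentration averages the panel and flags sparse points", {
  base <- tidyr::expand_grid(
    subject = "S01", time_days = c(1, 2, 3),
    peptide_id = c("P1", "P2", "P3", "P4")
  ) |>
    dplyr::mutate(mod_form = "none", light_area = 10, heavy_area = 10)
  tc <- total_concentration(base, c("P1", "P2", "P3", "P4"),
                            calibrant_ug = 2.5, serum_ul = 12.5)
  expect_equal(tc$concentration, rep(200, 3))
  # one peptide missing at one point: mean over the remainder
  miss <- base
  miss$heavy_area[miss$peptide_id == "P1" & miss$time_days == 2] <- 0
  tcm <- total_concentration(miss, c("P1", "P2", "P3", "P4"))
  expect_equal(tcm$concentration[tcm$time_days == 2], 200)
  expect_false(tcm$flagged[tcm$time_days == 2])
  # >50% missing flags the point
  sparse <- base
  sparse$heavy_area[sparse$time_days == 3 &
                      sparse$peptide_id %in% c("P1", "P2", "P3")] <- 0
  tcs <- total_concentration(sparse, c("P1", "P2", "P3", "P4"))
  expect_true(tcs$flagged[tcs$time_days == 3])
  expect_error(total_concentration(base, character(0)), "non-empty")
})

test_that("noise-free quantitation reproduces generator truth exactly", {
  qs <- quantified_study("deamidation", noise_cv = 0, seed = 2)
  truth_tc <- dplyr::filter(qs$study$truth$total_concentration,
                            time_days > 0)
  for (s in unique(qs$quant$total$subject)) {
    obs <- dplyr::filter(qs$quant$total, subject == s, time_days > 0)
    expect_lt(max(abs(obs$concentration - truth_tc$concentration) /
                    truth_tc$concentration), 1e-9)
  }
  m <- dplyr::inner_join(
    dplyr::filter(qs$quant$attributes, time_days > 0),
    dplyr::filter(qs$study$truth$attribute_series, time_days > 0),
    by = c("attribute", "time_days"), suffix = c("_obs", "_true"))
  expect_lt(max(abs(m$fraction_obs - m$fraction_true) /
                  pmax(m$fraction_true, 1e-12)), 1e-9)
})

test_that("degradation screen flags excess decay and only excess decay", {
  times <- c(1, 2, 4, 7, 14, 21, 42)
  total <- tibble::tibble(subject = "S01", time_days = times,
                          concentration = 100 * exp(-0.05 * times))
  pep_equal <- dplyr::mutate(total, peptide_id = "EQ")
  pep_decay <- dplyr::mutate(total, peptide_id = "DEC",
                             concentration = concentration *
                               exp(-0.05 * time_days))
  pep_rise <- dplyr::mutate(total, peptide_id = "UP",
                            concentration = concentration *
                              exp(0.03 * time_days))
  rep_tbl <- terminal_degradation_screen(
    dplyr::bind_rows(pep_equal, pep_decay, pep_rise), total)
  eq <- dplyr::filter(rep_tbl, peptide_id == "EQ")
  expect_equal(eq$slope, 0, tolerance = 1e-10)
  expect_false(eq$flagged)
  dec <- dplyr::filter(rep_tbl, peptide_id == "DEC")
  expect_equal(dec$slope, -0.05, tolerance = 1e-6)
  expect_true(dec$flagged)
  expect_false(dplyr::filter(rep_tbl, peptide_id == "UP")$flagged)
  expect_error(
    terminal_degradation_screen(pep_equal[1:2, ], total[1:2, ]),
    "3 shared time points")
})

test_that("injected extra decay is recovered through the full pipeline", {
  qs <- quantified_study("deamidation", noise_cv = 0, seed = 4)
  nterm <- absolute_concentration(qs$study$peak_table, "LC_NTERM_PEP",
                                  qs$config$calibrant_amount,
                                  qs$config$serum_volume) |>
    dplyr::mutate(peptide_id = "LC_NTERM_PEP") |>
    dplyr::filter(time_days > 0)
  rep_tbl <- terminal_degradation_screen(
    nterm, dplyr::filter(qs$quant$total, time_days > 0))
  expect_equal(rep_tbl$slope, -0.05, tolerance = 1e-6)
  expect_true(rep_tbl$flagged)
})
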