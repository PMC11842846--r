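test_that("symmetric division splits the mother area exactly in half", {
  tab <- simulate_lineage(lineage_params(
    division_asymmetry_sd = 0, growth_rate = 0.05, generations = 3, seed = 4
  ))
  kids <- tab[!is.na(tab$parent_id), ]
  births <- dplyr::slice_min(dplyr::group_by(kids, cell_id), time_h,
                             with_ties = FALSE)
  for (p in unique(births$parent_id)) {
    pair <- births[births$parent_id == p, ]
    expect_equal(pair$cell_area[1], pair$cell_area[2])
    mother_at_div <- tab$cell_area[tab$cell_id == p &
                                     tab$time_h == pair$time_h[1]]
    expect_equal(pair$cell_area[1], mother_at_div / 2)
  }
})

test_that("daughter areas sum exactly to the mother area at every division", {
  tab <- simulate_lineage(lineage_params(
    division_asymmetry_sd = 0.12, generations = 5, seed = 21
  ))
  kids <- tab[!is.na(tab$parent_id), ]
  births <- dplyr::slice_min(dplyr::group_by(kids, cell_id), time_h,
                             with_ties = FALSE)
  sums <- dplyr::summarise(
    dplyr::group_by(births, parent_id, time_h),
    total = sum(cell_area), n = dplyr::n(), .groups = "drop"
  )
  expect_true(all(sums$n == 2))
  for (k in seq_len(nrow(sums))) {
    mother_at_div <- tab$cell_area[tab$cell_id == sums$parent_id[k] &
                                     tab$time_h == sums$time_h[k]]
    expect_equal(sums$total[k], mother_at_div, tolerance = 1e-12)
  }
})

test_that("zero growth keeps every cell area constant over the window", {
  tab <- simulate_lineage(lineage_params(
    growth_rate = 0, growth_hours = 6, generations = 2, seed = 2
  ))
  spans <- dplyr::summarise(
    dplyr::group_by(tab, cell_id),
    delta = max(cell_area) - min(cell_area), .groups = "drop"
  )
  expect_true(all(spans$delta == 0))
})

test_that("log-area variance grows linearly at the Monte-Carlo oracle rate", {
  slope_one <- function(seed) {
    params <- lineage_params(division_asymmetry_sd = 0.1, generations = 12,
                             n_founders = 3, seed = seed)
    tab <- simulate_lineage(params)
    births <- dplyr::slice_min(dplyr::group_by(tab, cell_id), time_h,
                               with_ties = FALSE)
    v_by_gen <- dplyr::summarise(
      dplyr::group_by(births, generation),
      v = var(log(cell_area)), .groups = "drop"
    )
    v_by_gen <- v_by_gen[v_by_gen$generation >= 1, ]
    coef(lm(v ~ generation, data = v_by_gen))[["generation"]]
  }
  slope <- mean(vapply(c(8, 9, 10), slope_one, numeric(1)))
  set.seed(99)
  slope_oracle <- oracle_division_var_slope(0.1)
  expect_lt(abs(slope - slope_oracle) / slope_oracle, 0.05)
})

test_that("terminal population of the default simulation is log-normal with
           the steady-state width", {
  s2 <- vapply(1:5, function(s) {
    par <- lineage_params(seed = s)
    tab <- simulate_lineage(par)
    pop <- lineage_to_population(tab, par$generations * par$growth_hours)
    f <- fit_lognormal(pop$cell_area / mean(pop$cell_area))
    2 * f$params[["sigma2"]]
  }, numeric(1))
  expect_lt(abs(mean(s2) - 0.19), 0.05)
})

test_that("multiplicative division yields a log-normal terminal population
           (KS at alpha = 0.01, averaged over seeds)", {
  ps <- vapply(1:20, function(s) {
    par <- lineage_params(division_asymmetry_sd = 0.08, generations = 10,
                          seed = s)
    tab <- simulate_lineage(par)
    pop <- lineage_to_population(tab, par$generations * par$growth_hours)
    fit_lognormal(pop$cell_area / mean(pop$cell_area))$ks_p
  }, numeric(1))
  expect_gt(mean(ps), 0.01)
})

test_that("population extraction preserves pairing and signals empty times", {
  par <- lineage_params(n_founders = 2, generations = 2, seed = 5)
  tab <- simulate_lineage(par)
  pop0 <- lineage_to_population(tab, 0)
  expect_equal(nrow(pop0), 2)
  # at a division instant the mother is replaced by its two daughters
  pop6 <- lineage_to_population(tab, 6)
  expect_equal(nrow(pop6), 4)
  expect_error(lineage_to_population(tab, 1000),
               class = "nucmorph_empty_selection")
})

test_that("noise-free nucleus coupling gives perfect area correlation", {
  tab <- simulate_lineage(lineage_params(nc_noise_sd = 0, generations = 6,
                                         seed = 3))
  pop <- lineage_to_population(tab, 36)
  expect_equal(cor(pop$cell_area, pop$nucleus_area), 1.0,
               tolerance = 1e-12)
})

test_that("lineage simulation is bit-identical under the same seed", {
  p <- lineage_params(generations = 5, seed = 123)
  expect_identical(simulate_lineage(p), simulate_lineage(p))
})

test_that("invalid lineage parameters are rejected", {
  expect_error(lineage_params(initial_area = -1), "initial_area")
  expect_error(lineage_params(division_asymmetry_sd = 0.5),
               "division_asymmetry_sd")
  expect_error(lineage_params(nc_ratio = 1.2), "nc_ratio")
  expect_error(lineage_params(generations = 0), "generations")
  expect_error(lineage_params(growth_rate = Inf), "growth_rate")
})

test_that("water dilution scales osmolarity linearly", {
  expect_identical(dilution_osmolarity(290, 0.05), 14.5)
  expect_identical(dilution_osmolarity(321, 1.0), 321)
  expect_identical(dilution_osmolarity(300, 0.5), 150)
  expect_error(dilution_osmolarity(290, 1.5), "medium_fraction")
})
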