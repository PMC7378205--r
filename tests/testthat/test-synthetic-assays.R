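test_that("simulated death times have the configured median", {
  # low dispersion, many worms: empirical 50% day tightly brackets the median
  cfg <- survival_sim_config(effect_multipliers = c(control = 1),
                             n_wells_per_condition = 1L,
                             worms_per_well = 10000L,
                             control_median_days = 10, shape = 12, seed = 4)
  d <- simulate_survival(cfg)
  dt <- attr(d, "death_times")$death_day
  emp <- unname(stats::quantile(dt, 0.5))
  expect_gt(emp, 9.5)
  expect_lt(emp, 10.5)
})

test_that("null conditions are exchangeable with control", {
  cfg <- survival_sim_config(effect_multipliers = c(control = 1, a = 1, b = 1),
                             n_wells_per_condition = 1L, worms_per_well = 500L,
                             seed = 9)
  d <- simulate_survival(cfg)
  dt <- attr(d, "death_times")
  ks <- suppressWarnings(stats::ks.test(dt$death_day[dt$condition == "a"],
                                        dt$death_day[dt$condition == "control"]))
  expect_gt(ks$p.value, 0.01)
})

test_that("alive counts never increase within a well", {
  cfg <- survival_sim_config(effect_multipliers = c(control = 1, t = 0.7),
                             seed = 2)
  d <- simulate_survival(cfg)
  for (w in unique(d$well_id)) {
    a <- d$n_alive[d$well_id == w][order(d$day[d$well_id == w])]
    expect_true(all(diff(a) <= 0))
  }
  expect_true(all(d$n_alive <= d$n_total))
  expect_true(all(d$n_total >= 5 & d$n_total <= 18))
})

test_that("survival simulation is deterministic and validates its config", {
  cfg <- survival_sim_config(effect_multipliers = c(control = 1), seed = 1)
  expect_identical(simulate_survival(cfg), simulate_survival(cfg))
  expect_error(survival_sim_config(effect_multipliers = c(control = 1),
                                   observation_days = numeric(0)), "empty")
  expect_error(survival_sim_config(effect_multipliers = c(control = 1),
                                   observation_days = c(0, 2, 2)), "increasing")
  expect_error(survival_sim_config(effect_multipliers = c(control = 1, bad = -1)),
               "> 0")
  expect_error(survival_sim_config(effect_multipliers = c(a = 1)), "control")
})

test_that("nile red effect fractions scale sample means as configured", {
  cfg <- nilered_sim_config(effect_fractions = c(control = 1, t = 0.5),
                            n_replicate_wells = 60L, worms_per_well = 8L,
                            n_experiments = 1L, cv = 0.1, seed = 3)
  d <- simulate_nilered_plate(cfg)
  r <- mean(d$fluorescent_units[d$condition == "t"]) /
    mean(d$fluorescent_units[d$condition == "control"])
  expect_gt(r, 0.48)
  expect_lt(r, 0.52)
})

test_that("nile red simulation is deterministic, labelled, and validates", {
  cfg <- nilered_sim_config(effect_fractions = c(control = 1, t = 1), seed = 8)
  d <- simulate_nilered_plate(cfg)
  expect_identical(d, simulate_nilered_plate(cfg))
  expect_true(all(c("worm_id", "well_id", "condition", "experiment",
                    "fluorescent_units") %in% names(d)))
  expect_true(all(d$fluorescent_units > 0))
  # worms per well within the configured band
  per_well <- table(d$well_id)
  expect_true(all(per_well >= 3 & per_well <= 10))
  expect_error(nilered_sim_config(effect_fractions = c(control = 1), cv = -0.1),
               "cv")
})
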