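worm_table <- function(units_by_cond, experiment = 1) {
  do.call(rbind, lapply(names(units_by_cond), function(cond) {
    u <- units_by_cond[[cond]]
    data.frame(worm_id = paste0(cond, "_", seq_along(u), "_e", experiment),
               well_id = paste0(cond, "_w1"), condition = cond,
               experiment = experiment, fluorescent_units = u,
               stringsAsFactors = FALSE)
  }))
}

test_that("condition aggregation is the arithmetic mean per experiment", {
  d <- worm_table(list(a = c(100, 200, 300)))
  agg <- aggregate_condition(d)
  expect_equal(agg$mean_units, 200)
  # experiments are kept separate, never pooled
  d2 <- rbind(worm_table(list(a = c(100, 200))),
              worm_table(list(a = c(1000, 2000)), experiment = 2))
  agg2 <- aggregate_condition(d2)
  expect_equal(agg2$mean_units, c(150, 1500))
})

test_that("aggregation matches a brute-force group-by oracle on random tables", {
  set.seed(20)
  conds <- c("control", "x", "y", "z")
  d <- data.frame(condition = sample(conds, 200, replace = TRUE),
                  experiment = sample(1:3, 200, replace = TRUE),
                  fluorescent_units = stats::runif(200, 100, 5000))
  agg <- aggregate_condition(d)
  for (r in seq_len(nrow(agg))) {
    sel <- d$condition == agg$condition[r] & d$experiment == agg$experiment[r]
    expect_equal(agg$mean_units[r], sum(d$fluorescent_units[sel]) / sum(sel))
    expect_identical(agg$n_worms[r], sum(sel))
  }
})

test_that("plate-map joins resolve wells and report orphans", {
  d <- data.frame(well_id = c("A1", "A1", "B7"),
                  fluorescent_units = c(10, 20, 30))
  pm <- data.frame(well_id = c("A1", "B7"), condition = c("control", "t"),
                   experiment = 1)
  agg <- aggregate_condition(d, pm)
  expect_equal(agg$mean_units[agg$condition == "control"], 15)
  d$well_id[3] <- "Z9"
  expect_error(aggregate_condition(d, pm), "Z9")
})

test_that("the vehicle control normalizes to exactly 100%", {
  d <- rbind(worm_table(list(control = c(900, 1100), t = c(500, 634)), 1),
             worm_table(list(control = c(2000, 2000), t = c(1100, 1168)), 2))
  nrm <- normalize_to_control(aggregate_condition(d))
  ctl <- nrm$by_experiment$normalized_pct[nrm$by_experiment$condition == "control"]
  expect_identical(ctl, c(100, 100))
  expect_identical(nrm$summary$normalized_pct[nrm$summary$condition == "control"], 100)
  expect_identical(nrm$summary$sd_pct[nrm$summary$condition == "control"], 0)
  # treated mean 567 vs control 1000 -> 56.7%
  expect_equal(nrm$by_experiment$normalized_pct[
    nrm$by_experiment$condition == "t" & nrm$by_experiment$experiment == 1],
    56.7)
  expect_error(normalize_to_control(
    aggregate_condition(worm_table(list(control = c(0, 0), t = c(1, 2))))),
    "zero control")
})

test_that("normalization is invariant to a per-experiment gain factor", {
  set.seed(21)
  d <- rbind(worm_table(list(control = stats::runif(8, 500, 1500),
                             t = stats::runif(8, 200, 900)), 1),
             worm_table(list(control = stats::runif(8, 500, 1500),
                             t = stats::runif(8, 200, 900)), 2))
  base <- normalize_to_control(aggregate_condition(d))
  d2 <- d
  d2$fluorescent_units <- d$fluorescent_units * ifelse(d$experiment == 1, 3.7, 0.2)
  scaled <- normalize_to_control(aggregate_condition(d2))
  expect_equal(base$by_experiment$normalized_pct,
               scaled$by_experiment$normalized_pct)
})

test_that("Bonferroni adjustment is min(1, m x raw p) over the non-control family", {
  set.seed(22)
  by_exp <- expand.grid(experiment = 1:4,
                        condition = c("control", "a", "b", "c"),
                        stringsAsFactors = FALSE)
  by_exp$normalized_pct <- ifelse(by_exp$condition == "control", 100,
                                  stats::rnorm(nrow(by_exp), 95, 8))
  res <- anova_bonferroni(by_exp, "control")
  expect_identical(res$m, 3L)
  expect_equal(res$table$p_adj, pmin(1, res$m * res$table$p_raw))
  expect_false("control" %in% res$table$condition)
  expect_error(anova_bonferroni(by_exp[by_exp$experiment == 1, ], "control"),
               "two independent experiments")
})

test_that("family-wise error stays controlled under a simulated null", {
  set.seed(24)
  rej <- logical(2000)
  for (r in 1:2000) {
    cfg <- nilered_sim_config(effect_fractions = c(control = 1, a = 1, b = 1, c = 1),
                              n_replicate_wells = 3L, seed = sample.int(2^30, 1))
    pr <- plate_results(simulate_nilered_plate(cfg))
    rej[r] <- any(pr$significant, na.rm = TRUE)
  }
  expect_lte(mean(rej), 0.05 + 2 * sqrt(0.05 * 0.95 / 2000))
})

test_that("a 40%-of-control condition with cv 0.1 is detected in 3 experiments", {
  set.seed(25)
  for (s in 1:5) {
    cfg <- nilered_sim_config(effect_fractions = c(control = 1, down = 0.4,
                                                   null = 1),
                              cv = 0.1, seed = 600 + s)
    pr <- plate_results(simulate_nilered_plate(cfg))
    expect_true(pr$significant[pr$condition == "down"])
  }
})

test_that("a halved-fluorescence condition is detected across three experiments", {
  cfg <- nilered_sim_config(effect_fractions = c(control = 1, down = 0.4),
                            cv = 0.1, seed = 23)
  pr <- plate_results(simulate_nilered_plate(cfg))
  expect_true(pr$significant[pr$condition == "down"])
  expect_lt(pr$normalized_pct[pr$condition == "down"], 60)
  expect_identical(pr$normalized_pct[pr$condition == "control"], 100)
})
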