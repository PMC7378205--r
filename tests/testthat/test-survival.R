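make_log <- function(wells) {
  do.call(rbind, lapply(names(wells), function(w) {
    obs <- wells[[w]]
    data.frame(well_id = w, condition = sub("_w.*", "", w),
               day = as.numeric(names(obs)), n_alive = unname(obs),
               n_total = unname(obs)[1], stringsAsFactors = FALSE)
  }))
}

test_that("survival curves are direct per-well proportions", {
  log <- make_log(list(ctl_w1 = c(`0` = 10, `5` = 10, `10` = 5)))
  cu <- build_survival_curves(log, "well")
  expect_equal(cu$fraction_alive, c(1.0, 1.0, 0.5))
})

test_that("condition-level pooling weights wells by their worm counts", {
  log <- make_log(list(ctl_w1 = c(`0` = 10, `5` = 6),
                       ctl_w2 = c(`0` = 5, `5` = 4)))
  cu <- build_survival_curves(log, "condition")
  expect_equal(cu$fraction_alive, c(15 / 15, 10 / 15))
  expect_equal(cu$n_total, c(15, 15))
})

test_that("invalid survival logs are rejected", {
  bad <- make_log(list(ctl_w1 = c(`0` = 10, `5` = 8)))
  bad$n_alive[2] <- 12  # resurrection and > n_total
  expect_error(build_survival_curves(bad), "exceeds n_total")
  bad2 <- make_log(list(ctl_w1 = c(`0` = 10, `5` = 8, `10` = 9)))
  expect_error(build_survival_curves(bad2), "increase over time")
  bad3 <- make_log(list(ctl_w1 = c(`2` = 10, `5` = 8)))
  expect_error(build_survival_curves(bad3), "day-0")
})

test_that("DT50 is the exact crossing day or the linear interpolant", {
  expect_equal(as.numeric(estimate_dt50(c(0, 10), c(1.0, 0.5))), 10)
  expect_equal(as.numeric(estimate_dt50(c(8, 10, 12), c(1.0, 0.6, 0.4))), 11.0)
  cens <- estimate_dt50(c(0, 5, 10), c(1.0, 0.9, 0.7))
  expect_true(is.na(cens))
  expect_true(attr(cens, "censored"))
  # step mode returns the first observed day at or below one half
  expect_equal(as.numeric(estimate_dt50(c(8, 10, 12), c(1.0, 0.6, 0.4),
                                        method = "step")), 12)
})

test_that("DT50 interpolation is exact on curves linear between observations", {
  # oracle: dense resampling of the line through the observations
  set.seed(10)
  for (rep in 1:20) {
    d0 <- stats::runif(1, 0, 5); d1 <- d0 + stats::runif(1, 2, 10)
    f0 <- stats::runif(1, 0.55, 1); f1 <- stats::runif(1, 0, 0.45)
    dense_d <- seq(d0, d1, length.out = 5000)
    dense_f <- f0 + (dense_d - d0) / (d1 - d0) * (f1 - f0)
    oracle <- dense_d[which.min(abs(dense_f - 0.5))]
    est <- estimate_dt50(c(d0, d1), c(f0, f1))
    expect_equal(as.numeric(est), oracle, tolerance = 1e-3)
  }
})

test_that("DT50 extension implements the literal percentage formula", {
  expect_equal(dt50_extension(23.42, 17.42), 100 * (23.42 - 17.42) / 17.42)
  expect_equal(dt50_extension(17.42, 17.42), 0)
  expect_lt(dt50_extension(10, 17.42), 0)
  expect_error(dt50_extension(10, 0), "> 0")
})

test_that("Dunnett post-test flags an extreme shift and only that condition", {
  set.seed(11)
  d <- data.frame(condition = rep(c("control", "a", "b"), each = 4),
                  dt50 = c(stats::rnorm(4, 10, 0.5), stats::rnorm(4, 10, 0.5),
                           stats::rnorm(4, 15, 0.5)))
  res <- anova_dunnett(d, "control")
  tab <- res$table
  expect_lt(tab$p_adj[tab$condition == "b"], 0.001)
  expect_gt(tab$p_adj[tab$condition == "a"], 0.05)
})

test_that("Dunnett-adjusted p is never smaller than the pairwise t-test p", {
  set.seed(12)
  for (rep in 1:15) {
    k <- sample(2:4, 1)
    d <- data.frame(condition = rep(c("control", paste0("t", seq_len(k))),
                                    each = 4),
                    dt50 = stats::rnorm(4 * (k + 1), 10, 1))
    res <- anova_dunnett(d, "control")
    for (cond in paste0("t", seq_len(k))) {
      praw <- stats::t.test(d$dt50[d$condition == cond],
                            d$dt50[d$condition == "control"],
                            var.equal = TRUE)$p.value
      padj <- res$table$p_adj[res$table$condition == cond]
      expect_gte(padj, praw - 1e-6)
    }
  }
})

test_that("anova_dunnett names the offending single-replicate condition", {
  d <- data.frame(condition = c("control", "control", "lonely"),
                  dt50 = c(10, 11, 12))
  expect_error(anova_dunnett(d, "control"), "lonely")
})

test_that("the condition-level result table carries N, extension and p", {
  cfg <- survival_sim_config(effect_multipliers = c(control = 1, long = 1.5),
                             worms_per_well = 30L, seed = 14)
  res <- dt50_results(simulate_survival(cfg))
  expect_identical(res$condition, c("control", "long"))
  expect_true(is.na(res$extension_pct[1]))
  expect_identical(res$n_worms, c(90L, 90L))
  expect_gt(res$extension_pct[2], 20)
  expect_true(res$significant[2])
  expect_equal(res$extension_pct[2],
               dt50_extension(res$mean_dt50[2], res$mean_dt50[1]))
})
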