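#' Configuration for the liquid-culture survival simulation
#'
#' Emulates the raw data of a 96-well liquid survival assay: per well, a
#' small cohort of age-synchronized worms whose death times follow a Weibull
#' distribution parameterized by its median and a shape (dispersion)
#' parameter. Treatments act as multiplicative scalings of the median
#' lifetime. Alive/total counts are recorded on a thrice-weekly observation
#' grid, day 0 being the treatment start.
#'
#' Defaults follow the assay design: 5-18 worms seeded per well, triplicate
#' wells per condition, observations three times a week (days 2, 4, 7 of
#' each week), a control median survival of 10 days at 25 C, and Weibull
#' shape 4 (death times concentrated around the median, as worm survival
#' curves are sigmoidal rather than exponential).
#'
#' @param effect_multipliers named numeric vector: condition ->
#'   multiplicative scaling of the median lifetime; must include the control
#'   (multiplier 1 by convention). All entries > 0.
#' @param n_wells_per_condition wells per condition (default 3, the
#'   parallel-triplicate design).
#' @param worms_per_well integer range `c(min, max)` (default `c(5, 18)`) or
#'   a single fixed count.
#' @param observation_days strictly increasing assay days; must include 0.
#' @param control_median_days median death time of control worms, in days.
#' @param shape Weibull shape parameter (> 0); large values mean low
#'   dispersion around the median.
#' @param control_label name of the control condition.
#' @param seed RNG seed.
#' @return object of class `"survival_sim_config"`.
#' @export
survival_sim_config <- function(effect_multipliers = c(control = 1),
                                n_wells_per_condition = 3L,
                                worms_per_well = c(5L, 18L),
                                observation_days = default_observation_days(),
                                control_median_days = 10,
                                shape = 4,
                                control_label = "control",
                                seed = 1L) {
  if (is.null(names(effect_multipliers)) || any(names(effect_multipliers) == "")) {
    stop("effect_multipliers must be a named vector (condition -> multiplier)",
         call. = FALSE)
  }
  if (any(effect_multipliers <= 0)) stop("effect multipliers must be > 0", call. = FALSE)
  if (!control_label %in% names(effect_multipliers)) {
    stop(sprintf("control condition '%s' missing from effect_multipliers",
                 control_label), call. = FALSE)
  }
  if (length(observation_days) == 0L) stop("observation_days is empty", call. = FALSE)
  if (any(diff(observation_days) <= 0)) {
    stop("observation_days must be strictly increasing", call. = FALSE)
  }
  if (observation_days[1] != 0) {
    stop("observation_days must start at day 0 (the treatment-start baseline)",
         call. = FALSE)
  }
  if (length(worms_per_well) == 1L) worms_per_well <- rep(worms_per_well, 2L)
  if (worms_per_well[1] < 1L || worms_per_well[1] > worms_per_well[2]) {
    stop("worms_per_well must be a positive count or range", call. = FALSE)
  }
  if (control_median_days <= 0 || shape <= 0) {
    stop("control_median_days and shape must be > 0", call. = FALSE)
  }
  structure(list(effect_multipliers = effect_multipliers,
                 n_wells_per_condition = as.integer(n_wells_per_condition),
                 worms_per_well = as.integer(worms_per_well),
                 observation_days = observation_days,
                 control_median_days = control_median_days,
                 shape = shape,
                 control_label = control_label,
                 seed = as.integer(seed)),
            class = "survival_sim_config")
}

#' Thrice-weekly observation grid
#'
#' Days 2, 4 and 7 of each week (a Tue/Thu/Mon-style cadence) preceded by
#' the day-0 baseline.
#'
#' @param weeks number of weeks covered (default 6).
#' @return numeric vector of assay days starting at 0.
#' @export
default_observation_days <- function(weeks = 6L) {
  c(0, as.vector(outer(c(2, 4, 7), 7 * (seq_len(weeks) - 1L), "+")))
}

weibull_scale_from_median <- function(median, shape) median / log(2)^(1 / shape)

#' Simulate a survival experiment
#'
#' Draws per-worm death times from Weibull(shape, scale) with the scale set
#' so the condition's median equals `control_median_days` times its effect
#' multiplier, then tabulates alive counts at every observation day. Alive
#' counts are non-increasing within a well by construction.
#'
#' @param config a [survival_sim_config()].
#' @return data.frame of class `"survival_dataset"` with columns `well_id`,
#'   `condition`, `day`, `n_alive`, `n_total`; the per-worm death times are
#'   attached as attribute `death_times` (a data.frame `condition`, `well_id`,
#'   `death_day`) for diagnostics.
#' @export
simulate_survival <- function(config) {
  stopifnot(inherits(config, "survival_sim_config"))
  with_local_seed(config$seed, {
    rows <- list()
    deaths <- list()
    for (cond in names(config$effect_multipliers)) {
      med <- config$control_median_days * config$effect_multipliers[[cond]]
      scl <- weibull_scale_from_median(med, config$shape)
      for (w in seq_len(config$n_wells_per_condition)) {
        n <- if (config$worms_per_well[1] == config$worms_per_well[2]) {
          config$worms_per_well[1]
        } else {
          sample(config$worms_per_well[1]:config$worms_per_well[2], 1L)
        }
        dt <- stats::rweibull(n, shape = config$shape, scale = scl)
        well <- sprintf("%s_w%d", cond, w)
        alive <- vapply(config$observation_days,
                        function(d) sum(dt > d), integer(1))
        rows[[length(rows) + 1L]] <- data.frame(
          well_id = well, condition = cond, day = config$observation_days,
          n_alive = alive, n_total = n, stringsAsFactors = FALSE)
        deaths[[length(deaths) + 1L]] <- data.frame(
          condition = cond, well_id = well, death_day = dt,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "death_times") <- do.call(rbind, deaths)
    attr(out, "control_label") <- config$control_label
    class(out) <- c("survival_dataset", "data.frame")
    out
  })
}

#' Configuration for the simulated Nile red plate experiment
#'
#' Emulates per-worm fluorescent-unit tables from a multi-well Nile red
#' feeding assay: each imaged worm contributes one unit count drawn from a
#' log-normal whose mean is the control mean scaled by the condition's
#' effect fraction. Units are pixel areas — strictly positive and
#' right-skewed, hence the log-normal. Defaults follow the assay design:
#' 5 replicate wells per condition, 3-10 worms per well, three independent
#' biological experiments, and a per-worm coefficient of variation of 0.3
#' (substantial worm-to-worm spread in staining and size).
#'
#' @param effect_fractions named numeric vector: condition ->
#'   multiplicative effect on the mean units; must include the control
#'   (fraction 1). All entries > 0.
#' @param n_replicate_wells wells per condition per experiment (default 5).
#' @param worms_per_well integer range `c(min, max)` (default `c(3, 10)`).
#' @param n_experiments independent biological experiments (default 3).
#' @param control_mean_units mean fluorescent units of control worms.
#' @param cv per-worm coefficient of variation (>= 0).
#' @param control_label name of the control condition.
#' @param seed RNG seed.
#' @return object of class `"nilered_sim_config"`.
#' @export
nilered_sim_config <- function(effect_fractions = c(control = 1),
                               n_replicate_wells = 5L,
                               worms_per_well = c(3L, 10L),
                               n_experiments = 3L,
                               control_mean_units = 2000,
                               cv = 0.3,
                               control_label = "control",
                               seed = 1L) {
  if (is.null(names(effect_fractions)) || any(names(effect_fractions) == "")) {
    stop("effect_fractions must be a named vector (condition -> fraction)",
         call. = FALSE)
  }
  if (any(effect_fractions <= 0)) stop("effect fractions must be > 0", call. = FALSE)
  if (!control_label %in% names(effect_fractions)) {
    stop(sprintf("control condition '%s' missing from effect_fractions",
                 control_label), call. = FALSE)
  }
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  if (control_mean_units <= 0) stop("control_mean_units must be > 0", call. = FALSE)
  if (length(worms_per_well) == 1L) worms_per_well <- rep(worms_per_well, 2L)
  if (worms_per_well[1] < 1L || worms_per_well[1] > worms_per_well[2]) {
    stop("worms_per_well must be a positive count or range", call. = FALSE)
  }
  structure(list(effect_fractions = effect_fractions,
                 n_replicate_wells = as.integer(n_replicate_wells),
                 worms_per_well = as.integer(worms_per_well),
                 n_experiments = as.integer(n_experiments),
                 control_mean_units = control_mean_units,
                 cv = cv,
                 control_label = control_label,
                 seed = as.integer(seed)),
            class = "nilered_sim_config")
}

#' Simulate a Nile red plate experiment
#'
#' Per worm, draws fluorescent units from a log-normal with mean
#' `control_mean_units * effect_fraction` and the configured coefficient of
#' variation (meanlog/sdlog derived so the arithmetic mean and CV match).
#'
#' @param config a [nilered_sim_config()].
#' @return data.frame with columns `worm_id`, `well_id`, `condition`,
#'   `experiment`, `fluorescent_units`; attribute `control_label`.
#' @export
simulate_nilered_plate <- function(config) {
  stopifnot(inherits(config, "nilered_sim_config"))
  sdlog <- sqrt(log(1 + config$cv^2))
  with_local_seed(config$seed, {
    rows <- list()
    for (e in seq_len(config$n_experiments)) {
      for (cond in names(config$effect_fractions)) {
        m <- config$control_mean_units * config$effect_fractions[[cond]]
        meanlog <- log(m) - sdlog^2 / 2
        for (w in seq_len(config$n_replicate_wells)) {
          n <- if (config$worms_per_well[1] == config$worms_per_well[2]) {
            config$worms_per_well[1]
          } else {
            sample(config$worms_per_well[1]:config$worms_per_well[2], 1L)
          }
          units <- if (config$cv == 0) rep(m, n) else {
            stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
          }
          well <- sprintf("e%d_%s_w%d", e, cond, w)
          rows[[length(rows) + 1L]] <- data.frame(
            worm_id = sprintf("%s_worm%d", well, seq_len(n)),
            well_id = well, condition = cond, experiment = e,
            fluorescent_units = units, stringsAsFactors = FALSE)
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "control_label") <- config$control_label
    out
  })
}
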