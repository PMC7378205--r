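#' Validate a survival observation log
#'
#' Checks the per-well longitudinal structure: alive counts never exceed
#' totals, never increase over time within a well, and every well has a
#' day-0 baseline.
#'
#' @param data data.frame with columns `well_id`, `condition`, `day`,
#'   `n_alive`, `n_total`.
#' @return the data, invisibly, or an error describing the violation.
#' @export
validate_survival_data <- function(data) {
  need <- c("well_id", "condition", "day", "n_alive", "n_total")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("survival data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(data$n_alive > data$n_total)) {
    stop("n_alive exceeds n_total", call. = FALSE)
  }
  if (any(data$n_alive < 0)) stop("negative alive counts", call. = FALSE)
  for (w in unique(data$well_id)) {
    d <- data[data$well_id == w, ]
    d <- d[order(d$day), ]
    if (!any(d$day == 0)) {
      stop(sprintf("well '%s' lacks a day-0 baseline observation", w),
           call. = FALSE)
    }
    if (any(diff(d$n_alive) > 0)) {
      stop(sprintf("alive counts increase over time in well '%s'", w),
           call. = FALSE)
    }
  }
  invisible(data)
}

#' Build survival curves from an observation log
#'
#' Per well (or per condition, pooling wells weighted by their worm counts:
#' pooled fraction = total alive / total worms per day), the percentage of
#' living nematodes at each observation day.
#'
#' @param data a validated survival log (see [validate_survival_data()]).
#' @param level `"well"` or `"condition"`.
#' @return data.frame of class `"survival_curves"`: `curve_id`, `condition`,
#'   `day`, `fraction_alive`, `n_total`.
#' @export
build_survival_curves <- function(data, level = c("well", "condition")) {
  level <- match.arg(level)
  validate_survival_data(data)
  key <- if (level == "well") data$well_id else data$condition
  parts <- lapply(split(data, key), function(d) {
    agg <- stats::aggregate(cbind(n_alive, n_total) ~ day, data = d, FUN = sum)
    agg <- agg[order(agg$day), ]
    data.frame(curve_id = d[[if (level == "well") "well_id" else "condition"]][1],
               condition = d$condition[1],
               day = agg$day,
               fraction_alive = agg$n_alive / agg$n_total,
               n_total = agg$n_total,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  class(out) <- c("survival_curves", "data.frame")
  out
}

#' Estimate DT50 from one survival curve
#'
#' DT50 is the day at which half of the population is dead. If an observed
#' day sits exactly at fraction 0.5 that day is returned; otherwise the
#' crossing is linearly interpolated between the bracketing observation
#' days. A curve that never reaches 0.5 is censored: the estimate is `NA`
#' with attribute `censored = TRUE`. A step-function mode (first observed
#' day at or below 0.5) is available for sensitivity analysis.
#'
#' @param day observation days (increasing).
#' @param fraction_alive proportions alive in [0, 1] at those days.
#' @param method `"interpolate"` (default) or `"step"`.
#' @return DT50 in days (numeric scalar) with attribute `censored`;
#'   `NA` when censored.
#' @export
estimate_dt50 <- function(day, fraction_alive, method = c("interpolate", "step")) {
  method <- match.arg(method)
  if (length(day) != length(fraction_alive) || length(day) < 1L) {
    stop("day and fraction_alive must be equal-length, non-empty", call. = FALSE)
  }
  o <- order(day)
  day <- day[o]; f <- fraction_alive[o]
  i <- which(f <= 0.5)
  if (length(i) == 0L) {
    return(structure(NA_real_, censored = TRUE))
  }
  i <- i[1]
  if (f[i] == 0.5 || i == 1L || method == "step") {
    return(structure(day[i], censored = FALSE))
  }
  d0 <- day[i - 1L]; f0 <- f[i - 1L]
  d1 <- day[i]; f1 <- f[i]
  structure(d0 + (f0 - 0.5) / (f0 - f1) * (d1 - d0), censored = FALSE)
}

#' Per-well DT50 table for a survival dataset
#'
#' The replicate unit for survival statistics is the well; this computes the
#' well-level curves and one DT50 per well.
#'
#' @param data survival log.
#' @param method passed to [estimate_dt50()].
#' @return data.frame `condition`, `well_id`, `dt50`, `censored`, `n_total`.
#' @export
dt50_by_well <- function(data, method = "interpolate") {
  curves <- build_survival_curves(data, level = "well")
  parts <- lapply(split(curves, curves$curve_id), function(cu) {
    est <- estimate_dt50(cu$day, cu$fraction_alive, method)
    data.frame(condition = cu$condition[1], well_id = cu$curve_id[1],
               dt50 = as.numeric(est),
               censored = isTRUE(attr(est, "censored")),
               n_total = cu$n_total[1], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' DT50 extension relative to the vehicle control
#'
#' 100 * (treated - control) / control, in percent; negative values are
#' reductions.
#'
#' @param mean_treated mean DT50 of the treated condition, days.
#' @param mean_control mean DT50 of the vehicle control, days; must be > 0.
#' @return extension (or reduction, negative) in percent.
#' @export
dt50_extension <- function(mean_treated, mean_control) {
  stop_if_not_scalar_number(mean_control, "mean_control")
  if (mean_control <= 0) stop("control mean DT50 must be > 0", call. = FALSE)
  100 * (mean_treated - mean_control) / mean_control
}

#' One-way ANOVA with Dunnett's many-to-one post-test on replicate DT50s
#'
#' Tests each treatment against the designated control across replicate
#' (well-level) DT50s: a one-way ANOVA followed by Dunnett comparisons using
#' multivariate-t critical values (equal-variance, as implemented in
#' \pkg{multcomp}). Adjusted p-values are evaluated under a locally fixed
#' RNG state so identical inputs give identical output.
#'
#' @param dt50_table data.frame with columns `condition` and `dt50`
#'   (replicate level), e.g. from [dt50_by_well()]. Censored (NA) replicates
#'   are dropped with a message.
#' @param control_label the control condition.
#' @param alpha significance level (default 0.05).
#' @return list with `f_statistic`, `f_p_value`, and `table`: data.frame
#'   `condition`, `estimate` (difference vs control, days), `p_adj`,
#'   `significant`.
#' @export
anova_dunnett <- function(dt50_table, control_label = "control", alpha = 0.05) {
  d <- dt50_table[!is.na(dt50_table$dt50), c("condition", "dt50")]
  if (nrow(d) < nrow(dt50_table)) {
    message(sprintf("dropping %d censored replicate(s)",
                    nrow(dt50_table) - nrow(d)))
  }
  if (!control_label %in% d$condition) {
    stop(sprintf("control condition '%s' absent", control_label), call. = FALSE)
  }
  reps <- table(d$condition)
  single <- names(reps)[reps < 2L]
  if (length(single)) {
    stop("condition(s) with a single replicate: ",
         paste(single, collapse = ", "), call. = FALSE)
  }
  d$condition <- stats::relevel(factor(d$condition), ref = control_label)
  fit <- stats::aov(dt50 ~ condition, data = d)
  an <- summary(fit)[[1]]
  glt <- multcomp::glht(fit, linfct = multcomp::mcp(condition = "Dunnett"))
  smry <- with_local_seed(20030617L, summary(glt))
  cond <- sub(" - .*$", "", names(smry$test$coefficients))
  tab <- data.frame(condition = cond,
                    estimate = unname(smry$test$coefficients),
                    p_adj = unname(as.numeric(smry$test$pvalues)),
                    stringsAsFactors = FALSE)
  tab$significant <- tab$p_adj < alpha
  list(f_statistic = an[["F value"]][1], f_p_value = an[["Pr(>F)"]][1],
       table = tab)
}

#' Condition-level DT50 summary with extensions and Dunnett p-values
#'
#' The survival result table: per condition, mean and SD of well-level
#' DT50s, total worms assayed (N), DT50 extension/reduction in percent
#' relative to the control, and the Dunnett-adjusted p-value.
#'
#' @param data survival log.
#' @param control_label the control condition.
#' @param alpha significance level.
#' @param method DT50 estimation method, see [estimate_dt50()].
#' @return data.frame of class `"dt50_result"`: `condition`, `mean_dt50`,
#'   `sd_dt50`, `n_worms`, `extension_pct`, `p_adj`, `significant`
#'   (control row has `NA` extension and p).
#' @export
dt50_results <- function(data, control_label = "control", alpha = 0.05,
                         method = "interpolate") {
  wells <- dt50_by_well(data, method)
  ok <- !wells$censored
  smry <- do.call(rbind, lapply(split(wells[ok, ], wells$condition[ok]), function(d) {
    data.frame(condition = d$condition[1],
               mean_dt50 = mean(d$dt50),
               sd_dt50 = stats::sd(d$dt50),
               n_worms = sum(d$n_total),
               n_wells = nrow(d),
               stringsAsFactors = FALSE)
  }))
  if (!control_label %in% smry$condition) {
    stop(sprintf("control condition '%s' has no uncensored wells", control_label),
         call. = FALSE)
  }
  ctrl_mean <- smry$mean_dt50[smry$condition == control_label]
  smry$extension_pct <- ifelse(smry$condition == control_label, NA_real_,
                               dt50_extension(smry$mean_dt50, ctrl_mean))
  dun <- anova_dunnett(wells[ok, ], control_label, alpha)
  smry$p_adj <- dun$table$p_adj[match(smry$condition, dun$table$condition)]
  smry$significant <- !is.na(smry$p_adj) & smry$p_adj < alpha
  # control first, then by condition name
  smry <- smry[order(smry$condition != control_label, smry$condition), ]
  rownames(smry) <- NULL
  attr(smry, "anova") <- dun[c("f_statistic", "f_p_value")]
  class(smry) <- c("dt50_result", "data.frame")
  smry
}
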