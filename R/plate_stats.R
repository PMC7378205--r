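#' Aggregate per-worm fluorescent units to condition level
#'
#' Per independent experiment and condition, the mean fluorescent units over
#' all imaged worms across that condition's replicate wells. Experiments are
#' never pooled at this stage — each keeps its own mean. Worm tables that
#' carry only `well_id` are joined to a plate map (`well_id`, `condition`,
#' `experiment`); rows that map to no plate-map entry are an error.
#'
#' @param per_worm data.frame with `fluorescent_units` plus either
#'   `condition`/`experiment` columns or a `well_id` column.
#' @param plate_map optional data.frame `well_id`, `condition`,
#'   `experiment` (and free extra columns).
#' @return data.frame `experiment`, `condition`, `mean_units`, `n_worms`.
#' @export
aggregate_condition <- function(per_worm, plate_map = NULL) {
  if (!"fluorescent_units" %in% names(per_worm)) {
    stop("per_worm table lacks a fluorescent_units column", call. = FALSE)
  }
  if (!is.null(plate_map)) {
    need <- c("well_id", "condition", "experiment")
    if (!all(need %in% names(plate_map))) {
      stop("plate_map needs columns well_id, condition, experiment", call. = FALSE)
    }
    if (!"well_id" %in% names(per_worm)) {
      stop("per_worm table lacks well_id needed to join the plate map", call. = FALSE)
    }
    idx <- match(per_worm$well_id, plate_map$well_id)
    if (anyNA(idx)) {
      orphans <- unique(per_worm$well_id[is.na(idx)])
      stop("worms in wells absent from the plate map: ",
           paste(orphans, collapse = ", "), call. = FALSE)
    }
    per_worm$condition <- plate_map$condition[idx]
    per_worm$experiment <- plate_map$experiment[idx]
  }
  if (!all(c("condition", "experiment") %in% names(per_worm))) {
    stop("per_worm table needs condition and experiment columns ",
         "(directly or via a plate map)", call. = FALSE)
  }
  if (anyNA(per_worm$condition) || anyNA(per_worm$experiment)) {
    stop("unmapped worms: missing condition or experiment labels", call. = FALSE)
  }
  key <- interaction(per_worm$experiment, per_worm$condition, drop = TRUE)
  out <- do.call(rbind, lapply(split(per_worm, key), function(d) {
    data.frame(experiment = d$experiment[1], condition = d$condition[1],
               mean_units = mean(d$fluorescent_units), n_worms = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$experiment, out$condition), ]
}

#' Normalize condition means to the vehicle control
#'
#' Within each experiment the control mean is set to 100% and every
#' condition is expressed as percent of it; the cross-experiment mean and SD
#' of those percentages are then reported per condition.
#'
#' @param means data.frame from [aggregate_condition()].
#' @param control_label the vehicle-control condition.
#' @return list with `by_experiment` (`experiment`, `condition`,
#'   `normalized_pct`) and `summary` (`condition`, `normalized_pct`,
#'   `sd_pct`, `n_experiments`, `n_worms`).
#' @export
normalize_to_control <- function(means, control_label = "control") {
  parts <- lapply(split(means, means$experiment), function(d) {
    ctrl <- d$mean_units[d$condition == control_label]
    if (length(ctrl) != 1L) {
      stop(sprintf("experiment %s lacks a unique control ('%s')",
                   d$experiment[1], control_label), call. = FALSE)
    }
    if (ctrl == 0) {
      stop(sprintf("experiment %s has zero control mean", d$experiment[1]),
           call. = FALSE)
    }
    data.frame(experiment = d$experiment, condition = d$condition,
               normalized_pct = d$mean_units / ctrl * 100,
               n_worms = d$n_worms, stringsAsFactors = FALSE)
  })
  by_exp <- do.call(rbind, parts)
  rownames(by_exp) <- NULL
  smry <- do.call(rbind, lapply(split(by_exp, by_exp$condition), function(d) {
    data.frame(condition = d$condition[1],
               normalized_pct = mean(d$normalized_pct),
               sd_pct = stats::sd(d$normalized_pct),
               n_experiments = nrow(d),
               n_worms = sum(d$n_worms),
               stringsAsFactors = FALSE)
  }))
  rownames(smry) <- NULL
  list(by_experiment = by_exp, summary = smry)
}

#' One-way ANOVA with Bonferroni-corrected comparisons against the control
#'
#' Statistics run on experiment-level normalized values (n = number of
#' independent experiments, never pooled worms — pooling worms across
#' experiments would pseudo-replicate). Because the normalization pins the
#' control at exactly 100% in every experiment, the control carries no
#' variance and a naive pooled contrast against it is anti-conservative;
#' the calibrated form of "each condition versus control" is a contrast
#' against the constant 100 whose error is the within-condition variance
#' pooled over the non-control conditions (the one-way ANOVA residual on
#' those conditions). Raw two-sided p-values from that t statistic are
#' Bonferroni-adjusted over the family of all non-control conditions:
#' p_adj = min(1, m * p_raw). Significance tiers at 0.05 / 0.01 / 0.001 are
#' reported as stars.
#'
#' @param by_experiment data.frame `experiment`, `condition`,
#'   `normalized_pct` (from [normalize_to_control()]).
#' @param control_label the control condition.
#' @param alpha significance level (default 0.05).
#' @return list with `f_statistic`, `f_p_value` (one-way ANOVA among the
#'   non-control conditions), `m` (family size), `df` (pooled residual
#'   degrees of freedom) and `table`: `condition`, `estimate`
#'   (percentage-point difference vs control), `p_raw`, `p_adj`,
#'   `significant`, `stars`.
#' @export
anova_bonferroni <- function(by_experiment, control_label = "control",
                             alpha = 0.05) {
  d <- by_experiment[, c("experiment", "condition", "normalized_pct")]
  n_exp <- length(unique(d$experiment))
  if (n_exp < 2L) {
    stop("at least two independent experiments are required", call. = FALSE)
  }
  if (!control_label %in% d$condition) {
    stop(sprintf("control condition '%s' absent", control_label), call. = FALSE)
  }
  t <- d[d$condition != control_label, ]
  if (nrow(t) == 0L) {
    stop("no non-control conditions to test", call. = FALSE)
  }
  t$condition <- factor(t$condition)
  m <- nlevels(t$condition)
  if (m > 1) {
    fit <- stats::aov(normalized_pct ~ condition, data = t)
    an <- summary(fit)[[1]]
    mse <- an[["Mean Sq"]][length(an[["Mean Sq"]])]
    df <- an[["Df"]][length(an[["Df"]])]
    f_stat <- an[["F value"]][1]; f_p <- an[["Pr(>F)"]][1]
  } else {
    mse <- stats::var(t$normalized_pct)
    df <- nrow(t) - 1L
    f_stat <- NA_real_; f_p <- NA_real_
  }
  if (df < 1L || !is.finite(mse) || mse <= 0) {
    stop("no residual degrees of freedom to estimate the error variance",
         call. = FALSE)
  }
  per <- do.call(rbind, lapply(split(t, t$condition), function(x) {
    n <- nrow(x)
    est <- mean(x$normalized_pct) - 100
    tt <- est / sqrt(mse / n)
    data.frame(condition = x$condition[1], estimate = est,
               p_raw = 2 * stats::pt(-abs(tt), df),
               stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  per$p_adj <- pmin(1, m * per$p_raw)
  per$significant <- per$p_adj < alpha
  per$stars <- as.character(cut(per$p_adj,
                                breaks = c(-Inf, 0.001, 0.01, 0.05, Inf),
                                labels = c("***", "**", "*", "")))
  list(f_statistic = f_stat, f_p_value = f_p, m = m, df = df, table = per)
}

#' Full Nile red plate analysis
#'
#' Aggregation, normalization to the vehicle control (= 100%) and
#' Bonferroni-corrected testing in one call.
#'
#' @param per_worm per-worm fluorescent-unit table.
#' @param plate_map optional plate map, see [aggregate_condition()].
#' @param control_label the vehicle-control condition.
#' @param alpha significance level.
#' @return data.frame of class `"plate_result"`: `condition`,
#'   `normalized_pct`, `sd_pct`, `n_experiments`, `n_worms`, `p_adj`,
#'   `significant`, `stars` (control row: 100%, `NA` p).
#' @export
plate_results <- function(per_worm, plate_map = NULL,
                          control_label = "control", alpha = 0.05) {
  means <- aggregate_condition(per_worm, plate_map)
  nrm <- normalize_to_control(means, control_label)
  tst <- anova_bonferroni(nrm$by_experiment, control_label, alpha)
  out <- nrm$summary
  i <- match(out$condition, tst$table$condition)
  out$p_adj <- tst$table$p_adj[i]
  out$significant <- !is.na(out$p_adj) & out$p_adj < alpha
  out$stars <- ifelse(is.na(i), "", tst$table$stars[i])
  out <- out[order(out$condition != control_label, out$condition), ]
  rownames(out) <- NULL
  attr(out, "anova") <- tst[c("f_statistic", "f_p_value", "m")]
  class(out) <- c("plate_result", "data.frame")
  out
}
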