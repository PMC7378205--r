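#' Screening configuration
#'
#' Parameters of the combined survival + Nile red screen: the two test
#' concentrations, the significance level used for hit calling (applied to
#' post-test-adjusted p-values), the vehicle (DMSO) concentration carried as
#' metadata, and the simulation settings the orchestrator uses when it
#' generates data rather than reading it.
#'
#' A condition is "not evaluable" in the Nile red assay when fewer than
#' `evaluable_min_frac` of its wells contain at least one living worm on the
#' imaging day — the numeric form of "most worms were already dead".
#'
#' @param test_concentrations extract concentrations in ug/mL
#'   (default `c(25, 100)`).
#' @param alpha significance level in (0, 1) (default 0.05).
#' @param dmso_pct vehicle DMSO concentration in percent (default 1.00).
#' @param control_label vehicle-control condition name.
#' @param control_median_days simulated control median survival, days.
#' @param shape Weibull shape for simulated death times.
#' @param n_wells survival wells per condition (default 9: three parallel
#'   experiments of triplicate wells, the replicate structure behind the
#'   reported mean DT50s; the well is the replicate unit).
#' @param worms_per_well survival worms-per-well range (default `c(5, 18)`).
#' @param imaging_day Nile red imaging day (default 5, the treatment
#'   duration of the feeding assay).
#' @param evaluable_min_frac minimum fraction of Nile red wells with a
#'   living worm at imaging (default 0.5).
#' @param seed RNG seed governing every simulated component.
#' @return object of class `"screen_config"`.
#' @export
screen_config <- function(test_concentrations = c(25, 100),
                          alpha = 0.05,
                          dmso_pct = 1.00,
                          control_label = "control",
                          control_median_days = 10,
                          shape = 4,
                          n_wells = 9L,
                          worms_per_well = c(5L, 18L),
                          imaging_day = 5,
                          evaluable_min_frac = 0.5,
                          seed = 1L) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  if (any(test_concentrations <= 0)) {
    stop("test concentrations must be > 0", call. = FALSE)
  }
  structure(list(test_concentrations = test_concentrations, alpha = alpha,
                 dmso_pct = dmso_pct, control_label = control_label,
                 control_median_days = control_median_days, shape = shape,
                 n_wells = as.integer(n_wells),
                 worms_per_well = as.integer(worms_per_well),
                 imaging_day = imaging_day,
                 evaluable_min_frac = evaluable_min_frac,
                 seed = as.integer(seed)),
            class = "screen_config")
}

#' Map effect flags to a screening category
#'
#' The verdict table of the screen, total over all flag combinations:
#' a significant DT50 reduction is toxicity regardless of the fat readout; a
#' condition whose fluorescence could not be read (worms dead at imaging) is
#' not evaluable; significant fat reduction plus significant lifespan
#' extension is the top category, dual-active; a single significant effect
#' gives fat_reducer or lifespan_extender; everything else (including a fat
#' increase, which is not a hit in this screen) is inactive.
#'
#' @param fat_effect one of `"reduced"`, `"increased"`, `"none"`.
#' @param lifespan_effect one of `"extended"`, `"reduced"`, `"none"`.
#' @param evaluable was the Nile red readout evaluable?
#' @return category string, one of `"dual_active"`, `"fat_reducer"`,
#'   `"lifespan_extender"`, `"toxic"`, `"inactive"`, `"not_evaluable"`.
#' @export
categorize_effects <- function(fat_effect, lifespan_effect, evaluable = TRUE) {
  fat_effect <- match.arg(fat_effect, c("reduced", "increased", "none"))
  lifespan_effect <- match.arg(lifespan_effect, c("extended", "reduced", "none"))
  if (lifespan_effect == "reduced") return("toxic")
  if (!evaluable) return("not_evaluable")
  if (fat_effect == "reduced" && lifespan_effect == "extended") return("dual_active")
  if (fat_effect == "reduced") return("fat_reducer")
  if (lifespan_effect == "extended") return("lifespan_extender")
  "inactive"
}

#' Combine both assay result tables into hit calls
#'
#' Joins the survival and Nile red result tables on extract and
#' concentration, derives the per-assay effect flags from the adjusted
#' p-values and effect directions at level `alpha`, and assigns the
#' screening category via [categorize_effects()].
#'
#' @param dt50_tab data.frame with `extract_id`, `concentration`,
#'   `extension_pct`, `p_adj`.
#' @param plate_tab data.frame with `extract_id`, `concentration`,
#'   `normalized_pct`, `p_adj`, and optionally `evaluable` (default TRUE).
#' @param config a [screen_config()] (supplies `alpha`).
#' @return data.frame of class `"hit_calls"`: `extract_id`, `concentration`,
#'   `fat_effect`, `lifespan_effect`, `evaluable`, `category`.
#' @export
call_hits <- function(dt50_tab, plate_tab, config = screen_config()) {
  key <- function(d) paste(d$extract_id, d$concentration, sep = "@")
  k1 <- key(dt50_tab); k2 <- key(plate_tab)
  orphans <- c(setdiff(k1, k2), setdiff(k2, k1))
  if (length(orphans)) {
    stop("extract/concentration keys present in only one assay: ",
         paste(unique(orphans), collapse = ", "), call. = FALSE)
  }
  i <- match(k1, k2)
  evaluable <- if ("evaluable" %in% names(plate_tab)) {
    plate_tab$evaluable[i]
  } else rep(TRUE, nrow(plate_tab))[i]
  alpha <- config$alpha
  out <- do.call(rbind, lapply(seq_len(nrow(dt50_tab)), function(r) {
    sig_surv <- !is.na(dt50_tab$p_adj[r]) && dt50_tab$p_adj[r] < alpha
    lifespan <- if (sig_surv && dt50_tab$extension_pct[r] > 0) "extended"
                else if (sig_surv && dt50_tab$extension_pct[r] < 0) "reduced"
                else "none"
    sig_fat <- isTRUE(evaluable[r]) && !is.na(plate_tab$p_adj[i[r]]) &&
      plate_tab$p_adj[i[r]] < alpha
    fat <- if (sig_fat && plate_tab$normalized_pct[i[r]] < 100) "reduced"
           else if (sig_fat && plate_tab$normalized_pct[i[r]] > 100) "increased"
           else "none"
    data.frame(extract_id = dt50_tab$extract_id[r],
               concentration = dt50_tab$concentration[r],
               fat_effect = fat, lifespan_effect = lifespan,
               evaluable = isTRUE(evaluable[r]),
               category = categorize_effects(fat, lifespan, isTRUE(evaluable[r])),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("hit_calls", "data.frame")
  out
}

#' Extract design table for a simulated screen
#'
#' Convenience constructor: `n_extracts` extracts at one concentration, all
#' null (fluorescence fraction 1, lifespan multiplier 1) except a planted
#' dual-active one.
#'
#' @param n_extracts number of extracts (default 8).
#' @param dual_index which extract carries the planted dual activity.
#' @param fluor_fraction planted fluorescence effect (default 0.5).
#' @param lifespan_multiplier planted lifespan effect (default 1.4).
#' @param concentration tested concentration in ug/mL (default 100).
#' @return data.frame `extract_id`, `concentration`, `fluor_fraction`,
#'   `lifespan_multiplier`.
#' @export
planted_screen_extracts <- function(n_extracts = 8L, dual_index = 1L,
                                    fluor_fraction = 0.5,
                                    lifespan_multiplier = 1.4,
                                    concentration = 100) {
  if (n_extracts == 0L) {
    return(data.frame(extract_id = character(0), concentration = numeric(0),
                      fluor_fraction = numeric(0),
                      lifespan_multiplier = numeric(0),
                      stringsAsFactors = FALSE))
  }
  d <- data.frame(extract_id = sprintf("ext%02d", seq_len(n_extracts)),
                  concentration = concentration,
                  fluor_fraction = 1, lifespan_multiplier = 1,
                  stringsAsFactors = FALSE)
  d$fluor_fraction[dual_index] <- fluor_fraction
  d$lifespan_multiplier[dual_index] <- lifespan_multiplier
  d
}

#' Run a full simulated screen
#'
#' End-to-end orchestration over a table of extract conditions: simulates
#' the survival assay and the Nile red plate experiment with the configured
#' effects, runs DT50 estimation with ANOVA/Dunnett, plate normalization
#' with ANOVA/Bonferroni, determines Nile red evaluability from simulated
#' worm survival in the imaging wells, and calls hits. Rerunning with an
#' identical config and extract table reproduces the result tables
#' byte-identically.
#'
#' @param extracts data.frame `extract_id`, `concentration`,
#'   `fluor_fraction`, `lifespan_multiplier` (one row per extract x
#'   concentration), e.g. [planted_screen_extracts()]. An empty table gives
#'   an empty report.
#' @param config a [screen_config()].
#' @param out_dir optional directory; when given, the three result tables
#'   and a run manifest (every parameter and seed) are written as CSV/text.
#' @return list with `survival` (condition-level DT50 table), `nilered`
#'   (condition-level plate table), `hits` ([call_hits()] output) and
#'   `config`.
#' @export
run_screen <- function(extracts, config = screen_config(), out_dir = NULL) {
  stopifnot(inherits(config, "screen_config"))
  need <- c("extract_id", "concentration", "fluor_fraction", "lifespan_multiplier")
  if (!all(need %in% names(extracts))) {
    stop("extracts table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  ctl <- config$control_label
  if (nrow(extracts) == 0L) {
    empty <- data.frame(extract_id = character(0), concentration = numeric(0),
                        fat_effect = character(0), lifespan_effect = character(0),
                        evaluable = logical(0), category = character(0),
                        stringsAsFactors = FALSE)
    res <- list(survival = NULL, nilered = NULL, hits = empty, config = config)
    if (!is.null(out_dir)) write_screen_report(res, out_dir)
    return(res)
  }
  cond <- paste(extracts$extract_id, extracts$concentration, sep = "@")

  mult <- stats::setNames(c(1, extracts$lifespan_multiplier), c(ctl, cond))
  surv_cfg <- survival_sim_config(effect_multipliers = mult,
                                  n_wells_per_condition = config$n_wells,
                                  worms_per_well = config$worms_per_well,
                                  control_median_days = config$control_median_days,
                                  shape = config$shape,
                                  control_label = ctl,
                                  seed = config$seed)
  surv_data <- simulate_survival(surv_cfg)
  surv_tab <- dt50_results(surv_data, ctl, config$alpha)

  frac <- stats::setNames(c(1, extracts$fluor_fraction), c(ctl, cond))
  nr_cfg <- nilered_sim_config(effect_fractions = frac,
                               control_label = ctl,
                               seed = config$seed + 1L)
  per_worm <- simulate_nilered_plate(nr_cfg)
  plate_tab <- plate_results(per_worm, control_label = ctl,
                             alpha = config$alpha)

  # evaluability: simulate the imaging wells' survival to the imaging day
  evaluable <- with_local_seed(config$seed + 2L, {
    vapply(seq_len(nrow(extracts)), function(r) {
      med <- config$control_median_days * extracts$lifespan_multiplier[r]
      scl <- weibull_scale_from_median(med, config$shape)
      ok <- vapply(seq_len(nr_cfg$n_replicate_wells), function(w) {
        n <- sample(nr_cfg$worms_per_well[1]:nr_cfg$worms_per_well[2], 1L)
        any(stats::rweibull(n, config$shape, scl) > config$imaging_day)
      }, logical(1))
      mean(ok) >= config$evaluable_min_frac
    }, logical(1))
  })

  split_key <- function(tab) {
    is_ctl <- tab$condition == ctl
    tab$extract_id <- NA_character_
    tab$extract_id[!is_ctl] <- sub("@[^@]*$", "", tab$condition[!is_ctl])
    tab$concentration <- NA_real_
    tab$concentration[!is_ctl] <- as.numeric(sub("^.*@", "", tab$condition[!is_ctl]))
    tab
  }
  surv_tab <- split_key(surv_tab)
  plate_tab <- split_key(plate_tab)
  plate_tab$evaluable <- TRUE
  i <- match(cond, plate_tab$condition)
  plate_tab$evaluable[i] <- evaluable

  hits <- call_hits(surv_tab[surv_tab$condition != ctl, ],
                    plate_tab[plate_tab$condition != ctl, ],
                    config)
  res <- list(survival = surv_tab, nilered = plate_tab, hits = hits,
              config = config)
  if (!is.null(out_dir)) write_screen_report(res, out_dir)
  res
}

#' Write a screen report bundle
#'
#' Result tables as CSV plus a plain-text run manifest recording every
#' parameter and seed for reproducibility.
#'
#' @param res result of [run_screen()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_screen_report <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(res$survival)) {
    utils::write.csv(res$survival, file.path(out_dir, "survival_dt50.csv"),
                     row.names = FALSE)
  }
  if (!is.null(res$nilered)) {
    utils::write.csv(res$nilered, file.path(out_dir, "nilered_normalized.csv"),
                     row.names = FALSE)
  }
  utils::write.csv(res$hits, file.path(out_dir, "hit_calls.csv"),
                   row.names = FALSE)
  cfg <- res$config
  man <- vapply(names(cfg), function(k) {
    sprintf("%s: %s", k, paste(format(cfg[[k]], digits = 15), collapse = ", "))
  }, character(1))
  writeLines(man, file.path(out_dir, "run_manifest.txt"))
  invisible(out_dir)
}
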