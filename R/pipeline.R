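#' Simulate a study and write it to disk
#'
#' Thin orchestration over [simulate_study()] + [write_study()]:
#' idempotent for a fixed seed (byte-identical truth tables across
#' reruns).
#'
#' @param config A [study_config()].
#' @param out_dir Output directory.
#' @return The study manifest, invisibly.
#' @export
run_simulate <- function(config = study_config(), out_dir) {
  study <- simulate_study(config)
  write_study(study, out_dir)
}

#' Analyse a study end-to-end
#'
#' Runs the full analysis on a simulated (or loaded) study:
#' \enumerate{
#'   \item segmentation + morphometry of every treated darkfield frame;
#'   \item per-day size-mixture fits and Gompertz growth fit of the mean
#'     volume of the large (second-peak) population;
#'   \item kinetics: control-based background subtraction, compartment
#'     means, per-day series, two-phase slope fit (days >= delivery),
#'     plateau and crossover detection;
#'   \item clonogenic survival factors and SER per accumulation schedule.
#' }
#' Stages whose inputs are missing are reported as skipped rather than
#' failing the whole run.
#'
#' @param study A `gnp_study` (from [simulate_study()] or [read_study()]).
#' @param config Analysis configuration; defaults to the study's own.
#' @return A list of class `gnp_report` with elements `morphometry`,
#'   `growth`, `mixtures`, `kinetics`, `ser` and `stages`.
#' @export
analyze_study <- function(study, config = study$config) {
  stopifnot(inherits(study, "gnp_study"))
  cfg <- config
  stages <- list()
  report <- list()

  ## --- segmentation + morphometry (needs rendered frames) ---------------
  if (!is.null(study$frames)) {
    seg_ch <- cfg$segmentation$seg_channel
    meas_rows <- list(); morph_rows <- list()
    masks_by <- list()
    for (di in seq_along(study$days)) {
      day <- study$days[di]
      for (wi in seq_along(study$wells)) {
        if (!study$treated[wi]) next
        fr <- study$frames[[di]][[wi]]
        seg_img <- fr[[seg_ch]] %||% fr$darkfield
        masks <- segment_nodules(seg_img, cfg)
        masks_by[[paste(di, wi)]] <- masks
        rec <- measure_frame(fr$fluorescence, masks, cfg$pixel_size_um)
        if (nrow(rec)) {
          morph_rows[[length(morph_rows) + 1L]] <-
            cbind(data.frame(day = day, well = study$wells[wi]), rec)
        }
      }
    }
    morph <- if (length(morph_rows)) do.call(rbind, morph_rows) else NULL
    report$morphometry <- morph
    stages$morphometry <- "ok"

    ## --- growth + mixtures ------------------------------------------------
    if (!is.null(morph)) {
      mix <- lapply(split(morph, morph$day), function(d) {
        if (nrow(d) < 20L) return(NULL)
        f <- tryCatch(fit_size_mixture(log(d$area_um2), 2L),
                      error = function(e) NULL)
        if (is.null(f)) return(NULL)
        list(day = d$day[1], preferred = preferred_components(f),
             modes_um2 = exp(f$means), weights = f$weights,
             bic_1 = f$bic_1, bic_2 = f$bic_2)
      })
      mix <- mix[!vapply(mix, is.null, logical(1))]
      report$mixtures <- mix
      growth_pts <- lapply(split(morph, morph$day), function(d) {
        f <- tryCatch(fit_size_mixture(log(d$area_um2), 2L),
                      error = function(e) NULL)
        vols <- if (!is.null(f) && preferred_components(f) == 2L) {
          d$volume_um3[f$classification == 2L]
        } else d$volume_um3
        data.frame(day = d$day[1], mean_volume_um3 = mean(vols))
      })
      gp <- do.call(rbind, growth_pts)
      report$growth_points <- gp
      if (nrow(gp) >= 4L) {
        report$growth <- fit_gompertz(gp$day, gp$mean_volume_um3)
        stages$growth <- "ok"
      } else {
        stages$growth <- "skipped: fewer than 4 days with measurements"
      }
    } else {
      stages$growth <- "skipped: no morphometry records"
    }

    ## --- kinetics ---------------------------------------------------------
    ctrl_idx <- which(!study$treated)
    if (length(ctrl_idx)) {
      ctrl_levels <- vapply(seq_along(study$days), function(di) {
        mean(vapply(ctrl_idx, function(wi) {
          mean(study$frames[[di]][[wi]]$fluorescence)
        }, numeric(1)))
      }, numeric(1))
      meas <- list()
      for (di in seq_along(study$days)) {
        for (wi in which(study$treated)) {
          fr <- study$frames[[di]][[wi]]
          lvl <- if (isTRUE(cfg$kinetics$bg_subtract)) {
            control_level_for_day(study$days, ctrl_levels, study$days[di])
          } else 0
          corr <- background_subtract(fr$fluorescence, lvl)
          cm <- compartment_means(corr, masks_by[[paste(di, wi)]])
          meas[[length(meas) + 1L]] <- data.frame(
            day = study$days[di], well = study$wells[wi],
            fg_mean = cm$fg_mean, bg_mean = cm$bg_mean)
        }
      }
      series <- build_series(do.call(rbind, meas))
      post <- series[series$day >= cfg$transfer$t_delivery, ]
      class(post) <- class(series)
      kin <- list(series = series)
      if (nrow(post) >= 3L) {
        kin$peak <- detect_peak_day(post, cfg$kinetics$rel_tol)
        kin$crossover <- crossover_day(post)
        kin$two_phase <- tryCatch(
          fit_two_phase(post, cfg$kinetics$candidate_breaks,
                        continuity = cfg$kinetics$continuity),
          error = function(e) NULL)
      }
      report$kinetics <- kin
      stages$kinetics <- "ok"
    } else {
      stages$kinetics <- "skipped: no control wells"
    }
  } else {
    stages$morphometry <- stages$growth <- stages$kinetics <-
      "skipped: no rendered frames"
  }

  ## --- radiosensitization ------------------------------------------------
  if (!is.null(study$colonies) && nrow(study$colonies)) {
    report$ser <- analyze_colonies(study$colonies,
                                   cfg$arms$plating_efficiency)
    stages$ser <- "ok"
  } else {
    stages$ser <- "skipped: no input"
  }

  report$stages <- stages
  class(report) <- "gnp_report"
  report
}

#' SER analysis of a colony-count table
#'
#' Arms named `rt_only_<schedule>` / `rt_gnp_<schedule>` are paired into
#' one SER per schedule and compared across schedules.
#'
#' @param colonies Data frame: `arm`, `replicate`, `colonies`, `plated`.
#' @param plating_efficiency Passed to [survival_factor()].
#' @return List with `survival` (per-arm sf/se), `ser` (list of
#'   `ser_result`) and `comparison` (a `schedule_report`, when >= 2
#'   schedules).
#' @export
analyze_colonies <- function(colonies, plating_efficiency = 1) {
  sf_by_arm <- lapply(split(colonies, colonies$arm), function(d) {
    survival_factor(d$colonies, d$plated[1], plating_efficiency)
  })
  arms <- names(sf_by_arm)
  schedules <- unique(sub("^rt_(only|gnp)_", "", arms[grepl("^rt_", arms)]))
  sers <- list()
  for (s in schedules) {
    rt <- sf_by_arm[[paste0("rt_only_", s)]]
    gnp <- sf_by_arm[[paste0("rt_gnp_", s)]]
    if (is.null(rt) || is.null(gnp)) next
    sers[[s]] <- compute_ser(rt, gnp, schedule = s)
  }
  list(
    survival = data.frame(
      arm = arms,
      sf = vapply(sf_by_arm, `[[`, numeric(1), "sf"),
      se = vapply(sf_by_arm, `[[`, numeric(1), "se"),
      n = vapply(sf_by_arm, `[[`, numeric(1), "n"),
      row.names = NULL),
    ser = sers,
    comparison = if (length(sers) >= 2L) schedule_comparison(sers) else NULL
  )
}

#' Analyse a study directory and write results
#'
#' @param study_dir Directory written by [run_simulate()].
#' @param out_dir Results directory.
#' @param config Optional analysis configuration override.
#' @return The report, invisibly.
#' @export
run_analyze <- function(study_dir, out_dir, config = NULL) {
  study <- read_study(study_dir)
  report <- analyze_study(study, config %||% study$config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(report$morphometry)) {
    .write_csv(report$morphometry, file.path(out_dir, "nodule_records.csv"))
  }
  if (!is.null(report$kinetics$series)) {
    .write_csv(report$kinetics$series,
               file.path(out_dir, "intensity_series.csv"))
  }
  .write_json(report_summary(report), file.path(out_dir, "report.json"))
  invisible(report)
}

#' Plain-list summary of a report (JSON-stable)
#'
#' @param report A `gnp_report`.
#' @return Nested list of scalars/vectors suitable for JSON output.
#' @export
report_summary <- function(report) {
  g <- report$growth
  k <- report$kinetics
  list(
    stages = report$stages,
    growth = if (!is.null(g)) list(
      N0 = g$N0, A = g$A, alpha = g$alpha, tau_hours = g$tau_hours,
      rss = g$rss, converged = g$converged),
    mixtures = lapply(report$mixtures, function(m) {
      list(day = m$day, preferred = m$preferred,
           modes_um2 = m$modes_um2, weights = m$weights)
    }),
    kinetics = if (!is.null(k)) list(
      peak_day = k$peak$peak_day %||% NA,
      peak_censored = k$peak$censored %||% NA,
      crossover_day = k$crossover$day %||% NA,
      slope1 = k$two_phase$slope1 %||% NA,
      slope2 = k$two_phase$slope2 %||% NA,
      break_day = k$two_phase$break_day %||% NA),
    ser = if (!is.null(report$ser)) list(
      survival = report$ser$survival,
      ser = lapply(report$ser$ser, function(s) {
        list(schedule = s$schedule, ser = s$ser, se = s$se)
      }),
      pairwise = report$ser$comparison$pairwise)
  )
}
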