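#' Study configuration
#'
#' Builds the configuration shared by the synthetic-study generator and the
#' analysis pipeline. All physical quantities are in micrometres, square /
#' cubic micrometres, days and hours; pixels appear only inside the
#' segmentation internals. Unknown keys are rejected, so typos fail loudly.
#'
#' The defaults encode the study conditions the generator emulates: 3D
#' cultures seeded as ~19.3 um single cells, GNP delivery on day 7 with a
#' single-rate ECM-to-nodule transfer reaching 95% six days later (plateau
#' at day 13), day-7 projection-area modes near 1,300 and 19,300 um^2, and
#' clonogenic survival probabilities matching the four printed treatment
#' arms.
#'
#' @param ... Named overrides. Nested lists (e.g.
#'   `transfer = list(E0 = 50)`) are merged key-wise into the defaults.
#' @return A named list of class `study_config`.
#' @examples
#' cfg <- study_config(frame_dim = c(256, 256), n_cells = 12)
#' cfg$transfer$k
#' @export
study_config <- function(...) {
  defaults <- list(
    seed = 1L,
    pixel_size_um = 1.29,
    frame_dim = c(1024L, 1024L),
    n_wells = 3L,
    n_control_wells = 1L,
    imaging_days = 0:16,
    # nodule population
    n_cells = 80L,
    cell_diameter_um = 19.3,
    size_targets_um2 = c(small = 1300, large = 19300),
    area_sdlog = c(small = 0.35, large = 0.45),
    calibration_day = 7,
    aspect_ratio_range = c(1, 1.6),
    growth = list(A = 0.8, alpha = 0.35),
    aggregation = list(enabled = TRUE, p_max = 0.55, tau = 2,
                       count_decay = 3),
    # ECM -> nodule transfer (intensities in a.u.)
    transfer = list(E0 = 100, k = log(20) / 6, eta = 1, t_delivery = 7,
                    E_floor = 20, autofluor = 5),
    well_cv = 0.01,
    # camera / rendering
    noise = list(gain = 0.5, read_sd = 2, offset = 5),
    darkfield = list(fg_level = 200, bg_level = 10),
    # monolayer scenario
    monolayer = list(E0 = 100, k = log(50), t_delivery = 0, days = 1:8,
                     n_cells = 60L),
    # terminal lysate assay
    lysate = list(harvest_days = 7:16, replicates = 3L, noise_cv = 0.15,
                  scale = 1),
    # clonogenic arms (printed survival probabilities)
    arms = list(survival = c(rt_only_day4 = 0.680, rt_gnp_day4 = 0.246,
                             rt_only_day1 = 0.423, rt_gnp_day1 = 0.309),
                n_plated = 1000L, replicates = 3L, plating_efficiency = 1),
    # analysis parameters
    segmentation = list(method = "otsu", min_area_um2 = 100,
                        opening_radius_px = 2, seg_channel = "darkfield",
                        fixed_threshold = NA_real_),
    kinetics = list(rel_tol = 0.05, candidate_breaks = NULL,
                    continuity = FALSE, bg_subtract = TRUE),
    render = TRUE,
    # metadata recorded, not modelled (sub-day kinetics out of scope)
    metadata = list(exposure_min = 45, dose_gy = 2,
                    gnp_mg_au_ml = c(imaging = 0.0291, therapy = 0.278),
                    seeding_cells_per_ml = 7500)
  )
  cfg <- .merge_config(defaults, list(...), path = "")
  .validate_config(cfg)
  class(cfg) <- c("study_config", "list")
  cfg
}

.merge_config <- function(base, override, path) {
  if (length(override) == 0L) return(base)
  nms <- names(override)
  if (is.null(nms) || any(nms == "") || anyDuplicated(nms)) {
    stop("config overrides must be uniquely named", call. = FALSE)
  }
  bad <- setdiff(nms, names(base))
  if (length(bad)) {
    stop(sprintf("unknown config key%s: %s", if (length(bad) > 1) "s" else "",
                 paste0(path, bad, collapse = ", ")), call. = FALSE)
  }
  for (nm in nms) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], override[[nm]],
                                  paste0(path, nm, "$"))
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

.validate_config <- function(cfg) {
  stopifnot(
    cfg$pixel_size_um > 0,
    length(cfg$frame_dim) == 2L, all(cfg$frame_dim >= 32),
    cfg$n_wells >= 1L, cfg$n_control_wells >= 1L,
    cfg$n_cells >= 1L, cfg$cell_diameter_um > 0,
    all(cfg$size_targets_um2 > 0), all(cfg$area_sdlog > 0),
    cfg$calibration_day > 0,
    cfg$growth$A >= 0, cfg$growth$alpha > 0,
    cfg$transfer$E0 >= 0, cfg$transfer$k > 0,
    cfg$transfer$eta > 0, cfg$transfer$eta <= 1,
    cfg$transfer$E_floor >= 0, cfg$transfer$autofluor >= 0,
    cfg$well_cv >= 0,
    all(diff(cfg$imaging_days) > 0),
    cfg$segmentation$min_area_um2 > 0,
    cfg$kinetics$rel_tol > 0
  )
  if (cfg$transfer$t_delivery < min(cfg$imaging_days) ||
      cfg$transfer$t_delivery > max(cfg$imaging_days)) {
    stop("delivery day must fall within the imaging schedule", call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a study configuration from a YAML file
#'
#' Keys mirror [study_config()] arguments; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

#' Stable hash of a configuration
#'
#' @param cfg A `study_config`.
#' @return MD5 hex digest of the canonical JSON serialisation.
#' @export
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA,
                              pretty = FALSE), tmp)
  unname(tools::md5sum(tmp))
}
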