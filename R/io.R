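#' Read a (multi-page) grayscale TIFF as integer-count matrices
#'
#' @param path TIFF file; pages are days/frames.
#' @return List of numeric matrices in camera counts (0..65535).
#' @export
read_image_series <- function(path) {
  if (!file.exists(path)) stop("TIFF not found: ", path, call. = FALSE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) {
                      stop("malformed TIFF '", path, "': ",
                           conditionMessage(e), call. = FALSE)
                    })
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # grayscale stored per channel
    round(p * 65535)
  })
}

#' Write frames as a 16-bit multi-page grayscale TIFF
#'
#' Intensities (a.u.) are rounded to integer counts and clamped to the
#' 16-bit range; integer-valued images round-trip bit-identically through
#' [read_image_series()].
#'
#' @param frames A matrix or list of matrices (a.u.).
#' @param path Output path.
#' @export
write_image_series <- function(frames, path) {
  if (is.matrix(frames)) frames <- list(frames)
  scaled <- lapply(frames, function(m) pmin(pmax(round(m), 0), 65535) / 65535)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Write a binary mask (8-bit 0/255) or a label image (16-bit) as TIFF
#'
#' @param mask Logical matrix (mask) or integer matrix (labels).
#' @param path Output path.
#' @export
write_mask_tiff <- function(mask, path) {
  if (is.logical(mask)) {
    tiff::writeTIFF(ifelse(mask, 1, 0), path, bits.per.sample = 8,
                    compression = "none")
  } else {
    tiff::writeTIFF(mask / 65535, path, bits.per.sample = 16,
                    compression = "none")
  }
  invisible(path)
}

#' Read a CSV table, checking required columns
#'
#' @param path CSV path.
#' @param required Character vector of required column names.
#' @return Data frame.
#' @export
read_table_checked <- function(path, required = character(0)) {
  if (!file.exists(path)) stop("CSV not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("'", path, "' is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a simulated study to disk
#'
#' Layout: `images/<well>_<channel>.tif` (multi-page, page = imaging day),
#' `images/<well>_labels.tif` truth labels, `truth/nodules.csv`,
#' `truth/intensities.csv`, `tables/monolayer.csv`, `tables/lysate.csv`,
#' `tables/colonies.csv`, `config.json` and `manifest.json` (seed, config
#' hash, schedule, file list).
#'
#' @param study A `gnp_study` from [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "gnp_study"))
  ok <- dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create study directory: ", dir,
                             call. = FALSE)
  for (d in c("images", "truth", "tables")) {
    dir.create(file.path(dir, d), showWarnings = FALSE)
  }
  files <- character(0)
  if (!is.null(study$frames)) {
    for (wi in seq_along(study$wells)) {
      w <- study$wells[wi]
      for (ch in c("darkfield", "fluorescence", "labels")) {
        frames <- lapply(study$frames, function(dayf) dayf[[wi]][[ch]])
        f <- file.path(dir, "images", paste0(w, "_", ch, ".tif"))
        write_image_series(frames, f)
        files <- c(files, f)
      }
    }
  }
  files <- c(files,
             .write_csv(study$nodules, file.path(dir, "truth", "nodules.csv")),
             .write_csv(study$intensities,
                        file.path(dir, "truth", "intensities.csv")),
             .write_csv(study$monolayer$truth,
                        file.path(dir, "tables", "monolayer.csv")),
             .write_csv(study$lysate, file.path(dir, "tables", "lysate.csv")),
             .write_csv(study$colonies,
                        file.path(dir, "tables", "colonies.csv")))
  cfg_path <- file.path(dir, "config.json")
  .write_json(unclass(study$config), cfg_path)
  manifest <- list(
    tool = "spheroidGNP",
    version = as.character(utils::packageVersion("spheroidGNP")),
    seed = study$seed,
    config_hash = config_hash(study$config),
    schedule = list(imaging_days = study$days,
                    delivery_day = study$config$transfer$t_delivery,
                    harvest_days = study$config$lysate$harvest_days),
    wells = study$wells,
    control_wells = study$control_wells,
    rendered = !is.null(study$frames),
    files = basename(c(files, cfg_path)),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  .write_json(manifest, file.path(dir, "manifest.json"))
  invisible(manifest)
}

#' Read a study directory back into a `gnp_study`
#'
#' @param dir Directory written by [write_study()].
#' @return A `gnp_study` (frames present only if they were rendered).
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) {
    stop("not a study directory (no manifest.json): ", dir, call. = FALSE)
  }
  manifest <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  cfg <- do.call(study_config, jsonlite::read_json(
    file.path(dir, "config.json"), simplifyVector = TRUE))
  wells <- manifest$wells
  days <- manifest$schedule$imaging_days
  frames <- NULL
  if (isTRUE(manifest$rendered)) {
    per_well <- lapply(wells, function(w) {
      lapply(c(darkfield = "darkfield", fluorescence = "fluorescence",
               labels = "labels"), function(ch) {
        read_image_series(file.path(dir, "images", paste0(w, "_", ch, ".tif")))
      })
    })
    frames <- lapply(seq_along(days), function(di) {
      fr <- lapply(seq_along(wells), function(wi) {
        list(darkfield = per_well[[wi]]$darkfield[[di]],
             fluorescence = per_well[[wi]]$fluorescence[[di]],
             labels = {
               l <- per_well[[wi]]$labels[[di]]
               storage.mode(l) <- "integer"
               l
             })
      })
      names(fr) <- wells
      fr
    })
  }
  out <- list(
    config = cfg, seed = manifest$seed, days = days, wells = wells,
    treated = !wells %in% manifest$control_wells,
    control_wells = manifest$control_wells,
    nodules = read_table_checked(file.path(dir, "truth", "nodules.csv"),
                                 c("day", "well", "nodule_id", "area_um2")),
    intensities = read_table_checked(
      file.path(dir, "truth", "intensities.csv"),
      c("day", "well", "treated", "ecm_intensity", "nodule_intensity")),
    frames = frames,
    monolayer = list(truth = read_table_checked(
      file.path(dir, "tables", "monolayer.csv"),
      c("day", "well", "signal", "intensity"))),
    lysate = read_table_checked(file.path(dir, "tables", "lysate.csv"),
                                c("day", "replicate", "absorbance")),
    colonies = read_table_checked(file.path(dir, "tables", "colonies.csv"),
                                  c("arm", "replicate", "colonies", "plated"))
  )
  class(out) <- "gnp_study"
  out
}
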