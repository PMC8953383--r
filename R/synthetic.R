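#' @name synthetic_study
#' @title Synthetic 3D-culture study generator
#' @description
#' Generates the complete synthetic study the analysis pipeline is tested
#' against: time-lapse darkfield and fluorescence frames of nodule
#' populations growing on an ECM bed, matched no-treatment control wells,
#' monolayer contrast series, terminal lysate-absorbance tables and
#' clonogenic colony counts, all with ground truth recorded per frame.
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# seed = NULL uses (and advances) the ambient RNG.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Two-compartment ECM-to-nodule transfer intensities
#'
#' Minimal single-rate exchange model for fluorophore-labelled GNPs
#' delivered at `t_delivery`: the ECM compartment decays as
#' \eqn{E_{floor} + E_0 e^{-k(t - t_d)}} while the nodule compartment rises
#' as \eqn{autofluor + \eta E_0 (1 - e^{-k(t - t_d)})}. With `eta = 1` the
#' transfer conserves signal exactly:
#' (ecm - E_floor) + (nodule - autofluor) = E0. The default
#' `k = log(20)/6` per day places 95% transfer six days post-delivery.
#'
#' @param t Time in days, `>= p$t_delivery` (vectorised).
#' @param p Transfer parameters: list with `E0`, `k`, `eta`, `t_delivery`,
#'   `E_floor`, `autofluor` (see [study_config()]`$transfer`).
#' @return List with numeric vectors `ecm` and `nodule` (a.u.).
#' @examples
#' p <- study_config()$transfer
#' compartment_intensities(c(7, 13), p)
#' @export
compartment_intensities <- function(t, p) {
  stopifnot(p$E0 >= 0, p$k > 0, p$eta > 0, p$eta <= 1,
            p$E_floor >= 0, p$autofluor >= 0)
  if (any(t < p$t_delivery)) {
    stop("`t` earlier than the delivery day", call. = FALSE)
  }
  dt <- t - p$t_delivery
  list(
    ecm = p$E_floor + p$E0 * exp(-p$k * dt),
    nodule = p$autofluor + p$eta * p$E0 * (1 - exp(-p$k * dt))
  )
}

# Gompertz-shaped log-area trajectory anchored at the single-cell area and
# calibrated so the day-`calibration_day` geometric mean hits `target`.
# Aggregation-driven amplitude; alpha sets the plateau timing. A == 0
# freezes growth.
.meanlog_trajectory <- function(day, target, cfg) {
  cell_area <- pi * (cfg$cell_diameter_um / 2)^2
  if (cfg$growth$A == 0) return(log(cell_area))
  al <- cfg$growth$alpha
  s <- (1 - exp(-al * day)) / (1 - exp(-al * cfg$calibration_day))
  log(cell_area) + s * log(target / cell_area)
}

#' Generate the nodule population for one well on one day
#'
#' Day 0 yields only single cells whose projected areas are lognormal
#' around the configured ~19.3 um cell diameter. On later days a
#' persistent small-size population (single cells and small nodules)
#' coexists with an aggregation-plus-proliferation-driven large-nodule
#' population; by the calibration day (default 7) the two log-area modes
#' sit at the configured targets (defaults 1,300 and 19,300 um^2), giving
#' the emergent bimodal lognormal size distribution. Nodules are placed
#' uniformly at random without substantial overlap; objects that cannot be
#' placed are dropped.
#'
#' @param day Day since plating (`>= 0`).
#' @param config A [study_config()].
#' @param seed Optional integer seed (otherwise the ambient RNG is used).
#' @return A data frame of class `scene_nodules`, one row per nodule:
#'   `nodule_id`, `row`, `col` (centre, pixels, 0-based), `a_um`, `b_um`
#'   (semi-axes), `orientation` (radians), `area_um2` (= pi a b),
#'   `component` ("small"/"large"), `is_single_cell`, `birth_day`.
#' @export
evolve_population <- function(day, config = study_config(), seed = NULL) {
  stopifnot(day >= 0)
  .with_seed(seed, {
    cfg <- config
    cell_area <- pi * (cfg$cell_diameter_um / 2)^2
    agg <- cfg$aggregation
    n0 <- cfg$n_cells
    if (agg$enabled && day > 0) {
      p_large <- agg$p_max * (1 - exp(-day / agg$tau))
      n <- max(4L, round(n0 * (1 - 0.5 * (1 - exp(-day / agg$count_decay)))))
    } else {
      p_large <- 0
      n <- n0
    }
    comp <- ifelse(stats::runif(n) < p_large, "large", "small")
    mu_s <- .meanlog_trajectory(day, cfg$size_targets_um2[["small"]], cfg)
    mu_l <- .meanlog_trajectory(day, cfg$size_targets_um2[["large"]], cfg)
    areas <- ifelse(
      comp == "large",
      stats::rlnorm(n, mu_l, cfg$area_sdlog[["large"]]),
      stats::rlnorm(n, mu_s, cfg$area_sdlog[["small"]])
    )
    rho <- stats::runif(n, cfg$aspect_ratio_range[1], cfg$aspect_ratio_range[2])
    b <- sqrt(areas / (pi * rho))
    a <- rho * b
    pos <- .place_nodules(areas, a, cfg)
    keep <- pos$keep
    nn <- sum(keep)
    out <- data.frame(
      nodule_id = seq_len(nn),
      row = pos$row[keep], col = pos$col[keep],
      a_um = a[keep], b_um = b[keep],
      orientation = stats::runif(nn, 0, pi),
      area_um2 = areas[keep],
      component = comp[keep],
      is_single_cell = comp[keep] == "small" &
        (day == 0 | areas[keep] <= 2 * cell_area),
      birth_day = 0,
      stringsAsFactors = FALSE
    )
    class(out) <- c("scene_nodules", "data.frame")
    out
  })
}

# Uniform placement with separation rejection: centre distances must
# exceed the sum of semi-major axes plus a small gap, so rasterised
# objects never touch (segmentation sees one component per nodule).
.place_nodules <- function(areas, a_um, cfg) {
  ps <- cfg$pixel_size_um
  H <- cfg$frame_dim[1]; W <- cfg$frame_dim[2]
  n <- length(areas)
  a_px <- a_um / ps
  gap <- 3                                        # px; defeats 8-adjacency
  ord <- order(areas, decreasing = TRUE)          # pack large first
  row <- col <- rep(NA_real_, n)
  keep <- rep(FALSE, n)
  placed_r <- placed_c <- placed_rad <- numeric(0)
  for (i in ord) {
    m <- min(a_px[i], (min(H, W) - 2) / 2)        # keep inside bounds
    for (try in seq_len(300L)) {
      rr <- stats::runif(1, m, H - 1 - m)
      cc <- stats::runif(1, m, W - 1 - m)
      if (length(placed_r)) {
        d2 <- (placed_r - rr)^2 + (placed_c - cc)^2
        if (any(d2 < (placed_rad + a_px[i] + gap)^2)) next
      }
      row[i] <- rr; col[i] <- cc; keep[i] <- TRUE
      placed_r <- c(placed_r, rr); placed_c <- c(placed_c, cc)
      placed_rad <- c(placed_rad, a_px[i])
      break
    }
  }
  list(row = row, col = col, keep = keep)
}

# Rasterize ellipses into an integer label image (row-major, 0-based
# centres; pixel centres at integer coordinates).
.rasterize_labels <- function(nodules, dim_hw, pixel_size) {
  H <- dim_hw[1]; W <- dim_hw[2]
  labels <- matrix(0L, H, W)
  clipped <- 0L
  for (i in seq_len(nrow(nodules))) {
    a <- nodules$a_um[i] / pixel_size
    b <- nodules$b_um[i] / pixel_size
    th <- nodules$orientation[i]
    cy <- nodules$row[i]; cx <- nodules$col[i]
    r0 <- floor(cy - a); r1 <- ceiling(cy + a)
    c0 <- floor(cx - a); c1 <- ceiling(cx + a)
    if (r0 < 0 || c0 < 0 || r1 > H - 1 || c1 > W - 1) clipped <- clipped + 1L
    rs <- max(0, r0):min(H - 1, r1)
    cs <- max(0, c0):min(W - 1, c1)
    if (!length(rs) || !length(cs)) next
    dy <- rs - cy; dx <- cs - cx
    U <- outer(dy, dx, function(y, x) (x * cos(th) + y * sin(th)) / a)
    V <- outer(dy, dx, function(y, x) (-x * sin(th) + y * cos(th)) / b)
    inside <- U^2 + V^2 <= 1
    sub <- labels[rs + 1, cs + 1, drop = FALSE]
    sub[inside] <- nodules$nodule_id[i]
    labels[rs + 1, cs + 1] <- sub
  }
  if (clipped > 0L) {
    warning(sprintf("%d nodule(s) clipped at the frame boundary", clipped))
  }
  labels
}

#' Render one microscopy frame
#'
#' Rasterises the nodule ellipses and paints a darkfield (morphology) or
#' fluorescence (GNP) frame. The fluorescence channel paints ECM pixels at
#' the `ecm` level and nodule interiors at the `nodule` level; darkfield
#' paints nodules bright on a dark background independent of GNP state.
#' Noise is signal-dependent Gaussian (Poisson-like, variance =
#' `gain * signal`) plus additive read noise plus a constant camera
#' offset. Pixel values are returned un-quantised (a.u.); quantisation to
#' 16-bit counts happens at write time.
#'
#' @param nodules A `scene_nodules` data frame (see [evolve_population()]).
#' @param channel `"darkfield"` or `"fluorescence"`.
#' @param intensities List with `ecm` and `nodule` levels (a.u.); only used
#'   for the fluorescence channel.
#' @param config A [study_config()] (frame geometry, noise, darkfield levels).
#' @param seed Optional seed for the noise draws.
#' @return List with `image` (numeric matrix, a.u.) and `labels` (the
#'   rasterised ground-truth label matrix).
#' @export
render_frame <- function(nodules, channel = c("darkfield", "fluorescence"),
                         intensities = list(ecm = 0, nodule = 0),
                         config = study_config(), seed = NULL) {
  channel <- match.arg(channel)
  cfg <- config
  labels <- .rasterize_labels(nodules, cfg$frame_dim, cfg$pixel_size_um)
  fg <- labels > 0L
  img <- if (channel == "darkfield") {
    matrix(cfg$darkfield$bg_level, cfg$frame_dim[1], cfg$frame_dim[2])
  } else {
    matrix(intensities$ecm, cfg$frame_dim[1], cfg$frame_dim[2])
  }
  img[fg] <- if (channel == "darkfield") cfg$darkfield$fg_level
             else intensities$nodule
  .with_seed(seed, {
    nz <- cfg$noise
    if (nz$gain > 0) {
      img <- img + sqrt(nz$gain * pmax(img, 0)) * stats::rnorm(length(img))
    }
    if (nz$read_sd > 0) img <- img + stats::rnorm(length(img), sd = nz$read_sd)
    img <- pmax(img + nz$offset, 0)
    list(image = img, labels = labels)
  })
}

#' Monolayer (2D culture) intensity series
#'
#' Monolayer cultures take up GNPs within the first day and show no
#' continued accumulation: the cellular GNP signal follows
#' \eqn{E_0(1 - e^{-k t})} with a fast rate (default `k = log(50)` per day,
#' i.e. 98% of the asymptote at day 1), so the series over days 1--8 is
#' flat. Ground truth is the GNP signal alone (zero when `E0 = 0`).
#'
#' @param config A [study_config()]; `config$monolayer` holds `E0`, `k`,
#'   `t_delivery`, `days`, `n_cells`.
#' @param seed Optional seed.
#' @param render If `TRUE`, render fluorescence/darkfield frames per day.
#' @return List with `truth` (data frame: `day`, `well`, `signal`,
#'   `intensity` where intensity = autofluor + signal, well-jittered) and,
#'   if rendered, `frames[[day index]][[well]]` with `image`, `darkfield`,
#'   `labels`.
#' @export
generate_monolayer_series <- function(config = study_config(), seed = NULL,
                                      render = config$render) {
  cfg <- config
  m <- cfg$monolayer
  .with_seed(seed, {
    truth <- expand.grid(well = seq_len(cfg$n_wells), day = m$days,
                         KEEP.OUT.ATTRS = FALSE)
    truth <- truth[order(truth$day, truth$well), c("day", "well")]
    dt <- truth$day - m$t_delivery
    stopifnot(all(dt >= 0))
    sig <- m$E0 * (1 - exp(-m$k * dt))
    jit <- exp(stats::rnorm(nrow(truth), 0, cfg$well_cv))
    truth$signal <- sig * jit
    truth$intensity <- cfg$transfer$autofluor + truth$signal
    rownames(truth) <- NULL
    frames <- NULL
    if (isTRUE(render)) {
      mono_cfg <- cfg
      mono_cfg$n_cells <- m$n_cells
      mono_cfg$aggregation$enabled <- FALSE
      frames <- lapply(seq_along(m$days), function(di) {
        lapply(seq_len(cfg$n_wells), function(w) {
          cells <- evolve_population(0, mono_cfg)
          lev <- truth$intensity[truth$day == m$days[di] & truth$well == w]
          fr <- render_frame(cells, "fluorescence",
                             list(ecm = 0, nodule = lev), mono_cfg)
          df <- render_frame(cells, "darkfield", config = mono_cfg)
          list(image = fr$image, darkfield = df$image, labels = fr$labels)
        })
      })
    }
    list(truth = truth, frames = frames, days = m$days)
  })
}

#' Terminal lysate absorbance table
#'
#' Emulates plate-reader absorbance of fluorophore extracted from digested
#' cultures: proportional to the true per-well nodule GNP content on the
#' harvest day, with multiplicative noise of the stated coefficient of
#' variation.
#'
#' @param config A [study_config()] (transfer model and lysate settings).
#' @param harvest_days Days of harvest (all `>=` delivery day).
#' @param replicates Wells harvested per day.
#' @param noise_cv Multiplicative noise CV (0 = exactly proportional).
#' @param seed Optional seed.
#' @return Data frame: `day`, `replicate`, `absorbance` (a.u.).
#' @export
generate_lysate_table <- function(config = study_config(),
                                  harvest_days = config$lysate$harvest_days,
                                  replicates = config$lysate$replicates,
                                  noise_cv = config$lysate$noise_cv,
                                  seed = NULL) {
  p <- config$transfer
  if (any(harvest_days < p$t_delivery)) {
    stop("harvest days must be on/after the delivery day", call. = FALSE)
  }
  .with_seed(seed, {
    grid <- expand.grid(replicate = seq_len(replicates), day = harvest_days,
                        KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
    content <- p$eta * p$E0 * (1 - exp(-p$k * (grid$day - p$t_delivery)))
    noise <- if (noise_cv > 0) {
      pmax(0, 1 + noise_cv * stats::rnorm(nrow(grid)))
    } else 1
    grid$absorbance <- config$lysate$scale * content * noise
    rownames(grid) <- NULL
    grid
  })
}

#' Clonogenic colony-count table
#'
#' Draws colony counts per treatment arm as
#' Binomial(`n_plated`, `sf * plating_efficiency`). Default arm survival
#' probabilities are the study's printed survival factors for the four
#' radiotherapy arms (0.680/0.246 at the four-day accumulation schedule,
#' 0.423/0.309 at one day).
#'
#' @param sf Named vector of survival probabilities in `[0, 1]`.
#' @param n_plated Cells plated per replicate dish.
#' @param replicates Replicate dishes per arm.
#' @param plating_efficiency Colony-forming fraction of untreated cells.
#' @param seed Optional seed.
#' @return Data frame: `arm`, `replicate`, `colonies`, `plated`.
#' @export
generate_colony_counts <- function(sf = study_config()$arms$survival,
                                   n_plated = 1000L, replicates = 3L,
                                   plating_efficiency = 1, seed = NULL) {
  if (any(sf < 0 | sf > 1)) stop("`sf` must lie in [0, 1]", call. = FALSE)
  stopifnot(n_plated >= 1L, replicates >= 1L,
            plating_efficiency > 0, plating_efficiency <= 1)
  if (is.null(names(sf))) names(sf) <- paste0("arm", seq_along(sf))
  .with_seed(seed, {
    out <- do.call(rbind, lapply(names(sf), function(a) {
      data.frame(arm = a, replicate = seq_len(replicates),
                 colonies = stats::rbinom(replicates, n_plated,
                                          sf[[a]] * plating_efficiency),
                 plated = n_plated, stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    out
  })
}

#' Simulate the complete synthetic study
#'
#' Runs the full generator under a single master seed: per-day nodule
#' populations and (optionally) rendered darkfield + fluorescence frames
#' for treated and no-treatment control wells, per-well painted compartment
#' intensities (ground truth), the monolayer contrast series, the lysate
#' table and the clonogenic colony counts. Treated wells are painted with
#' the transfer-model intensities from the delivery day onward; control
#' wells and pre-delivery frames carry only nodule autofluorescence.
#' The same master seed reproduces the study bit-identically.
#'
#' @param config A [study_config()].
#' @param seed Master seed (default `config$seed`).
#' @return An object of class `gnp_study`: list with `config`, `seed`,
#'   `wells`, `control_wells`, `nodules` (truth geometry table),
#'   `intensities` (truth painted intensities: `day`, `well`, `treated`,
#'   `ecm_intensity`, `nodule_intensity`), `frames` (if rendered:
#'   `frames[[day index]][[well]]` with `darkfield`, `fluorescence`,
#'   `labels`), `monolayer`, `lysate`, `colonies`.
#' @export
simulate_study <- function(config = study_config(), seed = config$seed) {
  cfg <- config
  .with_seed(seed, {
    days <- cfg$imaging_days
    wells <- c(paste0("W", seq_len(cfg$n_wells)),
               paste0("C", seq_len(cfg$n_control_wells)))
    treated <- c(rep(TRUE, cfg$n_wells), rep(FALSE, cfg$n_control_wells))
    nod_rows <- list(); int_rows <- list(); frames <- NULL
    if (isTRUE(cfg$render)) frames <- vector("list", length(days))
    for (di in seq_along(days)) {
      day <- days[di]
      if (isTRUE(cfg$render)) frames[[di]] <- vector("list", length(wells))
      for (wi in seq_along(wells)) {
        pop <- evolve_population(day, cfg)
        if (treated[wi] && day >= cfg$transfer$t_delivery) {
          ci <- compartment_intensities(day, cfg$transfer)
        } else {
          ci <- list(ecm = 0, nodule = cfg$transfer$autofluor)
        }
        # independent session jitter per compartment
        ci$ecm <- ci$ecm * exp(stats::rnorm(1, 0, cfg$well_cv))
        ci$nodule <- ci$nodule * exp(stats::rnorm(1, 0, cfg$well_cv))
        if (nrow(pop)) {
          nod_rows[[length(nod_rows) + 1L]] <- cbind(
            data.frame(day = day, well = wells[wi]),
            pop[, c("nodule_id", "area_um2", "a_um", "b_um", "row", "col",
                    "component", "is_single_cell")]
          )
        }
        int_rows[[length(int_rows) + 1L]] <- data.frame(
          day = day, well = wells[wi], treated = treated[wi],
          ecm_intensity = ci$ecm, nodule_intensity = ci$nodule
        )
        if (isTRUE(cfg$render)) {
          df <- render_frame(pop, "darkfield", config = cfg)
          fl <- render_frame(pop, "fluorescence", ci, cfg)
          frames[[di]][[wi]] <- list(darkfield = df$image,
                                     fluorescence = fl$image,
                                     labels = fl$labels)
        }
      }
      if (isTRUE(cfg$render)) names(frames[[di]]) <- wells
    }
    mono <- generate_monolayer_series(cfg, render = FALSE)
    lys <- generate_lysate_table(cfg)
    col <- generate_colony_counts(cfg$arms$survival, cfg$arms$n_plated,
                                  cfg$arms$replicates,
                                  cfg$arms$plating_efficiency)
    nodules <- do.call(rbind, nod_rows); rownames(nodules) <- NULL
    ints <- do.call(rbind, int_rows); rownames(ints) <- NULL
    out <- list(config = cfg, seed = seed, days = days, wells = wells,
                treated = treated,
                control_wells = wells[!treated],
                nodules = nodules, intensities = ints, frames = frames,
                monolayer = mono, lysate = lys, colonies = col)
    class(out) <- "gnp_study"
    out
  })
}

#' @export
print.gnp_study <- function(x, ...) {
  cat("Synthetic GNP 3D-culture study\n")
  cat(sprintf("  days %s, %d treated + %d control wells, seed %s\n",
              paste(range(x$days), collapse = "-"),
              sum(x$treated), sum(!x$treated), format(x$seed)))
  cat(sprintf("  %d nodule truth rows; frames %s\n", nrow(x$nodules),
              if (is.null(x$frames)) "not rendered" else
                sprintf("%dx%d px", x$config$frame_dim[1],
                        x$config$frame_dim[2])))
  invisible(x)
}
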