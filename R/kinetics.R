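#' Control-based background subtraction
#'
#' Subtracts the scalar background level (the mean intensity of matched
#' no-treatment frames) from a frame, flooring at zero. The fraction of
#' floored pixels is attached as an attribute for QC.
#'
#' @param image Numeric matrix (a.u.).
#' @param control_level Scalar background level (a.u.).
#' @return Corrected matrix with attribute `floored_fraction`.
#' @export
background_subtract <- function(image, control_level) {
  stopifnot(is.numeric(control_level), length(control_level) == 1L,
            is.finite(control_level))
  corrected <- image - control_level
  floored <- mean(corrected < 0)
  corrected[corrected < 0] <- 0
  attr(corrected, "floored_fraction") <- floored
  corrected
}

#' Pick the control level for a day
#'
#' Exact-day match preferred; otherwise the nearest available control day
#' is used with a warning. No controls at all is an error.
#'
#' @param control_days Days with available control levels.
#' @param control_levels Matching mean control intensities.
#' @param day Day requested.
#' @return Scalar control level.
#' @export
control_level_for_day <- function(control_days, control_levels, day) {
  if (!length(control_days)) stop("no control frames available", call. = FALSE)
  stopifnot(length(control_days) == length(control_levels))
  i <- which(control_days == day)
  if (!length(i)) {
    i <- which.min(abs(control_days - day))
    warning(sprintf("no control for day %s; using nearest control day %s",
                    format(day), format(control_days[i])))
  }
  control_levels[i[1]]
}

#' Mean intensity per compartment
#'
#' Foreground (nodule) and background (ECM) mean intensities of a
#' corrected frame under a segmentation mask pair. An empty foreground
#' yields `NA` for the foreground mean (missing, not zero).
#'
#' @param corrected Corrected intensity matrix.
#' @param masks A `mask_pair`.
#' @return List with `fg_mean` and `bg_mean`.
#' @export
compartment_means <- function(corrected, masks) {
  stopifnot(inherits(masks, "mask_pair"))
  if (!all(dim(corrected) == dim(masks$foreground))) {
    stop("image/mask shape mismatch", call. = FALSE)
  }
  nfg <- sum(masks$foreground)
  list(
    fg_mean = if (nfg > 0) mean(corrected[masks$foreground]) else NA_real_,
    bg_mean = if (nfg < length(corrected)) mean(corrected[masks$background])
              else NA_real_
  )
}

#' Build the per-day intensity series across wells
#'
#' Aggregates per-well compartment means into per-day means and standard
#' errors. The nodule/ECM ratio is computed from the per-day mean
#' foreground and background intensities (not as the mean of per-well
#' ratios). Days with no usable well are dropped with a warning; a single
#' well gives `NA` standard errors.
#'
#' @param measurements Data frame with columns `day`, `well`, `fg_mean`,
#'   `bg_mean` (one row per well per day).
#' @return Data frame of class `intensity_series`: `day`, `fg_mean`,
#'   `bg_mean`, `fg_se`, `bg_se`, `ratio`, `n_wells`, sorted by day.
#' @export
build_series <- function(measurements) {
  req <- c("day", "well", "fg_mean", "bg_mean")
  if (!all(req %in% names(measurements))) {
    stop("measurements need columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  }
  ok <- is.finite(measurements$fg_mean) & is.finite(measurements$bg_mean)
  dropped <- setdiff(unique(measurements$day), unique(measurements$day[ok]))
  if (length(dropped)) {
    warning("dropping day(s) with no usable frames: ",
            paste(dropped, collapse = ", "))
  }
  m <- measurements[ok, , drop = FALSE]
  if (!nrow(m)) stop("no usable measurements", call. = FALSE)
  se <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else NA_real_
  agg <- lapply(split(m, m$day), function(d) {
    data.frame(day = d$day[1],
               fg_mean = mean(d$fg_mean), bg_mean = mean(d$bg_mean),
               fg_se = se(d$fg_mean), bg_se = se(d$bg_mean),
               n_wells = nrow(d))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$day), ]
  out$ratio <- out$fg_mean / out$bg_mean
  out <- out[, c("day", "fg_mean", "bg_mean", "fg_se", "bg_se", "ratio",
                 "n_wells")]
  rownames(out) <- NULL
  class(out) <- c("intensity_series", "data.frame")
  out
}

#' Two-phase piecewise-linear fit of an uptake series
#'
#' For every candidate break day, fits an ordinary least-squares line to
#' each segment (the break day belongs to both segments, matching the
#' days 7--11 / 11--28 windows convention) and returns the break
#' minimising the total residual sum of squares — an exhaustive search,
#' ties resolved to the earliest break. By default the two lines are
#' independent ("roughly linear" treatment of each window); a
#' continuity-constrained variant joins them at the break.
#'
#' @param series An `intensity_series` or any data frame with a `day`
#'   column and the response column.
#' @param candidate_breaks Days to consider; default: all observed days
#'   with at least 3 points on each side (inclusive).
#' @param response Column fitted (default `"ratio"`).
#' @param continuity If `TRUE`, constrain the segments to meet at the
#'   break.
#' @return Object of class `piecewise_fit`: `slope1`, `slope2` (response
#'   units/day), `break_day`, `intercepts` (length 2), `rss`, `n_left`,
#'   `n_right`, `continuity`.
#' @export
fit_two_phase <- function(series, candidate_breaks = NULL,
                          response = "ratio", continuity = FALSE) {
  day <- series$day
  y <- series[[response]]
  if (is.null(y)) stop("response column not found: ", response, call. = FALSE)
  keep <- is.finite(day) & is.finite(y)
  day <- day[keep]; y <- y[keep]
  o <- order(day); day <- day[o]; y <- y[o]
  if (is.null(candidate_breaks)) {
    candidate_breaks <- day[vapply(day, function(b) {
      sum(day <= b) >= 3L && sum(day >= b) >= 3L
    }, logical(1))]
  }
  candidate_breaks <- sort(candidate_breaks)
  best <- NULL
  for (b in candidate_breaks) {
    i1 <- day <= b; i2 <- day >= b
    if (sum(i1) < 3L || sum(i2) < 3L) next
    if (continuity) {
      h <- pmax(day - b, 0)
      f <- stats::lm(y ~ day + h)
      cf <- stats::coef(f)
      cand <- list(slope1 = cf[["day"]], slope2 = cf[["day"]] + cf[["h"]],
                   break_day = b,
                   intercepts = c(cf[["(Intercept)"]],
                                  cf[["(Intercept)"]] - cf[["h"]] * b),
                   rss = sum(stats::resid(f)^2),
                   n_left = sum(i1), n_right = sum(i2))
    } else {
      f1 <- stats::lm(y[i1] ~ day[i1])
      f2 <- stats::lm(y[i2] ~ day[i2])
      cand <- list(slope1 = stats::coef(f1)[[2]], slope2 = stats::coef(f2)[[2]],
                   break_day = b,
                   intercepts = c(stats::coef(f1)[[1]], stats::coef(f2)[[1]]),
                   rss = sum(stats::resid(f1)^2) + sum(stats::resid(f2)^2),
                   n_left = sum(i1), n_right = sum(i2))
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand  # ties -> earliest
  }
  if (is.null(best)) {
    stop("no candidate break with >= 3 points on each side", call. = FALSE)
  }
  best$continuity <- continuity
  class(best) <- "piecewise_fit"
  best
}

#' @export
print.piecewise_fit <- function(x, ...) {
  cat(sprintf("Two-phase linear fit: break day %s\n", format(x$break_day)))
  cat(sprintf("  slope1 = %.4g /day (n=%d)   slope2 = %.4g /day (n=%d)\n",
              x$slope1, x$n_left, x$slope2, x$n_right))
  cat(sprintf("  slope1/slope2 = %.3g   rss = %.4g   %s\n",
              x$slope1 / x$slope2, x$rss,
              if (x$continuity) "(continuous at break)" else
                "(independent segments)"))
  invisible(x)
}

#' Plateau (peak) day of the nodule-intensity series
#'
#' Earliest day whose foreground mean is within `rel_tol` of the series
#' maximum. If only the final day qualifies the plateau is censored (the
#' series is still rising at the end of observation).
#'
#' @param series An `intensity_series` (>= 3 days).
#' @param rel_tol Relative tolerance below the maximum (default 0.05).
#' @return List with `peak_day` and `censored`.
#' @export
detect_peak_day <- function(series, rel_tol = 0.05) {
  stopifnot(nrow(series) >= 3L, rel_tol > 0)
  fg <- series$fg_mean
  qual <- which(fg >= (1 - rel_tol) * max(fg))
  peak <- series$day[min(qual)]
  list(peak_day = peak, censored = peak == series$day[nrow(series)])
}

#' Nodule/ECM crossover day
#'
#' Earliest day at which the foreground (nodule) mean reaches the
#' background (ECM) mean, linearly interpolated between the bracketing
#' observation days. If the foreground never reaches the background the
#' result is censored.
#'
#' @param series An `intensity_series` with both compartments present.
#' @return List with `day` (possibly fractional; `NA` if censored) and
#'   `censored`.
#' @export
crossover_day <- function(series) {
  d <- series$fg_mean - series$bg_mean
  i <- which(d >= 0)
  if (!length(i)) return(list(day = NA_real_, censored = TRUE))
  i <- min(i)
  if (i == 1L || d[i] == 0) return(list(day = series$day[i], censored = FALSE))
  d0 <- d[i - 1]; d1 <- d[i]
  frac <- -d0 / (d1 - d0)
  list(day = series$day[i - 1] + frac * (series$day[i] - series$day[i - 1]),
       censored = FALSE)
}
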