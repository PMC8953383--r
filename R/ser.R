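#' Clonogenic survival factor
#'
#' Per-replicate survival factor `(colonies/plated)/plating_efficiency`,
#' summarised as mean and standard error across replicates. Values above 1
#' (more colonies than expected from plating efficiency alone) are clamped
#' to 1 with a warning.
#'
#' @param colonies Colony counts, one per replicate dish.
#' @param plated Cells plated per dish (`> 0`).
#' @param plating_efficiency Colony-forming fraction of untreated cells,
#'   in `(0, 1]` (default 1: survival factors taken at face value).
#' @return List with `sf`, `se` (`NA` for a single replicate), `n`.
#' @examples
#' survival_factor(c(680, 680, 680), 1000) # sf = 0.68, se = 0
#' @export
survival_factor <- function(colonies, plated, plating_efficiency = 1) {
  if (length(plated) != 1L || !is.finite(plated) || plated <= 0) {
    stop("`plated` must be a single count > 0", call. = FALSE)
  }
  stopifnot(plating_efficiency > 0, plating_efficiency <= 1)
  if (any(colonies < 0) || any(colonies > plated)) {
    stop("colony counts must lie in [0, plated]", call. = FALSE)
  }
  sf_i <- (colonies / plated) / plating_efficiency
  if (any(sf_i > 1)) {
    warning("survival factor(s) > 1 clamped to 1")
    sf_i <- pmin(sf_i, 1)
  }
  n <- length(sf_i)
  list(sf = mean(sf_i),
       se = if (n > 1L) stats::sd(sf_i) / sqrt(n) else NA_real_,
       n = n)
}

#' Sensitivity enhancement ratio (SER)
#'
#' SER is the ratio of the clonogenic survival factor upon radiation
#' without GNPs to the survival factor with GNPs; SER > 1 indicates
#' radiosensitization. The standard error is propagated to first order
#' (delta method): \eqn{se_{SER} = SER\sqrt{(se_1/sf_1)^2 + (se_2/sf_2)^2}}.
#'
#' @param sf_rt Survival without GNP: list/vector with `sf` and `se`.
#' @param sf_rt_gnp Survival with GNP: same form, `sf > 0`.
#' @param schedule Optional label for the accumulation schedule.
#' @return Object of class `ser_result`: `schedule`, `sf_rt`, `sf_rt_gnp`,
#'   `ser`, `se`.
#' @examples
#' compute_ser(c(sf = 0.680, se = 0), c(sf = 0.246, se = 0)) # SER 2.76
#' @export
compute_ser <- function(sf_rt, sf_rt_gnp, schedule = NA_character_) {
  a <- .as_sf(sf_rt); b <- .as_sf(sf_rt_gnp)
  if (a$sf <= 0) stop("sf_rt must be > 0", call. = FALSE)
  if (b$sf <= 0) stop("undefined ratio: sf_rt_gnp is 0", call. = FALSE)
  ser <- a$sf / b$sf
  se <- if (is.finite(a$se) && is.finite(b$se)) {
    ser * sqrt((a$se / a$sf)^2 + (b$se / b$sf)^2)
  } else NA_real_
  out <- list(schedule = schedule, sf_rt = a$sf, sf_rt_gnp = b$sf,
              ser = ser, se = se)
  class(out) <- "ser_result"
  out
}

.as_sf <- function(x) {
  x <- as.list(x)
  if (is.null(x$sf)) stop("need an `sf` component", call. = FALSE)
  list(sf = as.numeric(x$sf), se = as.numeric(x$se %||% NA_real_))
}

#' @export
print.ser_result <- function(x, ...) {
  cat(sprintf("SER%s = %.3f (%.3f/%.3f)%s\n",
              if (is.na(x$schedule)) "" else paste0(" [", x$schedule, "]"),
              x$ser, x$sf_rt, x$sf_rt_gnp,
              if (is.finite(x$se)) sprintf(" +/- %.3f", x$se) else ""))
  invisible(x)
}

#' Compare SERs across accumulation schedules
#'
#' Tabulates SER per schedule and all pairwise SER ratios, flagging pairs
#' whose ratio is at least 2 ("more than doubled" enhancement from the
#' longer accumulation period).
#'
#' @param results List of `ser_result` objects (>= 2 schedules).
#' @return List of class `schedule_report`: `table` (schedule, sf_rt,
#'   sf_rt_gnp, ser, se) and `pairwise` (schedule_hi, schedule_lo, ratio,
#'   doubled).
#' @export
schedule_comparison <- function(results) {
  if (length(results) < 2L) {
    stop("need at least 2 schedules to compare", call. = FALSE)
  }
  stopifnot(all(vapply(results, inherits, logical(1), "ser_result")))
  tab <- do.call(rbind, lapply(results, function(r) {
    data.frame(schedule = r$schedule, sf_rt = r$sf_rt,
               sf_rt_gnp = r$sf_rt_gnp, ser = r$ser, se = r$se,
               stringsAsFactors = FALSE)
  }))
  pw <- list()
  for (i in seq_along(results)) for (j in seq_along(results)) {
    if (i == j) next
    ratio <- results[[i]]$ser / results[[j]]$ser
    if (ratio < 1) next
    pw[[length(pw) + 1L]] <- data.frame(
      schedule_hi = results[[i]]$schedule,
      schedule_lo = results[[j]]$schedule,
      ratio = ratio, doubled = ratio >= 2, stringsAsFactors = FALSE)
  }
  out <- list(table = tab, pairwise = do.call(rbind, pw))
  class(out) <- "schedule_report"
  out
}

#' @export
print.schedule_report <- function(x, ...) {
  cat("SER by schedule:\n")
  print(x$table, row.names = FALSE)
  cat("Pairwise SER ratios:\n")
  p <- x$pairwise
  p$note <- ifelse(p$doubled, "more than doubled", "")
  print(p, row.names = FALSE)
  invisible(x)
}
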