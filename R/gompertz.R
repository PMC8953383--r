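#' Gompertzian size at a given time
#'
#' Evaluates the Gompertz growth law
#' \deqn{N(t) = N_0 \exp\left(A \frac{1 - e^{-\alpha t}}{\alpha}\right)}
#' used to describe the volumetric growth of 3D tumor nodules: exponential
#' early growth at rate `A` that decays at rate `alpha`, saturating at the
#' plateau \eqn{N_0 e^{A/\alpha}}.
#'
#' @param t Time in days (vectorised, `t >= 0`).
#' @param N0 Initial size (same units as the returned size), `> 0`.
#' @param A Growth rate coefficient in day^-1, `> 0`.
#' @param alpha Decay coefficient of the growth rate in day^-1, `> 0`.
#' @return Size at time `t`, same units as `N0`.
#' @seealso [doubling_time_hours()], [fit_gompertz()]
#' @examples
#' gompertz_size(0:9, N0 = 500, A = 0.8, alpha = 0.35)
#' @export
gompertz_size <- function(t, N0, A, alpha) {
  .check_gompertz_pars(N0, A, alpha)
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("`t` must be finite and >= 0", call. = FALSE)
  }
  N0 * exp(A * (1 - exp(-alpha * t)) / alpha)
}

#' Exponential-phase doubling time
#'
#' At small times the Gompertz law reduces to exponential growth
#' \eqn{N/N_0 \approx e^{At} = 2^{t/\tau}}, so the doubling time is
#' \eqn{\tau = \ln 2 / A}. With `A` in day^-1 the result is returned in
#' hours, i.e. \eqn{24 \ln 2 / A}.
#'
#' @param A Gompertz rate coefficient in day^-1, `> 0`.
#' @return Doubling time in hours.
#' @examples
#' doubling_time_hours(0.79872) # ~20.83 h
#' @export
doubling_time_hours <- function(A) {
  if (!is.numeric(A) || any(!is.finite(A)) || any(A <= 0)) {
    stop("`A` must be finite and > 0", call. = FALSE)
  }
  24 * log(2) / A
}

.check_gompertz_pars <- function(N0, A, alpha) {
  for (nm in c("N0", "A", "alpha")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop(sprintf("`%s` must be a single finite value > 0", nm), call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Fit the Gompertz growth law by nonlinear least squares
#'
#' Fits `gompertz_size()` to a size-versus-time series. Because nodule sizes
#' span orders of magnitude, the default loss is least squares on
#' log-residuals (multiplicative errors); `loss = "linear"` fits raw
#' residuals instead. Parameters are optimised on the log scale so
#' positivity is enforced by construction, with Levenberg--Marquardt
#' iterations.
#'
#' @param times Time points in days (>= 4 distinct values).
#' @param sizes Observed sizes (all `> 0`), same length as `times`.
#' @param init Optional named list/vector with starting values `N0`, `A`,
#'   `alpha`; defaults are data-driven (first size, early log-slope,
#'   `alpha = 0.3`).
#' @param loss `"log"` (default) or `"linear"` residuals.
#' @return An object of class `gompertz_fit`: a list with `N0`, `A`,
#'   `alpha` (day^-1), `tau_hours` (= `24 log(2)/A`), `rss` (in fit units
#'   squared), `loss`, `converged`, `message`, and `fitted` values at
#'   `times`.
#' @examples
#' t <- 0:9
#' y <- gompertz_size(t, 500, 0.8, 0.35)
#' fit_gompertz(t, y)
#' @export
fit_gompertz <- function(times, sizes, init = NULL,
                         loss = c("log", "linear")) {
  loss <- match.arg(loss)
  if (length(times) != length(sizes)) {
    stop("`times` and `sizes` must have the same length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(!is.finite(sizes))) {
    stop("non-finite values in `times` or `sizes`", call. = FALSE)
  }
  if (length(unique(times)) < 4L) {
    stop("need at least 4 distinct time points", call. = FALSE)
  }
  if (any(sizes <= 0)) stop("all sizes must be > 0", call. = FALSE)

  start <- .gompertz_start(times, sizes, init)
  df <- data.frame(t = times, y = sizes, ly = log(sizes))
  form <- if (loss == "log") {
    ly ~ lN0 + exp(lA) * (1 - exp(-exp(lal) * t)) / exp(lal)
  } else {
    y ~ exp(lN0 + exp(lA) * (1 - exp(-exp(lal) * t)) / exp(lal))
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(form, data = df, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(N0 = exp(start$lN0), A = exp(start$lA),
                alpha = exp(start$lal),
                tau_hours = doubling_time_hours(exp(start$lA)),
                rss = NA_real_, loss = loss, converged = FALSE,
                message = conditionMessage(fit), fitted = NULL)
    class(out) <- "gompertz_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  A <- exp(cf[["lA"]])
  out <- list(
    N0 = exp(cf[["lN0"]]), A = A, alpha = exp(cf[["lal"]]),
    tau_hours = doubling_time_hours(A),
    rss = sum(stats::resid(fit)^2), loss = loss,
    converged = fit$convInfo$isConv %||% TRUE,
    message = "converged",
    fitted = gompertz_size(times, exp(cf[["lN0"]]), A, exp(cf[["lal"]]))
  )
  class(out) <- "gompertz_fit"
  out
}

.gompertz_start <- function(times, sizes, init) {
  if (!is.null(init)) {
    init <- as.list(init)
    stopifnot(all(c("N0", "A", "alpha") %in% names(init)))
    return(list(lN0 = log(init$N0), lA = log(init$A), lal = log(init$alpha)))
  }
  o <- order(times)
  t <- times[o]; ly <- log(sizes[o])
  # early log-slope as starting growth rate
  k <- min(4L, length(t))
  sl <- tryCatch(stats::coef(stats::lm(ly[1:k] ~ t[1:k]))[[2]],
                 error = function(e) NA_real_)
  A0 <- if (is.finite(sl) && sl > 0.01) min(sl, 5) else 0.5
  list(lN0 = log(sizes[o][1]), lA = log(A0), lal = log(0.3))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gompertz_fit <- function(x, ...) {
  cat("Gompertz growth fit (", x$loss, "-residual least squares)\n", sep = "")
  cat(sprintf("  N0 = %.4g   A = %.4g /day   alpha = %.4g /day\n",
              x$N0, x$A, x$alpha))
  cat(sprintf("  doubling time tau = %.2f h   rss = %.4g   %s\n",
              x$tau_hours, x$rss, x$message))
  invisible(x)
}
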