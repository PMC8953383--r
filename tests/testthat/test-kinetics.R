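test_that("background subtraction floors at zero and tracks its control", {
  set.seed(1)
  ctrl <- matrix(5 + rnorm(64 * 64, sd = 2), 64)
  corr <- background_subtract(ctrl, mean(ctrl))
  expect_lt(mean(corr), sd(ctrl))                      # ~0 up to noise
  expect_lte(attr(corr, "floored_fraction"), 0.55)
  expect_true(all(corr >= 0))
  # control level 0 is the identity
  img <- matrix(runif(100, 1, 10), 10)
  expect_equal(as.numeric(background_subtract(img, 0)), as.numeric(img))
  # nearest-day fallback and hard error without controls
  expect_warning(l <- control_level_for_day(c(7, 9), c(5, 6), 8), "nearest")
  expect_true(l %in% c(5, 6))
  expect_equal(control_level_for_day(c(7, 9), c(5, 6), 9), 6)
  expect_error(control_level_for_day(numeric(0), numeric(0), 7), "no control")
})

test_that("zero-noise frames correct exactly to the painted truth", {
  cfg <- noiseless_config(pixel_size_um = 1)
  nod <- one_nodule(80, 80, 25, 18, 0.7)
  lvl <- list(ecm = 40, nodule = 85)
  fr <- render_frame(nod, "fluorescence", lvl, cfg)
  corr <- background_subtract(fr$image, 12)   # pretend control level
  masks <- .mask_pair_from_labels(fr$labels)
  cm <- compartment_means(corr, masks)
  expect_equal(cm$fg_mean, 85 - 12)
  expect_equal(cm$bg_mean, 40 - 12)
})

test_that("compartment means respect masks and contract cases", {
  img <- matrix(7.7, 32, 32)
  m <- .mask_pair_from_labels(matrix(c(rep(1L, 100), rep(0L, 924)), 32))
  cm <- compartment_means(img, m)
  expect_equal(cm$fg_mean, 7.7)
  expect_equal(cm$bg_mean, 7.7)
  # empty foreground -> missing, not zero
  m0 <- .mask_pair_from_labels(matrix(0L, 32, 32))
  cm0 <- compartment_means(img, m0)
  expect_true(is.na(cm0$fg_mean))
  expect_equal(cm0$bg_mean, 7.7)
  expect_error(compartment_means(matrix(0, 3, 3), m), "mismatch")
})

test_that("build_series aggregates wells into per-day means and SEs", {
  m <- expand.grid(well = 1:3, day = c(7, 8, 9))
  m$fg_mean <- 10; m$bg_mean <- 5
  s <- build_series(m)
  expect_s3_class(s, "intensity_series")
  expect_equal(s$fg_se, rep(0, 3))
  expect_equal(s$ratio, rep(2, 3))
  expect_equal(s$n_wells, rep(3, 3))
  # ratio from per-day means, not mean of per-well ratios
  m2 <- data.frame(day = 7, well = 1:2, fg_mean = c(2, 10), bg_mean = c(1, 10))
  expect_equal(build_series(m2)$ratio, 6 / 5.5)
  # single well -> SE missing
  expect_true(is.na(build_series(data.frame(day = 7, well = 1, fg_mean = 1,
                                            bg_mean = 2))$fg_se))
  # day with no usable frames dropped with warning
  m3 <- rbind(m2, data.frame(day = 8, well = 1, fg_mean = NA, bg_mean = 3))
  expect_warning(s3 <- build_series(m3), "dropping")
  expect_equal(s3$day, 7)
})

test_that("two-phase fit recovers exact piecewise-linear data", {
  # fixture built from the printed uptake slopes: 0.1655/day on days 7-11,
  # 0.0382/day on days 11-28, continuous at the break
  d <- 7:28
  y <- ifelse(d <= 11, 0.2 + 0.1655 * (d - 7),
              0.2 + 0.1655 * 4 + 0.0382 * (d - 11))
  f <- fit_two_phase(data.frame(day = d, ratio = y))
  expect_equal(f$break_day, 11)
  expect_equal(f$slope1, 0.1655, tolerance = 1e-10)
  expect_equal(f$slope2, 0.0382, tolerance = 1e-10)
  expect_gt(f$slope1 / f$slope2, 4)
  # single straight line: identical slopes, any break
  y2 <- 1 + 0.05 * d
  f2 <- fit_two_phase(data.frame(day = d, ratio = y2))
  expect_lt(abs(f2$slope1 - f2$slope2), 1e-8)
  # continuity-constrained variant agrees on continuous data
  fc <- fit_two_phase(data.frame(day = d, ratio = y), continuity = TRUE)
  expect_equal(fc$slope1, 0.1655, tolerance = 1e-8)
  expect_equal(fc$slope2, 0.0382, tolerance = 1e-8)
  expect_error(fit_two_phase(data.frame(day = 1:4, ratio = 1:4),
                             candidate_breaks = 1), "3 points")
})

test_that("chosen break is the exhaustive residual minimiser", {
  set.seed(5)
  d <- 7:28
  y <- log(d) + rnorm(length(d), 0, 0.05)
  f <- fit_two_phase(data.frame(day = d, ratio = y))
  # independent brute-force re-evaluation over every legal break
  rss_all <- vapply(d, function(b) {
    i1 <- d <= b; i2 <- d >= b
    if (sum(i1) < 3 || sum(i2) < 3) return(Inf)
    sum(resid(lm(y[i1] ~ d[i1]))^2) + sum(resid(lm(y[i2] ~ d[i2]))^2)
  }, numeric(1))
  expect_equal(f$rss, min(rss_all), tolerance = 1e-12)
  expect_equal(f$break_day, d[which.min(rss_all)])
})

test_that("peak and crossover detection honour their contracts", {
  mk <- function(fg, bg = rev(fg), day = seq_along(fg) + 6) {
    s <- data.frame(day = day, fg_mean = fg, bg_mean = bg)
    class(s) <- c("intensity_series", "data.frame")
    s
  }
  # strictly rising series: censored at the final day
  p1 <- detect_peak_day(mk(c(1, 2, 4, 8, 16)))
  expect_equal(p1$peak_day, 11)
  expect_true(p1$censored)
  # flat series: first day, not censored
  p2 <- detect_peak_day(mk(rep(3, 5)))
  expect_equal(p2$peak_day, 7)
  expect_false(p2$censored)
  # crossover: censored when fg stays below bg
  expect_true(crossover_day(mk(c(1, 2, 3), c(9, 9, 9)))$censored)
  # exact touch at a sampled day
  expect_equal(crossover_day(mk(c(1, 5, 9), c(9, 5, 1)))$day, 8)
  # interpolated crossing between days 8 and 9
  x <- crossover_day(mk(c(0, 2, 6), c(9, 5, 3)))
  expect_gt(x$day, 8); expect_lt(x$day, 9)
  expect_equal(x$day, 8.5)  # fg-bg goes -3 -> +3 between days 8 and 9
})

test_that("generator-default kinetics: two-phase uptake and ordering", {
  # measurement-level series over the extended day 7-28 run
  n_ok <- 0; ordered <- 0
  for (s in 1:20) {
    st <- simulate_study(study_config(render = FALSE, imaging_days = 7:28,
                                      seed = 100 + s))
    ser <- truth_series(st)
    f <- fit_two_phase(ser)
    if (f$slope1 / f$slope2 > 4) n_ok <- n_ok + 1
    pk <- detect_peak_day(ser)
    xo <- crossover_day(ser)
    if (!xo$censored && xo$day > 7 && xo$day < pk$peak_day) {
      ordered <- ordered + 1
    }
  }
  expect_gte(n_ok / 20, 0.8)
  expect_equal(ordered, 20)   # crossover strictly inside (delivery, peak)
})

test_that("slope ordering slope1 > slope2 > 0 holds across many seeds", {
  ok <- vapply(1:50, function(s) {
    st <- simulate_study(study_config(render = FALSE, imaging_days = 7:28,
                                      seed = 2000 + s))
    f <- fit_two_phase(truth_series(st))
    f$slope1 > f$slope2 && f$slope2 > 0
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("monolayer truth series is flat under the two-phase lens", {
  st <- study_config(render = FALSE)
  ml <- generate_monolayer_series(st, seed = 9)
  tr <- aggregate(intensity ~ day, ml$truth, mean)
  sl <- coef(lm(intensity ~ day, tr))[[2]]
  expect_lt(abs(sl) / tr$intensity[tr$day == 1], 0.02)
})

test_that("nodule/ECM ratio is invariant to global intensity rescaling", {
  cfg <- tiny_config(seed = 21)
  pop <- evolve_population(10, cfg, seed = 21)
  fr <- suppressWarnings(render_frame(pop, "fluorescence",
                                      list(ecm = 50, nodule = 70), cfg,
                                      seed = 3))
  ctrl <- suppressWarnings(render_frame(pop, "fluorescence",
                                        list(ecm = 0, nodule = 2), cfg,
                                        seed = 4))
  masks <- .mask_pair_from_labels(fr$labels)
  r <- function(im, cl) {
    cm <- compartment_means(background_subtract(im, cl), masks)
    cm$fg_mean / cm$bg_mean
  }
  r1 <- r(fr$image, mean(ctrl$image))
  r2 <- r(fr$image * 3.7, mean(ctrl$image * 3.7))
  expect_equal(r1, r2, tolerance = 1e-12)
})
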