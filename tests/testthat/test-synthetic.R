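test_that("compartment transfer: boundary values and conservation", {
  p <- study_config()$transfer
  # at delivery: everything in the ECM
  ci <- compartment_intensities(p$t_delivery, p)
  expect_equal(ci$ecm, p$E_floor + p$E0)
  expect_equal(ci$nodule, p$autofluor)
  # far future: complete transfer (eta = 1)
  ci_inf <- compartment_intensities(p$t_delivery + 1e4, p)
  expect_equal(ci_inf$ecm, p$E_floor, tolerance = 1e-12)
  expect_equal(ci_inf$nodule, p$autofluor + p$E0, tolerance = 1e-12)
  # exact analytic conservation at all times with eta = 1
  tt <- seq(p$t_delivery, p$t_delivery + 30, by = 0.1)
  ci_t <- compartment_intensities(tt, p)
  expect_equal((ci_t$ecm - p$E_floor) + (ci_t$nodule - p$autofluor),
               rep(p$E0, length(tt)), tolerance = 1e-12)
  # default k = ln(20)/6: 95% transfer six days post-delivery
  ci6 <- compartment_intensities(p$t_delivery + 6, p)
  expect_equal((ci6$nodule - p$autofluor) / p$E0, 0.95, tolerance = 1e-12)
  expect_error(compartment_intensities(p$t_delivery - 0.5, p), "delivery")
})

test_that("nodule-compartment truth plateaus after the 95%-transfer day", {
  p <- study_config()$transfer
  days <- p$t_delivery + 0:9
  nod <- compartment_intensities(days, p)$nodule
  ratio <- compartment_intensities(days, p)$nodule /
    compartment_intensities(days, p)$ecm
  d95 <- which(days == p$t_delivery + 6)
  expect_true(all(diff(ratio[1:d95]) > 0))          # rising to the peak day
  rel <- diff(nod) / nod[-length(nod)]
  expect_true(all(rel[d95:(length(days) - 1)] < 0.02))  # <2%/day plateau
})

test_that("day-0 populations are single cells around 19.3 um", {
  cfg <- study_config(frame_dim = c(512L, 512L), n_cells = 60L)
  diam <- unlist(lapply(1:20, function(s) {
    pop <- evolve_population(0, cfg, seed = s)
    expect_true(all(pop$is_single_cell))
    2 * sqrt(pop$area_um2 / pi)
  }))
  expect_lt(abs(mean(diam) - 19.3) / 19.3, 0.05)
})

test_that("bimodality emerges by day 7 and freezes without growth", {
  cfg <- study_config(frame_dim = c(768L, 768L), n_cells = 60L)
  pref <- vapply(1:20, function(s) {
    pop <- evolve_population(7, cfg, seed = s)
    preferred_components(fit_size_mixture(log(pop$area_um2)))
  }, integer(1))
  expect_gte(mean(pref == 2L), 0.9)
  # frozen dynamics: day 7 indistinguishable from day 0
  cfg0 <- study_config(frame_dim = c(512L, 512L), n_cells = 60L,
                       growth = list(A = 0), aggregation = list(enabled = FALSE))
  pvals <- vapply(1:20, function(s) {
    a0 <- evolve_population(0, cfg0, seed = s)
    a7 <- evolve_population(7, cfg0, seed = 1000 + s)
    suppressWarnings(stats::ks.test(log(a0$area_um2),
                                    log(a7$area_um2))$p.value)
  }, numeric(1))
  expect_gte(mean(pvals > 0.01), 0.9)
})

test_that("rendered frames: exact zero-noise levels and truth masks", {
  cfg <- noiseless_config(pixel_size_um = 1)
  nod <- one_nodule(80, 80, a_um = 30, b_um = 20, orientation = 0.4)
  fr <- render_frame(nod, "fluorescence", list(ecm = 17.5, nodule = 93.25), cfg)
  expect_equal(mean(fr$image[fr$labels > 0]), 93.25)     # interior exact
  expect_equal(mean(fr$image[fr$labels == 0]), 17.5)
  # no-treatment control (E0 = 0): frame = offset + autofluor contribution
  cfg2 <- cfg; cfg2$noise$offset <- 5
  ctrl <- render_frame(nod, "fluorescence",
                       list(ecm = 0, nodule = cfg$transfer$autofluor), cfg2)
  expect_equal(mean(ctrl$image[ctrl$labels == 0]), 5)
  expect_equal(mean(ctrl$image[ctrl$labels > 0]),
               5 + cfg$transfer$autofluor)
  # rasterized mask area tracks the analytic ellipse area
  rast <- sum(fr$labels > 0)
  expect_lt(abs(rast - pi * 30 * 20), pi * (30 + 20))  # within ~1 px ring
})

test_that("foreground mean is an unbiased estimate under default noise", {
  cfg <- study_config(frame_dim = c(160L, 160L), pixel_size_um = 1)
  nod <- one_nodule(80, 80, a_um = 30, b_um = 25)
  bias <- vapply(1:20, function(s) {
    fr <- render_frame(nod, "fluorescence", list(ecm = 20, nodule = 90),
                       cfg, seed = s)
    mean(fr$image[fr$labels > 0]) - cfg$noise$offset - 90
  }, numeric(1))
  expect_lt(abs(mean(bias)) / 90, 0.01)
})

test_that("monolayer series saturates within a day and stays flat", {
  cfg <- study_config(render = FALSE)
  ml <- generate_monolayer_series(cfg, seed = 1)
  tr <- aggregate(signal ~ day, ml$truth, mean)
  expect_gte(tr$signal[tr$day == 1] / cfg$monolayer$E0, 0.95)
  r51 <- tr$signal[tr$day == 5] / tr$signal[tr$day == 1]
  expect_true(r51 >= 0.95 && r51 <= 1.05)
  # flat-uptake contract: relative slope over days 1-8 below 2%/day
  sl <- coef(lm(signal ~ day, tr))[[2]]
  expect_lt(abs(sl) / tr$signal[tr$day == 1], 0.02)
  # E0 = 0: zero-signal series
  ml0 <- generate_monolayer_series(
    study_config(render = FALSE, monolayer = list(E0 = 0)), seed = 2)
  expect_true(all(ml0$truth$signal == 0))
})

test_that("lysate absorbance is proportional to nodule GNP content", {
  cfg <- study_config()
  p <- cfg$transfer
  exact <- generate_lysate_table(cfg, noise_cv = 0, seed = 1)
  content <- p$eta * p$E0 * (1 - exp(-p$k * (exact$day - p$t_delivery)))
  expect_equal(exact$absorbance, cfg$lysate$scale * content)
  # default CV: monotone rise in replicate means over the transfer window
  # (delivery day through the 95%-transfer day)
  window_max <- p$t_delivery + 6
  rho <- vapply(1:20, function(s) {
    tab <- generate_lysate_table(cfg, seed = s)
    m <- aggregate(absorbance ~ day, tab[tab$day <= window_max, ], mean)
    suppressWarnings(cor(m$day, m$absorbance, method = "spearman"))
  }, numeric(1))
  expect_gte(mean(rho), 0.9)
  # noisier assay keeps the trend in most seeds
  pos <- vapply(1:20, function(s) {
    tab <- generate_lysate_table(cfg, noise_cv = 0.3, seed = s)
    m <- aggregate(absorbance ~ day, tab[tab$day <= window_max, ], mean)
    suppressWarnings(cor(m$day, m$absorbance, method = "spearman")) > 0.7
  }, logical(1))
  expect_gte(mean(pos), 0.8)
  expect_error(generate_lysate_table(cfg, harvest_days = 5), "delivery")
})

test_that("colony counts are binomial draws at the arm survival levels", {
  expect_true(all(generate_colony_counts(c(a = 1), 500, 3,
                                         seed = 1)$colonies == 500))
  expect_true(all(generate_colony_counts(c(a = 0), 500, 3,
                                         seed = 1)$colonies == 0))
  expect_error(generate_colony_counts(c(a = 1.2)), "\\[0, 1\\]")
  # recovery of a printed survival factor within its binomial 99% CI
  tab <- generate_colony_counts(c(arm = 0.680), 1000L, 3L, seed = 5)
  sf <- survival_factor(tab$colonies, 1000L)
  ci99 <- 2.576 * sqrt(0.680 * 0.320 / 3000)
  expect_lt(abs(sf$sf - 0.680), ci99)
})

test_that("the same master seed reproduces the study bit-identically", {
  cfg <- tiny_config(imaging_days = c(0, 7, 10), seed = 11)
  a <- suppressWarnings(simulate_study(cfg))
  b <- suppressWarnings(simulate_study(cfg))
  expect_identical(a$frames, b$frames)
  expect_identical(a$nodules, b$nodules)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$colonies, b$colonies)
  c2 <- suppressWarnings(simulate_study(cfg, seed = 12))
  expect_false(identical(a$frames, c2$frames))
})

test_that("3D truth ratio rises to the plateau day in every study", {
  st <- simulate_study(study_config(render = FALSE, imaging_days = 7:16,
                                    seed = 3))
  ser <- truth_series(st)
  d95 <- st$config$transfer$t_delivery + 6
  expect_true(all(diff(ser$ratio[ser$day <= d95]) > 0))
})
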