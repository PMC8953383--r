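# Scaled-down study configurations used throughout the suite. Frame size
# and per-frame cell counts are sampling sizes, not model parameters: the
# distributions, rates and noise levels stay at package defaults.

.cfg_with <- function(defaults, dots) {
  do.call(study_config, utils::modifyList(defaults, dots))
}

tiny_config <- function(...) {
  .cfg_with(list(frame_dim = c(160L, 160L), n_cells = 6L), list(...))
}

# zero-noise rendering for exactness oracles
noiseless_config <- function(...) {
  .cfg_with(list(frame_dim = c(160L, 160L), n_cells = 6L,
                 noise = list(gain = 0, read_sd = 0, offset = 0)), list(...))
}

# kinetics-focused schedule (delivery day onward)
kinetics_config <- function(seed, ...) {
  .cfg_with(list(frame_dim = c(224L, 224L), n_cells = 8L,
                 imaging_days = 7:16, seed = seed), list(...))
}

# single-nodule scene for geometric oracles
one_nodule <- function(row, col, a_um, b_um, orientation = 0) {
  out <- data.frame(nodule_id = 1L, row = row, col = col, a_um = a_um,
                    b_um = b_um, orientation = orientation,
                    area_um2 = pi * a_um * b_um, component = "large",
                    is_single_cell = FALSE, birth_day = 0)
  class(out) <- c("scene_nodules", "data.frame")
  out
}

# mask pair built directly from a truth label image
.mask_pair_from_labels <- function(labels) {
  storage.mode(labels) <- "integer"
  spheroidGNP:::.mask_pair(labels > 0L, labels, NA_real_)
}

# measurement-level intensity series from a non-rendered study's painted
# per-well compartment truth
truth_series <- function(study) {
  ints <- study$intensities
  tr <- ints[ints$treated & ints$day >= study$config$transfer$t_delivery, ]
  build_series(data.frame(day = tr$day, well = tr$well,
                          fg_mean = tr$nodule_intensity,
                          bg_mean = tr$ecm_intensity))
}
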