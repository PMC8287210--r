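# Shared fixtures: small volumes and a compact phantom configuration
# used across the module tests.

vol <- function(values, affine = diag(4), unit = "") {
  if (!is.array(values)) values <- array(values, dim = c(length(values), 1, 1))
  volume_map(values, affine, unit)
}

const_vol <- function(value, dims = c(4, 4, 4), affine = diag(4)) {
  volume_map(array(value, dim = dims), affine)
}

# Small phantom: 16^3 grid, 6 ROIs + calibration region, 3 subjects.
small_phantom_config <- function(n_subjects = 3, n_sessions = 2,
                                 seed = 7, ...) {
  phantom_config(grid_shape = c(16L, 16L, 16L),
                 n_subjects = n_subjects, n_sessions = n_sessions,
                 roi_layout = default_roi_layout(c(16L, 16L, 16L),
                                                 n = c(3L, 2L, 1L)),
                 seed = seed, ...)
}

noiseless_args <- list(
  map_noise_sd = c(mtsat = 0, nu_icvf = 0, nu_iso = 0),
  ceiling_prob_fn = function(snr) rep(0, length(snr)))

noiseless_phantom_config <- function(b1_amplitude = 0, ...) {
  do.call(small_phantom_config,
          c(list(b1_amplitude = b1_amplitude, ...), noiseless_args))
}
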