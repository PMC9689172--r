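# Shared fixtures: scaled-down scanner geometry and network so that unit
# tests exercise the same code paths as the full 1247x256 / 1024-sample
# defaults at a fraction of the cost.

small_sim <- function(n_axial = 300L, n_lines = 16L) {
  sim_config(n_axial = n_axial, n_lines = n_lines)
}

# ROI/window pair compatible with small_sim() and small_cnn()
small_roi <- function() roi_spec(axial_start = 12L, axial_len = 276L,
                                 line_start = 0L, line_len = 16L)

small_cnn <- function() cnn_config(input_len = 256L)

# Simulated mini-cohort written to a fresh temp dir
small_cohort <- function(counts, seed = 1L, config = small_sim()) {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  simulate_cohort(counts, config, seed = seed, out_dir = dir)
}

# Quick separable two-class segment set for training tests: class 0 is
# narrow-band around mid-scale, class 1 spans the full [0,1] range.
separable_segments <- function(n = 400L, len = 256L, seed = 42L) {
  stopifnot(n %% 2L == 0L)
  set.seed(seed)
  x <- rbind(matrix(runif(n / 2 * len, 0.4, 0.6), n / 2),
             matrix(runif(n / 2 * len, 0, 1), n / 2))
  list(x = x, y = rep(0:1, each = n / 2))
}
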