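# Shared synthetic fixtures, all generated in code at test time.

# Noise-free acquisition configuration for deterministic geometry checks.
quiet_config <- function(n_frames = 1, seed = 1, ...) {
  sim_config(
    n_frames = n_frames, seed = seed,
    noise_model = list(poisson_scale = Inf, gaussian_sd = 0), ...
  )
}

# Fine-grained noise-free configuration for STED-like fields.
sted_config <- function(seed = 1, noise = FALSE) {
  sim_config(
    voxel_spacing = c(0.05, 0.05, 0.1), seed = seed,
    noise_model = if (noise) list(poisson_scale = 50, gaussian_sd = 0.02)
    else list(poisson_scale = Inf, gaussian_sd = 0)
  )
}

# One synthetic couple plus its truth-derived annotation.
make_annotated_couple <- function(label, config = quiet_config(),
                                  script = pattern_script(label)) {
  cc <- make_cell_couple(config, script)
  cc$annotation <- synapse_annotation(
    cc$truth$coupling_frame, cc$truth$interface_center, cc$truth$cell_rear
  )
  cc
}

# Rodrigues rotation matrix (test-side copy for constructing tilted cells).
rotation_matrix_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- rbind(
    c(0, -axis[3], axis[2]),
    c(axis[3], 0, -axis[1]),
    c(-axis[2], axis[1], 0)
  )
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# Binomial 95% CI half-width around a scheduled proportion.
binom_ci_halfwidth <- function(p, n) 1.96 * sqrt(p * (1 - p) / n)
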