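# shared fixtures and independent oracles used across the test files

`%||%` <- function(a, b) if (is.null(a)) b else a

p14 <- protocol_14b()

# independent Mann-Whitney-form AUC (rank arithmetic, no pROC)
oracle_auc <- function(scores, y) {
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# one Rician-corrupted voxel signal at the protocol's averaging schedule
rician_voxel <- function(clean, protocol, sigma) {
  vapply(seq_along(clean), function(j) {
    nav <- protocol$n_averages[j]
    mean(sqrt((clean[j] + rnorm(nav, sd = sigma))^2 +
                rnorm(nav, sd = sigma)^2))
  }, numeric(1))
}

# small single-lesion phantom used by fitting / quality tests
small_phantom <- function(noise_sigma = 0, seed = 1L,
                          lesion = froc_params(0.85, 0.73, 3.5)) {
  phantom_spec(
    grid_shape = c(12, 8, 4), voxel_size = c(1, 1, 4),
    lesions = list(list(center = c(8, 4, 2), semi_axes = c(2.5, 2.5, 1),
                        params = lesion, s0 = 100)),
    background = list(params = froc_params(1.8, 0.95, 5), s0 = 60),
    air_fraction = 0.25, noise_sigma = noise_sigma, seed = seed)
}
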