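# shared fixtures, all generated in code

# small noiseless two-compartment mean-signal phantom (effective rank 2)
two_compartment_means <- function(n_voxels = 150, sigma = 0, seed = 1) {
  make_shell_means(phantom_config(
    n_voxels = n_voxels,
    compartments = list(list(d = 0.8e-3), list(d = 2.5e-3)),
    sigma = sigma, seed = seed))
}

# mono-exponential phantom with per-voxel diffusivity (well-conditioned SVD)
mono_exponential_means <- function(n_voxels = 200, seed = 2,
                                   d_range = c(0.5e-3, 2e-3)) {
  set.seed(seed + 1000)
  dv <- stats::runif(n_voxels, d_range[1], d_range[2])
  make_shell_means(phantom_config(
    n_voxels = n_voxels,
    compartments = list(list(d = dv, f = 1)),
    sigma = 0, seed = seed))
}

# random orthonormal basis of a given size
random_orthonormal <- function(n, seed) {
  set.seed(seed)
  qr.Q(qr(matrix(stats::rnorm(n * n), n)))
}

# tiny direction-resolved phantom: 30 single-fibre + 30 isotropic voxels
mixed_fibre_dwi <- function(seed = 3) {
  f_aniso <- c(rep(1, 30), rep(0, 30))
  make_dwi(phantom_config(
    n_voxels = 60,
    compartments = list(list(ad = 1.9e-3, rd = 0.4e-3, f = f_aniso),
                        list(d = 1.3e-3, f = 1 - f_aniso)),
    bvalues = c(0, 1000, 2500), counts = c(4L, 30L, 40L),
    sigma = 0, seed = seed))
}

# copy of a phantom config with the noise switched off
within_sigma0 <- function(cfg) {
  cfg$sigma <- 0
  cfg
}

# small rotation matrix from an axis-angle pair
rotation_matrix <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}
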