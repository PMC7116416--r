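test_that("even-order coefficient counts follow (l+1)(l+2)/2", {
  expect_equal(n_even_sh_coeffs(0), 1L)
  expect_equal(n_even_sh_coeffs(2), 6L)
  expect_equal(n_even_sh_coeffs(4), 15L)
  expect_equal(n_even_sh_coeffs(6), 28L)
  expect_equal(n_even_sh_coeffs(8), 45L)
  for (l in seq(0, 12, by = 2))
    expect_equal(n_even_sh_coeffs(l), (l + 1) * (l + 2) / 2)
  expect_error(n_even_sh_coeffs(3), "even")
})

test_that("SH fit of a constant puts everything in the l=0 term", {
  dirs <- generate_directions(60, seed = 2)$vectors
  cf <- sh_fit(dirs, rep(1, 60), 4)
  expect_equal(cf[1], sqrt(4 * pi), tolerance = 1e-10)
  expect_lt(max(abs(cf[-1])), 1e-10)
})

test_that("SH fit reproduces a single basis function and round-trips", {
  dirs <- generate_directions(60, seed = 2)$vectors
  B <- sh_basis_matrix(dirs, 4)
  # unit coefficient on one l=2 basis function
  unitc <- numeric(15)
  unitc[5] <- 1
  cf <- sh_fit(dirs, as.vector(B %*% unitc), 4)
  expect_equal(cf[5], 1, tolerance = 1e-8)
  expect_lt(max(abs(cf[-5])), 1e-8)
  # random band-limited round trip
  set.seed(14)
  c0 <- rnorm(15)
  cf2 <- sh_fit(dirs, as.vector(B %*% c0), 4)
  expect_equal(as.numeric(cf2), c0, tolerance = 1e-6)
  expect_error(sh_fit(dirs[1:10, ], rep(1, 10), 4), "underdetermined")
})

test_that("power spectrum is a per-order sum of squares and rotation-invariant", {
  l <- c(0, rep(2, 5))
  pw <- rotational_power_spectrum(c(0, 0, 3, 0, 0, 0), l = l)
  expect_equal(unname(pw), c(0, 9))
  expect_equal(unname(rotational_power_spectrum(rep(0, 6), l = l)), c(0, 0))

  dirs <- generate_directions(60, seed = 2)$vectors
  B <- sh_basis_matrix(dirs, 4)
  set.seed(15)
  c0 <- rnorm(15)
  pw0 <- rotational_power_spectrum(sh_fit(dirs, as.vector(B %*% c0), 4))
  for (seed in 1:5) {
    set.seed(seed)
    R <- rotation_matrix(rnorm(3), runif(1, 0, pi))
    rotated <- as.vector(sh_basis_matrix(dirs %*% R, 4) %*% c0)
    pw1 <- rotational_power_spectrum(sh_fit(dirs, rotated, 4))
    expect_lt(max(abs(pw1 - pw0)), 1e-8)
  }
})

test_that("detectability analysis finds the band limit of noiseless signals", {
  dirs <- generate_directions(60, seed = 2)$vectors
  for (lmax_true in c(2, 4)) {
    p <- n_even_sh_coeffs(lmax_true)
    set.seed(20 + lmax_true)
    c0 <- rnorm(p)
    vals <- as.vector(sh_basis_matrix(dirs, lmax_true) %*% c0)
    spec <- angular_spectrum(dirs, vals, sigma = 0.01 * stats::sd(vals),
                             lmax = 8, seed = 1)
    expect_equal(spec$detectable_lmax, lmax_true)
    expect_equal(spec$min_directions, n_even_sh_coeffs(lmax_true))
  }
})

test_that("pure noise is detectable at order 0 only", {
  dirs <- generate_directions(60, seed = 2)$vectors
  set.seed(9)
  noise <- rnorm(60)
  spec <- angular_spectrum(dirs, noise, sigma = 1, lmax = 8, seed = 3)
  expect_equal(spec$detectable_lmax, 0L)
  expect_equal(spec$min_directions, 1L)
})

test_that("electrostatic repulsion gives deterministic well-spread sets", {
  d1 <- generate_directions(1)
  expect_equal(d1$energy, 0)
  expect_equal(sum(d1$vectors^2), 1)

  # three directions relax to a mutually orthogonal triad
  d3 <- generate_directions(3, seed = 1)
  dots <- abs(tcrossprod(d3$vectors))
  diag(dots) <- 0
  expect_lt(acos(pmin(max(dots), 1)) * 180 / pi - 90, 1)
  expect_gt(acos(pmin(max(dots), 1)) * 180 / pi, 89)

  # energy non-increasing along the descent
  d20 <- generate_directions(20, seed = 4)
  expect_true(all(diff(d20$energy_trace) <= 0))
  expect_equal(sqrt(rowSums(d20$vectors^2)), rep(1, 20), tolerance = 1e-6)

  # deterministic per seed
  expect_identical(generate_directions(15, seed = 6)$vectors,
                   generate_directions(15, seed = 6)$vectors)

  # n=50 within 5% of the best minimum angle found by independent restarts
  # (multi-restart optimum at development time: 19.78 degrees)
  d50 <- generate_directions(50, seed = 1)
  expect_gt(min_pairwise_angle(d50$vectors), 0.95 * 19.78)
})

test_that("single-fibre selection matches the phantom labels", {
  dwi <- mixed_fibre_dwi()
  sel <- select_single_fibre_voxels(dwi$dataset)
  expect_equal(sort(sel$voxels), which(dwi$truth$single_fibre))
  expect_equal(unname(sel$stage_counts["masked"]), 60L)

  # realigned average is zonal: m != 0 coefficients vanish
  co <- as.numeric(sel$mean_coefficients)
  l <- attr(sel$mean_coefficients, "l")
  m0 <- c(1, 4, 11)          # m = 0 columns for l = 0, 2, 4
  expect_gt(min(abs(co[m0[1:2]])), 1)
  expect_lt(max(abs(co[-m0])), 0.1)

  # isotropic phantom: no voxel survives, error reports stage counts
  iso <- make_dwi(phantom_config(n_voxels = 20,
    compartments = list(list(d = 1.3e-3)),
    bvalues = c(0, 1000, 2500), counts = c(4L, 30L, 40L),
    sigma = 0, seed = 3))
  expect_error(select_single_fibre_voxels(iso$dataset),
               "no single-fibre voxels")
})

test_that("tensor fit recovers FA of a noiseless single tensor", {
  ad <- 1.9e-3
  rd <- 0.4e-3
  dwi <- make_dwi(phantom_config(n_voxels = 4,
    compartments = list(list(ad = ad, rd = rd)),
    bvalues = c(0, 1000), counts = c(4L, 30L), sigma = 0, seed = 5))
  d <- dim(dwi$dataset$volumes)
  sig <- t(matrix(dwi$dataset$volumes, prod(d[1:3]), d[4]))
  tens <- fit_tensor(sig, dwi$dataset$bvals, dwi$dataset$bvecs)
  lam <- c(ad, rd, rd)
  fa_true <- sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
  expect_equal(tens$fa, rep(fa_true, 4), tolerance = 0.02)
  expect_equal(abs(tens$e1[3, ]), rep(1, 4), tolerance = 1e-3)
})
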