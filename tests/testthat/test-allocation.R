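test_that("closed-form fractions match hand-derived cases", {
  expect_equal(optimal_fractions(diag(2), c(1, 1)), c(0.5, 0.5))
  # eps (1, 0.5) -> n* proportional to (1, 2)
  expect_equal(optimal_fractions(diag(2), c(1, 0.5)), c(1, 2) / 3)
  expect_error(optimal_fractions(diag(2), c(1, 0)), "zero effect size")
})

test_that("fractions are independent of sigma and total budget", {
  basis <- shell_basis(two_compartment_means(n_voxels = 100)$data)
  ref <- NULL
  for (sigma in c(1, 5)) {
    for (n_total in c(50, 500)) {
      al <- allocate_volumes(basis, noise_model(sigma), n_total,
                             n_components = 2)
      if (is.null(ref)) ref <- al$fractions
      expect_identical(al$fractions, ref)   # bit-identical
      expect_equal(sum(al$counts), n_total)
    }
  }
  expect_equal(sum(ref), 1, tolerance = 1e-12)
})

test_that("largest-remainder integerisation is budget-exact and deterministic", {
  expect_equal(integerise_counts(c(1, 2) / 3, 30), c(10L, 20L))
  # tie: lower shell index receives the extra volume
  expect_equal(integerise_counts(c(0.5, 0.5), 5), c(3L, 2L))
  expect_error(integerise_counts(c(0.5, 0.5), 3, minima = c(2, 2)),
               "infeasible")
  # minima repair keeps the budget and honours the floor
  counts <- integerise_counts(c(0.05, 0.95), 20, minima = c(6, 1),
                              g = c(1, 10))
  expect_equal(sum(counts), 20)
  expect_true(counts[1] >= 6)
})

test_that("permuting shells permutes the fractions identically", {
  H <- random_orthonormal(3, 21)
  eps <- c(1.2, 0.3, 0.08)
  fr <- optimal_fractions(H, eps)
  perm <- c(3, 1, 2)
  expect_equal(optimal_fractions(H[perm, ], eps), fr[perm], tolerance = 1e-12)
})

test_that("brute-force oracle agrees with the closed form", {
  # worked 2-shell case: exact agreement
  bf <- brute_force_allocation(diag(2), noise_model(1), 30, eps = c(1, 0.5))
  expect_equal(bf$counts, c(10L, 20L))
  expect_equal(allocate_volumes(diag(2), noise_model(1), 30,
                                eps = c(1, 0.5))$counts, bf$counts)

  # single shell: everything lands there
  expect_equal(brute_force_allocation(matrix(1), noise_model(1), 12,
                                      eps = 1)$counts, 12L)

  # random instances: integerised closed form within 1% of the exhaustive optimum
  for (seed in 1:25) {
    n_shells <- 2 + seed %% 3
    H <- random_orthonormal(n_shells, seed)
    set.seed(seed + 500)
    eps <- sort(rexp(n_shells) + 0.05, decreasing = TRUE)
    noise <- noise_model(1)
    bf <- brute_force_allocation(H, noise, 30, eps = eps)
    al <- allocate_volumes(H, noise, 30, eps = eps)
    expect_lte(al$sscv, bf$sscv * 1.01)
    expect_gte(al$sscv, bf$sscv - 1e-12)   # oracle is the true optimum
  }
})

test_that("exhaustive optimum never loses to the equal split", {
  for (seed in 1:10) {
    H <- random_orthonormal(3, seed + 40)
    set.seed(seed)
    eps <- rexp(3) + 0.05
    noise <- noise_model(1)
    bf <- brute_force_allocation(H, noise, 30, eps = eps)
    equal_sscv <- sscv(H, eps, noise, rep(10, 3))
    expect_lte(bf$sscv, equal_sscv + 1e-12)
  }
})

test_that("continuous optimum is first-order optimal", {
  for (seed in 1:10) {
    H <- random_orthonormal(3, seed + 80)
    set.seed(seed)
    eps <- rexp(3) + 0.05
    fr <- optimal_fractions(H, eps)
    noise <- noise_model(1)
    base <- sscv(H, eps, noise, fr * 1000)
    # feasible perturbations: move 1% of mass between shell pairs
    for (i in 1:2) for (j in (i + 1):3) {
      d <- numeric(3)
      d[i] <- 0.01 * fr[i]
      d[j] <- -0.01 * fr[i]
      expect_gte(sscv(H, eps, noise, (fr + d) * 1000), base - 1e-10)
      expect_gte(sscv(H, eps, noise, (fr - d) * 1000), base - 1e-10)
    }
  }
})

test_that("composition enumeration guard trips on large problems", {
  expect_error(brute_force_allocation(random_orthonormal(4, 1),
                                      noise_model(1), 500,
                                      eps = c(1, 0.5, 0.2, 0.1)),
               "guard")
})
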