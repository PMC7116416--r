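noise1 <- noise_model(1)

test_that("cost at the measured b-values equals the direct SSCV", {
  ph <- two_compartment_means(n_voxels = 80)
  b <- ph$data$scheme$bvalues
  cost <- protocol_cost(ph$data, b, noise1, timing_model(), n_total = 100,
                        n_components = 2)
  basis <- shell_basis(ph$data)
  fr <- optimal_fractions(basis, n_components = 2)
  direct <- sscv(basis, basis$effect_sizes, noise1, fr * 100,
                 n_components = 2)
  expect_equal(cost, direct, tolerance = 1e-10)
})

test_that("cost is invariant to candidate ordering and penalises degeneracy", {
  ph <- two_compartment_means(n_voxels = 50)
  c1 <- protocol_cost(ph$data, c(0, 800, 2500), noise1)
  c2 <- protocol_cost(ph$data, c(0, 2500, 800), noise1)
  expect_identical(c1, c2)
  # duplicate shells give a large finite penalty, not an error
  pen <- protocol_cost(ph$data, c(0, 800, 805), noise1)
  expect_true(is.finite(pen))
  expect_gt(pen, 1e10)
  expect_gt(protocol_cost(ph$data, c(0, 800, 4500), noise1), 1e10)
  expect_error(protocol_cost(ph$data, c(100, 800), noise1), "b = 0")
})

test_that("allocation-optimal fractions beat the equal split inside the cost", {
  ph <- two_compartment_means(n_voxels = 60)
  b <- c(0, 700, 2800)
  cost_opt <- protocol_cost(ph$data, b, noise1, n_total = 100)
  interp <- interpolate_shell_signal(ph$data, b)
  basis <- shell_basis(interp)
  equal <- sscv(basis, basis$effect_sizes, noise1, rep(100 / 3, 3))
  expect_lte(cost_opt, equal + 1e-12)
})

test_that("simplex search matches a dense grid on a 1-shell phantom", {
  ph <- mono_exponential_means(n_voxels = 150)
  fit <- pchip_fit(ph$data$scheme$bvalues, ph$data$D)
  grid <- seq(20, 4000, by = 1)
  costs <- vapply(grid, function(b)
    protocol_cost(ph$data, c(0, b), noise1, timing_model(),
                  n_components = 2, .fit = fit), 0)
  b_grid <- grid[which.min(costs)]
  p <- optimise_bvalues(ph$data, 1, noise1, timing_model(),
                        n_components = 2, seed = 1, n_starts = 4)
  expect_lt(abs(p$bvalues[2] - b_grid), 10)
  best <- min(vapply(p$search_trace, function(t) t$sscv, 0))
  expect_lte(best, min(costs) + 1e-12)
})

test_that("re-running from the returned optimum is a fixed point", {
  ph <- mono_exponential_means(n_voxels = 100)
  p <- optimise_bvalues(ph$data, 1, noise1, timing_model(),
                        n_components = 2, seed = 1, n_starts = 3)
  p2 <- optimise_bvalues(ph$data, 1, noise1, timing_model(),
                         n_components = 2,
                         starts = matrix(p$bvalues[2], 1, 1))
  expect_equal(p2$bvalues, p$bvalues, tolerance = 1e-6)
})

test_that("T2 penalty never raises the selected maximum b-value", {
  ph <- two_compartment_means(n_voxels = 120)
  noise <- noise_from_snr(ph$data, 30)
  free <- optimise_protocol(ph$data, 2, n_total = 100, noise = noise,
                            t2 = Inf, seed = 1, n_starts = 4)
  pen <- optimise_protocol(ph$data, 2, n_total = 100, noise = noise,
                           t2 = 100, seed = 1, n_starts = 4)
  expect_lte(max(pen$bvalues), max(free$bvalues) + 1e-6)
})

test_that("neonatal-like 3-shell design has the in-vivo structure", {
  cfg <- neonatal_like_preset(n_voxels = 400, sigma = 0)
  ph <- make_shell_means(cfg)
  p <- optimise_protocol(ph$data, 3, n_total = 300, snr_b0 = 30, t2 = 150,
                         seed = 1, n_starts = 4)
  b <- p$bvalues
  expect_true(all(diff(b) > 0))
  # lowest nonzero b below the phantom's 1/MD
  md <- mean(vapply(cfg$compartments, `[[`, 0, "d"))
  expect_lt(b[2], 1 / md)
  # largest allocation fraction on the highest shell
  expect_equal(which.max(p$fractions), length(b))
  expect_equal(sum(p$counts), 300)
  # optimised protocol beats equally spaced shells with equal counts
  equal_b <- seq(0, max(ph$data$scheme$bvalues), length.out = 4)
  equal_cost <- protocol_cost(ph$data, equal_b,
                              noise_from_snr(ph$data, 30),
                              timing_model(t2 = 150), n_total = 300)
  interp <- interpolate_shell_signal(ph$data, b)
  basis <- shell_basis(interp)
  att <- attenuated_effect_sizes(basis$effect_sizes, max(b),
                                 timing_model(t2 = 150))
  opt_cost <- sscv(basis$H, att$eps, noise_from_snr(ph$data, 30),
                   p$fractions * 300)
  expect_lte(opt_cost, equal_cost)
})

test_that("fixed seed gives byte-identical protocol reports", {
  ph <- two_compartment_means(n_voxels = 60)
  run <- function() {
    p <- optimise_protocol(ph$data, 2, n_total = 100, snr_b0 = 30,
                           t2 = 150, seed = 7, n_starts = 3)
    f <- tempfile(fileext = ".json")
    write_protocol_json(p, f)
    readLines(f)
  }
  expect_identical(run(), run())
})

test_that("search input validation", {
  ph <- two_compartment_means(n_voxels = 30)
  expect_error(optimise_bvalues(ph$data, 6, noise1), "between")
  expect_error(optimise_bvalues(ph$data, 5, noise1), "n_shells \\+ 2")
})
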