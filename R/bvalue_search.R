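#' SSCV cost of a candidate set of shell b-values
#'
#' One evaluation of the protocol objective: resample the measured mean
#' signals at the candidate b-values, decompose them into a fresh SVD basis,
#' attenuate the effect sizes by the T2 penalty of the candidate's maximum
#' b-value, allocate the budget optimally across the candidate shells, and
#' return the SSCV at that optimal allocation. With continuous fractions the
#' allocation optimum has the closed form
#' SSCV = sigma^2 (sum_s sqrt(g_s))^2 / N_total.
#'
#' Candidates are sorted internally, so the cost is invariant to the order in
#' which b-values are supplied. Degenerate candidates (two b-values closer
#' than \code{degenerate_tol}) or candidates outside the measured range return
#' a large finite penalty rather than an error, so a simplex search can
#' recover from them.
#'
#' @param data a \code{mean_signal_matrix} of measured shell means.
#' @param candidate_bvals candidate b-values including b = 0, s/mm^2.
#' @param noise a [noise_model()].
#' @param timing a [timing_model()]; its T2 sets the echo-time penalty.
#' @param n_total total volume budget (scales the objective only).
#' @param n_components leading components retained in the SSCV (default: all
#'   = number of candidate shells).
#' @param degenerate_tol minimum separation between shells, s/mm^2.
#' @param .fit optional pre-computed [pchip_fit()] of \code{data} (internal
#'   speed-up for repeated evaluations).
#' @return scalar cost (SSCV at the optimal continuous allocation).
#' @export
protocol_cost <- function(data, candidate_bvals, noise,
                          timing = timing_model(), n_total = 100,
                          n_components = NULL, degenerate_tol = 10,
                          .fit = NULL) {
  b <- sort(as.numeric(candidate_bvals))
  if (abs(b[1]) > 1e-9)
    stop("candidate must include b = 0")
  penalty <- 1e12
  if (any(diff(b) < degenerate_tol))
    return(penalty * (1 + sum(pmax(degenerate_tol - diff(b), 0))))
  rng <- range(data$scheme$bvalues)
  if (b[length(b)] > rng[2] || b[1] < rng[1])
    return(penalty * (1 + (b[length(b)] - rng[2])))

  if (is.null(.fit)) .fit <- pchip_fit(data$scheme$bvalues, data$D)
  D <- pmax(pchip_eval(.fit, b), 0)
  basis <- shell_basis(D, shell_scheme(b, rep(1L, length(b))))
  att <- attenuated_effect_sizes(basis$effect_sizes, max(b), timing)
  eps <- att$eps
  nc <- if (is.null(n_components)) length(b) else min(n_components, length(b))
  if (any(eps[seq_len(nc)] <= 0)) return(penalty)
  g <- shell_sensitivity_weights(basis$H[, seq_len(nc), drop = FALSE],
                                 eps[seq_len(nc)])
  noise$sigma^2 * sum(sqrt(g))^2 / n_total
}

#' Optimise shell b-values for a fixed shell count
#'
#' Searches for the nonzero shell b-values minimising the T2-penalised,
#' allocation-optimised SSCV. The b = 0 shell is fixed; the simplex
#' (Nelder-Mead) search runs in log-b coordinates with multiple seeded starts
#' stratified over the measured b-value range, and the best start wins.
#'
#' @param data a \code{mean_signal_matrix} with at least
#'   \code{n_shells + 2} measured shells.
#' @param n_shells number of nonzero shells to place.
#' @param noise a [noise_model()].
#' @param timing a [timing_model()].
#' @param n_total total volume budget.
#' @param n_components leading components retained (default: n_shells + 1).
#' @param n_starts number of stratified simplex starts (default 8).
#' @param seed integer seed controlling start jitter (default 1).
#' @param maxit Nelder-Mead iteration cap per start (default 500).
#' @param minima per-shell minimum counts applied when integerising.
#' @param starts optional matrix of explicit starting b-values
#'   (rows = starts), overriding the stratified default.
#' @return an object of class \code{dwi_protocol}; see
#'   [optimise_protocol()] for the fields.
#' @export
optimise_bvalues <- function(data, n_shells, noise, timing = timing_model(),
                             n_total = 100, n_components = NULL,
                             n_starts = 8, seed = 1, maxit = 500,
                             minima = NULL, starts = NULL) {
  n_meas <- nrow(data$D)
  if (n_shells < 1 || n_shells > n_meas - 1)
    stop("n_shells must be between 1 and the number of measured shells - 1")
  if (n_meas < n_shells + 2)
    stop("need at least n_shells + 2 measured shells")
  bv <- data$scheme$bvalues
  b_lo <- min(bv[bv > 0])
  b_hi <- max(bv)
  if (is.null(n_components)) {
    # components beyond the measured data's numerical rank carry no signal;
    # excluding them keeps the objective driven by real effects
    sv <- svd(data$D)$d
    n_components <- min(n_shells + 1L, sum(sv > 1e-10 * sv[1]))
  }
  fit <- pchip_fit(bv, data$D)

  # cache keyed on b-values rounded to 0.1 s/mm^2
  cache <- new.env(parent = emptyenv())
  cost_b <- function(b_nonzero) {
    key <- paste(round(b_nonzero, 1), collapse = ",")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- protocol_cost(data, c(0, b_nonzero), noise, timing, n_total,
                         n_components, .fit = fit)
    cache[[key]] <- val
    val
  }
  cost_log <- function(par) cost_b(exp(par))

  if (is.null(starts)) {
    # stratified starts: jittered quantiles of the measured log-b range
    set.seed(seed)
    lo <- log(b_lo)
    hi <- log(b_hi)
    starts <- t(vapply(seq_len(n_starts), function(i) {
      q <- (seq_len(n_shells) - 0.5) / n_shells
      q <- pmin(pmax(q + stats::runif(n_shells, -0.3, 0.3) / n_shells,
                     0.02), 0.98)
      sort(exp(lo + q * (hi - lo)))
    }, numeric(n_shells)))
    if (n_shells == 1L) starts <- matrix(starts, ncol = 1L)
  } else {
    starts <- matrix(starts, ncol = n_shells)
  }

  trace <- vector("list", nrow(starts))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    # optim warns that 1-D Nelder-Mead can be unreliable; the multi-start
    # strategy plus the grid cross-checks in the tests cover that case
    res <- suppressWarnings(
      stats::optim(log(starts[i, ]), cost_log, method = "Nelder-Mead",
                   control = list(maxit = maxit, reltol = 1e-9)))
    cand <- list(start = starts[i, ], bvalues = sort(exp(res$par)),
                 sscv = res$value, iterations = res$counts[["function"]],
                 converged = res$convergence == 0)
    trace[[i]] <- cand
    if (is.null(best) || cand$sscv < best$sscv) best <- cand
  }
  if (is.null(best) || !is.finite(best$sscv))
    stop("b-value search failed from every start; trace attached",
         call. = FALSE)

  build_protocol(data, c(0, best$bvalues), noise, timing, n_total,
                 n_components, minima, trace)
}

# assemble the full report for a final set of b-values
build_protocol <- function(data, bvalues, noise, timing, n_total,
                           n_components, minima, trace) {
  rng <- range(data$scheme$bvalues)
  bvalues <- pmin(pmax(bvalues, rng[1]), rng[2])   # guard float overshoot
  fit <- pchip_fit(data$scheme$bvalues, data$D)
  D <- pmax(pchip_eval(fit, bvalues), 0)
  basis <- shell_basis(D, shell_scheme(bvalues, rep(1L, length(bvalues))))
  att <- attenuated_effect_sizes(basis$effect_sizes, max(bvalues), timing)
  nc <- if (is.null(n_components)) length(bvalues)
        else min(n_components, length(bvalues))
  alloc <- allocate_volumes(basis$H, noise, n_total, eps = att$eps,
                            minima = minima, n_components = nc)
  scheme <- shell_scheme(bvalues, alloc$counts)
  sigma_w <- coefficient_covariance(basis$H[, seq_len(nc), drop = FALSE],
                                    noise, scheme)
  cvs <- coefficient_cv(sigma_w, att$eps[seq_len(nc)])
  structure(
    list(bvalues = bvalues, fractions = alloc$fractions,
         counts = alloc$counts, n_total = n_total,
         sscv = sum(cvs$cv^2), cv = cvs$cv, cnr = cvs$cnr,
         te = att$te, attenuation = att$attenuation, t2 = timing$t2,
         sigma = noise$sigma, n_components = nc, basis = basis,
         search_trace = trace),
    class = "dwi_protocol"
  )
}

#' Design an optimal multi-shell protocol
#'
#' The top-level fitting function: given measured (or synthetic) mean shell
#' signals, a noise level and a scan budget, returns the optimised protocol
#' for a fixed number of nonzero shells -- shell b-values from the simplex
#' search, per-shell volume fractions and integer counts from the Lagrange
#' allocation, echo time and T2 attenuation for the selected maximum b-value,
#' and per-component CNR at the integer counts.
#'
#' @param data a \code{mean_signal_matrix}.
#' @param n_shells number of nonzero b-value shells (typically 2, 3 or 4).
#' @param n_total total number of volumes the scan time allows.
#' @param snr_b0 SNR of the b = 0 images, used to set the noise level from
#'   the data's own b = 0 signal; alternatively pass \code{noise}.
#' @param t2 tissue T2 in ms (\code{Inf} disables the echo-time penalty).
#' @param noise a [noise_model()] (overrides \code{snr_b0}).
#' @param timing a [timing_model()]; its \code{t2} is overridden by \code{t2}.
#' @param minima per-shell minimum counts, e.g. angular sampling minima from
#'   [detectable_lmax()].
#' @param ... further arguments passed to [optimise_bvalues()]
#'   (\code{n_starts}, \code{seed}, \code{maxit}, \code{n_components}).
#' @return a \code{dwi_protocol} object with print, summary and plot methods.
#' @examples
#' cfg <- neonatal_like_preset(n_voxels = 200, sigma = 0)
#' ms <- make_shell_means(cfg)$data
#' p <- optimise_protocol(ms, n_shells = 2, n_total = 100, snr_b0 = 30,
#'                        t2 = 150, n_starts = 2)
#' print(p)
#' @export
optimise_protocol <- function(data, n_shells, n_total = 100, snr_b0 = 30,
                              t2 = Inf, noise = NULL,
                              timing = timing_model(), minima = NULL, ...) {
  if (is.null(noise)) noise <- noise_from_snr(data, snr_b0)
  timing$t2 <- t2
  optimise_bvalues(data, n_shells, noise, timing, n_total = n_total,
                   minima = minima, ...)
}

#' @export
print.dwi_protocol <- function(x, ...) {
  cat(sprintf("Optimised multi-shell protocol: b=0 + %d shells, %d volumes\n",
              length(x$bvalues) - 1L, x$n_total))
  tab <- rbind(`b-value (s/mm^2)` = round(x$bvalues),
               `fraction (%)` = round(100 * x$fractions),
               `volumes` = x$counts)
  colnames(tab) <- paste0("shell", seq_along(x$bvalues) - 1L)
  print(tab)
  cat(sprintf("TE = %.1f ms, T2 attenuation = %.3f (T2 = %s)\n",
              x$te, x$attenuation,
              if (is.infinite(x$t2)) "ignored" else paste0(x$t2, " ms")))
  cat("CNR per component:", paste(signif(x$cnr, 3), collapse = ", "), "\n")
  cat(sprintf("SSCV = %.6g\n", x$sscv))
  invisible(x)
}

#' @export
summary.dwi_protocol <- function(object, ...) {
  print(object)
  cat("\nSearch starts:\n")
  for (i in seq_along(object$search_trace)) {
    tr <- object$search_trace[[i]]
    cat(sprintf("  start %d: b = (%s) -> (%s), SSCV %.6g, %d evals\n",
                i, paste(round(tr$start), collapse = ", "),
                paste(round(tr$bvalues), collapse = ", "),
                tr$sscv, tr$iterations))
  }
  invisible(object)
}

#' @export
plot.dwi_protocol <- function(x, ...) {
  plot(x$basis, ...)
  graphics::abline(v = x$bvalues, lty = 3)
  invisible(x)
}

#' Serialise a protocol report to JSON
#'
#' @param x a \code{dwi_protocol}.
#' @param path output path.
#' @export
write_protocol_json <- function(x, path) {
  rep <- list(
    bvalues = x$bvalues, fractions = x$fractions, counts = x$counts,
    n_total = x$n_total, sscv = x$sscv, cv = x$cv, cnr = x$cnr,
    te_ms = x$te, attenuation = x$attenuation,
    t2_ms = if (is.infinite(x$t2)) "inf" else x$t2,
    sigma = x$sigma, n_components = x$n_components,
    search_trace = lapply(x$search_trace, function(tr)
      list(start = tr$start, bvalues = tr$bvalues, sscv = tr$sscv,
           iterations = tr$iterations, converged = tr$converged))
  )
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
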