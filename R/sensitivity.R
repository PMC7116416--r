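#' Noise model for repeated shell measurements
#'
#' Noise is taken as independent, identically distributed and Gaussian on
#' every diffusion-weighted measurement, with standard deviation \code{sigma}
#' in signal units; \code{sigma} may be derived from the b=0 signal level and
#' its SNR.
#'
#' @param sigma per-measurement noise standard deviation (signal units).
#' @param snr_b0 optional SNR in the b=0 images used to derive sigma.
#' @return a \code{noise_model} object.
#' @export
noise_model <- function(sigma, snr_b0 = NULL) {
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (!is.null(snr_b0) && (!is.finite(snr_b0) || snr_b0 <= 0))
    stop("snr_b0 must be positive")
  structure(list(sigma = sigma, snr_b0 = snr_b0), class = "noise_model")
}

#' Noise model from b=0 SNR
#'
#' sigma = mean b=0 signal / SNR, using the first shell of the matrix.
#'
#' @param data a \code{mean_signal_matrix} whose first shell is b=0.
#' @param snr_b0 SNR in the b=0 images.
#' @export
noise_from_snr <- function(data, snr_b0) {
  if (data$scheme$bvalues[1] != 0)
    stop("first shell is not b=0; cannot derive sigma from b=0 SNR")
  s0 <- mean(data$D[1, ])
  noise_model(s0 / snr_b0, snr_b0 = snr_b0)
}

#' Per-shell variance of the mean DW signal
#'
#' With n_s volumes averaged on shell s, the variance of the shell mean is
#' sigma^2 / n_s.
#'
#' @param noise a [noise_model()].
#' @param scheme a [shell_scheme()] (or a bare vector of counts).
#' @return numeric vector of per-shell variances.
#' @export
shell_variance <- function(noise, scheme) {
  counts <- if (inherits(scheme, "shell_scheme")) scheme$counts else scheme
  if (any(counts < 1)) stop("per-shell counts must be >= 1")
  noise$sigma^2 / counts
}

#' Covariance of the basis coefficients
#'
#' Propagates the per-shell variances of the mean signal into the covariance
#' of the basis coefficients w = H'd:
#' Sigma_w = sigma^2 H' diag(1/n_s) H.
#'
#' @param H orthonormal basis matrix (shells x components), or a
#'   \code{shell_basis}.
#' @param noise a [noise_model()].
#' @param scheme a [shell_scheme()] or vector of per-shell counts.
#' @return symmetric positive semidefinite matrix (components x components).
#' @export
coefficient_covariance <- function(H, noise, scheme) {
  if (inherits(H, "shell_basis")) H <- H$H
  counts <- if (inherits(scheme, "shell_scheme")) scheme$counts else scheme
  if (nrow(H) != length(counts))
    stop("shell count of H does not match the scheme")
  S <- noise$sigma^2 * crossprod(H, H / counts)
  (S + t(S)) / 2    # enforce exact symmetry
}

#' Coefficient of variation and CNR per component
#'
#' CV_c = sd(w_c) / effect size_c; its reciprocal is the component's
#' contrast-to-noise ratio. Components with zero effect size are flagged
#' undetectable (infinite CV).
#'
#' @param sigma_w coefficient covariance from [coefficient_covariance()].
#' @param eps component effect sizes.
#' @return list with \code{cv}, \code{cnr} and logical \code{undetectable}.
#' @export
coefficient_cv <- function(sigma_w, eps) {
  sd_w <- sqrt(diag(sigma_w))
  if (length(sd_w) != length(eps))
    stop("effect-size length does not match covariance dimension")
  cv <- ifelse(eps > 0, sd_w / eps, Inf)
  list(cv = cv, cnr = 1 / cv, undetectable = eps <= 0)
}

#' Sum of squared coefficients of variation
#'
#' The scalar protocol objective: SSCV = sum_c CV_c^2 over the retained
#' components. Because H is orthonormal, this reduces to
#' sigma^2 * sum_s g_s / n_s with g_s = sum_c (H_sc / eps_c)^2, a form used
#' throughout the allocation code.
#'
#' @inheritParams coefficient_covariance
#' @param eps component effect sizes (all > 0 among retained components).
#' @param n_components number of leading components retained; defaults to all.
#' @return scalar SSCV.
#' @export
sscv <- function(H, eps, noise, scheme, n_components = NULL) {
  if (inherits(H, "shell_basis")) {
    if (missing(eps) || is.null(eps)) eps <- H$effect_sizes
    H <- H$H
  }
  counts <- if (inherits(scheme, "shell_scheme")) scheme$counts else scheme
  nc <- if (is.null(n_components)) ncol(H) else n_components
  keep <- seq_len(nc)
  if (any(eps[keep] <= 0))
    stop("zero effect size among retained components; truncate the basis")
  g <- shell_sensitivity_weights(H[, keep, drop = FALSE], eps[keep])
  noise$sigma^2 * sum(g / counts)
}

# g_s = sum_c (H_sc/eps_c)^2 : per-shell leverage of the retained components
shell_sensitivity_weights <- function(H, eps) {
  rowSums(sweep(H, 2, eps, "/")^2)
}

#' Sensitivity report for a candidate scheme
#'
#' Full error-propagation summary: coefficient covariance, per-component CV
#' and CNR, and the SSCV objective, for a basis evaluated under a noise model
#' and a per-shell volume allocation.
#'
#' @param basis a \code{shell_basis}.
#' @param noise a [noise_model()].
#' @param scheme a [shell_scheme()]; defaults to the basis' own scheme.
#' @param n_components components retained in the SSCV (default: all).
#' @return object of class \code{sensitivity_report}.
#' @export
protocol_sensitivity <- function(basis, noise, scheme = basis$scheme,
                                 n_components = NULL) {
  nc <- if (is.null(n_components)) ncol(basis$H) else n_components
  b <- truncate_basis(basis, nc)
  sigma_w <- coefficient_covariance(b$H, noise, scheme)
  cvs <- coefficient_cv(sigma_w, b$effect_sizes)
  structure(
    list(sigma_w = sigma_w, cv = cvs$cv, cnr = cvs$cnr,
         sscv = sum(cvs$cv^2),
         shell_variances = shell_variance(noise, scheme),
         scheme = scheme, n_components = nc, sigma = noise$sigma),
    class = "sensitivity_report"
  )
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity report (%d components, sigma = %.4g)\n",
              x$n_components, x$sigma))
  tab <- rbind(CV = signif(x$cv, 3), CNR = signif(x$cnr, 3))
  colnames(tab) <- paste0("c", seq_along(x$cv))
  print(tab)
  cat(sprintf("SSCV = %.6g\n", x$sscv))
  invisible(x)
}

#' Rescale listed CNR values to other scan conditions
#'
#' CNR tables are conventionally listed for N_total = 100 volumes at a
#' reference b=0 SNR. For other conditions,
#' CNR_actual = CNR_listed * (SNR_actual / SNR_listed) * sqrt(N_total / 100).
#'
#' @param cnr_listed CNR value(s) under the listed conditions.
#' @param snr_listed b=0 SNR the listing assumed.
#' @param snr_actual actual b=0 SNR.
#' @param n_total_actual actual total number of volumes.
#' @return rescaled CNR.
#' @examples
#' rescale_cnr(10, 30, 30, 400)  # 20
#' @export
rescale_cnr <- function(cnr_listed, snr_listed, snr_actual, n_total_actual) {
  stopifnot(all(cnr_listed > 0), snr_listed > 0, snr_actual > 0,
            n_total_actual > 0)
  cnr_listed * (snr_actual / snr_listed) * sqrt(n_total_actual / 100)
}
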