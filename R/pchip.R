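# Vectorised shape-preserving piecewise cubic Hermite interpolation
# (Fritsch-Carlson slopes with the Moler one-sided end conditions, i.e. the
# classic "pchip" rule). The b-value search interpolates every voxel's signal
# profile at each candidate evaluation, so the interpolant is fitted once per
# data matrix (common abscissae) and evaluated as matrix operations over all
# voxels; agreement with pracma::pchip is asserted in the test suite.

#' Fit a monotone piecewise-cubic interpolant to many curves at once
#'
#' @param x strictly increasing abscissae (length n >= 2).
#' @param Y numeric matrix, n rows; each column is one curve's ordinates.
#' @return a \code{pchip_fit} object usable with [pchip_eval()].
#' @export
pchip_fit <- function(x, Y) {
  x <- as.numeric(x)
  Y <- as.matrix(Y)
  n <- length(x)
  if (n < 2L) stop("need at least two sample points")
  if (is.unsorted(x, strictly = TRUE)) stop("x must be strictly increasing")
  if (nrow(Y) != n) stop("nrow(Y) must equal length(x)")

  h <- diff(x)                               # n-1
  del <- diff(Y) / h                         # (n-1) x m secant slopes
  m <- ncol(Y)
  d <- matrix(0, n, m)

  if (n == 2L) {
    d[1, ] <- del[1, ]
    d[2, ] <- del[1, ]
  } else {
    # interior: weighted harmonic mean where secants share a sign
    for (k in 2:(n - 1L)) {
      d1 <- del[k - 1L, ]
      d2 <- del[k, ]
      same <- (d1 * d2) > 0
      w1 <- 2 * h[k] + h[k - 1L]
      w2 <- h[k] + 2 * h[k - 1L]
      dk <- numeric(m)
      dk[same] <- (w1 + w2) / (w1 / d1[same] + w2 / d2[same])
      d[k, ] <- dk
    }
    d[1, ] <- pchip_end(h[1], h[2], del[1, ], del[2, ])
    d[n, ] <- pchip_end(h[n - 1L], h[n - 2L], del[n - 1L, ], del[n - 2L, ])
  }
  structure(list(x = x, Y = Y, d = d, h = h, del = del), class = "pchip_fit")
}

# one-sided three-point end slope with shape clamps (vectorised over curves)
pchip_end <- function(h1, h2, del1, del2) {
  d <- ((2 * h1 + h2) * del1 - h1 * del2) / (h1 + h2)
  bad <- sign(d) != sign(del1)
  d[bad] <- 0
  over <- (sign(del1) != sign(del2)) & (abs(d) > 3 * abs(del1))
  d[over] <- 3 * del1[over]
  d
}

#' Evaluate a fitted interpolant
#'
#' @param fit a [pchip_fit()] object.
#' @param xout evaluation points, all within \code{range(fit$x)}.
#' @return matrix with \code{length(xout)} rows and one column per curve.
#' @export
pchip_eval <- function(fit, xout) {
  x <- fit$x
  n <- length(x)
  if (any(xout < x[1] - 1e-9) || any(xout > x[n] + 1e-9))
    stop("extrapolation requested: evaluation points outside the measured range")
  xout <- pmin(pmax(xout, x[1]), x[n])
  k <- findInterval(xout, x, rightmost.closed = TRUE)
  k <- pmin(k, n - 1L)
  out <- matrix(0, length(xout), ncol(fit$Y))
  for (i in seq_along(xout)) {
    ki <- k[i]
    t <- xout[i] - x[ki]
    hk <- fit$h[ki]
    y0 <- fit$Y[ki, ]
    d0 <- fit$d[ki, ]
    d1 <- fit$d[ki + 1L, ]
    dl <- fit$del[ki, ]
    c2 <- (3 * dl - 2 * d0 - d1) / hk
    c3 <- (d0 + d1 - 2 * dl) / hk^2
    out[i, ] <- y0 + t * (d0 + t * (c2 + t * c3))
  }
  out
}

#' Resample mean shell signals at new b-values
#'
#' Per-voxel monotonicity-preserving cubic interpolation of the measured
#' shell-mean signals over b-value, evaluated at the target b-values.
#' Interpolation at measured b-values reproduces the measured values exactly;
#' extrapolation outside the measured range is refused.
#'
#' @param data a \code{mean_signal_matrix} with at least 3 measured shells.
#' @param target_bvals b-values to resample at (within the measured range).
#' @param counts per-shell counts for the returned scheme (default 1 each).
#' @return a \code{mean_signal_matrix} at the target b-values.
#' @export
interpolate_shell_signal <- function(data, target_bvals, counts = NULL) {
  if (nrow(data$D) < 3L)
    stop("need at least three measured shells to interpolate")
  if (is.unsorted(target_bvals, strictly = TRUE))
    stop("target b-values must be strictly increasing")
  fit <- pchip_fit(data$scheme$bvalues, data$D)
  D <- pchip_eval(fit, target_bvals)
  if (is.null(counts)) counts <- rep(1L, length(target_bvals))
  mean_signal_matrix(pmax(D, 0), shell_scheme(target_bvals, counts),
                     provenance = data$provenance)
}
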