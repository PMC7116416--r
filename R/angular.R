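# Angular-content analysis: real even-order spherical harmonics, per-order
# power spectra, noise-floor detectability, minimum direction counts, and
# electrostatic-repulsion direction generation.
#
# SH convention used throughout: real, orthonormal on the unit sphere, even
# orders only (antipodal symmetry of the DW signal). Columns are ordered by
# order l = 0, 2, 4, ... and within each order by m = -l..l, with
#   Y_{l,0}   = N_{l,0} P_l^0(cos theta)
#   Y_{l,m>0} = sqrt(2) N_{l,m} P_l^m(cos theta) cos(m phi)
#   Y_{l,m<0} = sqrt(2) N_{l,|m|} P_l^|m|(cos theta) sin(|m| phi)
# where N_{l,m} = sqrt((2l+1)/(4 pi) (l-m)!/(l+m)!) and P_l^m includes the
# Condon-Shortley phase (as returned by pracma::legendre). A constant signal
# of value a therefore has c_{0,0} = a * sqrt(4 pi).

#' Number of even-order spherical-harmonic coefficients up to order lmax
#'
#' Equals the minimum number of sampling directions required to determine a
#' signal band-limited at that order.
#'
#' @param lmax maximum (even) harmonic order.
#' @return (lmax + 1)(lmax + 2) / 2.
#' @examples
#' n_even_sh_coeffs(8)  # 45
#' @export
n_even_sh_coeffs <- function(lmax) {
  if (lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be an even non-negative order")
  as.integer((lmax + 1) * (lmax + 2) / 2)
}

#' Real even-order spherical-harmonic design matrix
#'
#' @param directions n x 3 matrix of unit vectors.
#' @param lmax maximum even order.
#' @return n x n_even_sh_coeffs(lmax) matrix; attribute \code{l} gives each
#'   column's harmonic order.
#' @export
sh_basis_matrix <- function(directions, lmax) {
  directions <- as_direction_matrix(directions)
  n <- nrow(directions)
  ct <- pmin(pmax(directions[, 3], -1), 1)         # cos(theta)
  phi <- atan2(directions[, 2], directions[, 1])
  p <- n_even_sh_coeffs(lmax)
  B <- matrix(0, n, p)
  lcol <- integer(p)
  col <- 1L
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct)                   # (l+1) x n, rows m=0..l
    if (is.null(dim(P))) P <- matrix(P, nrow = l + 1)
    for (m in -l:l) {
      am <- abs(m)
      nf <- sqrt((2 * l + 1) / (4 * pi) *
                 exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      y <- nf * P[am + 1, ]
      if (m > 0) y <- sqrt(2) * y * cos(m * phi)
      if (m < 0) y <- sqrt(2) * y * sin(am * phi)
      B[, col] <- y
      lcol[col] <- l
      col <- col + 1L
    }
  }
  attr(B, "l") <- lcol
  B
}

as_direction_matrix <- function(directions) {
  directions <- as.matrix(directions)
  if (ncol(directions) != 3 && nrow(directions) == 3)
    directions <- t(directions)
  if (ncol(directions) != 3) stop("directions must be n x 3 (or 3 x n)")
  directions
}

#' Least-squares spherical-harmonic fit
#'
#' Fits real even-order SH coefficients to signal samples on the sphere.
#' Optional Laplace-Beltrami regularisation penalises high orders by
#' lambda * l^2 (l+1)^2.
#'
#' @param directions n x 3 unit vectors.
#' @param values length-n signal vector, or n x k matrix (one column per
#'   voxel/realisation).
#' @param lmax maximum even order.
#' @param lambda regularisation weight (default 0).
#' @return coefficient vector (or p x k matrix); attribute \code{l} carries
#'   the per-coefficient order.
#' @export
sh_fit <- function(directions, values, lmax, lambda = 0) {
  B <- sh_basis_matrix(directions, lmax)
  p <- ncol(B)
  if (nrow(B) < p)
    stop("underdetermined fit: ", nrow(B), " directions for ", p,
         " coefficients")
  values <- as.matrix(values)
  if (lambda > 0) {
    l <- attr(B, "l")
    A <- crossprod(B) + lambda * diag(l^2 * (l + 1)^2)
    coefs <- solve(A, crossprod(B, values))
  } else {
    coefs <- qr.coef(qr(B), values)
  }
  if (ncol(coefs) == 1L) coefs <- drop(coefs)
  attr(coefs, "l") <- attr(B, "l")
  coefs
}

#' Rotationally invariant per-order power spectrum
#'
#' power_l = sum_m c_{lm}^2, invariant under 3-D rotations of the signal.
#'
#' @param coefficients SH coefficients from [sh_fit()] (vector, or matrix with
#'   one column per realisation), with their \code{l} attribute; otherwise
#'   supply \code{l}.
#' @param l per-coefficient harmonic orders when not attached.
#' @return named vector (or matrix, orders x realisations) of per-order power.
#' @export
rotational_power_spectrum <- function(coefficients, l = NULL) {
  if (is.null(l)) l <- attr(coefficients, "l")
  if (is.null(l)) stop("per-coefficient orders not available")
  cm <- as.matrix(coefficients)
  orders <- sort(unique(l))
  out <- vapply(orders, function(ll)
    colSums(cm[l == ll, , drop = FALSE]^2), numeric(ncol(cm)))
  out <- matrix(out, nrow = length(orders), byrow = TRUE,
                dimnames = list(paste0("l", orders), NULL))
  if (ncol(out) == 1L) return(stats::setNames(out[, 1], rownames(out)))
  out
}

#' Per-order noise floor of the SH power spectrum
#'
#' Simulates pure i.i.d. Gaussian noise of standard deviation \code{sigma} on
#' the given direction set, fits the SH basis to every draw, and returns the
#' requested percentile of each order's power: the level below which observed
#' power is indistinguishable from noise.
#'
#' @param directions n x 3 unit vectors of the shell being analysed.
#' @param lmax maximum even order analysed.
#' @param sigma noise standard deviation on each directional measurement.
#' @param n_sim number of noise draws (default 500).
#' @param probs floor percentile (default 0.95).
#' @param seed RNG seed.
#' @return named vector of per-order floor power.
#' @export
sh_noise_floor <- function(directions, lmax, sigma, n_sim = 500,
                           probs = 0.95, seed = 1) {
  directions <- as_direction_matrix(directions)
  set.seed(seed)
  noise <- matrix(stats::rnorm(nrow(directions) * n_sim, sd = sigma),
                  nrow(directions), n_sim)
  coefs <- sh_fit(directions, noise, lmax)
  pw <- rotational_power_spectrum(coefs)
  apply(pw, 1, stats::quantile, probs = probs, names = FALSE)
}

#' Detectable harmonic order and minimum direction count
#'
#' The highest even order whose fitted power exceeds the per-order noise
#' floor; orders at or below the floor are treated as undetectable. The
#' minimum number of directions needed to sample without angular aliasing is
#' the coefficient count at the detectable order.
#'
#' @param spectrum named per-order power vector (from
#'   [rotational_power_spectrum()]).
#' @param noise_floor per-order floor from [sh_noise_floor()], aligned with
#'   \code{spectrum}.
#' @return list with \code{lmax} and \code{min_directions}.
#' @export
detectable_lmax <- function(spectrum, noise_floor) {
  orders <- as.integer(sub("^l", "", names(spectrum)))
  above <- spectrum > noise_floor
  lmax <- if (any(above & orders > 0)) max(orders[above]) else 0L
  list(lmax = lmax, min_directions = n_even_sh_coeffs(lmax))
}

#' Angular spectrum analysis of one shell
#'
#' Fits the even-order SH basis to a shell's directional signal, compares the
#' per-order power against a pure-noise floor simulated at the same direction
#' set and noise level, and reports the highest detectable order with the
#' implied minimum direction count.
#'
#' @param directions n x 3 unit vectors.
#' @param values length-n directional signal (single profile, e.g. the
#'   realigned single-fibre average).
#' @param sigma noise standard deviation assumed for the floor.
#' @param lmax maximum even order analysed (default 8).
#' @param n_sim,probs,seed noise-floor simulation controls; see
#'   [sh_noise_floor()].
#' @return object of class \code{angular_spectrum}: \code{per_order_power},
#'   \code{noise_floor}, \code{detectable_lmax}, \code{min_directions},
#'   \code{sigma}.
#' @export
angular_spectrum <- function(directions, values, sigma, lmax = 8,
                             n_sim = 500, probs = 0.95, seed = 1) {
  directions <- as_direction_matrix(directions)
  coefs <- sh_fit(directions, values, lmax)
  pw <- rotational_power_spectrum(coefs)
  floor <- sh_noise_floor(directions, lmax, sigma, n_sim, probs, seed)
  det <- detectable_lmax(pw, floor)
  structure(
    list(per_order_power = pw, noise_floor = floor,
         detectable_lmax = det$lmax, min_directions = det$min_directions,
         sigma = sigma),
    class = "angular_spectrum"
  )
}

#' @export
print.angular_spectrum <- function(x, ...) {
  tab <- rbind(power = signif(x$per_order_power, 3),
               `noise floor` = signif(x$noise_floor, 3))
  print(tab)
  cat(sprintf("detectable order %d -> minimum %d directions (sigma = %g)\n",
              x$detectable_lmax, x$min_directions, x$sigma))
  invisible(x)
}

#' Electrostatic-repulsion direction sets
#'
#' Generates n near-uniform gradient directions by minimising the antipodally
#' symmetric Coulomb energy sum_{i<j} 1/|u_i - u_j| + 1/|u_i + u_j| with
#' projected gradient descent and backtracking line search (energy is
#' non-increasing across iterations). Deterministic for a given (n, seed).
#'
#' @param n number of directions.
#' @param seed RNG seed for the random initialisation.
#' @param max_iter iteration cap.
#' @param tol relative energy-change convergence tolerance.
#' @return object of class \code{direction_set}: \code{vectors} (n x 3, unit
#'   rows) and \code{energy} at convergence.
#' @export
generate_directions <- function(n, seed = 1, max_iter = 2000, tol = 1e-10) {
  stopifnot(n >= 1)
  set.seed(seed)
  if (n == 1L) {
    return(structure(list(vectors = matrix(c(0, 0, 1), 1, 3), energy = 0),
                     class = "direction_set"))
  }
  u <- matrix(stats::rnorm(3 * n), n, 3)
  u <- u / sqrt(rowSums(u^2))

  energy <- function(u) {
    e <- 0
    for (i in seq_len(n - 1L)) {
      dif <- sweep(u[(i + 1):n, , drop = FALSE], 2, u[i, ])
      sm <- sweep(u[(i + 1):n, , drop = FALSE], 2, -u[i, ])
      e <- e + sum(1 / sqrt(rowSums(dif^2))) + sum(1 / sqrt(rowSums(sm^2)))
    }
    e
  }
  gradient <- function(u) {
    g <- matrix(0, n, 3)
    for (i in seq_len(n)) {
      others <- u[-i, , drop = FALSE]
      dif <- sweep(-others, 2, u[i, ], "+")       # u_i - u_j
      sm <- sweep(others, 2, u[i, ], "+")         # u_i + u_j
      rd <- rowSums(dif^2)^1.5
      rs <- rowSums(sm^2)^1.5
      g[i, ] <- -colSums(dif / rd) - colSums(sm / rs)
    }
    g
  }

  e <- energy(u)
  trace <- e
  step <- 0.1
  for (it in seq_len(max_iter)) {
    g <- gradient(u)
    # project gradient onto the tangent plane of each point
    g <- g - u * rowSums(g * u)
    improved <- FALSE
    while (step > 1e-12) {
      v <- u - step * g
      v <- v / sqrt(rowSums(v^2))
      ev <- energy(v)
      if (ev < e) {
        improved <- TRUE
        break
      }
      step <- step / 2
    }
    if (!improved) break
    delta <- (e - ev) / e
    u <- v
    e <- ev
    trace <- c(trace, e)
    step <- step * 1.5
    if (delta < tol) break
  }

  # deterministic orientation: no two directions within 0.5 degrees
  dots <- abs(tcrossprod(u))
  diag(dots) <- 0
  if (max(dots) > cos(0.5 * pi / 180))
    warning("direction set contains a near-collinear pair")
  structure(list(vectors = u, energy = e, energy_trace = trace),
            class = "direction_set")
}

#' @export
print.direction_set <- function(x, ...) {
  ang <- min_pairwise_angle(x$vectors)
  cat(sprintf("%d directions, energy %.4f, minimum pairwise angle %.1f deg\n",
              nrow(x$vectors), x$energy, ang))
  invisible(x)
}

#' Minimum pairwise angle of an antipodally symmetric direction set
#'
#' @param u n x 3 unit vectors.
#' @return smallest angle (degrees) between any two directions or antipodes.
#' @export
min_pairwise_angle <- function(u) {
  u <- as_direction_matrix(u)
  if (nrow(u) < 2L) return(180)
  dots <- abs(tcrossprod(u))
  diag(dots) <- 0
  acos(pmin(max(dots), 1)) * 180 / pi
}
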