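# Single-fibre voxel selection: diffusion-tensor screen on the low-b shells,
# an SH peak-ratio screen on the highest shell, and realignment of each
# voxel's high-b profile so its principal diffusion axis maps onto z. The
# realigned profiles feed the angular-content analysis.

#' Weighted least-squares diffusion tensor fit
#'
#' Fits log S = log S0 - b g' D g per voxel by weighted least squares on the
#' log-signal, with the squared signal as weights.
#'
#' @param signals n_vol x n_vox matrix of DW intensities (positive).
#' @param bvals per-volume b-values.
#' @param bvecs 3 x n_vol unit directions.
#' @return list with \code{md}, \code{fa}, and \code{e1} (3 x n_vox principal
#'   eigenvectors).
#' @export
fit_tensor <- function(signals, bvals, bvecs) {
  signals <- as.matrix(signals)
  g <- t(bvecs)
  X <- cbind(1, -bvals * g[, 1]^2, -bvals * g[, 2]^2, -bvals * g[, 3]^2,
             -2 * bvals * g[, 1] * g[, 2], -2 * bvals * g[, 1] * g[, 3],
             -2 * bvals * g[, 2] * g[, 3])
  n_vox <- ncol(signals)
  md <- fa <- numeric(n_vox)
  e1 <- matrix(0, 3, n_vox)
  y <- log(pmax(signals, .Machine$double.eps))
  for (v in seq_len(n_vox)) {
    w <- signals[, v]^2
    beta <- tryCatch(stats::lm.wfit(X, y[, v], w)$coefficients,
                     error = function(e) rep(NA_real_, 7))
    if (anyNA(beta)) {
      md[v] <- NA
      fa[v] <- NA
      next
    }
    Dm <- matrix(c(beta[2], beta[5], beta[6],
                   beta[5], beta[3], beta[7],
                   beta[6], beta[7], beta[4]), 3, 3)
    ev <- eigen(Dm, symmetric = TRUE)
    lam <- ev$values
    md[v] <- mean(lam)
    num <- sqrt(sum((lam - md[v])^2))
    den <- sqrt(sum(lam^2))
    fa[v] <- if (den > 0) sqrt(1.5) * num / den else 0
    e1[, v] <- ev$vectors[, 1]
  }
  list(md = md, fa = fa, e1 = e1)
}

# rotation matrix mapping unit vector v onto +z (Rodrigues)
rotation_to_z <- function(v) {
  v <- v / sqrt(sum(v^2))
  z <- c(0, 0, 1)
  c_ <- sum(v * z)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) return(diag(c(1, -1, -1)))
  axis <- c(v[2] * z[3] - v[3] * z[2],
            v[3] * z[1] - v[1] * z[3],
            v[1] * z[2] - v[2] * z[1])
  s <- sqrt(sum(axis^2))
  axis <- axis / s
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + s * K + (1 - c_) * (K %*% K)
}

# peak amplitudes of the attenuation contrast of an SH signal profile.
# Fibres attenuate the DW signal most strongly along their own axis, so
# fibre orientations appear as peaks of (mean signal - signal); a single
# fibre gives one dominant antipodal peak pair, crossings give several.
sh_peak_amplitudes <- function(coefs, lmax, grid, neighbours) {
  amp <- as.vector(sh_basis_matrix(grid, lmax) %*% coefs)
  contrast <- mean(amp) - amp
  peaks <- numeric(0)
  for (i in seq_len(nrow(grid))) {
    if (contrast[i] > 0 && all(contrast[i] >= contrast[neighbours[[i]]]))
      peaks <- c(peaks, contrast[i])
  }
  sort(peaks, decreasing = TRUE)
}

#' Select single-fibre voxels and realign their high-b profiles
#'
#' Screens the masked voxels of a DWI dataset for a single dominant fibre
#' population: a diffusion-tensor fit on the b <= 1000 shells must give
#' fractional anisotropy above \code{fa_threshold}, and the ratio of the
#' second to the first SH peak amplitude on the highest shell must fall below
#' \code{peak_ratio}. Each retained voxel's highest-shell profile is then
#' realigned so its principal eigenvector maps onto the z-axis, and the
#' realigned SH coefficients are averaged across voxels.
#'
#' @param dataset a \code{dwi_dataset}.
#' @param fa_threshold minimum FA (default 0.25, suited to low-anisotropy
#'   neonatal-like data).
#' @param peak_ratio maximum second-to-first peak amplitude ratio (default
#'   0.5).
#' @param lmax SH order used for the peak screen and realigned fit.
#' @param tolerance shell-grouping tolerance.
#' @return list with \code{voxels} (indices into the masked voxel ordering),
#'   \code{mask} (3-D logical array), \code{stage_counts},
#'   \code{mean_coefficients} (averaged realigned SH coefficients),
#'   \code{directions} (highest-shell directions) and \code{fa}, \code{md}.
#' @export
select_single_fibre_voxels <- function(dataset, fa_threshold = 0.25,
                                       peak_ratio = 0.5, lmax = 4,
                                       tolerance = 50) {
  grp <- group_shells(dataset$bvals, tolerance)
  bv <- grp$scheme$bvalues
  if (max(bv) <= 0) stop("no nonzero shell present")
  idx <- which(dataset$mask)
  d <- dim(dataset$volumes)
  flat <- matrix(dataset$volumes, nrow = prod(d[1:3]), ncol = d[4])
  vox <- t(flat[idx, , drop = FALSE])               # n_vol x n_vox

  low <- dataset$bvals <= 1000 + tolerance
  tens <- fit_tensor(vox[low, , drop = FALSE], dataset$bvals[low],
                     dataset$bvecs[, low, drop = FALSE])
  pass_fa <- which(!is.na(tens$fa) & tens$fa > fa_threshold)
  counts <- c(masked = length(idx), fa = length(pass_fa))

  hi_shell <- which.max(bv)
  hi <- grp$shell_index == hi_shell
  dirs <- t(dataset$bvecs[, hi, drop = FALSE])
  p <- n_even_sh_coeffs(lmax)
  if (nrow(dirs) < p)
    stop("highest shell has fewer directions (", nrow(dirs),
         ") than SH coefficients (", p, ")")

  grid <- fibonacci_hemisphere(150)
  ang <- 25 * pi / 180
  adj <- abs(tcrossprod(grid)) > cos(ang)
  diag(adj) <- FALSE
  neighbours <- apply(adj, 1, which, simplify = FALSE)

  keep <- integer(0)
  coef_sum <- NULL
  for (v in pass_fa) {
    # peak screen at order 2: free of the truncation ringing that higher
    # orders show on sharp profiles, and sufficient to count fibre axes
    coefs <- sh_fit(dirs, vox[hi, v], 2)
    pk <- sh_peak_amplitudes(coefs, 2, grid, neighbours)
    ratio <- if (length(pk) >= 2) pk[2] / pk[1] else 0
    if (length(pk) >= 1 && ratio < peak_ratio) {
      keep <- c(keep, v)
      R <- rotation_to_z(tens$e1[, v])
      rdirs <- dirs %*% t(R)
      rc <- sh_fit(rdirs, vox[hi, v], lmax)
      coef_sum <- if (is.null(coef_sum)) rc else coef_sum + rc
    }
  }
  counts <- c(counts, peak = length(keep))
  if (length(keep) == 0L)
    stop("no single-fibre voxels found; stage counts: ",
         paste(names(counts), counts, sep = "=", collapse = ", "))

  mask <- array(FALSE, d[1:3])
  mask[idx[keep]] <- TRUE
  mean_coefs <- coef_sum / length(keep)
  attr(mean_coefs, "l") <- attr(sh_fit(dirs, vox[hi, keep[1]], lmax), "l")
  list(voxels = keep, mask = mask, stage_counts = counts,
       mean_coefficients = mean_coefs, directions = dirs,
       fa = tens$fa, md = tens$md)
}

# deterministic near-uniform hemisphere grid (golden-angle spiral)
fibonacci_hemisphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- i / n                       # upper hemisphere
  r <- sqrt(1 - z^2)
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}
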