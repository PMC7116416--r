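#' Fit the data-driven signal basis over b-values
#'
#' Decomposes the shells-by-voxels mean-signal matrix D by compact singular
#' value decomposition, D = U S V', and returns the orthonormal basis H = U,
#' the per-voxel weights W = S V' (so that D = H W), and the component effect
#' sizes. The effect size of component c is its singular value divided by
#' sqrt(N_v), which equals the root-mean-square of row c of W: the typical
#' magnitude of that component across the brain, in signal units.
#'
#' The SVD leaves the sign of each component arbitrary; for deterministic
#' output, each basis column is flipped so that its largest-magnitude entry is
#' positive (weights flipped accordingly). For exactly degenerate singular
#' values the solver's ordering is kept, so component order within a tie is
#' platform-defined.
#'
#' @param x a \code{mean_signal_matrix}, or a bare numeric matrix
#'   (shells x voxels).
#' @param scheme a [shell_scheme()]; required when \code{x} is a bare matrix.
#' @return an object of class \code{shell_basis}: list with \code{H}
#'   (N_s x N_s orthonormal), \code{singular_values}, \code{W}
#'   (N_s x N_v), \code{effect_sizes}, \code{n_voxels}, \code{scheme}.
#' @examples
#' D <- matrix(c(1, 1, 1, 1), 2, 2)
#' fit <- shell_basis(D, shell_scheme(c(0, 1000), c(1, 1)))
#' fit$singular_values   # (2, 0)
#' @export
shell_basis <- function(x, scheme = NULL) {
  if (inherits(x, "mean_signal_matrix")) {
    D <- x$D
    scheme <- x$scheme
  } else {
    D <- as.matrix(x)
    if (is.null(scheme))
      scheme <- shell_scheme(seq_len(nrow(D)) - 1, rep(1L, nrow(D)))
  }
  if (any(!is.finite(D))) stop("non-finite entries in D")
  n_s <- nrow(D)
  n_v <- ncol(D)
  if (n_s > n_v)
    stop("more shells than voxels: compact SVD basis requires N_s <= N_v")

  sv <- svd(D, nu = n_s, nv = n_s)
  H <- sv$u
  W <- sv$d * t(sv$v)                     # S V'

  # deterministic sign convention: largest-magnitude entry of each basis
  # column made positive
  for (c in seq_len(n_s)) {
    k <- which.max(abs(H[, c]))
    if (H[k, c] < 0) {
      H[, c] <- -H[, c]
      W[c, ] <- -W[c, ]
    }
  }

  structure(
    list(H = H, singular_values = sv$d, W = W,
         effect_sizes = sv$d / sqrt(n_v),
         n_voxels = n_v, scheme = scheme),
    class = "shell_basis"
  )
}

#' @export
print.shell_basis <- function(x, ...) {
  cat(sprintf("SVD signal basis: %d shells, %d voxels\n",
              nrow(x$H), x$n_voxels))
  eps <- x$effect_sizes
  rel <- if (eps[1] > 0) eps / eps[1] else eps
  tab <- rbind(`effect size` = signif(eps, 3),
               `relative` = round(rel, 3))
  colnames(tab) <- paste0("c", seq_along(eps))
  print(tab)
  invisible(x)
}

#' @export
summary.shell_basis <- function(object, ...) {
  cat("Data-driven multi-shell signal basis (compact SVD)\n")
  cat("b-values (s/mm^2):",
      paste(round(object$scheme$bvalues), collapse = ", "), "\n")
  print(object)
  ortho <- max(abs(crossprod(object$H) - diag(nrow(object$H))))
  cat(sprintf("max |H'H - I| = %.2e\n", ortho))
  invisible(object)
}

#' @export
coef.shell_basis <- function(object, ...) object$W

#' Plot the basis functions over b-value
#'
#' One curve per component of the orthonormal basis, against shell b-value;
#' the first component tracks the mean DW signal profile, higher components
#' oscillate increasingly rapidly.
#'
#' @param x a \code{shell_basis}.
#' @param n_components number of leading components to draw.
#' @param ... passed to \code{matplot}.
#' @export
plot.shell_basis <- function(x, n_components = ncol(x$H), ...) {
  b <- x$scheme$bvalues
  graphics::matplot(b, x$H[, seq_len(n_components), drop = FALSE],
                    type = "b", pch = 16, lty = 1,
                    xlab = expression(b ~ (s/mm^2)),
                    ylab = "basis amplitude", ...)
  graphics::abline(h = 0, col = "grey")
  graphics::legend("topright", legend = paste0("c", seq_len(n_components)),
                   col = seq_len(n_components), lty = 1, bty = "n")
  invisible(x)
}

#' Component effect sizes
#'
#' @param basis a \code{shell_basis}.
#' @return numeric vector: singular values / sqrt(N_v), non-increasing.
#' @export
effect_sizes <- function(basis) {
  stopifnot(inherits(basis, "shell_basis"))
  basis$effect_sizes
}

#' Truncate a basis to its leading components
#'
#' Keeps the \code{n_components} leading components; by the Eckart-Young
#' theorem the squared Frobenius reconstruction error equals the sum of the
#' squared discarded singular values.
#'
#' @param basis a \code{shell_basis}.
#' @param n_components number of components to keep (1..N_s).
#' @return a \code{shell_basis} with rectangular \code{H}
#'   (N_s x n_components) and \code{W} (n_components x N_v).
#' @export
truncate_basis <- function(basis, n_components) {
  stopifnot(inherits(basis, "shell_basis"))
  n_s <- ncol(basis$H)
  if (n_components < 1 || n_components > n_s)
    stop("n_components must be between 1 and the number of shells")
  keep <- seq_len(n_components)
  structure(
    list(H = basis$H[, keep, drop = FALSE],
         singular_values = basis$singular_values[keep],
         W = basis$W[keep, , drop = FALSE],
         effect_sizes = basis$effect_sizes[keep],
         n_voxels = basis$n_voxels, scheme = basis$scheme),
    class = "shell_basis"
  )
}
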