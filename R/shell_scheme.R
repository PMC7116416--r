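#' Multi-shell acquisition scheme
#'
#' A shell scheme records the nominal b-value of each shell together with the
#' number of diffusion-weighted volumes acquired on it. The b=0 volumes form a
#' shell like any other.
#'
#' @param bvalues numeric vector of nominal shell b-values (s/mm^2), strictly
#'   increasing.
#' @param counts integer vector of per-shell volume counts, all >= 1.
#' @return an object of class \code{shell_scheme} with elements \code{bvalues},
#'   \code{counts} and \code{n_total}.
#' @examples
#' shell_scheme(c(0, 400, 1000, 2600), c(20, 64, 88, 128))
#' @export
shell_scheme <- function(bvalues, counts) {
  bvalues <- as.numeric(bvalues)
  counts <- as.integer(round(counts))
  if (length(bvalues) != length(counts))
    stop("bvalues and counts must have the same length")
  if (any(!is.finite(bvalues)) || any(bvalues < 0))
    stop("shell b-values must be finite and non-negative")
  if (is.unsorted(bvalues, strictly = TRUE))
    stop("shell b-values must be strictly increasing")
  if (any(counts < 1L))
    stop("every shell must hold at least one volume")
  structure(
    list(bvalues = bvalues, counts = counts, n_total = sum(counts)),
    class = "shell_scheme"
  )
}

#' @export
print.shell_scheme <- function(x, ...) {
  cat("Multi-shell scheme:", length(x$bvalues), "shells,",
      x$n_total, "volumes\n")
  tab <- rbind(`b-value (s/mm^2)` = x$bvalues,
               `volumes` = x$counts,
               `fraction (%)` = round(100 * x$counts / x$n_total))
  colnames(tab) <- paste0("shell", seq_along(x$bvalues) - 1L)
  print(tab)
  invisible(x)
}

#' Group per-volume b-values into shells
#'
#' Clusters the per-volume b-values of an acquisition into nominal shells.
#' B-values within \code{tolerance} of a cluster centre share a shell; the
#' nominal shell b-value is the mean of its members. Scanner-reported
#' effective b-values therefore collapse onto their nominal shell.
#'
#' @param bvals numeric vector of per-volume b-values (s/mm^2).
#' @param tolerance clustering half-width (s/mm^2), default 50.
#' @return a list with \code{scheme} (a [shell_scheme()]) and
#'   \code{shell_index}, the 1-based shell index of every volume.
#' @examples
#' group_shells(c(0, 0, 495, 505, 1000))
#' @export
group_shells <- function(bvals, tolerance = 50) {
  bvals <- as.numeric(bvals)
  if (length(bvals) == 0L) stop("no b-values supplied")
  if (any(!is.finite(bvals)) || any(bvals < 0))
    stop("b-values must be finite and non-negative")
  if (!is.finite(tolerance) || tolerance <= 0)
    stop("tolerance must be positive")

  # single-pass agglomeration on the sorted unique values
  ord <- order(bvals)
  sorted <- bvals[ord]
  centre <- sorted[1]
  members <- 1L
  centres <- numeric(0)
  assign_sorted <- integer(length(bvals))
  for (i in seq_along(sorted)) {
    if (i > 1L && abs(sorted[i] - centre) > tolerance) {
      centres <- c(centres, centre)
      centre <- sorted[i]
      members <- 0L
    }
    # running mean keeps the centre at the mean of current members
    members <- members + 1L
    centre <- centre + (sorted[i] - centre) / members
    assign_sorted[i] <- length(centres) + 1L
  }
  centres <- c(centres, centre)

  if (length(centres) > 1L && any(diff(centres) < 2 * tolerance))
    stop("ambiguous shell structure: cluster centres closer than 2*tolerance")

  shell_index <- integer(length(bvals))
  shell_index[ord] <- assign_sorted
  counts <- tabulate(shell_index, nbins = length(centres))
  list(
    scheme = shell_scheme(centres, counts),
    shell_index = shell_index
  )
}
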