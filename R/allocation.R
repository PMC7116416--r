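#' Optimal per-shell measurement fractions
#'
#' Closed-form Lagrange solution for the per-shell volume counts minimising
#' the SSCV under a fixed total budget: the unnormalised optimum is
#' n_s* = sqrt(sum_c (H_sc / eps_c)^2), normalised to fractions summing to 1.
#' The fractions depend only on the basis and effect sizes -- not on the noise
#' level or the total budget.
#'
#' @param H orthonormal basis (shells x components) or a \code{shell_basis}.
#' @param eps component effect sizes; taken from the basis when omitted.
#' @param n_components leading components retained (default: all columns).
#' @return numeric vector of per-shell fractions summing to 1.
#' @examples
#' optimal_fractions(diag(2), c(1, 0.5))  # (1/3, 2/3)
#' @export
optimal_fractions <- function(H, eps = NULL, n_components = NULL) {
  if (inherits(H, "shell_basis")) {
    if (is.null(eps)) eps <- H$effect_sizes
    H <- H$H
  }
  nc <- if (is.null(n_components)) ncol(H) else n_components
  keep <- seq_len(nc)
  if (any(eps[keep] <= 0))
    stop("zero effect size among retained components: truncate the basis ",
         "before allocating")
  n_star <- sqrt(shell_sensitivity_weights(H[, keep, drop = FALSE], eps[keep]))
  n_star / sum(n_star)
}

#' Integerise fractional allocations
#'
#' Largest-remainder rounding of fractions * n_total (ties broken towards the
#' lower shell index), followed by repair to satisfy per-shell minimum counts:
#' deficits are filled by taking volumes from donor shells where removing one
#' volume increases the SSCV the least.
#'
#' @param fractions per-shell fractions summing to 1.
#' @param n_total total volume budget.
#' @param minima per-shell minimum counts (default 1 each).
#' @param g optional per-shell sensitivity weights (sum_c (H_sc/eps_c)^2) used
#'   to cost the repair moves; equal weights assumed when omitted.
#' @return integer vector of counts summing to \code{n_total}.
#' @export
integerise_counts <- function(fractions, n_total, minima = NULL, g = NULL) {
  n_shells <- length(fractions)
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (is.null(minima)) minima <- rep(1L, n_shells)
  minima <- pmax(as.integer(minima), 1L)
  if (sum(minima) > n_total)
    stop("infeasible minima: sum exceeds the total budget")
  if (is.null(g)) g <- rep(1, n_shells)

  target <- fractions * n_total
  counts <- floor(target)
  remainder <- target - counts
  deficit <- n_total - sum(counts)
  if (deficit > 0) {
    # largest remainder first; ties to the lower shell index
    ord <- order(-remainder, seq_len(n_shells))
    counts[ord[seq_len(deficit)]] <- counts[ord[seq_len(deficit)]] + 1
  }

  # repair to satisfy minima: donate from the shell whose SSCV penalty for
  # losing one volume (g_s/(n_s-1) - g_s/n_s) is smallest
  repeat {
    short <- which(counts < minima)
    if (length(short) == 0L) break
    s <- short[1]
    donors <- which(counts > minima)
    penalty <- g[donors] / (counts[donors] - 1) - g[donors] / counts[donors]
    d <- donors[which.min(penalty)]
    counts[d] <- counts[d] - 1
    counts[s] <- counts[s] + 1
  }
  as.integer(counts)
}

#' Allocate a volume budget across shells
#'
#' Combines [optimal_fractions()] and [integerise_counts()] and evaluates the
#' SSCV at the returned integer counts. Fractions are independent of
#' \code{noise} and \code{n_total}; both enter only the integer counts and the
#' reported objective value.
#'
#' @param basis a \code{shell_basis} (or orthonormal matrix, with \code{eps}).
#' @param noise a [noise_model()].
#' @param n_total total number of volumes to allocate.
#' @param eps effect sizes when \code{basis} is a bare matrix.
#' @param minima per-shell minimum counts (e.g. angular sampling minima).
#' @param n_components leading components retained.
#' @return object of class \code{allocation_result}: \code{fractions},
#'   \code{counts}, \code{sscv}, \code{scheme}.
#' @export
allocate_volumes <- function(basis, noise, n_total, eps = NULL, minima = NULL,
                             n_components = NULL) {
  if (inherits(basis, "shell_basis")) {
    H <- basis$H
    if (is.null(eps)) eps <- basis$effect_sizes
    bvalues <- basis$scheme$bvalues
  } else {
    H <- basis
    bvalues <- seq_len(nrow(H)) - 1
  }
  nc <- if (is.null(n_components)) ncol(H) else n_components
  keep <- seq_len(nc)
  fr <- optimal_fractions(H, eps, nc)
  g <- shell_sensitivity_weights(H[, keep, drop = FALSE], eps[keep])
  counts <- integerise_counts(fr, n_total, minima, g)
  scheme <- shell_scheme(bvalues, counts)
  structure(
    list(fractions = fr, counts = counts,
         sscv = noise$sigma^2 * sum(g / counts), scheme = scheme),
    class = "allocation_result"
  )
}

#' @export
print.allocation_result <- function(x, ...) {
  tab <- rbind(`b-value` = x$scheme$bvalues,
               `fraction (%)` = round(100 * x$fractions),
               `volumes` = x$counts)
  colnames(tab) <- paste0("shell", seq_along(x$counts) - 1L)
  print(tab)
  cat(sprintf("SSCV at counts = %.6g\n", x$sscv))
  invisible(x)
}

#' Exhaustive-search allocation oracle
#'
#' Enumerates every positive integer composition of \code{n_total} over the
#' shells and returns the SSCV-minimising counts (ties broken towards the
#' lexicographically smallest composition). Intended as an independent check
#' of the closed-form allocation on small budgets.
#'
#' @inheritParams allocate_volumes
#' @param max_compositions guard on the enumeration size (default 1e6).
#' @return list with \code{counts} and \code{sscv}.
#' @export
brute_force_allocation <- function(basis, noise, n_total, eps = NULL,
                                   n_components = NULL,
                                   max_compositions = 1e6) {
  if (inherits(basis, "shell_basis")) {
    H <- basis$H
    if (is.null(eps)) eps <- basis$effect_sizes
  } else H <- basis
  nc <- if (is.null(n_components)) ncol(H) else n_components
  keep <- seq_len(nc)
  if (any(eps[keep] <= 0)) stop("zero effect size among retained components")
  g <- shell_sensitivity_weights(H[, keep, drop = FALSE], eps[keep])
  n_shells <- nrow(H)
  n_comp <- choose(n_total - 1, n_shells - 1)
  if (n_comp > max_compositions)
    stop("composition count ", n_comp, " exceeds the enumeration guard")

  comp <- compositions(n_total, n_shells)      # matrix, rows = compositions
  obj <- noise$sigma^2 * as.vector(comp_inv(comp) %*% g)
  # lexicographically smallest among ties: compositions() emits rows in
  # lexicographic order, so the first minimiser wins
  best <- which.min(obj)
  list(counts = as.integer(comp[best, ]), sscv = obj[best])
}

# all positive integer compositions of n into k parts, lexicographic rows
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1, 1))
  out <- vector("list", n - k + 1L)
  for (first in seq_len(n - k + 1L)) {
    rest <- compositions(n - first, k - 1L)
    out[[first]] <- cbind(first, rest)
  }
  do.call(rbind, out)
}

comp_inv <- function(m) 1 / m
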