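#' PGSE timing model
#'
#' Timing skeleton of a pulsed-gradient spin-echo sequence with square
#' diffusion gradients, used to map a maximum b-value to the minimum
#' achievable echo time and the resulting T2 attenuation. The gradients are
#' packed tightly around the refocusing window: equal gradient durations
#' delta, gradient separation Delta = delta + t_refocus, and
#' TE = t_pre + 2 delta + t_refocus + t_post. Spin-echo symmetry of the
#' refocusing pulse (excitation-to-180 centre = TE/2) is not enforced; the
#' model is a lower bound on TE for the stated constants.
#'
#' @param t_pre delay from the 90 degree excitation pulse to the onset of the
#'   first diffusion gradient, ms (default 5).
#' @param t_refocus duration of the 180 degree refocusing window including
#'   slice-selection and crushers, ms (default 5).
#' @param t_post delay from the end of the second gradient to the echo, ms
#'   (default 15).
#' @param gradient_strength maximum gradient amplitude, mT/m (default 80).
#' @param t2 tissue T2, ms; \code{Inf} disables relaxation.
#' @param gamma proton gyromagnetic ratio, rad s^-1 T^-1.
#' @return a \code{timing_model} object.
#' @export
timing_model <- function(t_pre = 5, t_refocus = 5, t_post = 15,
                         gradient_strength = 80, t2 = Inf,
                         gamma = 2.6752219e8) {
  stopifnot(t_pre >= 0, t_refocus >= 0, t_post >= 0,
            gradient_strength > 0, t2 > 0, gamma > 0)
  structure(list(t_pre = t_pre, t_refocus = t_refocus, t_post = t_post,
                 gradient_strength = gradient_strength, t2 = t2,
                 gamma = gamma),
            class = "timing_model")
}

#' @export
print.timing_model <- function(x, ...) {
  cat(sprintf(
    "PGSE timing: t_pre %g ms, refocus %g ms, t_post %g ms, G %g mT/m, T2 %s\n",
    x$t_pre, x$t_refocus, x$t_post, x$gradient_strength,
    if (is.infinite(x$t2)) "ignored" else paste0(x$t2, " ms")))
  invisible(x)
}

#' Minimum echo time for a maximum b-value
#'
#' Solves b = gamma^2 G^2 delta^2 (Delta - delta/3) with
#' Delta = delta + t_refocus for the gradient duration delta (monotone
#' root-finding to 1e-6 ms), then returns
#' TE = t_pre + 2 delta + t_refocus + t_post. TE is continuous and strictly
#' increasing in b_max, with TE(0) = t_pre + t_refocus + t_post.
#'
#' @param b_max maximum b-value of the protocol, s/mm^2.
#' @param model a [timing_model()].
#' @return echo time in ms, with the solved \code{delta} (ms) as attribute.
#' @examples
#' min_echo_time(0, timing_model())     # 25 ms
#' @export
min_echo_time <- function(b_max, model = timing_model()) {
  if (b_max < 0) stop("b_max must be non-negative")
  te0 <- model$t_pre + model$t_refocus + model$t_post
  if (b_max == 0) return(structure(te0, delta = 0))

  G <- model$gradient_strength * 1e-3          # T/m
  tr <- model$t_refocus * 1e-3                 # s
  b_si <- b_max * 1e6                          # s/m^2
  k <- model$gamma^2 * G^2
  f <- function(delta) k * delta^2 * (delta * 2 / 3 + tr) - b_si

  upper <- 1e-3
  while (f(upper) < 0) upper <- upper * 2
  delta <- stats::uniroot(f, c(0, upper), tol = 1e-6 * 1e-3)$root  # s
  delta_ms <- delta * 1e3
  structure(te0 + 2 * delta_ms, delta = delta_ms)
}

#' T2 attenuation factor
#'
#' exp(-TE / T2); equals 1 when relaxation is ignored (T2 = Inf) or TE = 0.
#'
#' @param te echo time, ms.
#' @param t2 tissue T2, ms (\code{Inf} allowed).
#' @return attenuation factor in (0, 1].
#' @export
t2_attenuation <- function(te, t2) {
  stopifnot(all(te >= 0), t2 > 0)
  if (is.infinite(t2)) return(rep(1, length(te)) + te * 0)
  exp(-te / t2)
}

#' Effect sizes attenuated by the echo-time penalty of b_max
#'
#' Scales all component effect sizes uniformly by the T2 attenuation at the
#' minimum echo time the protocol's maximum b-value allows, so that protocols
#' reaching for high b-values pay a sensitivity penalty.
#'
#' @param eps component effect sizes.
#' @param b_max maximum b-value of the candidate protocol, s/mm^2.
#' @param model a [timing_model()].
#' @return list with \code{eps} (attenuated), \code{te} (ms) and
#'   \code{attenuation}.
#' @export
attenuated_effect_sizes <- function(eps, b_max, model = timing_model()) {
  te <- min_echo_time(b_max, model)
  a <- t2_attenuation(as.numeric(te), model$t2)
  list(eps = a * eps, te = as.numeric(te), attenuation = a)
}
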