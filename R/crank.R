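#' Crank sphere-diffusion extraction model
#'
#' Analytic series solution of Fick's second law for a sphere initially at
#' uniform solute concentration with the surface held at zero concentration:
#'
#'   M_t / M_inf = 1 - (6/pi^2) * sum_{n>=1} (1/n^2) exp(-D n^2 pi^2 t / r^2)
#'
#' The fraction released depends on time only through the Fourier number
#' `Fo = D t / r^2`. The series is truncated adaptively: summation stops when
#' the next term falls below `tol`, with a hard cap of `max_terms` terms. For
#' very small Fourier numbers (< 1e-4) the series converges slowly and a
#' warning is raised; no short-time approximation is substituted.
#'
#' @param t Time(s), s (non-negative).
#' @param D Internal diffusivity, m^2 s^-1 (> 0).
#' @param r Particle radius, m (> 0).
#' @param tol Series-term truncation tolerance.
#' @param max_terms Hard cap on the number of series terms.
#' @return Normalized cumulative yield `M_t / M_inf` in `[0, 1]`, one value
#'   per element of `t`.
#' @examples
#' crank_yield(c(0, 600, 3600), D = 1e-12, r = 1e-4)
#' @export
crank_yield <- function(t, D, r, tol = 1e-12, max_terms = 1e5) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0) abort("D must be a single positive number")
  if (!is.numeric(r) || length(r) != 1L || r <= 0) abort("r must be a single positive number")
  if (any(t < 0)) abort("t must be non-negative")
  fo <- D * t / r^2
  out <- numeric(length(fo))
  pos <- fo > 0
  if (any(fo[pos] < 1e-4)) {
    warn("Fourier number below 1e-4: the diffusion series converges slowly")
  }
  if (any(pos)) out[pos] <- vapply(fo[pos], crank_series, numeric(1),
                                   tol = tol, max_terms = max_terms)
  pmin(pmax(out, 0), 1)
}

crank_series <- function(fo, tol, max_terms) {
  s <- 0
  n <- 0L
  chunk <- 256L
  repeat {
    idx <- (n + 1L):min(n + chunk, max_terms)
    terms <- exp(-(idx^2) * pi^2 * fo) / idx^2
    s <- s + sum(terms)
    n <- idx[length(idx)]
    if (terms[length(terms)] < tol || n >= max_terms) break
  }
  1 - (6 / pi^2) * s
}
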