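# RNG hygiene: run `code` under `seed` and restore the caller's RNG state
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Specify replicate noise for the synthetic-data generator
#'
#' Emulates the replicate-level scatter of extraction experiments, which is
#' unpublished for the embedded study (extractions were run in triplicate);
#' the default 2% multiplicative noise is typical of gravimetric yield
#' determinations.
#'
#' @param kind `"multiplicative"` (`y * (1 + sigma * eps)`) or `"additive"`
#'   (`y + sigma * eps`), `eps ~ N(0, 1)`.
#' @param sigma Noise scale, `>= 0`.
#' @param seed Integer seed; the same spec always produces the same noise.
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(kind = c("multiplicative", "additive"), sigma = 0.02,
                       seed = 1L) {
  kind <- match.arg(kind)
  if (!is.numeric(sigma) || sigma < 0) abort("sigma must be non-negative")
  structure(list(kind = kind, sigma = sigma, seed = as.integer(seed)),
            class = "noise_spec")
}

#' Default sampling grid for synthetic extraction curves
#'
#' A 6-hour horizon with sampling biased toward early times, matching how
#' supercritical-extraction curves are usually collected (frequent early
#' weighings through the near-linear period, sparser ones in the
#' diffusion-limited tail).
#'
#' @param horizon Final time, s.
#' @return Increasing numeric vector of times in seconds (17 points for the
#'   default horizon).
#' @export
default_sampling_times <- function(horizon = 6 * 3600) {
  minutes <- c(5, 10, 15, 20, 30, 40, 50, 60, 80, 100, 120, 150, 180, 210,
               240, 300, 360)
  tt <- minutes * 60
  tt <- tt[tt <= horizon]
  if (max(tt) < horizon) tt <- c(tt, horizon)
  tt
}

#' Simulate a noisy extraction curve with known ground truth
#'
#' Evaluates one of the three forward models on a time grid, applies the
#' noise specification and clips negative values at zero (yields cannot be
#' negative; noisy curves are deliberately not monotonized, so fitters must
#' tolerate non-monotone data). The noise-free truth is stored alongside.
#'
#' @param model `"crank"`, `"sovova"` or `"reverchon"`.
#' @param params Named list of model parameters:
#'   crank `D, r`; sovova `x0, xk, yr, Z, W, qdot`;
#'   reverchon `ti, K, bed` (+ optional `q0`, `n_cells`).
#' @param times Strictly increasing times, s.
#' @param noise A [noise_spec()]; the default is noise-free.
#' @return Tibble with `time` and `yield`, carrying attributes `"truth"`
#'   (model, parameters and the clean curve) and `"noise"`.
#' @examples
#' simulate_curve("crank", list(D = 1e-12, r = 1e-4),
#'                times = default_sampling_times(),
#'                noise = noise_spec(sigma = 0.02, seed = 7))
#' @export
simulate_curve <- function(model, params, times = default_sampling_times(),
                           noise = noise_spec(sigma = 0)) {
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  stopifnot(inherits(noise, "noise_spec"))
  clean <- forward_curve(model, params, times)
  y <- if (noise$sigma == 0) {
    clean
  } else {
    eps <- with_preserved_seed(noise$seed, rnorm(length(clean)))
    if (noise$kind == "multiplicative") clean * (1 + noise$sigma * eps)
    else clean + noise$sigma * eps
  }
  out <- tibble::tibble(time = times, yield = pmax(y, 0))
  attr(out, "truth") <- list(model = model, params = params, clean = clean)
  attr(out, "noise") <- noise
  out
}

#' Simulate design responses from a known surface
#'
#' Evaluates a fitted (or constructed) quadratic surface at every run of a
#' design and adds per-run noise, giving design tables with known ground
#' truth for parameter-recovery studies. Replicated centre points receive
#' independent noise.
#'
#' @param surface An `sfe_surface` whose factors all appear in `design`.
#' @param design A design table.
#' @param noise A [noise_spec()]; additive noise acts on the surface's
#'   response scale.
#' @return The design with the surface's response column replaced by the
#'   simulated values (response scale metadata updated to the surface's).
#' @export
simulate_design_response <- function(surface, design, noise = noise_spec(
                                       kind = "additive", sigma = 0)) {
  stopifnot(inherits(surface, "sfe_surface"), inherits(noise, "noise_spec"))
  fac <- surface$factors$name
  meta <- design_meta(design)
  if (is.null(meta$factors)) abort("`design` must be a design table")
  if (!setequal(fac, meta$factors$name)) {
    abort(paste0("surface factors (", paste(fac, collapse = ", "),
                 ") do not match design factors (",
                 paste(meta$factors$name, collapse = ", "), ")"))
  }
  clean <- predict(surface, design, warn_extrapolation = FALSE)
  y <- if (noise$sigma == 0) {
    clean
  } else {
    eps <- with_preserved_seed(noise$seed, rnorm(length(clean)))
    if (noise$kind == "multiplicative") clean * (1 + noise$sigma * eps)
    else clean + noise$sigma * eps
  }
  design[[surface$response]] <- y
  responses <- meta$responses
  responses[[surface$response]] <- surface$response_scale
  attr(design, "responses") <- responses
  design
}
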