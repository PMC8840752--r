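# forward evaluation shared by the simulator and the fitter ------------------

forward_curve <- function(model, params, times) {
  switch(model,
    crank = crank_yield(times, D = params$D, r = params$r),
    sovova = {
      p <- sovova_parameters(params$x0, params$xk, params$yr, params$Z, params$W)
      sovova_yield(params$qdot * times, p)
    },
    reverchon = reverchon_yield(
      times, ti = params$ti, K = params$K, bed = params$bed,
      q0 = params$q0 %||% 1, n_cells = params$n_cells %||% 50
    )$yield,
    abort(paste0("unknown model kind `", model, "`"))
  )
}

model_free_parameters <- function(model) {
  switch(model,
    crank = "D", sovova = c("Z", "W", "xk", "yr"), reverchon = c("ti", "K"))
}

#' Fit a kinetic extraction model to an observed curve
#'
#' Least-squares estimation of the free parameters of one of the three
#' forward models from a cumulative extraction curve, using multi-start
#' Nelder-Mead on transformed parameters. Strictly positive parameters are
#' optimized on the log scale; the Sovova constraint `xk <= x0` is enforced
#' through a logit transform of `xk / x0`. Starts beyond the first jitter the
#' heuristic (or supplied) initial point with seeded Gaussian perturbations,
#' so a fit is bit-reproducible for a given seed and data.
#'
#' Free parameters and required fixed quantities per model:
#'
#' * `"crank"`: fits `D`; requires `fixed$r` (particle radius, m). Curve
#'   values on the normalized `M_t / M_inf` basis.
#' * `"sovova"`: fits `Z, W, xk, yr`; requires `fixed$qdot` (specific solvent
#'   flow, s^-1). `fixed$x0` defaults to the curve's final/maximum value (the
#'   exhaustion asymptote). Curve values on the extract-per-insoluble-solid
#'   basis.
#' * `"reverchon"`: fits `ti, K`; requires `fixed$bed` (a [bed_properties()]
#'   object). Curve values on the normalized basis.
#'
#' @param curve Tibble/data frame with `time` (s) and `yield` columns.
#' @param model `"crank"`, `"sovova"` or `"reverchon"`.
#' @param fixed Named list of known quantities (see above).
#' @param init Optional named list of starting values for the free
#'   parameters; defaults to moment-based heuristics (e.g. `D` from the 63.2%
#'   crossing time).
#' @param n_starts Number of Nelder-Mead starts (first is the heuristic
#'   start, the rest are jittered).
#' @param seed Integer seed controlling the start jitter.
#' @param control Overrides for [stats::optim()] control (defaults:
#'   `reltol = 1e-12`, `maxit = 1e4`).
#' @return An object of class `sfe_kinfit` with `tidy()`, `glance()`,
#'   `augment()`, `predict()` and `autoplot()` methods. Contains the best
#'   estimates over all starts, the SSE, R2, evaluation count, per-start
#'   results and any derived physical coefficients (`kf`/`ks` for Sovova,
#'   `Di`/`kTM` for Reverchon) obtainable from `fixed`.
#' @examples
#' curve <- simulate_curve("crank", list(D = 1e-12, r = 1e-4),
#'                         times = seq(60, 7200, by = 240))
#' fit <- fit_kinetics(curve, "crank", fixed = list(r = 1e-4), n_starts = 2)
#' glance(fit)
#' @export
fit_kinetics <- function(curve, model = c("crank", "sovova", "reverchon"),
                         fixed = list(), init = NULL, n_starts = 8, seed = 1,
                         control = list()) {
  model <- match.arg(model)
  curve <- tibble::as_tibble(curve)
  if (!all(c("time", "yield") %in% names(curve))) {
    abort("curve must have `time` and `yield` columns")
  }
  curve <- curve[stats::complete.cases(curve[, c("time", "yield")]), ]
  free <- model_free_parameters(model)
  if (nrow(curve) == 0) abort("curve is empty")
  if (nrow(curve) < 2 * length(free)) {
    abort(paste0("need at least ", 2 * length(free), " observations to fit ",
                 length(free), " parameter(s); have ", nrow(curve)))
  }
  tt <- curve$time
  yy <- curve$yield

  fixed <- check_fixed(model, fixed, curve)
  flags <- character(0)
  ord <- order(tt)
  y_ord <- yy[ord]
  n <- length(y_ord)
  if (n >= 3) {
    last_step <- y_ord[n] - y_ord[n - 1]
    if (is.finite(last_step) && max(y_ord) > 0 && last_step > 0.05 * max(y_ord)) {
      flags <- c(flags, "asymptote_uncertain")
      warn("curve is still rising by > 5% of its maximum at the last point; asymptote may be unidentifiable")
    }
  }

  theta0 <- transform_to_theta(model, init %||% default_init(model, curve, fixed), fixed)
  d <- length(theta0)
  n_eval <- 0L
  objective <- function(theta) {
    n_eval <<- n_eval + 1L
    pars <- transform_from_theta(model, theta, fixed)
    # extreme trial parameters may trip slow-convergence warnings; the
    # objective only needs the value
    pred <- tryCatch(suppressWarnings(forward_curve(model, pars, tt)),
                     error = function(e) NULL)
    if (is.null(pred) || any(!is.finite(pred))) return(1e300)
    sum((pred - yy)^2)
  }

  ctl <- modifyList(list(reltol = 1e-12, maxit = 1e4), control)
  jitters <- with_preserved_seed(as.integer(seed), {
    matrix(rnorm((n_starts - 1) * d, sd = 0.5), ncol = d)
  })
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    th <- if (s == 1) theta0 else theta0 + jitters[s - 1, ]
    res <- withCallingHandlers(
      optim(th, objective, method = "Nelder-Mead", control = ctl),
      warning = function(w) {
        # Nelder-Mead is used deliberately for 1-parameter fits too
        if (grepl("one-dimensional optimization", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    starts[[s]] <- list(par = res$par, sse = res$value,
                        converged = res$convergence == 0L)
  }
  sses <- vapply(starts, `[[`, numeric(1), "sse")
  best <- starts[[which.min(sses)]]
  est <- transform_from_theta(model, best$par, fixed)

  fitted_vals <- forward_curve(model, est, tt)
  sse <- sum((fitted_vals - yy)^2)
  sst <- sum((yy - mean(yy))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_

  derived <- derived_coefficients(model, est, fixed)
  structure(
    list(
      model = model,
      estimates = est[model_free_parameters(model)],
      fixed = fixed,
      derived = derived,
      sse = sse,
      r_squared = r2,
      n_evaluations = n_eval,
      converged = best$converged,
      starts = tibble::tibble(
        start = seq_len(n_starts), sse = sses,
        converged = vapply(starts, `[[`, logical(1), "converged")
      ),
      seed = as.integer(seed),
      flags = flags,
      curve = curve,
      fitted = fitted_vals
    ),
    class = "sfe_kinfit"
  )
}

check_fixed <- function(model, fixed, curve) {
  need <- switch(model, crank = "r", sovova = "qdot", reverchon = "bed")
  missing_f <- setdiff(need, names(fixed))
  if (length(missing_f) > 0) {
    abort(paste0("fit for model `", model, "` requires fixed quantities: ",
                 paste(missing_f, collapse = ", ")))
  }
  if (model == "sovova" && is.null(fixed$x0)) {
    fixed$x0 <- max(curve$yield) # exhaustion asymptote estimate
    if (fixed$x0 <= 0) abort("cannot fix x0 from a non-positive curve; supply fixed$x0")
  }
  if (model == "reverchon" && is.null(fixed$q0)) fixed$q0 <- 1
  fixed
}

default_init <- function(model, curve, fixed) {
  tt <- curve$time
  yy <- curve$yield
  ymax <- max(yy)
  t63 <- {
    i <- which(yy >= 0.632 * ymax)[1]
    if (is.na(i) || tt[i] <= 0) max(tt) / 2 else tt[i]
  }
  switch(model,
    crank = list(D = fixed$r^2 / (pi^2 * t63)),
    sovova = {
      x0 <- fixed$x0
      qq <- fixed$qdot * tt
      i2 <- max(2L, which(qq > 0)[1])
      slope <- yy[i2] / qq[i2] # initial de/dq ~ yr (1 - exp(-Z))
      Z0 <- 0.1
      yr0 <- max(slope / (1 - exp(-Z0)), 1e-6)
      list(Z = Z0, W = 0.1, xk = x0 / 2, yr = yr0)
    },
    reverchon = list(ti = t63, K = 1e-3)
  )
}

transform_to_theta <- function(model, init, fixed) {
  free <- model_free_parameters(model)
  missing_f <- setdiff(free, names(init))
  if (length(missing_f) > 0) {
    abort(paste0("init lacks parameter(s): ", paste(missing_f, collapse = ", ")))
  }
  if (model == "sovova") {
    frac <- min(max(init$xk / fixed$x0, 1e-8), 1 - 1e-8)
    c(log(init$Z), log(init$W), stats::qlogis(frac), log(init$yr))
  } else {
    log(unlist(init[free]))
  }
}

transform_from_theta <- function(model, theta, fixed) {
  theta <- unname(theta)
  switch(model,
    crank = list(D = exp(theta[1]), r = fixed$r),
    sovova = list(
      x0 = fixed$x0, xk = fixed$x0 * stats::plogis(theta[3]),
      yr = exp(theta[4]), Z = exp(theta[1]), W = exp(theta[2]),
      qdot = fixed$qdot
    ),
    reverchon = list(ti = exp(theta[1]), K = exp(theta[2]), bed = fixed$bed,
                     q0 = fixed$q0, n_cells = fixed$n_cells %||% 50)
  )
}

derived_coefficients <- function(model, est, fixed) {
  out <- list()
  if (model == "sovova" && !is.null(fixed$bed)) {
    mt <- tryCatch(sovova_mass_transfer(est$Z, est$W, fixed$bed),
                   error = function(e) NULL)
    if (!is.null(mt)) out <- as.list(mt)
  }
  if (model == "reverchon" && !is.null(fixed$geometry)) {
    rc <- tryCatch(reverchon_coefficients(est$ti, fixed$geometry, fixed$bed),
                   error = function(e) NULL)
    if (!is.null(rc)) out <- as.list(rc)
  }
  out
}

#' Coefficient of determination of a kinetic fit
#'
#' `R2 = 1 - SSE / SST`, with the total sum of squares about the curve mean.
#' A constant curve has `SST = 0` and the statistic is undefined (`NA` with a
#' warning).
#'
#' @param curve Data frame with `time` and `yield`.
#' @param fit An `sfe_kinfit` (or any object `predict()` accepts the times
#'   of).
#' @return R-squared, possibly `NA`.
#' @export
goodness_of_fit <- function(curve, fit) {
  yy <- curve$yield
  pred <- predict(fit, newtimes = curve$time)
  sst <- sum((yy - mean(yy))^2)
  if (sst == 0) {
    warn("constant curve: R-squared undefined")
    return(NA_real_)
  }
  1 - sum((pred - yy)^2) / sst
}

#' @export
predict.sfe_kinfit <- function(object, newtimes = NULL, ...) {
  tt <- newtimes %||% object$curve$time
  pars <- c(object$estimates, object$fixed)
  forward_curve(object$model, pars, tt)
}

#' @export
print.sfe_kinfit <- function(x, ...) {
  cat("Kinetic model fit (", x$model, "), ", nrow(x$curve), " points\n", sep = "")
  est <- unlist(x$estimates)
  cat("estimates: ", paste0(names(est), " = ", format(est, digits = 5), collapse = ", "), "\n")
  if (length(x$derived) > 0) {
    dv <- unlist(x$derived)
    cat("derived:   ", paste0(names(dv), " = ", format(dv, digits = 5), collapse = ", "), "\n")
  }
  cat("SSE = ", format(x$sse, digits = 6), ", R2 = ", format(x$r_squared, digits = 6),
      ", evaluations = ", x$n_evaluations, ", converged = ", x$converged, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.sfe_kinfit <- function(x, ...) {
  est <- unlist(x$estimates)
  out <- tibble::tibble(term = names(est), estimate = unname(est), kind = "fitted")
  if (length(x$derived) > 0) {
    dv <- unlist(x$derived)
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = names(dv), estimate = unname(dv), kind = "derived"
    ))
  }
  out
}

#' @export
glance.sfe_kinfit <- function(x, ...) {
  tibble::tibble(
    model = x$model, sse = x$sse, r.squared = x$r_squared,
    n.evaluations = x$n_evaluations, converged = x$converged,
    nobs = nrow(x$curve), n.starts = nrow(x$starts), seed = x$seed
  )
}

#' @export
augment.sfe_kinfit <- function(x, ...) {
  dplyr::mutate(x$curve, .fitted = x$fitted, .resid = .data$yield - x$fitted)
}
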