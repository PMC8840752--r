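#' Fit a full second-order response surface
#'
#' Fits the 10-term full quadratic basis (intercept, linear, pure quadratic
#' and all two-way interaction terms) to one response of a design table by
#' ordinary least squares, the standard response-surface model for
#' Box-Behnken data. By default the fit is in natural (uncoded) units, the
#' parameterization under which sequential sums of squares reproduce
#' Minitab-style ANOVA tables for these designs.
#'
#' @param data A design table from [design_table()] or [sfe_fixture()].
#' @param response Name of the response column to fit.
#' @param scale Response scale to fit on: `"as_stored"` keeps the scale the
#'   table declares, `"percent"`/`"fraction"` convert first. Rescaling the
#'   response by 100 multiplies every coefficient by 100 and leaves R2, all
#'   F ratios and p-values unchanged.
#' @param coding `"natural"` (default) or `"coded"` factor units.
#' @return An object of class `sfe_surface` with [tidy()], [glance()],
#'   [predict()][predict.sfe_surface], [surface_anova()], [optimize_surface()]
#'   and [autoplot()] methods.
#' @examples
#' bbd <- sfe_fixture("table3")
#' fit <- fit_surface(bbd, "selectivity", scale = "fraction")
#' glance(fit)
#' @export
fit_surface <- function(data, response,
                        scale = c("as_stored", "percent", "fraction"),
                        coding = c("natural", "coded")) {
  scale <- match.arg(scale)
  coding <- match.arg(coding)
  meta <- design_meta(data)
  if (is.null(meta$factors)) abort("`data` must be a design table (see design_table())")
  if (!response %in% names(meta$responses)) {
    abort(paste0("unknown response `", response, "`; available: ",
                 paste(names(meta$responses), collapse = ", ")))
  }
  if (scale != "as_stored") data <- convert_response_scale(data, response, scale)
  if (coding == "coded") data <- encode_design(data)

  drop <- is.na(data[[response]])
  if (any(drop)) {
    warn(paste0("dropping ", sum(drop), " run(s) with missing `", response,
                "`: ", paste(data$run[drop], collapse = ", ")))
    data <- data[!drop, , drop = FALSE]
  }

  fac <- design_meta(data)$factors$name
  terms <- quadratic_terms(fac)
  fml <- stats::reformulate(terms, response = as.name(response))
  n <- nrow(data)
  p <- length(terms) + 1L
  if (n < p) {
    abort(paste0("need at least ", p, " runs to fit ", p, " coefficients; have ", n))
  }
  X <- stats::model.matrix(fml, data = data)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    abort(paste0("design is rank deficient; collinear terms: ",
                 paste(aliased, collapse = ", ")))
  }
  fit <- lm(fml, data = data)

  new_surface(fit, data, response, design_meta(data)$responses[[response]], coding)
}

quadratic_terms <- function(fac) {
  k <- length(fac)
  sq <- paste0("I(", fac, "^2)")
  inter <- character(0)
  if (k >= 2) {
    pairs <- utils::combn(fac, 2)
    inter <- paste0(pairs[1, ], ":", pairs[2, ])
  }
  c(fac, sq, inter)
}

new_surface <- function(fit, data, response, response_scale, coding) {
  fac <- design_meta(data)$factors$name
  cf <- coef(fit)
  se <- sqrt(diag(suppressWarnings(stats::vcov(fit))))
  k <- length(fac)
  linear <- setNames(cf[fac], fac)
  quadratic <- setNames(cf[paste0("I(", fac, "^2)")], fac)
  inter <- setNames(numeric(0), character(0))
  if (k >= 2) {
    pairs <- utils::combn(fac, 2)
    nm <- paste0(pairs[1, ], ":", pairs[2, ])
    # lm may report either A:B or B:A depending on formula order
    got <- vapply(seq_along(nm), function(i) {
      alt <- paste0(pairs[2, i], ":", pairs[1, i])
      if (nm[i] %in% names(cf)) cf[[nm[i]]] else cf[[alt]]
    }, numeric(1))
    inter <- setNames(got, nm)
  }
  r2 <- suppressWarnings(summary(fit))$r.squared
  structure(
    list(
      coefficients = list(
        intercept = unname(cf[["(Intercept)"]]),
        linear = linear, quadratic = quadratic, interaction = inter
      ),
      std_error = se,
      factors = design_meta(data)$factors,
      response = response,
      response_scale = response_scale,
      coding = coding,
      r_squared = r2,
      lm = fit,
      data = data
    ),
    class = "sfe_surface"
  )
}

#' Rescale a fitted surface between percent and fraction response scales
#'
#' Multiplies (or divides) every coefficient by exactly 100 and rescales the
#' stored response data to match, leaving R2 and all inference invariant.
#'
#' @param object An `sfe_surface`.
#' @param scale Target scale.
#' @return A rescaled `sfe_surface`.
#' @export
rescale_surface <- function(object, scale = c("percent", "fraction")) {
  scale <- match.arg(scale)
  if (object$response_scale == scale) return(object)
  f <- if (scale == "percent") 100 else 1 / 100
  object$coefficients$intercept <- object$coefficients$intercept * f
  object$coefficients$linear <- object$coefficients$linear * f
  object$coefficients$quadratic <- object$coefficients$quadratic * f
  object$coefficients$interaction <- object$coefficients$interaction * f
  object$std_error <- object$std_error * f
  object$data <- convert_response_scale(object$data, object$response, scale)
  object$lm <- NULL # invalidated; refit lazily from data when needed
  object$response_scale <- scale
  object
}

surface_lm <- function(object) {
  if (!is.null(object$lm)) return(object$lm)
  fac <- object$factors$name
  fml <- stats::reformulate(quadratic_terms(fac), response = as.name(object$response))
  lm(fml, data = object$data)
}

#' Evaluate a fitted surface at new factor settings
#'
#' Pure polynomial evaluation of the stored coefficients (no call into the
#' underlying `lm`), on the surface's declared factor coding and response
#' scale. Points outside the experimental box trigger an extrapolation
#' warning.
#'
#' @param object An `sfe_surface`.
#' @param newdata Data frame with one column per factor.
#' @param warn_extrapolation Warn when a point lies outside `[low, high]`.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.sfe_surface <- function(object, newdata, warn_extrapolation = TRUE, ...) {
  fac <- object$factors$name
  missing_cols <- setdiff(fac, names(newdata))
  if (length(missing_cols) > 0) {
    abort(paste0("newdata lacks factor column(s): ", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(newdata)[, fac, drop = FALSE])
  if (!is.numeric(X)) abort("factor columns must be numeric")
  if (warn_extrapolation && object$coding == "natural") {
    lo <- object$factors$low
    hi <- object$factors$high
    out <- apply(X, 1L, function(x) any(x < lo - 1e-9) || any(x > hi + 1e-9))
    if (any(out)) warn(paste0("predicting outside the experimental box for ",
                              sum(out), " point(s)"))
  }
  eval_quadratic(object$coefficients, X)
}

eval_quadratic <- function(cf, X) {
  fac <- names(cf$linear)
  val <- rep(cf$intercept, nrow(X))
  for (f in fac) val <- val + cf$linear[[f]] * X[, f] + cf$quadratic[[f]] * X[, f]^2
  for (nm in names(cf$interaction)) {
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    val <- val + cf$interaction[[nm]] * X[, ab[1]] * X[, ab[2]]
  }
  unname(val)
}

#' @export
print.sfe_surface <- function(x, ...) {
  cat("Full quadratic response surface for `", x$response, "` (",
      x$response_scale, " scale, ", x$coding, " units)\n", sep = "")
  cat("R-squared:", format(x$r_squared, digits = 6), "\n\n")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' @export
tidy.sfe_surface <- function(x, ...) {
  cf <- x$coefficients
  tibble::tibble(
    term = c("(Intercept)", names(cf$linear), paste0(names(cf$quadratic), "^2"),
             names(cf$interaction)),
    type = c("intercept", rep("linear", length(cf$linear)),
             rep("quadratic", length(cf$quadratic)),
             rep("interaction", length(cf$interaction))),
    estimate = unname(c(cf$intercept, cf$linear, cf$quadratic, cf$interaction)),
    std.error = unname(x$std_error)
  )
}

#' @export
glance.sfe_surface <- function(x, ...) {
  sm <- suppressWarnings(summary(surface_lm(x)))
  tibble::tibble(
    r.squared = x$r_squared,
    adj.r.squared = sm$adj.r.squared,
    sigma = sm$sigma,
    df.residual = sm$df[2L],
    nobs = nrow(x$data),
    response = x$response,
    scale = x$response_scale
  )
}

#' Fit a two-level factorial model with optional centre-point curvature
#'
#' Fits the first-order model with interaction, `y ~ x1 + x2 + x1:x2`, on the
#' coded -1/+1 scale by least squares. With `center_term = TRUE`, an
#' indicator for the centre replicates is added, whose coefficient is the
#' curvature estimate `mean(centre) - mean(corners)`. Factorial effects are
#' twice the coded coefficients.
#'
#' @param data A design table with two factors (e.g. `sfe_fixture("table1")`).
#' @param response Response column name.
#' @param center_term Add the centre-point curvature indicator.
#' @param scale As in [fit_surface()].
#' @return An object of class `sfe_factorial` with `tidy()`/`glance()`.
#' @examples
#' fit <- fit_factorial(sfe_fixture("table1"), "yield", center_term = TRUE)
#' tidy(fit)
#' @export
fit_factorial <- function(data, response, center_term = FALSE,
                          scale = c("as_stored", "percent", "fraction")) {
  scale <- match.arg(scale)
  meta <- design_meta(data)
  if (is.null(meta$factors)) abort("`data` must be a design table")
  if (nrow(meta$factors) != 2L) abort("fit_factorial() expects exactly two factors")
  if (!response %in% names(meta$responses)) abort(paste0("unknown response `", response, "`"))
  if (scale != "as_stored") data <- convert_response_scale(data, response, scale)
  coded <- encode_design(data)
  fac <- meta$factors$name
  is_center <- coded[[fac[1]]] == 0 & coded[[fac[2]]] == 0
  if (center_term && !any(is_center)) {
    abort("center_term = TRUE but the design has no centre-point runs")
  }
  df <- tibble::tibble(
    y = coded[[response]],
    x1 = coded[[fac[1]]], x2 = coded[[fac[2]]],
    ctr = as.numeric(is_center)
  )
  fml <- if (center_term) y ~ x1 + x2 + x1:x2 + ctr else y ~ x1 + x2 + x1:x2
  fit <- lm(fml, data = df)
  cf <- coef(fit)
  structure(
    list(
      coefficients = list(
        intercept = unname(cf[["(Intercept)"]]),
        linear = setNames(unname(cf[c("x1", "x2")]), fac),
        interaction = setNames(unname(cf[["x1:x2"]]), paste0(fac[1], ":", fac[2])),
        curvature = if (center_term) unname(cf[["ctr"]]) else NA_real_
      ),
      effects = setNames(2 * unname(cf[c("x1", "x2", "x1:x2")]),
                         c(fac, paste0(fac[1], ":", fac[2]))),
      factors = meta$factors,
      response = response,
      response_scale = design_meta(data)$responses[[response]],
      r_squared = suppressWarnings(summary(fit))$r.squared,
      lm = fit,
      data = data
    ),
    class = "sfe_factorial"
  )
}

#' @export
tidy.sfe_factorial <- function(x, ...) {
  cf <- x$coefficients
  terms <- c("(Intercept)", names(cf$linear), names(cf$interaction))
  est <- c(cf$intercept, unname(cf$linear), unname(cf$interaction))
  eff <- c(NA_real_, unname(x$effects))
  out <- tibble::tibble(term = terms, estimate = est, effect = eff)
  if (!is.na(cf$curvature)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "curvature", estimate = cf$curvature, effect = NA_real_
    ))
  }
  out
}

#' @export
glance.sfe_factorial <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    nobs = nrow(x$data),
    response = x$response,
    scale = x$response_scale
  )
}

#' @export
print.sfe_factorial <- function(x, ...) {
  cat("Two-level factorial fit for `", x$response, "` (coded units)\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}

#' Published regression coefficients shipped for display
#'
#' The source study printed two regression equations: a coded-unit factorial
#' model for global extract yield and an uncoded full quadratic for p-anisic
#' acid selectivity. These printed coefficients are provided verbatim for
#' display and comparison only; all package computations refit the embedded
#' design tables, because the printed coefficients are not exactly
#' reproducible from the rounded published responses (the factorial equation
#' was evidently fitted on unrounded data, and the quadratic's printed
#' constant is inconsistent with its own reported optimum).
#'
#' @param which `"factorial_yield"` or `"bbd_selectivity"`.
#' @return Tibble of printed terms and coefficients.
#' @export
printed_surface_coefficients <- function(which = c("factorial_yield", "bbd_selectivity")) {
  which <- match.arg(which)
  if (which == "factorial_yield") {
    tibble::tibble(
      term = c("(Intercept)", "P", "M", "P:M"),
      estimate = c(1.81281, 0.32906, 0.29094, 0.06094),
      units = "coded", response = "global yield (% w/w)"
    )
  } else {
    tibble::tibble(
      term = c("(Intercept)", "P", "T", "G", "P^2", "T^2", "G^2", "P:T", "P:G", "T:G"),
      estimate = c(-9.742, 8.782e-2, 5.495e-2, 1.660e-2, -1.429e-4, -1.631e-3,
                   -3.523e-5, -1.003e-5, -1.858e-4, -7.097e-4),
      units = "natural", response = "selectivity (% w/w)"
    )
  }
}
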