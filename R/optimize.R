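#' Maximize a fitted quadratic surface over the experimental box
#'
#' Finds the exact global maximum (or minimum) of a quadratic response
#' surface over a finite box by face enumeration: on every face of the box
#' (including the interior and the vertices) the restriction of a quadratic
#' is a lower-dimensional quadratic whose stationary point is a linear solve,
#' so comparing all in-box stationary points and vertices is exhaustive. No
#' iterative search is involved. Ties within `tie_tol` of the optimum are all
#' reported, ordered by the first factor ascending (lower pressure first,
#' matching the usual energy-efficiency preference).
#'
#' @param fit An `sfe_surface`.
#' @param lower,upper Named or positional numeric bounds per factor; default
#'   is the declared `[low, high]` range of each factor. Must be finite.
#' @param maximize Maximize (default) or minimize.
#' @param tie_tol Absolute tolerance for reporting tied optima.
#' @return A tibble of class `sfe_optimum`: one row per (tied) optimum with
#'   the factor settings, the predicted response `.fitted`, one
#'   `<factor>_bound` column per factor (`"at-lower"`, `"at-upper"` or
#'   `"interior"`) and an `interior` flag.
#' @examples
#' fit <- fit_surface(sfe_fixture("table3"), "selectivity", scale = "percent")
#' optimize_surface(fit)
#' @export
optimize_surface <- function(fit, lower = NULL, upper = NULL, maximize = TRUE,
                             tie_tol = 1e-9) {
  if (!inherits(fit, "sfe_surface")) abort("`fit` must be an sfe_surface")
  fac <- fit$factors$name
  k <- length(fac)
  if (is.null(lower)) {
    lower <- if (fit$coding == "coded") rep(-1, k) else fit$factors$low
  }
  if (is.null(upper)) {
    upper <- if (fit$coding == "coded") rep(1, k) else fit$factors$high
  }
  lower <- expand_bound(lower, fac)
  upper <- expand_bound(upper, fac)
  if (any(!is.finite(lower)) || any(!is.finite(upper))) {
    abort("bounds must be finite")
  }
  if (any(lower > upper)) abort("lower bounds exceed upper bounds")

  qd <- quadratic_form(fit$coefficients)
  sign <- if (maximize) 1 else -1

  cands <- enumerate_box_candidates(qd, lower, upper)
  vals <- apply(cands, 1L, function(x) quad_value(qd, x))
  best <- if (maximize) max(vals) else min(vals)
  keep <- which(sign * (best - vals) <= tie_tol * max(1, abs(best)))
  pts <- cands[keep, , drop = FALSE]
  vals <- vals[keep]
  # deduplicate coincident candidate points
  key <- apply(round(pts, 9), 1L, paste, collapse = "|")
  first <- !duplicated(key)
  pts <- pts[first, , drop = FALSE]
  vals <- vals[first]
  ord <- order(pts[, 1])
  pts <- pts[ord, , drop = FALSE]
  vals <- vals[ord]

  tol_b <- 1e-9 * pmax(1, abs(upper - lower))
  flags <- t(apply(pts, 1L, function(x) {
    ifelse(abs(x - lower) <= tol_b, "at-lower",
           ifelse(abs(x - upper) <= tol_b, "at-upper", "interior"))
  }))
  out <- tibble::as_tibble(as.data.frame(pts))
  names(out) <- fac
  out$.fitted <- vals
  for (i in seq_len(k)) out[[paste0(fac[i], "_bound")]] <- flags[, i]
  out$interior <- apply(flags, 1L, function(fl) all(fl == "interior"))
  structure(out,
    class = c("sfe_optimum", class(out)),
    response = fit$response,
    scale = fit$response_scale,
    maximize = maximize
  )
}

expand_bound <- function(b, fac) {
  k <- length(fac)
  if (!is.null(names(b))) {
    if (!setequal(names(b), fac)) abort("bound names must match the factors")
    b <- b[fac]
  }
  if (length(b) == 1L) b <- rep(b, k)
  if (length(b) != k) abort("bounds must have one value per factor")
  as.numeric(b)
}

# quadratic f(x) = a + b'x + x' Q x with Q symmetric
quadratic_form <- function(cf) {
  fac <- names(cf$linear)
  k <- length(fac)
  Q <- matrix(0, k, k, dimnames = list(fac, fac))
  diag(Q) <- cf$quadratic[fac]
  for (nm in names(cf$interaction)) {
    ab <- strsplit(nm, ":", fixed = TRUE)[[1]]
    Q[ab[1], ab[2]] <- Q[ab[1], ab[2]] + cf$interaction[[nm]] / 2
    Q[ab[2], ab[1]] <- Q[ab[2], ab[1]] + cf$interaction[[nm]] / 2
  }
  list(a = cf$intercept, b = cf$linear[fac], Q = Q)
}

quad_value <- function(qd, x) {
  qd$a + sum(qd$b * x) + drop(t(x) %*% qd$Q %*% x)
}

# all vertices and all in-box stationary points of face restrictions
enumerate_box_candidates <- function(qd, lower, upper) {
  k <- length(lower)
  cands <- list()
  subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  for (si in seq_len(nrow(subsets))) {
    free <- which(unlist(subsets[si, ]))
    fixed <- setdiff(seq_len(k), free)
    fixed_assign <- if (length(fixed) > 0) {
      as.matrix(expand.grid(rep(list(c(1, 2)), length(fixed))))
    } else {
      matrix(numeric(0), nrow = 1, ncol = 0)
    }
    for (ai in seq_len(nrow(fixed_assign))) {
      x <- numeric(k)
      if (length(fixed) > 0) {
        x[fixed] <- ifelse(fixed_assign[ai, ] == 1, lower[fixed], upper[fixed])
      }
      if (length(free) == 0L) {
        cands[[length(cands) + 1L]] <- x
        next
      }
      H <- 2 * qd$Q[free, free, drop = FALSE]
      rhs <- -(qd$b[free] + if (length(fixed) > 0) {
        2 * drop(qd$Q[free, fixed, drop = FALSE] %*% x[fixed])
      } else 0)
      sol <- tryCatch(solve(H, rhs), error = function(e) NULL)
      if (is.null(sol) || any(!is.finite(sol))) next # flat direction: covered by sub-faces
      tol <- 1e-9 * pmax(1, upper[free] - lower[free])
      if (all(sol >= lower[free] - tol) && all(sol <= upper[free] + tol)) {
        x[free] <- pmin(pmax(sol, lower[free]), upper[free])
        cands[[length(cands) + 1L]] <- x
      }
    }
  }
  do.call(rbind, cands)
}
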