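# shared fixtures and oracles for the test suite

bbd3 <- function() sfe_fixture("table3")
fact1 <- function() sfe_fixture("table1")

# the reference Sovova parameter set used throughout (magnitudes as published)
ref_sovova <- function() {
  sovova_parameters(x0 = 0.06, xk = 0.035, yr = 0.54, Z = 0.05, W = 0.08)
}

# random valid Sovova parameter sets in the model's physical regime
random_sovova <- function(n, seed = 20260920) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    x0 <- runif(1, 0.01, 0.2)
    sovova_parameters(
      x0 = x0, xk = runif(1, 0, 1) * x0, yr = runif(1, 0.05, 1),
      Z = runif(1, 0.01, 1), W = runif(1, 0.01, 1)
    )
  })
}

# 3-factor Box-Behnken point set (coded), centre replicated three times
bbd_coded_points <- function() {
  pts <- rbind(
    expand.grid(x1 = c(-1, 1), x2 = c(-1, 1), x3 = 0),
    expand.grid(x1 = c(-1, 1), x2 = 0, x3 = c(-1, 1)),
    expand.grid(x1 = 0, x2 = c(-1, 1), x3 = c(-1, 1)),
    data.frame(x1 = 0, x2 = 0, x3 = 0)[rep(1, 3), ]
  )
  rownames(pts) <- NULL
  pts
}

# design table on natural units P/T/G from coded Box-Behnken points
bbd_design_from_surface <- function() {
  fac <- design_factors(
    name = c("P", "T", "G"), unit = c("bar", "degC", "mesh"),
    low = c(200, 40, 42), center = c(250, 50, 60), high = c(300, 60, 150)
  )
  pts <- bbd_coded_points()
  to_nat <- function(code, lo, ce, hi) c(lo, ce, hi)[match(code, c(-1, 0, 1))]
  data <- tibble::tibble(
    run = as.character(seq_len(nrow(pts))),
    P = to_nat(pts$x1, 200, 250, 300),
    T = to_nat(pts$x2, 40, 50, 60),
    G = to_nat(pts$x3, 42, 60, 150),
    y = 0
  )
  design_table(data, fac, c(y = "fraction"))
}

# a known quadratic surface over P/T/G, built by fitting noise-free values
known_surface <- function(coefs = NULL) {
  design <- bbd_design_from_surface()
  if (is.null(coefs)) {
    coefs <- list(
      intercept = 1.2, linear = c(P = 0.01, T = -0.05, G = 0.002),
      quadratic = c(P = -2e-5, T = 6e-4, G = -1e-5),
      interaction = c(`P:T` = 1e-5, `P:G` = -2e-5, `T:G` = 3e-5)
    )
  }
  X <- as.matrix(as.data.frame(design)[, c("P", "T", "G")])
  design$y <- sfekin:::eval_quadratic(coefs, X)
  list(design = design, coefs = coefs)
}

# independent finite-difference oracle for diffusion out of a sphere:
# concentric shells, surface held at zero, released fraction vs Fourier number
fd_sphere_release <- function(fo_out, n_shells = 200) {
  # nondimensional: radius 1, D = 1, time = Fo
  dr <- 1 / n_shells
  r_mid <- (seq_len(n_shells) - 0.5) * dr
  vol <- ((r_mid + dr / 2)^3 - (r_mid - dr / 2)^3) # ~ shell volumes * 3
  rhs <- function(t, u, p) {
    # flux at shell faces; u = concentration per shell midpoint
    r_face <- seq_len(n_shells - 1) * dr
    flux <- -(u[-1] - u[-n_shells]) / dr * r_face^2
    flux_out <- -(0 - u[n_shells]) / (dr / 2) * 1 # surface at r = 1, c = 0
    du <- numeric(n_shells)
    du[1] <- 3 * (-flux[1]) / ((r_face[1])^3 - 0)
    inner <- 2:(n_shells - 1)
    du[inner] <- 3 * (flux[inner - 1] - flux[inner]) /
      ((inner * dr)^3 - ((inner - 1) * dr)^3)
    du[n_shells] <- 3 * (flux[n_shells - 1] - flux_out) /
      (1 - ((n_shells - 1) * dr)^3)
    list(du)
  }
  u0 <- rep(1, n_shells)
  sol <- deSolve::ode(u0, c(0, fo_out), rhs, NULL, method = "lsoda",
                      rtol = 1e-9, atol = 1e-12)
  mass <- apply(sol[, -1, drop = FALSE], 1L, function(u) sum(u * vol))
  released <- 1 - mass / mass[1]
  released[match(fo_out, sol[, 1])]
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), .Machine$double.eps), tol)
}
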