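# Isochoric thermodynamics: the Helmholtz energy density Psi(rho_1, ..,
# rho_n) as fundamental potential, its gradient (chemical potentials) and
# Hessian, isothermal binodal tracing by ODE integration in pressure, and
# critical-point location where det H vanishes.
#
# Psi carries an analytic ideal part, T * sum rho_i (ln rho_i - 1); only the
# smooth excess part is differentiated numerically (central differences with
# Richardson extrapolation).

# Excess Helmholtz energy density (hard-sphere + bonding), ctx-based.
ctx_psi_ex <- function(ctx, T, rho_vec) {
  rho <- sum(rho_vec)
  if (rho <= 0) return(0)
  x <- rho_vec / rho
  phi <- rho * ctx$vs
  db <- ctx_delta(ctx, T, rho)
  mb <- ctx_mass_balance(ctx, rho, x, db$value)
  f_hs <- phi * (4 - 3 * phi) / (1 - phi)^2
  f_b <- sum(x[ctx$sp] * (log(mb$X) - mb$X / 2 + 0.5))
  T * rho * (f_hs + f_b)
}

# FD steps per component: relative with an absolute floor so dilute phases
# stay differentiable.
psi_fd_step <- function(rho_vec) pmax(0.01 * rho_vec, 1e-9)

ctx_psi_grad_ex <- function(ctx, T, rho_vec) {
  n <- length(rho_vec)
  h <- psi_fd_step(rho_vec)
  g <- numeric(n)
  for (i in seq_len(n)) {
    e <- rep(0, n); e[i] <- 1
    d1 <- (ctx_psi_ex(ctx, T, rho_vec + h[i] * e) -
             ctx_psi_ex(ctx, T, rho_vec - h[i] * e)) / (2 * h[i])
    d2 <- (ctx_psi_ex(ctx, T, rho_vec + h[i] / 2 * e) -
             ctx_psi_ex(ctx, T, rho_vec - h[i] / 2 * e)) / h[i]
    g[i] <- (4 * d2 - d1) / 3
  }
  g
}

ctx_psi_hessian <- function(ctx, T, rho_vec) {
  n <- length(rho_vec)
  h <- psi_fd_step(rho_vec)
  f0 <- ctx_psi_ex(ctx, T, rho_vec)
  H <- matrix(0, n, n)
  second <- function(i, hi) {
    e <- rep(0, n); e[i] <- 1
    (ctx_psi_ex(ctx, T, rho_vec + hi * e) - 2 * f0 +
        ctx_psi_ex(ctx, T, rho_vec - hi * e)) / hi^2
  }
  cross <- function(i, j, hi, hj) {
    ei <- rep(0, n); ei[i] <- 1
    ej <- rep(0, n); ej[j] <- 1
    (ctx_psi_ex(ctx, T, rho_vec + hi * ei + hj * ej) -
       ctx_psi_ex(ctx, T, rho_vec + hi * ei - hj * ej) -
       ctx_psi_ex(ctx, T, rho_vec - hi * ei + hj * ej) +
       ctx_psi_ex(ctx, T, rho_vec - hi * ei - hj * ej)) / (4 * hi * hj)
  }
  for (i in seq_len(n)) {
    d1 <- second(i, h[i]); d2 <- second(i, h[i] / 2)
    H[i, i] <- (4 * d2 - d1) / 3
    if (i < n) for (j in (i + 1):n) {
      d1 <- cross(i, j, h[i], h[j])
      d2 <- cross(i, j, h[i] / 2, h[j] / 2)
      H[i, j] <- H[j, i] <- (4 * d2 - d1) / 3
    }
  }
  # ideal part is diagonal and analytic
  H + diag(T / rho_vec, n)
}

#' Helmholtz energy density
#'
#' \eqn{\Psi(\boldsymbol\rho) = \rho\, a(\rho, x)} where a is the Helmholtz
#' free energy per particle; the independent variables are the per-species
#' molar densities.  Units: epsilon / sigma^3.
#'
#' @param rho_vec per-species number densities (length `n_species`).
#' @param T temperature.
#' @param mixture a [mixture_spec()].
#' @param order g_HS expansion order.
#' @return Psi (scalar); 0 at zero total density.
#' @export
psi <- function(rho_vec, T, mixture, order = 1) {
  stopifnot(all(rho_vec >= 0))
  rho <- sum(rho_vec)
  if (rho == 0) return(0)
  ctx <- wertheim_ctx(mixture, order = order)
  id <- sum(ifelse(rho_vec > 0, rho_vec * (log(rho_vec) - 1), 0))
  T * id + ctx_psi_ex(ctx, T, rho_vec)
}

#' Chemical potentials from the Helmholtz energy density
#'
#' \eqn{\mu_i = \partial\Psi/\partial\rho_i}; the ideal part is analytic and
#' the excess part is differentiated by Richardson-extrapolated central
#' differences.
#'
#' @inheritParams psi
#' @return vector of chemical potentials (units epsilon).
#' @export
chemical_potentials <- function(rho_vec, T, mixture, order = 1) {
  stopifnot(all(rho_vec > 0))
  ctx <- wertheim_ctx(mixture, order = order)
  T * log(rho_vec) + ctx_psi_grad_ex(ctx, T, rho_vec)
}

#' Pressure from the isochoric potential
#'
#' \eqn{P = -\Psi + \sum_i \rho_i \mu_i}.
#'
#' @inheritParams psi
#' @return pressure (epsilon/sigma^3).
#' @export
pressure_isochoric <- function(rho_vec, T, mixture, order = 1) {
  sum(rho_vec * chemical_potentials(rho_vec, T, mixture, order)) -
    psi(rho_vec, T, mixture, order)
}

#' Hessian of the Helmholtz energy density
#'
#' \eqn{H_{ij} = \partial^2\Psi/\partial\rho_i\partial\rho_j}, symmetric by
#' construction; positive definiteness marks a locally stable state and a
#' vanishing determinant marks a critical point.
#'
#' @inheritParams psi
#' @return symmetric `n_species` x `n_species` matrix.
#' @export
hessian_psi <- function(rho_vec, T, mixture, order = 1) {
  stopifnot(all(rho_vec > 0))
  ctx <- wertheim_ctx(mixture, order = order)
  ctx_psi_hessian(ctx, T, rho_vec)
}

# ctx-level phase evaluation: mu vector and P.
ctx_phase_eval <- function(ctx, T, r) {
  mu <- T * log(r) + ctx_psi_grad_ex(ctx, T, r)
  id <- sum(r * (log(r) - 1))
  P <- sum(r * mu) - (T * id + ctx_psi_ex(ctx, T, r))
  list(mu = mu, P = P)
}

#' A coexistence point in the isochoric representation
#'
#' Validates (and optionally Newton-refines) a pair of phases against the
#' defining conditions: equal pressure and equal chemical potentials.
#'
#' @param mixture a [mixture_spec()].
#' @param T temperature.
#' @param rho_a,rho_b per-species density vectors of the two phases.
#' @param refine Newton-project onto the coexistence manifold first.
#' @param tol accepted disagreement in P and mu.
#' @return object of class `coexistence_point` with elements `phase_a`,
#'   `phase_b`, `pressure`, `temperature`.
#' @export
coexistence_point <- function(mixture, T, rho_a, rho_b, refine = TRUE,
                              tol = 1e-8) {
  ctx <- wertheim_ctx(mixture)
  if (refine) {
    st <- ctx_project_coexistence(ctx, T, rho_a, rho_b,
                                  P_target = NULL, tol = tol)
    rho_a <- st$rho_a; rho_b <- st$rho_b
  }
  ea <- ctx_phase_eval(ctx, T, rho_a)
  eb <- ctx_phase_eval(ctx, T, rho_b)
  if (abs(ea$P - eb$P) > tol || max(abs(ea$mu - eb$mu)) > tol)
    stop(sprintf(
      "phases do not coexist: |dP| = %.2e, max|dmu| = %.2e",
      abs(ea$P - eb$P), max(abs(ea$mu - eb$mu))))
  structure(list(phase_a = rho_a, phase_b = rho_b,
                 pressure = (ea$P + eb$P) / 2, temperature = T),
            class = "coexistence_point")
}

#' @export
print.coexistence_point <- function(x, ...) {
  xa <- x$phase_a / sum(x$phase_a); xb <- x$phase_b / sum(x$phase_b)
  cat(sprintf(
    "coexistence at T = %g, P = %.6g:\n  phase A rho = %.6g (x1 = %.5f)\n  phase B rho = %.6g (x1 = %.5f)\n",
    x$temperature, x$pressure, sum(x$phase_a), xa[1], sum(x$phase_b), xb[1]))
  invisible(x)
}

# Newton projection onto the coexistence manifold: unknowns (rho_a, rho_b),
# equations mu_a = mu_b (n) and P_a = P_b ( + P_a = P_target when given).
ctx_project_coexistence <- function(ctx, T, rho_a, rho_b, P_target = NULL,
                                    tol = 1e-9, max_iter = 40) {
  y <- c(rho_a, rho_b)
  n <- length(rho_a)
  resid <- function(y) {
    ea <- ctx_phase_eval(ctx, T, y[1:n])
    eb <- ctx_phase_eval(ctx, T, y[n + 1:n])
    r <- c(ea$mu - eb$mu, ea$P - eb$P)
    if (!is.null(P_target)) r <- c(r, ea$P - P_target)
    r
  }
  for (it in seq_len(max_iter)) {
    r0 <- resid(y)
    if (max(abs(r0)) < tol) break
    m <- length(r0)
    J <- matrix(0, m, 2 * n)
    for (j in seq_len(2 * n)) {
      h <- max(1e-6 * abs(y[j]), 1e-9)
      yj <- y; yj[j] <- yj[j] + h
      J[, j] <- (resid(yj) - r0) / h
    }
    step <- tryCatch(qr.solve(J, r0), error = function(e) NULL)
    if (is.null(step)) break
    # damp so densities stay positive
    lam <- 1
    repeat {
      yn <- y - lam * step
      if (all(yn > 0) || lam < 1e-4) break
      lam <- lam / 2
    }
    y <- yn
  }
  list(rho_a = y[1:n], rho_b = y[n + 1:n], residual = max(abs(resid(y))))
}

# Right-hand side of the isothermal coexistence ODE system: with
# mu' = mu'' along the boundary, d mu / dP =: v satisfies rho_a . v = 1 and
# rho_b . v = 1; then d rho_a / dP = H_a^{-1} v, d rho_b / dP = H_b^{-1} v.
ctx_binodal_rhs <- function(ctx, T, y) {
  n <- length(y) / 2
  ra <- y[1:n]; rb <- y[n + 1:n]
  Ha <- ctx_psi_hessian(ctx, T, ra)
  Hb <- ctx_psi_hessian(ctx, T, rb)
  v <- solve(rbind(ra, rb), c(1, 1))
  list(dy = c(solve(Ha, v), solve(Hb, v)),
       detH = c(det(Ha), det(Hb)))
}

#' Trace an isothermal binodal by integrating the coexistence ODEs
#'
#' Starting from a valid coexistence pair, integrates
#' \eqn{d\boldsymbol\rho'/dP} and \eqn{d\boldsymbol\rho''/dP} with an
#' adaptive Runge-Kutta (step-doubling RK4) scheme; every accepted step is
#' Newton-projected back onto the equal-P, equal-mu manifold.  Integration
#' stops at the end of the pressure range, when the step collapses, or when
#' the Hessian determinant of either phase falls below `det_floor` times its
#' starting magnitude (approach to a critical point).
#'
#' @param start a [coexistence_point()].
#' @param T temperature (must match `start`).
#' @param P_range pressure interval `c(from, to)`; `from` defaults to the
#'   start's pressure.
#' @param mixture a [mixture_spec()].
#' @param rtol relative local error tolerance of the integrator.
#' @param det_floor critical-point termination threshold.
#' @param max_steps accepted-step cap.
#' @param order g_HS expansion order.
#' @return object of class `coexistence_curve`: a data frame of points
#'   (P, per-phase densities and compositions) with attributes
#'   `termination` and `temperature`.
#' @export
trace_binodal <- function(start, T, P_range, mixture, rtol = 1e-6,
                          det_floor = 1e-4, max_steps = 400, order = 1) {
  stopifnot(inherits(start, "coexistence_point"))
  if (abs(start$temperature - T) > 1e-12)
    stop("start point temperature does not match T")
  ctx <- wertheim_ctx(mixture, order = order)
  P0 <- if (length(P_range) == 2) P_range[1] else start$pressure
  P_end <- P_range[length(P_range)]
  y <- c(start$phase_a, start$phase_b)
  n <- length(start$phase_a)
  # move the start to P0 if needed
  if (abs(P0 - start$pressure) > 1e-14) {
    pr <- ctx_project_coexistence(ctx, T, y[1:n], y[n + 1:n], P_target = P0)
    y <- c(pr$rho_a, pr$rho_b)
  }
  rhs0 <- ctx_binodal_rhs(ctx, T, y)
  det_ref <- abs(rhs0$detH)
  dirn <- sign(P_end - P0)
  hP <- dirn * max(abs(P_end - P0) / 50, 1e-12)
  P <- P0
  rows <- list()
  push <- function(P, y) {
    ra <- y[1:n]; rb <- y[n + 1:n]
    data.frame(P = P, rho_a = sum(ra), rho_b = sum(rb),
               x_a = ra[1] / sum(ra), x_b = rb[1] / sum(rb),
               rho_a1 = ra[1], rho_a2 = ra[2],
               rho_b1 = rb[1], rho_b2 = rb[2])
  }
  rows[[1]] <- push(P, y)
  termination <- "end of range"
  rk4 <- function(y, P, h) {
    k1 <- ctx_binodal_rhs(ctx, T, y)$dy
    k2 <- ctx_binodal_rhs(ctx, T, y + h / 2 * k1)$dy
    k3 <- ctx_binodal_rhs(ctx, T, y + h / 2 * k2)$dy
    k4 <- ctx_binodal_rhs(ctx, T, y + h * k3)$dy
    y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  steps <- 0L
  while (steps < max_steps) {
    if (dirn * (P + hP - P_end) > 0) hP <- P_end - P
    y_big <- tryCatch(rk4(y, P, hP), error = function(e) NULL)
    y_two <- tryCatch({
      ym <- rk4(y, P, hP / 2); rk4(ym, P + hP / 2, hP / 2)
    }, error = function(e) NULL)
    if (is.null(y_big) || is.null(y_two) || any(!is.finite(y_two)) ||
        any(y_two <= 0)) {
      hP <- hP / 4
      if (abs(hP) < 1e-10 * max(abs(P), 1e-12)) {
        termination <- "step collapse"; break
      }
      next
    }
    err <- max(abs(y_two - y_big) / pmax(abs(y_two), 1e-12))
    if (err > rtol) {
      hP <- hP / 2
      if (abs(hP) < 1e-10 * max(abs(P), 1e-12)) {
        termination <- "step collapse"; break
      }
      next
    }
    P_new <- P + hP
    pr <- ctx_project_coexistence(ctx, T, y_two[1:n], y_two[n + 1:n],
                                  P_target = P_new, tol = 1e-10)
    if (pr$residual > 1e-7) { termination <- "projection failure"; break }
    y <- c(pr$rho_a, pr$rho_b)
    P <- P_new
    steps <- steps + 1L
    rows[[length(rows) + 1L]] <- push(P, y)
    dets <- abs(ctx_binodal_rhs(ctx, T, y)$detH)
    if (any(dets < det_floor * det_ref)) {
      termination <- "critical point"; break
    }
    if (abs(P - P_end) < 1e-14) break
    if (abs(hP) < 1e-9 * max(abs(P), 1e-12)) {
      termination <- "step collapse"; break
    }
    if (err < rtol / 16) hP <- hP * 2
  }
  out <- do.call(rbind, rows)
  attr(out, "termination") <- termination
  attr(out, "temperature") <- T
  class(out) <- c("coexistence_curve", class(out))
  out
}

#' Locate a critical point at fixed temperature
#'
#' Searches a density segment for a sign change of det H, then polishes with
#' a two-unknown Newton iteration on det H = 0 together with the stability
#' condition that the determinant is stationary along the vanishing
#' eigenvector (u . grad det H = 0).
#'
#' @param T temperature.
#' @param mixture a [mixture_spec()].
#' @param bracket list/matrix of two density vectors delimiting the search
#'   segment.
#' @param order g_HS expansion order.
#' @return list with `rho` (critical density vector), `P`, `detH`.
#' @export
find_critical_point <- function(T, mixture, bracket, order = 1) {
  ctx <- wertheim_ctx(mixture, order = order)
  r1 <- bracket[[1]]; r2 <- bracket[[2]]
  f <- function(t) det(ctx_psi_hessian(ctx, T, r1 + t * (r2 - r1)))
  ts <- seq(0, 1, length.out = 25)
  fv <- vapply(ts, f, numeric(1))
  k <- which(fv[-length(fv)] * fv[-1] < 0)
  if (!length(k))
    stop("no critical point: det H has no sign change in the bracket")
  t0 <- uniroot(f, c(ts[k[1]], ts[k[1] + 1]), tol = 1e-12)$root
  r <- r1 + t0 * (r2 - r1)
  # Newton polish on (det H, u . grad det H)
  detgrad <- function(r) {
    H <- ctx_psi_hessian(ctx, T, r)
    ev <- eigen(H, symmetric = TRUE)
    u <- ev$vectors[, which.min(abs(ev$values))]
    g <- numeric(2)
    for (i in 1:2) {
      h <- max(1e-5 * r[i], 1e-8)
      e <- c(0, 0); e[i] <- 1
      g[i] <- (det(ctx_psi_hessian(ctx, T, r + h * e)) -
                 det(ctx_psi_hessian(ctx, T, r - h * e))) / (2 * h)
    }
    c(det(H), sum(u * g))
  }
  for (it in 1:30) {
    Fv <- detgrad(r)
    if (abs(Fv[1]) < 1e-9 && abs(Fv[2]) < 1e-7) break
    J <- matrix(0, 2, 2)
    for (j in 1:2) {
      h <- max(1e-5 * r[j], 1e-8)
      rj <- r; rj[j] <- rj[j] + h
      J[, j] <- (detgrad(rj) - Fv) / h
    }
    step <- tryCatch(solve(J, Fv), error = function(e) NULL)
    if (is.null(step)) break
    step <- pmin(pmax(step, -0.2 * r), 0.2 * r)
    r <- r - step
  }
  ctxp <- ctx_phase_eval(ctx, T, r)
  list(rho = r, P = ctxp$P, detH = det(ctx_psi_hessian(ctx, T, r)))
}

#' Critical temperature at fixed composition
#'
#' Along the fixed-composition ray the determinant of the Hessian dips
#' negative inside the spinodal region; the critical temperature is where
#' the minimum of det H over density touches zero.
#'
#' @param mixture a [mixture_spec()].
#' @param x composition of species 1 (binary).
#' @param T_range temperature bracket `c(lo, hi)` with a sign change of the
#'   det H minimum.
#' @param rho_range total-density scan range.
#' @param order g_HS expansion order.
#' @return list with `T_c`, `rho_c` (total density) and the det minimum.
#' @export
critical_temperature_at_x <- function(mixture, x, T_range,
                                      rho_range = c(1e-3, 0.9), order = 1) {
  ctx <- wertheim_ctx(mixture, order = order)
  xv <- c(x, 1 - x)
  min_det <- function(T) {
    f <- function(lr) det(ctx_psi_hessian(ctx, T, exp(lr) * xv))
    o <- optimize(f, log(rho_range))
    list(val = o$objective, rho = exp(o$minimum))
  }
  g <- function(T) min_det(T)$val
  lo <- T_range[1]; hi <- T_range[2]
  glo <- g(lo); ghi <- g(hi)
  if (glo * ghi > 0)
    stop("T_range does not bracket the critical temperature")
  rt <- uniroot(g, c(lo, hi), f.lower = glo, f.upper = ghi, tol = 1e-5)
  md <- min_det(rt$root)
  list(T_c = rt$root, rho_c = md$rho, det_min = md$val)
}
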