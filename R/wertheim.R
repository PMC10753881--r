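# Multicomponent Wertheim first-order perturbation theory: bond integrals,
# law of mass action, Helmholtz/Gibbs free energies, common-tangent
# coexistence at fixed (T, P).
#
# Reduced units throughout: energies in epsilon, lengths in sigma, k_B = 1,
# pressure in epsilon/sigma^3.  Free energies per particle are reported in
# units of k_B T.

#' Thermodynamic state of a mixture
#'
#' @param temperature temperature in units of epsilon/k_B.
#' @param density total number density in sigma^-3.
#' @param composition mole-fraction vector.
#' @param sigma particle diameter.
#' @return an object of class `thermo_state`.
#' @export
thermo_state <- function(temperature, density, composition, sigma = 1) {
  stopifnot(temperature > 0, density >= 0,
            all(composition >= 0), abs(sum(composition) - 1) < 1e-12)
  phi <- density * pi * sigma^3 / 6
  if (phi >= 0.7405)
    stop("packing fraction at or beyond close packing")
  structure(list(temperature = temperature, density = density,
                 composition = as.numeric(composition),
                 packing_fraction = phi, sigma = sigma),
            class = "thermo_state")
}

# Carnahan-Starling contact value of g_HS and the linear expansion slope
# (first derivative of g_HS at contact), both as functions of phi.
cs_contact <- function(phi) (1 - phi / 2) / (1 - phi)^3
cs_contact_slope <- function(phi, sigma = 1)
  -(9 / 2) * phi * (1 + phi) / ((1 - phi)^3 * sigma)

# ---------------------------------------------------------------------------
# Fast internal context: everything about a mixture that does not depend on
# the thermodynamic state is precomputed once.
# ---------------------------------------------------------------------------
wertheim_ctx <- function(mixture, order = 1) {
  cols <- unlist(lapply(mixture$species, function(s) s$patch_colors))
  sp <- rep(seq_len(mixture$n_species), each = mixture$n_patches)
  kf <- mixture$kf
  s <- kf$sigma; d <- kf$delta
  i0 <- ((s + d)^3 - s^3) / 3
  i1 <- ((s + d)^4 - s^4) / 4 - s * ((s + d)^3 - s^3) / 3
  list(ups = mixture$matrix$entries[cols, cols, drop = FALSE],
       sp = sp, n = length(cols),
       nsp = mixture$n_species, np = mixture$n_patches,
       kf = kf, vs = pi * s^3 / 6, vb = bonding_volume(kf),
       j = if (order >= 1) i1 / i0 else 0)
}

# Delta and d Delta / d rho.
ctx_delta <- function(ctx, T, rho) {
  phi <- rho * ctx$vs
  cc <- ctx$vb * expm1(ctx$kf$epsilon / T)
  val <- cc * (cs_contact(phi) + cs_contact_slope(phi, ctx$kf$sigma) * ctx$j)
  dA <- (5 / 2 - phi) / (1 - phi)^4
  dB <- -(9 / 2) * (1 + 4 * phi + phi^2) / ((1 - phi)^4 * ctx$kf$sigma)
  list(value = val, drho = cc * (dA + dB * ctx$j) * ctx$vs)
}

# Law of mass action: damped fixed point (0.5) from X = 1, Newton polish.
ctx_mass_balance <- function(ctx, rho, x, delta, tol = 1e-13) {
  K <- (rho * delta) * ctx$ups * rep(x[ctx$sp], each = ctx$n)
  n <- ctx$n
  X <- rep(1, n)
  it <- 0L
  repeat {
    X2 <- 0.5 * X + 0.5 / (1 + drop(K %*% X))
    it <- it + 1L
    if (max(abs(X2 - X)) < 1e-4 || it >= 400L) { X <- X2; break }
    X <- X2
  }
  repeat {
    S <- drop(K %*% X)
    Fv <- X * (1 + S) - 1
    if (max(abs(Fv)) < tol || it >= 1e5) break
    J <- diag(1 + S, n) + X * K
    X <- pmin(pmax(X - solve(J, Fv), 1e-300), 1)
    it <- it + 1L
  }
  S <- drop(K %*% X)
  res <- max(abs(X * (1 + S) - 1))
  if (res > 1e-12)
    stop(sprintf(
      "mass-balance solver did not converge (residual %.3e after %d iterations)",
      res, it))
  list(X = X, S = S, K = K, iterations = it, residual = res)
}

# beta * f (per particle) from a solved state.
ctx_betaf <- function(ctx, rho, x, mb) {
  phi <- rho * ctx$vs
  xl <- x[x > 0]
  f_id <- log(rho * ctx$kf$sigma^3) + sum(xl * log(xl)) - 1
  f_hs <- phi * (4 - 3 * phi) / (1 - phi)^2
  f_b <- sum(x[ctx$sp] * (log(mb$X) - mb$X / 2 + 0.5))
  c(f_id, f_hs, f_b)
}

# Pressure in epsilon/sigma^3, analytic in rho (implicit differentiation of
# the mass balance, including Delta(rho)).
ctx_pressure <- function(ctx, T, rho, x) {
  db <- ctx_delta(ctx, T, rho)
  mb <- ctx_mass_balance(ctx, rho, x, db$value)
  phi <- rho * ctx$vs
  bp_ref <- rho + rho * phi * (4 - 2 * phi) / (1 - phi)^3
  sfac <- 1 / rho + db$drho / db$value
  rhs <- -(mb$X^2) * sfac * mb$S
  A <- diag(ctx$n) + (mb$X^2) * mb$K
  dX <- solve(A, rhs)
  dfb <- sum(x[ctx$sp] * (1 / mb$X - 0.5) * dX)
  T * (bp_ref + rho^2 * dfb)
}

ctx_g_of_rho <- function(ctx, T, P, rho, x) {
  db <- ctx_delta(ctx, T, rho)
  mb <- ctx_mass_balance(ctx, rho, x, db$value)
  T * sum(ctx_betaf(ctx, rho, x, mb)) + P / rho
}

# All local minima of g(rho) = T beta f + P / rho: up-crossing roots of
# P(rho) = P on a log grid, refined by bisection.
ctx_g_minima <- function(ctx, T, P, x, rho_range = c(1e-9, 1.1),
                         n_grid = 90) {
  grid <- exp(seq(log(rho_range[1]), log(rho_range[2]), length.out = n_grid))
  h <- vapply(grid, function(r) ctx_pressure(ctx, T, r, x) - P, numeric(1))
  roots <- numeric(0)
  for (k in seq_len(n_grid - 1)) {
    if (h[k] < 0 && h[k + 1] >= 0) {
      rt <- uniroot(function(r) ctx_pressure(ctx, T, r, x) - P,
                    c(grid[k], grid[k + 1]), f.lower = h[k],
                    f.upper = h[k + 1], tol = 1e-13)$root
      roots <- c(roots, rt)
    }
  }
  if (!length(roots))
    stop("no free-energy minimum in the density range")
  gv <- vapply(roots, function(r) ctx_g_of_rho(ctx, T, P, r, x), numeric(1))
  list(rho = roots, g = gv)
}

# Re-solve P(rho) = P near a previously known minimum: expand a bracket
# around the old root until the sign changes, then bisect.  Returns NA when
# the minimum has disappeared (spinodal passed).
ctx_track_root <- function(ctx, T, P, x, r0) {
  f <- function(r) ctx_pressure(ctx, T, r, x) - P
  lo <- r0 * 0.7; hi <- min(r0 * 1.4, 1.3)
  flo <- f(lo); fhi <- f(hi)
  for (k in 1:6) {
    if (flo < 0 && fhi >= 0) break
    if (flo >= 0) { hi <- lo; fhi <- flo; lo <- lo * 0.5; flo <- f(lo) }
    else { lo <- hi; flo <- fhi; hi <- min(hi * 1.6, 1.35); fhi <- f(hi) }
    if (lo < 1e-12) return(NA_real_)
  }
  if (!(flo < 0 && fhi >= 0)) return(NA_real_)
  uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-13)$root
}

# Local minima of g(rho) warm-started from known roots; falls back to the
# full scan when tracking loses every root.
ctx_g_minima_warm <- function(ctx, T, P, x, roots) {
  rs <- vapply(roots, function(r) ctx_track_root(ctx, T, P, x, r),
               numeric(1))
  rs <- rs[!is.na(rs)]
  if (length(rs) > 1)  # deduplicate merged minima
    rs <- rs[c(TRUE, abs(diff(rs)) / rs[-length(rs)] > 0.01)]
  if (!length(rs)) return(ctx_g_minima(ctx, T, P, x))
  gv <- vapply(rs, function(r) ctx_g_of_rho(ctx, T, P, r, x), numeric(1))
  list(rho = rs, g = gv)
}

# g(x) sampled on a composition grid at fixed (T, P), walking outward from
# the centre of the window so density roots can be warm-started; a minimum
# can disappear moving outward (spinodal) but not appear.
ctx_gx_scan <- function(ctx, T, P, xs) {
  n <- length(xs)
  mid <- which.min(abs(xs - mean(range(xs))))
  g <- numeric(n); nmin <- integer(n)
  centre <- ctx_g_minima(ctx, T, P, c(xs[mid], 1 - xs[mid]))
  g[mid] <- min(centre$g); nmin[mid] <- length(centre$rho)
  for (dir in c(-1L, 1L)) {
    roots <- centre$rho
    k <- mid + dir
    while (k >= 1 && k <= n) {
      m <- ctx_g_minima_warm(ctx, T, P, c(xs[k], 1 - xs[k]), roots)
      g[k] <- min(m$g); nmin[k] <- length(m$rho)
      roots <- m$rho
      k <- k + dir
    }
  }
  list(x = xs, g = g, n_minima = nmin)
}

# ---------------------------------------------------------------------------
# Public API
# ---------------------------------------------------------------------------

#' Bond integral Delta
#'
#' \eqn{\Delta = V_b (e^{\beta\epsilon} - 1) \langle g_{HS}\rangle}, with the
#' hard-sphere radial distribution function approximated by its expansion
#' around contact: order 0 keeps the Carnahan-Starling contact value, order 1
#' (default) adds the linear term in (r - sigma) with the standard
#' first-derivative coefficient.  The average is volume-weighted over the
#' square-well shell.
#'
#' @param kf [kf_params()].
#' @param T temperature (epsilon/k_B).
#' @param rho total number density (sigma^-3).
#' @param order expansion order of g_HS about contact (0 or 1).
#' @param deriv if `TRUE`, also return the density derivative.
#' @return Delta in sigma^3, or `list(value, drho)` when `deriv = TRUE`.
#' @export
bond_integral <- function(kf, T, rho, order = 1, deriv = FALSE) {
  stopifnot(T > 0, rho >= 0, order %in% c(0, 1))
  tet <- tetrahedral_vectors()
  dummy <- mixture_spec(list(species_spec(tet[1, , drop = FALSE], 1L)),
                        1, kf, interaction_matrix(matrix(1L, 1, 1)))
  ctx <- wertheim_ctx(dummy, order = order)
  db <- ctx_delta(ctx, T, rho)
  if (deriv) db else db$value
}

#' Solve the law of mass action
#'
#' Finds the unbonded-patch probabilities \eqn{X_\alpha^{(i)}} satisfying
#' \deqn{X_\alpha^{(i)} = \Big[1 + \rho \sum_j x^{(j)}
#'   \sum_{\gamma\in\Gamma(j)} \Upsilon_{\alpha\gamma}\,\Delta\,
#'   X_\gamma^{(j)}\Big]^{-1}}
#' by damped fixed-point iteration (damping 0.5, start X = 1) followed by a
#' Newton polish to residual `tol`.
#'
#' @param mixture a [mixture_spec()].
#' @param state a [thermo_state()].
#' @param delta_bond bond integral; computed from `mixture$kf` and the state
#'   when omitted.
#' @param tol residual tolerance.
#' @return matrix of probabilities (species x patch slot), class
#'   `bond_probabilities`, with attributes `iterations` and `residual`.
#' @export
solve_mass_balance <- function(mixture, state, delta_bond = NULL,
                               tol = 1e-13) {
  ctx <- wertheim_ctx(mixture)
  if (is.null(delta_bond))
    delta_bond <- ctx_delta(ctx, state$temperature, state$density)$value
  mb <- ctx_mass_balance(ctx, state$density, state$composition, delta_bond,
                         tol = tol)
  out <- matrix(mb$X, nrow = mixture$n_species, byrow = TRUE)
  class(out) <- c("bond_probabilities", class(out))
  attr(out, "iterations") <- mb$iterations
  attr(out, "residual") <- mb$residual
  out
}

#' Helmholtz free energy per particle (Wertheim TPT1)
#'
#' \eqn{\beta f = \beta f_{ideal} + \beta f_{HS} + \beta f_{bond}} with the
#' ideal mixture term (thermal volumes set to sigma^3), the Carnahan-Starling
#' hard-sphere excess, and the bonding term
#' \deqn{\beta f_{bond} = \sum_i x^{(i)} \sum_{\alpha\in\Gamma(i)}
#'   \left(\ln X_\alpha^{(i)} - \frac{X_\alpha^{(i)}}{2} +
#'   \frac{1}{2}\right)}
#' evaluated at the mass-balance solution.
#'
#' @param mixture a [mixture_spec()].
#' @param state a [thermo_state()] with positive density.
#' @param order g_HS expansion order passed to [bond_integral()].
#' @return list of class `free_energy_breakdown` with elements `f_ideal`,
#'   `f_hs`, `f_bond`, `f_total` (all per particle, units k_B T).
#' @export
helmholtz_free_energy <- function(mixture, state, order = 1) {
  if (state$density <= 0)
    stop("free energy per particle requires positive density")
  ctx <- wertheim_ctx(mixture, order = order)
  db <- ctx_delta(ctx, state$temperature, state$density)
  mb <- ctx_mass_balance(ctx, state$density, state$composition, db$value)
  f3 <- ctx_betaf(ctx, state$density, state$composition, mb)
  structure(list(f_ideal = f3[1], f_hs = f3[2], f_bond = f3[3],
                 f_total = sum(f3)),
            class = "free_energy_breakdown")
}

#' @export
print.free_energy_breakdown <- function(x, ...) {
  cat(sprintf("beta*f: ideal %.6f + hard-sphere %.6f + bonding %.6f = %.6f\n",
              x$f_ideal, x$f_hs, x$f_bond, x$f_total))
  invisible(x)
}

#' Pressure from Wertheim theory
#'
#' \eqn{P = T \rho^2 \partial(\beta f)/\partial\rho} at fixed composition,
#' with the bonding contribution obtained by implicit differentiation of the
#' mass-balance equations (including the density dependence of Delta).
#'
#' @inheritParams helmholtz_free_energy
#' @return pressure in epsilon/sigma^3.
#' @export
wertheim_pressure <- function(mixture, state, order = 1) {
  ctx <- wertheim_ctx(mixture, order = order)
  ctx_pressure(ctx, state$temperature, state$density, state$composition)
}

#' Gibbs free energy per particle at fixed (T, P, x)
#'
#' Minimises \eqn{g(\rho) = T\,\beta f(\rho, x) + P/\rho} over the density.
#' Minima are located as up-crossing roots of \eqn{P(\rho) = P} on a
#' logarithmic density grid and refined by bisection; in a two-phase region
#' all local minima are reported alongside the global one.
#'
#' @param mixture a [mixture_spec()].
#' @param T temperature.
#' @param P pressure (epsilon/sigma^3).
#' @param x composition vector.
#' @param rho_range density scan interval.
#' @param n_grid number of logarithmic grid points.
#' @param order g_HS expansion order.
#' @return list with `g` (global minimum, units epsilon), `rho` (minimising
#'   density) and `minima` (data frame of all local minima).
#' @export
gibbs_free_energy <- function(mixture, T, P, x,
                              rho_range = c(1e-9, 1.1), n_grid = 90,
                              order = 1) {
  stopifnot(P > 0)
  ctx <- wertheim_ctx(mixture, order = order)
  mins <- ctx_g_minima(ctx, T, P, x, rho_range, n_grid)
  best <- which.min(mins$g)
  list(g = mins$g[best], rho = mins$rho[best],
       minima = data.frame(rho = mins$rho, g = mins$g))
}

# g(x) for a binary mixture at fixed (T, P); internal, ctx-based.
ctx_g_of_x <- function(ctx, T, P, x1) {
  mins <- ctx_g_minima(ctx, T, P, c(x1, 1 - x1))
  min(mins$g)
}

#' Common-tangent coexistence at fixed (T, P)
#'
#' Samples g(x) on a composition grid, detects concave gaps via the lower
#' convex hull, and refines the coexisting pair (x', x'') by Newton
#' iteration on equal slope and equal tangent intercept.
#'
#' @param mixture a binary [mixture_spec()].
#' @param T temperature.
#' @param P pressure.
#' @param dx composition grid spacing for hull detection.
#' @param xlim composition window to scan (default the full range).
#' @param tol convergence tolerance on the tangent residual.
#' @param order g_HS expansion order.
#' @return list with `phase` (`"two-phase"` or `"single-phase"`) and, for
#'   two-phase states, `x` (sorted coexisting compositions of species 1),
#'   `g`, `rho` (phase densities), and the tangent `slope`.
#' @export
common_tangent <- function(mixture, T, P, dx = 0.005, xlim = c(0, 1),
                           tol = 1e-9, order = 1) {
  if (mixture$n_species != 2)
    stop("common tangent construction implemented for binary mixtures")
  ctx <- wertheim_ctx(mixture, order = order)
  ctx_common_tangent(ctx, T, P, dx, xlim, tol)
}

ctx_common_tangent <- function(ctx, T, P, dx = 0.005, xlim = c(0, 1),
                               tol = 1e-9) {
  xs <- seq(xlim[1], xlim[2], by = dx)
  scan <- ctx_gx_scan(ctx, T, P, xs)
  gs <- scan$g
  # lower convex hull (monotone chain over increasing x)
  hull <- integer(0)
  for (k in seq_along(xs)) {
    while (length(hull) >= 2) {
      i <- hull[length(hull) - 1]; j <- hull[length(hull)]
      cross <- (xs[j] - xs[i]) * (gs[k] - gs[i]) -
        (xs[k] - xs[i]) * (gs[j] - gs[i])
      if (cross <= 0) hull <- hull[-length(hull)] else break
    }
    hull <- c(hull, k)
  }
  gaps <- which(diff(hull) > 1)
  if (!length(gaps)) return(list(phase = "single-phase"))
  wid <- vapply(gaps, function(g) xs[hull[g + 1]] - xs[hull[g]], numeric(1))
  g0 <- gaps[which.max(wid)]
  p <- c(xs[hull[g0]], xs[hull[g0 + 1]])
  # warm-started g(x) evaluators anchored at the two hull endpoints
  warm_g <- function(x1_init) {
    roots <- ctx_g_minima(ctx, T, P, c(x1_init, 1 - x1_init))$rho
    function(x1) {
      m <- ctx_g_minima_warm(ctx, T, P, c(x1, 1 - x1), roots)
      roots <<- m$rho
      min(m$g)
    }
  }
  g_a <- warm_g(p[1]); g_b <- warm_g(p[2])
  gp <- function(gf, x1, h = 1e-6) {
    x1 <- min(max(x1, h), 1 - h)
    (gf(x1 + h) - gf(x1 - h)) / (2 * h)
  }
  Ffun <- function(p) {
    s1 <- gp(g_a, p[1]); s2 <- gp(g_b, p[2])
    c(s1 - s2, (g_b(p[2]) - g_a(p[1])) / (p[2] - p[1]) - s1)
  }
  for (iter in 1:60) {
    Fv <- Ffun(p)
    if (max(abs(Fv)) < tol) break
    J <- matrix(0, 2, 2)
    hj <- 1e-6
    for (j in 1:2) {
      pj <- p; pj[j] <- pj[j] + hj
      J[, j] <- (Ffun(pj) - Fv) / hj
    }
    step <- tryCatch(solve(J, Fv), error = function(e) Fv * 0)
    pn <- p - pmin(pmax(step, -0.1), 0.1)
    pn <- pmin(pmax(pn, 1e-4), 1 - 1e-4)
    if (pn[1] >= pn[2]) break
    p <- pn
  }
  if (p[1] >= p[2] || (p[2] - p[1]) < dx * 0.5)
    return(list(phase = "single-phase"))
  p <- sort(p)
  ma <- ctx_g_minima(ctx, T, P, c(p[1], 1 - p[1]))
  mb <- ctx_g_minima(ctx, T, P, c(p[2], 1 - p[2]))
  list(phase = "two-phase", x = p,
       g = c(min(ma$g), min(mb$g)),
       rho = c(ma$rho[which.min(ma$g)], mb$rho[which.min(mb$g)]),
       slope = gp(g_a, p[1]))
}

#' Locate the azeotropic point at fixed temperature
#'
#' For a negative azeotrope the coexistence lens in the (x, P) plane sits
#' above a pressure minimum where dew and bubble curves are tangent and the
#' composition gap closes.  The locator bisects in pressure between a
#' single-phase and a two-phase state, narrowing the composition window as
#' the gap shrinks, and reports the composition at which the gap closes.
#'
#' @param mixture a binary [mixture_spec()].
#' @param T temperature.
#' @param P_bracket pressures `c(single_phase, two_phase)` bracketing the
#'   lens minimum; found by a logarithmic pressure scan when omitted.
#' @param x_tol target width of the composition gap at termination.
#' @param order g_HS expansion order.
#' @return list with `x_az` (azeotropic composition), `P_az` (lens-minimum
#'   pressure, upper bound of the final bracket) and `gap` (final
#'   composition gap).
#' @export
azeotrope_point <- function(mixture, T, P_bracket = NULL, x_tol = 2e-4,
                            order = 1) {
  ctx <- wertheim_ctx(mixture, order = order)
  gap_at <- function(P, xlim = c(0, 1), dx = 0.005) {
    ct <- ctx_common_tangent(ctx, T, P, dx = dx, xlim = xlim)
    if (ct$phase == "single-phase") NULL else ct
  }
  if (is.null(P_bracket)) {
    Ps <- 10^seq(-8, -1.5, length.out = 27)
    two <- vapply(Ps, function(P) !is.null(gap_at(P, dx = 0.02)), logical(1))
    if (!any(two)) stop("no two-phase region found on the pressure scan")
    k <- which(two)[1]
    if (k == 1) stop("pressure scan starts inside the two-phase region")
    P_lo <- Ps[k - 1]; P_hi <- Ps[k]
    last <- gap_at(P_hi)
  } else {
    P_lo <- P_bracket[1]; P_hi <- P_bracket[2]
    last <- gap_at(P_hi)
    if (is.null(last)) stop("upper bracket pressure is single phase")
  }
  for (iter in 1:60) {
    Pm <- sqrt(P_lo * P_hi)
    gap <- diff(last$x)
    pad <- 2 * gap + 0.002
    win <- c(max(0, last$x[1] - pad), min(1, last$x[2] + pad))
    ct <- gap_at(Pm, xlim = win, dx = max(gap / 15, 1e-5))
    if (is.null(ct)) P_lo <- Pm else { P_hi <- Pm; last <- ct }
    if (diff(last$x) < x_tol && (P_hi - P_lo) / P_hi < 1e-3) break
  }
  list(x_az = mean(last$x), P_az = P_hi, gap = diff(last$x))
}

#' Dew/bubble points over a pressure range (common-tangent route)
#'
#' @param mixture a binary [mixture_spec()].
#' @param T temperature.
#' @param P_values pressures to solve at.
#' @param order g_HS expansion order.
#' @return data frame with columns T, P, x_dew, x_bubble, rho_dew,
#'   rho_bubble (single-phase pressures are dropped).
#' @export
binodal_common_tangent <- function(mixture, T, P_values, order = 1) {
  ctx <- wertheim_ctx(mixture, order = order)
  rows <- lapply(P_values, function(P) {
    ct <- ctx_common_tangent(ctx, T, P)
    if (ct$phase != "two-phase") return(NULL)
    dense <- which.max(ct$rho); dilute <- 3 - dense
    data.frame(T = T, P = P,
               x_dew = ct$x[dilute], x_bubble = ct$x[dense],
               rho_dew = ct$rho[dilute], rho_bubble = ct$rho[dense])
  })
  do.call(rbind, rows)
}
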