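test_that("Psi, chemical potentials and pressure are mutually consistent", {
  T <- 0.07
  r <- c(0.15, 0.15)
  expect_identical(psi(c(0, 0), T, n2c8s2), 0)
  # mu from Psi against the definition g = f + P/rho: P identity
  P_iso <- pressure_isochoric(r, T, n2c8s2)
  P_an <- wertheim_pressure(n2c8s2, thermo_state(T, sum(r), r / sum(r)))
  expect_equal(P_iso, P_an, tolerance = 1e-7)
  # finite-difference of Psi itself reproduces mu
  mu <- chemical_potentials(r, T, n2c8s2)
  for (i in 1:2) {
    h <- 1e-4
    e <- c(0, 0); e[i] <- h
    mu_fd <- (psi(r + e, T, n2c8s2) - psi(r - e, T, n2c8s2)) / (2 * h)
    expect_equal(mu[i], mu_fd, tolerance = 1e-6)
  }
})

test_that("the Hessian is symmetric, ideal in the dilute limit, and stable", {
  T <- 0.07
  H <- hessian_psi(c(0.1, 0.2), T, n2c8s2)
  expect_lt(max(abs(H - t(H))), 1e-9)
  # near-ideal limit
  mix0 <- build_n2c8s2(kf = kf_params(epsilon = 1e-9))
  r0 <- c(1e-3, 2e-3)
  H0 <- hessian_psi(r0, T, mix0)
  expect_equal(diag(H0), T / r0, tolerance = 0.02)
  # positive definite at a dilute stable state (phi ~ 0.01)
  Hs <- hessian_psi(c(0.01, 0.01), 0.12, n2c8s2)
  expect_true(all(eigen(Hs, symmetric = TRUE)$values > 0))
})

test_that("coexistence points satisfy equal P and mu; invalid pairs are rejected", {
  T <- 0.07
  ct <- common_tangent(n2c8s2, T, 2e-5)
  cp <- coexistence_point(n2c8s2, T,
                          ct$rho[1] * c(ct$x[1], 1 - ct$x[1]),
                          ct$rho[2] * c(ct$x[2], 1 - ct$x[2]))
  ea_mu <- chemical_potentials(cp$phase_a, T, n2c8s2)
  eb_mu <- chemical_potentials(cp$phase_b, T, n2c8s2)
  expect_lt(max(abs(ea_mu - eb_mu)), 1e-8)
  expect_lt(abs(pressure_isochoric(cp$phase_a, T, n2c8s2) -
                  pressure_isochoric(cp$phase_b, T, n2c8s2)), 1e-8)
  expect_error(coexistence_point(n2c8s2, T, c(0.01, 0.01), c(0.3, 0.1),
                                 refine = FALSE),
               "do not coexist")
})

test_that("isochoric tracing reproduces the common-tangent binodal", {
  T <- 0.07
  ct <- common_tangent(n2c8s2, T, 2e-5)
  cp <- coexistence_point(n2c8s2, T,
                          ct$rho[1] * c(ct$x[1], 1 - ct$x[1]),
                          ct$rho[2] * c(ct$x[2], 1 - ct$x[2]))
  cv <- trace_binodal(cp, T, c(cp$pressure, 3e-5), n2c8s2)
  expect_gt(nrow(cv), 5)
  # every accepted point re-satisfies the coexistence conditions
  for (k in c(2, nrow(cv) %/% 2, nrow(cv))) {
    ra <- c(cv$rho_a1[k], cv$rho_a2[k]); rb <- c(cv$rho_b1[k], cv$rho_b2[k])
    expect_lt(max(abs(chemical_potentials(ra, T, n2c8s2) -
                        chemical_potentials(rb, T, n2c8s2))), 1e-7)
    expect_lt(abs(pressure_isochoric(ra, T, n2c8s2) -
                    pressure_isochoric(rb, T, n2c8s2)), 1e-7)
  }
  # two independent routes to the same curve: compare against the common
  # tangent at interior pressures
  for (P in c(2.3e-5, 2.7e-5)) {
    k <- which.min(abs(cv$P - P))
    ct_P <- common_tangent(n2c8s2, T, cv$P[k])
    expect_identical(ct_P$phase, "two-phase")
    expect_lt(abs(min(cv$x_a[k], cv$x_b[k]) - min(ct_P$x)), 1e-4)
    expect_lt(abs(max(cv$x_a[k], cv$x_b[k]) - max(ct_P$x)), 1e-4)
  }
  # mirrored start traces the mirror curve (species-swap symmetry)
  cp_m <- coexistence_point(n2c8s2, T,
                            ct$rho[1] * c(1 - ct$x[1], ct$x[1]),
                            ct$rho[2] * c(1 - ct$x[2], ct$x[2]))
  cv_m <- trace_binodal(cp_m, T, c(cp$pressure, 3e-5), n2c8s2)
  k <- min(nrow(cv), nrow(cv_m))
  expect_equal(cv_m$x_a[1:k], 1 - cv$x_a[1:k], tolerance = 1e-6)
})

test_that("critical point search: none for ideal gas, consistent T_c at x = 0.5", {
  mix0 <- build_n2c8s2(kf = kf_params(epsilon = 1e-9))
  expect_error(find_critical_point(0.08, mix0,
                                   list(c(0.005, 0.005), c(0.3, 0.3))),
               "no critical point")
  # det-H route vs closing of the coexistence lens at the azeotropic
  # composition
  tc <- critical_temperature_at_x(n2c8s2, 0.5, c(0.07, 0.11))
  # bisection on the existence of a two-phase gap at fixed T
  lens_exists <- function(T) {
    ok <- FALSE
    for (P in 10^seq(-6, -2.5, length.out = 10)) {
      ct <- common_tangent(n2c8s2, T, P, dx = 0.01)
      if (ct$phase == "two-phase") { ok <- TRUE; break }
    }
    ok
  }
  lo <- tc$T_c - 0.004; hi <- tc$T_c + 0.004
  expect_true(lens_exists(lo))
  expect_false(lens_exists(hi))
})

test_that("critical temperature falls toward the pure-component limits", {
  tcs <- vapply(c(0.5, 0.3, 0.2, 0.1), function(x)
    critical_temperature_at_x(n2c8s2, x, c(0.07, 0.11))$T_c, numeric(1))
  expect_true(all(diff(tcs) < 0))
})
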