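test_that("bond integral limits and quadrature oracle", {
  kf <- kf_params()
  # high-temperature limit
  expect_lt(bond_integral(kf, 1e6, 0.3), 1e-9)
  # zero-density limit: contact value 1, slope term vanishes with phi
  expect_equal(bond_integral(kf, 0.1, 0),
               bonding_volume(kf) * expm1(1 / 0.1), tolerance = 1e-12)
  # independent quadrature of the shell average at the working point
  T <- 0.08; rho <- 0.3
  phi <- rho * pi / 6
  A <- (1 - phi / 2) / (1 - phi)^3
  B <- -4.5 * phi * (1 + phi) / (1 - phi)^3
  num <- integrate(function(r) (A + B * (r - 1)) * r^2, 1, 1.2,
                   rel.tol = 1e-12)$value
  den <- integrate(function(r) r^2, 1, 1.2, rel.tol = 1e-12)$value
  oracle <- bonding_volume(kf) * expm1(1 / T) * num / den
  expect_equal(bond_integral(kf, T, rho), oracle, tolerance = 1e-10)
})

test_that("mass balance: trivial limit, azeotropic solution, multi-start oracle", {
  st <- thermo_state(0.08, 0.3, c(0.5, 0.5))
  X0 <- solve_mass_balance(n2c8s2, st, delta_bond = 0)
  expect_true(all(X0 == 1))
  X <- solve_mass_balance(n2c8s2, st)
  expect_lt(max(X) - min(X), 1e-12)   # azeotropic: all equal
  expect_lt(attr(X, "residual"), 1e-12)
  # random small system vs brute-force damped iteration from random starts
  set.seed(91)
  v2 <- matrix(c(0, 0, 1, 0, 0, -1), ncol = 3, byrow = TRUE)
  m <- matrix(c(1L, 1L, 1L, 0L), 2, 2)
  mix <- mixture_spec(list(species_spec(v2, c(1L, 2L)),
                           species_spec(v2, c(1L, 1L))),
                      c(0.3, 0.7), kf_params(), interaction_matrix(m))
  st2 <- thermo_state(0.09, 0.2, mix$composition)
  db <- bond_integral(mix$kf, 0.09, 0.2)
  X2 <- as.numeric(t(solve_mass_balance(mix, st2, db)))
  cols <- c(1, 2, 1, 1)
  sp <- c(1, 1, 2, 2)
  K <- 0.2 * db * m[cols, cols] * rep(mix$composition[sp], each = 4)
  for (s in 1:50) {
    X_it <- runif(4)
    for (it in 1:20000) {
      Xn <- 0.7 * X_it + 0.3 / (1 + drop(K %*% X_it))
      if (max(abs(Xn - X_it)) < 1e-14) break
      X_it <- Xn
    }
    expect_lt(max(abs(X_it - X2)), 1e-10)
  }
})

test_that("free energy decomposes correctly and obeys the reductions", {
  st <- thermo_state(0.08, 0.3, c(0.5, 0.5))
  # Delta = 0 leaves ideal + Carnahan-Starling
  fb0 <- helmholtz_free_energy(n2c8s2, thermo_state(1e5, 0.3, c(0.5, 0.5)))
  expect_lt(abs(fb0$f_bond), 1e-6)
  phi <- st$packing_fraction
  expect_equal(fb0$f_hs, phi * (4 - 3 * phi) / (1 - phi)^2, tolerance = 1e-12)
  # fully connected: f_bond identical across compositions (one-component
  # reduction)
  set.seed(37)
  fc <- generate_rule_matrix("fully_connected", 2, 4)
  fbs <- vapply(seq(0.05, 0.95, length.out = 7), function(x1)
    helmholtz_free_energy(fc, thermo_state(0.09, 0.3, c(x1, 1 - x1)))$f_bond,
    numeric(1))
  expect_lt(max(fbs) - min(fbs), 1e-12)
  # N2c8s2 equimolar bonding term equals a one-component 4-patch exclusivity
  # system with the same Delta at half the density (each patch sees half the
  # partners through the composition weight)
  db <- bond_integral(n2c8s2$kf, 0.08, 0.3)
  f_mix <- local({
    X <- solve_mass_balance(n2c8s2, st, db)
    sum(0.5 * (log(X) - X / 2 + 0.5))
  })
  f_one <- local({
    st1 <- thermo_state(0.08, 0.15, 1)
    X <- solve_mass_balance(one_comp_excl, st1, db)
    sum(log(X) - X / 2 + 0.5)
  })
  expect_equal(f_mix, f_one, tolerance = 1e-12)
  # species swap symmetry of the design: f(rho, x) = f(rho, 1 - x)
  for (x1 in c(0.1, 0.3, 0.45)) {
    fa <- helmholtz_free_energy(n2c8s2, thermo_state(0.08, 0.3, c(x1, 1 - x1)))
    fb <- helmholtz_free_energy(n2c8s2, thermo_state(0.08, 0.3, c(1 - x1, x1)))
    expect_equal(fa$f_total, fb$f_total, tolerance = 1e-12)
  }
  # close packing is rejected
  expect_error(thermo_state(0.08, 1.5, c(0.5, 0.5)), "close packing")
})

test_that("mass balance is invariant under color/species relabelling", {
  # swap the two species and relabel colors with the mirror permutation:
  # the solution must map onto itself
  tet <- tetrahedral_vectors()
  perm <- c(5:8, 1:4)
  m2 <- n2c8s2$matrix$entries[perm, perm]
  swapped <- mixture_spec(
    list(species_spec(tet, 1:4), species_spec(tet, 5:8)),
    c(0.4, 0.6), kf_params(), interaction_matrix(m2))
  st_a <- thermo_state(0.08, 0.3, c(0.6, 0.4))
  st_b <- thermo_state(0.08, 0.3, c(0.4, 0.6))
  Xa <- solve_mass_balance(n2c8s2, st_a)
  Xb <- solve_mass_balance(swapped, st_b)
  expect_equal(unclass(Xa)[1, ], unclass(Xb)[2, ], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pressure is thermodynamically consistent", {
  # analytic pressure equals the numerical density derivative of beta f
  for (rho in c(0.05, 0.3)) {
    st <- thermo_state(0.08, rho, c(0.5, 0.5))
    P <- wertheim_pressure(n2c8s2, st)
    h <- 1e-5 * rho
    fp <- helmholtz_free_energy(n2c8s2,
                                thermo_state(0.08, rho + h, c(0.5, 0.5)))$f_total
    fm <- helmholtz_free_energy(n2c8s2,
                                thermo_state(0.08, rho - h, c(0.5, 0.5)))$f_total
    expect_equal(P, 0.08 * rho^2 * (fp - fm) / (2 * h),
                 tolerance = 1e-6)
  }
})

test_that("Gibbs free energy minimisation is self-consistent", {
  # near-ideal limit: minimising density satisfies P = rho T
  mix0 <- build_n2c8s2(kf = kf_params(epsilon = 1e-9))
  g <- gibbs_free_energy(mix0, 0.1, 1e-6, c(0.5, 0.5))
  expect_equal(g$rho * 0.1, 1e-6, tolerance = 1e-4)
  # interacting case: pressure recomputed at the reported density matches
  g2 <- gibbs_free_energy(n2c8s2, 0.07, 2e-5, c(0.5, 0.5))
  P2 <- wertheim_pressure(n2c8s2,
                          thermo_state(0.07, g2$rho, c(0.5, 0.5)))
  expect_equal(P2, 2e-5, tolerance = 1e-8)
  # two minima inside the coexistence region
  expect_gte(nrow(g2$minima), 2)
})

test_that("common tangent: convexity at high T, mirror pairs in the lens", {
  expect_identical(common_tangent(n2c8s2, 0.2, 1e-4)$phase, "single-phase")
  # inside the lens at T = 0.07 the construction yields a two-phase pair;
  # by the species-swap symmetry the mirrored window holds the mirror pair
  ct <- common_tangent(n2c8s2, 0.07, 2e-5)
  expect_identical(ct$phase, "two-phase")
  ct_r <- common_tangent(n2c8s2, 0.07, 2e-5, xlim = c(0.4, 1), dx = 0.005)
  expect_equal(sort(1 - ct_r$x), ct$x, tolerance = 1e-4)
  # the tangency conditions hold to high precision
  expect_lt(abs((ct$g[2] - ct$g[1]) / (ct$x[2] - ct$x[1]) - ct$slope), 1e-7)
})

test_that("pure components show no liquid-gas transition", {
  for (T in c(0.06, 0.07, 0.08)) {
    for (P in 10^seq(-7, -2, length.out = 6)) {
      for (x1 in c(0, 1)) {
        g <- gibbs_free_energy(n2c8s2, T, P, c(x1, 1 - x1))
        expect_identical(nrow(g$minima), 1L)
      }
    }
  }
})
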