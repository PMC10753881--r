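test_that("bond exclusivity verdicts", {
  r <- check_bond_exclusivity(n2c8s2)
  expect_true(r$satisfied)
  expect_equal(r$predicted_azeotrope, c(0.5, 0.5))
  # identity matrix, one color per patch: one partner per row
  tet <- tetrahedral_vectors()
  idm <- mixture_spec(
    list(species_spec(tet, 1:4), species_spec(tet, 5:8)),
    c(0.5, 0.5), kf_params(), interaction_matrix(diag(8)))
  expect_true(check_bond_exclusivity(idm)$satisfied)
  # a row with two ones violates exclusivity
  m <- diag(8); m[1, 2] <- m[2, 1] <- 1; m[2, 2] <- 0; m[1, 1] <- 1
  bad <- mixture_spec(
    list(species_spec(tet, 1:4), species_spec(tet, 5:8)),
    c(0.5, 0.5), kf_params(), interaction_matrix(m))
  expect_false(check_bond_exclusivity(bad)$satisfied)
})

test_that("bond multiplicity generalises exclusivity and shifts the azeotrope", {
  # n = 1 reduces to exclusivity on a binary mixture
  expect_true(check_bond_multiplicity(n2c8s2, 1)$satisfied)
  set.seed(5)
  mix2 <- generate_rule_matrix("multiplicity", 2, 4, n = 2)
  r <- check_bond_multiplicity(mix2, 2)
  expect_true(r$satisfied)
  expect_equal(r$predicted_azeotrope, c(1 / 3, 2 / 3))
  # N2c8s2 does not satisfy triple multiplicity
  expect_false(check_bond_multiplicity(n2c8s2, 3)$satisfied)
  # non-binary mixtures are rejected
  tet <- tetrahedral_vectors()
  tern <- mixture_spec(
    list(species_spec(tet, 1:4), species_spec(tet, 5:8),
         species_spec(tet, 9:12)),
    rep(1 / 3, 3), kf_params(), interaction_matrix(diag(12)))
  expect_error(check_bond_multiplicity(tern, 2), "binary")
})

test_that("fully connected bond condition", {
  # single species, one self-complementary color per patch (N_s = 1)
  tet <- tetrahedral_vectors()
  single <- mixture_spec(list(species_spec(tet, 1:4)), 1, kf_params(),
                         interaction_matrix(diag(4)))
  expect_true(check_fully_connected(single)$satisfied)
  expect_identical(check_fully_connected(single)$predicted_azeotrope, "all")
  # the N2c8s2 matrix routes each patch to a single species
  expect_false(check_fully_connected(n2c8s2)$satisfied)
  # a generated fully connected binary design passes its checker
  set.seed(11)
  fc <- generate_rule_matrix("fully_connected", 2, 4)
  expect_true(check_fully_connected(fc)$satisfied)
})

test_that("the 1:3 tetrahedral binary design is infeasible", {
  expect_error(generate_rule_matrix("multiplicity", 2, 4, n = 3),
               "infeasible")
})

test_that("reduced azeotropic equation limits and cross-check", {
  r <- check_bond_exclusivity(n2c8s2)
  expect_equal(solve_azeotropic_x(r, 0.3, 0), 1)
  expect_equal(solve_azeotropic_x(r, 0, 123), 1)
  db <- bond_integral(n2c8s2$kf, 0.08, 0.3)
  st <- thermo_state(0.08, 0.3, c(0.5, 0.5))
  X <- solve_mass_balance(n2c8s2, st, db)
  expect_lt(abs(solve_azeotropic_x(r, st$packing_fraction, db) - X[1, 1]),
            1e-10)
})

test_that("rule-satisfying matrices give uniform X at the predicted azeotrope", {
  set.seed(23)
  cases <- list(
    list(rule = "exclusivity", ns = 2, np = 4),
    list(rule = "exclusivity", ns = 3, np = 4),
    list(rule = "multiplicity", ns = 2, np = 4, n = 2),
    list(rule = "fully_connected", ns = 2, np = 4),
    list(rule = "fully_connected", ns = 3, np = 4))
  for (cs in cases) {
    for (rep in 1:4) {
      mix <- generate_rule_matrix(cs$rule, cs$ns, cs$np, n = cs$n)
      st <- thermo_state(0.09, 0.25, mix$composition)
      X <- solve_mass_balance(mix, st)
      expect_lt(max(X) - min(X), 1e-10)
    }
  }
})

test_that("fully connected designs are azeotropic at every composition", {
  set.seed(29)
  mix <- generate_rule_matrix("fully_connected", 2, 4)
  for (x1 in seq(0.05, 0.95, by = 0.15)) {
    st <- thermo_state(0.09, 0.3, c(x1, 1 - x1))
    X <- solve_mass_balance(mix, st)
    expect_lt(max(X) - min(X), 1e-10)
  }
})

test_that("X decreases with packing fraction and bond strength", {
  r <- check_bond_exclusivity(n2c8s2)
  phis <- seq(0.01, 0.4, length.out = 12)
  xs <- vapply(phis, function(p) solve_azeotropic_x(r, p, 50), numeric(1))
  expect_true(all(diff(xs) < 0))
  ds <- 10^seq(-2, 3, length.out = 12)
  xs2 <- vapply(ds, function(d) solve_azeotropic_x(r, 0.2, d), numeric(1))
  expect_true(all(diff(xs2) < 0))
})
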