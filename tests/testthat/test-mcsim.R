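test_that("total energy counts constructed bonds", {
  kf <- n2c8s2$kf
  # two particles beyond the well: no bonds
  far <- configuration(rbind(c(1, 1, 1), c(4, 4, 4)),
                       rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                       c(1L, 2L), 8)
  te <- total_energy(far, n2c8s2)
  expect_identical(nrow(te$bonds), 0L)
  expect_identical(te$energy, 0)
  # hand-built dimer: species-1 color 3 facing species-2 color 7 (slot 3)
  u <- tetrahedral_vectors()[3, ]
  q1 <- quat_from_matrix(frame_to(u, c(1, 0, 0)))
  q2 <- quat_from_matrix(frame_to(u, c(-1, 0, 0)))
  dim2 <- configuration(rbind(c(2, 2, 2), c(2 + kf$sigma + kf$delta / 2, 2, 2)),
                        rbind(q1, q2), c(1L, 2L), 8)
  te2 <- total_energy(dim2, n2c8s2)
  expect_identical(nrow(te2$bonds), 1L)
  expect_equal(te2$energy, -kf$epsilon)
  expect_identical(te2$max_patch_use, 1L)
  # overlap is an invariant violation
  bad <- configuration(rbind(c(0, 0, 0), c(0.5, 0, 0)),
                       rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                       c(1L, 1L), 8, validate = FALSE)
  expect_error(total_energy(bad, n2c8s2), "overlap")
  # the compiled (cubic) and R (any box) routes agree on a random gas
  set.seed(12)
  g <- random_gas(40, 0.3, c(0.5, 0.5), n2c8s2)
  teC <- total_energy(g, n2c8s2)
  bR <- bond_graph(g, n2c8s2)
  expect_identical(nrow(teC$bonds), nrow(bR))
})

test_that("AVB acceptance satisfies detailed balance arithmetically", {
  # fixed microstate pair: s (unbonded) -> s' (bonded) via a bind move;
  # the probability flows pi(s) q_B acc_B and pi(s') q_U acc_U must be equal
  V <- 1000; Vb <- bonding_volume(kf_params())
  for (case in list(list(dU = -1, N = 64, Nj_s = 2, np = 4, T = 0.08),
                    list(dU = -1 + 0.0, N = 2, Nj_s = 0, np = 1, T = 0.15),
                    list(dU = -2, N = 128, Nj_s = 3, np = 2, T = 0.1))) {
    Nj_sp <- case$Nj_s + 1           # target gains the new bond in s'
    M_out_s <- case$N - 1 - case$Nj_s
    M_out_sp <- case$N - 1 - Nj_sp
    q_B <- (1 / case$N) * (1 / M_out_s) * (1 / case$np) * (1 / Vb)
    q_U <- (1 / case$N) * (1 / Nj_sp) * (1 / V)
    acc_B <- min(1, avb_acceptance("bind", case$dU, case$T, M_out_s, Nj_sp,
                                   case$np, V, Vb))
    # the release move from s' lands in s, so its M_out factor is M_out(s)
    acc_U <- min(1, avb_acceptance("release", -case$dU, case$T, M_out_s,
                                   Nj_sp, case$np, V, Vb))
    boltz <- exp(-case$dU / case$T)  # pi(s') / pi(s)
    lhs <- q_B * acc_B
    rhs <- boltz * q_U * acc_U
    expect_equal(lhs / rhs, 1, tolerance = 1e-12)
  }
})

test_that("two-particle AVB sampling matches the exact partition function", {
  L <- 4; V <- L^3
  Vb <- bonding_volume(kf_params())
  Vcore <- 4 * pi / 3
  for (T in c(0.09, 0.11, 0.14)) {
    cfg <- configuration(rbind(c(0.5, 0.5, 0.5), c(2.5, 2.5, 2.5)),
                         rbind(c(1, 0, 0, 0), c(1, 0, 0, 0)),
                         c(1L, 1L), L)
    r <- run_nvt(cfg, one_patch_mix, T, n_sweeps = 1.5e5, seed = 101,
                 move_mix = c(0.6, 0.2, 0.2), cadence = 20)
    b <- r$observables$n_bonds > 0
    nb <- 20
    idx <- cut(seq_along(b), nb, labels = FALSE)
    bm <- tapply(b, idx, mean)
    se <- stats::sd(bm) / sqrt(nb)
    p_exact <- Vb * exp(1 / T) / (V - Vcore - Vb + Vb * exp(1 / T))
    expect_lt(abs(mean(b) - p_exact), 3 * se + 1e-12)
  }
})

test_that("seeded runs are bit-reproducible", {
  set.seed(2)
  cfg <- random_gas(32, 0.2, c(0.5, 0.5), n2c8s2)
  r1 <- run_nvt(cfg, n2c8s2, 0.1, n_sweeps = 500, seed = 77)
  r2 <- run_nvt(cfg, n2c8s2, 0.1, n_sweeps = 500, seed = 77)
  expect_identical(r1$config$positions, r2$config$positions)
  expect_identical(r1$config$quaternions, r2$config$quaternions)
  expect_identical(r1$observables$energy, r2$observables$energy)
})

test_that("non-interacting sampling stays a uniform hard-sphere gas", {
  # epsilon ~ 0: mean energy 0 and pair distances follow the ideal CDF
  mix0 <- build_n2c8s2(kf = kf_params(epsilon = 1e-12))
  set.seed(4)
  cfg <- random_gas(48, 0.05, c(0.5, 0.5), mix0)
  r <- run_nvt(cfg, mix0, 0.1, n_sweeps = 4000, seed = 13,
               snap_every = 200)
  expect_true(all(r$observables$energy == 0))
  L <- cfg$box_length[1]
  rmax <- L / 2
  ds <- unlist(lapply(r$snapshots, function(s) {
    p <- s$pos
    n <- nrow(p)
    out <- numeric(0)
    for (i in seq_len(n - 1)) {
      d <- sweep(p[(i + 1):n, , drop = FALSE], 2, p[i, ])
      d <- d - L * round(d / L)      # minimum image
      out <- c(out, sqrt(rowSums(d^2)))
    }
    out
  }))
  ds <- ds[ds < rmax & ds > 1]
  # ideal-gas CDF for r in (sigma, rmax): proportional to r^3 - 1
  ks <- suppressWarnings(stats::ks.test(
    ds, function(q) (q^3 - 1) / (rmax^3 - 1)))
  expect_gt(ks$p.value, 0.001)
})

test_that("pure species aggregate into chains only (valence two)", {
  set.seed(6)
  for (xs in list(c(1, 0), c(0, 1))) {
    cfg <- random_gas(64, 0.3, xs, n2c8s2)
    r <- run_nvt(cfg, n2c8s2, 0.08, n_sweeps = 1.2e4, seed = 19,
                 cadence = 100)
    expect_gt(max(r$observables$n_bonds), 0)    # bonding does happen
    expect_lte(max(r$observables$max_bond_degree), 2)
  }
})

test_that("a deep quench lowers the energy in expectation", {
  set.seed(8)
  cfg <- random_gas(64, 0.3, c(0.5, 0.5), n2c8s2)
  r <- run_nvt(cfg, n2c8s2, 0.09, n_sweeps = 1e4, seed = 23, cadence = 100)
  e <- r$observables$energy
  fit <- stats::lm(e ~ seq_along(e))
  expect_lt(coef(fit)[2], 0)
  expect_lt(e[length(e)], e[1])
})

test_that("Gibbs ensemble conserves totals exactly and mixes ideal gases", {
  set.seed(14)
  mix0 <- build_n2c8s2(kf = kf_params(epsilon = 1e-12))
  a <- random_gas(32, 0.25, c(0.5, 0.5), mix0)
  b <- random_gas(32, 0.10, c(0.5, 0.5), mix0)
  gs <- gibbs_state(a, b)
  r <- run_gibbs(gs, mix0, 0.1, n_sweeps = 8000, seed = 31)
  ob <- r$observables
  vols <- ob$n_a / ob$rho_a + ob$n_b / ob$rho_b
  expect_lt(max(abs(vols - gs$total_volume)), 1e-8 * gs$total_volume)
  expect_true(all(ob$n_a + ob$n_b == 64))
  st <- r$state
  expect_equal(st$total_per_species, gs$total_per_species)
  # hard spheres at low phi: both boxes end at equal densities
  expect_lt(abs(r$summary$rho[1] - r$summary$rho[2]),
            6 * sqrt(sum(r$summary$rho_se^2)) + 0.02)
})

test_that("crystal detector: gas scores zero, seeds classify by flavor", {
  set.seed(16)
  gas <- random_gas(60, 0.1, c(0.5, 0.5), n2c8s2)
  expect_identical(crystal_fraction(gas, n2c8s2)$fraction, 0)
  seed <- build_diamond_seed(2, "cubic", n2c8s2)
  cf <- crystal_fraction(seed, n2c8s2)
  expect_identical(cf$fraction, 1)
  expect_identical(cf$largest_cluster, nrow(seed$positions))
  hseed <- build_diamond_seed(c(2, 2, 2), "hexagonal")
  expect_identical(crystal_fraction(hseed, attr(hseed, "mixture"))$fraction, 0)
})

test_that("XYZ round trip preserves configurations", {
  set.seed(18)
  cfg <- random_gas(20, 0.1, c(0.5, 0.5), n2c8s2)
  p <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(cfg, p)
  cfg2 <- read_xyz(p)
  expect_equal(cfg2$positions, cfg$positions, tolerance = 1e-10)
  expect_equal(cfg2$quaternions, cfg$quaternions, tolerance = 1e-10)
  expect_identical(cfg2$species, cfg$species)
  expect_equal(cfg2$box_length, cfg$box_length, tolerance = 1e-10)
})
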