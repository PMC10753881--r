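test_that("pair energy respects the hard core, the well edge and alignment", {
  kf <- n2c8s2$kf
  s1 <- n2c8s2$species[[1]]; s2 <- n2c8s2$species[[2]]
  idq <- c(1, 0, 0, 0)
  # inside the core
  r <- pair_energy(list(pos = c(0, 0, 0), quat = idq),
                   list(pos = c(0.5, 0, 0), quat = idq),
                   s1, s2, kf, n2c8s2$matrix, box = 20)
  expect_identical(r$energy, Inf)
  # beyond the well
  r <- pair_energy(list(pos = c(0, 0, 0), quat = idq),
                   list(pos = c(kf$sigma + kf$delta + 1e-6, 0, 0), quat = idq),
                   s1, s2, kf, n2c8s2$matrix, box = 20)
  expect_identical(r$energy, 0)
  # facing compatible patches at mid-well: color 3 (slot 3 of species 1)
  # pairs with color 7 (slot 3 of species 2); align both patch vectors with
  # the centre line
  u <- tetrahedral_vectors()[3, ]
  R1 <- frame_to(u, c(1, 0, 0))
  R2 <- frame_to(u, c(-1, 0, 0))
  r <- pair_energy(list(pos = c(0, 0, 0), quat = quat_from_matrix(R1)),
                   list(pos = c(kf$sigma + kf$delta / 2, 0, 0),
                        quat = quat_from_matrix(R2)),
                   s1, s2, kf, n2c8s2$matrix, box = 20)
  expect_equal(r$energy, -kf$epsilon)
  expect_equal(r$bond, c(3, 3))
})

test_that("pair energy is symmetric under particle exchange", {
  set.seed(41)
  kf <- n2c8s2$kf
  for (k in 1:100) {
    p1 <- random_pose(3); p2 <- random_pose(3)
    sa <- sample(2, 1); sb <- sample(2, 1)
    e12 <- pair_energy(p1, p2, n2c8s2$species[[sa]], n2c8s2$species[[sb]],
                       kf, n2c8s2$matrix, box = 3)
    e21 <- pair_energy(p2, p1, n2c8s2$species[[sb]], n2c8s2$species[[sa]],
                       kf, n2c8s2$matrix, box = 3)
    expect_identical(e12$energy, e21$energy)
  }
})

test_that("an all-zero matrix never produces a bond", {
  set.seed(42)
  zmat <- interaction_matrix(matrix(0L, 8, 8))
  kf <- kf_params(delta = 0.5, cos_theta_max = 0.5)  # huge patches
  for (k in 1:200) {
    p1 <- random_pose(3.2); p2 <- random_pose(3.2)
    e <- pair_energy(p1, p2, n2c8s2$species[[1]], n2c8s2$species[[2]],
                     kf, zmat, box = 3.2)
    expect_true(e$energy %in% c(0, Inf))
  }
})

test_that("pair energy validates orientations and the minimum-image box", {
  idq <- c(1, 0, 0, 0)
  expect_error(pair_energy(list(pos = c(0, 0, 0), quat = c(2, 0, 0, 0)),
                           list(pos = c(2, 0, 0), quat = idq),
                           n2c8s2$species[[1]], n2c8s2$species[[2]],
                           n2c8s2$kf, n2c8s2$matrix, box = 10),
               "unit norm")
  expect_error(pair_energy(list(pos = c(0, 0, 0), quat = idq),
                           list(pos = c(1.5, 0, 0), quat = idq),
                           n2c8s2$species[[1]], n2c8s2$species[[2]],
                           n2c8s2$kf, n2c8s2$matrix, box = 2),
               "minimum image")
})

test_that("the N2c8s2 design has the published structure", {
  m <- n2c8s2$matrix$entries
  expect_identical(m, t(m))
  expect_true(all(rowSums(m) == 1))          # bond exclusivity
  expect_identical(sum(diag(m)), 2L)         # two self-interacting colors
  expect_identical(n2c8s2$n_species, 2L)
  expect_identical(n2c8s2$matrix$n_colors, 8L)
  expect_equal(n2c8s2$composition, c(0.5, 0.5))
  # patch vectors are the unit tetrahedron for both species
  for (s in n2c8s2$species)
    expect_equal(s$patch_vectors, tetrahedral_vectors())
})

test_that("bonding volume limits and closed form", {
  expect_equal(bonding_volume(kf_params(delta = 1e-12)), 0, tolerance = 1e-10)
  expect_equal(bonding_volume(kf_params(cos_theta_max = 1)), 0)
  # closed form at the working point
  kf <- kf_params()
  expect_equal(bonding_volume(kf),
               pi / 3 * (1.2^3 - 1) * (1 - 0.98)^2, tolerance = 1e-12)
})

test_that("bonding volume matches the pose-sampling Monte Carlo oracle", {
  # brute force: relative position uniform in the shell, both orientations
  # uniform; bonded fraction times shell volume estimates V_b
  mc_vb <- function(kf, n) {
    shell <- (4 * pi / 3) * ((kf$sigma + kf$delta)^3 - kf$sigma^3)
    hits <- 0
    for (chunk in seq_len(n / 1e5)) {
      m <- 1e5
      r3 <- kf$sigma^3 + runif(m) * ((kf$sigma + kf$delta)^3 - kf$sigma^3)
      r <- r3^(1 / 3)
      z <- 2 * runif(m) - 1
      phi <- 2 * pi * runif(m)
      rh <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      # rotated body z-axis, vectorised over quaternions
      rotz <- function(q) cbind(2 * (q[, 2] * q[, 4] + q[, 1] * q[, 3]),
                                2 * (q[, 3] * q[, 4] - q[, 1] * q[, 2]),
                                1 - 2 * (q[, 2]^2 + q[, 3]^2))
      c1 <- rowSums(rotz(random_quaternion(m)) * rh)
      c2 <- -rowSums(rotz(random_quaternion(m)) * rh)
      hits <- hits + sum(c1 >= kf$cos_theta_max & c2 >= kf$cos_theta_max)
    }
    p <- hits / n
    list(vb = shell * p, se = shell * sqrt(p * (1 - p) / n))
  }
  set.seed(7)
  # wide patches: tight statistics
  for (pars in list(c(0.3, 0.80), c(0.15, 0.90))) {
    kf <- kf_params(delta = pars[1], cos_theta_max = pars[2])
    est <- mc_vb(kf, 2e5)
    expect_lt(abs(est$vb - bonding_volume(kf)), 3 * est$se)
  }
  # the design's working point (narrow patches, larger relative error)
  kf <- kf_params()
  est <- mc_vb(kf, 2e6)
  expect_lt(abs(est$vb - bonding_volume(kf)), 3 * est$se)
})

test_that("matrix and mixture round-trip through CSV / JSON / YAML", {
  td <- withr::local_tempdir()
  for (ext in c("csv", "json")) {
    p <- file.path(td, paste0("m.", ext))
    write_interaction_matrix(n2c8s2$matrix, p)
    m2 <- read_interaction_matrix(p)
    expect_identical(m2$entries, n2c8s2$matrix$entries)
  }
  for (ext in c("yaml", "json")) {
    p <- file.path(td, paste0("mix.", ext))
    write_mixture(n2c8s2, p)
    mx <- read_mixture(p)
    expect_identical(mx$matrix$entries, n2c8s2$matrix$entries)
    expect_equal(mx$composition, n2c8s2$composition)
    expect_equal(mx$species[[2]]$patch_colors, n2c8s2$species[[2]]$patch_colors)
    expect_equal(mx$kf$delta, n2c8s2$kf$delta)
  }
  # unknown keys are rejected
  p <- file.path(td, "bad.yaml")
  write_mixture(n2c8s2, p)
  txt <- readLines(p)
  writeLines(c(txt, "bogus_key: 1"), p)
  expect_error(read_mixture(p), "unknown config keys")
})
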