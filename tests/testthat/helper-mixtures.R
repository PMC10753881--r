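# Shared fixtures for the test suite (built once per file load).
n2c8s2 <- build_n2c8s2()

# single species, one patch, self-complementary color: the minimal bonding
# system used by the two-particle oracles
one_patch_mix <- mixture_spec(
  list(species_spec(rbind(c(0, 0, 1)), 1L)),
  1, kf_params(), interaction_matrix(matrix(1L, 1, 1)))

# one-component exclusivity reference: 4 tetrahedral patches, two
# complementary pairs (every patch has exactly one partner)
one_comp_excl <- mixture_spec(
  list(species_spec(tetrahedral_vectors(), c(1L, 2L, 3L, 4L))),
  1, kf_params(),
  interaction_matrix(rbind(c(0, 1, 0, 0), c(1, 0, 0, 0),
                           c(0, 0, 0, 1), c(0, 0, 1, 0))))

random_pose <- function(box = 10) {
  list(pos = runif(3) * box, quat = drop(random_quaternion(1)))
}

# minimal rotation matrix taking unit vector u to unit vector v (Rodrigues)
frame_to <- function(u, v) {
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    a <- a - sum(a * u) * u; a <- a / sqrt(sum(a^2))
    K <- rbind(c(0, -a[3], a[2]), c(a[3], 0, -a[1]), c(-a[2], a[1], 0))
    return(diag(3) + 2 * K %*% K)
  }
  w <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
         u[1] * v[2] - u[2] * v[1])
  K <- rbind(c(0, -w[3], w[2]), c(w[3], 0, -w[1]), c(-w[2], w[1], 0))
  diag(3) + K + K %*% K / (1 + c_)
}
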