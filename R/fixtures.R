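# Fixture generators: rule-satisfying interaction matrices for property
# tests, diamond seed lattices (ground truth for the crystal detector), and
# overlap-free random gas configurations.  Every fixture is validated by the
# corresponding checker or energy routine before it is returned.

#' Generate a mixture whose matrix provably satisfies a design rule
#'
#' Matrices are built constructively (random matchings/regular graphs over
#' colors) and then verified with the rule checkers before being returned.
#' Every color is used exactly once: species i carries colors
#' `(i-1)*n_patches + 1 .. i*n_patches`.
#'
#' For the multiplicity rule the generator additionally requires the design
#' to couple the two species (at least one inter-species bond); purely
#' intra-species solutions satisfy the patch-level counts but describe two
#' decoupled fluids, not a mixture design.  With four tetrahedral patches
#' this makes the 1:3 ratio (n = 3) infeasible.
#'
#' @param rule `"exclusivity"`, `"multiplicity"` or `"fully_connected"`.
#' @param n_species number of species (2 for multiplicity).
#' @param n_patches patches per species.
#' @param n bond multiplicity (multiplicity rule only).
#' @param kf [kf_params()].
#' @param self_prob probability of drawing a self-complementary color where
#'   the construction allows one (exclusivity rule).
#' @return a [mixture_spec()] whose composition is the rule's predicted
#'   azeotrope (equimolar for fully connected).
#' @export
generate_rule_matrix <- function(rule = c("exclusivity", "multiplicity",
                                          "fully_connected"),
                                 n_species, n_patches, n = NULL,
                                 kf = kf_params(), self_prob = 0.3) {
  rule <- match.arg(rule)
  ncol_tot <- n_species * n_patches
  ents <- matrix(0L, ncol_tot, ncol_tot)
  colors_of <- function(i) (i - 1L) * n_patches + seq_len(n_patches)
  if (rule == "exclusivity") {
    pool <- sample(ncol_tot)
    while (length(pool)) {
      c1 <- pool[1]; pool <- pool[-1]
      if (!length(pool) || stats::runif(1) < self_prob) {
        ents[c1, c1] <- 1L
      } else {
        c2 <- pool[1]; pool <- pool[-1]
        ents[c1, c2] <- ents[c2, c1] <- 1L
      }
    }
    comp <- rep(1 / n_species, n_species)
  } else if (rule == "fully_connected") {
    for (i in seq_len(n_species)) {
      ci <- colors_of(i)
      for (j in i:n_species) {
        cj <- colors_of(j)
        if (i == j) {
          # matching within a species (self-complementary when odd count)
          perm <- sample(ci)
          while (length(perm)) {
            if (length(perm) == 1 || stats::runif(1) < self_prob) {
              ents[perm[1], perm[1]] <- 1L
              perm <- perm[-1]
            } else {
              ents[perm[1], perm[2]] <- ents[perm[2], perm[1]] <- 1L
              perm <- perm[-(1:2)]
            }
          }
          # a matching with pairs leaves some patches without an intra
          # partner?  no: every color got exactly one partner above
        } else {
          perm <- sample(cj)
          for (k in seq_len(n_patches))
            ents[ci[k], perm[k]] <- ents[perm[k], ci[k]] <- 1L
        }
      }
    }
    comp <- rep(1 / n_species, n_species)
  } else {
    if (is.null(n) || n < 1) stop("multiplicity rule needs n >= 1")
    if (n_species != 2) stop("multiplicity rule supports binary mixtures")
    # a2 hub colors on species 2, each bonded to n exclusive colors of
    # species 1; remaining species-1 colors form an n-regular graph; the
    # remaining species-2 colors pair up among themselves.
    a2 <- NA
    for (cand in seq(floor(n_patches / n), 1)) {
      m1 <- n_patches - n * cand
      if (m1 == 0 || m1 >= n + ifelse(n %% 2 == 1 && m1 %% 2 == 1, 0, 0) &&
          m1 > n - 1 + (n %% 2) * 0) {
        if (m1 == 0 || m1 >= n) { a2 <- cand; break }
      }
      if (m1 == 0) { a2 <- cand; break }
    }
    if (is.na(a2) || a2 < 1)
      stop(sprintf(
        "no mixed design satisfies the multiplicity rule for n = %d with %d patches (ratio 1:%d infeasible)",
        n, n_patches, n))
    c1 <- colors_of(1); c2 <- colors_of(2)
    m1 <- n_patches - n * a2
    reg <- if (m1 > 0) sample(c1)[seq_len(m1)] else integer(0)
    excl <- setdiff(c1, reg)
    hubs <- sample(c2)[seq_len(a2)]
    rest2 <- setdiff(c2, hubs)
    # hubs: n exclusive species-1 partners each
    grp <- split(sample(excl), rep(seq_len(a2), each = n))
    for (h in seq_len(a2))
      for (cc in grp[[h]])
        ents[cc, hubs[h]] <- ents[hubs[h], cc] <- 1L
    # n-regular (circulant) graph on the remaining species-1 colors
    if (m1 > 0) {
      half <- n %/% 2
      for (v in seq_len(m1)) {
        for (d in seq_len(half)) {
          w <- ((v - 1 + d) %% m1) + 1
          ents[reg[v], reg[w]] <- ents[reg[w], reg[v]] <- 1L
        }
        if (n %% 2 == 1) {
          if (m1 %% 2 == 0) {
            w <- ((v - 1 + m1 / 2) %% m1) + 1
            ents[reg[v], reg[w]] <- ents[reg[w], reg[v]] <- 1L
          } else {
            ents[reg[v], reg[v]] <- 1L
          }
        }
      }
    }
    # matching among the remaining species-2 colors
    while (length(rest2)) {
      if (length(rest2) == 1) {
        ents[rest2[1], rest2[1]] <- 1L
        rest2 <- rest2[-1]
      } else {
        ents[rest2[1], rest2[2]] <- ents[rest2[2], rest2[1]] <- 1L
        rest2 <- rest2[-(1:2)]
      }
    }
    comp <- c(1 / (n + 1), n / (n + 1))
  }
  pv <- if (n_patches == 4) tetrahedral_vectors() else {
    v <- matrix(stats::rnorm(3 * n_patches), ncol = 3)
    v / sqrt(rowSums(v^2))
  }
  species <- lapply(seq_len(n_species),
                    function(i) species_spec(pv, colors_of(i)))
  mix <- mixture_spec(species, comp, kf, interaction_matrix(ents))
  rep_ok <- switch(rule,
                   exclusivity = check_bond_exclusivity(mix),
                   multiplicity = check_bond_multiplicity(mix, n),
                   fully_connected = check_fully_connected(mix))
  if (!rep_ok$satisfied)
    stop("internal error: generated matrix fails its own rule check")
  mix
}

# Tetrahedral bond direction set in units of the quarter lattice constant.
diamond_t <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))

# quaternions of the four orientation forms used by the cubic-diamond
# decoration: identity, 180deg about x, about (0,1,1)/sqrt(2), about
# (0,1,-1)/sqrt(2)
seed_quats <- rbind(
  c(1, 0, 0, 0),
  c(0, 1, 0, 0),
  c(0, 0, 1 / sqrt(2), 1 / sqrt(2)),
  c(0, 0, 1 / sqrt(2), -1 / sqrt(2)))

#' Build a periodic diamond seed lattice
#'
#' `flavor = "cubic"` decorates the cubic-diamond lattice with N2c8s2
#' species and orientations so that every patch faces a color-compatible
#' partner: slabs of width a/2 along x cycle through four
#' (species, orientation) forms with period 2a, so the cell count along x
#' must be even.  `flavor = "hexagonal"` builds the ideal wurtzite
#' (hexagonal-diamond) lattice in an orthorhombic box; orientations point
#' the patches at the four neighbours, and a single-species all-bonding
#' mixture is used by default (the N2c8s2 matrix deliberately frustrates
#' this lattice).
#'
#' @param n_cells cells per dimension: scalar or length-3 (cubic flavour
#'   needs an even count along x).
#' @param flavor `"cubic"` or `"hexagonal"`.
#' @param mixture mixture for the cubic decoration; defaults to
#'   [build_n2c8s2()].
#' @param bond_length nearest-neighbour distance, default `sigma + delta/2`
#'   (mid-well).
#' @return a [configuration()]; for hexagonal seeds the attribute
#'   `mixture` holds the permissive single-species mixture to analyse with.
#' @export
build_diamond_seed <- function(n_cells, flavor = c("cubic", "hexagonal"),
                               mixture = build_n2c8s2(),
                               bond_length = NULL) {
  flavor <- match.arg(flavor)
  if (length(n_cells) == 1) n_cells <- rep(n_cells, 3)
  stopifnot(all(n_cells >= 1))
  kf <- mixture$kf
  if (is.null(bond_length)) bond_length <- kf$sigma + kf$delta / 2
  if (flavor == "cubic") {
    if (mixture$n_patches != 4)
      stop("diamond decoration requires 4 tetrahedral patches")
    if (n_cells[1] %% 2 != 0)
      stop("cubic seed needs an even cell count along x (orientation pattern has period 2a)")
    a <- 4 * bond_length / sqrt(3)
    u <- a / 4
    fcc <- rbind(c(0, 0, 0), c(0, 2, 2), c(2, 0, 2), c(2, 2, 0))
    pos <- list(); spc <- integer(0); qt <- list()
    # per slab (width 2u) cycle alpha(sp1) delta(sp2) beta(sp1) gamma(sp2)
    # A-form / B-form quaternion rows in seed_quats:
    formq <- list(
      alpha = c(A = 1, B = 4), beta = c(A = 2, B = 3),
      gamma = c(A = 1, B = 3), delta = c(A = 2, B = 4))
    cyc <- c("alpha", "delta", "beta", "gamma")
    spof <- c(alpha = 1L, beta = 1L, gamma = 2L, delta = 2L)
    for (cx in 0:(n_cells[1] - 1)) for (cy in 0:(n_cells[2] - 1))
      for (cz in 0:(n_cells[3] - 1)) {
        base <- c(cx, cy, cz) * 4
        for (k in 1:4) for (sub in 0:1) {
          p <- base + fcc[k, ] + sub * c(1, 1, 1)
          slab <- floor(p[1] / 2) %% 4
          form <- cyc[slab + 1]
          ab <- if (p[1] %% 2 == 0) "A" else "B"
          pos[[length(pos) + 1L]] <- p * u
          spc <- c(spc, spof[[form]])
          qt[[length(qt) + 1L]] <- seed_quats[formq[[form]][[ab]], ]
        }
      }
    cfg <- configuration(do.call(rbind, pos), do.call(rbind, qt), spc,
                         n_cells * a, sigma = kf$sigma)
    te <- total_energy(cfg, mixture)
    if (any(te$degree != 4))
      stop("internal error: cubic seed is not fully tetravalent")
    attr(cfg, "mixture") <- mixture
    cfg
  } else {
    # ideal wurtzite in an orthorhombic cell (a, sqrt(3) a, c), 8 atoms;
    # bond along c: u*c with u = 3/8, c = sqrt(8/3) a  ->  bond = 0.6124 a
    a_hex <- bond_length / (3 / 8 * sqrt(8 / 3))
    c_hex <- sqrt(8 / 3) * a_hex
    base <- rbind(
      c(0, 0, 0), c(1 / 2, 1 / 2 * sqrt(3), 0),
      c(1 / 2, sqrt(3) / 6, 1 / 2), c(0, sqrt(3) * 2 / 3, 1 / 2))
    pos <- list(); spc <- integer(0)
    for (cx in 0:(n_cells[1] - 1)) for (cy in 0:(n_cells[2] - 1))
      for (cz in 0:(n_cells[3] - 1)) {
        for (k in 1:4) {
          p0 <- c((base[k, 1] + cx) * a_hex, (base[k, 2] + cy * sqrt(3)) * a_hex,
                  (base[k, 3] + cz) * c_hex)
          p1 <- p0 + c(0, 0, 3 / 8 * c_hex)
          pos[[length(pos) + 1L]] <- p0
          pos[[length(pos) + 1L]] <- p1
          spc <- c(spc, 1L, 1L)
        }
      }
    P <- do.call(rbind, pos)
    box <- c(n_cells[1] * a_hex, n_cells[2] * sqrt(3) * a_hex,
             n_cells[3] * c_hex)
    # permissive one-species mixture: every patch same self-complementary
    # color, so orientation assignment only needs geometry
    permissive <- mixture_spec(
      list(species_spec(tetrahedral_vectors(), rep(1L, 4))),
      1, kf, interaction_matrix(matrix(1L, 1, 1)))
    # orient each particle so its patches point at its 4 nearest neighbours
    Q <- matrix(0, nrow(P), 4)
    for (i in seq_len(nrow(P))) {
      d <- sweep(P, 2, P[i, ])
      for (kk in 1:3) d[, kk] <- d[, kk] - box[kk] * round(d[, kk] / box[kk])
      r <- sqrt(rowSums(d^2)); r[i] <- Inf
      nb <- order(r)[1:4]
      dirs <- d[nb, ] / r[nb]
      Q[i, ] <- orient_to_directions(tetrahedral_vectors(), dirs)
    }
    cfg <- configuration(P, Q, spc, box, sigma = kf$sigma)
    te <- total_energy(cfg, permissive)
    if (any(te$degree != 4))
      stop("internal error: hexagonal seed is not fully tetravalent")
    attr(cfg, "mixture") <- permissive
    cfg
  }
}

# Proper rotation mapping the body tetrahedron onto 4 target directions
# (any assignment); returns a quaternion.
orient_to_directions <- function(body, dirs) {
  perms <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ,
                 drop = FALSE]
  for (p in seq_len(nrow(perms))) {
    tgt <- dirs[perms[p, ], , drop = FALSE]
    # rotation from two exact correspondences
    R <- frame_rotation(body[1, ], body[2, ], tgt[1, ], tgt[2, ])
    if (is.null(R)) next
    if (max(abs(body %*% t(R) - tgt)) < 1e-6)
      return(quat_from_matrix(R))
  }
  stop("no proper rotation maps the patch tetrahedron onto the neighbour directions")
}

frame_rotation <- function(u1, u2, v1, v2) {
  b3 <- function(a, b) {
    e1 <- a / sqrt(sum(a^2))
    e2 <- b - sum(b * e1) * e1
    n2 <- sqrt(sum(e2^2))
    if (n2 < 1e-9) return(NULL)
    e2 <- e2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2], e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    cbind(e1, e2, e3)
  }
  B <- b3(u1, u2); V <- b3(v1, v2)
  if (is.null(B) || is.null(V)) return(NULL)
  V %*% t(B)
}

#' Overlap-free random gas configuration
#'
#' Sequential random insertion with retries; species counts follow the
#' requested composition by largest-remainder rounding.
#'
#' @param n particle count.
#' @param rho total number density (sigma^-3).
#' @param x composition vector.
#' @param mixture a [mixture_spec()].
#' @param max_tries insertion attempts per particle.
#' @return a [configuration()] in a cubic box.
#' @export
random_gas <- function(n, rho, x, mixture, max_tries = 2000) {
  kf <- mixture$kf
  L <- (n / rho)^(1 / 3)
  phi <- rho * pi * kf$sigma^3 / 6
  if (phi > 0.45) stop("packing fraction too high for random insertion")
  # largest-remainder species allocation
  raw <- x * n
  cnt <- floor(raw)
  rem <- n - sum(cnt)
  if (rem > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(rem)]] <- cnt[ord[seq_len(rem)]] + 1
  }
  species <- rep(seq_along(x), times = cnt)
  pos <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (t in seq_len(max_tries)) {
      p <- runif(3) * L
      if (i == 1) { ok <- TRUE; break }
      d <- sweep(pos[seq_len(i - 1), , drop = FALSE], 2, p)
      d <- d - L * round(d / L)
      if (min(rowSums(d^2)) >= kf$sigma^2) { ok <- TRUE; break }
    }
    if (!ok) stop("packing failure: could not insert particle ", i)
    pos[i, ] <- p
  }
  configuration(pos, random_quaternion(n), species, L, sigma = kf$sigma)
}
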