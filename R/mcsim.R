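# Monte Carlo front end: configurations, energy/bond analysis, NVT and
# Gibbs-ensemble runs (the sampling loops live in compiled code), the AVB
# acceptance bookkeeping, and the dihedral-based crystal detector.

#' A particle configuration
#'
#' @param positions N x 3 matrix of coordinates (sigma units).
#' @param quaternions N x 4 matrix of unit orientation quaternions
#'   `(w, x, y, z)`.
#' @param species integer vector of species labels (1-based).
#' @param box_length cubic box edge, or a length-3 vector for orthorhombic
#'   boxes (analysis only; the samplers require cubic boxes).
#' @param validate check unit quaternions and hard-core overlaps.
#' @param sigma hard-core diameter used for the overlap check.
#' @return object of class `configuration`.
#' @export
configuration <- function(positions, quaternions, species, box_length,
                          validate = TRUE, sigma = 1) {
  positions <- as.matrix(positions)
  quaternions <- as.matrix(quaternions)
  species <- as.integer(species)
  stopifnot(ncol(positions) == 3, ncol(quaternions) == 4,
            nrow(positions) == nrow(quaternions),
            nrow(positions) == length(species),
            length(box_length) %in% c(1, 3), all(box_length > 0))
  if (length(box_length) == 1) box_length <- rep(box_length, 3)
  if (validate) {
    qn <- rowSums(quaternions^2)
    if (any(abs(qn - 1) > 1e-9))
      stop("quaternions must have unit norm")
    if (nrow(positions) > 1) {
      d2 <- min_pair_dist2(positions, box_length)
      if (d2 < sigma^2 * (1 - 1e-12))
        stop(sprintf("hard-core overlap: minimum pair distance %.6f < sigma",
                     sqrt(d2)))
    }
  }
  structure(list(positions = positions, quaternions = quaternions,
                 species = species, box_length = box_length),
            class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("configuration: %d particles, box %s (species counts: %s)\n",
              nrow(x$positions),
              paste(signif(x$box_length, 6), collapse = " x "),
              paste(tabulate(x$species), collapse = "/")))
  invisible(x)
}

# minimum-image squared distances (R fallback, any box)
min_pair_dist2 <- function(pos, box) {
  n <- nrow(pos)
  best <- Inf
  for (i in seq_len(n - 1)) {
    d <- sweep(pos[(i + 1):n, , drop = FALSE], 2, pos[i, ])
    for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    best <- min(best, min(rowSums(d^2)))
  }
  best
}

# mixture -> compact list handed to the compiled engine
mix_to_engine <- function(mixture) {
  list(patchv = lapply(mixture$species, function(s) s$patch_vectors),
       patchc = lapply(mixture$species, function(s) as.integer(s$patch_colors)),
       ups = mixture$matrix$entries,
       eps = mixture$kf$epsilon, delta = mixture$kf$delta,
       cosmax = mixture$kf$cos_theta_max, sigma = mixture$kf$sigma)
}

#' Bond graph of a configuration (R implementation, any box shape)
#'
#' A bond joins two particles at centre distance in `[sigma, sigma+delta]`
#' whose best color-compatible patch pair is mutually aligned within
#' `theta_max`; at most one bond per pair is counted.
#'
#' @param config a [configuration()].
#' @param mixture a [mixture_spec()].
#' @return data frame with columns i, patch_i, j, patch_j (1-based).
#' @export
bond_graph <- function(config, mixture) {
  n <- nrow(config$positions)
  kf <- mixture$kf
  box <- config$box_length
  pw <- lapply(seq_len(n), function(i)
    quat_rotate(config$quaternions[i, ],
                mixture$species[[config$species[i]]]$patch_vectors))
  rows <- list()
  rc2 <- (kf$sigma + kf$delta)^2
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- config$positions[j, ] - config$positions[i, ]
      d <- d - box * round(d / box)
      r2 <- sum(d * d)
      if (r2 > rc2 || r2 < kf$sigma^2) next
      rhat <- d / sqrt(r2)
      ci <- drop(pw[[i]] %*% rhat)
      cj <- drop(pw[[j]] %*% -rhat)
      coli <- mixture$species[[config$species[i]]]$patch_colors
      colj <- mixture$species[[config$species[j]]]$patch_colors
      best <- -Inf; ba <- NA; bb <- NA
      for (a in which(ci >= kf$cos_theta_max))
        for (b in which(cj >= kf$cos_theta_max))
          if (mixture$matrix$entries[coli[a], colj[b]] == 1L &&
              ci[a] + cj[b] > best) {
            best <- ci[a] + cj[b]; ba <- a; bb <- b
          }
      if (!is.na(ba))
        rows[[length(rows) + 1L]] <- c(i, ba, j, bb)
    }
  }
  out <- if (length(rows)) as.data.frame(do.call(rbind, rows))
  else as.data.frame(matrix(numeric(0), ncol = 4))
  names(out) <- c("i", "patch_i", "j", "patch_j")
  out
}

#' Total energy and bond graph
#'
#' Sum of Kern-Frenkel pair energies: `-epsilon` per bonded pair.  Uses the
#' compiled cell-list engine for cubic boxes and the R pairwise routine
#' otherwise.
#'
#' @param config a [configuration()].
#' @param mixture a [mixture_spec()].
#' @return list with `energy`, `bonds` (data frame as [bond_graph()]),
#'   `degree` (per-particle bond count) and `max_patch_use` (should be 1:
#'   one bond per patch).
#' @export
total_energy <- function(config, mixture) {
  box <- config$box_length
  cubic <- max(box) - min(box) < 1e-12
  if (cubic) {
    res <- .mc_total_energy(config$positions, config$quaternions,
                            config$species, box[1], mix_to_engine(mixture))
    if (res$overlap)
      stop("hard-core overlap in configuration")
    bonds <- as.data.frame(res$edges)
    names(bonds) <- c("i", "patch_i", "j", "patch_j")
    energy <- res$energy
  } else {
    bonds <- bond_graph(config, mixture)
    energy <- -mixture$kf$epsilon * nrow(bonds)
  }
  n <- nrow(config$positions)
  degree <- tabulate(c(bonds$i, bonds$j), nbins = n)
  use <- table(c(paste(bonds$i, bonds$patch_i),
                 paste(bonds$j, bonds$patch_j)))
  list(energy = energy, bonds = bonds, degree = degree,
       max_patch_use = if (length(use)) max(use) else 0L)
}

#' AVB acceptance factor
#'
#' The bind move (AVB-B) places a particle k, chosen uniformly among the
#' particles not bonded to a target j, uniformly inside the bonding volume
#' of a uniformly chosen compatible patch pair; the release move (AVB-U)
#' moves a bonded neighbour to a uniform pose in the box.  With proposal
#' densities written out, the Metropolis ratios are
#' \deqn{acc_B = e^{-\beta\Delta U}\,
#'   \frac{p_U}{p_B}\frac{M_{out}(s)\,n_{pairs} V_b}{N_j(s') V},\qquad
#'   acc_U = e^{-\beta\Delta U}\,
#'   \frac{p_B}{p_U}\frac{N_j(s)\, V}{M_{out}(s')\,n_{pairs} V_b}}
#' where \eqn{N_j} counts bonded neighbours of the target, \eqn{M_{out} =
#' N - 1 - N_j}, and \eqn{n_{pairs}} is the number of compatible patch pairs
#' for the two species.  The ratio V/V_b >> 1 is what makes bond breaking
#' tractable at low temperature.
#'
#' @param direction `"bind"` or `"release"`.
#' @param dU energy change of the move.
#' @param T temperature.
#' @param M_out non-bonded candidate count in the state the bind move
#'   starts from.
#' @param N_j bonded-neighbour count of the target in the state the release
#'   move starts from.
#' @param n_pairs compatible patch pairs between the two species.
#' @param V box volume; `V_b` bonding volume.
#' @param V_b bonding volume.
#' @param p_b,p_u selection probabilities of the two move types.
#' @return the (uncapped) acceptance ratio.
#' @export
avb_acceptance <- function(direction, dU, T, M_out, N_j, n_pairs, V, V_b,
                           p_b = 0.1, p_u = 0.1) {
  base <- exp(-dU / T)
  if (direction == "bind")
    base * (p_u / p_b) * M_out * n_pairs * V_b / (N_j * V)
  else
    base * (p_b / p_u) * N_j * V / (M_out * n_pairs * V_b)
}

#' NVT Monte Carlo run
#'
#' Metropolis sampling with a configurable mix of rototranslation and
#' AVB bind/release moves (N attempted moves per sweep).
#'
#' @param config starting [configuration()] (cubic box).
#' @param mixture a [mixture_spec()].
#' @param T temperature.
#' @param n_sweeps number of sweeps.
#' @param seed RNG seed (runs are bit-reproducible given the seed).
#' @param move_mix probabilities `c(rototranslation, avb_bind, avb_release)`.
#' @param dmax,rmax maximum displacement (sigma) and rotation (rad).
#' @param cadence record observables every this many sweeps.
#' @param snap_every store configuration snapshots at this cadence (0 = no
#'   snapshots).
#' @return list with the final `config`, `observables` (sweep, energy,
#'   n_bonds, largest_cluster, max_bond_degree), `acceptance` counts, and
#'   `snapshots`; the seed is recorded in `meta`.
#' @export
run_nvt <- function(config, mixture, T, n_sweeps, seed,
                    move_mix = c(0.8, 0.1, 0.1), dmax = 0.1, rmax = 0.1,
                    cadence = max(1L, n_sweeps %/% 200L), snap_every = 0) {
  box <- config$box_length
  if (max(box) - min(box) > 1e-12) stop("NVT sampler requires a cubic box")
  if (box[1] < 2 * (mixture$kf$sigma + mixture$kf$delta))
    stop("box smaller than 2*(sigma + delta)")
  move_mix <- move_mix / sum(move_mix)
  res <- .mc_run_nvt(config$positions, config$quaternions, config$species,
                     box[1], mix_to_engine(mixture), T,
                     as.integer(n_sweeps), as.integer(seed),
                     move_mix[1], move_mix[2], move_mix[3],
                     dmax, rmax, as.integer(cadence),
                     as.integer(snap_every))
  final <- configuration(res$pos, res$quat, config$species, box[1],
                         validate = FALSE)
  list(config = final, observables = res$observables,
       acceptance = res$acceptance, snapshots = res$snapshots,
       meta = list(seed = seed, T = T, n_sweeps = n_sweeps,
                   move_mix = move_mix))
}

#' Two coupled boxes for Gibbs-ensemble sampling
#'
#' @param box_a,box_b [configuration()] objects (cubic boxes).
#' @return object of class `gibbs_state` with conserved totals recorded.
#' @export
gibbs_state <- function(box_a, box_b) {
  structure(list(box_a = box_a, box_b = box_b,
                 total_volume = prod(box_a$box_length) +
                   prod(box_b$box_length),
                 total_per_species =
                   tabulate(box_a$species,
                            nbins = max(box_a$species, box_b$species)) +
                   tabulate(box_b$species,
                            nbins = max(box_a$species, box_b$species))),
            class = "gibbs_state")
}

#' Gibbs-ensemble Monte Carlo run
#'
#' Two boxes exchange volume (one move per sweep, uniform in ln V) and
#' particles (`transfer_per_sweep` attempts per sweep) on top of the NVT
#' move mix; total volume and per-species counts are conserved exactly.
#'
#' @param state a [gibbs_state()].
#' @param mixture a [mixture_spec()].
#' @param T temperature.
#' @param n_sweeps sweeps.
#' @param seed RNG seed.
#' @param move_mix,dmax,rmax as in [run_nvt()].
#' @param dlnV half-width of the ln-volume step.
#' @param transfer_per_sweep particle-transfer attempts per sweep.
#' @param cadence observable recording cadence (sweeps).
#' @param equil_fraction fraction of the run discarded before averaging.
#' @param n_blocks blocks for the error bars.
#' @return list with `observables` (per-cadence trajectory), `summary`
#'   (block-averaged rho and x per box with standard errors, dilute/dense
#'   assignment by density), final `state`, and `acceptance`.
#' @export
run_gibbs <- function(state, mixture, T, n_sweeps, seed,
                      move_mix = c(0.8, 0.1, 0.1), dmax = 0.1, rmax = 0.1,
                      dlnV = 0.1, transfer_per_sweep = NULL,
                      cadence = max(1L, n_sweeps %/% 500L),
                      equil_fraction = 0.2, n_blocks = 10) {
  a <- state$box_a; b <- state$box_b
  for (cfg in list(a, b))
    if (max(cfg$box_length) - min(cfg$box_length) > 1e-12)
      stop("Gibbs sampler requires cubic boxes")
  if (is.null(transfer_per_sweep))
    transfer_per_sweep <- max(1L, (nrow(a$positions) + nrow(b$positions)) %/% 10L)
  move_mix <- move_mix / sum(move_mix)
  res <- .mc_run_gibbs(a$positions, a$quaternions, a$species, a$box_length[1],
                       b$positions, b$quaternions, b$species, b$box_length[1],
                       mix_to_engine(mixture), T, as.integer(n_sweeps),
                       as.integer(seed), move_mix[1], move_mix[2],
                       move_mix[3], dmax, rmax, dlnV,
                       as.integer(transfer_per_sweep), as.integer(cadence))
  ob <- res$observables
  keep <- ob$sweep > equil_fraction * n_sweeps
  obp <- ob[keep, , drop = FALSE]
  # per sample, order phases by density so averages track branches
  dilute_rho <- pmin(obp$rho_a, obp$rho_b)
  dense_rho <- pmax(obp$rho_a, obp$rho_b)
  a_is_dilute <- obp$rho_a <= obp$rho_b
  dilute_x <- ifelse(a_is_dilute, obp$x_a, obp$x_b)
  dense_x <- ifelse(a_is_dilute, obp$x_b, obp$x_a)
  block_stats <- function(v) {
    v <- v[!is.na(v)]
    nb <- min(n_blocks, length(v))
    idx <- cut(seq_along(v), nb, labels = FALSE)
    m <- tapply(v, idx, mean)
    c(mean = mean(m), se = stats::sd(m) / sqrt(nb))
  }
  summary <- rbind(
    data.frame(branch = "dilute", t(block_stats(dilute_rho)),
               x = block_stats(dilute_x)[1], x_se = block_stats(dilute_x)[2]),
    data.frame(branch = "dense", t(block_stats(dense_rho)),
               x = block_stats(dense_x)[1], x_se = block_stats(dense_x)[2]))
  names(summary)[2:3] <- c("rho", "rho_se")
  fa <- res$box_a; fb <- res$box_b
  out_state <- gibbs_state(
    configuration(fa$pos, fa$quat, fa$species, fa$L, validate = FALSE),
    configuration(fb$pos, fb$quat, fb$species, fb$L, validate = FALSE))
  list(observables = ob, summary = summary, state = out_state,
       acceptance = res$acceptance,
       meta = list(seed = seed, T = T, n_sweeps = n_sweeps))
}

#' Fraction of particles in a cubic-diamond-like environment
#'
#' A particle is classified cubic-diamond-like when it carries 4 bonds and
#' every bond to a 4-bonded neighbour is staggered: all dihedral angles
#' k-i-j-l across the bond satisfy cos(3 theta) < 0 (staggered minima at
#' 60/180/300 degrees give -1, eclipsed at 0/120/240 give +1, so the sign
#' separates cubic from hexagonal diamond).
#'
#' @param config a [configuration()].
#' @param mixture a [mixture_spec()].
#' @param bonds optional precomputed bond data frame (as [bond_graph()]).
#' @return list with `fraction`, `n_crystal`, `largest_cluster` (largest
#'   connected crystalline cluster), and the per-particle logical `is_cubic`.
#' @export
crystal_fraction <- function(config, mixture, bonds = NULL) {
  if (is.null(bonds)) bonds <- bond_graph(config, mixture)
  n <- nrow(config$positions)
  box <- config$box_length
  nbrs <- vector("list", n)
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    nbrs[[bonds$i[k]]] <- c(nbrs[[bonds$i[k]]], bonds$j[k])
    nbrs[[bonds$j[k]]] <- c(nbrs[[bonds$j[k]]], bonds$i[k])
  }
  disp <- function(i, j) {
    d <- config$positions[j, ] - config$positions[i, ]
    d - box * round(d / box)
  }
  bond_staggered <- function(i, j) {
    a <- disp(i, j); a <- a / sqrt(sum(a^2))
    ks <- setdiff(nbrs[[i]], j); ls <- setdiff(nbrs[[j]], i)
    if (!length(ks) || !length(ls)) return(TRUE)
    for (k in ks) {
      v1 <- disp(i, k); v1 <- v1 - sum(v1 * a) * a
      n1 <- sqrt(sum(v1^2)); if (n1 < 1e-9) next
      v1 <- v1 / n1
      for (l in ls) {
        v2 <- disp(j, l); v2 <- v2 - sum(v2 * a) * a
        n2 <- sqrt(sum(v2^2)); if (n2 < 1e-9) next
        v2 <- v2 / n2
        cth <- max(min(sum(v1 * v2), 1), -1)
        if (4 * cth^3 - 3 * cth >= 0) return(FALSE)
      }
    }
    TRUE
  }
  is_cubic <- vapply(seq_len(n), function(i) {
    if (length(nbrs[[i]]) != 4) return(FALSE)
    all(vapply(nbrs[[i]], function(j) bond_staggered(i, j), logical(1)))
  }, logical(1))
  # largest crystalline cluster (bonds among classified particles)
  parent <- seq_len(n)
  findp <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(bonds)) for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]
    if (is_cubic[i] && is_cubic[j]) {
      ri <- findp(i); rj <- findp(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  cl <- if (any(is_cubic))
    max(table(vapply(which(is_cubic), findp, integer(1)))) else 0L
  list(fraction = mean(is_cubic), n_crystal = sum(is_cubic),
       largest_cluster = as.integer(cl), is_cubic = is_cubic)
}

# ---------------------------------------------------------------------------
# Extended XYZ I/O (species + quaternion columns)
# ---------------------------------------------------------------------------

#' Write / read configurations as extended XYZ
#'
#' Row format: `species x y z qw qx qy qz`; the comment line carries the
#' box as `Lattice="Lx 0 0 0 Ly 0 0 0 Lz"`.
#'
#' @param config a [configuration()].
#' @param path file path.
#' @export
write_xyz <- function(config, path) {
  n <- nrow(config$positions)
  L <- config$box_length
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(n), con)
  writeLines(sprintf(
    'Lattice="%.12g 0 0 0 %.12g 0 0 0 %.12g" Properties=species:I:1:pos:R:3:quat:R:4',
    L[1], L[2], L[3]), con)
  rows <- cbind(config$species, config$positions, config$quaternions)
  writeLines(apply(rows, 1, function(r)
    paste(c(sprintf("%d", r[1]), sprintf("%.12g", r[-1])), collapse = " ")),
    con)
  invisible(path)
}

#' @rdname write_xyz
#' @param validate passed to [configuration()].
#' @return for `read_xyz`, a [configuration()].
#' @export
read_xyz <- function(path, validate = TRUE) {
  lines <- readLines(path)
  n <- as.integer(lines[1])
  lat <- regmatches(lines[2],
                    regexpr('Lattice="[^"]*"', lines[2]))
  nums <- as.numeric(strsplit(sub('Lattice="([^"]*)"', "\\1", lat),
                              "\\s+")[[1]])
  L <- nums[c(1, 5, 9)]
  dat <- do.call(rbind, lapply(lines[3:(2 + n)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
  configuration(dat[, 2:4, drop = FALSE], dat[, 5:8, drop = FALSE],
                as.integer(dat[, 1]), L, validate = validate)
}
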