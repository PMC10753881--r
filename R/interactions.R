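#' @useDynLib azeopatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize runif setNames uniroot
#' @importFrom utils head read.csv write.csv
NULL

# ---------------------------------------------------------------------------
# Kern-Frenkel parameters
# ---------------------------------------------------------------------------

#' Kern-Frenkel interaction parameters
#'
#' The Kern-Frenkel potential is a hard sphere of diameter `sigma` decorated
#' with attractive patches: two particles at centre distance r in
#' `[sigma, sigma + delta]` gain energy `-epsilon` when a compatible patch
#' pair is mutually aligned, i.e. the cosine of the angle between each patch
#' vector and the centre-to-centre unit vector is at least `cos_theta_max`.
#'
#' @param epsilon well depth (energy unit; 1 by convention).
#' @param delta well width, in units of `sigma`.
#' @param cos_theta_max cosine of the angular half-width of a patch.
#' @param sigma hard-core diameter (length unit; 1 by convention).
#' @return an object of class `kf_params`.
#' @export
kf_params <- function(epsilon = 1, delta = 0.2, cos_theta_max = 0.98,
                      sigma = 1) {
  stopifnot(epsilon > 0, delta > 0, sigma > 0,
            cos_theta_max > 0, cos_theta_max <= 1)
  structure(list(epsilon = epsilon, delta = delta,
                 cos_theta_max = cos_theta_max, sigma = sigma),
            class = "kf_params")
}

#' @export
print.kf_params <- function(x, ...) {
  cat(sprintf(
    "Kern-Frenkel parameters: epsilon = %g, delta = %g, cos(theta_max) = %g, sigma = %g\n",
    x$epsilon, x$delta, x$cos_theta_max, x$sigma))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Species, interaction matrix, mixture
# ---------------------------------------------------------------------------

#' Define a patchy-particle species
#'
#' @param patch_vectors numeric matrix (n_patches x 3) of unit patch vectors
#'   in the body frame.
#' @param patch_colors integer vector of patch colors (1-based indices into
#'   the interaction matrix), one per patch.
#' @return an object of class `species_spec`.
#' @export
species_spec <- function(patch_vectors, patch_colors) {
  patch_vectors <- as.matrix(patch_vectors)
  stopifnot(ncol(patch_vectors) == 3,
            nrow(patch_vectors) == length(patch_colors))
  nrm <- sqrt(rowSums(patch_vectors^2))
  if (any(abs(nrm - 1) > 1e-12))
    stop("patch vectors must have unit norm")
  patch_colors <- as.integer(patch_colors)
  structure(list(patch_vectors = patch_vectors,
                 patch_colors = patch_colors),
            class = "species_spec")
}

#' Symmetric boolean color-compatibility matrix
#'
#' @param entries square 0/1 matrix; `entries[a, g] = 1` means patches of
#'   color a and color g can bond.
#' @return an object of class `interaction_matrix`.
#' @export
interaction_matrix <- function(entries) {
  entries <- as.matrix(entries)
  storage.mode(entries) <- "integer"
  if (nrow(entries) != ncol(entries))
    stop("interaction matrix must be square")
  if (!all(entries %in% c(0L, 1L)))
    stop("interaction matrix entries must be 0 or 1")
  if (!identical(entries, t(entries)))
    stop("interaction matrix must be symmetric")
  dimnames(entries) <- NULL
  structure(list(entries = entries, n_colors = nrow(entries)),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat(sprintf("interaction matrix over %d colors (trace %d)\n",
              x$n_colors, sum(diag(x$entries))))
  print(x$entries)
  invisible(x)
}

#' Multicomponent patchy-particle mixture
#'
#' All species share the diameter and the number of patches; they differ only
#' in the colors painted on the patches (and possibly in the body-frame patch
#' placement, though the azeotropy rules assume a common placement).
#'
#' @param species list of [species_spec()] objects.
#' @param composition mole-fraction vector (one entry per species, sums to 1).
#' @param kf a [kf_params()] object.
#' @param matrix an [interaction_matrix()].
#' @return an object of class `mixture_spec`.
#' @export
mixture_spec <- function(species, composition, kf = kf_params(),
                         matrix) {
  stopifnot(is.list(species), length(species) == length(composition))
  composition <- as.numeric(composition)
  if (any(composition < 0) || abs(sum(composition) - 1) > 1e-12)
    stop("composition entries must be >= 0 and sum to 1")
  n_p <- vapply(species, function(s) nrow(s$patch_vectors), integer(1))
  if (length(unique(n_p)) != 1)
    stop("all species must carry the same number of patches")
  for (s in species) {
    if (any(s$patch_colors < 1L | s$patch_colors > matrix$n_colors))
      stop("patch colors must be valid indices into the interaction matrix")
  }
  structure(list(species = species, composition = composition,
                 kf = kf, matrix = matrix,
                 n_species = length(species), n_patches = n_p[[1]]),
            class = "mixture_spec")
}

#' @export
print.mixture_spec <- function(x, ...) {
  cat(sprintf("patchy mixture: %d species, %d patches each, %d colors\n",
              x$n_species, x$n_patches, x$matrix$n_colors))
  cat("composition:", paste(signif(x$composition, 6), collapse = ", "), "\n")
  print(x$kf)
  invisible(x)
}

#' Tetrahedral patch directions
#'
#' The four unit vectors (1,1,1), (1,-1,-1), (-1,1,-1), (-1,-1,1)
#' normalised by sqrt(3): the standard patch placement for
#' diamond-forming patchy particles.
#'
#' @return a 4 x 3 matrix of unit vectors.
#' @export
tetrahedral_vectors <- function() {
  v <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  v / sqrt(3)
}

#' The N2c8s2 cubic-diamond binary mixture
#'
#' The minimal two-species design that assembles cubic (and only cubic)
#' diamond: two species with four tetrahedral patches each, eight patch
#' colors in total, and an 8x8 interaction matrix with exactly one 1 per row
#' (bond exclusivity) and two self-interacting colors (trace 2).  Colors 1
#' and 2 (species 1) are self-complementary, colors 5 and 6 (species 2) are
#' mutually complementary, and the cross pairs (3,7) and (4,8) tie the two
#' species together.  Pure species therefore carry only two bondable patches
#' and aggregate into chains, while the equimolar mixture is fully tetravalent.
#'
#' @param composition mole fractions of the two species (default equimolar).
#' @param kf Kern-Frenkel parameters; defaults to the design's working point
#'   `delta = 0.2`, `cos_theta_max = 0.98`.
#' @return a [mixture_spec()] for the binary design.
#' @export
build_n2c8s2 <- function(composition = c(0.5, 0.5), kf = kf_params()) {
  ents <- matrix(0L, 8, 8)
  pairs <- rbind(c(1, 1), c(2, 2), c(5, 6), c(3, 7), c(4, 8))
  for (k in seq_len(nrow(pairs))) {
    ents[pairs[k, 1], pairs[k, 2]] <- 1L
    ents[pairs[k, 2], pairs[k, 1]] <- 1L
  }
  tet <- tetrahedral_vectors()
  sp1 <- species_spec(tet, 1:4)
  sp2 <- species_spec(tet, 5:8)
  mixture_spec(list(sp1, sp2), composition, kf, interaction_matrix(ents))
}

# ---------------------------------------------------------------------------
# Quaternions
# ---------------------------------------------------------------------------

#' Rotate body-frame vectors by a unit quaternion
#'
#' @param q unit quaternion `c(w, x, y, z)`.
#' @param v numeric matrix (n x 3) of body-frame vectors.
#' @return rotated vectors (n x 3).
#' @export
quat_rotate <- function(q, v) {
  v <- rbind(v)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    3, 3, byrow = TRUE)
  v %*% t(R)
}

#' Quaternion from a rotation matrix
#' @param R 3x3 proper rotation matrix.
#' @return unit quaternion `c(w, x, y, z)`.
#' @export
quat_from_matrix <- function(R) {
  tr <- R[1, 1] + R[2, 2] + R[3, 3]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(c(R[1, 1], R[2, 2], R[3, 3]))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, s / 4, (R[1, 2] + R[2, 1]) / s,
             (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s, s / 4,
             (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, s / 4)
    }
  }
  q / sqrt(sum(q^2))
}

#' Random unit quaternion
#' @param n number of quaternions.
#' @return n x 4 matrix of unit quaternions (uniform on SO(3)).
#' @export
random_quaternion <- function(n = 1) {
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n)
  cbind(sqrt(1 - u1) * sin(2 * pi * u2),
        sqrt(1 - u1) * cos(2 * pi * u2),
        sqrt(u1) * sin(2 * pi * u3),
        sqrt(u1) * cos(2 * pi * u3))
}

# ---------------------------------------------------------------------------
# Pair energy (reference R implementation; the MC engine has its own in C++)
# ---------------------------------------------------------------------------

#' Kern-Frenkel pair energy between two posed particles
#'
#' Applies the minimum-image convention in a cubic box.  A bond requires the
#' centre distance in `[sigma, sigma + delta]`, a color-compatible patch
#' pair, and mutual alignment: both patch vectors within `theta_max` of the
#' centre-to-centre line.  If several patch pairs satisfy the criterion, only
#' the one with the largest alignment sum counts (single bond per pair).
#'
#' @param p1,p2 lists with elements `pos` (length-3 position) and `quat`
#'   (unit quaternion).
#' @param s1,s2 [species_spec()] objects for the two particles.
#' @param kf [kf_params()].
#' @param matrix [interaction_matrix()].
#' @param box cubic box edge length (use `Inf` for an open system).
#' @return list with `energy` (`Inf` for hard-core overlap, `-epsilon` for a
#'   bond, else 0) and `bond` (`c(patch1, patch2)` or `NULL`).
#' @export
pair_energy <- function(p1, p2, s1, s2, kf, matrix, box = Inf) {
  for (p in list(p1, p2))
    if (abs(sum(p$quat^2) - 1) > 1e-9)
      stop("orientation quaternions must have unit norm")
  if (is.finite(box) && box < 2 * (kf$sigma + kf$delta))
    stop("box smaller than 2*(sigma + delta): minimum image is ambiguous")
  dr <- p2$pos - p1$pos
  if (is.finite(box)) dr <- dr - box * round(dr / box)
  r <- sqrt(sum(dr^2))
  if (r < kf$sigma) return(list(energy = Inf, bond = NULL))
  if (r > kf$sigma + kf$delta) return(list(energy = 0, bond = NULL))
  rhat <- dr / r
  v1 <- quat_rotate(p1$quat, s1$patch_vectors)
  v2 <- quat_rotate(p2$quat, s2$patch_vectors)
  c1 <- drop(v1 %*% rhat)     # patch on 1 toward 2
  c2 <- drop(v2 %*% -rhat)    # patch on 2 toward 1
  best <- NULL; best_score <- -Inf
  for (a in seq_along(c1)) {
    if (c1[a] < kf$cos_theta_max) next
    for (g in seq_along(c2)) {
      if (c2[g] < kf$cos_theta_max) next
      if (matrix$entries[s1$patch_colors[a], s2$patch_colors[g]] == 0L) next
      sc <- c1[a] + c2[g]
      if (sc > best_score) { best_score <- sc; best <- c(a, g) }
    }
  }
  if (is.null(best)) list(energy = 0, bond = NULL)
  else list(energy = -kf$epsilon, bond = best)
}

# ---------------------------------------------------------------------------
# Bonding volume
# ---------------------------------------------------------------------------

#' Kern-Frenkel bonding volume
#'
#' Phase-space volume (position x normalised orientation measure) over which
#' two particles with one compatible patch pair remain bonded:
#' \deqn{V_b = \frac{\pi}{3}\left[(\sigma+\delta)^3-\sigma^3\right]
#'       (1-\cos\theta_{max})^2}
#' i.e. the spherical-shell volume times the squared patch-cone fraction
#' `(1 - cos_theta_max)/2` for each particle.
#'
#' @param kf [kf_params()].
#' @return bonding volume in units of `sigma^3`.
#' @export
bonding_volume <- function(kf) {
  shell <- (4 * pi / 3) * ((kf$sigma + kf$delta)^3 - kf$sigma^3)
  p <- (1 - kf$cos_theta_max) / 2
  shell * p^2
}

# ---------------------------------------------------------------------------
# I/O: interaction matrices (CSV / JSON) and mixtures (YAML / JSON)
# ---------------------------------------------------------------------------

#' Read or write an interaction matrix
#'
#' CSV files are square 0/1 tables with a color-index header; JSON files hold
#' the matrix as an array of rows.
#'
#' @param path file path (`.csv` or `.json`).
#' @return an [interaction_matrix()].
#' @export
read_interaction_matrix <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::fromJSON(path)
    if (is.list(m) && !is.null(m$entries)) m <- m$entries
    interaction_matrix(do.call(rbind, lapply(seq_len(nrow(m)),
                                             function(i) m[i, ])))
  } else {
    m <- as.matrix(read.csv(path, row.names = 1, check.names = FALSE))
    interaction_matrix(m)
  }
}

#' @rdname read_interaction_matrix
#' @param matrix an [interaction_matrix()] to write.
#' @export
write_interaction_matrix <- function(matrix, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(n_colors = matrix$n_colors,
                              entries = matrix$entries),
                         path, auto_unbox = TRUE)
  } else {
    m <- matrix$entries
    dimnames(m) <- list(seq_len(nrow(m)), seq_len(ncol(m)))
    write.csv(m, path)
  }
  invisible(path)
}

#' Read or write a mixture specification
#'
#' The config is a YAML or JSON document with keys `composition`, `kf`
#' (epsilon/delta/cos_theta_max/sigma), `matrix` (array of 0/1 rows) and
#' `species` (list of blocks with `patch_vectors` and `patch_colors`).
#' Unknown keys are an error.
#'
#' @param path file path (`.yaml`, `.yml` or `.json`).
#' @return a [mixture_spec()].
#' @export
read_mixture <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  else yaml::read_yaml(path)
  known <- c("composition", "kf", "matrix", "species")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config keys: ", paste(extra, collapse = ", "))
  kf <- do.call(kf_params, as.list(cfg$kf))
  ents <- cfg$matrix
  if (is.list(ents)) ents <- do.call(rbind, ents)
  mat <- interaction_matrix(ents)
  species <- lapply(cfg$species, function(s) {
    pv <- s$patch_vectors
    if (is.list(pv)) pv <- do.call(rbind, pv)
    species_spec(pv, s$patch_colors)
  })
  mixture_spec(species, cfg$composition, kf, mat)
}

#' @rdname read_mixture
#' @param mixture a [mixture_spec()] to write.
#' @export
write_mixture <- function(mixture, path) {
  cfg <- list(
    composition = mixture$composition,
    kf = mixture$kf[c("epsilon", "delta", "cos_theta_max", "sigma")],
    matrix = lapply(seq_len(mixture$matrix$n_colors),
                    function(i) mixture$matrix$entries[i, ]),
    species = lapply(mixture$species, function(s) list(
      patch_vectors = lapply(seq_len(nrow(s$patch_vectors)),
                             function(i) s$patch_vectors[i, ]),
      patch_colors = s$patch_colors)))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, path, precision = 15)
  invisible(path)
}
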