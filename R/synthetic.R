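#' Synthetic capsid and interface fixtures
#'
#' Seeded generators that build inputs with known ground truth: an exactly
#' icosahedral shell capsid from a single asymmetric unit, two-body
#' interface fixtures with closed-form buried areas, and pseudo-random
#' polyprotein sequences. Every fixture ships the analytic values the
#' geometry/SASA operations are expected to recover, so the full pipeline is
#' testable without downloading any deposited structure.
#'
#' @name synthetic-fixtures
NULL

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# generic reference direction defining the canonical asymmetric wedge:
# a point's canonical image is the group image with maximal dot product
.wedge_ref <- function() {
  v <- c(0.2173, 0.4591, 0.8614)
  v / sqrt(sum(v^2))
}

.canonicalize <- function(xyz, ops) {
  # (R x) . v0 = x . (R^T v0): one matrix product scores all images at once
  v0 <- .wedge_ref()
  M <- vapply(ops$rotations, function(R) as.numeric(t(R) %*% v0), numeric(3))
  best <- max.col(xyz %*% M, ties.method = "first")
  out <- xyz
  for (k in unique(best)) {
    i <- best == k
    out[i, ] <- xyz[i, , drop = FALSE] %*% t(ops$rotations[[k]])
  }
  out
}

.in_wedge <- function(xyz, ops) {
  v0 <- .wedge_ref()
  M <- vapply(ops$rotations, function(R) as.numeric(t(R) %*% v0), numeric(3))
  S <- xyz %*% M
  S[, 1] >= apply(S, 1, max) - 1e-12
}

#' Build a seeded synthetic shell capsid with known radii
#'
#' Places carbon atoms inside one icosahedral asymmetric wedge at radii
#' uniform in `[inner_radius, outer_radius]`, so that expansion by the
#' 60-element group yields an exactly symmetric shell whose true inner/outer
#' radial extent is known by construction. Placement is rejection-sampled so
#' no atom sits closer than `min_image_spacing` to any of its own symmetry
#' images (no clashes or duplicates on wedge boundaries).
#'
#' With `surface_coverage` set, atoms are instead laid on concentric
#' near-uniform spherical layers (spiral point sets thinned to the wedge)
#' with roughly that nearest-neighbour spacing in Angstrom — the dense,
#' watertight variant needed for voxel flood-fill tests; `atoms_per_au` is
#' then derived from the coverage and ignored.
#'
#' @param inner_radius,outer_radius shell extent, Angstrom (0 < inner < outer).
#' @param atoms_per_au atoms in the asymmetric unit (random mode).
#' @param n_chains_per_au number of chains the AU atoms are split into
#'   (contiguous blocks named A, B, C, ...; default 3, mirroring a capsid AU
#'   of three subunits).
#' @param seed integer seed; same seed, same coordinates.
#' @param surface_coverage target point spacing in Angstrom (dense mode), or
#'   NULL (default) for random placement.
#' @param min_image_spacing minimum distance to own symmetry images, Angstrom.
#' @return list: `au` ([structure_model]), `ops` (`symmetry_operators`),
#'   `truth` (list with `inner_radius`, `outer_radius`, `n_atoms_au`,
#'   `n_atoms_expanded`, `watertight`).
#' @export
make_shell_capsid <- function(inner_radius, outer_radius, atoms_per_au = 500,
                              n_chains_per_au = 3, seed = 1,
                              surface_coverage = NULL, min_image_spacing = 1.0) {
  stopifnot(inner_radius > 0, outer_radius > inner_radius,
            atoms_per_au >= n_chains_per_au)
  ops <- icosahedral_operators()
  xyz <- .with_seed(seed, {
    if (is.null(surface_coverage)) {
      pts <- matrix(NA_real_, atoms_per_au, 3)
      got <- 0
      while (got < atoms_per_au) {
        m <- (atoms_per_au - got) * 2 + 8
        d <- matrix(stats::rnorm(3 * m), m, 3)
        d <- d / sqrt(rowSums(d^2))
        d <- .canonicalize(d, ops)
        r <- stats::runif(m, inner_radius, outer_radius)
        cand <- d * r
        d2min <- Reduce(pmin, lapply(ops$rotations[-1], function(R)
          rowSums((cand %*% t(R) - cand)^2)))
        ok <- which(d2min >= min_image_spacing^2)
        take <- utils::head(ok, atoms_per_au - got)
        pts[got + seq_along(take), ] <- cand[take, ]
        got <- got + length(take)
      }
      pts
    } else {
      s <- surface_coverage
      radii <- seq(inner_radius, outer_radius, by = s)
      blocks <- lapply(radii, function(r) {
        n <- max(60, round(4 * pi * r^2 / s^2))
        p <- sphere_points(n) * r
        # keep points already canonical (inside the fundamental wedge)
        p[.in_wedge(p, ops), , drop = FALSE]
      })
      do.call(rbind, blocks)
    }
  })
  n <- nrow(xyz)
  chain_sizes <- diff(round(seq(0, n, length.out = n_chains_per_au + 1)))
  chains <- rep(LETTERS[seq_len(n_chains_per_au)], times = chain_sizes)
  res_seq <- unlist(lapply(chain_sizes, seq_len), use.names = FALSE)
  au <- structure_model(data.frame(
    serial = seq_len(n), name = "CA", element = "C", res_name = "GLY",
    res_seq = res_seq, chain_id = chains,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = 1, b_factor = 0, stringsAsFactors = FALSE))
  # crude watertightness guess: mean spacing on the inner layer vs 2 A disks
  spacing <- if (is.null(surface_coverage))
    sqrt(4 * pi * inner_radius^2 / (60 * n)) else surface_coverage
  list(au = au, ops = ops,
       truth = list(inner_radius = inner_radius, outer_radius = outer_radius,
                    n_atoms_au = n, n_atoms_expanded = 60L * n,
                    watertight = spacing <= 4))
}

#' Two-body interface fixtures with closed-form buried area
#'
#' `"two_spheres"`: two atoms of radii `r_a`, `r_b` at centre distance `d`.
#' The expected buried area follows the spherical-cap formula on the
#' probe-inflated spheres (R = r + probe): each sphere loses a cap of height
#' h = R - (d^2 + R^2 - R'^2) / (2d), and the buried area
#' (2 pi R_a h_a + 2 pi R_b h_b) / 2 = pi (R_a h_a + R_b h_b); zero when
#' d >= (r_a + probe) + (r_b + probe).
#'
#' `"two_slabs"`: two square carbon monolayers stacked along z, the smaller
#' (side `side_b`) fully overhung by the larger so its whole face is buried.
#' The analytic expected area is the planar closed form for ideal continuum
#' slabs under the accessible-surface definition: the face `side_b^2` plus a
#' probe-scale rim on the upper slab (arc of the edge half-cylinders that
#' falls inside the lower slab's inflated surface) and a lateral burial
#' margin on the lower one. The bare face area alone underestimates the
#' buried area by the rim terms, which vanish only for slabs much larger
#' than the probe; `face_area` is returned alongside for reference.
#'
#' @param kind `"two_spheres"` or `"two_slabs"`.
#' @param r_a,r_b sphere radii, Angstrom (two_spheres).
#' @param d centre distance, Angstrom (two_spheres; must exceed `|r_a - r_b|`).
#' @param probe probe radius used in the closed form (default 1.4).
#' @param side_a,side_b slab side lengths, Angstrom (two_slabs).
#' @param spacing slab lattice spacing, Angstrom (two_slabs).
#' @return list: `set_a`, `set_b` (atom data.frames), `expected_bsa`
#'   (Angstrom^2), `radii_table`, `probe`.
#' @export
make_interface_fixture <- function(kind = c("two_spheres", "two_slabs"),
                                   r_a = 1.7, r_b = 1.7, d = 3.0, probe = 1.4,
                                   side_a = 44, side_b = 30, spacing = 1.0) {
  kind <- match.arg(kind)
  if (kind == "two_spheres") {
    if (d <= abs(r_a - r_b)) stop("one sphere engulfs the other; need d > |r_a - r_b|")
    Ra <- r_a + probe; Rb <- r_b + probe
    expected <- if (d >= Ra + Rb) 0 else {
      ha <- Ra - (d^2 + Ra^2 - Rb^2) / (2 * d)
      hb <- Rb - (d^2 + Rb^2 - Ra^2) / (2 * d)
      pi * (Ra * ha + Rb * hb)
    }
    atom <- function(el, x) data.frame(
      serial = 1L, name = "X1", element = el, res_name = "UNK", res_seq = 1L,
      chain_id = el, x = x, y = 0, z = 0, occupancy = 1, b_factor = 0,
      stringsAsFactors = FALSE)
    list(set_a = atom("A", 0), set_b = atom("B", d),
         expected_bsa = expected,
         radii_table = c(A = r_a, B = r_b), probe = probe)
  } else {
    if (side_a < side_b + 4 * (1.7 + probe))
      stop("slab A must overhang slab B by at least 2 (r + probe) per side")
    grid <- function(side, z, chain) {
      u <- seq(-side / 2, side / 2, by = spacing)
      g <- expand.grid(x = u, y = u)
      data.frame(serial = seq_len(nrow(g)), name = "X1", element = "C",
                 res_name = "UNK", res_seq = seq_len(nrow(g)), chain_id = chain,
                 x = g$x, y = g$y, z = z, occupancy = 1, b_factor = 0,
                 stringsAsFactors = FALSE)
    }
    r_c <- 1.7
    h <- 2 * r_c                       # van der Waals contact of atom planes
    R <- r_c + probe
    m <- sqrt(R^2 - (h - R)^2)         # lateral burial margin on the lower slab
    th0 <- asin((h - R) / R)           # where the upper-slab edge rim starts burying
    a_loss <- side_b^2 + 4 * side_b * m + pi * m^2
    b_loss <- side_b^2 + 4 * side_b * R * (pi / 2 - th0) + 2 * pi * R * (2 * R - h)
    list(set_a = grid(side_a, 0, "A"),
         set_b = grid(side_b, h, "B"),
         expected_bsa = (a_loss + b_loss) / 2,
         face_area = side_b^2,
         radii_table = c(C = r_c), probe = probe)
  }
}

#' Seeded pseudo-random polyprotein sequence
#'
#' @param length residue count (>= 1).
#' @param seed integer seed.
#' @return residue string over the 20-letter alphabet.
#' @export
make_polyprotein <- function(length, seed = 1) {
  stopifnot(length >= 1)
  aa <- setdiff(names(residue_masses()), "X")
  .with_seed(seed, paste(sample(aa, length, replace = TRUE), collapse = ""))
}
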