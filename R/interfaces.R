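#' Standard van der Waals radii for protein heavy atoms
#'
#' A single published protein radii set (Bondi-style values commonly used in
#' accessibility calculations): C 1.70, N 1.55, O 1.52, S 1.80, P 1.80,
#' H 1.20 Angstrom. Overridable wherever a `radii_table` argument appears;
#' absolute buried-area numbers are convention-dependent and should only be
#' compared across structures computed with one table.
#'
#' @return named numeric vector, Angstrom.
#' @export
default_vdw_radii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20)
}

#' Deterministic near-uniform unit-sphere point set (generalised spiral)
#'
#' Fibonacci-lattice points on the unit sphere. Deterministic, so SASA is
#' bit-reproducible for a fixed `n`.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  th <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(th), r * sin(th), z)
}

.atom_radii <- function(elements, radii_table) {
  r <- radii_table[elements]
  if (anyNA(r)) {
    bad <- sort(unique(elements[is.na(r)]))
    stop("no van der Waals radius for element(s): ", paste(bad, collapse = ", "))
  }
  unname(r)
}

.as_xyz <- function(atoms) {
  if (inherits(atoms, "structure_model")) atoms <- atoms$atoms
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

.as_atoms <- function(atoms) {
  if (inherits(atoms, "structure_model")) atoms$atoms else atoms
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Native implementation: each atom's sphere of radius (vdW + probe) is
#' sampled with a deterministic spiral point set; points falling inside any
#' neighbour's probe-inflated sphere are occluded; the accessible fraction
#' times the sphere area is the atom's SASA. No randomness: fixed `n_points`
#' gives bit-identical results.
#'
#' @param atoms atom data.frame (or [structure_model]).
#' @param probe probe radius, Angstrom (default 1.4, a water molecule).
#' @param n_points sphere sample points per atom (default 960).
#' @param radii_table named element -> radius vector (default
#'   [default_vdw_radii]).
#' @return An object of class `sasa_result`: list with `per_atom_area`
#'   (Angstrom^2 per atom, in input order), `total`, `probe_radius`,
#'   `n_sphere_points`.
#' @export
shrake_rupley_sasa <- function(atoms, probe = 1.4, n_points = 960,
                               radii_table = default_vdw_radii()) {
  a <- .as_atoms(atoms)
  if (nrow(a) == 0) stop("need at least one atom")
  radii <- .atom_radii(a$element, radii_table)
  per <- .cpp_sasa(.as_xyz(a), radii, probe, sphere_points(n_points))
  structure(list(per_atom_area = per, total = sum(per),
                 probe_radius = probe, n_sphere_points = n_points),
            class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("sasa_result: %d atoms, total %.1f A^2 (probe %.1f A, %d points)\n",
              length(x$per_atom_area), x$total, x$probe_radius, x$n_sphere_points))
  invisible(x)
}

#' Buried surface area between two atom sets
#'
#' BSA = (SASA(A) + SASA(B) - SASA(A union B)) / 2 — the mean accessible
#' area each partner loses on association. Symmetric in its arguments and
#' non-negative up to quadrature noise.
#'
#' @param set_a,set_b disjoint atom data.frames (or [structure_model]s).
#' @param probe,n_points,radii_table passed to [shrake_rupley_sasa].
#' @return buried area in Angstrom^2.
#' @export
buried_surface_area <- function(set_a, set_b, probe = 1.4, n_points = 960,
                                radii_table = default_vdw_radii()) {
  a <- .as_atoms(set_a); b <- .as_atoms(set_b)
  if (nrow(a) == 0 || nrow(b) == 0) stop("both atom sets must be non-empty")
  key <- function(d) paste(d$chain_id, d$res_seq, d$name, round(d$x, 3),
                           round(d$y, 3), round(d$z, 3))
  if (length(intersect(key(a), key(b))) > 0)
    stop("atom sets overlap; buried area requires disjoint sets")
  sa <- shrake_rupley_sasa(a, probe, n_points, radii_table)$total
  sb <- shrake_rupley_sasa(b, probe, n_points, radii_table)$total
  sab <- shrake_rupley_sasa(rbind(a[, names(a)], b[, names(a)]),
                            probe, n_points, radii_table)$total
  (sa + sb - sab) / 2
}

#' Total buried surface area of an asymmetric unit within the capsid
#'
#' Expands the AU, finds every symmetry copy in contact with copy 0, and
#' sums the buried area of each unique AU-copy interface (each interface
#' counted once). `mode = "per_asym_unit_neighbors"` reports that sum — the
#' area one AU buries against all its neighbours, each shared interface
#' counted at half weight via the BSA definition. `mode = "total"` scales to
#' the whole particle: sum x 60 / 2 (each interface is shared by two AUs).
#'
#' @param au asymmetric-unit [structure_model].
#' @param ops `symmetry_operators`.
#' @param mode `"per_asym_unit_neighbors"` or `"total"`.
#' @param contact_cutoff neighbour detection cutoff, Angstrom (default 5).
#' @param probe,n_points,radii_table SASA parameters.
#' @return list: `area` (10^3 nm^2), `mode`, `n_interfaces`,
#'   `neighbor_copies` (operator indices in contact).
#' @export
capsid_buried_area <- function(au, ops, mode = c("per_asym_unit_neighbors", "total"),
                               contact_cutoff = 5, probe = 1.4, n_points = 960,
                               radii_table = default_vdw_radii()) {
  mode <- match.arg(mode)
  xyz0 <- coords(au)
  neighbors <- integer()
  for (k in seq_along(ops$rotations)[-1]) {
    xyzk <- xyz0 %*% t(ops$rotations[[k]])
    hits <- .cpp_pairs_within(xyz0, xyzk, contact_cutoff)
    if (nrow(hits) > 0) neighbors <- c(neighbors, k - 1L)
  }
  total <- 0
  for (k in neighbors) {
    ak <- au$atoms
    p <- xyz0 %*% t(ops$rotations[[k + 1]])
    ak$x <- p[, 1]; ak$y <- p[, 2]; ak$z <- p[, 3]
    ak$chain_id <- paste0(ak$chain_id, "_", k)
    total <- total + buried_surface_area(au$atoms, ak, probe, n_points, radii_table)
  }
  if (mode == "total") total <- total * 60 / 2
  list(area = total / 1e5,  # A^2 -> 10^3 nm^2
       mode = mode, n_interfaces = length(neighbors),
       neighbor_copies = neighbors)
}

#' Residue-level contact network between two atom selections
#'
#' Every residue pair with any inter-atomic distance at or below the cutoff,
#' with the per-pair minimum distance and the number of atom pairs within
#' the cutoff. Cell-list spatial indexing keeps expanded capsids (10^5-10^6
#' atoms) tractable.
#'
#' @param group_a,group_b atom data.frames (e.g. from [select_atoms]).
#' @param cutoff heavy-atom distance cutoff, Angstrom (default 4.0).
#' @return data.frame of contact edges: `chain_a`, `res_seq_a`, `res_name_a`,
#'   `chain_b`, `res_seq_b`, `res_name_b`, `min_distance`, `n_atom_pairs`.
#'   Self-pairs (identical chain and residue) are excluded.
#' @export
contact_network <- function(group_a, group_b, cutoff = 4.0) {
  a <- .as_atoms(group_a); b <- .as_atoms(group_b)
  empty <- data.frame(chain_a = character(), res_seq_a = integer(),
                      res_name_a = character(), chain_b = character(),
                      res_seq_b = integer(), res_name_b = character(),
                      min_distance = numeric(), n_atom_pairs = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(a) == 0 || nrow(b) == 0 || cutoff <= 0) return(empty)
  hits <- .cpp_pairs_within(.as_xyz(a), .as_xyz(b), cutoff)
  if (nrow(hits) == 0) return(empty)
  i <- hits[, 1]; j <- hits[, 2]
  same <- a$chain_id[i] == b$chain_id[j] & a$res_seq[i] == b$res_seq[j]
  hits <- hits[!same, , drop = FALSE]
  if (nrow(hits) == 0) return(empty)
  i <- hits[, 1]; j <- hits[, 2]
  key <- paste(a$chain_id[i], a$res_seq[i], b$chain_id[j], b$res_seq[j], sep = "\r")
  agg_min <- tapply(hits[, 3], key, min)
  agg_n <- tapply(hits[, 3], key, length)
  first <- !duplicated(key)
  ord <- key[first]
  out <- data.frame(
    chain_a = a$chain_id[i][first], res_seq_a = a$res_seq[i][first],
    res_name_a = a$res_name[i][first],
    chain_b = b$chain_id[j][first], res_seq_b = b$res_seq[j][first],
    res_name_b = b$res_name[j][first],
    min_distance = as.numeric(agg_min[ord]),
    n_atom_pairs = as.integer(agg_n[ord]),
    stringsAsFactors = FALSE)
  out <- out[order(out$chain_a, out$res_seq_a, out$chain_b, out$res_seq_b), ]
  rownames(out) <- NULL
  out
}

#' Which chains populate the neighbourhood of each symmetry-axis class
#'
#' For every two-, three- and five-fold axis, atoms of the expanded capsid
#' within a cylindrical shell around the axis are attributed to their source
#' chain (operator suffix stripped), and chains are ranked by atom count per
#' axis class. This reproduces statements of the form "the five-fold
#' vertices are composed of chain X".
#'
#' @param au asymmetric-unit [structure_model].
#' @param ops `symmetry_operators`.
#' @param radius_shell cylinder radius around each axis, Angstrom.
#' @return data.frame: `axis_order`, `chain`, `n_atoms`, ranked within class.
#' @export
axis_neighborhood_report <- function(au, ops, radius_shell = 10) {
  expanded <- expand_capsid(au, ops)
  axes <- find_axes(ops)
  xyz <- coords(expanded)
  base_chain <- sub("_[0-9]+$", "", expanded$atoms$chain_id)
  rows <- list()
  for (ord in c(2L, 3L, 5L)) {
    sub <- axes[axes$order == ord, , drop = FALSE]
    near <- rep(FALSE, nrow(xyz))
    for (r in seq_len(nrow(sub))) {
      d <- c(sub$dx[r], sub$dy[r], sub$dz[r])
      proj <- xyz %*% d
      # perpendicular distance to the axis line; only the outward half-axis
      perp2 <- rowSums(xyz^2) - proj^2
      near <- near | (perp2 <= radius_shell^2 & proj > 0)
    }
    if (!any(near)) next
    tab <- sort(table(base_chain[near]), decreasing = TRUE)
    rows[[length(rows) + 1]] <- data.frame(
      axis_order = ord, chain = names(tab), n_atoms = as.integer(tab),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(axis_order = integer(), chain = character(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
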