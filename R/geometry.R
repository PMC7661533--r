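#' Radial atom-density profile of a capsid
#'
#' Histogram of atom distances from the capsid centre, the raw measurement
#' behind inner/outer diameter estimates.
#'
#' @param capsid a [structure_model] (normally the 60-fold expanded particle;
#'   pass `allow_au = TRUE` to profile a lone asymmetric unit).
#' @param center 3-vector, Angstrom; default the origin.
#' @param bin_width bin width in Angstrom (> 0).
#' @param allow_au do not warn when the model looks like a single AU.
#' @return An object of class `radial_profile`: list with `bin_edges`,
#'   `counts`, `r_min`, `r_max`, `radii`.
#' @export
radial_profile <- function(capsid, center = c(0, 0, 0), bin_width = 1,
                           allow_au = FALSE) {
  if (bin_width <= 0) stop("bin_width must be positive")
  if (n_atoms(capsid) == 0) stop("empty model")
  if (!allow_au && is.null(capsid$atoms$copy) && n_atoms(capsid) < 1000)
    warning("model does not look symmetry-expanded; pass allow_au = TRUE to silence")
  xyz <- sweep(coords(capsid), 2, center)
  r <- sqrt(rowSums(xyz^2))
  edges <- seq(0, max(r) + bin_width, by = bin_width)
  counts <- tabulate(findInterval(r, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  structure(list(bin_edges = edges, counts = counts,
                 r_min = min(r), r_max = max(r), radii = r),
            class = "radial_profile")
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("radial_profile: %d atoms, r in [%.2f, %.2f] A\n",
              sum(x$counts), x$r_min, x$r_max))
  invisible(x)
}

#' Inner and outer shell radius from a radial profile
#'
#' The inner (outer) radius is a low (high) percentile of the radial atom
#' distances rather than the extreme value, so a few inward-hanging termini
#' do not drag the estimate. Defaults 0.5 / 99.5; percentiles 0 and 100 give
#' the exact minimum and maximum.
#'
#' @param profile a [radial_profile].
#' @param inner_pct,outer_pct percentiles in \[0, 100\], inner < outer.
#' @return list with `inner`, `outer`, `thickness` (all Angstrom) and the
#'   percentiles used.
#' @export
inner_outer_radius <- function(profile, inner_pct = 0.5, outer_pct = 99.5) {
  if (sum(profile$counts) == 0) stop("empty profile")
  if (!(inner_pct >= 0 && inner_pct < outer_pct && outer_pct <= 100))
    stop("need 0 <= inner_pct < outer_pct <= 100")
  q <- stats::quantile(profile$radii, c(inner_pct, outer_pct) / 100,
                       names = FALSE, type = 7)
  list(inner = q[1], outer = q[2], thickness = q[2] - q[1],
       inner_pct = inner_pct, outer_pct = outer_pct)
}

#' Inner capsid volume under the sphere model
#'
#' The cavity is modelled as the sphere of the measured inner diameter:
#' V = (pi/6) d^3. With d in nm the result is reported in 10^3 nm^3 — the
#' convention under which published capsid-size tables tabulate inner
#' volumes.
#'
#' @param inner_diameter_nm inner diameter in nm (>= 0).
#' @return volume in 10^3 nm^3 (unrounded).
#' @export
sphere_inner_volume <- function(inner_diameter_nm) {
  if (any(inner_diameter_nm < 0)) stop("inner diameter must be non-negative")
  (pi / 6) * inner_diameter_nm^3 / 1000
}

#' Packaging density: capsid volume per genome nucleotide
#'
#' Divides the inner volume by the poly-A-adjusted genome length. Genome
#' lengths are supplied raw (nt); a poly-A allowance (default 200 nt) is
#' added here, not pre-baked into the input.
#'
#' @param inner_volume_1e3nm3 inner volume, 10^3 nm^3.
#' @param genome_nt raw genome length in nucleotides (> 0).
#' @param polya_nt poly-A tail allowance, nt (default 200).
#' @return nm^3 per nucleotide (unrounded).
#' @export
volume_per_nucleotide <- function(inner_volume_1e3nm3, genome_nt, polya_nt = 200) {
  if (any(genome_nt <= 0)) stop("genome length must be positive")
  inner_volume_1e3nm3 * 1000 / (genome_nt + polya_nt)
}

#' Voxel flood-fill cavity volume
#'
#' Independent cross-check of the sphere model. Space is discretised on a
#' cubic grid; voxels within `atom_radius` of any atom are solid; the void
#' component containing the capsid centre is flood-filled (6-connected) and
#' then dilated by `atom_radius`, so the cavity is measured out to the atom
#' centres of the innermost shell layer (matching how an inner diameter read
#' off atom positions defines the cavity). If the fill escapes the particle
#' (a leaky shell) the result is flagged and should not be trusted.
#'
#' @param capsid expanded [structure_model].
#' @param voxel grid spacing in Angstrom, in \[0.5, 4\].
#' @param atom_radius effective atom radius for solidity, Angstrom.
#' @param center cavity seed point (default origin).
#' @return list: `volume` (10^3 nm^3), `leaked` (logical), `no_cavity`
#'   (logical: seed voxel solid).
#' @export
voxel_cavity_volume <- function(capsid, voxel = 2, atom_radius = 3,
                                center = c(0, 0, 0)) {
  if (voxel < 0.5 || voxel > 4) stop("voxel size must be in [0.5, 4] Angstrom")
  xyz <- coords(capsid)
  pad <- atom_radius + 2 * voxel
  lo <- apply(xyz, 2, min) - pad
  hi <- apply(xyz, 2, max) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel)) + 1L
  res <- .cpp_cavity_fill(xyz, atom_radius, voxel, lo, dims, center)
  vol_a3 <- res[1] * voxel^3                      # Angstrom^3
  list(volume = vol_a3 / 1e3 / 1e3,               # A^3 -> nm^3 -> 10^3 nm^3
       leaked = res[2] > 0, no_cavity = res[3] > 0)
}

#' One row of a capsid-size comparison report
#'
#' Runs the full shell-geometry pipeline on one structure: symmetry
#' expansion (unless already expanded), radial profile, percentile
#' inner/outer radii, sphere-model inner volume and volume per nucleotide.
#' Rounding follows the comparative-table convention — diameters and volumes
#' to 1 decimal, volume per nucleotide to 2, genome size to 0.1 kb —
#' with unrounded values kept alongside (`*_raw`).
#'
#' @param model asymmetric-unit or expanded [structure_model].
#' @param ops `symmetry_operators` (ignored when the model is already expanded).
#' @param genome_nt raw genome length, nt.
#' @param label report row label.
#' @param pdb_id optional accession tag.
#' @param t_number optional lattice tag, e.g. `"T=1 (pseudo T=3)"`.
#' @param inner_pct,outer_pct radial percentiles (see [inner_outer_radius]).
#' @param polya_nt poly-A allowance (default 200 nt).
#' @param bin_width radial profile bin, Angstrom.
#' @param buried_area optional buried-surface area (10^3 nm^2) to attach.
#' @param voxel_check also run [voxel_cavity_volume] and attach it.
#' @return An object of class `capsid_geometry_report` (a one-row list).
#' @export
build_geometry_report <- function(model, ops = NULL, genome_nt, label,
                                  pdb_id = "", t_number = "",
                                  inner_pct = 0.5, outer_pct = 99.5,
                                  polya_nt = 200, bin_width = 1,
                                  buried_area = NA_real_, voxel_check = FALSE) {
  expanded <- if (!is.null(model$atoms$copy)) model
              else if (!is.null(ops)) expand_capsid(model, ops)
              else stop("need symmetry operators or an already expanded model")
  cen <- colMeans(coords(expanded))
  if (sqrt(sum(cen^2)) > 1) {
    warning(sprintf("expanded-capsid centroid is %.2f A from the origin; %s",
                    sqrt(sum(cen^2)), "check the symmetry frame"))
  }
  prof <- radial_profile(expanded, center = c(0, 0, 0), bin_width = bin_width)
  rad <- inner_outer_radius(prof, inner_pct, outer_pct)
  inner_d_nm <- 2 * rad$inner / 10
  outer_d_nm <- 2 * rad$outer / 10
  vol <- sphere_inner_volume(inner_d_nm)
  vpn <- volume_per_nucleotide(vol, genome_nt, polya_nt)
  rep <- list(
    label = label, pdb_id = pdb_id, t_number = t_number,
    inner_diameter = round(inner_d_nm, 1), outer_diameter = round(outer_d_nm, 1),
    shell_thickness = round(outer_d_nm / 2 - inner_d_nm / 2, 1),
    inner_volume = round(vol, 1),
    genome_size = round((genome_nt + polya_nt) / 1000, 1),
    volume_per_nt = round(vpn, 2),
    buried_area = buried_area,
    inner_diameter_raw = inner_d_nm, outer_diameter_raw = outer_d_nm,
    inner_volume_raw = vol, volume_per_nt_raw = vpn,
    inner_pct = inner_pct, outer_pct = outer_pct, polya_nt = polya_nt)
  if (voxel_check)
    rep$voxel_volume <- voxel_cavity_volume(expanded)
  class(rep) <- "capsid_geometry_report"
  rep
}

#' @export
print.capsid_geometry_report <- function(x, ...) {
  cat(sprintf(
    "%s [%s] %s\n  inner d %.1f nm | outer d %.1f nm | inner V %.1f x10^3 nm^3\n  genome %.1f kb (+%d nt polyA) | V/nt %.2f nm^3\n",
    x$label, x$pdb_id, x$t_number, x$inner_diameter, x$outer_diameter,
    x$inner_volume, x$genome_size, x$polya_nt, x$volume_per_nt))
  invisible(x)
}

#' Coerce geometry reports to a data.frame in comparison-table column order
#' @param reports a list of `capsid_geometry_report` objects (or one).
#' @return data.frame, one row per report.
#' @export
geometry_report_table <- function(reports) {
  if (inherits(reports, "capsid_geometry_report")) reports <- list(reports)
  cols <- c("label", "pdb_id", "inner_diameter", "shell_thickness",
            "inner_volume", "genome_size", "volume_per_nt", "buried_area",
            "t_number")
  do.call(rbind, lapply(reports, function(r)
    as.data.frame(r[cols], stringsAsFactors = FALSE)))
}
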