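#' Average residue masses for the 20 standard amino acids
#'
#' Average (not monoisotopic) residue masses in Da, i.e. the mass each
#' residue contributes inside a chain; one water (18.01528 Da) is added per
#' chain. `X` carries the 20-residue average mass.
#'
#' @return named numeric vector, Da.
#' @export
residue_masses <- function() {
  c(A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326,
    X = 110.0)
}

#' Cleave a polyprotein at given positions
#'
#' "Cleaved at position s" means the peptide bond after residue s is cut, so
#' a site at 264 ends the first product at residue 264. The products tile
#' the polyprotein: lengths always sum to the input length.
#'
#' @param length_or_sequence total length (integer) or the residue string.
#' @param sites strictly ascending 1-based cut positions, each in
#'   `(0, length)`; empty for no cleavage.
#' @param names optional product names (length `length(sites) + 1`).
#' @return data.frame of cleavage products: `name`, `start`, `end`, `length`,
#'   and `sequence`, `approx_mass_kda` when a sequence was supplied.
#' @export
cleave_polyprotein <- function(length_or_sequence, sites = integer(), names = NULL) {
  seq_str <- NULL
  if (is.character(length_or_sequence)) {
    seq_str <- length_or_sequence
    len <- nchar(seq_str)
  } else {
    len <- as.integer(length_or_sequence)
  }
  if (len < 1) stop("polyprotein length must be >= 1")
  sites <- as.integer(sites)
  if (length(sites) > 0) {
    if (any(diff(sites) <= 0)) stop("cut sites must be strictly ascending")
    if (any(sites <= 0 | sites >= len))
      stop("cut sites must lie strictly inside (0, length)")
  }
  starts <- c(1L, sites + 1L)
  ends <- c(sites, len)
  if (is.null(names)) names <- paste0("product_", seq_along(starts))
  if (length(names) != length(starts))
    stop("need ", length(starts), " product names")
  out <- data.frame(name = names, start = starts, end = ends,
                    length = ends - starts + 1L, stringsAsFactors = FALSE)
  if (!is.null(seq_str)) {
    out$sequence <- substring(seq_str, starts, ends)
    out$approx_mass_kda <- vapply(out$sequence, approx_mass, numeric(1),
                                  USE.NAMES = FALSE)
  }
  out
}

#' Approximate average molecular mass of a peptide
#'
#' Sum of average residue masses plus one water, in kDa. Additive over
#' concatenation minus one water per junction.
#'
#' @param sequence residue string over the standard 20-letter alphabet
#'   (X allowed, average mass).
#' @return mass in kDa.
#' @export
approx_mass <- function(sequence) {
  water <- 18.01528
  if (nchar(sequence) == 0) return(water / 1000)
  aa <- strsplit(toupper(sequence), "")[[1]]
  m <- residue_masses()[aa]
  if (anyNA(m)) {
    bad <- which(is.na(m))[1]
    stop(sprintf("illegal residue '%s' at position %d", aa[bad], bad))
  }
  (sum(m) + water) / 1000
}

#' Read sequences from a FASTA file
#'
#' Minimal plain-text FASTA reader for polyprotein inputs.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop("no FASTA headers in ", path)
  id <- cumsum(hdr)
  names_ <- sub("^>\\s*", "", lines[hdr])
  names_ <- sub("\\s.*$", "", names_)
  seqs <- vapply(split(lines[!hdr], id[!hdr]),
                 function(x) paste(gsub("\\s", "", x), collapse = ""),
                 character(1))
  stats::setNames(unname(seqs), names_)
}

# terminal side-chain atom carrying the positive charge, per residue type
.basic_terminal_atom <- c(LYS = "NZ", ARG = "CZ", HIS = "NE2")

#' Map basic residues onto the capsid inner surface
#'
#' Finds every arginine, lysine and histidine whose charged side-chain
#' terminal atom (NZ / CZ / NE2; CB fallback when the side chain is not
#' modelled) lies within a radial shell — typically the inner capsid surface
#' where such residues neutralise and order the packaged RNA — and annotates
#' each with its radial position and nearest symmetry axis.
#'
#' @param expanded symmetry-expanded [structure_model] in the symmetry frame.
#' @param axes axis table from [find_axes] (optional; omit to skip axis
#'   annotation).
#' @param inner_shell radial interval `c(lo, hi)` in Angstrom.
#' @return data.frame: `chain`, `res_seq`, `res_name`, `radial_position`,
#'   `nearest_axis_order`, `nearest_axis_distance` (Angstrom, perpendicular).
#' @export
basic_residue_map <- function(expanded, axes = NULL, inner_shell) {
  stopifnot(length(inner_shell) == 2, inner_shell[1] <= inner_shell[2])
  a <- expanded$atoms
  bas <- a[a$res_name %in% c("ARG", "LYS", "HIS"), , drop = FALSE]
  empty <- data.frame(chain = character(), res_seq = integer(),
                      res_name = character(), radial_position = numeric(),
                      nearest_axis_order = integer(),
                      nearest_axis_distance = numeric(), stringsAsFactors = FALSE)
  if (nrow(bas) == 0) return(empty)
  keys <- split(seq_len(nrow(bas)), paste(bas$chain_id, bas$res_seq))
  picks <- vapply(keys, function(ii) {
    want <- .basic_terminal_atom[[bas$res_name[ii[1]]]]
    hit <- ii[bas$name[ii] == want]
    if (length(hit) == 0) hit <- ii[bas$name[ii] == "CB"]
    if (length(hit) == 0) return(NA_integer_)
    hit[1]
  }, integer(1))
  picks <- picks[!is.na(picks)]
  if (length(picks) == 0) return(empty)
  sel <- bas[picks, , drop = FALSE]
  r <- sqrt(sel$x^2 + sel$y^2 + sel$z^2)
  keep <- r >= inner_shell[1] & r <= inner_shell[2]
  sel <- sel[keep, , drop = FALSE]; r <- r[keep]
  if (nrow(sel) == 0) return(empty)
  ax_ord <- rep(NA_integer_, nrow(sel)); ax_d <- rep(NA_real_, nrow(sel))
  if (!is.null(axes) && nrow(axes) > 0) {
    xyz <- as.matrix(sel[, c("x", "y", "z")])
    dmat <- sapply(seq_len(nrow(axes)), function(k) {
      d <- c(axes$dx[k], axes$dy[k], axes$dz[k])
      proj <- xyz %*% d
      sqrt(pmax(0, rowSums(xyz^2) - proj^2))  # line through origin, both halves
    })
    dmat <- matrix(dmat, nrow = nrow(sel))
    best <- max.col(-dmat, ties.method = "first")
    ax_ord <- axes$order[best]; ax_d <- dmat[cbind(seq_len(nrow(sel)), best)]
  }
  out <- data.frame(chain = sel$chain_id, res_seq = sel$res_seq,
                    res_name = sel$res_name, radial_position = r,
                    nearest_axis_order = ax_ord, nearest_axis_distance = ax_d,
                    stringsAsFactors = FALSE)
  out <- out[order(out$chain, out$res_seq), ]
  rownames(out) <- NULL
  out
}

#' Modeled-residue accounting per chain
#'
#' Counts the residues possessing a CA atom in each mapped chain and reports
#' first/last modelled residue, modelled count and the expected full-length
#' count — the bookkeeping behind statements like "residues 2-242 out of
#' 251" for a chain with disordered termini.
#'
#' @param model [structure_model].
#' @param chain_map named character vector: chain token -> protein name.
#' @param expected_lengths named numeric vector: protein name -> full length.
#' @return data.frame: `chain`, `protein`, `first_modeled`, `last_modeled`,
#'   `modeled`, `expected`.
#' @export
modeled_residue_accounting <- function(model, chain_map, expected_lengths) {
  rows <- lapply(names(chain_map), function(ch) {
    prot <- chain_map[[ch]]
    if (!prot %in% names(expected_lengths))
      stop("no expected length for protein ", prot)
    ca <- select_atoms(model, chain = ch, atom_names = "CA")
    if (nrow(ca) == 0)
      stop("chain ", ch, " has no CA atoms (unmapped or absent chain)")
    res <- sort(unique(ca$res_seq))
    data.frame(chain = ch, protein = prot,
               first_modeled = as.integer(min(res)),
               last_modeled = as.integer(max(res)),
               modeled = length(res),
               expected = as.integer(expected_lengths[[prot]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
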