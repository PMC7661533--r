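#' Atomic structure container
#'
#' A `structure_model` holds an ordered atom table plus file-level metadata.
#' Atoms live in a data.frame with columns `serial`, `name`, `element`,
#' `res_name`, `res_seq`, `chain_id`, `x`, `y`, `z`, `occupancy`, `b_factor`
#' (coordinates in Angstrom). `biomt` is an optional list of
#' `list(rotation = 3x3 matrix, translation = length-3 vector)` operators
#' parsed from REMARK 350 / `_pdbx_struct_oper_list`.
#'
#' @param atoms data.frame with the columns above (missing `serial`,
#'   `element`, `occupancy`, `b_factor` are filled with defaults).
#' @param source_format `"pdb"`, `"mmcif"` or `"memory"`.
#' @param biomt optional list of rotation/translation operators.
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, source_format = "memory", biomt = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "res_name", "res_seq", "chain_id", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atoms is missing required columns: ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(max(n, 0L))
  if (is.null(atoms$element))
    atoms$element <- toupper(substr(gsub("[^A-Za-z].*$", "", atoms$name), 1, 1))
  if (is.null(atoms$occupancy)) atoms$occupancy <- rep(1, n)
  if (is.null(atoms$b_factor)) atoms$b_factor <- rep(0, n)
  if (n > 0 && !all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (n > 0 && any(!nzchar(atoms$name))) stop("empty atom name")
  if (!is.null(biomt)) {
    for (op in biomt) {
      R <- op$rotation
      if (max(abs(R %*% t(R) - diag(3))) > 1e-6 || abs(det(R) - 1) > 1e-6)
        stop("biomt operator is not a proper rotation")
    }
  }
  structure(
    list(atoms = atoms[, c("serial", "name", "element", "res_name", "res_seq",
                           "chain_id", "x", "y", "z", "occupancy", "b_factor")],
         chains = unique(atoms$chain_id),
         source_format = source_format,
         biomt = biomt),
    class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d chain(s) [%s]%s\n",
              nrow(x$atoms), length(x$chains),
              paste(utils::head(x$chains, 8), collapse = ","),
              if (is.null(x$biomt)) "" else
                sprintf(", %d assembly operator(s)", length(x$biomt))))
  invisible(x)
}

#' Number of atoms in a structure model
#' @param model a [structure_model]
#' @return integer atom count
#' @export
n_atoms <- function(model) nrow(model$atoms)

#' Atom coordinates as a matrix
#' @param model a [structure_model]
#' @return numeric n x 3 matrix (Angstrom)
#' @export
coords <- function(model) {
  as.matrix(model$atoms[, c("x", "y", "z"), drop = FALSE])
}

# ---------------------------------------------------------------------------
# PDB fixed-column format
# ---------------------------------------------------------------------------

.parse_pdb <- function(lines, path, keep_water) {
  rec <- substr(lines, 1, 6)
  idx <- which(rec == "ATOM  " | rec == "HETATM")
  n <- length(idx)
  al <- lines[idx]
  num <- function(s) suppressWarnings(as.numeric(s))
  x <- num(substr(al, 31, 38)); y <- num(substr(al, 39, 46)); z <- num(substr(al, 47, 54))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0)
    stop(sprintf("malformed coordinate field at line %d of %s", idx[bad[1]], path))
  atoms <- data.frame(
    serial   = num(substr(al, 7, 11)),
    name     = trimws(substr(al, 13, 16)),
    altloc   = substr(al, 17, 17),
    res_name = trimws(substr(al, 18, 20)),
    chain_id = trimws(substr(al, 22, 22)),
    res_seq  = num(substr(al, 23, 26)),
    x = x, y = y, z = z,
    occupancy = ifelse(is.na(num(substr(al, 55, 60))), 1, num(substr(al, 55, 60))),
    b_factor  = ifelse(is.na(num(substr(al, 61, 66))), 0, num(substr(al, 61, 66))),
    element   = toupper(trimws(substr(al, 77, 78))),
    hetatm    = rec[idx] == "HETATM",
    stringsAsFactors = FALSE)
  noel <- !nzchar(atoms$element)
  atoms$element[noel] <- toupper(substr(gsub("^[0-9]*", "", atoms$name[noel]), 1, 1))
  list(atoms = atoms, biomt = .parse_biomt(lines))
}

.parse_biomt <- function(lines) {
  bm <- grep("^REMARK 350   BIOMT", lines, value = TRUE)
  if (length(bm) == 0) return(NULL)
  row_no <- as.integer(substr(bm, 19, 19))
  op_id <- as.integer(substr(bm, 20, 23))
  vals <- lapply(bm, function(l) as.numeric(strsplit(trimws(substr(l, 24, 200)), "\\s+")[[1]]))
  ops <- list()
  for (id in sort(unique(op_id))) {
    rows <- lapply(1:3, function(r) vals[[which(op_id == id & row_no == r)[1]]])
    R <- do.call(rbind, lapply(rows, function(v) v[1:3]))
    t <- vapply(rows, function(v) v[4], numeric(1))
    ops[[length(ops) + 1]] <- list(rotation = R, translation = t)
  }
  ops
}

.format_pdb_name <- function(name, element) {
  # 4-char atom-name field: element right-justified in cols 13-14 convention
  ifelse(nchar(name) >= 4, substr(name, 1, 4),
         ifelse(nchar(element) == 1 & nchar(name) <= 3,
                sprintf(" %-3s", name), sprintf("%-4s", name)))
}

.write_pdb <- function(model, path) {
  a <- model$atoms
  if (nrow(a) > 99999)
    stop("more than 99,999 atoms: strict PDB serials overflow; write mmCIF instead")
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(model$biomt)) {
    for (k in seq_along(model$biomt)) {
      op <- model$biomt[[k]]
      for (r in 1:3)
        writeLines(sprintf("REMARK 350   BIOMT%d%4d%10.6f%10.6f%10.6f%15.5f",
                           r, k, op$rotation[r, 1], op$rotation[r, 2],
                           op$rotation[r, 3], op$translation[r]), con)
    }
  }
  chain1 <- substr(a$chain_id, 1, 1) # PDB has a 1-char chain field
  lines <- sprintf(
    "ATOM  %5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000L, .format_pdb_name(a$name, a$element), substr(a$res_name, 1, 3),
    chain1, a$res_seq, a$x, a$y, a$z, a$occupancy, a$b_factor, a$element)
  writeLines(c(lines, "END"), con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# mmCIF atom_site loop (the subset this pipeline needs)
# ---------------------------------------------------------------------------

.parse_mmcif <- function(lines, path) {
  loops <- which(trimws(lines) == "loop_")
  atoms <- NULL
  for (L in loops) {
    i <- L + 1
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(startsWith(tags, "_atom_site."))) next
    rows <- list()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "" || startsWith(l, "#") || startsWith(l, "_") || l == "loop_") break
      rows[[length(rows) + 1]] <- strsplit(l, "\\s+")[[1]]
      i <- i + 1
    }
    if (length(rows) == 0) stop("empty atom_site loop in ", path)
    m <- do.call(rbind, rows)
    if (ncol(m) != length(tags))
      stop(sprintf("malformed atom_site row (got %d fields, expected %d) in %s",
                   ncol(m), length(tags), path))
    colnames(m) <- tags
    g <- function(tag, alt = NULL) {
      if (tag %in% tags) m[, tag]
      else if (!is.null(alt) && alt %in% tags) m[, alt]
      else rep(NA_character_, nrow(m))
    }
    num <- function(v) suppressWarnings(as.numeric(v))
    atoms <- data.frame(
      serial = num(g("_atom_site.id")),
      name = gsub('"', "", g("_atom_site.label_atom_id")),
      altloc = ifelse(g("_atom_site.label_alt_id") %in% c(".", "?", NA), "",
                      g("_atom_site.label_alt_id")),
      res_name = g("_atom_site.label_comp_id"),
      chain_id = ifelse(is.na(g("_atom_site.auth_asym_id")),
                        g("_atom_site.label_asym_id"), g("_atom_site.auth_asym_id")),
      res_seq = num(ifelse(is.na(g("_atom_site.auth_seq_id")),
                           g("_atom_site.label_seq_id"), g("_atom_site.auth_seq_id"))),
      x = num(g("_atom_site.Cartn_x")),
      y = num(g("_atom_site.Cartn_y")),
      z = num(g("_atom_site.Cartn_z")),
      occupancy = ifelse(is.na(num(g("_atom_site.occupancy"))), 1,
                         num(g("_atom_site.occupancy"))),
      b_factor = ifelse(is.na(num(g("_atom_site.B_iso_or_equiv"))), 0,
                        num(g("_atom_site.B_iso_or_equiv"))),
      element = toupper(g("_atom_site.type_symbol")),
      hetatm = g("_atom_site.group_PDB") == "HETATM",
      stringsAsFactors = FALSE)
    if (any(!is.finite(atoms$x)))
      stop("malformed Cartn_x in atom_site loop of ", path)
    break
  }
  if (is.null(atoms)) stop("no atom_site loop found in ", path)
  list(atoms = atoms, biomt = .parse_cif_opers(lines))
}

.parse_cif_opers <- function(lines) {
  # _pdbx_struct_oper_list written by .write_mmcif (loop form)
  loops <- which(trimws(lines) == "loop_")
  for (L in loops) {
    i <- L + 1
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(startsWith(tags, "_pdbx_struct_oper_list."))) next
    rows <- list()
    while (i <= length(lines)) {
      l <- trimws(lines[i])
      if (l == "" || startsWith(l, "#") || startsWith(l, "_") || l == "loop_") break
      rows[[length(rows) + 1]] <- as.numeric(strsplit(l, "\\s+")[[1]][-1])
      i <- i + 1
    }
    ops <- lapply(rows, function(v)
      list(rotation = matrix(v[1:9], 3, 3, byrow = TRUE), translation = v[10:12]))
    return(ops)
  }
  NULL
}

.write_mmcif <- function(model, path) {
  a <- model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("data_icocapsid", con)
  if (!is.null(model$biomt)) {
    writeLines(c("loop_", "_pdbx_struct_oper_list.id",
                 paste0("_pdbx_struct_oper_list.matrix", rep(1:3, each = 3), 1:3),
                 paste0("_pdbx_struct_oper_list.vector", 1:3)), con)
    for (k in seq_along(model$biomt)) {
      op <- model$biomt[[k]]
      writeLines(paste(c(k, sprintf("%.9f", t(op$rotation)),
                         sprintf("%.5f", op$translation)), collapse = " "), con)
    }
    writeLines("#", con)
  }
  writeLines(c("loop_", "_atom_site.group_PDB", "_atom_site.id",
               "_atom_site.type_symbol", "_atom_site.label_atom_id",
               "_atom_site.label_alt_id", "_atom_site.label_comp_id",
               "_atom_site.auth_asym_id", "_atom_site.auth_seq_id",
               "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
               "_atom_site.occupancy", "_atom_site.B_iso_or_equiv"), con)
  writeLines(sprintf("ATOM %d %s %s . %s %s %d %.3f %.3f %.3f %.2f %.2f",
                     a$serial, a$element, a$name, a$res_name, a$chain_id,
                     a$res_seq, a$x, a$y, a$z, a$occupancy, a$b_factor), con)
  writeLines("#", con)
  invisible(NULL)
}

# ---------------------------------------------------------------------------
# public I/O surface
# ---------------------------------------------------------------------------

#' Read an atomic model from PDB or mmCIF
#'
#' Parses ATOM/HETATM records in file order. Waters (HOH/WAT/DOD) and, for
#' alternate locations, all but the highest-occupancy conformer are dropped
#' by default, so downstream geometry sees one position per atom.
#' Biological-assembly operators (REMARK 350 BIOMT or
#' `_pdbx_struct_oper_list`) are captured in `$biomt` when present.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by extension; `.cif`/`.mmcif`
#'   is mmCIF, anything else PDB).
#' @param keep_water keep water HETATM records (default FALSE).
#' @return A [structure_model].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           keep_water = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  parsed <- if (format == "pdb") .parse_pdb(lines, path, keep_water)
            else .parse_mmcif(lines, path)
  a <- parsed$atoms
  if (!keep_water) a <- a[!(a$hetatm & a$res_name %in% c("HOH", "WAT", "DOD")), ]
  # altloc: keep the highest-occupancy conformer per (chain, res, atom name)
  if (any(nzchar(a$altloc) & a$altloc != " ")) {
    key <- paste(a$chain_id, a$res_seq, a$res_name, a$name)
    keep <- unlist(lapply(split(seq_len(nrow(a)), key), function(ii) {
      if (length(ii) == 1) return(ii)
      ii[which.max(a$occupancy[ii])]
    }), use.names = FALSE)
    a <- a[sort(keep), ]
  }
  a$altloc <- NULL
  a$hetatm <- NULL
  rownames(a) <- NULL
  structure_model(a, source_format = format, biomt = parsed$biomt)
}

#' Write an atomic model to PDB or mmCIF
#'
#' PDB output is strict fixed-column; models above 99,999 atoms must go to
#' mmCIF (`format = "auto"` switches automatically). Assembly operators in
#' `$biomt` are emitted as REMARK 350 BIOMT / `_pdbx_struct_oper_list`.
#'
#' @param model a non-empty [structure_model].
#' @param path output path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!inherits(model, "structure_model")) stop("model must be a structure_model")
  if (n_atoms(model) == 0) stop("refusing to write an empty model")
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    wide_chain <- any(nchar(model$atoms$chain_id) > 1)  # PDB chain field is 1 char
    format <- if (ext %in% c("cif", "mmcif") || n_atoms(model) > 99999 || wide_chain)
      "mmcif" else "pdb"
  }
  if (format == "pdb") .write_pdb(model, path) else .write_mmcif(model, path)
  invisible(path)
}

#' Select atoms by chain, residue range and atom name
#'
#' All supplied filters are intersected; file order is preserved. An empty
#' selection is a legal value, not an error. Composable and idempotent.
#'
#' @param model a [structure_model].
#' @param chain chain token(s), or NULL for all.
#' @param res_range inclusive integer interval `c(lo, hi)`, or NULL.
#' @param atom_names atom-name token set (e.g. `"CA"`, `c("CA","CB")`), or NULL.
#' @param res_name residue-name token set (e.g. `"LYS"`), or NULL.
#' @return A data.frame of atoms (same columns as `model$atoms`).
#' @export
select_atoms <- function(model, chain = NULL, res_range = NULL,
                         atom_names = NULL, res_name = NULL) {
  a <- model$atoms
  keep <- rep(TRUE, nrow(a))
  if (!is.null(chain)) keep <- keep & a$chain_id %in% chain
  if (!is.null(res_range)) {
    stopifnot(length(res_range) == 2)
    keep <- keep & a$res_seq >= res_range[1] & a$res_seq <= res_range[2]
  }
  if (!is.null(atom_names)) keep <- keep & a$name %in% atom_names
  if (!is.null(res_name)) keep <- keep & a$res_name %in% res_name
  out <- a[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
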