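#' The icosahedral rotation group and symmetry-mate measurements
#'
#' The proper icosahedral group I has exactly 60 rotations: the identity,
#' 15 two-folds, 20 rotations about 10 three-fold axes and 24 rotations about
#' 6 five-fold axes. [icosahedral_operators] builds the group numerically by
#' closure from generators in the requested orientation convention and
#' validates the group axioms; [find_axes] classifies the rotation axes;
#' [expand_capsid] applies all 60 operators to an asymmetric unit;
#' [symmetry_mate_distance] measures an atom's distance to its symmetry
#' images, the quantity used to characterise contacts across two-fold axes.
#'
#' @name icosahedral-symmetry
NULL

.rot_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c <- cos(angle); s <- sin(angle)
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0), 3, 3, byrow = TRUE)
  diag(3) * c + s * K + (1 - c) * (u %o% u)
}

#' Generate the 60 rotations of the icosahedral group
#'
#' Convention `"I222"` (the default, and the common cryoEM deposition frame)
#' places three mutually perpendicular two-fold axes on x, y and z; the
#' five-fold axes then lie along (0, +-1, +-phi) and permutations, phi the
#' golden ratio. Convention `"I"` is accepted as a synonym for the same
#' orientation. The group is generated by numerical closure and validated:
#' orthogonality and unit determinant to 1e-9, closure to 1e-6, order 60.
#'
#' @param convention `"I222"` or `"I"`.
#' @return An object of class `symmetry_operators`: list with `rotations`
#'   (list of 60 3x3 matrices, element 1 the identity), `convention`, `origin`.
#' @export
icosahedral_operators <- function(convention = c("I222", "I")) {
  convention <- match.arg(convention)
  phi <- (1 + sqrt(5)) / 2
  gens <- list(
    diag(c(-1, -1, 1)),                        # two-fold on z
    matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE), # three-fold on (1,1,1)
    .rot_about(c(0, 1, phi), 2 * pi / 5))      # five-fold on a vertex axis
  ops <- list(diag(3))
  key <- function(R) paste(sprintf("%.6f", round(R, 6) + 0), collapse = ",")
  seen <- new.env(parent = emptyenv())
  assign(key(diag(3)), TRUE, envir = seen)
  frontier <- ops
  while (length(frontier) > 0) {
    nxt <- list()
    for (A in frontier) for (G in gens) {
      P <- G %*% A
      k <- key(P)
      if (!exists(k, envir = seen)) {
        assign(k, TRUE, envir = seen)
        ops[[length(ops) + 1]] <- P
        nxt[[length(nxt) + 1]] <- P
      }
    }
    frontier <- nxt
    if (length(ops) > 120) stop("group closure failed to terminate")
  }
  if (length(ops) != 60) stop("expected 60 operators, got ", length(ops))
  for (R in ops) {
    if (max(abs(R %*% t(R) - diag(3))) > .ico_tol$orthogonality ||
        abs(det(R) - 1) > .ico_tol$orthogonality)
      stop("generated operator failed orthogonality validation")
  }
  structure(list(rotations = ops, convention = convention, origin = c(0, 0, 0)),
            class = "symmetry_operators")
}

#' @export
print.symmetry_operators <- function(x, ...) {
  cat(sprintf("symmetry_operators: %d rotations, convention %s\n",
              length(x$rotations), x$convention))
  invisible(x)
}

#' Construct a symmetry operator set from parsed assembly operators
#'
#' Wraps the BIOMT / struct_oper_list rotations of a file into a
#' `symmetry_operators` object so that measurements use the deposition's own
#' symmetry frame (translations must be zero for a particle centred at the
#' origin; non-zero translations are rejected).
#'
#' @param model a [structure_model] whose `$biomt` is non-NULL.
#' @return A `symmetry_operators` object tagged convention `"biomt"`.
#' @export
operators_from_biomt <- function(model) {
  if (is.null(model$biomt)) stop("model carries no assembly operators")
  for (op in model$biomt)
    if (max(abs(op$translation)) > 1e-3)
      stop("assembly operators include translations; particle not origin-centred")
  structure(list(rotations = lapply(model$biomt, `[[`, "rotation"),
                 convention = "biomt", origin = c(0, 0, 0)),
            class = "symmetry_operators")
}

.rotation_angle <- function(R) {
  acos(max(-1, min(1, (sum(diag(R)) - 1) / 2)))
}

.rotation_axis <- function(R) {
  e <- eigen(R)
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sqrt(sum(v^2))
  # deterministic sign: positive z, tie-break on x then y
  s <- sign(v[3])
  if (abs(v[3]) < 1e-9) s <- sign(v[1])
  if (abs(v[3]) < 1e-9 && abs(v[1]) < 1e-9) s <- sign(v[2])
  if (s < 0) v <- -v
  v
}

#' Enumerate the symmetry axes of an icosahedral operator set
#'
#' Non-identity rotations are classified by rotation angle: pi gives the
#' 15 two-folds, 2pi/3 the 10 three-folds, multiples of 2pi/5 the 6
#' five-folds. Axis directions are sign-normalised (positive z, then x).
#'
#' @param ops a `symmetry_operators` object.
#' @return data.frame with columns `order` (2, 3 or 5) and unit direction
#'   `dx`, `dy`, `dz`; 31 rows (15 + 10 + 6).
#' @export
find_axes <- function(ops) {
  axes <- list()
  for (R in ops$rotations) {
    ang <- .rotation_angle(R)
    if (ang < 1e-6) next # identity
    ord <- round(2 * pi / ang)
    # 3-fold at 240deg and 5-fold at 144/216/288deg report the base order
    order <- if (abs(ang - pi) < 1e-6) 2L
             else if (min(abs(ang - c(2, 4) * pi / 3)) < 1e-6) 3L
             else 5L
    axes[[length(axes) + 1]] <- c(order, .rotation_axis(R))
  }
  m <- do.call(rbind, axes)
  df <- data.frame(order = as.integer(m[, 1]), dx = m[, 2], dy = m[, 3], dz = m[, 4])
  df <- df[!duplicated(round(df, 6)), ]
  df <- df[order(df$order, -df$dz, -df$dx, -df$dy), ]
  rownames(df) <- NULL
  df
}

#' Expand an asymmetric unit to the full 60-copy capsid
#'
#' Applies every rotation of the group to the AU. Copy k (k = 0 for the
#' identity) is tagged by renaming each chain `<orig>_<k>`, so interfaces can
#' be traced back to operators. Column `copy` is also added to the atom table.
#'
#' @param au a non-empty [structure_model], already in the operator frame
#'   (capsid centre at the origin).
#' @param ops a `symmetry_operators` object.
#' @return A [structure_model] with `60 * n_atoms(au)` atoms.
#' @export
expand_capsid <- function(au, ops) {
  if (n_atoms(au) == 0) stop("cannot expand an empty asymmetric unit")
  xyz <- coords(au)
  blocks <- lapply(seq_along(ops$rotations) - 1L, function(k) {
    a <- au$atoms
    p <- xyz %*% t(ops$rotations[[k + 1]])
    a$x <- p[, 1]; a$y <- p[, 2]; a$z <- p[, 3]
    a$chain_id <- paste0(a$chain_id, "_", k)
    a$copy <- k
    a
  })
  out <- do.call(rbind, blocks)
  out$serial <- seq_len(nrow(out))
  rownames(out) <- NULL
  m <- structure_model(out, source_format = "memory")
  m$atoms$copy <- out$copy
  m
}

#' Distance from an atom to its symmetry mates
#'
#' Resolves a single atom by (chain, residue, atom name) in the asymmetric
#' unit and returns the minimal distance to its images under the requested
#' axis class (all group rotations of that order), or under all 59
#' non-identity rotations when `axis_order = "nearest"`. This is the
#' measurement behind, e.g., the separation of two-fold related CB atoms in
#' the surface helices flanking a capsid two-fold axis.
#'
#' @param au a [structure_model] in the symmetry frame.
#' @param ops a `symmetry_operators` object.
#' @param chain chain token.
#' @param res_seq residue number.
#' @param atom_name atom name token (e.g. `"CB"`).
#' @param axis_order 2, 3, 5 or `"nearest"`.
#' @return distance in Angstrom (named with the operator index used).
#' @export
symmetry_mate_distance <- function(au, ops, chain, res_seq, atom_name,
                                   axis_order = "nearest") {
  sel <- select_atoms(au, chain = chain, res_range = c(res_seq, res_seq),
                      atom_names = atom_name)
  if (nrow(sel) == 0)
    stop(sprintf("selection %s/%s/%s matches no atom", chain, res_seq, atom_name))
  if (nrow(sel) > 1)
    stop(sprintf("selection %s/%s/%s is ambiguous (%d atoms)",
                 chain, res_seq, atom_name, nrow(sel)))
  x <- c(sel$x, sel$y, sel$z)
  dist_k <- vapply(ops$rotations, function(R) sqrt(sum((R %*% x - x)^2)), numeric(1))
  ang <- vapply(ops$rotations, .rotation_angle, numeric(1))
  keep <- if (identical(axis_order, "nearest")) {
    ang > 1e-6
  } else {
    ord <- as.integer(axis_order)
    if (!ord %in% c(2L, 3L, 5L)) stop("axis_order must be 2, 3, 5 or 'nearest'")
    cls <- switch(as.character(ord),
                  "2" = abs(ang - pi) < 1e-6,
                  "3" = pmin(abs(ang - 2 * pi / 3), abs(ang - 4 * pi / 3)) < 1e-6,
                  "5" = vapply(ang, function(a)
                    min(abs(a - (1:4) * 2 * pi / 5)) < 1e-6, logical(1)))
    cls
  }
  i <- which(keep)[which.min(dist_k[keep])]
  stats::setNames(dist_k[i], paste0("operator_", i - 1L))
}

#' Format operators as REMARK 350 BIOMT text
#'
#' @param ops a `symmetry_operators` object.
#' @return character vector of REMARK 350 lines (3 per operator).
#' @export
biomt_text <- function(ops) {
  unlist(lapply(seq_along(ops$rotations), function(k) {
    R <- ops$rotations[[k]]
    sprintf("REMARK 350   BIOMT%d%4d%10.6f%10.6f%10.6f%15.5f",
            1:3, k, R[, 1], R[, 2], R[, 3], 0)
  }))
}
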