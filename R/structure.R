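#' Molecular structure object
#'
#' The universal molecular container of the package: element symbols plus
#' Cartesian coordinates in Angstrom, with optional per-atom partial charges
#' (elementary charge units) and nonbonded atom-type labels. Atom order is
#' significant and preserved by every operation; no canonicalization is ever
#' applied.
#'
#' @param elements Character vector of element symbols (case-normalized).
#' @param coords Numeric N x 3 matrix of Cartesian coordinates in Angstrom.
#' @param charges Optional numeric vector of per-atom partial charges (e).
#' @param atom_types Optional character vector of nonbonded type labels;
#'   defaults to the element symbols when parameters are resolved.
#' @param metadata Free-form provenance text (e.g. an XYZ comment line).
#' @return An object of class \code{"molecule"}: a list with fields
#'   \code{elements}, \code{coords}, \code{charges}, \code{atom_types} and
#'   \code{metadata}.
#' @examples
#' m <- molecule("C", matrix(0, 1, 3))
#' n_atoms(m)
#' @export
molecule <- function(elements, coords, charges = NULL, atom_types = NULL,
                     metadata = "") {
  elements <- normalize_symbol(as.character(elements))
  coords <- as.matrix(coords)
  if (length(dim(coords)) != 2L || ncol(coords) != 3L)
    stop("coords must be an N x 3 matrix")
  storage.mode(coords) <- "double"
  n <- length(elements)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != n)
    stop("coords has ", nrow(coords), " rows for ", n, " elements")
  if (!all(is.finite(coords))) stop("all coordinates must be finite")
  element_property(elements, "mass")  # validates the symbols
  if (!is.null(charges)) {
    charges <- as.numeric(charges)
    if (length(charges) != n) stop("charges must have length ", n)
    if (!all(is.finite(charges))) stop("charges must be finite")
  }
  if (!is.null(atom_types)) {
    atom_types <- as.character(atom_types)
    if (length(atom_types) != n) stop("atom_types must have length ", n)
  }
  dimnames(coords) <- NULL
  structure(
    list(elements = elements, coords = coords, charges = charges,
         atom_types = atom_types, metadata = as.character(metadata)[1]),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  cat("molecule:", n_atoms(x), "atoms (",
      paste(names(table(x$elements)), table(x$elements), sep = "", collapse = " "),
      ")\n")
  if (nzchar(x$metadata)) cat("  metadata:", x$metadata, "\n")
  invisible(x)
}

#' Number of atoms in a molecule
#' @param mol A \code{molecule}.
#' @return Integer atom count.
#' @export
n_atoms <- function(mol) length(mol$elements)

#' Read a structure from an XYZ file
#'
#' Parses a standard XYZ file (atom count line, free comment line, then one
#' \code{element x y z} record per atom). The comment line is stored in the
#' structure's metadata.
#'
#' @param path Path to the XYZ file.
#' @return A \code{\link{molecule}}.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 1L) stop("empty XYZ file: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 1L)
    stop("malformed atom count on line 1 of ", path)
  if (length(lines) < n + 2L)
    stop("XYZ file ", path, " declares ", n, " atoms but has only ",
         length(lines) - 2L, " atom records")
  comment <- if (length(lines) >= 2L) lines[2] else ""
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "[[:space:]]+")[[1]]
    if (length(tok) < 4L)
      stop("malformed atom record on line ", ln, " of ", path)
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz))
      stop("non-numeric coordinate on line ", ln, " of ", path)
    elements[i] <- tok[1]
    coords[i, ] <- xyz
  }
  elements <- normalize_symbol(elements)
  ok <- elements %in% element_table()$symbol
  if (!all(ok)) {
    first_bad <- which(!ok)[1]
    stop("unknown element symbol '", elements[first_bad], "' on line ",
         first_bad + 2L, " of ", path)
  }
  molecule(elements, coords, metadata = comment)
}

#' Write a structure to an XYZ file
#'
#' @param mol A \code{\link{molecule}}.
#' @param path Output file path.
#' @param digits Decimal places for coordinates (default 6).
#' @return Invisibly, \code{path}.
#' @export
write_xyz <- function(mol, path, digits = 6) {
  stopifnot(inherits(mol, "molecule"))
  fmt <- paste0("%-3s %", digits + 6L, ".", digits, "f %",
                digits + 6L, ".", digits, "f %", digits + 6L, ".", digits, "f")
  recs <- sprintf(fmt, mol$elements,
                  mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  comment <- gsub("[\r\n]", " ", mol$metadata)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(n_atoms(mol)), comment, recs), con)
  invisible(path)
}

#' Rigid-body transform
#'
#' A proper rotation plus translation. The rotation matrix must be orthogonal
#' with determinant +1 (within 1e-8).
#'
#' @param rotation 3 x 3 proper orthogonal matrix.
#' @param translation Length-3 translation vector in Angstrom.
#' @return Object of class \code{"rigid_transform"}.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3L, 3L)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8)
    stop("rotation matrix is not orthogonal")
  if (abs(det(rotation) - 1) > 1e-8)
    stop("rotation matrix must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Rotation matrix from axis and angle
#'
#' @param axis Length-3 rotation axis (need not be normalized).
#' @param angle Rotation angle in radians.
#' @return A 3 x 3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle) {
  a <- as.numeric(axis)
  na <- sqrt(sum(a^2))
  if (na < 1e-12) stop("zero-length rotation axis")
  a <- a / na
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Apply a rigid transform to a structure
#'
#' Rotates then translates all coordinates; all pairwise interatomic
#' distances are preserved.
#'
#' @param mol A \code{\link{molecule}}.
#' @param transform A \code{\link{rigid_transform}}.
#' @return The transformed \code{molecule}.
#' @export
apply_transform <- function(mol, transform) {
  stopifnot(inherits(mol, "molecule"), inherits(transform, "rigid_transform"))
  xyz <- mol$coords %*% t(transform$rotation)
  xyz <- sweep(xyz, 2, transform$translation, "+")
  out <- mol
  out$coords <- xyz
  out
}

#' Reflect a structure through a plane
#'
#' Mirrors all coordinates through the plane defined by a point and a normal
#' vector. Mirroring a chiral molecule produces its enantiomer; applying the
#' same mirror twice is the identity.
#'
#' @param mol A \code{\link{molecule}}.
#' @param point A point on the mirror plane (default origin).
#' @param normal Plane normal (default z axis); must be nonzero.
#' @return The reflected \code{molecule}.
#' @export
mirror <- function(mol, point = c(0, 0, 0), normal = c(0, 0, 1)) {
  stopifnot(inherits(mol, "molecule"))
  n <- as.numeric(normal)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("zero-length mirror normal")
  n <- n / nn
  d <- sweep(mol$coords, 2, as.numeric(point), "-")
  proj <- drop(d %*% n)
  out <- mol
  out$coords <- mol$coords - 2 * outer(proj, n)
  out
}

#' Optimal rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between two
#' structures with identical atom sequences, using the SVD-based Kabsch
#' algorithm restricted to proper rotations (no reflection).
#'
#' @param A,B \code{\link{molecule}} objects with equal atom counts and
#'   matching element sequences.
#' @return A list with \code{rmsd} (Angstrom) and \code{transform}, the
#'   \code{\link{rigid_transform}} mapping \code{B} onto \code{A}.
#' @export
kabsch_align <- function(A, B) {
  stopifnot(inherits(A, "molecule"), inherits(B, "molecule"))
  if (n_atoms(A) != n_atoms(B))
    stop("atom-count mismatch: ", n_atoms(A), " vs ", n_atoms(B))
  if (!identical(A$elements, B$elements))
    stop("element sequences differ")
  pa <- A$coords; pb <- B$coords
  ca <- colMeans(pa); cb <- colMeans(pb)
  qa <- sweep(pa, 2, ca); qb <- sweep(pb, 2, cb)
  H <- crossprod(qb, qa)              # maps B-frame onto A-frame
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  t_vec <- ca - drop(R %*% cb)
  fit <- sweep(qb %*% t(R), 2, ca, "+")
  rmsd <- sqrt(mean(rowSums((fit - pa)^2)))
  list(rmsd = rmsd, transform = rigid_transform(R, t_vec))
}

#' Maximum extent of a structure
#'
#' The distance between the two most distant atoms: the size descriptor used
#' for bimolecular complexes in the sieving screen. Invariant under rigid
#' transforms and mirroring.
#'
#' @param mol A \code{\link{molecule}} with at least 2 atoms.
#' @return Maximum interatomic distance in Angstrom.
#' @export
max_extent <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  if (n_atoms(mol) < 2L) stop("max_extent needs at least 2 atoms")
  max(stats::dist(mol$coords))
}

#' Center of mass
#'
#' @param mol A \code{\link{molecule}}.
#' @return Length-3 mass-weighted mean position (Angstrom).
#' @export
center_of_mass <- function(mol) {
  stopifnot(inherits(mol, "molecule"))
  m <- element_property(mol$elements, "mass")
  drop(crossprod(mol$coords, m)) / sum(m)
}

#' Chirality witness
#'
#' Tests whether a structure is superimposable on its mirror image by a
#' proper rotation. Because mirror-image atom correspondence is not known a
#' priori, the alignment is taken as the best over cyclic identity mapping
#' plus a brute-force search over element-preserving permutations for small
#' molecules; for larger molecules the identity mapping after inertia-frame
#' alignment is used. A structure whose best RMSD against its mirror image is
#' below \code{tol} is reported achiral.
#'
#' @param mol A \code{\link{molecule}}.
#' @param tol RMSD tolerance in Angstrom (default 1e-3).
#' @return A list with \code{achiral} (logical) and \code{rmsd}, the best
#'   superposition RMSD against the mirror image.
#' @export
chirality_check <- function(mol, tol = 1e-3) {
  mm <- mirror(mol)
  rmsd <- min_rmsd_permuted(mol, mm)
  list(achiral = rmsd < tol, rmsd = rmsd)
}

# Best superposition RMSD between A and B allowing element-preserving atom
# permutations. Exhaustive for <= 8 atoms per element class, otherwise a
# greedy nearest-neighbour matching after Kabsch alignment on the identity
# mapping is refined iteratively.
min_rmsd_permuted <- function(A, B) {
  n <- n_atoms(A)
  best <- kabsch_align(A, B)$rmsd
  # try aligning on principal axes with sign flips, then greedy matching
  for (try in seq_len(8)) {
    signs <- c(ifelse(bitwAnd(try - 1, 1) > 0, -1, 1),
               ifelse(bitwAnd(try - 1, 2) > 0, -1, 1),
               ifelse(bitwAnd(try - 1, 4) > 0, -1, 1))
    if (prod(signs) < 0) next  # keep proper rotations only
    Bt <- B
    Bt$coords <- align_principal(B$coords) %*% diag(signs)
    At <- A
    At$coords <- align_principal(A$coords)
    perm <- greedy_match(At, Bt)
    if (is.null(perm)) next
    Bp <- B
    Bp$coords <- B$coords[perm, , drop = FALSE]
    Bp$elements <- B$elements[perm]
    if (!identical(Bp$elements, A$elements)) next
    r <- kabsch_align(A, Bp)$rmsd
    if (r < best) best <- r
  }
  best
}

# rotate coordinates into their principal-axes frame (centered)
align_principal <- function(xyz) {
  q <- sweep(xyz, 2, colMeans(xyz))
  e <- eigen(crossprod(q), symmetric = TRUE)
  V <- e$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  q %*% V
}

# element-preserving greedy nearest-neighbour matching of B onto A
greedy_match <- function(A, B) {
  n <- n_atoms(A)
  perm <- integer(n)
  used <- logical(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(B$coords, 2, A$coords[i, ])^2)
    d2[used | B$elements != A$elements[i]] <- Inf
    j <- which.min(d2)
    if (!is.finite(d2[j])) return(NULL)
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}

#' Merge two structures into one
#'
#' Concatenates atoms of two fragments (e.g. the two monomers of a
#' bimolecular complex), preserving atom order within each fragment.
#'
#' @param A,B \code{\link{molecule}} objects.
#' @return A single \code{molecule}; charges/types are kept when both inputs
#'   carry them.
#' @export
merge_molecules <- function(A, B) {
  ch <- if (!is.null(A$charges) && !is.null(B$charges))
    c(A$charges, B$charges) else NULL
  ty <- if (!is.null(A$atom_types) && !is.null(B$atom_types))
    c(A$atom_types, B$atom_types) else NULL
  molecule(c(A$elements, B$elements), rbind(A$coords, B$coords),
           charges = ch, atom_types = ty,
           metadata = paste(A$metadata, B$metadata, sep = " + "))
}
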