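#' Lattice geometry specification
#'
#' Bond lengths (Angstrom) used by the membrane model builders. Defaults are
#' the standard idealized values: aromatic C-C 1.42, C-H 1.09; for the
#' graphdiyne links an aryl-sp single bond of 1.40, a triple bond of 1.24 and
#' an sp-sp single bond of 1.33.
#'
#' @param cc_bond Aromatic C-C bond length.
#' @param ch_bond C-H bond length.
#' @param gd_single Aryl-C(sp) single bond in graphdiyne links.
#' @param gd_triple C-C triple bond in graphdiyne links.
#' @param gd_inter Single bond between the two diacetylene units.
#' @return A list of class \code{"lattice_spec"}.
#' @export
lattice_spec <- function(cc_bond = 1.42, ch_bond = 1.09,
                         gd_single = 1.40, gd_triple = 1.24,
                         gd_inter = 1.33) {
  vals <- c(cc_bond, ch_bond, gd_single, gd_triple, gd_inter)
  if (any(vals <= 0.5 | vals >= 3.0))
    stop("all bond lengths must lie in (0.5, 3.0) Angstrom")
  structure(list(cc_bond = cc_bond, ch_bond = ch_bond,
                 gd_single = gd_single, gd_triple = gd_triple,
                 gd_inter = gd_inter),
            class = "lattice_spec")
}

# ring-center position for axial indices (q, r) on the triangular lattice of
# hexagon centers; spacing d = cc * sqrt(3)
ring_centers <- function(rings, cc) {
  d <- cc * sqrt(3)
  q <- rings[, 1]; r <- rings[, 2]
  cbind(d * (q + r / 2), d * r * sqrt(3) / 2)
}

# the 6 vertex offsets of a hexagonal ring (vertices at 30 + 60k degrees,
# so that flat edges face the 6 neighbouring ring centers)
hex_vertices <- function(cc) {
  ang <- (30 + 60 * (0:5)) * pi / 180
  cbind(cc * cos(ang), cc * sin(ang))
}

# unique 2D points (rows) within tolerance, preserving first occurrence order
unique_points <- function(pts, tol = 1e-6) {
  key <- paste(round(pts[, 1] / tol) * tol, round(pts[, 2] / tol) * tol)
  pts[!duplicated(key), , drop = FALSE]
}

# row indices of `pts` that occur (within tol) in `ref`
match_points <- function(pts, ref, tol = 1e-4) {
  hit <- logical(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    d2 <- (ref[, 1] - pts[i, 1])^2 + (ref[, 2] - pts[i, 2])^2
    hit[i] <- any(d2 < tol^2)
  }
  hit
}

# axial neighbour offsets of a hexagon on the ring lattice
ring_neighbour_offsets <- function() {
  rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1), c(1, -1), c(-1, 1))
}

# expand a set of axial ring indices by all rings adjacent to it
expand_rings <- function(rings) {
  offs <- ring_neighbour_offsets()
  all <- rings
  for (k in seq_len(nrow(offs)))
    all <- rbind(all, sweep(rings, 2, offs[k, ], "+"))
  all[!duplicated(paste(all[, 1], all[, 2])), , drop = FALSE]
}

#' Build a finite hydrogen-passivated graphene flake
#'
#' Constructs a planar sp2 flake from a set of hexagonal rings given as axial
#' indices on the ring lattice. Every carbon missing one of its three ideal
#' lattice neighbours is terminated with a hydrogen along the missing bond
#' direction, in-plane. The flake lies in the z = 0 plane.
#'
#' @param rings Integer matrix (n x 2) of axial ring indices (q, r); a single
#'   ring may be given as \code{c(0, 0)}.
#' @param lattice A \code{\link{lattice_spec}}.
#' @return A \code{\link{molecule}} with extra fields \code{rings} (the ring
#'   index matrix) and \code{lattice}, used by \code{\link{cut_pore}}.
#' @examples
#' benzene <- build_graphene_flake(c(0, 0))
#' table(benzene$elements)  # 6 C, 6 H
#' @export
build_graphene_flake <- function(rings, lattice = lattice_spec()) {
  if (is.null(dim(rings))) rings <- matrix(rings, ncol = 2)
  rings <- as.matrix(rings)
  storage.mode(rings) <- "double"
  if (nrow(rings) > 1L && !rings_connected(rings))
    stop("disconnected ring layout")
  cc <- lattice$cc_bond; ch <- lattice$ch_bond
  centers <- ring_centers(rings, cc)
  hv <- hex_vertices(cc)
  verts <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(hv, 2, centers[i, ], "+")))
  carbons <- unique_points(verts)
  # ideal neighbour candidates come from the lattice extended by one ring shell
  ext_centers <- ring_centers(expand_rings(rings), cc)
  ext_verts <- unique_points(do.call(rbind, lapply(seq_len(nrow(ext_centers)),
    function(i) sweep(hv, 2, ext_centers[i, ], "+"))))
  elements <- rep("C", nrow(carbons))
  xy <- carbons
  hxy <- NULL
  for (i in seq_len(nrow(carbons))) {
    d2 <- (ext_verts[, 1] - carbons[i, 1])^2 + (ext_verts[, 2] - carbons[i, 2])^2
    ideal <- ext_verts[abs(sqrt(d2) - cc) < 1e-6, , drop = FALSE]
    present <- match_points(ideal, carbons)
    miss <- ideal[!present, , drop = FALSE]
    if (nrow(miss) > 0) {
      dir <- sweep(miss, 2, carbons[i, ], "-") / cc
      hxy <- rbind(hxy, sweep(dir * ch, 2, carbons[i, ], "+"))
    }
  }
  if (!is.null(hxy)) {
    elements <- c(elements, rep("H", nrow(hxy)))
    xy <- rbind(xy, hxy)
  }
  mol <- molecule(elements, cbind(xy, 0), metadata = "graphene flake")
  mol$rings <- rings
  mol$lattice <- lattice
  mol
}

# connectivity of a set of rings under hexagon adjacency
rings_connected <- function(rings) {
  n <- nrow(rings)
  if (n <= 1L) return(TRUE)
  key <- paste(rings[, 1], rings[, 2])
  offs <- ring_neighbour_offsets()
  seen <- logical(n); seen[1] <- TRUE
  queue <- 1L
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    nb_keys <- paste(rings[i, 1] + offs[, 1], rings[i, 2] + offs[, 2])
    hits <- which(key %in% nb_keys & !seen)
    seen[hits] <- TRUE
    queue <- c(queue, hits)
  }
  all(seen)
}

#' Pore model
#'
#' A finite membrane model: a planar structure plus pore center, membrane
#' normal, the indices of rim atoms bordering the pore, and the pore diameter
#' under a named convention.
#'
#' @param structure A \code{\link{molecule}}.
#' @param center Length-3 pore center.
#' @param normal Unit membrane normal.
#' @param rim_indices Indices of the atoms bordering the pore.
#' @param convention Diameter convention label (see
#'   \code{\link{pore_diameter}}).
#' @param preset Optional preset name.
#' @param porous Logical; \code{FALSE} for an uncut flake.
#' @return Object of class \code{"pore_model"} with a \code{diameter} field
#'   (\code{NA} for non-porous models).
#' @export
pore_model <- function(structure, center, normal = c(0, 0, 1),
                       rim_indices = integer(0),
                       convention = "geometric", preset = NA_character_,
                       porous = TRUE) {
  normal <- as.numeric(normal)
  normal <- normal / sqrt(sum(normal^2))
  pm <- structure(list(structure = structure, center = as.numeric(center),
                       normal = normal, rim_indices = as.integer(rim_indices),
                       diameter = NA_real_, convention = convention,
                       preset = preset, porous = porous),
                  class = "pore_model")
  if (porous) {
    if (length(pm$rim_indices) == 0)
      stop("a porous model needs non-empty rim_indices")
    pm$diameter <- pore_diameter(pm, convention)
  }
  pm
}

#' @export
print.pore_model <- function(x, ...) {
  cat("pore_model:", n_atoms(x$structure), "atoms")
  if (!is.na(x$preset)) cat(", preset", x$preset)
  if (x$porous)
    cat(sprintf(", diameter %.3f A (%s)", x$diameter, x$convention))
  else cat(" (non-porous)")
  cat("\n")
  invisible(x)
}

#' Cut a pore into a graphene flake
#'
#' Removes the carbon atoms of the listed rings and passivates every newly
#' exposed carbon with a hydrogen placed in-plane along the former bond
#' direction. The pore center is the centroid of the removed ring centers;
#' the rim is the set of new hydrogens and their carbons.
#'
#' @param flake A flake from \code{\link{build_graphene_flake}}.
#' @param rings_to_remove Integer vector of row indices into
#'   \code{flake$rings}, or an n x 2 matrix of axial ring indices.
#' @param convention Diameter convention for the resulting model.
#' @param preset Optional preset label carried into the model.
#' @return A \code{\link{pore_model}}; with an empty removal set, the
#'   unchanged flake flagged non-porous.
#' @export
cut_pore <- function(flake, rings_to_remove, convention = "geometric",
                     preset = NA_character_) {
  stopifnot(inherits(flake, "molecule"), !is.null(flake$rings))
  lattice <- flake$lattice
  cc <- lattice$cc_bond; ch <- lattice$ch_bond
  if (is.matrix(rings_to_remove)) {
    key_all <- paste(flake$rings[, 1], flake$rings[, 2])
    key_rm <- paste(rings_to_remove[, 1], rings_to_remove[, 2])
    prior <- if (is.null(flake$removed_rings)) character(0) else
      paste(flake$removed_rings[, 1], flake$removed_rings[, 2])
    idx <- match(key_rm, key_all)
    if (anyNA(idx) && !all(key_rm[is.na(idx)] %in% prior))
      stop("rings_to_remove contains rings not in the flake")
    # rings already removed earlier are skipped: cutting twice with the
    # same ring set equals cutting once
    if (all(is.na(idx)) && length(idx) > 0) {
      rm_centers <- ring_centers(flake$removed_rings, cc)
      rim <- detect_rim(flake, center = c(colMeans(rm_centers), 0))
      return(pore_model(flake, center = c(colMeans(rm_centers), 0),
                        rim_indices = rim, convention = convention,
                        preset = preset))
    }
    rings_to_remove <- idx[!is.na(idx)]
  }
  rings_to_remove <- as.integer(rings_to_remove)
  if (length(rings_to_remove) == 0) {
    return(pore_model(flake, center = c(colMeans(ring_centers(flake$rings, cc)), 0),
                      porous = FALSE, preset = preset,
                      convention = convention))
  }
  if (any(rings_to_remove < 1 | rings_to_remove > nrow(flake$rings)))
    stop("ring index out of range")
  keep_rings <- flake$rings[-rings_to_remove, , drop = FALSE]
  if (nrow(keep_rings) == 0)
    stop("removing all rings leaves no membrane")
  if (!rings_connected(keep_rings))
    stop("removing these rings disconnects the flake")
  rm_rings <- flake$rings[rings_to_remove, , drop = FALSE]
  rm_centers <- ring_centers(rm_rings, cc)
  hv <- hex_vertices(cc)
  rm_verts <- unique_points(do.call(rbind, lapply(seq_len(nrow(rm_centers)),
    function(i) sweep(hv, 2, rm_centers[i, ], "+"))))
  xy <- flake$coords[, 1:2, drop = FALSE]
  is_rm_carbon <- flake$elements == "C" & match_points(xy, rm_verts)
  # hydrogens whose carbon is removed go too
  bonds <- bond_list(flake)
  h_rm <- rep(FALSE, n_atoms(flake))
  for (i in which(flake$elements == "H")) {
    nb <- bonds[[i]]
    if (length(nb) > 0 && all(is_rm_carbon[nb])) h_rm[i] <- TRUE
  }
  removed <- is_rm_carbon | h_rm
  keep_idx <- which(!removed)
  new_xy <- xy[keep_idx, , drop = FALSE]
  new_el <- flake$elements[keep_idx]
  # passivate kept carbons that lost a carbon neighbour
  rim_c_new <- integer(0)
  add_h <- NULL
  for (i in keep_idx) {
    if (flake$elements[i] != "C") next
    lost <- bonds[[i]][removed[bonds[[i]]] & flake$elements[bonds[[i]]] == "C"]
    for (j in lost) {
      dir <- (xy[j, ] - xy[i, ])
      dir <- dir / sqrt(sum(dir^2))
      add_h <- rbind(add_h, xy[i, ] + ch * dir)
      rim_c_new <- c(rim_c_new, match(i, keep_idx))
    }
  }
  rim <- integer(0)
  if (!is.null(add_h)) {
    h_start <- length(new_el)
    new_el <- c(new_el, rep("H", nrow(add_h)))
    new_xy <- rbind(new_xy, add_h)
    rim <- sort(unique(c(rim_c_new, h_start + seq_len(nrow(add_h)))))
  }
  mol <- molecule(new_el, cbind(new_xy, 0),
                  metadata = paste0("graphene pore (", nrow(rm_rings),
                                    " rings removed)"))
  mol$rings <- keep_rings
  mol$lattice <- lattice
  mol$removed_rings <- rbind(flake$removed_rings, rm_rings)
  pore_model(mol, center = c(colMeans(rm_centers), 0), rim_indices = rim,
             convention = convention, preset = preset)
}

#' Build the triangular graphdiyne pore unit
#'
#' A single triangular pore of graphdiyne: three corner benzene rings joined
#' pairwise by diacetylene (-C#C-C#C-) links, with all remaining ring
#' positions hydrogen-terminated. The unit is three-fold symmetric and lies
#' in the z = 0 plane with the pore center at the origin.
#'
#' @param lattice A \code{\link{lattice_spec}}.
#' @param convention Diameter convention for the model.
#' @return A \code{\link{pore_model}}.
#' @export
build_graphdiyne_pore <- function(lattice = lattice_spec(),
                                  convention = "geometric") {
  cc <- lattice$cc_bond; ch <- lattice$ch_bond
  link_len <- 2 * lattice$gd_single + 2 * lattice$gd_triple + lattice$gd_inter
  L <- link_len + 2 * cc                 # ring-center separation
  rc <- L / sqrt(3)
  corner_ang <- c(90, 210, 330) * pi / 180
  centers <- cbind(rc * cos(corner_ang), rc * sin(corner_ang))
  el <- character(0); xy <- NULL
  rim <- integer(0)
  for (k in 1:3) {
    ck <- centers[k, ]
    others <- centers[-k, , drop = FALSE]
    dir1 <- (others[1, ] - ck); dir1 <- dir1 / sqrt(sum(dir1^2))
    a1 <- atan2(dir1[2], dir1[1])
    # hexagon vertices every 60 deg starting at the first attachment
    vang <- a1 + (0:5) * pi / 3
    vxy <- cbind(ck[1] + cc * cos(vang), ck[2] + cc * sin(vang))
    # which vertices point to the two other corners (attachment sites)?
    attach <- logical(6)
    for (m in 1:2) {
      dm <- (others[m, ] - ck); dm <- dm / sqrt(sum(dm^2))
      am <- atan2(dm[2], dm[1])
      attach[which.min(abs(((vang - am + pi) %% (2 * pi)) - pi))] <- TRUE
    }
    el <- c(el, rep("C", 6)); xy <- rbind(xy, vxy)
    # hydrogens on non-attachment vertices, radial out from the ring center
    for (v in which(!attach)) {
      dir <- (vxy[v, ] - ck); dir <- dir / sqrt(sum(dir^2))
      el <- c(el, "H"); xy <- rbind(xy, vxy[v, ] + ch * dir)
    }
  }
  # diacetylene chains along each edge, built once per unordered corner pair
  chain_first <- length(el) + 1L
  for (k in 1:2) for (m in (k + 1):3) {
    ck <- centers[k, ]; cm <- centers[m, ]
    u <- (cm - ck) / sqrt(sum((cm - ck)^2))
    a1 <- ck + cc * u                    # attachment vertex of ring k
    s <- cumsum(c(lattice$gd_single, lattice$gd_triple, lattice$gd_inter,
                  lattice$gd_triple))
    for (t in s) {
      el <- c(el, "C"); xy <- rbind(xy, a1 + t * u)
    }
  }
  rim <- chain_first:length(el)          # the sp carbons line the pore
  mol <- molecule(el, cbind(xy, 0), metadata = "graphdiyne triangular unit")
  pore_model(mol, center = c(0, 0, 0), rim_indices = rim,
             convention = convention, preset = "graphdiyne")
}

# bond list from covalent radii (pairs within 1.15 x sum of covalent radii)
bond_list <- function(mol) {
  n <- n_atoms(mol)
  rcov <- element_property(mol$elements, "covalent")
  d <- as.matrix(stats::dist(mol$coords))
  cut <- 1.15 * outer(rcov, rcov, "+")
  adj <- d < cut & d > 1e-6
  lapply(seq_len(n), function(i) which(adj[i, ]))
}

#' Substitute rim carbons by nitrogen
#'
#' Replaces each listed rim carbon (which must carry exactly one hydrogen) by
#' a nitrogen atom and deletes its hydrogen, the standard minimal pore
#' enlargement. Atom count decreases by one per substitution.
#'
#' @param pore A \code{\link{pore_model}}.
#' @param carbon_indices Indices (into the pore structure) of rim carbons.
#' @return The modified \code{\link{pore_model}} with rim and diameter
#'   recomputed.
#' @export
substitute_nitrogen <- function(pore, carbon_indices) {
  stopifnot(inherits(pore, "pore_model"))
  carbon_indices <- as.integer(carbon_indices)
  if (length(carbon_indices) == 0) return(pore)
  mol <- pore$structure
  bonds <- bond_list(mol)
  drop_h <- integer(0)
  for (i in carbon_indices) {
    if (i < 1 || i > n_atoms(mol) || mol$elements[i] != "C")
      stop("index ", i, " is not a carbon atom")
    if (!(i %in% pore$rim_indices))
      stop("index ", i, " is not a rim atom")
    hs <- bonds[[i]][mol$elements[bonds[[i]]] == "H"]
    if (length(hs) != 1L)
      stop("rim carbon ", i, " does not carry exactly one hydrogen")
    mol$elements[i] <- "N"
    drop_h <- c(drop_h, hs)
  }
  keep <- setdiff(seq_len(n_atoms(mol)), drop_h)
  new <- molecule(mol$elements[keep], mol$coords[keep, , drop = FALSE],
                  charges = mol$charges[keep], atom_types = mol$atom_types[keep],
                  metadata = paste(mol$metadata, "+ N substitution"))
  new$rings <- mol$rings
  new$lattice <- mol$lattice
  rim_new <- match(setdiff(pore$rim_indices, drop_h), keep)
  pore_model(new, center = pore$center, normal = pore$normal,
             rim_indices = rim_new, convention = pore$convention,
             preset = pore$preset)
}

#' Detect the rim of a pore from its bond graph
#'
#' Traces the planar face of the bond graph that encloses the pore center
#' (the shortest enclosing cycle, including any hydrogens dangling into the
#' hole) and returns the indices of its atoms.
#'
#' @param pore A \code{\link{pore_model}} (or a planar \code{molecule} plus
#'   an explicit \code{center}).
#' @param center Pore center; defaults to the model's.
#' @return Integer vector of rim atom indices.
#' @export
detect_rim <- function(pore, center = NULL) {
  if (inherits(pore, "pore_model")) {
    mol <- pore$structure
    if (is.null(center)) center <- pore$center
  } else {
    mol <- pore
    if (is.null(center)) stop("center required for a bare molecule")
  }
  xy <- mol$coords[, 1:2, drop = FALSE]
  c2 <- center[1:2]
  bonds <- bond_list(mol)
  # half-edge face traversal on the planar bond graph
  faces <- trace_faces(xy, bonds)
  containing <- Filter(function(f) point_in_polygon(c2, xy[f$cycle, , drop = FALSE]),
                       faces)
  if (length(containing) == 0) stop("no hole found")
  areas <- vapply(containing, function(f) f$area, numeric(1))
  cyc <- unique(containing[[which.min(areas)]]$cycle)
  if (length(cyc) <= 6) stop("no hole found")
  # the rim proper: hydrogens dangling into the hole, their carbons, and
  # under-coordinated (sp) carbons lining the hole
  deg <- lengths(bonds)
  h_in <- cyc[mol$elements[cyc] == "H"]
  c_h <- unlist(lapply(h_in, function(h) bonds[[h]]))
  c_sp <- cyc[mol$elements[cyc] == "C" & deg[cyc] == 2]
  sort(unique(c(h_in, c_h, c_sp)))
}

# trace all bounded faces of a planar straight-line graph.
# Returns list of list(cycle = atom indices, area = |signed area|).
trace_faces <- function(xy, bonds) {
  # directed half-edges
  he <- NULL
  for (i in seq_along(bonds)) for (j in bonds[[i]]) he <- rbind(he, c(i, j))
  if (is.null(he)) return(list())
  used <- rep(FALSE, nrow(he))
  key <- paste(he[, 1], he[, 2])
  next_he <- function(u, v) {
    # among neighbours w of v, take the next edge clockwise from (v -> u)
    nb <- bonds[[v]]
    ang_back <- atan2(xy[u, 2] - xy[v, 2], xy[u, 1] - xy[v, 1])
    ang <- atan2(xy[nb, 2] - xy[v, 2], xy[nb, 1] - xy[v, 1])
    rel <- (ang_back - ang) %% (2 * pi)
    rel[rel < 1e-12] <- 2 * pi           # the reverse edge is last resort
    nb[which.min(rel)]
  }
  faces <- list()
  for (e in seq_len(nrow(he))) {
    if (used[e]) next
    u0 <- he[e, 1]; v0 <- he[e, 2]
    cyc <- u0
    u <- u0; v <- v0
    repeat {
      used[match(paste(u, v), key)] <- TRUE
      cyc <- c(cyc, v)
      w <- next_he(u, v)
      u <- v; v <- w
      if (u == u0 && v == v0) break
      if (length(cyc) > length(bonds) * 4) break   # safety
    }
    cyc <- cyc[-length(cyc)]
    a <- signed_area(xy[cyc, , drop = FALSE])
    if (a < -1e-9) next                  # outer (clockwise) face
    faces[[length(faces) + 1]] <- list(cycle = cyc, area = abs(a))
  }
  faces
}

signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  j <- c(2:n, 1)
  sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2]) / 2
}

point_in_polygon <- function(pt, poly) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  j <- c(2:n, 1)
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j[i], 1]; yj <- poly[j[i], 2]
    if (((yi > pt[2]) != (yj > pt[2])) &&
        (pt[1] < (xj - xi) * (pt[2] - yi) / (yj - yi) + xi))
      inside <- !inside
  }
  inside
}

#' Pore diameter
#'
#' Diameter of the largest circle, centered in the membrane plane near the
#' pore center, that fits inside the pore. Under the \code{"geometric"}
#' convention the circle touches rim atom centers; under \code{"vdw"} each
#' rim atom is inflated by its van der Waals radius. The in-plane circle
#' center is optimized (Nelder-Mead) starting from the pore center, so the
#' measure is the Chebyshev opening of the rim. \code{"geometric"} is the
#' package's calibrated default: with the shipped presets and the default
#' lattice constants it reproduces the reference openings 6.0, 5.6 and 5.6
#' Angstrom for the 4-ring graphene, 3-ring graphene and graphdiyne models.
#'
#' @param pore A \code{\link{pore_model}}.
#' @param convention \code{"geometric"} or \code{"vdw"}.
#' @return Diameter in Angstrom.
#' @export
pore_diameter <- function(pore, convention = c("geometric", "vdw")) {
  convention <- match.arg(convention)
  stopifnot(inherits(pore, "pore_model"))
  if (!pore$porous) stop("model is not porous")
  mol <- pore$structure
  idx <- pore$rim_indices
  if (length(idx) == 0) idx <- seq_len(n_atoms(mol))
  # in-plane coordinates relative to the center
  n <- pore$normal
  e1 <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- e1 - sum(e1 * n) * n; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(n[2] * e1[3] - n[3] * e1[2],
          n[3] * e1[1] - n[1] * e1[3],
          n[1] * e1[2] - n[2] * e1[1])
  rel <- sweep(mol$coords[idx, , drop = FALSE], 2, pore$center, "-")
  uv <- cbind(rel %*% e1, rel %*% e2)
  corr <- if (convention == "vdw")
    element_property(mol$elements[idx], "vdw") else rep(0, length(idx))
  clearance <- function(p)
    min(sqrt((uv[, 1] - p[1])^2 + (uv[, 2] - p[2])^2) - corr)
  opt <- stats::optim(c(0, 0), function(p) -clearance(p),
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 2000))
  2 * clearance(opt$par)
}

# shipped ring layouts (axial indices) of the pore presets
preset_layouts <- function() {
  list(
    graphene4 = rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, -1)),
    graphene3 = rbind(c(0, 0), c(1, 0), c(0, 1)),
    graphene5 = rbind(c(0, 0), c(1, 0), c(-1, 1), c(0, -1), c(1, -1))
  )
}

#' Build a named pore preset
#'
#' The shipped membrane models: \code{"graphene4"}, a finite graphene sheet
#' with 4 rings removed (a central ring plus three alternating neighbours,
#' giving a three-fold opening of 6.0 Angstrom); \code{"graphene3"}, 3 rings
#' removed in a compact triangle (5.5 Angstrom); \code{"graphdiyne"}, the
#' triangular graphdiyne unit (5.6 Angstrom); and \code{"graphene5"}, a
#' 5-ring pore used for chiral functionalization studies. Graphene flakes
#' include the rings adjacent to the hole, hydrogen-passivated.
#'
#' @param preset One of \code{"graphene4"}, \code{"graphene3"},
#'   \code{"graphdiyne"}, \code{"graphene5"}.
#' @param lattice A \code{\link{lattice_spec}}.
#' @param convention Diameter convention (default calibrated
#'   \code{"geometric"}).
#' @return A \code{\link{pore_model}}.
#' @examples
#' p <- build_pore("graphene3")
#' p$diameter
#' @export
build_pore <- function(preset = c("graphene4", "graphene3", "graphdiyne",
                                  "graphene5"),
                       lattice = lattice_spec(),
                       convention = "geometric") {
  preset <- match.arg(preset)
  if (preset == "graphdiyne")
    return(build_graphdiyne_pore(lattice, convention))
  hole <- preset_layouts()[[preset]]
  flake <- build_graphene_flake(expand_rings(hole), lattice)
  cut_pore(flake, hole, convention = convention, preset = preset)
}

#' Write a pore model with sidecar metadata
#'
#' Writes the structure as XYZ plus a plain-text key-value sidecar
#' (\code{<path>.meta}) recording center, normal, 0-based rim indices,
#' diameter, convention and preset.
#'
#' @param pore A \code{\link{pore_model}}.
#' @param path Output XYZ path.
#' @return Invisibly, \code{path}.
#' @export
write_pore <- function(pore, path) {
  stopifnot(inherits(pore, "pore_model"))
  write_xyz(pore$structure, path)
  meta <- c(
    paste("preset", pore$preset),
    paste("center", paste(sprintf("%.6f", pore$center), collapse = " ")),
    paste("normal", paste(sprintf("%.6f", pore$normal), collapse = " ")),
    paste("rim_indices", paste(pore$rim_indices - 1L, collapse = " ")),
    paste("diameter", sprintf("%.6f", pore$diameter)),
    paste("convention", pore$convention)
  )
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}
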