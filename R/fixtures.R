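# --- internal z-matrix style construction -----------------------------------

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Place a new atom at distance r from A, bond angle theta (deg) with respect
# to B, and dihedral phi (deg) with respect to the B-C axis (NeRF placement).
zmat_place <- function(A, B, C, r, theta, phi) {
  th <- theta * pi / 180; ph <- phi * pi / 180
  b1 <- A - B; b1 <- b1 / sqrt(sum(b1^2))
  b0 <- B - C
  n <- cross3(b0, b1)
  nn <- sqrt(sum(n^2))
  if (nn < 1e-10) stop("collinear reference atoms in zmat_place")
  n <- n / nn
  m <- cross3(n, b1)
  A + r * (-cos(th) * b1 + sin(th) * (cos(ph) * m + sin(ph) * n))
}

tet <- 109.4712206344907  # ideal tetrahedral angle, degrees

# --- probe fixtures ----------------------------------------------------------

#' Generate a deterministic probe or template fixture
#'
#' Builds the idealized probe geometries used throughout the package's tests
#' and examples. All generators are deterministic (no randomness) and use
#' standard literature bond lengths, not optimized geometries:
#' \describe{
#'   \item{co2_like}{linear O=C=O, r(C-O) = 1.16 Angstrom: the prototype of
#'     an elongated, cigar-shaped, radially symmetric electron density.}
#'   \item{ch4_like}{tetrahedral CH4, r(C-H) = 1.09, one C-H bond along +z
#'     (the "tip"): an almost spherical density.}
#'   \item{ethane_like}{staggered C2H6, r(C-C) = 1.54, C-C along z: a
#'     corrugated density with a slight constriction.}
#'   \item{chiral_probe}{a tetrahedral carbon with four distinct,
#'     deliberately size-mismatched substituents (H, F, Cl, Br) - the
#'     minimal chiral molecule.}
#'   \item{aminoethanol}{1-aminoethanol CH3-CH(OH)-NH2, the classic
#'     gatekeeper/target molecule; \code{enantiomer} selects the hand.}
#' }
#' All fixtures carry simple stand-in partial charges (not derived from any
#' published charge model).
#'
#' @param id Generator id (see above).
#' @param enantiomer \code{"R"} or \code{"S"} for chiral fixtures; the S form
#'   is the mirror image of the R form.
#' @return A \code{\link{molecule}}.
#' @examples
#' co2 <- generate_fixture("co2_like")
#' max_extent(co2)  # 2.32
#' @export
generate_fixture <- function(id = c("co2_like", "ch4_like", "ethane_like",
                                    "chiral_probe", "aminoethanol"),
                             enantiomer = c("R", "S")) {
  id <- match.arg(id)
  enantiomer <- match.arg(enantiomer)
  mol <- switch(id,
    co2_like = molecule(c("O", "C", "O"),
                        rbind(c(0, 0, -1.16), c(0, 0, 0), c(0, 0, 1.16)),
                        charges = c(-0.35, 0.70, -0.35),
                        metadata = "co2_like probe"),
    ch4_like = {
      dirs <- rbind(c(0, 0, 1),
                    c(2 * sqrt(2) / 3, 0, -1 / 3),
                    c(-sqrt(2) / 3,  sqrt(2 / 3), -1 / 3),
                    c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
      molecule(c("C", rep("H", 4)), rbind(c(0, 0, 0), 1.09 * dirs),
               charges = c(-0.24, rep(0.06, 4)),
               metadata = "ch4_like probe (tip on +z)")
    },
    ethane_like = {
      z0 <- 1.54 / 2
      hz <- 1.09 * cos(tet * pi / 180)      # negative: H bends back
      hr <- 1.09 * sin(tet * pi / 180)
      top <- t(vapply(c(0, 120, 240) * pi / 180, function(a)
        c(hr * cos(a), hr * sin(a), z0 - hz), numeric(3)))
      bot <- t(vapply(c(60, 180, 300) * pi / 180, function(a)
        c(hr * cos(a), hr * sin(a), -z0 + hz), numeric(3)))
      molecule(c("C", "C", rep("H", 6)),
               rbind(c(0, 0, z0), c(0, 0, -z0), top, bot),
               charges = c(-0.18, -0.18, rep(0.06, 6)),
               metadata = "ethane_like probe (C-C on z)")
    },
    chiral_probe = {
      dirs <- rbind(c(0, 0, 1),
                    c(2 * sqrt(2) / 3, 0, -1 / 3),
                    c(-sqrt(2) / 3,  sqrt(2 / 3), -1 / 3),
                    c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
      # artificial probe: the four arms are deliberately size-mismatched
      # (the heavy arm is elongated well past a covalent Br bond) and the
      # H/F arms carry a +/-0.3 e polar lock, so that the lowest RS and SS
      # dimers dock in distinctly sized geometries
      r <- c(1.09, 1.35, 1.77, 2.30)       # H, F, Cl, elongated Br arm
      molecule(c("C", "H", "F", "Cl", "Br"),
               rbind(c(0, 0, 0), dirs * r),
               charges = c(0, 0.30, -0.30, 0, 0),
               metadata = "chiral tetrahedral probe (synthetic)")
    },
    aminoethanol = build_aminoethanol()
  )
  if (enantiomer == "S" && id %in% c("chiral_probe", "aminoethanol")) {
    mol <- mirror(mol)
    mol$metadata <- paste(mol$metadata, "(S)")
  }
  mol
}

# idealized 1-aminoethanol, R configuration at the stereocenter
build_aminoethanol <- function() {
  xyz <- matrix(0, 11, 3)
  el <- c("C", "C", "O", "N", "H", "H", "H", "H", "H", "H", "H")
  # 1 C* stereocenter, 2 methyl C, 3 O, 4 N
  xyz[1, ] <- c(0, 0, 0)
  xyz[2, ] <- c(1.54, 0, 0)
  a <- tet * pi / 180
  xyz[3, ] <- c(1.43 * cos(a), 1.43 * sin(a), 0)        # O in the xy plane
  xyz[4, ] <- zmat_place(xyz[1, ], xyz[2, ], xyz[3, ], 1.47, tet, 120)
  xyz[5, ] <- zmat_place(xyz[1, ], xyz[2, ], xyz[3, ], 1.09, tet, -120)  # H on C*
  xyz[6, ] <- zmat_place(xyz[2, ], xyz[1, ], xyz[3, ], 1.09, tet, 60)    # methyl H
  xyz[7, ] <- zmat_place(xyz[2, ], xyz[1, ], xyz[3, ], 1.09, tet, 180)
  xyz[8, ] <- zmat_place(xyz[2, ], xyz[1, ], xyz[3, ], 1.09, tet, 300)
  xyz[9, ] <- zmat_place(xyz[3, ], xyz[1, ], xyz[2, ], 0.96, 108, 180)   # O-H
  xyz[10, ] <- zmat_place(xyz[4, ], xyz[1, ], xyz[2, ], 1.01, 109.5, 60) # N-H
  xyz[11, ] <- zmat_place(xyz[4, ], xyz[1, ], xyz[2, ], 1.01, 109.5, 300)
  q <- c(0.15, -0.18, -0.40, -0.60, 0.06, 0.06, 0.06, 0.06, 0.30, 0.245, 0.245)
  molecule(el, xyz, charges = q - mean(q), metadata = "1-aminoethanol (R)")
}

# --- chiral template library -------------------------------------------------

# stereocenter scaffold: C* bonded to H, CH3, X and a functional group
# attachment point; returns coords for C*, C(methyl), X, H plus methyl H and
# the attachment frame (origin + direction) of the functional group
template_scaffold <- function(x_element, x_bond) {
  xyz <- matrix(0, 0, 3)
  cstar <- c(0, 0, 0)
  cme <- c(1.54, 0, 0)
  a <- tet * pi / 180
  x <- c(x_bond * cos(a), x_bond * sin(a), 0)
  h <- zmat_place(cstar, cme, x, 1.09, tet, -120)
  fg_dir <- zmat_place(cstar, cme, x, 1.00, tet, 120) - cstar  # unit-ish
  fg_dir <- fg_dir / sqrt(sum(fg_dir^2))
  hme <- rbind(zmat_place(cme, cstar, x, 1.09, tet, 60),
               zmat_place(cme, cstar, x, 1.09, tet, 180),
               zmat_place(cme, cstar, x, 1.09, tet, 300))
  list(cstar = cstar, cme = cme, x = x, h = h, hme = hme, fg_dir = fg_dir,
       x_element = x_element)
}

#' Generate the chiral template library
#'
#' Five idealized chiral template molecules - an organic acid, an aldehyde,
#' an alcohol, an olefinic alcohol and an ether - each with both enantiomers.
#' Every template carries a stereocenter with four distinct substituents and
#' fails the achirality witness; the S enantiomer is the exact mirror image
#' of the R form, so both have identical maximum extents.
#'
#' @return A named list of five entries, each a list with \code{name},
#'   \code{R} and \code{S} (\code{\link{molecule}} objects).
#' @examples
#' lib <- generate_template_library()
#' names(lib)
#' @export
generate_template_library <- function() {
  specs <- list(
    acid         = build_template_acid(),
    aldehyde     = build_template_aldehyde(),
    alcohol      = build_template_alcohol(),
    olef_alcohol = build_template_olef_alcohol(),
    ether        = build_template_ether()
  )
  lapply(names(specs), function(nm) {
    r <- specs[[nm]]
    s <- mirror(r); s$metadata <- paste(r$metadata, "(S)")
    list(name = nm, R = r, S = s)
  }) -> out
  names(out) <- names(specs)
  out
}

finish_template <- function(el, xyz, q, what) {
  molecule(el, xyz, charges = q - mean(q), metadata = what)
}

# 2-fluoropropanoic acid: C*(H)(CH3)(F)(COOH)
build_template_acid <- function() {
  s <- template_scaffold("F", 1.35)
  cacid <- s$cstar + 1.52 * s$fg_dir
  odb <- zmat_place(cacid, s$cstar, s$cme, 1.21, 121, 0)
  ooh <- zmat_place(cacid, s$cstar, s$cme, 1.34, 115, 180)
  hooh <- zmat_place(ooh, cacid, s$cstar, 0.96, 107, 180)
  el <- c("C", "C", "F", "H", "H", "H", "H", "C", "O", "O", "H")
  xyz <- rbind(s$cstar, s$cme, s$x, s$h, s$hme, cacid, odb, ooh, hooh)
  q <- c(0.10, -0.18, -0.22, 0.06, 0.06, 0.06, 0.06, 0.52, -0.44, -0.46, 0.38)
  finish_template(el, xyz, q, "acid template (R)")
}

# 2-fluoropropanal: C*(H)(CH3)(F)(CHO)
build_template_aldehyde <- function() {
  s <- template_scaffold("F", 1.35)
  cald <- s$cstar + 1.50 * s$fg_dir
  odb <- zmat_place(cald, s$cstar, s$cme, 1.21, 121, 0)
  hald <- zmat_place(cald, s$cstar, s$cme, 1.11, 115, 180)
  el <- c("C", "C", "F", "H", "H", "H", "H", "C", "O", "H")
  xyz <- rbind(s$cstar, s$cme, s$x, s$h, s$hme, cald, odb, hald)
  q <- c(0.10, -0.18, -0.22, 0.06, 0.06, 0.06, 0.06, 0.40, -0.42, 0.08)
  finish_template(el, xyz, q, "aldehyde template (R)")
}

# 1-fluoroethanol: C*(H)(CH3)(F)(OH)
build_template_alcohol <- function() {
  s <- template_scaffold("F", 1.35)
  o <- s$cstar + 1.43 * s$fg_dir
  hoh <- zmat_place(o, s$cstar, s$cme, 0.96, 108, 180)
  el <- c("C", "C", "F", "H", "H", "H", "H", "O", "H")
  xyz <- rbind(s$cstar, s$cme, s$x, s$h, s$hme, o, hoh)
  q <- c(0.20, -0.18, -0.22, 0.06, 0.06, 0.06, 0.06, -0.55, 0.35)
  finish_template(el, xyz, q, "alcohol template (R)")
}

# but-3-en-2-ol: C*(H)(CH3)(OH)(CH=CH2)
build_template_olef_alcohol <- function() {
  s <- template_scaffold("O", 1.43)
  cvin <- s$cstar + 1.50 * s$fg_dir
  cvin2 <- zmat_place(cvin, s$cstar, s$cme, 1.33, 124, 0)
  hvin <- zmat_place(cvin, s$cstar, s$cme, 1.08, 118, 180)
  hvin2a <- zmat_place(cvin2, cvin, s$cstar, 1.08, 121, 0)
  hvin2b <- zmat_place(cvin2, cvin, s$cstar, 1.08, 121, 180)
  hoh <- zmat_place(s$x, s$cstar, s$cme, 0.96, 108, 180)
  el <- c("C", "C", "O", "H", "H", "H", "H", "C", "C", "H", "H", "H", "H")
  xyz <- rbind(s$cstar, s$cme, s$x, s$h, s$hme, cvin, cvin2, hvin,
               hvin2a, hvin2b, hoh)
  q <- c(0.15, -0.18, -0.55, 0.06, 0.06, 0.06, 0.06, -0.15, -0.25,
         0.10, 0.10, 0.10, 0.35)
  finish_template(el, xyz, q, "olefinic alcohol template (R)")
}

# 2-fluoro methyl ether: C*(H)(CH3)(F)(OCH3)
build_template_ether <- function() {
  s <- template_scaffold("F", 1.35)
  o <- s$cstar + 1.41 * s$fg_dir
  cme2 <- zmat_place(o, s$cstar, s$cme, 1.41, 112, 180)
  hme2 <- rbind(zmat_place(cme2, o, s$cstar, 1.09, tet, 60),
                zmat_place(cme2, o, s$cstar, 1.09, tet, 180),
                zmat_place(cme2, o, s$cstar, 1.09, tet, 300))
  el <- c("C", "C", "F", "H", "H", "H", "H", "O", "C", "H", "H", "H")
  xyz <- rbind(s$cstar, s$cme, s$x, s$h, s$hme, o, cme2, hme2)
  q <- c(0.18, -0.18, -0.22, 0.06, 0.06, 0.06, 0.06, -0.40, 0.02,
         0.12, 0.12, 0.12)
  finish_template(el, xyz, q, "ether template (R)")
}
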