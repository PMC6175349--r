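# --- rigid 6-DOF pose machinery ---------------------------------------------

# rotation matrix from a rotation vector (axis * angle)
rotvec_matrix <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(diag(3))
  rotation_about_axis(v, th)
}

# apply pose = c(t, rv) to base coordinates centered at the origin
pose_coords <- function(base, pose) {
  R <- rotvec_matrix(pose[4:6])
  sweep(base %*% t(R), 2, pose[1:3], "+")
}

# fast interaction-energy closure for a fixed fragment pair under the
# internal model: E(pose of B). Overlaps are capped to keep searches finite.
make_pose_energy <- function(molA, molB, params, cap = 1e6) {
  pa <- resolve_params(molA, params)
  pb <- resolve_params(molB, params)
  ax <- molA$coords
  bx0 <- sweep(molB$coords, 2, colMeans(molB$coords))
  nA <- nrow(ax)
  a2 <- rowSums(ax^2)
  ke <- params$coulomb_constant
  cutoff2 <- if (identical(params$cutoff, "none")) Inf else params$cutoff^2
  if (params$combination_rule == "lorentz_berthelot") {
    sig <- outer(pa$sig, pb$sig, "+") / 2
  } else {
    sig <- sqrt(outer(pa$sig, pb$sig))
  }
  sig6 <- sig^6
  eps4 <- 4 * sqrt(outer(pa$eps, pb$eps))
  qq <- ke * outer(pa$q, pb$q)
  function(pose) {
    # inline Rodrigues rotation (pose[4:6] = axis * angle)
    th2 <- pose[4]^2 + pose[5]^2 + pose[6]^2
    if (th2 < 1e-24) {
      bx <- bx0
    } else {
      th <- sqrt(th2)
      u <- pose[4:6] / th
      K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
      bx <- bx0 %*% t(R)
    }
    bx[, 1] <- bx[, 1] + pose[1]
    bx[, 2] <- bx[, 2] + pose[2]
    bx[, 3] <- bx[, 3] + pose[3]
    d2 <- a2 - 2 * tcrossprod(ax, bx) +
      rep(bx[, 1]^2 + bx[, 2]^2 + bx[, 3]^2, each = nA)
    if (any(d2 < 0.01)) return(cap)
    x <- sig6 / (d2 * d2 * d2)
    e <- eps4 * x * (x - 1) + qq / sqrt(d2)
    tot <- sum(e[d2 <= cutoff2])
    if (tot > cap) cap else tot
  }
}

# derivative-free compass/pattern search on a continuous objective, with
# opportunistic repeated moves along an improving direction
pattern_search <- function(f, x0, step = c(rep(0.4, 3), rep(0.35, 3)),
                           tol = 1e-5, max_iter = 400) {
  x <- x0
  fx <- f(x)
  n <- length(x)
  for (it in seq_len(max_iter)) {
    improved <- FALSE
    for (i in seq_len(n)) {
      for (s in c(1, -1)) {
        repeat {
          xt <- x
          xt[i] <- xt[i] + s * step[i]
          ft <- f(xt)
          if (ft < fx - 1e-13) {
            x <- xt; fx <- ft; improved <- TRUE
          } else break
        }
      }
    }
    if (!improved) {
      step <- step / 2
      if (max(step) < tol) break
    }
  }
  list(par = x, value = fx)
}

# quasi-uniform directions on the unit sphere (Fibonacci lattice)
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (1 + sqrt(5)) * i
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

# prefix-stable low-discrepancy sphere sequence: the first k directions do
# not depend on n, so enlarging n_starts only appends starts
start_directions <- function(n) {
  k <- seq_len(n)
  z <- 2 * ((k * 0.6180339887498949) %% 1) - 1
  az <- 2 * pi * ((k * 0.7548776662466927) %% 1)
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(az), r * sin(az), z)
}

#' Search configuration for the complex screen
#'
#' @param n_starts Number of rigid-body starting poses per pairing
#'   (Fibonacci-sphere placements times seeded orientations).
#' @param seed Integer seed controlling the start orientations; mandatory
#'   for reproducibility.
#' @param dedup_rmsd Candidates within this RMSD (Angstrom) after optimal
#'   alignment are merged, keeping the lower-energy one.
#' @param tol Pattern-search step-size convergence tolerance.
#' @return List of class \code{"search_config"}.
#' @export
search_config <- function(n_starts = 64, seed = 7, dedup_rmsd = 0.25,
                          tol = 1e-5) {
  stopifnot(n_starts >= 1, is.numeric(seed))
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 dedup_rmsd = dedup_rmsd, tol = tol),
            class = "search_config")
}

#' Find low-energy rigid bimolecular complex geometries
#'
#' Multi-start rigid-body search for local minima of the interaction energy
#' of two rigid monomers: molecule A stays fixed, molecule B is optimized
#' over its 6 pose degrees of freedom (rotation + translation) by a
#' derivative-free pattern search, from \code{n_starts} seeded starting
#' poses placed on a Fibonacci sphere around A with randomized orientations.
#' Candidates are deduplicated by aligned RMSD and returned sorted by
#' energy. Monomer internal geometry is exactly preserved (rigid search).
#'
#' @param molA,molB \code{\link{molecule}} monomers with charges/types.
#' @param engine An \code{"energy_engine"}; the internal engine takes a fast
#'   path, any other engine is evaluated through its contract. Engine
#'   failures on a start discard that start with a warning.
#' @param config A \code{\link{search_config}}.
#' @return A list of candidates, each a list with \code{geometry} (merged
#'   complex, A atoms first), \code{energy} (kcal/mol), \code{size_R}
#'   (Angstrom), \code{pose}, and \code{start_id}; sorted ascending by
#'   energy.
#' @details Only bound candidates are returned: poses whose closest
#'   inter-fragment atom pair is farther than 5 Angstrom are discarded.
#'   With a finite cutoff and partial charges, hard truncation creates
#'   shallow artificial wells at the cutoff edge (only part of a neutral
#'   fragment's charges are inside the sphere); such separated poses are
#'   not complexes and are excluded by the contact criterion.
#' @export
find_complex_minima <- function(molA, molB, engine = lj_engine(),
                                config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  n_starts <- config$n_starts
  bx0 <- sweep(molB$coords, 2, colMeans(molB$coords))
  if (!is.null(engine$params)) {
    efun <- make_pose_energy(molA, molB, engine$params)
  } else {
    molB0 <- molB; molB0$coords <- bx0
    efun <- function(pose) {
      mb <- molB0; mb$coords <- pose_coords(bx0, pose)
      tryCatch(engine$energy(molA, mb), error = function(e) NA_real_)
    }
  }
  ca <- colMeans(molA$coords)
  d0 <- 0.5 * (max_extent_safe(molA) + max_extent_safe(molB)) + 3.0
  dirs <- start_directions(n_starts)
  set.seed(config$seed)
  orients <- matrix(stats::runif(3 * n_starts, -pi, pi), ncol = 3,
                    byrow = TRUE)
  # two-stage search: coarse polish of every start, then full refinement of
  # the distinct low-energy candidates
  coarse_tol <- max(config$tol, 2e-3)
  coarse <- list()
  n_fail <- 0L
  for (k in seq_len(n_starts)) {
    pose0 <- c(ca + d0 * dirs[k, ], orients[k, ])
    e0 <- efun(pose0)
    if (!is.finite(e0)) { n_fail <- n_fail + 1L; next }
    opt <- pattern_search(efun, pose0, tol = coarse_tol)
    if (!is.finite(opt$value)) { n_fail <- n_fail + 1L; next }
    coarse[[length(coarse) + 1]] <- list(pose = opt$par, energy = opt$value,
                                         start_id = k)
  }
  # keep only candidates in molecular contact (see Details)
  ax <- molA$coords
  min_sep <- function(pose) {
    bx <- pose_coords(bx0, pose)
    sqrt(min(outer(rowSums(ax^2), rowSums(bx^2), "+") -
               2 * tcrossprod(ax, bx)))
  }
  if (length(coarse) > 0) {
    in_contact <- vapply(coarse, function(cd) min_sep(cd$pose) <= 5.0,
                         logical(1))
    if (any(in_contact)) coarse <- coarse[in_contact]
    else warning("no bound candidate found; returning separated poses")
  }
  if (length(coarse) > 0 && coarse_tol > config$tol) {
    ord <- order(vapply(coarse, `[[`, 0, "energy"))
    n_refine <- min(length(coarse), max(12L, ceiling(n_starts / 4)))
    for (idx in ord[seq_len(n_refine)]) {
      opt <- pattern_search(efun, coarse[[idx]]$pose,
                            step = rep(2 * coarse_tol, 6), tol = config$tol)
      coarse[[idx]]$pose <- opt$par
      coarse[[idx]]$energy <- opt$value
    }
  }
  cands <- lapply(coarse, function(cd) {
    mb <- molB
    mb$coords <- pose_coords(bx0, cd$pose)
    geom <- merge_molecules(molA, mb)
    list(geometry = geom, energy = cd$energy, size_R = max_extent(geom),
         pose = cd$pose, start_id = cd$start_id)
  })
  if (n_fail > 0)
    warning(n_fail, " of ", n_starts, " starts discarded (engine failure)")
  if (length(cands) == 0) stop("all starting poses failed")
  cands <- cands[order(vapply(cands, `[[`, 0, "energy"),
                       vapply(cands, `[[`, 0, "size_R"),
                       vapply(cands, `[[`, 0, "start_id"))]
  dedup_candidates(cands, config$dedup_rmsd)
}

max_extent_safe <- function(mol)
  if (n_atoms(mol) >= 2) max_extent(mol) else 0

# merge candidates whose complexes superimpose within rmsd_tol
dedup_candidates <- function(cands, rmsd_tol) {
  keep <- list()
  for (cand in cands) {
    dup <- FALSE
    for (kc in keep) {
      if (abs(kc$energy - cand$energy) > 0.5) next
      r <- tryCatch(kabsch_align(kc$geometry, cand$geometry)$rmsd,
                    error = function(e) Inf)
      if (r < rmsd_tol) { dup <- TRUE; break }
    }
    if (!dup) keep[[length(keep) + 1]] <- cand
  }
  keep
}

#' Select the best complex candidate
#'
#' The lowest-energy candidate; ties are broken by smaller complex size,
#' then by start id.
#'
#' @param candidates Non-empty candidate list from
#'   \code{\link{find_complex_minima}}.
#' @return A single candidate.
#' @export
best_complex <- function(candidates) {
  if (length(candidates) == 0) stop("empty candidate list")
  ord <- order(vapply(candidates, `[[`, 0, "energy"),
               vapply(candidates, `[[`, 0, "size_R"),
               vapply(candidates, `[[`, 0, "start_id"))
  candidates[[ord[1]]]
}

#' Opposite- vs same-chirality pairing deltas
#'
#' Runs the complex search for the opposite-chirality (RS) and the
#' same-chirality (SS) pairing of a target/partner combination and reports
#' the energy and size differences
#' \eqn{\Delta E = E_{RS} - E_{SS}} and \eqn{\Delta R = R_{RS} - R_{SS}},
#' each taken between the lowest minima of the two pairings. A positive
#' \eqn{\Delta R} means the opposite-chirality complex is larger.
#'
#' @param molA_R,molA_S The two enantiomers of monomer A (mirror images).
#' @param molB_S The S enantiomer of monomer B.
#' @param engine An \code{"energy_engine"}.
#' @param config A \code{\link{search_config}}.
#' @param combo_label Text label for the combination.
#' @return A one-row data.frame with columns \code{combo_label},
#'   \code{E_RS}, \code{E_SS}, \code{R_RS}, \code{R_SS}, \code{delta_E},
#'   \code{delta_R}.
#' @export
pairing_deltas <- function(molA_R, molA_S, molB_S, engine = lj_engine(),
                           config = search_config(),
                           combo_label = "A-B") {
  chk <- kabsch_align_mirror_ok(molA_R, molA_S)
  if (!chk)
    warning("molA_R does not superimpose on mirror(molA_S); ",
            "pairing labels may be inconsistent")
  rs <- best_complex(find_complex_minima(molA_R, molB_S, engine, config))
  ss <- best_complex(find_complex_minima(molA_S, molB_S, engine, config))
  data.frame(combo_label = combo_label,
             E_RS = rs$energy, E_SS = ss$energy,
             R_RS = rs$size_R, R_SS = ss$size_R,
             delta_E = rs$energy - ss$energy,
             delta_R = rs$size_R - ss$size_R,
             stringsAsFactors = FALSE)
}

kabsch_align_mirror_ok <- function(molA_R, molA_S, tol = 1e-6) {
  if (n_atoms(molA_R) != n_atoms(molA_S)) return(FALSE)
  r <- tryCatch(kabsch_align(molA_R, mirror(molA_S))$rmsd,
                error = function(e) Inf)
  r < tol
}

#' Screen all bimolecular combinations of a chiral template library
#'
#' Evaluates every unordered combination (including self-pairings) of a
#' library of chiral monomers: for each combination the opposite-chirality
#' and same-chirality complexes are searched and the size/energy deltas
#' reported, one row per combination. A library of 5 templates yields the
#' canonical 15-row screening table.
#'
#' @param library A list of entries with fields \code{name}, \code{R} and
#'   \code{S}, as produced by \code{\link{generate_template_library}}.
#' @param engine An \code{"energy_engine"}.
#' @param config A \code{\link{search_config}}.
#' @return A data.frame with one row per combination; monomers failing the
#'   chirality witness are flagged in an \code{achiral} column (with a
#'   warning).
#' @export
screen_matrix <- function(library, engine = lj_engine(),
                          config = search_config()) {
  stopifnot(length(library) >= 2)
  n <- length(library)
  rows <- list()
  flags <- vapply(library, function(e)
    chirality_check(e$R)$achiral, logical(1))
  if (any(flags))
    warning("achiral monomer(s) in library: ",
            paste(vapply(library[flags], `[[`, "", "name"), collapse = ", "))
  for (i in seq_len(n)) for (j in i:n) {
    a <- library[[i]]; b <- library[[j]]
    lab <- paste(a$name, b$name, sep = "-")
    row <- pairing_deltas(a$R, a$S, b$S, engine, config, combo_label = lab)
    row$achiral <- flags[i] || flags[j]
    rows[[length(rows) + 1]] <- row
  }
  do.call(rbind, rows)
}
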