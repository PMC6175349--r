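kB_KCAL <- 0.0019872  # Boltzmann constant, kcal/(mol K)

#' Rigid scan protocol
#'
#' Settings for the constrained propagation scan: the molecule's center of
#' mass is translated along the membrane normal through the pore center on a
#' regular grid, with both pore and molecule kept rigid and no rotation
#' allowed. The zero of energy is the infinitely separated pair.
#'
#' @param step Grid spacing in Angstrom (default 0.25).
#' @param z_range Scan range along the normal, Angstrom.
#' @param orientation Optional \code{\link{rigid_transform}} applied to the
#'   molecule (about its center of mass) before scanning, fixing its axis.
#' @param cap Overlap energy cap in kcal/mol: energies above it are clamped
#'   and flagged so that splines stay finite near hard-core overlap.
#' @return List of class \code{"scan_protocol"}.
#' @export
scan_protocol <- function(step = 0.25, z_range = c(-8, 8),
                          orientation = NULL, cap = 1e4) {
  stopifnot(step > 0, length(z_range) == 2, z_range[1] < z_range[2])
  structure(list(step = step, z_range = z_range, orientation = orientation,
                 rigid = TRUE, reference = "infinite separation", cap = cap),
            class = "scan_protocol")
}

#' Rigid constrained energy scan through a pore
#'
#' For each grid point z, the rigid molecule's center of mass is placed at
#' \code{pore$center + z * pore$normal} (fixed orientation, no rotation) and
#' the pore-molecule interaction energy is evaluated, referenced to infinite
#' separation. The reference is realized deterministically by an evaluation
#' with the molecule displaced to 3 x (cutoff + both extents) along the
#' normal, where the internal engine is exactly zero. Overlapping geometries
#' are capped, not fatal. Samples are interpolated by a cubic spline and
#' extrema classified.
#'
#' @param pore A \code{\link{pore_model}}, or \code{NULL} for a free
#'   molecule (all energies zero).
#' @param mol The target \code{\link{molecule}}.
#' @param protocol A \code{\link{scan_protocol}}.
#' @param engine An \code{"energy_engine"}.
#' @return An \code{"energy_profile"}: list with \code{z}, \code{energy},
#'   \code{capped} (logical per point), \code{spline}, \code{extrema}
#'   (data.frame z/energy/kind) and \code{pathway}
#'   (\code{\link{find_extrema}} output).
#' @export
rigid_scan <- function(pore, mol, protocol = scan_protocol(),
                       engine = lj_engine()) {
  stopifnot(inherits(protocol, "scan_protocol"))
  z <- seq(protocol$z_range[1], protocol$z_range[2], by = protocol$step)
  if (is.null(pore)) {
    return(energy_profile(z, rep(0, length(z)), capped = rep(FALSE, length(z))))
  }
  m <- mol
  if (!is.null(protocol$orientation)) {
    com0 <- center_of_mass(m)
    m$coords <- sweep(m$coords, 2, com0)
    m <- apply_transform(m, protocol$orientation)
    m$coords <- sweep(m$coords, 2, com0, "+")
  }
  com <- center_of_mass(m)
  base <- sweep(m$coords, 2, com)        # molecule with COM at origin
  pmol <- pore$structure
  cap <- protocol$cap
  eval_at <- function(zi) {
    mm <- m
    mm$coords <- sweep(base, 2, pore$center + zi * pore$normal, "+")
    tryCatch(engine$energy(pmol, mm), error = function(e) cap)
  }
  cutoff <- if (!is.null(engine$params) &&
                !identical(engine$params$cutoff, "none"))
    engine$params$cutoff else 12
  z_far <- 3 * (cutoff + max_extent_safe(pmol) + max_extent_safe(m))
  e_ref <- eval_at(z_far)
  e <- vapply(z, eval_at, numeric(1)) - e_ref
  capped <- e >= cap - abs(e_ref) - 1e-9
  e[capped] <- cap
  energy_profile(z, e, capped = capped)
}

#' Cubic-spline interpolation of a sampled profile
#'
#' Fits the classic cubic interpolation spline (Forsythe-Malcolm-Moler end
#' conditions, which reproduce cubic polynomials exactly) through the
#' samples. Evaluation is defined on \code{[min(z), max(z)]}.
#'
#' @param z Strictly increasing coordinate grid (>= 4 points).
#' @param energy Sampled energies.
#' @return A spline function \code{f(z, deriv = 0)}.
#' @export
interpolate_profile <- function(z, energy) {
  if (length(z) < 4) stop("need at least 4 points for a cubic spline")
  if (anyDuplicated(z) || is.unsorted(z, strictly = TRUE))
    stop("z must be strictly increasing without duplicates")
  stats::splinefun(z, energy, method = "fmm")
}

#' Energy profile container
#'
#' Bundles a sampled propagation profile with its spline interpolant and
#' classified extrema.
#'
#' @param z Sampled coordinates (Angstrom).
#' @param energy Energies (kcal/mol), zero-referenced to infinite
#'   separation.
#' @param capped Logical per-point overlap-cap flags.
#' @return List of class \code{"energy_profile"}.
#' @export
energy_profile <- function(z, energy, capped = rep(FALSE, length(z))) {
  stopifnot(length(z) == length(energy), all(is.finite(energy)))
  sp <- interpolate_profile(z, energy)
  prof <- structure(list(z = z, energy = energy, capped = capped,
                         spline = sp, extrema = NULL, pathway = NULL),
                    class = "energy_profile")
  prof$pathway <- find_extrema(prof)
  prof$extrema <- prof$pathway$extrema
  prof
}

#' @export
print.energy_profile <- function(x, ...) {
  cat(sprintf("energy_profile: %d points on [%.2f, %.2f] A; min %.3f, max %.3f kcal/mol\n",
              length(x$z), min(x$z), max(x$z), min(x$energy), max(x$energy)))
  if (!is.null(x$extrema) && nrow(x$extrema) > 0) {
    cat("extrema:\n"); print(x$extrema, row.names = FALSE)
  }
  invisible(x)
}

#' Locate and classify profile extrema on the pathway schema
#'
#' Finds interior extrema of the spline by root-finding on its derivative,
#' classifies them by the second derivative, and maps them in z-order onto
#' the five-slot propagation pathway schema: left minimum, 1st transition
#' state, intermediate, 2nd transition state, right minimum. Missing slots
#' are absent (\code{NULL}); the rate-determining step is the highest
#' transition state.
#'
#' @param profile An \code{"energy_profile"}, or anything with \code{z} and
#'   \code{spline} fields.
#' @return List of class \code{"pathway_extrema"} with fields
#'   \code{left_minimum}, \code{ts1}, \code{intermediate}, \code{ts2},
#'   \code{right_minimum} (each \code{c(z =, energy =)} or \code{NULL}),
#'   \code{rate_determining}, and \code{extrema}, a data.frame of all
#'   interior extrema.
#' @export
find_extrema <- function(profile) {
  sp <- profile$spline
  zr <- range(profile$z)
  grid <- seq(zr[1], zr[2], length.out = max(2001L, 8L * length(profile$z)))
  d1 <- sp(grid, deriv = 1)
  ext_z <- numeric(0)
  sgn <- sign(d1)
  # sign changes, treating exact zeros of the derivative as crossings
  changes <- which(sgn[-1] != sgn[-length(sgn)])
  for (i in changes) {
    f1 <- d1[i]; f2 <- d1[i + 1]
    root <- if (f1 == 0) grid[i] else if (f2 == 0) grid[i + 1] else
      if (f1 * f2 < 0) tryCatch(
        stats::uniroot(function(z) sp(z, deriv = 1),
                       c(grid[i], grid[i + 1]), tol = 1e-12)$root,
        error = function(e) (grid[i] + grid[i + 1]) / 2)
      else NA_real_
    if (!is.na(root) && root >= grid[i] - 1e-9 && root <= grid[i + 1] + 1e-9)
      ext_z <- c(ext_z, root)
  }
  # drop duplicates (a zero at a grid point borders two intervals) and
  # boundary artefacts within numerical reach of the ends
  ext_z <- sort(ext_z)
  if (length(ext_z) > 1)
    ext_z <- ext_z[c(TRUE, diff(ext_z) > 1e-8)]
  ext_z <- ext_z[ext_z > zr[1] + 1e-9 & ext_z < zr[2] - 1e-9]
  kind <- ifelse(vapply(ext_z, function(z) sp(z, deriv = 2), 0) > 0,
                 "minimum", "maximum")
  ext <- data.frame(z = ext_z, energy = sp(ext_z), kind = kind,
                    stringsAsFactors = FALSE)
  ext <- ext[order(ext$z), , drop = FALSE]
  slot <- function(row) if (is.null(row)) NULL else
    c(z = row$z, energy = row$energy)
  mins <- ext[ext$kind == "minimum", , drop = FALSE]
  maxs <- ext[ext$kind == "maximum", , drop = FALSE]
  ts1 <- if (nrow(maxs) >= 1) maxs[1, ] else NULL
  ts2 <- if (nrow(maxs) >= 2) maxs[2, ] else NULL
  left <- NULL; inter <- NULL; right <- NULL
  if (nrow(mins) > 0) {
    if (is.null(ts1)) {
      left <- mins[1, ]
      if (nrow(mins) > 1) right <- mins[nrow(mins), ]
    } else {
      lm <- mins[mins$z < ts1$z, , drop = FALSE]
      if (nrow(lm) > 0) left <- lm[1, ]
      last_max_z <- maxs$z[nrow(maxs)]
      rm_ <- mins[mins$z > last_max_z, , drop = FALSE]
      if (nrow(rm_) > 0) right <- rm_[nrow(rm_), ]
      if (!is.null(ts2)) {
        im <- mins[mins$z > ts1$z & mins$z < ts2$z, , drop = FALSE]
        if (nrow(im) > 0) inter <- im[which.min(im$energy), ]
      }
    }
  }
  rd <- if (nrow(maxs) > 0) maxs[which.max(maxs$energy), ] else NULL
  structure(list(left_minimum = slot(left), ts1 = slot(ts1),
                 intermediate = slot(inter), ts2 = slot(ts2),
                 right_minimum = slot(right), rate_determining = slot(rd),
                 extrema = ext),
            class = "pathway_extrema")
}

# --- nudged elastic band -----------------------------------------------------

#' Shipped two-dimensional double-well test surface
#'
#' \eqn{E(x, y) = (x^2 - 1)^2 + (y - 0.3 x^2)^2}: two minima at
#' (+/-1, 0.3) with E = 0, connected by a curved minimum-energy path over a
#' saddle at (0, 0) with E = 1. Used as the analytic benchmark for the band
#' optimizer.
#'
#' @param x Numeric vector of length 2, or a matrix with 2 columns.
#' @return Energy value(s).
#' @export
double_well_2d <- function(x) {
  if (is.matrix(x)) {
    (x[, 1]^2 - 1)^2 + (x[, 2] - 0.3 * x[, 1]^2)^2
  } else {
    (x[1]^2 - 1)^2 + (x[2] - 0.3 * x[1]^2)^2
  }
}

# central finite-difference gradient
fd_grad <- function(f, x, h = 1e-5) {
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + h
    xm <- x; xm[i] <- xm[i] - h
    g[i] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

#' Nudged elastic band on a generic coordinate space
#'
#' Improved-tangent NEB: a chain of images between two endpoint minima is
#' relaxed under the true force perpendicular to the path plus a spring
#' force along it, using finite-difference gradients and a projected
#' velocity (quick-min) integrator. A climbing image is optional. The
#' saddle estimate is the maximum of a cubic spline of energy over
#' normalized arc length.
#'
#' @param energy_fn Function of a coordinate vector returning an energy.
#' @param x0,x1 Endpoint coordinate vectors (locally minimized geometries).
#' @param n_images Total images including endpoints (>= 3).
#' @param k_spring Spring constant.
#' @param climbing Use a climbing image for the highest interior image.
#' @param max_iter Iteration budget.
#' @param f_tol Convergence threshold on the maximum perpendicular force
#'   component.
#' @param step0 Initial integrator time step.
#' @return List with \code{images} (matrix, one row per image),
#'   \code{energies}, \code{converged}, \code{saddle} (c(s, energy)) and
#'   \code{pathway} (\code{\link{find_extrema}} over arc length).
#' @export
neb_band <- function(energy_fn, x0, x1, n_images = 11, k_spring = 1,
                     climbing = FALSE, max_iter = 500, f_tol = 1e-3,
                     step0 = 0.05) {
  stopifnot(n_images >= 3, length(x0) == length(x1))
  n <- n_images; d <- length(x0)
  lam <- seq(0, 1, length.out = n)
  X <- t(vapply(lam, function(a) (1 - a) * x0 + a * x1, numeric(d)))
  if (max(abs(x1 - x0)) < 1e-12) {
    e <- energy_fn(x0)
    return(list(images = X, energies = rep(e, n), converged = TRUE,
                saddle = c(s = 0, energy = e), pathway = NULL))
  }
  V <- matrix(0, n, d)
  dt <- step0
  conv <- FALSE
  for (iter in seq_len(max_iter)) {
    E <- apply(X, 1, energy_fn)
    Fmat <- matrix(0, n, d)
    fmax <- 0
    i_cl <- if (climbing) which.max(E[2:(n - 1)]) + 1L else 0L
    for (i in 2:(n - 1)) {
      g <- fd_grad(energy_fn, X[i, ])
      # improved tangent (upwind, energy-weighted at extrema)
      dp <- X[i + 1, ] - X[i, ]
      dm <- X[i, ] - X[i - 1, ]
      if (E[i + 1] > E[i] && E[i] > E[i - 1]) {
        tau <- dp
      } else if (E[i + 1] < E[i] && E[i] < E[i - 1]) {
        tau <- dm
      } else {
        dEmax <- max(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        dEmin <- min(abs(E[i + 1] - E[i]), abs(E[i - 1] - E[i]))
        tau <- if (E[i + 1] > E[i - 1]) dp * dEmax + dm * dEmin
               else dp * dEmin + dm * dEmax
      }
      tau <- tau / sqrt(sum(tau^2))
      f_perp <- -(g - sum(g * tau) * tau)
      if (climbing && i == i_cl) {
        Fmat[i, ] <- -g + 2 * sum(g * tau) * tau
      } else {
        f_spring <- k_spring * (sqrt(sum(dp^2)) - sqrt(sum(dm^2))) * tau
        Fmat[i, ] <- f_perp + f_spring
      }
      fmax <- max(fmax, max(abs(f_perp)))
    }
    if (fmax < f_tol) { conv <- TRUE; break }
    # quick-min: keep velocity only along the force
    for (i in 2:(n - 1)) {
      f <- Fmat[i, ]
      vf <- sum(V[i, ] * f)
      V[i, ] <- if (vf > 0) vf * f / sum(f^2 + 1e-30) else 0 * f
      V[i, ] <- V[i, ] + dt * f
      X[i, ] <- X[i, ] + dt * V[i, ]
    }
  }
  E <- apply(X, 1, energy_fn)
  if (!conv)
    warning("NEB not converged within ", max_iter,
            " iterations (partial result)")
  # arc-length parameterization and spline saddle estimate
  seg <- sqrt(rowSums((X[-1, , drop = FALSE] - X[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(seg))
  if (max(s) > 0) s <- s / max(s)
  pathway <- NULL
  saddle <- c(s = s[which.max(E)], energy = max(E))
  if (n >= 4 && !anyDuplicated(s)) {
    prof <- energy_profile(s, E)
    pathway <- prof$pathway
    if (!is.null(pathway$rate_determining))
      saddle <- c(s = unname(pathway$rate_determining["z"]),
                  energy = unname(pathway$rate_determining["energy"]))
  }
  list(images = X, energies = E, converged = conv, saddle = saddle,
       pathway = pathway)
}

#' Nudged elastic band for a rigid molecule in a frozen pore
#'
#' Relaxes a band of rigid-molecule poses (6 degrees of freedom per image:
#' translation plus rotation vector, relative to the frozen pore) between
#' two endpoint poses.
#'
#' @param pore A \code{\link{pore_model}}.
#' @param mol The target \code{\link{molecule}}.
#' @param pose0,pose1 Endpoint poses \code{c(tx, ty, tz, rx, ry, rz)} (see
#'   \code{\link{find_complex_minima}} for the pose convention; rotation
#'   about the molecule's center of mass).
#' @param engine An \code{"energy_engine"}.
#' @param n_images,k_spring,... Passed to \code{\link{neb_band}}.
#' @return The \code{\link{neb_band}} result, with energies referenced to
#'   infinite separation.
#' @export
neb_path <- function(pore, mol, pose0, pose1, engine = lj_engine(),
                     n_images = 11, k_spring = 1, ...) {
  com <- center_of_mass(mol)
  base <- sweep(mol$coords, 2, com)
  cap <- 1e4
  efun <- function(pose) {
    mm <- mol
    mm$coords <- pose_coords(base, pose)
    tryCatch(engine$energy(pore$structure, mm), error = function(e) cap)
  }
  cutoff <- if (!is.null(engine$params) &&
                !identical(engine$params$cutoff, "none"))
    engine$params$cutoff else 12
  z_far <- 3 * (cutoff + max_extent_safe(pore$structure) +
                  max_extent_safe(mol))
  e_ref <- efun(c(pore$center + z_far * pore$normal, 0, 0, 0))
  res <- neb_band(efun, pose0, pose1, n_images = n_images,
                  k_spring = k_spring, ...)
  res$energies <- res$energies - e_ref
  res$saddle["energy"] <- res$saddle["energy"] - e_ref
  res
}

# --- selectivity / permeance -------------------------------------------------

rate_barrier <- function(pathway) {
  if (inherits(pathway, "energy_profile")) pathway <- pathway$pathway
  if (inherits(pathway, "pathway_extrema")) {
    rd <- pathway$rate_determining
    if (is.null(rd)) stop("pathway has no rate-determining barrier")
    # barrier from the preceding minimum, when one exists
    mins <- pathway$extrema[pathway$extrema$kind == "minimum" &
                              pathway$extrema$z < rd["z"], , drop = FALSE]
    rel <- if (nrow(mins) > 0) rd["energy"] - min(mins$energy)
           else NA_real_
    return(c(absolute = unname(rd["energy"]), relative = unname(rel)))
  }
  if (is.numeric(pathway) && length(pathway) == 1)
    return(c(absolute = pathway, relative = NA_real_))
  stop("cannot extract a barrier from this pathway object")
}

#' Boltzmann selectivity estimate from two pathway barriers
#'
#' Maps the difference between the rate-determining barriers of two
#' propagation pathways (e.g. the two enantiomers of a target) onto a
#' Boltzmann rate ratio \eqn{exp(-(\Delta\Delta E)/(k_B T))}. Barriers are
#' reported both from the shared zero of energy (separated species) and
#' from each pathway's preceding minimum.
#'
#' @param pathway_A,pathway_B \code{"energy_profile"} or
#'   \code{"pathway_extrema"} objects (or bare barrier heights in kcal/mol).
#' @param temperature Temperature in K (default 298.15).
#' @return List of class \code{"selectivity_estimate"} with
#'   \code{barrier_A}, \code{barrier_B} (absolute and relative conventions),
#'   \code{ddE} (kcal/mol, absolute convention), \code{ddE_relative},
#'   \code{temperature} and \code{ratio}.
#' @export
selectivity_estimate <- function(pathway_A, pathway_B,
                                 temperature = 298.15) {
  ba <- rate_barrier(pathway_A)
  bb <- rate_barrier(pathway_B)
  dd <- ba["absolute"] - bb["absolute"]
  ddr <- ba["relative"] - bb["relative"]
  structure(list(barrier_A = ba, barrier_B = bb,
                 ddE = unname(dd), ddE_relative = unname(ddr),
                 temperature = temperature,
                 ratio = exp(-unname(dd) / (kB_KCAL * temperature))),
            class = "selectivity_estimate")
}

#' Boltzmann permeance indicator for a single pathway
#'
#' \eqn{exp(-max(0, barrier)/(k_B T))} with the barrier taken from the
#' rate-determining step measured from the shared zero: a dimensionless,
#' monotone-decreasing indicator of how permeable a pore is to the target.
#'
#' @param pathway As in \code{\link{selectivity_estimate}}.
#' @param temperature Temperature in K.
#' @return Dimensionless indicator in (0, 1].
#' @export
permeance_indicator <- function(pathway, temperature = 298.15) {
  b <- rate_barrier(pathway)["absolute"]
  exp(-max(0, b) / (kB_KCAL * temperature))
}

#' Write an energy profile as CSV
#'
#' Columns: z, energy, capped, is_extremum, kind.
#'
#' @param profile An \code{"energy_profile"}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_profile <- function(profile, path) {
  is_ext <- rep(FALSE, length(profile$z))
  kind <- rep("", length(profile$z))
  if (!is.null(profile$extrema) && nrow(profile$extrema) > 0) {
    for (i in seq_len(nrow(profile$extrema))) {
      j <- which.min(abs(profile$z - profile$extrema$z[i]))
      is_ext[j] <- TRUE
      kind[j] <- profile$extrema$kind[i]
    }
  }
  utils::write.csv(
    data.frame(z = profile$z, energy = profile$energy,
               capped = profile$capped, is_extremum = is_ext, kind = kind),
    path, row.names = FALSE)
  invisible(path)
}
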