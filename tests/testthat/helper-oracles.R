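# Independent oracles used across the suite. The energy oracle re-implements
# the nonbonded model as a plain scalar double loop (no vectorization, no
# shared code with the package's evaluators); the search oracles are pure
# grid searches.

# double-loop LJ + Coulomb energy, optionally without cutoff
oracle_energy <- function(molA, molB, params = nb_params(), cutoff = params$cutoff) {
  tab <- params$table
  row_of <- function(mol, i) {
    ty <- if (!is.null(mol$atom_types)) mol$atom_types[i] else mol$elements[i]
    k <- match(ty, tab$type)
    if (is.na(k)) k <- match(mol$elements[i], tab$type)
    q <- if (!is.null(mol$charges)) mol$charges[i] else tab$charge[k]
    c(eps = tab$epsilon[k], sig = tab$sigma[k], q = q)
  }
  tot <- 0
  for (i in seq_len(n_atoms(molA))) {
    pi_ <- row_of(molA, i)
    for (j in seq_len(n_atoms(molB))) {
      pj <- row_of(molB, j)
      r <- sqrt(sum((molA$coords[i, ] - molB$coords[j, ])^2))
      if (!identical(cutoff, "none") && r > cutoff) next
      if (params$combination_rule == "lorentz_berthelot") {
        sig <- (pi_["sig"] + pj["sig"]) / 2
      } else {
        sig <- sqrt(pi_["sig"] * pj["sig"])
      }
      eps <- sqrt(pi_["eps"] * pj["eps"])
      tot <- tot + 4 * eps * ((sig / r)^12 - (sig / r)^6) +
        332.0636 * pi_["q"] * pj["q"] / r
    }
  }
  unname(tot)
}

# place molB (centered at its centroid) at pose = c(t, rotation vector)
oracle_pose <- function(molB, pose) {
  b <- sweep(molB$coords, 2, colMeans(molB$coords))
  th <- sqrt(sum(pose[4:6]^2))
  R <- if (th < 1e-14) diag(3) else rotation_about_axis(pose[4:6], th)
  out <- molB
  out$coords <- sweep(b %*% t(R), 2, pose[1:3], "+")
  out
}

# dense 6-DOF grid search for the minimum interaction energy of a rigid
# pair: a coarse global stage (directions x orientations x separations)
# followed by factorial zoom refinement around the best grid point
oracle_grid_min <- function(molA, molB, params = nb_params(),
                            n_dir = 64, n_axis = 13,
                            angles = c(0, 0.6, 1.2, 1.8, 2.4, 3.0),
                            zoom_stages = 9) {
  # grid search on the same engine as the implementation; only the search
  # strategy (pure factorial grids) is independent
  efun <- chirasieve:::make_pose_energy(molA, molB, params, cap = 1e6)
  fib <- function(n) {
    i <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * i
    z <- 1 - 2 * i / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
  }
  dirs <- fib(n_dir)
  axes <- fib(n_axis)
  ca <- colMeans(molA$coords)
  extA <- if (n_atoms(molA) > 1) max(dist(molA$coords)) else 0
  extB <- if (n_atoms(molB) > 1) max(dist(molB$coords)) else 0
  radii <- seq(1.5, 0.5 * (extA + extB) + 6, by = 0.25)
  poses <- NULL; evals <- numeric(0)
  for (kd in seq_len(nrow(dirs))) for (ka in seq_len(nrow(axes)))
    for (ang in angles) {
      rv <- axes[ka, ] * ang
      best_r <- Inf; best_pose <- NULL
      for (r in radii) {
        pose <- c(ca + r * dirs[kd, ], rv)
        e <- efun(pose)
        if (e < best_r) { best_r <- e; best_pose <- pose }
      }
      poses <- rbind(poses, best_pose)
      evals <- c(evals, best_r)
    }
  # zoom the most promising, mutually distinct coarse poses by nested
  # factorial grids, then polish the overall best
  ord <- order(evals)
  picks <- list()
  for (i in ord) {
    if (length(picks) >= 24) break
    p <- poses[i, ]
    distinct <- all(vapply(picks, function(q)
      sqrt(sum((q - p)^2)) > 0.7, logical(1)))
    if (length(picks) == 0 || distinct)
      picks[[length(picks) + 1]] <- p
  }
  zoom <- function(pose, w, npts, stages, shrink) {
    g1 <- seq(-1, 1, length.out = npts)
    pts <- as.matrix(expand.grid(g1, g1, g1, g1, g1, g1))
    e_best <- efun(pose)
    for (st in seq_len(stages)) {
      cand <- sweep(pts %*% diag(w), 2, pose, "+")
      for (m in seq_len(nrow(cand))) {
        e <- efun(cand[m, ])
        if (e < e_best) { e_best <- e; pose <- cand[m, ] }
      }
      w <- w * shrink
    }
    list(pose = pose, energy = e_best)
  }
  best <- NULL; best_e <- Inf
  for (p in picks) {
    z <- zoom(p, c(rep(0.5, 3), rep(0.6, 3)), 3, 14, 0.65)
    if (z$energy < best_e) { best_e <- z$energy; best <- z$pose }
  }
  z <- zoom(best, c(rep(0.05, 3), rep(0.08, 3)), 5, zoom_stages, 0.5)
  best <- z$pose; best_e <- z$energy
  list(energy = best_e, pose = best,
       complex = merge_molecules(molA, oracle_pose(molB, best)))
}

# minimax saddle estimate on a 2D surface by threshold bisection over grid
# connectivity between the two endpoint basins
oracle_grid_saddle <- function(f2d, p0, p1, lim = c(-2, 2, -1.5, 2.5),
                               n = 161, iters = 40) {
  xs <- seq(lim[1], lim[2], length.out = n)
  ys <- seq(lim[3], lim[4], length.out = n)
  E <- outer(xs, ys, function(x, y)
    apply(cbind(as.vector(x), as.vector(y)), 1, f2d))
  idx0 <- c(which.min(abs(xs - p0[1])), which.min(abs(ys - p0[2])))
  idx1 <- c(which.min(abs(xs - p1[1])), which.min(abs(ys - p1[2])))
  connected_below <- function(thr) {
    open <- E <= thr
    if (!open[idx0[1], idx0[2]] || !open[idx1[1], idx1[2]]) return(FALSE)
    seen <- matrix(FALSE, n, n)
    stack <- list(idx0)
    seen[idx0[1], idx0[2]] <- TRUE
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (cur[1] == idx1[1] && cur[2] == idx1[2]) return(TRUE)
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        nx <- cur + d
        if (nx[1] < 1 || nx[1] > n || nx[2] < 1 || nx[2] > n) next
        if (open[nx[1], nx[2]] && !seen[nx[1], nx[2]]) {
          seen[nx[1], nx[2]] <- TRUE
          stack[[length(stack) + 1]] <- nx
        }
      }
    }
    FALSE
  }
  lo <- max(f2d(p0), f2d(p1)); hi <- max(E)
  for (k in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (connected_below(mid)) hi <- mid else lo <- mid
  }
  hi
}

# deterministic random rigid transform for property tests
random_rigid <- function(seed) {
  set.seed(seed)
  ax <- stats::rnorm(3)
  rigid_transform(rotation_about_axis(ax, stats::runif(1, 0, 2 * pi)),
                  stats::runif(3, -5, 5))
}
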