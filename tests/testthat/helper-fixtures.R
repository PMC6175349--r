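# small shared builders for tests

# asymmetric 4-atom set with 4 distinct elements (chiral arrangement)
asym4 <- function() {
  molecule(c("C", "N", "O", "F"),
           rbind(c(0, 0, 0), c(1.4, 0, 0), c(0.3, 1.2, 0.2), c(-0.2, 0.4, 1.1)))
}

# dense rotation-grid brute force for the minimum superposition RMSD of two
# centered structures (proper rotations only), with factorial zoom polish
rmsd_rotation_oracle <- function(A, B) {
  qa <- sweep(A$coords, 2, colMeans(A$coords))
  qb <- sweep(B$coords, 2, colMeans(B$coords))
  rmsd_of <- function(rv) {
    th <- sqrt(sum(rv^2))
    R <- if (th < 1e-14) diag(3) else rotation_about_axis(rv, th)
    sqrt(mean(rowSums((qb %*% t(R) - qa)^2)))
  }
  i <- seq_len(60) - 0.5
  axes <- cbind(sqrt(1 - (1 - 2 * i / 60)^2) * cos(pi * (1 + sqrt(5)) * i),
                sqrt(1 - (1 - 2 * i / 60)^2) * sin(pi * (1 + sqrt(5)) * i),
                1 - 2 * i / 60)
  best <- c(0, 0, 0); best_r <- rmsd_of(best)
  for (k in seq_len(nrow(axes))) for (ang in seq(0.1, pi, by = 0.1)) {
    rv <- axes[k, ] * ang
    r <- rmsd_of(rv)
    if (r < best_r) { best_r <- r; best <- rv }
  }
  g1 <- seq(-1, 1, length.out = 5)
  pts <- as.matrix(expand.grid(g1, g1, g1))
  w <- 0.1
  for (st in 1:12) {
    for (m in seq_len(nrow(pts))) {
      r <- rmsd_of(best + pts[m, ] * w)
      if (r < best_r) { best_r <- r; best <- best + pts[m, ] * w }
    }
    w <- w / 2
  }
  best_r
}

# a diatomic HCl-like probe with a small dipole
diatomic_probe <- function() {
  molecule(c("H", "Cl"), rbind(c(0, 0, 0), c(0, 0, 1.27)),
           charges = c(0.2, -0.2))
}

# deliberately broken engine whose energy depends on a coordinate sign
broken_engine <- function() {
  structure(list(
    name = "broken",
    energy = function(a, b) interaction_energy(a, b) + 0.01 * sign(sum(b$coords[, 3]) + 1e-30),
    has_gradients = FALSE), class = "energy_engine")
}
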