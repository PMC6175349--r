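test_that("a single ring builds benzene with ideal bond lengths", {
  b <- build_graphene_flake(c(0, 0))
  expect_equal(sum(b$elements == "C"), 6)
  expect_equal(sum(b$elements == "H"), 6)
  cc <- b$coords[b$elements == "C", ]
  d <- as.matrix(dist(cc))
  nn <- apply(d + diag(Inf, 6), 1, min)
  expect_lt(max(abs(nn - 1.42)), 1e-9)
})

test_that("the closed 7-ring flake has coronene stoichiometry and sp2 valence", {
  rings <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, -1), c(-1, 1))
  f <- build_graphene_flake(rings)
  expect_equal(sum(f$elements == "C"), 24)
  expect_equal(sum(f$elements == "H"), 12)
  bonds <- chirasieve:::bond_list(f)
  deg <- lengths(bonds)
  expect_true(all(deg[f$elements == "C"] == 3))
  expect_true(all(deg[f$elements == "H"] == 1))
  expect_lt(max(abs(f$coords[, 3])), 1e-6)  # planar
})

test_that("disconnected ring layouts are rejected", {
  expect_error(build_graphene_flake(rbind(c(0, 0), c(3, 0))), "disconnected")
})

test_that("cutting one interior ring creates a 6-hydrogen hole", {
  rings <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0, 1), c(0, -1),
                 c(1, -1), c(-1, 1))
  f <- build_graphene_flake(rings)
  p <- cut_pore(f, matrix(c(0, 0), 1, 2))
  expect_equal(sum(p$structure$elements == "C"),
               sum(f$elements == "C") - 6)
  expect_equal(sum(p$structure$elements == "H"),
               sum(f$elements == "H") + 6)
  expect_equal(length(detect_rim(p)), 12)  # 6 C + 6 rim H
})

test_that("removing no rings returns the unchanged flake flagged non-porous", {
  f <- build_graphene_flake(rbind(c(0, 0), c(1, 0)))
  p <- cut_pore(f, integer(0))
  expect_false(p$porous)
  expect_identical(p$structure$coords, f$coords)
  expect_true(is.na(p$diameter))
})

test_that("cutting a pore twice with the same ring set equals cutting once", {
  hole <- rbind(c(0, 0), c(1, 0), c(0, 1))
  f <- build_graphene_flake(chirasieve:::expand_rings(hole))
  p1 <- cut_pore(f, hole)
  p2 <- cut_pore(p1$structure, hole)
  expect_identical(p1$structure$coords, p2$structure$coords)
  expect_identical(p1$structure$elements, p2$structure$elements)
  expect_equal(p1$diameter, p2$diameter, tolerance = 1e-9)
})

test_that("the graphdiyne unit is three-fold symmetric with sp valence", {
  gd <- build_graphdiyne_pore()
  s <- gd$structure
  expect_lt(max(abs(s$coords[, 3])), 1e-6)
  # rotating by 120 deg about the pore center and re-matching atoms
  rot <- apply_transform(s, rigid_transform(
    rotation_about_axis(c(0, 0, 1), 2 * pi / 3)))
  d2 <- as.matrix(dist(rbind(s$coords, rot$coords)))
  n <- n_atoms(s)
  cross <- d2[seq_len(n), n + seq_len(n)]
  nearest <- apply(cross, 1, min)
  expect_lt(max(nearest), 1e-6)
  # every triple-bond (sp) carbon has exactly two neighbours
  deg <- lengths(chirasieve:::bond_list(s))
  sp <- which(s$elements == "C" & deg == 2)
  expect_equal(length(sp), 12)
  expect_true(all(sp %in% gd$rim_indices))
})

test_that("pore_diameter follows its two conventions on a ring of atoms", {
  ring <- t(vapply(seq(0, 300, by = 60) * pi / 180,
                   function(a) c(3 * cos(a), 3 * sin(a), 0), numeric(3)))
  pm_c <- pore_model(molecule(rep("C", 6), ring), center = c(0, 0, 0),
                     rim_indices = 1:6)
  expect_equal(pore_diameter(pm_c, "geometric"), 6.0, tolerance = 1e-6)
  pm_h <- pore_model(molecule(rep("H", 6), ring), center = c(0, 0, 0),
                     rim_indices = 1:6)
  expect_equal(pore_diameter(pm_h, "vdw"), 6.0 - 2 * 1.20, tolerance = 1e-6)
  expect_error(pore_diameter(pm_h, "banana"))
})

test_that("pore_diameter is rigid-invariant and shrinks when rim moves inward", {
  p <- build_pore("graphene3")
  d0 <- p$diameter
  tr <- random_rigid(11)
  moved <- p
  moved$structure <- apply_transform(p$structure, tr)
  moved$center <- drop(tr$rotation %*% p$center) + tr$translation
  moved$normal <- drop(tr$rotation %*% p$normal)
  expect_equal(pore_diameter(moved, "geometric"), d0, tolerance = 1e-6)

  shrunk <- p
  i <- p$rim_indices[1]
  v <- p$center - shrunk$structure$coords[i, ]
  shrunk$structure$coords[i, ] <- shrunk$structure$coords[i, ] + 0.4 * v
  expect_lte(pore_diameter(shrunk, "geometric"), d0 + 1e-9)
})

test_that("nitrogen substitution removes the hydrogen and widens the opening", {
  p <- build_pore("graphene5")
  sites <- nitrogen_sites(p, "opposite",
                          site = chirasieve:::rim_carbons_with_h(p)[1])
  q <- substitute_nitrogen(p, sites)
  tab_p <- table(p$structure$elements)
  tab_q <- table(q$structure$elements)
  expect_equal(n_atoms(q$structure), n_atoms(p$structure) - 2)
  expect_equal(unname(tab_q["C"]), unname(tab_p["C"]) - 2)
  expect_equal(unname(tab_q["H"]), unname(tab_p["H"]) - 2)
  expect_equal(unname(tab_q["N"]), 2)
  expect_gt(q$diameter, p$diameter)

  expect_identical(substitute_nitrogen(p, integer(0)), p)
  expect_error(substitute_nitrogen(p, 1e6), "not a carbon")
  not_rim <- setdiff(which(p$structure$elements == "C"),
                     p$rim_indices)[1]
  expect_error(substitute_nitrogen(p, not_rim), "not a rim")
})

test_that("detect_rim errors on a pristine flake", {
  f <- build_graphene_flake(rbind(c(0, 0), c(1, 0), c(0, 1)))
  expect_error(detect_rim(f, center = c(1.2, 0.7, 0)), "no hole")
})

test_that("gatekeeper attachment bonds the anchor atom to the rim carbon", {
  p <- build_pore("graphene5")
  g <- attach_gatekeeper(p)
  expect_equal(n_atoms(g$structure), n_atoms(p$structure) - 1 + 11)
  site <- g$gatekeeper_site
  anchor <- g$gatekeeper_atoms[4]  # amine N of the fixture
  d <- sqrt(sum((g$structure$coords[site, ] - g$structure$coords[anchor, ])^2))
  expect_equal(d, 1.40, tolerance = 1e-9)
  expect_identical(g$structure$elements[anchor], "N")
})
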