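test_that("cubic splines interpolate samples and reproduce cubics exactly", {
  z <- seq(-3, 3, by = 0.5)
  f <- function(x) 0.3 * x^3 - x^2 + 2 * x - 1
  sp <- interpolate_profile(z, f(z))
  expect_lt(max(abs(sp(z) - f(z))), 1e-12)
  mids <- head(z, -1) + 0.25
  expect_lt(max(abs(sp(mids) - f(mids))), 1e-9)
  expect_error(interpolate_profile(c(0, 1, 1, 2), 1:4), "strictly increasing")
  expect_error(interpolate_profile(c(0, 1, 2), 1:3), "at least 4")
})

test_that("a 0.25-step spline of sin stays within 1e-3 on [-5, 5]", {
  z <- seq(-5, 5, by = 0.25)
  sp <- interpolate_profile(z, sin(z))
  dense <- seq(-5, 5, by = 0.01)
  expect_lt(max(abs(sp(dense) - sin(dense))), 1e-3)
})

test_that("extrema of the symmetric double well are found at closed-form roots", {
  z <- seq(-4, 4, by = 0.25)
  prof <- energy_profile(z, (z^2 - 4)^2 / 16 - 1)
  ext <- prof$extrema
  expect_equal(nrow(ext), 3)
  expect_equal(sort(ext$z), c(-2, 0, 2), tolerance = 1e-3)
  expect_equal(ext$energy[order(ext$z)], c(-1, 0, -1), tolerance = 1e-3)
  expect_identical(ext$kind[order(ext$z)], c("minimum", "maximum", "minimum"))
  pw <- prof$pathway
  expect_equal(unname(pw$left_minimum["energy"]), -1, tolerance = 1e-3)
  expect_equal(unname(pw$ts1["energy"]), 0, tolerance = 1e-3)
  expect_equal(unname(pw$right_minimum["energy"]), -1, tolerance = 1e-3)
  expect_null(pw$ts2)
  expect_null(pw$intermediate)
})

test_that("a monotone profile has no interior extrema", {
  z <- seq(0, 5, by = 0.25)
  prof <- energy_profile(z, 2 * z + 1)
  expect_equal(nrow(prof$extrema), 0)
  expect_null(prof$pathway$rate_determining)
})

test_that("an asymmetric two-barrier profile fills all five pathway slots", {
  f <- function(z) -cos(2 * z) * (1 + 0.05 * z)
  z <- seq(-3.5, 3.5, by = 0.25)
  prof <- energy_profile(z, f(z))
  pw <- prof$pathway
  for (slot in c("left_minimum", "ts1", "intermediate", "ts2", "right_minimum"))
    expect_false(is.null(pw[[slot]]), label = slot)
  # rate-determining barrier equals the dense-grid argmax of the spline
  dense <- seq(-3.5, 3.5, by = 1e-4)
  vals <- prof$spline(dense)
  expect_equal(unname(pw$rate_determining["energy"]), max(vals),
               tolerance = 1e-6)
  expect_equal(unname(pw$rate_determining["z"]), dense[which.max(vals)],
               tolerance = 1e-3)
  # slots alternate minimum / maximum along z
  zs <- c(pw$left_minimum["z"], pw$ts1["z"], pw$intermediate["z"],
          pw$ts2["z"], pw$right_minimum["z"])
  expect_true(all(diff(zs) > 0))
})

test_that("every sampled scan energy equals an independent re-evaluation", {
  pore <- build_pore("graphene3")
  co2 <- generate_fixture("co2_like")
  proto <- scan_protocol(step = 0.5, z_range = c(-4, 4))
  prof <- rigid_scan(pore, co2, proto, lj_engine())
  base <- sweep(co2$coords, 2, center_of_mass(co2))
  for (k in seq_along(prof$z)) {
    m <- co2
    m$coords <- sweep(base, 2, pore$center + prof$z[k] * pore$normal, "+")
    expect_equal(prof$energy[k], interaction_energy(pore$structure, m),
                 tolerance = 1e-10)
  }
})

test_that("scanning without a pore gives identically zero energies", {
  prof <- rigid_scan(NULL, generate_fixture("co2_like"))
  expect_true(all(prof$energy == 0))
})

test_that("band with identical endpoints collapses to zero barrier", {
  res <- neb_band(double_well_2d, c(-1, 0.3), c(-1, 0.3), n_images = 7)
  expect_true(res$converged)
  expect_equal(unname(res$saddle["energy"]), double_well_2d(c(-1, 0.3)))
})

test_that("the band maximum is never below the endpoint energies", {
  res <- neb_band(double_well_2d, c(-1, 0.3), c(1, 0.3), n_images = 11)
  expect_gte(max(res$energies),
             max(double_well_2d(c(-1, 0.3)), double_well_2d(c(1, 0.3))) - 1e-9)
})

test_that("selectivity and permeance follow the Boltzmann forms", {
  s_eq <- selectivity_estimate(5, 5)
  expect_equal(s_eq$ratio, 1.0)
  s <- selectivity_estimate(6.3645, 5.0, temperature = 298.15)
  expect_equal(s$ddE, 1.3645)
  expect_equal(s$ratio, exp(-1.3645 / (0.0019872 * 298.15)), tolerance = 1e-12)
  expect_equal(s$ratio, 0.1, tolerance = 1e-3)
  s_hot <- selectivity_estimate(6.3645, 5.0, temperature = 1e9)
  expect_equal(s_hot$ratio, 1.0, tolerance = 1e-6)

  expect_equal(permeance_indicator(0), 1.0)
  expect_equal(permeance_indicator(-3), 1.0)  # barrierless
  expect_equal(permeance_indicator(5.925, 298.15),
               exp(-5.925 / (0.0019872 * 298.15)), tolerance = 1e-12)
  expect_equal(permeance_indicator(5.925, 298.15), 4.54e-5, tolerance = 1e-3)
  # the two formulas are mutually consistent for the same barrier difference
  expect_equal(permeance_indicator(7) / permeance_indicator(5),
               selectivity_estimate(7, 5)$ratio, tolerance = 1e-10)
})

test_that("barriers are reported from both conventions", {
  f <- function(z) -cos(2 * z) * (1 + 0.05 * z)
  z <- seq(-3.5, 3.5, by = 0.25)
  prof <- energy_profile(z, f(z))
  s <- selectivity_estimate(prof, prof)
  expect_equal(s$ratio, 1.0)
  expect_true(is.finite(s$barrier_A["relative"]))
  expect_gt(s$barrier_A["relative"], s$barrier_A["absolute"] - 1e-9)
})

test_that("radially dilating a pore never raises the rate-determining barrier", {
  ch4 <- generate_fixture("ch4_like")
  base <- build_pore("graphene3")
  proto <- scan_protocol(step = 0.25, z_range = c(-6, 6))
  barriers <- vapply(c(1.0, 1.1, 1.2, 1.35), function(s) {
    p <- base
    rel <- sweep(p$structure$coords[, 1:2, drop = FALSE], 2, p$center[1:2])
    p$structure$coords[, 1:2] <- sweep(rel * s, 2, p$center[1:2], "+")
    prof <- rigid_scan(p, ch4, proto, lj_engine())
    rd <- prof$pathway$rate_determining
    if (is.null(rd)) -Inf else unname(rd["energy"])
  }, numeric(1))
  expect_true(all(diff(barriers) <= 1e-9))
})

test_that("a larger rigid complex never has a lower barrier than a smaller one", {
  pore <- build_pore("graphene3")
  proto <- scan_protocol(step = 0.25, z_range = c(-6, 6))
  widths <- c(0.0, 1.0, 2.0, 3.0)
  barriers <- vapply(widths, function(w) {
    m <- if (w == 0) molecule("C", matrix(0, 1, 3), charges = 0) else
      molecule(c("C", "C"), rbind(c(-w / 2, 0, 0), c(w / 2, 0, 0)),
               charges = c(0, 0))
    prof <- rigid_scan(pore, m, proto, lj_engine())
    max(prof$energy)
  }, numeric(1))
  expect_true(all(diff(barriers) >= -1e-9))
})

test_that("the free band saddle does not exceed the constrained scan maximum", {
  pore <- build_pore("graphene4")
  co2 <- generate_fixture("co2_like")
  proto <- scan_protocol(step = 0.25, z_range = c(-3, 3))
  prof <- rigid_scan(pore, co2, proto, lj_engine())
  res <- neb_path(pore, co2,
                  c(pore$center - 3 * pore$normal, 0, 0, 0),
                  c(pore$center + 3 * pore$normal, 0, 0, 0),
                  lj_engine(), n_images = 11, max_iter = 300)
  expect_lte(unname(res$saddle["energy"]), max(prof$energy) + 1e-6)
})
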