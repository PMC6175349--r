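test_that("two single-site molecules dock at the LJ minimum", {
  a <- molecule("C", matrix(0, 1, 3), charges = 0)
  b <- molecule("C", matrix(c(6, 0, 0), 1), charges = 0)
  cands <- find_complex_minima(a, b, lj_engine(),
                               search_config(n_starts = 8, seed = 1))
  bc <- best_complex(cands)
  tab <- default_nb_table()
  sig <- tab$sigma[tab$type == "C"]; eps <- tab$epsilon[tab$type == "C"]
  expect_equal(unname(dist(bc$geometry$coords))[1], 2^(1 / 6) * sig,
               tolerance = 1e-4)
  expect_equal(bc$energy, -eps, tolerance = 1e-4)
  # rigid search: monomer geometry is untouched
  expect_identical(bc$geometry$coords[1, ], a$coords[1, ])
})

test_that("best_complex breaks ties by energy, size, then start id", {
  mk <- function(e, r, id) list(geometry = NULL, energy = e, size_R = r,
                                start_id = id)
  expect_equal(best_complex(list(mk(-5, 8, 1)))$energy, -5)
  expect_equal(best_complex(list(mk(-5, 8, 1), mk(-7, 9, 2)))$energy, -7)
  expect_equal(best_complex(list(mk(-5, 8.1, 1), mk(-5, 7.9, 2)))$size_R, 7.9)
  expect_equal(best_complex(list(mk(-5, 8, 2), mk(-5, 8, 1)))$start_id, 1)
  expect_error(best_complex(list()), "empty")
})

test_that("injected energies verify the delta arithmetic exactly", {
  # stub engine: the energy depends only on the chirality (signed volume)
  # of fragment A, so E_RS = -10 and E_SS = -5 by construction
  stub <- structure(list(
    name = "stub",
    energy = function(a, b) {
      v <- det(rbind(a$coords[3, ] - a$coords[1, ],
                     a$coords[4, ] - a$coords[1, ],
                     a$coords[5, ] - a$coords[1, ]))
      if (v < 0) -10 else -5
    },
    has_gradients = FALSE), class = "energy_engine")
  pr <- generate_fixture("chiral_probe")
  ps <- generate_fixture("chiral_probe", "S")
  v_r <- det(rbind(pr$coords[3, ] - pr$coords[1, ],
                   pr$coords[4, ] - pr$coords[1, ],
                   pr$coords[5, ] - pr$coords[1, ]))
  expect_true(v_r < 0)  # the R fixture triggers the -10 branch
  row <- pairing_deltas(pr, ps, ps, stub,
                        search_config(n_starts = 2, seed = 1), "stub")
  expect_identical(row$E_RS, -10)
  expect_identical(row$E_SS, -5)
  expect_identical(row$delta_E, -5)
  expect_identical(row$delta_E, row$E_RS - row$E_SS)
  expect_identical(row$delta_R, row$R_RS - row$R_SS)
})

test_that("mirroring both partners of a candidate preserves energy and size", {
  pr <- generate_fixture("chiral_probe")
  ps <- generate_fixture("chiral_probe", "S")
  eng <- lj_engine()
  cands <- find_complex_minima(pr, ps, eng, search_config(n_starts = 8, seed = 2))
  for (cand in cands[seq_len(min(3, length(cands)))]) {
    nA <- n_atoms(pr)
    fa <- pr; fa$coords <- cand$geometry$coords[seq_len(nA), ]
    fb <- ps; fb$coords <- cand$geometry$coords[-seq_len(nA), ]
    e_m <- eng$energy(mirror(fa), mirror(fb))
    expect_lt(abs(e_m - cand$energy), 1e-8)
    expect_lt(abs(max_extent(mirror(cand$geometry)) - cand$size_R), 1e-12)
  }
})

test_that("best energy is non-increasing in the number of starts", {
  pr <- generate_fixture("chiral_probe")
  ps <- generate_fixture("chiral_probe", "S")
  e_prev <- Inf
  for (ns in c(4, 8, 16, 32)) {
    bc <- best_complex(find_complex_minima(pr, ps, lj_engine(),
                                           search_config(n_starts = ns, seed = 7)))
    expect_lte(bc$energy, e_prev + 1e-9)
    e_prev <- bc$energy
  }
})

test_that("identical seeds give bit-identical screening results", {
  pr <- generate_fixture("chiral_probe")
  ps <- generate_fixture("chiral_probe", "S")
  cfg <- search_config(n_starts = 12, seed = 5)
  r1 <- pairing_deltas(pr, ps, ps, lj_engine(), cfg, "probe")
  r2 <- pairing_deltas(pr, ps, ps, lj_engine(), cfg, "probe")
  expect_identical(r1, r2)
})

test_that("screen_matrix enumerates unordered combinations with repetition", {
  lib2 <- generate_template_library()[c("acid", "alcohol")]
  tab <- screen_matrix(lib2, lj_engine(), search_config(n_starts = 6, seed = 3))
  expect_equal(nrow(tab), 3)
  expect_setequal(tab$combo_label,
                  c("acid-acid", "acid-alcohol", "alcohol-alcohol"))
  expect_equal(tab$delta_E, tab$E_RS - tab$E_SS, tolerance = 1e-12)
  expect_equal(tab$delta_R, tab$R_RS - tab$R_SS, tolerance = 1e-12)
})

test_that("achiral library members are flagged with near-zero deltas", {
  co2 <- generate_fixture("co2_like")
  lib <- list(a = list(name = "a", R = co2, S = co2),
              b = list(name = "b", R = co2, S = co2))
  expect_warning(
    tab <- screen_matrix(lib, lj_engine(), search_config(n_starts = 12, seed = 2)),
    "achiral")
  expect_true(all(tab$achiral))
  expect_lt(max(abs(tab$delta_E)), 1e-4)
  expect_lt(max(abs(tab$delta_R)), 1e-3)
})
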