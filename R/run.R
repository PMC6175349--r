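#' Attach a rigid gatekeeper molecule to a pore rim
#'
#' Replaces a rim hydrogen by a covalent bond to a gatekeeper molecule (by
#' default 1-aminoethanol, bonded through its nitrogen): the rim carbon's
#' hydrogen is deleted and the gatekeeper is placed rigidly with its anchor
#' atom along the former C-H direction at the given bond length, its anchor
#' bond axis aligned with that direction and the rest of the molecule tilted
#' out of the membrane plane. Purely geometric, deterministic placement of
#' the idealized fixture geometry.
#'
#' @param pore A \code{\link{pore_model}}.
#' @param mol Gatekeeper \code{\link{molecule}}; default the R enantiomer of
#'   the 1-aminoethanol fixture.
#' @param site Index of the rim carbon to functionalize; default the first
#'   rim carbon carrying exactly one hydrogen.
#' @param anchor Index of the gatekeeper atom bonded to the rim (default 4,
#'   the amine nitrogen of the fixture).
#' @param bond_length C-N bond length in Angstrom.
#' @param tilt Out-of-plane tilt of the gatekeeper, degrees.
#' @return A \code{\link{pore_model}} whose structure includes the
#'   gatekeeper atoms (appended last); fields \code{gatekeeper_site} and
#'   \code{gatekeeper_atoms} record the attachment.
#' @export
attach_gatekeeper <- function(pore, mol = generate_fixture("aminoethanol"),
                              site = NULL, anchor = 4L, bond_length = 1.40,
                              tilt = 35) {
  stopifnot(inherits(pore, "pore_model"))
  ps <- pore$structure
  bonds <- bond_list(ps)
  rim_c <- rim_carbons_with_h(pore, bonds)
  if (length(rim_c) == 0) stop("no rim carbon with a single hydrogen")
  if (is.null(site)) site <- rim_c[1]
  if (!(site %in% rim_c)) stop("site is not a rim carbon with one hydrogen")
  h <- bonds[[site]][ps$elements[bonds[[site]]] == "H"]
  u <- ps$coords[h, ] - ps$coords[site, ]
  u <- u / sqrt(sum(u^2))
  # tilt the attachment direction out of the membrane plane
  ax <- cross3(u, pore$normal)
  ax <- ax / sqrt(sum(ax^2))
  u_t <- drop(rotation_about_axis(ax, tilt * pi / 180) %*% u)
  target <- ps$coords[site, ] + bond_length * u_t
  # orient the gatekeeper: anchor at target, anchor->neighbour axis along u_t
  g <- mol
  nb_g <- bond_list(g)[[anchor]]
  heavy <- nb_g[g$elements[nb_g] != "H"]
  ref <- if (length(heavy) > 0) heavy[1] else nb_g[1]
  v <- g$coords[ref, ] - g$coords[anchor, ]
  v <- v / sqrt(sum(v^2))
  R <- rotation_between(v, u_t)
  g$coords <- sweep(g$coords, 2, g$coords[anchor, ])
  g$coords <- g$coords %*% t(R)
  g$coords <- sweep(g$coords, 2, target, "+")
  keep <- setdiff(seq_len(n_atoms(ps)), h)
  newmol <- molecule(c(ps$elements[keep], g$elements),
                     rbind(ps$coords[keep, , drop = FALSE], g$coords),
                     charges = if (!is.null(ps$charges) || !is.null(g$charges))
                       c(if (is.null(ps$charges)) rep(0, length(keep))
                         else ps$charges[keep],
                         if (is.null(g$charges)) rep(0, n_atoms(g))
                         else g$charges) else NULL,
                     metadata = paste(ps$metadata, "+ gatekeeper"))
  newmol$rings <- ps$rings; newmol$lattice <- ps$lattice
  rim_new <- match(setdiff(pore$rim_indices, h), keep)
  rim_new <- rim_new[!is.na(rim_new)]
  out <- pore_model(newmol, center = pore$center, normal = pore$normal,
                    rim_indices = rim_new, convention = pore$convention,
                    preset = paste0(pore$preset, "-gatekeeper"))
  out$gatekeeper_site <- match(site, keep)
  out$gatekeeper_atoms <- length(keep) + seq_len(n_atoms(g))
  out
}

# minimal rotation matrix taking unit vector a onto unit vector b
rotation_between <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- cross3(a, b)
  c_ <- sum(a * b)
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- cross3(a, p); ax <- ax / sqrt(sum(ax^2))
    return(rotation_about_axis(ax, pi))
  }
  K <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + K + K %*% K / (1 + c_)
}

# rim carbons carrying exactly one hydrogen
rim_carbons_with_h <- function(pore, bonds = bond_list(pore$structure)) {
  ps <- pore$structure
  cs <- pore$rim_indices[ps$elements[pore$rim_indices] == "C"]
  cs[vapply(cs, function(i)
    sum(ps$elements[bonds[[i]]] == "H") == 1L, logical(1))]
}

#' Pick nitrogen substitution sites relative to a gatekeeper
#'
#' Returns two rim carbons to replace by nitrogen: either the pair
#' \code{"opposite"} the gatekeeper attachment (farthest around the rim,
#' enlarging the open pore area) or the pair \code{"adjacent"} to it
#' (nearest, freeing the gatekeeper's swinging motion with little effect on
#' the opening).
#'
#' @param pore A \code{\link{pore_model}} (with or without a gatekeeper).
#' @param mode \code{"opposite"} or \code{"adjacent"}.
#' @param site Gatekeeper attachment carbon; defaults to the model's
#'   recorded \code{gatekeeper_site} or the first eligible rim carbon.
#' @return Integer vector of two rim carbon indices.
#' @export
nitrogen_sites <- function(pore, mode = c("opposite", "adjacent"),
                           site = NULL) {
  mode <- match.arg(mode)
  bonds <- bond_list(pore$structure)
  cand <- rim_carbons_with_h(pore, bonds)
  if (is.null(site)) site <- if (!is.null(pore$gatekeeper_site))
    pore$gatekeeper_site else cand[1]
  cand <- setdiff(cand, site)
  if (length(cand) < 2) stop("fewer than two eligible rim carbons")
  xy <- pore$structure$coords
  d <- sqrt(rowSums(sweep(xy[cand, , drop = FALSE], 2, xy[site, ])^2))
  ord <- if (mode == "opposite") order(-d) else order(d)
  sort(cand[ord[1:2]])
}

#' Run configuration
#'
#' Loads (or builds) the configuration controlling the end-to-end runs:
#' engine and parameter file, search settings, scan settings, band settings,
#' temperature and output directory. Round-trips losslessly through YAML.
#'
#' @param path Optional YAML file; fields override the defaults.
#' @param ... Named overrides applied after the file.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(path = NULL, ...) {
  cfg <- list(
    engine = "internal", param_file = NULL,
    combination_rule = "lorentz_berthelot", cutoff = 12,
    n_starts = 64, seed = 7, dedup_rmsd = 0.25,
    scan_step = 0.25, scan_range = c(-8, 8),
    neb_images = 11, neb_spring = 1, neb_tol = 1e-3,
    temperature = 298.15, outdir = ".",
    schema_version = 1
  )
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    over <- yaml::read_yaml(path)
    cfg[names(over)] <- over
  }
  dots <- list(...)
  cfg[names(dots)] <- dots
  if (is.null(cfg$seed)) stop("config field 'seed' is mandatory")
  structure(cfg, class = "run_config")
}

#' Save a run configuration as YAML
#' @param config A \code{\link{run_config}}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_engine <- function(config) {
  params <- if (!is.null(config$param_file)) {
    read_nb_params(config$param_file, combination_rule = config$combination_rule,
                   cutoff = config$cutoff)
  } else {
    nb_params(combination_rule = config$combination_rule,
              cutoff = config$cutoff)
  }
  lj_engine(params)
}

#' Run the full chirality screen
#'
#' Screens the shipped 5-template chiral library (or a caller-supplied one)
#' over all bimolecular combinations and writes the result table as CSV,
#' plus a log recording the seed and settings. Re-running with the same
#' configuration is bit-identical.
#'
#' @param config A \code{\link{run_config}}.
#' @param library Optional template library (default the shipped fixtures).
#' @return The screening data.frame, invisibly; files are written under
#'   \code{config$outdir}.
#' @export
run_screen <- function(config = run_config(), library = NULL) {
  if (is.null(library)) library <- generate_template_library()
  if (!is.null(config$param_file) && !file.exists(config$param_file))
    stop("parameter file not found: ", config$param_file)
  engine <- config_engine(config)
  sc <- search_config(n_starts = config$n_starts, seed = config$seed,
                      dedup_rmsd = config$dedup_rmsd)
  tab <- screen_matrix(library, engine, sc)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$outdir, "screen.csv")
  utils::write.csv(format(tab, digits = 10), out, row.names = FALSE)
  writeLines(c(paste("engine", engine$name),
               paste("seed", config$seed),
               paste("n_starts", config$n_starts),
               paste("package", as.character(utils::packageVersion("chirasieve")))),
             file.path(config$outdir, "screen.log"))
  invisible(tab)
}

#' Run the pore-propagation matrix
#'
#' Scans each requested probe through each requested pore preset with the
#' rigid constrained protocol, writes one profile CSV per combination and a
#' summary table of classified pathway extrema (left minimum, transition
#' states, intermediate, right minimum, rate-determining barrier).
#'
#' @param config A \code{\link{run_config}}.
#' @param pores Character vector of pore presets.
#' @param probes Character vector of probe fixture ids.
#' @return The summary data.frame, invisibly; files under
#'   \code{config$outdir}.
#' @export
run_sieve <- function(config = run_config(),
                      pores = c("graphene4", "graphene3", "graphdiyne"),
                      probes = c("co2_like", "ch4_like", "ethane_like")) {
  if (length(probes) == 0) stop("nothing to scan: empty probe list")
  if (length(pores) == 0) stop("nothing to scan: empty pore list")
  engine <- config_engine(config)
  proto <- scan_protocol(step = config$scan_step, z_range = config$scan_range)
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  for (pname in pores) {
    pore <- build_pore(pname)
    for (mname in probes) {
      mol <- generate_fixture(mname)
      prof <- rigid_scan(pore, mol, proto, engine)
      write_profile(prof, file.path(config$outdir,
                                    paste0("profile_", pname, "_", mname, ".csv")))
      pw <- prof$pathway
      get_e <- function(slot) if (is.null(slot)) NA_real_ else
        unname(slot["energy"])
      sym <- all(abs(prof$energy - rev(prof$energy)) < 1e-8)
      rows[[length(rows) + 1]] <- data.frame(
        pore = pname, probe = mname,
        diameter = pore$diameter,
        left_minimum = get_e(pw$left_minimum),
        ts1 = get_e(pw$ts1),
        intermediate = get_e(pw$intermediate),
        ts2 = get_e(pw$ts2),
        right_minimum = get_e(pw$right_minimum),
        rate_determining = get_e(pw$rate_determining),
        symmetric = sym,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, file.path(config$outdir, "sieve_summary.csv"),
                   row.names = FALSE)
  invisible(tab)
}
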