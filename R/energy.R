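#' Nonbonded parameter table
#'
#' Per-type Lennard-Jones parameters and partial charges defining the
#' package's internal interaction model: a 12-6 Lennard-Jones term plus a
#' Coulomb term, combined with a named mixing rule and truncated at a cutoff.
#' The shipped defaults are UFF-derived sigma/epsilon per element — a clearly
#' labeled generic stand-in parameter set, not a reimplementation of any
#' published biomolecular force field.
#'
#' @param table data.frame with columns \code{type}, \code{epsilon}
#'   (kcal/mol), \code{sigma} (Angstrom), \code{charge} (e).
#' @param combination_rule \code{"lorentz_berthelot"} (arithmetic sigma,
#'   geometric epsilon) or \code{"geometric"} (both geometric).
#' @param cutoff Cutoff distance in Angstrom, or \code{"none"}. The default
#'   12 Angstrom is the conventional force-field truncation for both the
#'   van der Waals and electrostatic terms; interactions beyond it are
#'   dropped (hard truncation, energies unshifted).
#' @return Object of class \code{"nb_params"}.
#' @export
nb_params <- function(table = default_nb_table(),
                      combination_rule = c("lorentz_berthelot", "geometric"),
                      cutoff = 12) {
  combination_rule <- match.arg(combination_rule)
  stopifnot(is.data.frame(table),
            all(c("type", "epsilon", "sigma", "charge") %in% names(table)))
  if (any(table$epsilon < 0)) stop("epsilon must be >= 0")
  if (any(table$sigma <= 0)) stop("sigma must be > 0")
  if (anyDuplicated(table$type)) stop("duplicate atom types in table")
  if (!identical(cutoff, "none")) {
    cutoff <- as.numeric(cutoff)
    if (!is.finite(cutoff) || cutoff <= 6)
      stop("a finite cutoff must exceed 6 Angstrom")
  }
  structure(list(table = table, combination_rule = combination_rule,
                 cutoff = cutoff, coulomb_constant = 332.0636),
            class = "nb_params")
}

#' Default per-element Lennard-Jones table
#'
#' UFF-derived sigma/epsilon (epsilon in kcal/mol, sigma in Angstrom,
#' sigma = x_vdW / 2^(1/6)) with zero default charges; charges normally come
#' from the structures themselves.
#'
#' @return data.frame usable with \code{\link{nb_params}}.
#' @export
default_nb_table <- function() {
  x <- c(H = 2.886, C = 3.851, N = 3.660, O = 3.500,
         F = 3.364, Cl = 3.947, Br = 4.389)
  d <- c(H = 0.044, C = 0.105, N = 0.069, O = 0.060,
         F = 0.050, Cl = 0.227, Br = 0.251)
  data.frame(type = names(x), epsilon = unname(d),
             sigma = unname(x) / 2^(1 / 6), charge = 0,
             stringsAsFactors = FALSE)
}

#' Read a nonbonded parameter file
#'
#' Plain-text whitespace-separated table \code{type epsilon sigma charge},
#' with \code{#} comments.
#'
#' @param path File path.
#' @param ... Passed to \code{\link{nb_params}} (rule, cutoff).
#' @return An \code{\link{nb_params}} object.
#' @export
read_nb_params <- function(path, ...) {
  tab <- utils::read.table(path, comment.char = "#",
                           col.names = c("type", "epsilon", "sigma", "charge"),
                           stringsAsFactors = FALSE)
  nb_params(tab, ...)
}

#' Combine Lennard-Jones parameters for an unlike pair
#'
#' @param eps_i,sig_i,eps_j,sig_j Per-type epsilon (kcal/mol) and sigma
#'   (Angstrom).
#' @param rule \code{"lorentz_berthelot"} or \code{"geometric"}.
#' @return Named numeric vector \code{c(epsilon =, sigma =)}.
#' @export
combine_lj <- function(eps_i, sig_i, eps_j, sig_j,
                       rule = c("lorentz_berthelot", "geometric")) {
  rule <- match.arg(rule)
  eps <- sqrt(eps_i * eps_j)
  sig <- if (rule == "lorentz_berthelot") (sig_i + sig_j) / 2
         else sqrt(sig_i * sig_j)
  c(epsilon = eps, sigma = sig)
}

# resolve per-atom (epsilon, sigma, charge) for a molecule against params;
# atom_types fall back to element symbols, charges in the structure win
resolve_params <- function(mol, params) {
  types <- if (!is.null(mol$atom_types)) mol$atom_types else mol$elements
  idx <- match(types, params$table$type)
  if (anyNA(idx)) {
    # fall back to element symbol for unknown specialized types
    idx2 <- match(mol$elements, params$table$type)
    idx[is.na(idx)] <- idx2[is.na(idx)]
  }
  if (anyNA(idx))
    stop("no nonbonded parameters for type(s): ",
         paste(unique(types[is.na(idx)]), collapse = ", "))
  q <- if (!is.null(mol$charges)) mol$charges else params$table$charge[idx]
  list(eps = params$table$epsilon[idx], sig = params$table$sigma[idx],
       q = q)
}

#' Pairwise nonbonded energy
#'
#' Energy of a single atom pair: \eqn{4\epsilon[(\sigma/r)^{12} -
#' (\sigma/r)^6] + k_e q_i q_j / r} with the combination rule of
#' \code{params} and \eqn{k_e = 332.0636} kcal A / (mol e^2); zero beyond
#' the cutoff.
#'
#' @param r Distance in Angstrom (> 0); vectorized.
#' @param type_i,type_j Atom type labels present in \code{params}.
#' @param params An \code{\link{nb_params}}.
#' @param q_i,q_j Partial charges; default to the table's.
#' @return Energy in kcal/mol.
#' @export
pair_energy <- function(r, type_i, type_j, params = nb_params(),
                        q_i = NULL, q_j = NULL) {
  stopifnot(all(r > 0))
  tab <- params$table
  i <- match(type_i, tab$type); j <- match(type_j, tab$type)
  if (is.na(i)) stop("unknown type: ", type_i)
  if (is.na(j)) stop("unknown type: ", type_j)
  mix <- combine_lj(tab$epsilon[i], tab$sigma[i], tab$epsilon[j], tab$sigma[j],
                    params$combination_rule)
  if (is.null(q_i)) q_i <- tab$charge[i]
  if (is.null(q_j)) q_j <- tab$charge[j]
  sr6 <- (mix["sigma"] / r)^6
  e <- 4 * mix["epsilon"] * (sr6^2 - sr6) +
    params$coulomb_constant * q_i * q_j / r
  if (!identical(params$cutoff, "none")) e[r > params$cutoff] <- 0
  unname(e)
}

#' Rigid-fragment interaction energy
#'
#' Sum of pairwise Lennard-Jones + Coulomb energies over all inter-fragment
#' atom pairs within the cutoff. Intra-fragment terms are excluded (the
#' fragments are rigid). Atom pairs closer than 0.1 Angstrom raise an
#' overlap error unless \code{cap} is given, in which case the energy is
#' capped at that value (used by the scan machinery to keep hard-core
#' overlaps finite).
#'
#' @param fragA,fragB \code{\link{molecule}} fragments.
#' @param params An \code{\link{nb_params}}.
#' @param cap Optional finite energy cap in kcal/mol.
#' @return Interaction energy in kcal/mol.
#' @export
interaction_energy <- function(fragA, fragB, params = nb_params(),
                               cap = NULL) {
  pa <- resolve_params(fragA, params)
  pb <- resolve_params(fragB, params)
  ax <- fragA$coords; bx <- fragB$coords
  # squared distance matrix (nA x nB)
  d2 <- outer(rowSums(ax^2), rowSums(bx^2), "+") - 2 * tcrossprod(ax, bx)
  d2[d2 < 0] <- 0
  r <- sqrt(d2)
  if (any(r < 0.1)) {
    if (is.null(cap)) stop("fragment overlap: atom pair at r < 0.1 Angstrom")
    return(cap)
  }
  rule <- params$combination_rule
  if (rule == "lorentz_berthelot") {
    sig <- outer(pa$sig, pb$sig, "+") / 2
  } else {
    sig <- sqrt(outer(pa$sig, pb$sig))
  }
  eps <- sqrt(outer(pa$eps, pb$eps))
  qq <- outer(pa$q, pb$q)
  sr6 <- (sig / r)^6
  e <- 4 * eps * (sr6^2 - sr6) + params$coulomb_constant * qq / r
  if (!identical(params$cutoff, "none")) e[r > params$cutoff] <- 0
  tot <- sum(e)
  if (!is.null(cap) && tot > cap) tot <- cap
  tot
}

#' Internal Lennard-Jones + Coulomb energy engine
#'
#' Wraps the internal nonbonded model in the engine contract used by the
#' complex search, the scan machinery and the band optimizer: a list with an
#' \code{energy(fragA, fragB)} evaluator (kcal/mol), a gradient capability
#' flag, and a name. The functional form depends only on interatomic
#' distances, so the engine is translation-, rotation- and mirror-invariant
#' and decays to exactly zero beyond the cutoff.
#'
#' @param params An \code{\link{nb_params}}.
#' @param cap Optional overlap energy cap passed through to
#'   \code{\link{interaction_energy}}.
#' @return Object of class \code{"energy_engine"}.
#' @export
lj_engine <- function(params = nb_params(), cap = NULL) {
  structure(
    list(name = "internal-LJ-Coulomb",
         energy = function(fragA, fragB)
           interaction_energy(fragA, fragB, params, cap = cap),
         has_gradients = FALSE,
         params = params),
    class = "energy_engine"
  )
}

#' Check mirror invariance of an engine
#'
#' A physically meaningful engine must assign the same energy to a complex
#' and its mirror image; this is the property that makes same-chirality
#' versus opposite-chirality energy comparisons well defined.
#'
#' @param engine An \code{"energy_engine"}.
#' @param fragA,fragB \code{\link{molecule}} fragments.
#' @param tol Tolerance in kcal/mol (default 1e-8).
#' @return \code{TRUE} iff |E(original) - E(reflected)| < \code{tol}.
#' @export
mirror_invariance_check <- function(engine, fragA, fragB, tol = 1e-8) {
  e1 <- engine$energy(fragA, fragB)
  e2 <- engine$energy(mirror(fragA), mirror(fragB))
  abs(e1 - e2) < tol
}

#' External engine adapter
#'
#' Wraps a user command that reads two XYZ files and prints a single energy
#' (kcal/mol) on stdout into the engine contract, so that external backends
#' (e.g. a semiempirical tight-binding code) can stand behind the same
#' search and scan machinery. The adapter declares its failure mode: a
#' non-zero exit status or unparseable output raises an error, which the
#' multi-start search logs and skips. No external engine is required by any
#' part of the package.
#'
#' @param command Command to run; it receives the two XYZ paths as arguments.
#' @param name Engine label.
#' @return Object of class \code{"energy_engine"}.
#' @export
external_engine <- function(command, name = "external") {
  structure(
    list(name = name,
         energy = function(fragA, fragB) {
           fa <- tempfile(fileext = ".xyz"); fb <- tempfile(fileext = ".xyz")
           on.exit(unlink(c(fa, fb)))
           write_xyz(fragA, fa); write_xyz(fragB, fb)
           out <- suppressWarnings(system2(command, c(fa, fb), stdout = TRUE))
           status <- attr(out, "status")
           if (!is.null(status) && status != 0)
             stop("external engine '", name, "' failed (exit ", status, ")")
           val <- suppressWarnings(as.numeric(out[length(out)]))
           if (!is.finite(val))
             stop("external engine '", name, "' produced no numeric energy")
           val
         },
         has_gradients = FALSE),
    class = "energy_engine"
  )
}
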