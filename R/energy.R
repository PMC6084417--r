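KIND_CODE <- c(bond = 1L, constraint = 2L, angle = 3L, dihedral_proper = 4L,
               dihedral_improper = 5L, flat_bottom_restraint = 6L)

# Encode a terms tibble for the C++ kernels: indices as an n x 4 matrix
# (NA -> 1, unused), parameters with angular quantities converted
# (angle c0 -> cos(theta0), dihedral phase / improper reference -> radians).
terms_to_cpp <- function(terms) {
  kind <- KIND_CODE[terms$kind]
  if (anyNA(kind)) stop("unknown term kind", call. = FALSE)
  tidx <- cbind(terms$i, terms$j, terms$k, terms$l)
  tidx[is.na(tidx)] <- 1L
  storage.mode(tidx) <- "integer"
  c0 <- terms$c0; c1 <- terms$c1; c2 <- terms$c2
  ang <- terms$kind == "angle"
  c0[ang] <- cos(c0[ang] * pi / 180)
  rad <- terms$kind %in% c("dihedral_proper", "dihedral_improper")
  c0[rad] <- c0[rad] * pi / 180
  tpar <- cbind(c0, c1, c2)
  tpar[is.na(tpar)] <- 0
  list(tidx = tidx, tkind = unname(kind), tpar = tpar)
}

coords_from <- function(coords, n) {
  xyz <- if (inherits(coords, "cg_frame")) coords_matrix(coords)
         else as.matrix(coords)
  if (ncol(xyz) != 3) stop("coordinates must be n x 3", call. = FALSE)
  if (nrow(xyz) != n) {
    stop("coordinate count (", nrow(xyz), ") does not match topology bead count (",
         n, ")", call. = FALSE)
  }
  if (any(!is.finite(xyz))) stop("non-finite coordinates", call. = FALSE)
  xyz
}

#' Bonded energy of a configuration
#'
#' Evaluates the bonded potential of a topology at one set of coordinates:
#' harmonic bonds `U = kb/2 (b - b0)^2`, cosine-harmonic (G96) angles
#' `U = ka/2 (cos(theta) - cos(theta0))^2`, periodic proper dihedrals
#' `U = kphi (1 + cos(n phi - phi_s))`, harmonic improper dihedrals
#' `U = kxi/2 (xi - xi0)^2` and flat-bottomed z-restraints. Constraints
#' contribute zero energy, but deviations of more than `1e-3` nm from their
#' reference length are counted and reported with a warning.
#'
#' @param topology an `sma_topology`.
#' @param coords a `cg_frame` or n x 3 matrix (nm) matching the topology.
#' @return An `energy_breakdown` list: per-kind sums, `total` (kJ/mol),
#'   `constraint_violations` count and `constraint_max_dev` (nm).
#' @export
bonded_energy <- function(topology, coords) {
  validate_topology(topology)
  xyz <- coords_from(coords, n_beads(topology))
  enc <- terms_to_cpp(topology$terms)
  e <- cpp_term_energies(as.numeric(t(xyz)), enc$tidx, enc$tkind, enc$tpar)
  kinds <- topology$terms$kind
  by_kind <- function(k) sum(e[kinds %in% k])
  cons <- topology$terms[kinds == "constraint", ]
  max_dev <- 0; n_viol <- 0L
  if (nrow(cons) > 0) {
    d <- sqrt(rowSums((xyz[cons$i, , drop = FALSE] -
                         xyz[cons$j, , drop = FALSE])^2))
    dev <- abs(d - cons$c0)
    max_dev <- max(dev)
    n_viol <- sum(dev > 1e-3)
    if (n_viol > 0) {
      warning(n_viol, " constraint(s) deviate by more than 1e-3 nm (max ",
              signif(max_dev, 3), " nm)")
    }
  }
  parts <- c(
    bond = by_kind("bond"),
    angle = by_kind("angle"),
    dihedral_proper = by_kind("dihedral_proper"),
    dihedral_improper = by_kind("dihedral_improper"),
    restraint = by_kind("flat_bottom_restraint")
  )
  structure(
    list(bond = parts[["bond"]], angle = parts[["angle"]],
         dihedral_proper = parts[["dihedral_proper"]],
         dihedral_improper = parts[["dihedral_improper"]],
         restraint = parts[["restraint"]], total = sum(parts),
         constraint_violations = n_viol, constraint_max_dev = max_dev),
    class = "energy_breakdown"
  )
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat("<energy_breakdown> kJ/mol\n")
  for (k in c("bond", "angle", "dihedral_proper", "dihedral_improper",
              "restraint", "total")) {
    cat(sprintf("  %-18s %12.4f\n", k, x[[k]]))
  }
  if (x$constraint_violations > 0) {
    cat(sprintf("  constraint violations: %d (max %.2g nm)\n",
                x$constraint_violations, x$constraint_max_dev))
  }
  invisible(x)
}

#' Flat-bottomed distance restraint energy
#'
#' Zero inside the onset distance `d0`, harmonic `k/2 (d - d0)^2` beyond it.
#' The default onset of 3.0 nm mirrors the adsorption restraint used to keep
#' copolymers near the membrane surface before binding.
#'
#' @param distance distance(s) in nm (>= 0).
#' @param d0 onset distance, nm.
#' @param k force constant, kJ mol^-1 nm^-2 (>= 0).
#' @return Energy in kJ/mol (vectorised over `distance`).
#' @export
#' @examples
#' flat_bottom_restraint(3.5, d0 = 3.0, k = 100) # 12.5
flat_bottom_restraint <- function(distance, d0 = 3.0, k = 1000) {
  if (k < 0) stop("force constant must be non-negative", call. = FALSE)
  if (any(distance < 0)) stop("distance must be >= 0", call. = FALSE)
  ifelse(distance <= d0, 0, 0.5 * k * (distance - d0)^2)
}
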