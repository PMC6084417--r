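# Boltzmann constant, kJ mol^-1 K^-1
KB <- 0.0083145

# Atomic masses (Da) used for repeat-unit molecular weights
ATOMIC_MASS <- c(C = 12.011, H = 1.008, O = 15.999)

#' Default bead and bonded-parameter table for the CG SMA model
#'
#' The coarse-grained styrene-maleic acid (SMA) repeat unit is
#' styrene-styrene-maleic acid (2:1). Each styrene contributes one backbone
#' bead plus a three-bead ring held together by constraints (small-bead
#' class); the maleic acid contributes two one-bead carboxylate groups that
#' each carry a full negative charge when deprotonated. Masses follow the
#' Martini convention (72 Da regular, 45 Da small ring beads). All values are
#' overridable: the mapping is a table, not a hard-coded molecule.
#'
#' @return A list of defaults consumed by [build_sma_chain()]:
#'   `mass_regular`, `mass_small`, type-code strings, and bonded parameters
#'   (`b0`/`kb` in nm and kJ mol^-1 nm^-2, angles in degrees with
#'   cosine-harmonic `ka` in kJ mol^-1, proper dihedral `kphi` in kJ mol^-1,
#'   improper `kxi` in kJ mol^-1 rad^-2, ring constraint length in nm).
#' @export
sma_defaults <- function() {
  list(
    mass_regular = 72, mass_small = 45,
    type_backbone = "SC1", type_ring = "SC4",
    type_carboxylate = "Qa", type_carboxylate_protonated = "P3",
    bond_bb = c(b0 = 0.26, kb = 7000),       # styrene backbone links
    bond_bc = c(b0 = 0.28, kb = 5000),       # backbone - carboxylate
    bond_cc = c(b0 = 0.28, kb = 5000),       # carboxylate - carboxylate
    bond_ring = c(b0 = 0.27, kb = 8000),     # backbone - ring anchor
    constraint_ring = 0.27,                  # aromatic ring edges
    angle_bb = c(theta0 = 136, ka = 50),     # backbone angles
    angle_bc = c(theta0 = 120, ka = 50),
    angle_ring = c(theta0 = 120, ka = 50),   # ring attachment
    dihedral_bb = c(phase = 0, kphi = 1.8, mult = 1),
    improper_ring = c(xi0 = 180, kxi = 50)  # planar ring, anchor outside
  )
}

# 10 beads per repeat unit: 2 x (backbone + 3-bead ring) + 2 carboxylates
BEADS_PER_UNIT <- 10L

resolve_pattern <- function(n_units, protonation) {
  if (is.character(protonation) && length(protonation) == 1) {
    charged <- switch(protonation,
      full = rep(TRUE, n_units),
      # every second maleic acid unit protonated (neutral); odd units charged
      alternate = (seq_len(n_units) %% 2L) == 1L,
      stop("unknown protonation preset: ", protonation, call. = FALSE)
    )
  } else {
    charged <- as.logical(protonation)
    if (length(charged) != n_units || anyNA(charged)) {
      stop("protonation pattern length must equal n_units", call. = FALSE)
    }
  }
  charged
}

#' Build a coarse-grained SMA copolymer topology
#'
#' Constructs a parametric chain of `n_units` styrene-styrene-maleic-acid
#' repeat units. Each unit contributes two styrene groups (one backbone bead
#' and a three-bead aromatic ring closed by three constraints apiece) and one
#' maleic acid as two carboxylate beads; deprotonated (charged) units carry
#' -1 e on each carboxylate, i.e. -2 e per unit. Bonds and improper
#' dihedrals are harmonic, angles use the cosine-harmonic (G96) form, and
#' backbone torsions a periodic dihedral.
#'
#' @param n_units number of repeat units (>= 1); 23 reproduces the ~7.4 kDa
#'   chain used throughout.
#' @param protonation `"full"` (all units deprotonated / charged),
#'   `"alternate"` (every second unit protonated, odd units charged), or a
#'   logical vector of length `n_units` with `TRUE` = charged.
#' @param defaults parameter table from [sma_defaults()].
#' @param molecule_name name written to the ITP `[moleculetype]` section.
#' @return An `sma_topology`: list with `molecule_name`, `n_units`,
#'   `charged_units`, a `beads` tibble (index, name, bead_class, type_code,
#'   mass, charge, unit_index, role) and a `terms` tibble (kind, i, j, k, l,
#'   c0, c1, c2).
#' @export
#' @examples
#' top <- build_sma_chain(23, "full")
#' total_charge(top) # -46
build_sma_chain <- function(n_units, protonation = "full",
                            defaults = sma_defaults(),
                            molecule_name = "SMA") {
  n_units <- as.integer(n_units)
  if (is.na(n_units) || n_units < 1) stop("n_units must be >= 1", call. = FALSE)
  charged <- resolve_pattern(n_units, protonation)
  d <- defaults

  unit_beads <- function(u) {
    q <- if (charged[u]) -1 else 0
    tq <- if (charged[u]) d$type_carboxylate else d$type_carboxylate_protonated
    tibble::tibble(
      name = c("BB1", "RA1", "RA2", "RA3", "BB2", "RB1", "RB2", "RB3",
               "MA1", "MA2"),
      bead_class = c("regular", "small", "small", "small",
                     "regular", "small", "small", "small",
                     "regular", "regular"),
      type_code = c(d$type_backbone, rep(d$type_ring, 3),
                    d$type_backbone, rep(d$type_ring, 3), tq, tq),
      mass = c(d$mass_regular, rep(d$mass_small, 3),
               d$mass_regular, rep(d$mass_small, 3),
               d$mass_regular, d$mass_regular),
      charge = c(0, 0, 0, 0, 0, 0, 0, 0, q, q),
      unit_index = u,
      role = c("backbone", "ring", "ring", "ring",
               "backbone", "ring", "ring", "ring",
               "carboxylate", "carboxylate")
    )
  }
  beads <- purrr::map_dfr(seq_len(n_units), unit_beads)
  beads <- dplyr::mutate(beads, index = dplyr::row_number(),
                         .before = "name")

  term <- function(kind, idx, c0 = NA_real_, c1 = NA_real_, c2 = NA_real_) {
    idx <- c(idx, rep(NA_integer_, 4 - length(idx)))
    tibble::tibble(kind = kind, i = idx[1], j = idx[2], k = idx[3], l = idx[4],
                   c0 = c0, c1 = c1, c2 = c2)
  }
  unit_terms <- function(u) {
    b <- (u - 1L) * BEADS_PER_UNIT
    out <- list(
      term("bond", b + c(1L, 5L), d$bond_bb[["b0"]], d$bond_bb[["kb"]]),
      term("bond", b + c(5L, 9L), d$bond_bc[["b0"]], d$bond_bc[["kb"]]),
      term("bond", b + c(9L, 10L), d$bond_cc[["b0"]], d$bond_cc[["kb"]]),
      term("bond", b + c(1L, 2L), d$bond_ring[["b0"]], d$bond_ring[["kb"]]),
      term("bond", b + c(5L, 6L), d$bond_ring[["b0"]], d$bond_ring[["kb"]]),
      term("constraint", b + c(2L, 3L), d$constraint_ring),
      term("constraint", b + c(3L, 4L), d$constraint_ring),
      term("constraint", b + c(4L, 2L), d$constraint_ring),
      term("constraint", b + c(6L, 7L), d$constraint_ring),
      term("constraint", b + c(7L, 8L), d$constraint_ring),
      term("constraint", b + c(8L, 6L), d$constraint_ring),
      term("angle", b + c(1L, 5L, 9L), d$angle_bb[["theta0"]], d$angle_bb[["ka"]]),
      term("angle", b + c(5L, 9L, 10L), d$angle_bc[["theta0"]], d$angle_bc[["ka"]]),
      term("angle", b + c(2L, 1L, 5L), d$angle_ring[["theta0"]], d$angle_ring[["ka"]]),
      term("angle", b + c(6L, 5L, 9L), d$angle_ring[["theta0"]], d$angle_ring[["ka"]]),
      term("dihedral_proper", b + c(1L, 5L, 9L, 10L),
           d$dihedral_bb[["phase"]], d$dihedral_bb[["kphi"]],
           d$dihedral_bb[["mult"]]),
      term("dihedral_improper", b + c(1L, 2L, 3L, 4L),
           d$improper_ring[["xi0"]], d$improper_ring[["kxi"]]),
      term("dihedral_improper", b + c(5L, 6L, 7L, 8L),
           d$improper_ring[["xi0"]], d$improper_ring[["kxi"]])
    )
    if (u < n_units) {
      out <- c(out, list(
        term("bond", b + c(10L, 11L), d$bond_bc[["b0"]], d$bond_bc[["kb"]]),
        term("angle", b + c(9L, 10L, 11L), d$angle_bc[["theta0"]],
             d$angle_bc[["ka"]]),
        term("angle", b + c(10L, 11L, 15L), d$angle_bb[["theta0"]],
             d$angle_bb[["ka"]])
      ))
    }
    dplyr::bind_rows(out)
  }
  # canonical kind-grouped order so ITP round-trips are the identity
  terms <- canonical_terms(purrr::map_dfr(seq_len(n_units), unit_terms))

  top <- structure(
    list(
      molecule_name = molecule_name,
      n_units = n_units,
      charged_units = charged,
      beads = beads,
      terms = terms,
      exclusions = tibble::tibble(i = integer(), j = integer())
    ),
    class = "sma_topology"
  )
  validate_topology(top)
  top
}

#' @rdname build_sma_chain
#' @param topology an `sma_topology`.
#' @export
total_charge <- function(topology) sum(topology$beads$charge)

#' @rdname build_sma_chain
#' @export
n_beads <- function(topology) nrow(topology$beads)

#' @export
print.sma_topology <- function(x, ...) {
  cat(sprintf(
    "<sma_topology> %s: %d units, %d beads, %d bonded terms, charge %+g e\n",
    x$molecule_name, x$n_units, n_beads(x), nrow(x$terms), total_charge(x)
  ))
  invisible(x)
}

validate_topology <- function(top) {
  b <- top$beads
  if (nrow(b) == 0) stop("empty topology", call. = FALSE)
  if (!identical(b$index, seq_len(nrow(b)))) {
    stop("bead indices must be contiguous from 1", call. = FALSE)
  }
  if (any(b$mass <= 0)) stop("bead masses must be positive", call. = FALSE)
  if (any(b$role == "ring" & b$bead_class != "small")) {
    stop("ring beads must be small-class", call. = FALSE)
  }
  if (any(b$role == "carboxylate" & !(b$charge %in% c(0, -1)))) {
    stop("carboxylate charge must be 0 or -1", call. = FALSE)
  }
  t <- top$terms
  idx <- cbind(t$i, t$j, t$k, t$l)
  narg <- c(bond = 2, constraint = 2, angle = 3, dihedral_proper = 4,
            dihedral_improper = 4, flat_bottom_restraint = 1)
  for (r in seq_len(nrow(t))) {
    use <- idx[r, seq_len(narg[[t$kind[r]]])]
    if (anyNA(use) || any(use < 1 | use > nrow(b)) || anyDuplicated(use)) {
      stop(sprintf("term %d (%s): invalid bead indices", r, t$kind[r]),
           call. = FALSE)
    }
  }
  if (any(t$c0[t$kind %in% c("bond", "constraint")] <= 0, na.rm = TRUE)) {
    stop("bond/constraint reference lengths must be positive", call. = FALSE)
  }
  mult <- t$c2[t$kind == "dihedral_proper"]
  if (any(mult < 1 | mult != round(mult))) {
    stop("proper dihedral multiplicity must be a positive integer", call. = FALSE)
  }
  invisible(top)
}

#' Molecular weight of an SMA chain
#'
#' Sums vinyl-addition repeat-unit masses: styrene repeat C8H8 (104.152 Da)
#' twice per unit plus the maleic diacid repeat C4H4O4 (116.072 Da). Under
#' the `deprotonated_anion` convention one hydrogen-atom mass is removed per
#' deprotonated carboxylate charge. Chain-end hydrogens are neglected.
#'
#' @param topology an `sma_topology`.
#' @param convention `"deprotonated_anion"` (default; matches the ~7.4 kDa
#'   quoted for the 23-unit chain) or `"neutral_acid"`.
#' @return Molecular weight in Da.
#' @export
#' @examples
#' round(molecular_weight(build_sma_chain(23)) / 1000, 1) # 7.4 kDa
molecular_weight <- function(topology,
                             convention = c("deprotonated_anion",
                                            "neutral_acid")) {
  convention <- match.arg(convention)
  if (!inherits(topology, "sma_topology") || topology$n_units < 1) {
    stop("need a valid sma_topology with >= 1 unit", call. = FALSE)
  }
  m <- ATOMIC_MASS
  styrene <- 8 * m[["C"]] + 8 * m[["H"]]
  maleic <- 4 * m[["C"]] + 4 * m[["H"]] + 4 * m[["O"]]
  mw <- topology$n_units * (2 * styrene + maleic)
  if (convention == "deprotonated_anion") {
    mw <- mw - abs(total_charge(topology)) * m[["H"]]
  }
  mw
}
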