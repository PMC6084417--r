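# Hand-built minimal topologies used across the suite.

new_test_topology <- function(beads, terms, name = "TST") {
  structure(
    list(
      molecule_name = name, n_units = 1L, charged_units = TRUE,
      beads = beads, terms = terms,
      exclusions = tibble::tibble(i = integer(), j = integer())
    ),
    class = "sma_topology"
  )
}

plain_beads <- function(n) {
  tibble::tibble(
    index = seq_len(n), name = paste0("B", seq_len(n)),
    bead_class = "regular", type_code = "SC1", mass = 72, charge = 0,
    unit_index = 1L, role = "backbone"
  )
}

term_row <- function(kind, idx, c0, c1 = NA_real_, c2 = NA_real_) {
  idx <- c(idx, rep(NA_integer_, 4 - length(idx)))
  tibble::tibble(kind = kind, i = idx[1], j = idx[2], k = idx[3], l = idx[4],
                 c0 = c0, c1 = c1, c2 = c2)
}

# single harmonic bond
bond_topology <- function(b0 = 0.5, kb = 1250) {
  new_test_topology(plain_beads(2), term_row("bond", c(1L, 2L), b0, kb))
}

# 4-bead linear chain: 3 bonds, 2 cosine angles, 1 proper dihedral
linear_chain_topology <- function(b = c(0.35, 0.40, 0.30),
                                  kb = c(5000, 7000, 4000),
                                  th = c(120, 130), ka = c(50, 60),
                                  phase = 0, kphi = 3, mult = 2) {
  terms <- dplyr::bind_rows(
    term_row("bond", c(1L, 2L), b[1], kb[1]),
    term_row("bond", c(2L, 3L), b[2], kb[2]),
    term_row("bond", c(3L, 4L), b[3], kb[3]),
    term_row("angle", c(1L, 2L, 3L), th[1], ka[1]),
    term_row("angle", c(2L, 3L, 4L), th[2], ka[2]),
    term_row("dihedral_proper", c(1L, 2L, 3L, 4L), phase, kphi, mult)
  )
  new_test_topology(plain_beads(4), terms)
}

random_chain_params <- function() {
  list(
    b = stats::runif(3, 0.30, 0.45), kb = stats::runif(3, 3000, 9000),
    th = stats::runif(2, 105, 135), ka = stats::runif(2, 35, 85),
    phase = sample(c(0, 180), 1), kphi = stats::runif(1, 1.5, 4.5),
    mult = sample(1:3, 1)
  )
}

chain_from_params <- function(p) {
  linear_chain_topology(p$b, p$kb, p$th, p$ka, p$phase, p$kphi, p$mult)
}

# frame from a bare coordinate matrix
frame_from_xyz <- function(xyz, box = c(100, 100, 100), mass = NULL,
                           resname = "TST") {
  n <- nrow(xyz)
  cg_frame(tibble::tibble(
    molid = 1L, resid = 1L, resname = resname, name = paste0("B", seq_len(n)),
    mass = if (is.null(mass)) 72 else mass,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  ), box = box)
}

KBT310 <- 0.0083145 * 310
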