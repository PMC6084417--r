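test_that("lattice bilayers realise the requested geometry exactly", {
  bl <- make_bilayer(26, 26, 0.63, 2.4)
  expect_equal(length(unique(bl$molid)), 1352L)   # 26 x 26 x 2 leaflets
  box <- frame_box(bl)
  expect_equal(box[1] * box[2] / (26 * 26), 0.63) # area per lipid exact
  lf <- assign_leaflets(bl)
  expect_equal(unname(table(lf$leaflet)["upper"]), 676L)
  expect_error(make_bilayer(1, 5), ">= 2")
  expect_error(make_bilayer(4, 4, area_per_lipid = -1), "positive")
})

test_that("punched pores remove exactly the lattice sites in the circle", {
  bl <- make_bilayer(16, 16, 0.63, 2.4)
  a <- sqrt(0.63)
  ctr <- c(8 * a, 8 * a)
  r <- 2.0
  pf <- punch_pore(bl, ctr, r)
  # lattice enumeration oracle: site centres within the circle, per leaflet
  sites <- expand.grid(i = 0:15, j = 0:15)
  d2 <- ((sites$i + 0.5) * a - ctr[1])^2 + ((sites$j + 0.5) * a - ctr[2])^2
  expect_equal(length(attr(pf, "removed_molids")), 2L * sum(d2 < r^2))
  expect_equal(length(unique(pf$molid)), 512L - 2L * sum(d2 < r^2))
  # radius zero leaves the frame unchanged
  pf0 <- punch_pore(bl, ctr, 0)
  expect_equal(nrow(pf0), nrow(bl))
  expect_length(attr(pf0, "removed_molids"), 0L)
})

test_that("two planted pores are found by detection (planted truth)", {
  bl <- make_bilayer(26, 26, 0.63, 2.4)
  pf <- punch_pore(punch_pore(bl, c(4.5, 4.5), 1.8), c(14.5, 14.5), 1.2)
  expect_equal(nrow(detect_pores(pf)), 2L)
})

test_that("nanodisk fixtures carry their ground truth", {
  nd <- make_nanodisk(150, 0.63, n_polymers = 1)
  expect_equal(attr(nd, "diameter_geometric"),
               2 * sqrt(75 * 0.63 / pi))
  expect_length(attr(nd, "lipid_molids"), 150L)
  expect_length(attr(nd, "polymer_molids"), 1L)
  expect_equal(sum(nd$resname == "SMA"), n_beads(build_sma_chain(23)))
  bare <- make_nanodisk(60, 0.63, n_polymers = 0)
  expect_length(attr(bare, "polymer_molids"), 0L)
  expect_equal(characterize_disk(bare, attr(bare, "lipid_molids"))$n_polymers,
               0L)
})

test_that("reference ensembles match their closed-form moments", {
  top <- bond_topology(b0 = 0.4, kb = 5000)
  ref <- sample_reference_ensemble(top, n = 1e5, seed = 13)
  s <- ref$samples$bond_1_2
  expect_lt(abs(var(s) / (KBT310 / 5000) - 1), 0.05)
  expect_lt(abs(mean(s) - 0.4), 0.001)
  # identical seeds give identical draws and targets
  ref2 <- sample_reference_ensemble(top, n = 1e5, seed = 13)
  expect_identical(ref$samples, ref2$samples)
  expect_identical(ref$targets$bond_1_2$density, ref2$targets$bond_1_2$density)
})

test_that("dihedral draws live on the wrapped support (-180, 180]", {
  top <- new_test_topology(plain_beads(4), dplyr::bind_rows(
    term_row("dihedral_proper", 1:4, 180, 2, 1)
  ))
  ref <- sample_reference_ensemble(top, n = 2e4, seed = 14)
  s <- ref$samples$dihedral_proper_1_2_3_4
  expect_true(all(s > -180 & s <= 180))
  # the potential minimum for phase 180 sits at phi = 0
  expect_gt(mean(abs(s) < 90), 0.5)
})

test_that("chain coordinates reproduce the drawn internal coordinates", {
  top <- linear_chain_topology()
  ref <- sample_reference_ensemble(top, n = 500, seed = 15)
  expect_false(is.null(ref$traj))
  for (key in names(ref$samples)) {
    parts <- strsplit(key, "_(?=[0-9])", perl = TRUE)[[1]]
    kind <- parts[1]
    idx <- as.integer(parts[-1])
    m <- as.numeric(measure_term(ref$traj, kind, idx))
    dd <- abs(((m - ref$samples[[key]] + 180) %% 360) - 180)
    if (kind == "bond") {
      expect_lt(max(abs(m - ref$samples[[key]])), 1e-9)
    } else {
      expect_lt(max(dd), 1e-6)
    }
  }
  # ringed topologies cannot be rebuilt from internals: no trajectory
  ringed <- build_sma_chain(1)
  expect_null(sample_reference_ensemble(ringed, n = 10, seed = 1)$traj)
})
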