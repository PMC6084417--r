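test_that("bonded energy terms follow their closed forms", {
  # one bond, kb = 1250, displaced 0.1 nm -> 6.25 kJ/mol
  top <- bond_topology(b0 = 0.5, kb = 1250)
  e <- bonded_energy(top, rbind(c(0, 0, 0), c(0.6, 0, 0)))
  expect_equal(e$bond, 6.25)
  expect_equal(e$total, 6.25)
  # at equilibrium everything vanishes
  e0 <- bonded_energy(top, rbind(c(0, 0, 0), c(0.5, 0, 0)))
  expect_equal(e0$total, 0)
  # proper dihedral kphi = 5, n = 1, phase 0: 0 at 180 deg, 10 at 0
  dtop <- new_test_topology(plain_beads(4), dplyr::bind_rows(
    term_row("dihedral_proper", 1:4, 0, 5, 1)
  ))
  planar_trans <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  planar_cis <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(1.5, -1, 0))
  expect_equal(bonded_energy(dtop, planar_trans)$total, 0, tolerance = 1e-12)
  expect_equal(bonded_energy(dtop, planar_cis)$total, 10, tolerance = 1e-9)
  # cosine angle term: ka/2 (cos - cos0)^2
  atop <- new_test_topology(plain_beads(3),
                            term_row("angle", 1:3, 90, 40))
  right <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(bonded_energy(atop, right)$angle, 0, tolerance = 1e-12)
  straight <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(bonded_energy(atop, straight)$angle, 0.5 * 40 * 1,
               tolerance = 1e-12)
})

test_that("energy breakdown parts sum to the total and inputs are checked", {
  top <- linear_chain_topology()
  f <- generate_initial_coords(top)
  e <- bonded_energy(top, f)
  expect_equal(e$total,
               e$bond + e$angle + e$dihedral_proper + e$dihedral_improper +
                 e$restraint)
  expect_error(bonded_energy(top, rbind(c(0, 0, 0))), "does not match")
  bad <- cbind(c(0, NA, 1, 2), 0, 0)
  expect_error(bonded_energy(top, bad), "non-finite")
})

test_that("constraint violations beyond 1e-3 nm are reported", {
  top <- new_test_topology(plain_beads(2),
                           term_row("constraint", c(1L, 2L), 0.27))
  expect_warning(e <- bonded_energy(top, rbind(c(0, 0, 0), c(0.30, 0, 0))),
                 "constraint")
  expect_equal(e$constraint_violations, 1L)
  expect_equal(e$total, 0)  # constraints carry no energy
  e2 <- bonded_energy(top, rbind(c(0, 0, 0), c(0.2705, 0, 0)))
  expect_equal(e2$constraint_violations, 0L)
})

test_that("flat-bottomed restraint is zero inside the onset", {
  expect_equal(flat_bottom_restraint(2.0, d0 = 3.0, k = 100), 0)
  expect_equal(flat_bottom_restraint(3.0, d0 = 3.0, k = 100), 0)
  expect_equal(flat_bottom_restraint(3.5, d0 = 3.0, k = 100), 12.5)
  expect_error(flat_bottom_restraint(1, k = -5), "non-negative")
  expect_error(flat_bottom_restraint(-1), ">= 0")
})

test_that("single-bond sampling satisfies equipartition at 310 K", {
  top <- bond_topology(b0 = 0.5, kb = 1250)
  traj <- sample_bonded_ensemble(top, temperature = 310, n_steps = 1e5,
                                 seed = 42)
  b <- as.numeric(measure_term(traj, "bond", c(1, 2)))
  expect_lt(abs(var(b) / (KBT310 / 1250) - 1), 0.05)
  expect_lt(abs(mean(b) - 0.5), 0.01)
  acc <- attr(traj, "acceptance")
  expect_gt(acc, 0); expect_lt(acc, 1)
})

test_that("ring constraints stay rigid across all samples", {
  top <- build_sma_chain(1)
  traj <- sample_bonded_ensemble(top, n_steps = 2e4, seed = 3)
  cons <- top$terms[top$terms$kind == "constraint", ]
  for (r in seq_len(nrow(cons))) {
    d <- as.numeric(measure_term(traj, "constraint", c(cons$i[r], cons$j[r])))
    expect_lt(max(abs(d - cons$c0[r])), 1e-6)
  }
})

test_that("sampling is deterministic in the seed", {
  top <- linear_chain_topology()
  t1 <- sample_bonded_ensemble(top, n_steps = 5000, seed = 11)
  t2 <- sample_bonded_ensemble(top, n_steps = 5000, seed = 11)
  expect_identical(attr(t1, "samples"), attr(t2, "samples"))
  t3 <- sample_bonded_ensemble(top, n_steps = 5000, seed = 12)
  expect_false(identical(attr(t1, "samples"), attr(t3, "samples")))
})

test_that("extended starting coordinates carry zero bond energy", {
  top <- build_sma_chain(3)
  f <- generate_initial_coords(top)
  expect_equal(bonded_energy(top, f)$bond, 0, tolerance = 1e-20)
})
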