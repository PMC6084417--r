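test_that("Boltzmann inversion recovers harmonic bond parameters", {
  set.seed(21)
  s <- rnorm(2e5, 0.30, 0.02)
  d <- make_distribution(s, "bond")
  out <- boltzmann_invert(d, "bond", temperature = 310)
  expect_equal(out$kind, "bond")
  # kb = kBT / sigma^2 = 2.577 / 4e-4 ~ 6443
  expect_lt(abs(out$c1 / (KBT310 / 4e-4) - 1), 0.03)
  expect_lt(abs(out$c0 - 0.30), 0.001)
})

test_that("near-delta bonds are promoted to constraints", {
  set.seed(22)
  d <- make_distribution(rnorm(5e4, 0.27, 0.002), "bond")
  expect_message(out <- boltzmann_invert(d, "bond"), "constraint")
  expect_equal(out$kind, "constraint")
  expect_lt(abs(out$c0 - 0.27), 0.001)
})

test_that("multimodal bond distributions are rejected", {
  set.seed(23)
  s <- c(rnorm(3e4, 0.25, 0.01), rnorm(3e4, 0.40, 0.01))
  d <- make_distribution(s, "bond")
  expect_error(boltzmann_invert(d, "bond"), "multimodal")
})

test_that("angle inversion works on the cosine", {
  top <- new_test_topology(plain_beads(3),
                           term_row("angle", 1:3, 120, 55))
  ref <- sample_reference_ensemble(top, n = 1e5, seed = 9)
  out <- boltzmann_invert(ref$targets$angle_1_2_3, "angle")
  expect_lt(abs(out$c0 - 120), 2)
  expect_lt(abs(out$c1 / 55 - 1), 0.15)  # truncation-free region
})

test_that("dihedral inversion recovers multiplicity, amplitude and phase", {
  for (true in list(c(kphi = 5, n = 2, phase = 0),
                    c(kphi = 3, n = 1, phase = 180),
                    c(kphi = 2.5, n = 3, phase = 0))) {
    top <- new_test_topology(plain_beads(4), dplyr::bind_rows(
      term_row("dihedral_proper", 1:4, true[["phase"]], true[["kphi"]],
               true[["n"]])
    ))
    ref <- sample_reference_ensemble(top, n = 5e4, seed = 31)
    out <- boltzmann_invert(ref$targets$dihedral_proper_1_2_3_4,
                            "dihedral_proper")
    expect_equal(out$c2, true[["n"]])
    expect_lt(abs(out$c1 / true[["kphi"]] - 1), 0.10)
    dphase <- abs(((out$c0 - true[["phase"]] + 180) %% 360) - 180)
    expect_lt(dphase, 5)
  }
})

test_that("refinement is a fixed point on the model's own distributions", {
  top <- linear_chain_topology()
  traj <- sample_bonded_ensemble(top, n_steps = 3e4, seed = 50)
  targets <- compute_bonded_targets(traj, top)
  fit <- refine_parameters(top, targets, seed = 50, n_steps = 3e4)
  expect_true(fit$converged)
  expect_equal(fit$iterations, 0L)
  expect_equal(max(fit$terms$jsd), 0)
  expect_equal(fit$topology$terms, top$terms)
})

test_that("perturbed parameters are recovered by iterative matching", {
  bw <- c(length = 0.002, angle = 4, dihedral = 6)
  set.seed(77)
  for (rep in 1:2) {
    p <- random_chain_params()
    top <- chain_from_params(p)
    traj <- sample_bonded_ensemble(top, n_steps = 4e5, seed = 300 + rep)
    targets <- compute_bonded_targets(traj, top, bin_width = bw)
    guess <- p
    guess$kb <- p$kb * runif(3, 0.7, 1.3)
    guess$ka <- p$ka * runif(2, 0.7, 1.3)
    guess$kphi <- p$kphi * runif(1, 0.7, 1.3)
    guess$b <- p$b * runif(3, 0.98, 1.02)
    guess$th <- p$th * runif(2, 0.98, 1.02)
    fit <- refine_parameters(chain_from_params(guess), targets,
                             seed = 400 + rep, n_steps = 4e5, tol = 0.0025,
                             bin_width = bw)
    expect_true(fit$converged)
    expect_lte(fit$iterations, 10L)
    expect_lt(max(abs(fit$topology$terms$c1 / top$terms$c1 - 1)), 0.10)
    expect_lt(max(abs(fit$topology$terms$c0[1:3] / top$terms$c0[1:3] - 1)),
              0.02)
  }
})

test_that("unreachable tolerance yields a non-convergence flag and best model", {
  top <- linear_chain_topology()
  traj <- sample_bonded_ensemble(top, n_steps = 2e4, seed = 60)
  targets <- compute_bonded_targets(traj, top)
  fit <- refine_parameters(top, targets, tol = 0, max_iters = 3, seed = 61,
                           n_steps = 2e4)
  expect_false(fit$converged)
  expect_true(all(fit$terms$jsd >= 0))
  expect_true(all(fit$topology$terms$c1 > 0, na.rm = TRUE))
  # best-seen metric equals the minimum of the history
  expect_equal(max(fit$terms$jsd),
               min(fit$history$metric_max))
})

test_that("near-rigid bond targets become constraints during refinement", {
  top <- bond_topology(b0 = 0.27, kb = 5e5)  # essentially rigid
  set.seed(71)
  tg <- list(bond_1_2 = make_distribution(rnorm(5e4, 0.27, 0.001), "bond"))
  fit <- refine_parameters(top, tg, seed = 71, n_steps = 1000)
  expect_equal(fit$topology$terms$kind, "constraint")
  expect_lt(abs(fit$topology$terms$c0 - 0.27), 0.001)
})

test_that("tidy and glance summarise a fit", {
  top <- linear_chain_topology()
  traj <- sample_bonded_ensemble(top, n_steps = 2e4, seed = 80)
  fit <- refine_parameters(top, compute_bonded_targets(traj, top),
                           seed = 80, n_steps = 2e4)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("term", "kind", "jsd", "c0", "c1") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})
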