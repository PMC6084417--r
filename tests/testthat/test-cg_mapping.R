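two_atom_frame <- function(x1, x2, box = c(10, 10, 10)) {
  cg_frame(tibble::tibble(
    molid = 1L, resid = 1L, resname = "TST", name = c("C1", "C2"),
    x = c(x1[1], x2[1]), y = c(x1[2], x2[2]), z = c(x1[3], x2[3])
  ), box = box)
}

test_that("beads sit at the mass-weighted centroid", {
  f <- two_atom_frame(c(0, 0, 0), c(1, 0, 0))
  sch <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C2"),
                                   weight = c(1, 1)))
  m <- map_frame(f, sch)
  expect_equal(c(m$x, m$y, m$z), c(0.5, 0, 0))
  # masses 12 and 1 at 0 and 1.3 -> 0.1
  sch2 <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C2"),
                                    weight = c(12, 1)))
  m2 <- map_frame(two_atom_frame(c(0, 0, 0), c(1.3, 0, 0)), sch2)
  expect_equal(m2$x, 0.1)
  expect_equal(m2$mass, 13)
})

test_that("groups split across the periodic boundary are unwrapped", {
  f <- two_atom_frame(c(9.9, 0, 0), c(0.1, 0, 0))
  sch <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C2"),
                                   weight = c(1, 1)))
  m <- map_frame(f, sch)
  # manual unwrap: 0.1 -> 10.1, centroid 10.0 (not the wrapped-mean 5.0)
  expect_equal(m$x %% 10, 0)
  expect_false(isTRUE(all.equal(m$x, 5)))
})

test_that("mapping commutes with translation and conserves mass", {
  set.seed(3)
  atoms <- tibble::tibble(
    molid = 1L, resid = 1L, resname = "TST",
    name = paste0("C", 1:6),
    x = runif(6, 2, 4), y = runif(6, 2, 4), z = runif(6, 2, 4)
  )
  f <- cg_frame(atoms, box = c(50, 50, 50))
  sch <- mapping_scheme(data.frame(
    bead = rep(c("B1", "B2"), each = 3), atom = paste0("C", 1:6),
    weight = runif(6, 1, 16)
  ))
  m <- map_frame(f, sch)
  expect_equal(sum(m$mass), sum(sch$weight))
  v <- c(1.5, -2, 0.25)
  f2 <- f; f2$x <- f$x + v[1]; f2$y <- f$y + v[2]; f2$z <- f$z + v[3]
  m2 <- map_frame(f2, sch)
  expect_equal(m2$x, m$x + v[1], tolerance = 1e-12)
  expect_equal(m2$z, m$z + v[3], tolerance = 1e-12)
})

test_that("mapping errors name the offending atoms", {
  f <- two_atom_frame(c(0, 0, 0), c(1, 0, 0))
  missing <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C9")))
  expect_error(map_frame(f, missing), "C9")
  partial <- mapping_scheme(data.frame(bead = "B", atom = "C1"))
  expect_error(map_frame(f, partial), "C2")
  expect_error(
    mapping_scheme(data.frame(bead = c("B1", "B2"), atom = c("C1", "C1"))),
    "more than one bead"
  )
})

test_that("trajectory mapping preserves frame count and times", {
  sch <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C2"),
                                   weight = c(1, 1)))
  frames <- lapply(1:10, function(k) {
    f <- two_atom_frame(c(k / 10, 0, 0), c(k / 10 + 1, 0, 0))
    attr(f, "time") <- k * 2
    f
  })
  traj <- cg_trajectory(frames)
  out <- map_trajectory(traj, sch)
  expect_equal(n_frames(out), 10L)
  expect_equal(frame_times(out), frame_times(traj))
  # identity scheme: one atom per bead, weight 1 -> coordinates unchanged
  ident <- mapping_scheme(data.frame(bead = c("C1", "C2"),
                                     atom = c("C1", "C2"), weight = c(1, 1)))
  f <- frames[[1]]
  m <- map_frame(f, ident)
  expect_equal(m$x, f$x)
  expect_equal(m$z, f$z)
  expect_error(cg_trajectory(list()), "empty")
})

test_that("scheme files round trip", {
  sch <- mapping_scheme(data.frame(
    bead = rep(c("B1", "B2"), each = 2), atom = c("C1", "H1", "C2", "O1")
  ), resname = "STY")
  tf <- withr::local_tempfile(fileext = ".map")
  write_mapping(sch, tf)
  back <- read_mapping(tf)
  expect_equal(back$bead, sch$bead)
  expect_equal(back$atom, sch$atom)
  expect_equal(back$weight, sch$weight, tolerance = 1e-6)
  expect_equal(attr(back, "resname"), "STY")
})
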