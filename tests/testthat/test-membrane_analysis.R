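test_that("radius of gyration matches closed forms and the pairwise oracle", {
  rod <- frame_from_xyz(rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(radius_of_gyration(rod)$rg, 0.5)
  single <- frame_from_xyz(rbind(c(2, 3, 4)))
  expect_equal(radius_of_gyration(single)$rg, 0)
  set.seed(12)
  xyz <- matrix(runif(150, 0, 3), ncol = 3)
  mass <- runif(50, 40, 80)
  f <- frame_from_xyz(xyz, mass = mass)
  rg <- radius_of_gyration(f)$rg
  # independent pairwise oracle: Rg^2 = sum_ij m_i m_j |ri-rj|^2 / (2 M^2)
  M <- sum(mass)
  s <- 0
  for (i in 1:49) for (j in (i + 1):50) {
    s <- s + mass[i] * mass[j] * sum((xyz[i, ] - xyz[j, ])^2)
  }
  expect_lt(abs(rg - sqrt(s / M^2)), 1e-10)
  expect_error(radius_of_gyration(f, name == "NOPE"), "empty selection")
})

test_that("rg unwraps molecules split across the box", {
  xyz <- rbind(c(9.8, 0, 0), c(0.2, 0, 0))  # a 0.4 nm rod across the wall
  f <- cg_frame(tibble::tibble(molid = 1L, resid = 1L, resname = "P",
                               name = c("A", "B"), mass = 1,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                box = c(10, 10, 10))
  expect_equal(radius_of_gyration(f)$rg, 0.2)
})

test_that("a uniform gas has a flat density profile (Poisson bound)", {
  set.seed(33)
  n <- 20000
  f <- cg_frame(tibble::tibble(molid = 1L, resid = 1L, resname = "W",
                               name = "W", mass = 72,
                               x = runif(n, 0, 5), y = runif(n, 0, 5),
                               z = runif(n, 0, 5)), box = c(5, 5, 5))
  dp <- density_profile(f, n_bins = 20)
  expect_cnt <- n / 20
  counts <- dp$density * (5 / 20) * 25
  expect_true(all(abs(counts - expect_cnt) <= 3 * sqrt(expect_cnt)))
  # integral recovers the particle count
  expect_equal(sum(dp$density) * (5 / 20) * 25, n)
})

test_that("ion asymmetry hits its symmetric and one-sided limits", {
  bl <- make_bilayer(6, 6, 0.63, 2.4)
  mid <- attr(bl, "midplane")
  ion_frame <- function(z) {
    cg_frame(dplyr::bind_rows(
      tibble::as_tibble(bl),
      tibble::tibble(molid = 9000L + seq_along(z), resid = 9000L + seq_along(z),
                     resname = "ION", name = "NA", mass = 23,
                     x = seq_along(z) * 0.3, y = 1, z = z)
    ), box = frame_box(bl) + c(0, 0, 2))
  }
  sym <- ion_frame(mid + c(-2, -1.2, 1.2, 2))
  expect_equal(ion_asymmetry(sym, resname == "ION", midplane = mid), 0)
  above <- ion_frame(mid + c(1, 1.5, 2))
  expect_equal(ion_asymmetry(above, resname == "ION", midplane = mid), 1)
  expect_error(ion_asymmetry(sym, resname == "XX"), "empty selection")
})

test_that("leaflet assignment splits a planted bilayer exactly in half", {
  bl <- make_bilayer(8, 8, 0.63, 2.4)
  lf <- assign_leaflets(bl)
  expect_equal(sum(lf$leaflet == "upper"), 64L)
  expect_equal(sum(lf$leaflet == "lower"), 64L)
  expect_error(assign_leaflets(frame_from_xyz(rbind(c(0, 0, 0)))), "head")
})

test_that("flip-flop counting respects the dwell window", {
  bl <- make_bilayer(4, 4, 0.63, 2.4)
  mid <- attr(bl, "midplane")
  flip <- function(f, mol) {
    sel <- f$molid == mol
    f$z[sel] <- 2 * mid - f$z[sel]
    f
  }
  # one lipid crosses at frame 6 of 12 and stays: exactly one event
  frames <- lapply(1:12, function(k) {
    f <- bl
    if (k >= 6) f <- flip(f, 3L)
    attr(f, "time") <- k
    f
  })
  ev <- count_flip_flops(cg_trajectory(frames), dwell = 5)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$molid, 3L)
  # flicker shorter than the dwell window: no events
  frames2 <- lapply(1:12, function(k) {
    f <- bl
    if (k %in% 6:8) f <- flip(f, 3L)
    attr(f, "time") <- k
    f
  })
  expect_equal(nrow(count_flip_flops(cg_trajectory(frames2), dwell = 5)), 0L)
})

test_that("dwell filtering matches a brute-force oracle on label series", {
  # oracle: walk the series; count changes that persist >= dwell frames
  oracle <- function(lab, dwell) {
    r <- rle(lab)
    keep <- r$lengths >= dwell
    v <- r$values[keep]
    if (length(v) < 2) 0L else sum(v[-1] != v[-length(v)])
  }
  set.seed(44)
  for (rep in 1:20) {
    lab <- sample(c("upper", "lower"), 40, replace = TRUE,
                  prob = c(0.7, 0.3))
    dwell <- sample(2:6, 1)
    got <- smalpr:::flip_events(lab, dwell, 1L, seq_along(lab))
    expect_equal(if (is.null(got)) 0L else nrow(got), oracle(lab, dwell))
  }
})

test_that("extracted lipids need both displacement and polymer contact", {
  bl <- make_bilayer(6, 6, 0.63, 2.4)
  box <- frame_box(bl) + c(0, 0, 6)
  lift <- function(f, mol, dz) {
    sel <- f$molid == mol
    f$z[sel] <- f$z[sel] + dz
    f
  }
  with_poly <- function(f, near_mol) {
    sel <- f$molid == near_mol
    cg_frame(dplyr::bind_rows(
      tibble::as_tibble(f),
      tibble::tibble(molid = 900L, resid = 900L, resname = "SMA",
                     name = "BB1", mass = 72,
                     x = mean(f$x[sel]), y = mean(f$y[sel]),
                     z = mean(f$z[sel]) + 0.3)
    ), box = box)
  }
  intact <- with_poly(bl, 1L)  # polymer sits near an in-membrane lipid
  expect_length(detect_extracted_lipids(intact), 0L)
  pulled <- with_poly(lift(bl, 7L, 4), 7L)
  expect_equal(detect_extracted_lipids(pulled), 7L)
  # displaced but far from any polymer: not extracted
  lonely <- with_poly(lift(bl, 7L, 4), 1L)
  expect_length(detect_extracted_lipids(lonely), 0L)
})
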