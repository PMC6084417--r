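test_that("constant geometries give delta-like histograms", {
  xyz <- rbind(c(0, 0, 0), c(0.27, 0, 0))
  traj <- cg_trajectory(lapply(1:5, function(k) frame_from_xyz(xyz)))
  d <- compute_distribution(traj, list(kind = "bond", idx = c(1, 2)))
  hot <- which(d$density > 0)
  expect_length(hot, 1L)
  expect_lt(abs(d$mid[hot] - 0.27), 0.001)
  expect_equal(sum(d$density * diff(attr(d, "edges"))), 1)
})

test_that("histogram moments match drawn Gaussian samples", {
  set.seed(2)
  s <- rnorm(1e5, 0.3, 0.02)
  d <- make_distribution(s, "bond")
  m <- sum(d$density * diff(attr(d, "edges")) * d$mid)
  v <- sum(d$density * diff(attr(d, "edges")) * (d$mid - m)^2)
  expect_lt(abs(m - 0.3), 0.001)
  expect_lt(abs(v / 4e-4 - 1), 0.05)
})

test_that("planar zig-zag measures a 180-degree dihedral", {
  xyz <- rbind(c(0, 0, 0), c(1, 1, 0), c(2, 0, 0), c(3, 1, 0))
  f <- frame_from_xyz(xyz)
  v <- measure_term(f, "dihedral_proper", 1:4)
  expect_equal(abs(as.numeric(v)), 180)
  # and a right angle measures 90 degrees
  xyz2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(as.numeric(measure_term(frame_from_xyz(xyz2), "angle", 1:3)), 90)
})

test_that("degenerate angle geometry is excluded with a warning", {
  xyz <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0))
  f <- frame_from_xyz(xyz)
  expect_warning(v <- measure_term(f, "angle", 1:3), "degenerate")
  expect_length(as.numeric(v), 0)
})

test_that("Jensen-Shannon distance honours its bounds", {
  set.seed(4)
  a <- make_distribution(rnorm(2e4, 0.30, 0.01), "bond")
  expect_equal(distribution_distance(a, a), 0)
  b <- make_distribution(rnorm(2e4, 0.60, 0.01), "bond")
  expect_equal(distribution_distance(a, b), 1, tolerance = 1e-6)
  expect_equal(distribution_overlap(a, b), 0, tolerance = 1e-6)
  # two Gaussians 5 sigma apart: numerically integrated JSD oracle
  grid <- seq(-0.1, 0.2, by = 1e-4)
  p <- dnorm(grid, 0, 0.01); q <- dnorm(grid, 0.05, 0.01)
  p <- p / sum(p); q <- q / sum(q); m <- (p + q) / 2
  kl <- function(x, y) { i <- x > 0; sum(x[i] * log2(x[i] / y[i])) }
  oracle <- (kl(p, m) + kl(q, m)) / 2
  a5 <- make_distribution(rnorm(5e4, 0.10, 0.01), "bond", bin_width = 0.001)
  b5 <- make_distribution(rnorm(5e4, 0.15, 0.01), "bond", bin_width = 0.001)
  expect_gt(oracle, 0.97)   # 5 sigma apart: almost disjoint
  expect_lt(abs(distribution_distance(a5, b5) - oracle), 0.02)
})

test_that("distance is symmetric and rebinning preserves normalisation", {
  set.seed(6)
  a <- make_distribution(rnorm(1e4, 0.3, 0.02), "bond")
  b <- make_distribution(rnorm(1e4, 0.31, 0.03), "bond", bin_width = 0.002)
  expect_equal(distribution_distance(a, b), distribution_distance(b, a))
  edges <- attr(a, "edges")
  coarse <- seq(min(edges), max(edges), length.out = 12)
  r <- rebin_distribution(a, coarse)
  expect_equal(sum(r$density * diff(coarse)), 1)
  # the mean is preserved to within half a coarse bin
  mean_of <- function(d) sum(d$density * diff(attr(d, "edges")) * d$mid)
  expect_lt(abs(mean_of(r) - mean_of(a)), diff(coarse)[1] / 2)
  expect_error(distribution_distance(a, make_distribution(runif(100, 0, 180),
                                                          "angle")),
               "different variable kinds")
})

test_that("two-column text output is XVG-flavoured", {
  d <- make_distribution(rnorm(1000, 0.3, 0.02), "bond", term_id = "bond_1_2")
  tf <- withr::local_tempfile(fileext = ".xvg")
  write_distribution(d, tf)
  lines <- readLines(tf)
  expect_true(any(grepl("^@ xaxis", lines)))
  body <- lines[!grepl("^[@#]", lines)]
  expect_equal(length(body), nrow(d))
})
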