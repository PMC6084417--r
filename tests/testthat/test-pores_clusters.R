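test_that("an intact bilayer has no pores and the grid areas conserve", {
  bl <- make_bilayer(20, 20, 0.63, 2.4)
  p <- detect_pores(bl)
  expect_equal(nrow(p), 0L)
  expect_equal(attr(p, "occupied_area") + attr(p, "empty_area"),
               attr(p, "grid_area"))
})

test_that("a planted circular pore is recovered at its size", {
  bl <- make_bilayer(26, 26, 0.63, 2.4)
  a <- sqrt(0.63)
  pf <- punch_pore(bl, c(13.5 * a, 13.5 * a), 2.0)
  p <- detect_pores(pf)
  expect_equal(nrow(p), 1L)
  expect_lt(abs(p$diameter[1] - 4.0), 0.6)        # two grid cells
  expect_equal(p$diameter[1], 2 * sqrt(p$area[1] / pi))
  expect_equal(p$radius[1], p$diameter[1] / 2)
})

test_that("planted-pore diameters are accurate across radii and placements", {
  bl <- make_bilayer(26, 26, 0.63, 2.4)
  box <- frame_box(bl)
  set.seed(7)
  for (r in c(1, 2, 3.5, 5)) {
    for (k in 1:2) {
      ctr <- runif(2, 6, box[1] - 6)
      p <- detect_pores(punch_pore(bl, ctr, r))
      expect_equal(nrow(p), 1L)
      expect_lt(abs(p$diameter[1] - 2 * r), 0.6)
    }
  }
})

test_that("pores straddling the periodic boundary are one pore", {
  bl <- make_bilayer(20, 20, 0.63, 2.4)
  p <- detect_pores(punch_pore(bl, c(0, 8), 2.0))
  expect_equal(nrow(p), 1L)
  expect_lt(abs(p$diameter[1] - 4.0), 0.6)
  # oracle: area must match the same pore punched in the box centre
  ctr <- detect_pores(punch_pore(bl, frame_box(bl)[1:2] / 2, 2.0))
  expect_lt(abs(p$area[1] - ctr$area[1]) / ctr$area[1], 0.25)
})

test_that("two separated pores are reported separately", {
  bl <- make_bilayer(26, 26, 0.63, 2.4)
  pf <- punch_pore(punch_pore(bl, c(5, 5), 1.5), c(14, 14), 2.0)
  p <- detect_pores(pf)
  expect_equal(nrow(p), 2L)
  expect_gt(p$area[1], p$area[2])  # ordered by size
})

test_that("pore tracking follows a growing pore across frames", {
  bl <- make_bilayer(20, 20, 0.63, 2.4)
  ctr <- frame_box(bl)[1:2] / 2
  frames <- lapply(seq(1, 3, by = 0.5), function(r) {
    f <- punch_pore(bl, ctr, r)
    attr(f, "time") <- r * 10
    f
  })
  kin <- pore_kinetics(frames)
  expect_equal(length(unique(kin$track_id)), 1L)
  expect_true(all(diff(kin$area) > 0))  # monotone growth
})

test_that("toroidal rims pull headgroups into the pore mouth", {
  bl <- make_bilayer(20, 20, 0.63, 2.4)
  ctr <- frame_box(bl)[1:2] / 2
  plain <- punch_pore(bl, ctr, 2.0, toroidal = FALSE)
  toro <- punch_pore(bl, ctr, 2.0, toroidal = TRUE)
  rim_heads <- function(f) {
    h <- f[grepl("NC3|PO4", f$name), ]
    d <- sqrt((h$x - ctr[1])^2 + (h$y - ctr[2])^2)
    mean(d[d < 3.2])
  }
  expect_lt(rim_heads(toro), rim_heads(plain))
  expect_equal(nrow(detect_pores(toro)), 1L)
})

test_that("aggregate partitions equal a brute-force union-find oracle", {
  uf_oracle <- function(xyz, box, cutoff) {
    n <- nrow(xyz)
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- xyz[j, ] - xyz[i, ]
      d <- d - round(d / box) * box
      if (sum(d^2) <= cutoff^2) {
        a <- find(i); b <- find(j)
        if (a != b) parent[a] <- b
      }
    }
    vapply(seq_len(n), find, integer(1))
  }
  set.seed(15)
  for (rep in 1:5) {
    n <- 60
    xyz <- matrix(runif(3 * n, 0, 6), ncol = 3)
    f <- cg_frame(tibble::tibble(molid = seq_len(n), resid = seq_len(n),
                                 resname = "W", name = "W", mass = 72,
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                  box = c(6, 6, 6))
    got <- find_aggregates(f, cutoff = 0.9)
    want <- uf_oracle(xyz, c(6, 6, 6), 0.9)
    # same partition: cluster labels must be a bijection of oracle roots
    expect_equal(length(unique(got$beads$cluster)), length(unique(want)))
    tab <- table(got$beads$cluster, want)
    expect_true(all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1))
  }
})

test_that("cluster labelling is invariant under particle re-ordering", {
  set.seed(16)
  n <- 40
  xyz <- matrix(runif(3 * n, 0, 5), ncol = 3)
  f <- cg_frame(tibble::tibble(molid = seq_len(n), resid = seq_len(n),
                               resname = "W", name = "W", mass = 72,
                               x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]),
                box = c(5, 5, 5))
  perm <- sample(n)
  f2 <- cg_frame(tibble::as_tibble(f)[perm, ], box = c(5, 5, 5))
  a <- find_aggregates(f, cutoff = 0.8)$molecules
  b <- find_aggregates(f2, cutoff = 0.8)$molecules
  expect_equal(dplyr::arrange(a, molid), dplyr::arrange(b, molid))
})

test_that("separated chains cluster apart; one blob clusters together", {
  chain <- function(x0, molid) {
    tibble::tibble(molid = molid, resid = molid, resname = "SMA",
                   name = paste0("B", 1:5), mass = 72,
                   x = x0 + (0:4) * 0.3, y = 1, z = 1)
  }
  f <- cg_frame(dplyr::bind_rows(chain(1, 1L), chain(8, 2L)),
                box = c(20, 20, 20))
  expect_equal(find_aggregates(f, cutoff = 0.6)$n_clusters, 2L)
  f2 <- cg_frame(dplyr::bind_rows(chain(1, 1L), chain(1.15, 2L)),
                 box = c(20, 20, 20))
  expect_equal(find_aggregates(f2, cutoff = 0.6)$n_clusters, 1L)
  expect_error(find_aggregates(f, cutoff = -1), "positive")
})

test_that("planted nanodisks are characterized faithfully", {
  nd <- make_nanodisk(150, 0.63, n_polymers = 1)
  rec <- characterize_disk(nd, attr(nd, "lipid_molids"))
  expect_equal(rec$n_lipids, 150L)
  expect_equal(rec$leaflet_upper, 75L)
  expect_equal(rec$leaflet_lower, 75L)
  expect_equal(rec$n_polymers, 1L)
  expect_gte(rec$diameter, 7); expect_lte(rec$diameter, 9)
  expect_lt(rec$planarity, 0.2)
  # diameter within 5% of the geometric value across sizes
  for (n in c(50, 150, 400)) {
    d <- make_nanodisk(n, 0.63, n_polymers = 0)
    r <- characterize_disk(d, attr(d, "lipid_molids"))
    expect_lt(abs(r$diameter / attr(d, "diameter_geometric") - 1), 0.05)
    expect_equal(r$n_polymers, 0L)
  }
  expect_error(characterize_disk(nd, 1:2), "at least 3")
})
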