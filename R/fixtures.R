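#' Coarse-grained lipid template
#'
#' An 8-bead phosphatidylcholine stand-in (choline, phosphate, two
#' glycerols, two tails of `n_tail_beads` beads) described by fractional
#' depth below the head surface (0 = head, 1 = bilayer midplane) and small
#' xy offsets that spread the two tails. The default 2-bead tails model a
#' short-tail didecanoyl-PC (DDPC); 3 or 4 tail beads give
#' dimyristoyl/dipalmitoyl-length analogues.
#'
#' @param n_tail_beads beads per acyl tail (2-4).
#' @return Tibble with `name`, `role`, `depth`, `dx`, `dy`, `mass`.
#' @export
lipid_template <- function(n_tail_beads = 2) {
  stopifnot(n_tail_beads >= 1, n_tail_beads <= 4)
  tails <- purrr::map_dfr(c("A", "B"), function(chain) {
    s <- if (chain == "A") -0.16 else 0.16
    tibble::tibble(
      name = paste0("C", seq_len(n_tail_beads), chain),
      role = "tail",
      depth = 0.35 + 0.65 * seq_len(n_tail_beads) / n_tail_beads,
      dx = s, dy = 0, mass = 72
    )
  })
  dplyr::bind_rows(
    tibble::tibble(
      name = c("NC3", "PO4", "GL1", "GL2"),
      role = c("head", "head", "glycerol", "glycerol"),
      depth = c(0, 0.125, 0.3, 0.3),
      dx = c(0, 0, -0.16, 0.16), dy = c(0, 0, 0, 0), mass = 72
    ),
    tails
  )
}

#' Build a planted lipid bilayer on a lattice
#'
#' Two leaflets of `nx * ny` lipids each on a square lattice with spacing
#' `sqrt(area_per_lipid)`, heads outward and tails meeting at the midplane.
#' The box fits the lattice exactly, so the realised area per lipid equals
#' the request. 26 x 26 reproduces the 1352-lipid reference system.
#'
#' @param nx,ny lattice dimensions (>= 2).
#' @param area_per_lipid nm^2 per lipid per leaflet.
#' @param thickness bilayer (head-to-head) thickness, nm.
#' @param template lipid bead table from [lipid_template()].
#' @param resname residue name stamped on the lipids.
#' @param water_margin empty solvent space above and below, nm.
#' @return A `cg_frame`; attribute `midplane` gives the bilayer midplane z.
#' @export
make_bilayer <- function(nx = 26, ny = 26, area_per_lipid = 0.63,
                         thickness = 2.4, template = lipid_template(),
                         resname = "DDPC", water_margin = 2) {
  if (nx < 2 || ny < 2) stop("nx and ny must be >= 2", call. = FALSE)
  if (area_per_lipid <= 0 || thickness <= 0) {
    stop("area_per_lipid and thickness must be positive", call. = FALSE)
  }
  a <- sqrt(area_per_lipid)
  box <- c(nx * a, ny * a, thickness + 2 * water_margin)
  z0 <- box[3] / 2
  half <- thickness / 2
  sites <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
  place <- function(leaflet) {
    sgn <- if (leaflet == "upper") 1 else -1
    purrr::pmap_dfr(sites, function(i, j) {
      tibble::tibble(
        name = template$name, mass = template$mass,
        x = (i + 0.5) * a + template$dx,
        y = (j + 0.5) * a + template$dy,
        z = z0 + sgn * (half - template$depth * half)
      )
    })
  }
  up <- place("upper"); lo <- place("lower")
  nlip <- nrow(sites)
  nb <- nrow(template)
  atoms <- dplyr::bind_rows(up, lo)
  atoms$molid <- rep(seq_len(2L * nlip), each = nb)
  atoms$resid <- atoms$molid
  atoms$resname <- resname
  f <- cg_frame(atoms, box = box)
  attr(f, "midplane") <- z0
  f
}

#' Punch a pore into a planted bilayer
#'
#' Removes every lipid whose xy centroid lies within `radius` of `center`
#' (minimum image). With `toroidal = TRUE`, rim lipids (within `rim_width`
#' outside the pore edge) are tilted head-inward so headgroups line the
#' aqueous channel, emulating a toroidal pore.
#'
#' @param frame a bilayer `cg_frame` (e.g. from [make_bilayer()]).
#' @param center xy pore centre, nm.
#' @param radius pore radius, nm (0 leaves the frame unchanged).
#' @param toroidal tilt rim lipids head-inward.
#' @param rim_width rim annulus width, nm.
#' @return A `cg_frame`; attribute `removed_molids` lists the deleted
#'   lipids.
#' @export
punch_pore <- function(frame, center, radius, toroidal = FALSE,
                       rim_width = 0.8) {
  stopifnot(inherits(frame, "cg_frame"), length(center) == 2, radius >= 0)
  if (radius == 0) {
    attr(frame, "removed_molids") <- integer()
    return(frame)
  }
  box <- frame_box(frame)
  cent <- frame |>
    dplyr::group_by(.data$molid) |>
    dplyr::summarise(cx = mean(.data$x), cy = mean(.data$y),
                     .groups = "drop")
  dx <- cent$cx - center[1]; dx <- dx - round(dx / box[1]) * box[1]
  dy <- cent$cy - center[2]; dy <- dy - round(dy / box[2]) * box[2]
  d <- sqrt(dx^2 + dy^2)
  gone <- cent$molid[d < radius]
  out <- frame[!frame$molid %in% gone, ]
  if (toroidal) {
    rim <- cent$molid[d >= radius & d < radius + rim_width]
    mid <- attr(frame, "midplane")
    if (is.null(mid)) mid <- stats::median(out$z)
    heads <- out$molid %in% rim & grepl(DEFAULT_HEAD_PATTERN, out$name)
    if (any(heads)) {
      hx <- out$x[heads] - center[1]
      hx <- hx - round(hx / box[1]) * box[1]
      hy <- out$y[heads] - center[2]
      hy <- hy - round(hy / box[2]) * box[2]
      hd <- pmax(sqrt(hx^2 + hy^2), 1e-6)
      # pull heads toward the pore axis and half-way to the midplane
      out$x[heads] <- out$x[heads] - 0.3 * hx / hd
      out$y[heads] <- out$y[heads] - 0.3 * hy / hd
      out$z[heads] <- out$z[heads] - 0.5 * (out$z[heads] - mid)
    }
  }
  f <- cg_frame(out, box = box, time = frame_time(frame))
  attr(f, "midplane") <- attr(frame, "midplane")
  attr(f, "removed_molids") <- sort(gone)
  f
}

#' Build a planted SMALP nanodisk
#'
#' A circular bilayer patch of `n_lipids` lipids (split evenly between
#' leaflets) laid out on concentric rings whose outermost ring sits at the
#' nominal disk radius `sqrt(n_half * area_per_lipid / pi)`, so the
#' realised area per lipid matches the request and the disk edge is well
#' populated. `n_polymers` SMA chains are wound along the rim at
#' `rim_offset` outside the lipid edge.
#'
#' @param n_lipids total lipid count (>= 6).
#' @param area_per_lipid nm^2 per lipid per leaflet.
#' @param n_polymers rim polymer chains (0 for a bare disk).
#' @param polymer_topology topology for the rim chains; defaults to the
#'   23-unit fully deprotonated chain when `n_polymers > 0`.
#' @param thickness bilayer thickness, nm.
#' @param rim_offset polymer rim clearance outside the lipid edge, nm.
#' @param template lipid bead table.
#' @param margin empty box margin around the disk, nm.
#' @return A `cg_frame` with lipids (`resname "DDPC"`) and rim polymers
#'   (`resname "SMA"`). Attributes: `diameter_geometric` (nm),
#'   `lipid_molids`, `polymer_molids`, `midplane`.
#' @export
make_nanodisk <- function(n_lipids = 150, area_per_lipid = 0.63,
                          n_polymers = 1, polymer_topology = NULL,
                          thickness = 2.4, rim_offset = 0.5,
                          template = lipid_template(), margin = 3) {
  if (n_lipids < 6) stop("need at least 6 lipids", call. = FALSE)
  if (area_per_lipid <= 0) stop("area_per_lipid must be positive",
                                call. = FALSE)
  n_up <- ceiling(n_lipids / 2)
  n_lo <- n_lipids - n_up
  r_disk <- sqrt(n_up * area_per_lipid / pi)
  # concentric rings, ring capacity proportional to circumference, the
  # outermost exactly at r_disk
  rings <- function(n) {
    m <- max(1L, round(r_disk / sqrt(area_per_lipid)))
    w <- 2 * seq_len(m) - 1
    n_i <- floor(n * w / sum(w))
    rem <- n - sum(n_i)
    if (rem > 0) {
      top <- order(w, decreasing = TRUE)[seq_len(rem)]
      n_i[top] <- n_i[top] + 1L
    }
    out <- matrix(numeric(), 0, 2)
    for (i in seq_len(m)) {
      if (n_i[i] == 0) next
      th <- 2 * pi * (seq_len(n_i[i]) - 1) / n_i[i] + 0.5 * i
      r <- r_disk * i / m
      out <- rbind(out, cbind(r * cos(th), r * sin(th)))
    }
    out
  }
  half <- thickness / 2
  L <- 2 * (r_disk + rim_offset) + 2 * margin
  box <- c(L, L, thickness + 2 * margin)
  ctr <- c(L / 2, L / 2)
  z0 <- box[3] / 2
  nb <- nrow(template)
  leaflet_atoms <- function(xy, sgn) {
    purrr::map_dfr(seq_len(nrow(xy)), function(k) {
      tibble::tibble(
        name = template$name, mass = template$mass,
        x = ctr[1] + xy[k, 1] + template$dx,
        y = ctr[2] + xy[k, 2] + template$dy,
        z = z0 + sgn * (half - template$depth * half)
      )
    })
  }
  atoms <- dplyr::bind_rows(leaflet_atoms(rings(n_up), 1),
                            leaflet_atoms(rings(n_lo), -1))
  atoms$molid <- rep(seq_len(n_lipids), each = nb)
  atoms$resid <- atoms$molid
  atoms$resname <- "DDPC"
  poly_molids <- integer()
  if (n_polymers > 0) {
    if (is.null(polymer_topology)) polymer_topology <- build_sma_chain(23)
    npb <- n_beads(polymer_topology)
    r_rim <- r_disk + rim_offset
    dth <- 0.26 / r_rim                 # ~bond-length arc spacing
    for (p in seq_len(n_polymers)) {
      th0 <- 2 * pi * (p - 1) / n_polymers
      th <- th0 + dth * (seq_len(npb) - 1)
      molid <- n_lipids + p
      poly_molids <- c(poly_molids, molid)
      atoms <- dplyr::bind_rows(atoms, tibble::tibble(
        molid = molid, resid = molid, resname = "SMA",
        name = polymer_topology$beads$name,
        mass = polymer_topology$beads$mass,
        x = ctr[1] + r_rim * cos(th),
        y = ctr[2] + r_rim * sin(th),
        z = z0 + 0.15 * rep_len(c(-1, 1), npb)
      ))
    }
  }
  f <- cg_frame(atoms, box = box)
  attr(f, "midplane") <- z0
  attr(f, "diameter_geometric") <- 2 * r_disk
  attr(f, "lipid_molids") <- seq_len(n_lipids)
  attr(f, "polymer_molids") <- poly_molids
  f
}

#' Draw an independent reference ensemble from bonded Boltzmann densities
#'
#' Ground-truth generator for parameter-recovery tests: every fitted term
#' of `topology` is sampled directly from the Boltzmann density of its
#' potential (Gaussian for bonds; Gaussian in `cos(theta)` for angles,
#' truncated to `[-1, 1]`; rejection sampling under the periodic potential
#' for proper dihedrals; wrapped Gaussian for impropers), with no Monte
#' Carlo involved. Alongside the raw draws it returns analytic target
#' histograms (the normalised Boltzmann density evaluated on the bin grid)
#' and, for unbranched constraint-free chains, coordinates built from the
#' drawn internal coordinates.
#'
#' @param topology an `sma_topology`.
#' @param n draws per term.
#' @param temperature K.
#' @param seed RNG seed; identical seeds give identical output.
#' @param bin_width optional named per-variable bin width overrides.
#' @return List with `samples` (named list of numeric vectors), `targets`
#'   (named list of `sma_distribution`), and `traj` (a `cg_traj` of `n`
#'   frames, or `NULL` when the topology is branched or constrained).
#' @export
sample_reference_ensemble <- function(topology, n = 1e5, temperature = 310,
                                      seed = 1, bin_width = NULL) {
  validate_topology(topology)
  kT <- KB * temperature
  t <- topology$terms
  fit <- t[t$kind %in% FITTED_KINDS, ]
  keys <- term_key(fit)
  bw <- function(variable) {
    if (!is.null(bin_width) && variable %in% names(bin_width)) {
      unname(bin_width[variable])
    } else default_bin_width(variable)
  }
  res <- with_seed(seed, function() {
    samples <- list(); targets <- list()
    for (r in seq_len(nrow(fit))) {
      kind <- fit$kind[r]
      if (kind == "bond") {
        s <- stats::rnorm(n, fit$c0[r], sqrt(kT / fit$c1[r]))
        s <- abs(s)  # lengths are positive; reflection negligible in range
        edges <- NULL
        dens <- function(x) exp(-(x - fit$c0[r])^2 * fit$c1[r] / (2 * kT))
        d <- make_distribution(s, "bond", bin_width = bw("length"),
                               term_id = keys[r])
        d$density <- analytic_density(attr(d, "edges"), dens)
      } else if (kind == "angle") {
        u0 <- cos(fit$c0[r] * pi / 180)
        sd <- sqrt(kT / fit$c1[r])
        u <- numeric(0)
        while (length(u) < n) {
          cand <- stats::rnorm(ceiling((n - length(u)) * 1.5) + 16, u0, sd)
          u <- c(u, cand[cand >= -1 & cand <= 1])
        }
        u <- u[seq_len(n)]
        s <- acos(u) * 180 / pi
        dens <- function(x) exp(-(cos(x * pi / 180) - u0)^2 *
                                  fit$c1[r] / (2 * kT)) *
          sin(x * pi / 180) * pi / 180
        d <- make_distribution(s, "angle", bin_width = bw("angle"),
                               term_id = keys[r])
        d$density <- analytic_density(attr(d, "edges"), dens)
      } else if (kind == "dihedral_proper") {
        pot <- function(phi) fit$c1[r] *
          (1 + cos(fit$c2[r] * phi * pi / 180 - fit$c0[r] * pi / 180))
        s <- rejection_sample_dihedral(n, pot, kT)
        dens <- function(x) exp(-pot(x) / kT)
        d <- make_distribution(s, "dihedral_proper",
                               bin_width = bw("dihedral"), term_id = keys[r])
        d$density <- analytic_density(attr(d, "edges"), dens)
      } else {
        sd <- sqrt(kT / fit$c1[r]) * 180 / pi
        s <- stats::rnorm(n, fit$c0[r], sd)
        s <- ((s + 180) %% 360) - 180
        s[s <= -180] <- s[s <= -180] + 360
        dens <- function(x) {
          dx <- ((x - fit$c0[r] + 180) %% 360) - 180
          exp(-(dx * pi / 180)^2 * fit$c1[r] / (2 * kT))
        }
        d <- make_distribution(s, "dihedral_improper",
                               bin_width = bw("dihedral"), term_id = keys[r])
        d$density <- analytic_density(attr(d, "edges"), dens)
      }
      samples[[keys[r]]] <- s
      targets[[keys[r]]] <- d
    }
    list(samples = samples, targets = targets)
  })
  res$traj <- build_chain_traj(topology, res$samples, n)
  res
}

# Normalised analytic density on a bin grid (midpoint evaluation).
analytic_density <- function(edges, dens) {
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  w <- diff(edges)
  v <- dens(mids)
  v / sum(v * w)
}

rejection_sample_dihedral <- function(n, pot, kT) {
  umin <- min(pot(seq(-180, 180, by = 0.5)))
  out <- numeric(0)
  while (length(out) < n) {
    m <- ceiling((n - length(out)) * 2.5)
    x <- stats::runif(m, -180, 180)
    acc <- stats::runif(m) < exp(-(pot(x) - umin) / kT)
    out <- c(out, x[acc])
  }
  s <- out[seq_len(n)]
  s[s <= -180] <- s[s <= -180] + 360
  s
}

# Build frames from drawn internal coordinates for an unbranched,
# constraint-free chain (NeRF-style placement); NULL otherwise.
build_chain_traj <- function(topology, samples, n) {
  t <- topology$terms
  if (any(t$kind == "constraint")) return(NULL)
  nb <- n_beads(topology)
  bonds <- t[t$kind == "bond", ]
  chain <- all(bonds$i == seq_len(nb - 1) & bonds$j == 2:nb) &&
    nrow(bonds) == nb - 1
  if (!chain || nb < 2) return(NULL)
  key_of <- function(kind, idx) paste(c(kind, idx), collapse = "_")
  get_samples <- function(kind, idx, default) {
    k <- key_of(kind, idx)
    if (k %in% names(samples)) samples[[k]] else rep(default, n)
  }
  b <- lapply(seq_len(nb - 1), function(i) {
    get_samples("bond", c(i, i + 1), 0.3)
  })
  a <- if (nb >= 3) lapply(seq_len(nb - 2), function(i) {
    get_samples("angle", c(i, i + 1, i + 2), 120) * pi / 180
  }) else list()
  dih <- if (nb >= 4) lapply(seq_len(nb - 3), function(i) {
    get_samples("dihedral_proper", c(i, i + 1, i + 2, i + 3), 180) * pi / 180
  }) else list()
  arr <- array(0, dim = c(n, nb, 3))
  arr[, 2, 1] <- b[[1]]
  if (nb >= 3) {
    th <- pi - a[[1]]
    arr[, 3, 1] <- arr[, 2, 1] + b[[2]] * cos(th)
    arr[, 3, 2] <- b[[2]] * sin(th)
  }
  if (nb >= 4) {
    for (i in 4:nb) {
      p1 <- arr[, i - 3, ]; p2 <- arr[, i - 2, ]; p3 <- arr[, i - 1, ]
      bl <- b[[i - 1]]; th <- a[[i - 2]]; ph <- dih[[i - 3]]
      e1 <- p3 - p2
      e1 <- e1 / sqrt(rowSums(e1^2))
      v12 <- p1 - p2
      nrm <- cross3(v12, e1)
      nrm <- nrm / pmax(sqrt(rowSums(nrm^2)), 1e-12)
      m1 <- cross3(nrm, e1)
      d <- cbind(-bl * cos(th), -bl * sin(th) * cos(ph),
                 -bl * sin(th) * sin(ph))
      arr[, i, ] <- p3 + d[, 1] * e1 + d[, 2] * m1 + d[, 3] * nrm
    }
  }
  template <- tibble::tibble(
    molid = 1L, resid = 1L,
    resname = substr(topology$molecule_name, 1, 5),
    name = topology$beads$name, mass = topology$beads$mass,
    x = 0, y = 0, z = 0
  )
  frames <- vector("list", n)
  box <- rep(1e6, 3)
  for (s in seq_len(n)) {
    f <- template
    f$x <- arr[s, , 1]; f$y <- arr[s, , 2]; f$z <- arr[s, , 3]
    frames[[s]] <- structure(f, box = box, time = s,
                             class = c("cg_frame", class(tibble::tibble())))
  }
  traj <- cg_trajectory(frames)
  attr(traj, "samples") <- arr
  traj
}
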