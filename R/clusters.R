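#' Find aggregates by single-linkage distance clustering
#'
#' Connected components of the selected beads under a minimum-image
#' distance cutoff (single linkage), computed with a cell list and
#' igraph components. Each molecule is assigned to the cluster containing
#' its beads; cluster labels are canonical (decreasing bead count, ties by
#' smallest molid), so the partition does not depend on particle order.
#'
#' @inheritParams radius_of_gyration
#' @param frame a `cg_frame`.
#' @param cutoff linkage distance, nm (> 0).
#' @return A list with `beads` (tibble: row, molid, cluster), `molecules`
#'   (tibble: molid, cluster, n_beads) and `n_clusters`.
#' @export
find_aggregates <- function(frame, ..., cutoff = 0.6) {
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  dots <- rlang::enquos(...)
  rows <- select_rows(frame, dots)
  if (length(rows) == 0) stop("empty selection", call. = FALSE)
  sub <- frame[rows, ]
  box <- frame_box(frame)
  xyz <- coords_matrix(sub)
  pairs <- neighbor_pairs(xyz, box, cutoff)
  g <- igraph::make_empty_graph(n = nrow(sub), directed = FALSE)
  if (nrow(pairs) > 0) g <- igraph::add_edges(g, t(pairs))
  memb <- igraph::components(g)$membership
  # canonical labels: size desc, then smallest molid
  info <- tibble::tibble(raw = memb, molid = sub$molid) |>
    dplyr::group_by(.data$raw) |>
    dplyr::summarise(n = dplyr::n(), mmin = min(.data$molid),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$mmin) |>
    dplyr::mutate(cluster = dplyr::row_number())
  relabel <- info$cluster[match(memb, info$raw)]
  beads <- tibble::tibble(row = rows, molid = sub$molid, cluster = relabel)
  mols <- beads |>
    dplyr::group_by(.data$molid) |>
    dplyr::summarise(cluster = min(.data$cluster), n_beads = dplyr::n(),
                     .groups = "drop")
  list(beads = beads, molecules = mols, n_clusters = max(relabel))
}

# All bead pairs within cutoff (minimum image), via cutoff-sized cell bins.
neighbor_pairs <- function(xyz, box, cutoff) {
  n <- nrow(xyz)
  if (n < 2) return(matrix(integer(), 0, 2))
  nxyz <- pmax(1L, floor(box / cutoff))
  cs <- box / nxyz
  ci <- floor(sweep(xyz %% rep(box, each = n), 2, cs, "/"))
  ci <- sweep(ci, 2, nxyz, "%%")
  key <- ci[, 1] + nxyz[1] * (ci[, 2] + nxyz[2] * ci[, 3])
  cells <- split(seq_len(n), key)
  cell_of <- stats::setNames(names(cells), names(cells))
  # neighbour cell offsets (half to avoid double visits handled by i<j test)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  out <- list()
  keymap <- new.env()
  for (nm in names(cells)) assign(nm, cells[[nm]], envir = keymap)
  for (nm in names(cells)) {
    idx <- cells[[nm]]
    k <- as.numeric(nm)
    c0 <- c(k %% nxyz[1],
            (k %/% nxyz[1]) %% nxyz[2],
            k %/% (nxyz[1] * nxyz[2]))
    for (o in seq_len(nrow(offs))) {
      cn <- (c0 + offs[o, ]) %% nxyz
      kn <- cn[1] + nxyz[1] * (cn[2] + nxyz[2] * cn[3])
      other <- keymap[[as.character(kn)]]
      if (is.null(other)) next
      pr <- expand.grid(i = idx, j = other)
      pr <- pr[pr$i < pr$j, , drop = FALSE]
      if (nrow(pr) == 0) next
      d <- min_image(xyz[pr$j, , drop = FALSE] - xyz[pr$i, , drop = FALSE],
                     box)
      hit <- rowSums(d^2) <= cutoff^2
      if (any(hit)) out[[length(out) + 1L]] <- cbind(pr$i[hit], pr$j[hit])
    }
  }
  if (length(out) == 0) return(matrix(integer(), 0, 2))
  unique(do.call(rbind, out))
}

#' Characterize a lipid nanodisk
#'
#' Fits the disk plane by principal axes of the per-lipid centroids,
#' reports the equivalent-circle diameter of the convex hull of all lipid
#' beads projected into that plane, per-leaflet lipid counts (sign of head
#' position along the plane normal), planarity (RMS deviation of the
#' bilayer midsurface, taken as the terminal tail beads, from the plane,
#' nm) and the number of polymer chains bound to the disk (chains with at
#' least half their beads within `assoc_cutoff` of a lipid bead).
#'
#' @param frame a `cg_frame`.
#' @param lipids integer molids of one connected lipid aggregate (>= 3).
#' @param polymers molids of candidate polymer chains; default every
#'   molecule with resname `"SMA"`.
#' @param assoc_cutoff polymer-lipid association distance, nm.
#' @param head_pattern regex for lipid head beads.
#' @param tail_pattern regex for lipid tail beads (midsurface/planarity).
#' @return A `disk_record` tibble (one row): `n_lipids`, `leaflet_upper`,
#'   `leaflet_lower`, `n_polymers`, `area` (nm^2), `diameter` (nm),
#'   `planarity` (nm). The diameter convention (equivalent circle of the
#'   convex-hull area) is recorded in the `diameter_convention` attribute.
#' @export
characterize_disk <- function(frame, lipids, polymers = NULL,
                              assoc_cutoff = 1.0,
                              head_pattern = DEFAULT_HEAD_PATTERN,
                              tail_pattern = DEFAULT_TAIL_PATTERN) {
  stopifnot(inherits(frame, "cg_frame"))
  lipids <- unique(lipids)
  if (length(lipids) < 3) stop("need at least 3 lipids", call. = FALSE)
  box <- frame_box(frame)
  lb <- frame[frame$molid %in% lipids, ]
  if (nrow(lb) == 0) stop("no beads for the given lipid molids", call. = FALSE)
  xyz <- unwrap_group(coords_matrix(lb), box)
  cent <- rowsum(xyz, lb$molid) / as.vector(table(lb$molid))
  pc <- stats::prcomp(cent, center = TRUE, scale. = FALSE)
  normal <- pc$rotation[, 3]
  # midsurface = terminal tail beads (highest tail index per lipid chain)
  tsel <- grepl(tail_pattern, lb$name)
  planarity <- if (any(tsel)) {
    tno <- suppressWarnings(as.integer(gsub("\\D", "", lb$name)))
    term <- tsel & !is.na(tno) & tno == max(tno[tsel], na.rm = TRUE)
    if (!any(term)) term <- tsel
    sqrt(mean((sweep(xyz[term, , drop = FALSE], 2, pc$center) %*% normal)^2))
  } else sqrt(mean(pc$x[, 3]^2))
  # project every lipid bead into the disk plane
  rel <- sweep(xyz, 2, pc$center)
  uv <- rel %*% pc$rotation[, 1:2]
  hull <- grDevices::chull(uv)
  area <- polygon_area(uv[hull, , drop = FALSE])
  # leaflets from head beads relative to the fitted plane
  hsel <- grepl(head_pattern, lb$name)
  hz <- if (any(hsel)) {
    rowsum((rel %*% normal)[hsel], lb$molid[hsel]) /
      as.vector(table(lb$molid[hsel]))
  } else rowsum(rel %*% normal, lb$molid) / as.vector(table(lb$molid))
  upper <- sum(hz >= 0); lower <- sum(hz < 0)
  # bound polymer chains
  if (is.null(polymers)) polymers <- unique(frame$molid[frame$resname == "SMA"])
  n_poly <- 0L
  for (p in polymers) {
    pb <- coords_matrix(frame[frame$molid == p, ])
    if (nrow(pb) == 0) next
    near <- vapply(seq_len(nrow(pb)), function(r) {
      d <- min_image(xyz - matrix(pb[r, ], nrow(xyz), 3, byrow = TRUE), box)
      min(rowSums(d^2)) <= assoc_cutoff^2
    }, logical(1))
    if (mean(near) >= 0.5) n_poly <- n_poly + 1L
  }
  structure(
    tibble::tibble(
      n_lipids = length(unique(lb$molid)),
      leaflet_upper = upper, leaflet_lower = lower,
      n_polymers = n_poly, area = area,
      diameter = 2 * sqrt(area / pi), planarity = planarity
    ),
    diameter_convention = "equivalent circle of convex-hull area",
    class = c("disk_record", class(tibble::tibble()))
  )
}

# Shoelace area of a planar polygon given as ordered vertices.
polygon_area <- function(v) {
  n <- nrow(v)
  i2 <- c(2:n, 1)
  abs(sum(v[, 1] * v[i2, 2] - v[i2, 1] * v[, 2])) / 2
}

#' Detect lipids extracted from the membrane into polymer aggregates
#'
#' A lipid counts as extracted when all of its tail beads lie outside the
#' membrane slab and at least one of its beads is within `cutoff` of a
#' polymer bead (minimum image).
#'
#' @param frame a `cg_frame`.
#' @param slab numeric `c(zmin, zmax)` of the membrane slab (nm), or
#'   `NULL` to infer `midplane +- half_width` from tail beads.
#' @param half_width slab half-width used when `slab` is `NULL`, nm.
#' @param polymers polymer molids; default molecules with resname `"SMA"`.
#' @param cutoff lipid-polymer association distance, nm.
#' @param tail_pattern regex for lipid tail beads.
#' @return Integer vector of extracted lipid molids.
#' @export
detect_extracted_lipids <- function(frame, slab = NULL, half_width = 1.5,
                                    polymers = NULL, cutoff = 0.6,
                                    tail_pattern = DEFAULT_TAIL_PATTERN) {
  stopifnot(inherits(frame, "cg_frame"))
  box <- frame_box(frame)
  tails <- frame[grepl(tail_pattern, frame$name), ]
  if (nrow(tails) == 0) stop("no lipid tail beads found", call. = FALSE)
  if (is.null(slab)) {
    mid <- stats::median(tails$z)
    slab <- c(mid - half_width, mid + half_width)
  }
  if (is.null(polymers)) polymers <- unique(frame$molid[frame$resname == "SMA"])
  pxyz <- coords_matrix(frame[frame$molid %in% polymers, ])
  outside <- tails |>
    dplyr::group_by(.data$molid) |>
    dplyr::summarise(out = all(.data$z < slab[1] | .data$z > slab[2]),
                     .groups = "drop")
  cand <- outside$molid[outside$out]
  if (length(cand) == 0 || nrow(pxyz) == 0) return(integer())
  hit <- vapply(cand, function(m) {
    lx <- coords_matrix(frame[frame$molid == m, ])
    any(vapply(seq_len(nrow(lx)), function(r) {
      d <- min_image(pxyz - matrix(lx[r, ], nrow(pxyz), 3, byrow = TRUE), box)
      min(rowSums(d^2)) <= cutoff^2
    }, logical(1)))
  }, logical(1))
  sort(cand[hit])
}
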