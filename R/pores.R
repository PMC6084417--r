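#' Detect transmembrane pores on an xy occupancy grid
#'
#' Lipid-tail beads within `slab_half_width` of the bilayer midplane are
#' rasterised onto an xy grid of ~`cell` nm cells (cell sizes are adjusted
#' to divide the box exactly); a cell is occupied when its centre lies
#' within `r_occ` (the physical bead radius) of a tail bead, minimum image.
#' A morphological closing of radius `close_cells` then fills the narrow
#' packing corridors between neighbouring lipids, so only genuine defects
#' survive as empty space. Pores are the 4-connected components of empty
#' cells, with periodic wrap in x and y, of at least `min_area`. The
#' reported pore area is cell count times cell area; the equivalent
#' diameter is `2 sqrt(A / pi)`.
#'
#' @param frame a `cg_frame` with the bilayer normal along z.
#' @param cell target grid cell edge, nm.
#' @param slab_half_width half-width of the midplane slab, nm.
#' @param r_occ occupancy footprint radius of a tail bead, nm (default the
#'   Martini bead radius 0.264).
#' @param close_cells radius (in cells) of the morphological closing
#'   applied to the occupied set.
#' @param min_area smallest empty-cell component reported as a pore, nm^2.
#' @param midplane optional fixed midplane z (nm); default median tail z.
#' @param tail_pattern regex selecting lipid-tail beads.
#' @return A `pore_records` tibble (`pore_id`, `n_cells`, `area` nm^2,
#'   `diameter` and `radius` nm, centroid `x`, `y`, `time`), with
#'   attributes `occupied_area`, `empty_area`, `grid_area` (conservation:
#'   occupied + empty = grid).
#' @export
detect_pores <- function(frame, cell = 0.3, slab_half_width = 0.8,
                         r_occ = 0.264, close_cells = 1, min_area = 0.5,
                         midplane = NULL,
                         tail_pattern = DEFAULT_TAIL_PATTERN) {
  stopifnot(inherits(frame, "cg_frame"))
  box <- frame_box(frame)
  tails <- frame[grepl(tail_pattern, frame$name), ]
  if (nrow(tails) == 0) stop("no lipid tail beads found", call. = FALSE)
  if (is.null(midplane)) midplane <- stats::median(tails$z)
  slab <- tails[abs(tails$z - midplane) <= slab_half_width, ]
  if (nrow(slab) == 0) stop("midplane slab contains no tail beads",
                            call. = FALSE)
  nx <- max(3L, round(box[1] / cell)); ny <- max(3L, round(box[2] / cell))
  cx <- box[1] / nx; cy <- box[2] / ny
  occ <- matrix(FALSE, nx, ny)
  # mark cells whose centre is within r_occ of a bead (periodic)
  rx <- ceiling(r_occ / cx); ry <- ceiling(r_occ / cy)
  bx <- slab$x %% box[1]; by <- slab$y %% box[2]
  ix <- floor(bx / cx); iy <- floor(by / cy)         # 0-based home cell
  for (b in seq_len(nrow(slab))) {
    for (dx in -rx:rx) {
      ccx <- (ix[b] + dx) %% nx
      px <- (ccx + 0.5) * cx
      ddx <- px - bx[b]; ddx <- ddx - round(ddx / box[1]) * box[1]
      if (abs(ddx) > r_occ) next
      for (dy in -ry:ry) {
        ccy <- (iy[b] + dy) %% ny
        py <- (ccy + 0.5) * cy
        ddy <- py - by[b]; ddy <- ddy - round(ddy / box[2]) * box[2]
        if (ddx * ddx + ddy * ddy <= r_occ * r_occ) {
          occ[ccx + 1L, ccy + 1L] <- TRUE
        }
      }
    }
  }
  if (close_cells > 0) occ <- grid_close(occ, close_cells)
  comp <- grid_components(!occ, wrap = TRUE)
  cell_area <- cx * cy
  recs <- list()
  if (max(comp) > 0) {
    for (id in seq_len(max(comp))) {
      cells <- which(comp == id, arr.ind = TRUE)
      area <- nrow(cells) * cell_area
      if (area < min_area) next
      cxm <- periodic_mean((cells[, 1] - 0.5) * cx, box[1])
      cym <- periodic_mean((cells[, 2] - 0.5) * cy, box[2])
      recs[[length(recs) + 1L]] <- tibble::tibble(
        n_cells = nrow(cells), area = area,
        diameter = 2 * sqrt(area / pi), radius = sqrt(area / pi),
        x = cxm, y = cym
      )
    }
  }
  out <- if (length(recs)) dplyr::bind_rows(recs) else
    tibble::tibble(n_cells = integer(), area = numeric(),
                   diameter = numeric(), radius = numeric(),
                   x = numeric(), y = numeric())
  out <- dplyr::arrange(out, dplyr::desc(.data$area))
  out <- dplyr::mutate(out, pore_id = dplyr::row_number(),
                       time = frame_time(frame), .before = 1)
  structure(out,
    occupied_area = sum(occ) * cell_area,
    empty_area = sum(!occ) * cell_area,
    grid_area = nx * ny * cell_area,
    cell_area = cell_area,
    class = c("pore_records", class(tibble::tibble()))
  )
}

# Morphological closing (dilate then erode, Chebyshev radius k, periodic).
grid_close <- function(occ, k) {
  shift2 <- function(m, dx, dy) {
    nx <- nrow(m); ny <- ncol(m)
    m[((seq_len(nx) - 1 - dx) %% nx) + 1, ((seq_len(ny) - 1 - dy) %% ny) + 1]
  }
  sweep_set <- function(m, grow) {
    out <- m
    for (dx in -k:k) for (dy in -k:k) {
      if (dx == 0 && dy == 0) next
      out <- if (grow) out | shift2(m, dx, dy) else out & shift2(m, dx, dy)
    }
    out
  }
  sweep_set(sweep_set(occ, TRUE), FALSE)
}

# Connected components (4-connectivity) of TRUE cells on a grid, with
# optional periodic wrap; returns an integer matrix of component labels
# (0 = FALSE cells).
grid_components <- function(mask, wrap = TRUE) {
  nx <- nrow(mask); ny <- ncol(mask)
  comp <- matrix(0L, nx, ny)
  nextid <- 0L
  for (sx in seq_len(nx)) for (sy in seq_len(ny)) {
    if (!mask[sx, sy] || comp[sx, sy] != 0L) next
    nextid <- nextid + 1L
    stack <- matrix(c(sx, sy), 1)
    comp[sx, sy] <- nextid
    while (nrow(stack) > 0) {
      cx <- stack[nrow(stack), 1]; cy <- stack[nrow(stack), 2]
      stack <- stack[-nrow(stack), , drop = FALSE]
      for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
        px <- cx + d[1]; py <- cy + d[2]
        if (wrap) {
          px <- ((px - 1) %% nx) + 1; py <- ((py - 1) %% ny) + 1
        } else if (px < 1 || px > nx || py < 1 || py > ny) next
        if (mask[px, py] && comp[px, py] == 0L) {
          comp[px, py] <- nextid
          stack <- rbind(stack, c(px, py))
        }
      }
    }
  }
  comp
}

# Mean of positions on a circle of circumference L.
periodic_mean <- function(x, L) {
  th <- x / L * 2 * pi
  m <- atan2(mean(sin(th)), mean(cos(th)))
  (m / (2 * pi) * L) %% L
}

#' Track pores through a trajectory
#'
#' Runs [detect_pores()] on every frame and links pores across frames by
#' greedy nearest-centroid matching (periodic distance), ties broken in
#' favour of larger pores. A match requires the centroid displacement to be
#' below `match_dist` or the sum of the two equivalent radii, whichever is
#' larger.
#'
#' @param traj a `cg_traj`.
#' @param ... passed to [detect_pores()].
#' @param match_dist baseline matching distance, nm.
#' @return Tibble of per-frame pore records with persistent `track_id`.
#' @export
pore_kinetics <- function(traj, ..., match_dist = 1.0) {
  frames <- as_frames(traj)
  box <- frame_box(frames[[1]])
  prev <- NULL
  next_track <- 0L
  out <- list()
  for (k in seq_along(frames)) {
    rec <- detect_pores(frames[[k]], ...)
    rec <- tibble::as_tibble(rec)
    rec$frame <- k
    rec$track_id <- NA_integer_
    if (!is.null(prev) && nrow(prev) > 0 && nrow(rec) > 0) {
      # greedy: biggest current pores claim nearest previous track first
      for (r in order(-rec$area)) {
        dx <- rec$x[r] - prev$x; dx <- dx - round(dx / box[1]) * box[1]
        dy <- rec$y[r] - prev$y; dy <- dy - round(dy / box[2]) * box[2]
        d <- sqrt(dx^2 + dy^2)
        lim <- pmax(match_dist, rec$radius[r] + prev$radius)
        cand <- which(d <= lim & !prev$claimed)
        if (length(cand) > 0) {
          pick <- cand[which.min(d[cand])]
          rec$track_id[r] <- prev$track_id[pick]
          prev$claimed[pick] <- TRUE
        }
      }
    }
    for (r in which(is.na(rec$track_id))) {
      next_track <- next_track + 1L
      rec$track_id[r] <- next_track
    }
    out[[k]] <- rec
    prev <- dplyr::mutate(rec, claimed = FALSE)
  }
  res <- dplyr::bind_rows(out)
  dplyr::select(res, "frame", "time", "track_id", "pore_id", "n_cells",
                "area", "diameter", "radius", "x", "y")
}
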