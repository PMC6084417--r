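DEFAULT_HEAD_PATTERN <- "^(NC3|PO4)"
DEFAULT_TAIL_PATTERN <- "^C[0-9]+[AB]$"

# Sequential periodic unwrap: each bead placed by minimum image relative to
# the previous one, so connected chains come out whole.
unwrap_sequential <- function(xyz, box) {
  if (nrow(xyz) < 2) return(xyz)
  d <- min_image(diff(xyz), box)
  cs <- apply(d, 2, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1)
  rbind(xyz[1, , drop = FALSE], sweep(cs, 2, xyz[1, ], "+"))
}

#' Radius of gyration per frame
#'
#' Mass-weighted root-mean-square distance of the selected particles from
#' their centre of mass, after unwrapping the selection across periodic
#' boundaries (sequential minimum image, so bonded chains reassemble).
#' Missing masses count as 1.
#'
#' @param traj a `cg_traj` or `cg_frame`.
#' @param ... selection conditions evaluated against the frame columns
#'   (e.g. `resname == "SMA"`); empty selects everything.
#' @return Tibble with `frame`, `time` (ps) and `rg` (nm).
#' @export
#' @examples
#' # a rigid two-bead rod of length 1 nm has rg = 0.5 nm
radius_of_gyration <- function(traj, ...) {
  dots <- rlang::enquos(...)
  frames <- as_frames(traj)
  rows <- select_rows(frames[[1]], dots)
  if (length(rows) == 0) stop("empty selection", call. = FALSE)
  purrr::imap_dfr(frames, function(f, k) {
    sub <- f[rows, ]
    m <- ifelse(is.na(sub$mass), 1, sub$mass)
    xyz <- unwrap_sequential(coords_matrix(sub), frame_box(f))
    com <- colSums(xyz * (m / sum(m)))
    d2 <- rowSums(sweep(xyz, 2, com)^2)
    tibble::tibble(frame = k, time = frame_time(f),
                   rg = sqrt(sum(m * d2) / sum(m)))
  })
}

#' Number-density profile along a box axis
#'
#' Time-averaged number density of the selected particles in slabs along
#' `axis`. The per-bin integral times the box cross-section recovers the
#' selection count.
#'
#' @inheritParams radius_of_gyration
#' @param axis `"x"`, `"y"` or `"z"` (the membrane normal is z by
#'   convention).
#' @param n_bins number of slabs.
#' @return A `density_profile` tibble with bin centre (`pos`, nm) and
#'   number density (`density`, nm^-3).
#' @export
density_profile <- function(traj, ..., axis = "z", n_bins = 100) {
  axis <- match.arg(axis, c("x", "y", "z"))
  dots <- rlang::enquos(...)
  frames <- as_frames(traj)
  rows <- select_rows(frames[[1]], dots)
  if (length(rows) == 0) stop("empty selection", call. = FALSE)
  box <- frame_box(frames[[1]])
  ai <- match(axis, c("x", "y", "z"))
  L <- box[ai]
  cross <- prod(box[-ai])
  edges <- seq(0, L, length.out = n_bins + 1)
  counts <- numeric(n_bins)
  for (f in frames) {
    v <- f[[axis]][rows] %% L
    counts <- counts + tabulate(pmin(n_bins, floor(v / (L / n_bins)) + 1L),
                                nbins = n_bins)
  }
  dens <- counts / length(frames) / (L / n_bins * cross)
  structure(
    tibble::tibble(pos = (edges[-1] + edges[-(n_bins + 1)]) / 2,
                   density = dens),
    axis = axis, n_selected = length(rows), box = box,
    class = c("density_profile", class(tibble::tibble()))
  )
}

#' Ion (or any selection) asymmetry across the bilayer midplane
#'
#' `(N_upper - N_lower) / (N_upper + N_lower)` for the selected particles,
#' summed over frames. The midplane defaults to the median z of lipid-tail
#' beads (names matching `tail_pattern`); particles further than
#' `max_distance` from the midplane are ignored when it is finite, so the
#' measure reflects the interfacial slabs.
#'
#' @inheritParams radius_of_gyration
#' @param midplane z position of the bilayer midplane (nm); `NULL` infers
#'   it from tail beads.
#' @param max_distance half-width of the interfacial region considered
#'   (nm); `Inf` uses every selected particle.
#' @param tail_pattern regex identifying tail beads for the midplane.
#' @return A single number in `[-1, 1]`.
#' @export
ion_asymmetry <- function(traj, ..., midplane = NULL, max_distance = Inf,
                          tail_pattern = DEFAULT_TAIL_PATTERN) {
  dots <- rlang::enquos(...)
  frames <- as_frames(traj)
  rows <- select_rows(frames[[1]], dots)
  if (length(rows) == 0) stop("empty selection", call. = FALSE)
  upper <- 0; lower <- 0
  for (f in frames) {
    mid <- midplane
    if (is.null(mid)) {
      tails <- grepl(tail_pattern, f$name)
      if (!any(tails)) stop("no tail beads found to locate the midplane",
                            call. = FALSE)
      mid <- stats::median(f$z[tails])
    }
    dz <- f$z[rows] - mid
    keep <- abs(dz) <= max_distance
    upper <- upper + sum(dz[keep] > 0)
    lower <- lower + sum(dz[keep] < 0)
  }
  if (upper + lower == 0) stop("no particles within the slabs", call. = FALSE)
  (upper - lower) / (upper + lower)
}

#' Assign lipids to leaflets
#'
#' The bilayer midplane is the median z of tail beads; each lipid is
#' labelled by the sign of its head-bead z (mean over head beads) relative
#' to that midplane.
#'
#' @param frame a `cg_frame`.
#' @param head_pattern regex for head beads.
#' @param tail_pattern regex for tail beads.
#' @param midplane optional fixed midplane (nm).
#' @return Tibble with `molid`, `head_z`, `midplane`, `leaflet`
#'   (`"upper"`/`"lower"`).
#' @export
assign_leaflets <- function(frame, head_pattern = DEFAULT_HEAD_PATTERN,
                            tail_pattern = DEFAULT_TAIL_PATTERN,
                            midplane = NULL) {
  heads <- frame[grepl(head_pattern, frame$name), ]
  if (nrow(heads) == 0) stop("no lipid head beads found", call. = FALSE)
  if (is.null(midplane)) {
    tails <- frame$z[grepl(tail_pattern, frame$name)]
    if (length(tails) == 0) stop("no lipid tail beads found", call. = FALSE)
    midplane <- stats::median(tails)
  }
  heads |>
    dplyr::group_by(.data$molid) |>
    dplyr::summarise(head_z = mean(.data$z), .groups = "drop") |>
    dplyr::mutate(
      midplane = midplane,
      leaflet = ifelse(.data$head_z >= midplane, "upper", "lower")
    )
}

#' Count lipid flip-flop events
#'
#' A flip-flop is a leaflet-label change that persists for at least `dwell`
#' frames; shorter flickers (a head bead briefly crossing the midplane) are
#' ignored. Labels are computed per frame with [assign_leaflets()].
#'
#' @param traj a `cg_traj`.
#' @param dwell minimum persistence (frames) for a change to count.
#' @inheritParams assign_leaflets
#' @return Tibble of events: `molid`, `frame`, `time`, `from`, `to`.
#' @export
count_flip_flops <- function(traj, dwell = 5,
                             head_pattern = DEFAULT_HEAD_PATTERN,
                             tail_pattern = DEFAULT_TAIL_PATTERN,
                             midplane = NULL) {
  frames <- as_frames(traj)
  labs <- purrr::map(frames, function(f) {
    assign_leaflets(f, head_pattern, tail_pattern, midplane)
  })
  mol <- labs[[1]]$molid
  mat <- vapply(labs, function(l) l$leaflet[match(mol, l$molid)],
                character(length(mol)))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = length(mol))
  events <- list()
  for (r in seq_along(mol)) {
    events[[r]] <- flip_events(mat[r, ], dwell, mol[r],
                               vapply(frames, frame_time, numeric(1)))
  }
  out <- dplyr::bind_rows(events)
  if (nrow(out) == 0) {
    out <- tibble::tibble(molid = integer(), frame = integer(),
                          time = numeric(), from = character(),
                          to = character())
  }
  out
}

# Dwell-filtered transition counting on a label series: runs shorter than
# `dwell` are treated as flicker and dropped before counting changes.
flip_events <- function(labels, dwell, molid, times) {
  r <- rle(labels)
  keep <- r$lengths >= dwell
  if (!any(keep)) return(NULL)
  vals <- r$values[keep]
  starts <- (cumsum(r$lengths) - r$lengths + 1)[keep]
  ev <- which(vals[-1] != vals[-length(vals)])
  if (length(ev) == 0) return(NULL)
  tibble::tibble(
    molid = molid, frame = starts[ev + 1],
    time = times[starts[ev + 1]],
    from = vals[ev], to = vals[ev + 1]
  )
}
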