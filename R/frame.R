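#' Coordinate frames and trajectories
#'
#' A frame is a tibble with one row per particle and columns `molid`, `resid`,
#' `resname`, `name`, `mass`, `x`, `y`, `z` (coordinates in nm), carrying an
#' orthorhombic `box` (three edge lengths, nm) and a `time` stamp (ps) as
#' attributes. A trajectory is an ordered list of frames sharing a particle
#' layout.
#'
#' @param atoms data frame with at least `name`, `x`, `y`, `z`; missing
#'   `molid`/`resid` default to 1, missing `resname` to `"MOL"`, missing
#'   `mass` to `NA`.
#' @param box numeric length-3 box edge lengths in nm (all > 0).
#' @param time frame time in ps.
#' @return A `cg_frame` tibble.
#' @export
#' @examples
#' f <- cg_frame(data.frame(name = "W", x = 1, y = 2, z = 3), box = c(5, 5, 5))
#' frame_box(f)
cg_frame <- function(atoms, box, time = 0) {
  stopifnot(is.data.frame(atoms))
  if (!all(c("name", "x", "y", "z") %in% names(atoms))) {
    stop("`atoms` needs columns name, x, y, z", call. = FALSE)
  }
  box <- as.numeric(box)
  if (length(box) != 3 || any(!is.finite(box)) || any(box <= 0)) {
    stop("`box` must be three positive finite lengths (nm)", call. = FALSE)
  }
  atoms <- tibble::as_tibble(atoms)
  if (!"molid" %in% names(atoms)) atoms$molid <- 1L
  if (!"resid" %in% names(atoms)) atoms$resid <- atoms$molid
  if (!"resname" %in% names(atoms)) atoms$resname <- "MOL"
  if (!"mass" %in% names(atoms)) atoms$mass <- NA_real_
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  atoms <- dplyr::select(
    atoms, "molid", "resid", "resname", "name", "mass", "x", "y", "z",
    dplyr::everything()
  )
  structure(atoms,
    box = box, time = as.numeric(time),
    class = c("cg_frame", class(tibble::tibble()))
  )
}

#' @rdname cg_frame
#' @param x a `cg_frame`.
#' @export
frame_box <- function(x) attr(x, "box")

#' @rdname cg_frame
#' @export
frame_time <- function(x) attr(x, "time")

#' @rdname cg_frame
#' @param frames list of `cg_frame` objects (equal particle counts).
#' @export
cg_trajectory <- function(frames) {
  if (length(frames) == 0) stop("empty trajectory", call. = FALSE)
  ok <- vapply(frames, inherits, logical(1), what = "cg_frame")
  if (!all(ok)) stop("all elements must be cg_frame objects", call. = FALSE)
  n <- vapply(frames, nrow, integer(1))
  if (length(unique(n)) != 1) {
    stop("inconsistent particle count across frames", call. = FALSE)
  }
  structure(unname(frames), class = "cg_traj")
}

#' @rdname cg_frame
#' @export
n_frames <- function(x) {
  if (inherits(x, "cg_frame")) return(1L)
  length(x)
}

#' @rdname cg_frame
#' @export
frame_times <- function(x) {
  vapply(as_frames(x), frame_time, numeric(1))
}

# Normalise frame-or-trajectory input to a list of frames. A plain list of
# cg_frame objects is accepted too (frames need not share a particle
# layout, e.g. pore fixtures with different lipid counts).
as_frames <- function(x) {
  if (inherits(x, "cg_frame")) return(list(x))
  if (inherits(x, "cg_traj")) return(x)
  if (is.list(x) && length(x) > 0 &&
      all(vapply(x, inherits, logical(1), "cg_frame"))) {
    return(x)
  }
  stop("expected a cg_frame, cg_traj, or list of cg_frame objects",
       call. = FALSE)
}

#' @export
print.cg_traj <- function(x, ...) {
  cat(sprintf(
    "<cg_traj> %d frames x %d particles, t = %.6g..%.6g ps\n",
    length(x), nrow(x[[1]]), frame_time(x[[1]]), frame_time(x[[length(x)]])
  ))
  invisible(x)
}

#' @export
print.cg_frame <- function(x, ...) {
  b <- frame_box(x)
  cat(sprintf(
    "<cg_frame> %d particles, box %.4g x %.4g x %.4g nm, t = %.6g ps\n",
    nrow(x), b[1], b[2], b[3], frame_time(x)
  ))
  NextMethod()
}

# Minimum-image displacement(s) b - a in an orthorhombic box.
# a, b: n x 3 matrices (or length-3 vectors); box: length-3.
min_image <- function(d, box) {
  d <- d - sweep(round(sweep(d, 2, box, "/")), 2, box, "*")
  d
}

coords_matrix <- function(frame) {
  cbind(frame$x, frame$y, frame$z)
}

set_coords <- function(frame, xyz) {
  frame$x <- xyz[, 1]; frame$y <- xyz[, 2]; frame$z <- xyz[, 3]
  frame
}

# Unwrap a particle group across periodic boundaries by minimum image
# relative to its first row. Returns the n x 3 coordinate matrix.
unwrap_group <- function(xyz, box) {
  if (nrow(xyz) == 1) return(xyz)
  ref <- xyz[rep(1L, nrow(xyz)), , drop = FALSE]
  ref + min_image(xyz - ref, box)
}

# Evaluate dplyr-style filter quosures against a frame; empty dots = all rows.
select_rows <- function(frame, dots) {
  if (length(dots) == 0) return(seq_len(nrow(frame)))
  keep <- rep(TRUE, nrow(frame))
  for (q in dots) {
    v <- rlang::eval_tidy(q, data = frame)
    if (!is.logical(v)) stop("selection must be a logical condition", call. = FALSE)
    keep <- keep & !is.na(v) & v
  }
  which(keep)
}
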