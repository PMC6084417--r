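#' Track one bead across a trajectory
#'
#' @param traj a `cg_traj` or `cg_frame`.
#' @param i bead (row) index.
#' @return An `n_frames` x 3 coordinate matrix (nm).
#' @keywords internal
bead_track <- function(traj, i) {
  frames <- as_frames(traj)
  t(vapply(frames, function(f) c(f$x[i], f$y[i], f$z[i]), numeric(3)))
}

#' Measure a bonded coordinate over a trajectory
#'
#' Bond lengths use the minimum-image convention; angles are computed via
#' the arccosine of the normalised dot product (degrees in `[0, 180]`);
#' dihedrals are signed torsions wrapped to `(-180, 180]`. Samples with a
#' degenerate geometry (a zero-length bond vector inside an angle or
#' torsion) are excluded and counted.
#'
#' @param traj a `cg_traj` or `cg_frame`.
#' @param kind `"bond"`, `"constraint"`, `"angle"`, `"dihedral_proper"` or
#'   `"dihedral_improper"`.
#' @param idx 2-4 bead indices.
#' @return Numeric samples (nm or degrees) with attribute `n_degenerate`.
#' @export
measure_term <- function(traj, kind, idx) {
  arr <- attr(traj, "samples")
  if (!is.null(arr)) return(measure_term_array(arr, kind, idx))
  frames <- as_frames(traj)
  box <- frame_box(frames[[1]])
  variable <- term_variable(kind)
  p <- lapply(seq_along(idx), function(k) bead_track(traj, idx[k]))
  if (variable == "length") {
    d <- min_image(p[[2]] - p[[1]], box)
    out <- sqrt(rowSums(d^2))
    attr(out, "n_degenerate") <- 0L
    return(out)
  }
  if (variable == "angle") {
    u <- min_image(p[[1]] - p[[2]], box)
    v <- min_image(p[[3]] - p[[2]], box)
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ok <- nu > 1e-9 & nv > 1e-9
    ct <- rowSums(u * v)[ok] / (nu[ok] * nv[ok])
    out <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  } else {
    b1 <- min_image(p[[2]] - p[[1]], box)
    b2 <- min_image(p[[3]] - p[[2]], box)
    b3 <- min_image(p[[4]] - p[[3]], box)
    n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
    nb2 <- sqrt(rowSums(b2^2))
    ok <- sqrt(rowSums(n1^2)) > 1e-12 & sqrt(rowSums(n2^2)) > 1e-12 & nb2 > 1e-9
    x <- rowSums(n1 * n2)[ok]
    y <- rowSums(cross3(n1, n2) * (b2 / nb2))[ok]
    out <- atan2(y, x) * 180 / pi
    out[out <= -180] <- out[out <= -180] + 360
  }
  nd <- sum(!ok)
  if (nd > 0) warning(nd, " degenerate geometry sample(s) excluded")
  attr(out, "n_degenerate") <- nd
  out
}

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

term_variable <- function(kind) {
  switch(kind,
    bond = , constraint = "length",
    angle = "angle",
    dihedral_proper = , dihedral_improper = "dihedral",
    stop("unknown term kind: ", kind, call. = FALSE)
  )
}

default_bin_width <- function(variable) {
  switch(variable, length = 0.001, angle = 1, dihedral = 2)
}

#' Normalized bonded distributions
#'
#' `make_distribution()` histograms raw samples into a density normalised so
#' that `sum(density * bin width) = 1`. `compute_distribution()` measures a
#' bonded term over a whole trajectory first. Dihedral support is fixed to
#' `(-180, 180]`, angles to `[0, 180]`; bond supports are padded to bin
#' boundaries around the data.
#'
#' @param values numeric samples (nm or degrees).
#' @param kind term kind (see [measure_term()]).
#' @param bin_width histogram bin width (default 0.001 nm for bonds, 1 deg
#'   for angles, 2 deg for dihedrals).
#' @param edges explicit bin edges (overrides `bin_width`).
#' @param term_id label carried into outputs.
#' @return An `sma_distribution` tibble with columns `mid`, `density` and
#'   attributes `kind` (variable kind), `edges`, `term_id`, `n_samples`,
#'   `n_degenerate`.
#' @export
make_distribution <- function(values, kind, bin_width = NULL, edges = NULL,
                              term_id = NULL) {
  variable <- term_variable(kind)
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("no samples to histogram", call. = FALSE)
  if (is.null(edges)) {
    if (is.null(bin_width)) bin_width <- default_bin_width(variable)
    edges <- switch(variable,
      dihedral = seq(-180, 180, by = bin_width),
      angle = seq(0, 180, by = bin_width),
      length = {
        lo <- floor(min(values) / bin_width - 1) * bin_width
        hi <- ceiling(max(values) / bin_width + 1) * bin_width
        seq(max(0, lo), hi, by = bin_width)
      }
    )
    if (variable != "length" && abs(edges[length(edges)] - switch(variable,
        dihedral = 180, angle = 180)) > 1e-9) {
      edges <- c(edges, switch(variable, dihedral = 180, angle = 180))
    }
  }
  h <- graphics::hist(values, breaks = edges, plot = FALSE,
                      include.lowest = TRUE, right = TRUE)
  widths <- diff(edges)
  dens <- h$counts / (sum(h$counts) * widths)
  structure(
    tibble::tibble(mid = h$mids, density = dens),
    kind = variable, edges = edges, term_id = term_id,
    n_samples = length(values), n_degenerate = 0L,
    class = c("sma_distribution", class(tibble::tibble()))
  )
}

#' @rdname make_distribution
#' @param traj a `cg_traj` or `cg_frame`.
#' @param term one row of a topology `terms` tibble, or a list with `kind`
#'   and `idx`.
#' @export
compute_distribution <- function(traj, term, bin_width = NULL, edges = NULL) {
  if (n_frames(traj) < 1) stop("empty trajectory", call. = FALSE)
  if (is.data.frame(term)) {
    kind <- term$kind[1]
    idx <- stats::na.omit(c(term$i[1], term$j[1], term$k[1], term$l[1]))
  } else {
    kind <- term$kind; idx <- term$idx
  }
  vals <- measure_term(traj, kind, idx)
  d <- make_distribution(as.numeric(vals), kind, bin_width = bin_width,
                         edges = edges,
                         term_id = paste(c(kind, idx), collapse = "_"))
  attr(d, "n_degenerate") <- attr(vals, "n_degenerate")
  d
}

dist_widths <- function(d) diff(attr(d, "edges"))
dist_probs <- function(d) d$density * dist_widths(d)
dist_mean <- function(d) sum(dist_probs(d) * d$mid)
dist_var <- function(d) {
  m <- dist_mean(d)
  sum(dist_probs(d) * (d$mid - m)^2)
}

#' Rebin a distribution onto new edges
#'
#' Treats the density as piecewise constant and redistributes probability
#' mass by interval overlap, so normalisation is preserved exactly.
#'
#' @param d an `sma_distribution`.
#' @param edges new bin edges (must cover the old support).
#' @return An `sma_distribution` on the new grid.
#' @export
rebin_distribution <- function(d, edges) {
  old <- attr(d, "edges")
  mass <- dist_probs(d)
  k_new <- length(edges) - 1
  new_mass <- numeric(k_new)
  for (i in seq_len(k_new)) {
    lo <- edges[i]; hi <- edges[i + 1]
    ov <- pmax(0, pmin(hi, old[-1]) - pmax(lo, old[-length(old)]))
    w <- diff(old)
    new_mass[i] <- sum(mass * ifelse(w > 0, ov / w, 0))
  }
  widths <- diff(edges)
  structure(
    tibble::tibble(mid = (edges[-1] + edges[-length(edges)]) / 2,
                   density = new_mass / sum(new_mass) / widths),
    kind = attr(d, "kind"), edges = edges, term_id = attr(d, "term_id"),
    n_samples = attr(d, "n_samples"), n_degenerate = attr(d, "n_degenerate"),
    class = class(d)
  )
}

#' Distance between two bonded distributions
#'
#' Jensen-Shannon divergence in base 2, bounded in `[0, 1]`: 0 for
#' identical distributions, 1 for fully disjoint supports. Distributions on
#' different grids are first rebinned onto a common grid covering both
#' supports at the finer bin width.
#'
#' @param a,b `sma_distribution` objects of the same variable kind.
#' @return A scalar in `[0, 1]`.
#' @export
distribution_distance <- function(a, b) {
  if (!identical(attr(a, "kind"), attr(b, "kind"))) {
    stop("cannot compare distributions of different variable kinds",
         call. = FALSE)
  }
  ea <- attr(a, "edges"); eb <- attr(b, "edges")
  if (!isTRUE(all.equal(ea, eb))) {
    w <- min(min(diff(ea)), min(diff(eb)))
    lo <- min(ea, eb); hi <- max(ea, eb)
    edges <- seq(lo, hi, by = w)
    if (edges[length(edges)] < hi) edges <- c(edges, hi)
    a <- rebin_distribution(a, edges)
    b <- rebin_distribution(b, edges)
  }
  p <- dist_probs(a); q <- dist_probs(b)
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(x, y) {
    i <- x > 0
    sum(x[i] * log2(x[i] / y[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Overlap coefficient of two distributions
#'
#' `sum(min(p, q))` on the common grid: 1 for identical distributions, 0
#' for disjoint supports. Reported alongside the Jensen-Shannon divergence
#' in fit reports.
#'
#' @inheritParams distribution_distance
#' @return A scalar in `[0, 1]`.
#' @export
distribution_overlap <- function(a, b) {
  1 - distribution_distance_raw(a, b)
}

distribution_distance_raw <- function(a, b) {
  ea <- attr(a, "edges"); eb <- attr(b, "edges")
  if (!isTRUE(all.equal(ea, eb))) {
    w <- min(min(diff(ea)), min(diff(eb)))
    edges <- seq(min(ea, eb), max(ea, eb), by = w)
    if (edges[length(edges)] < max(ea, eb)) edges <- c(edges, max(ea, eb))
    a <- rebin_distribution(a, edges)
    b <- rebin_distribution(b, edges)
  }
  p <- dist_probs(a); q <- dist_probs(b)
  sum(abs(p / sum(p) - q / sum(q))) / 2
}

#' Write a distribution as two-column text
#'
#' Value and density columns, with `@`/`#` header comments in the style of
#' XVG plotting files.
#'
#' @param d an `sma_distribution`.
#' @param path output path.
#' @export
write_distribution <- function(d, path) {
  hdr <- c(
    sprintf("# smalpr distribution: %s",
            if (is.null(attr(d, "term_id"))) "unnamed" else attr(d, "term_id")),
    sprintf("@ xaxis label \"%s\"",
            switch(attr(d, "kind"), length = "length (nm)",
                   angle = "angle (deg)", dihedral = "dihedral (deg)")),
    "@ yaxis label \"density\""
  )
  writeLines(c(hdr, sprintf("%.8g %.8g", d$mid, d$density)), path)
  invisible(path)
}
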