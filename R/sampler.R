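# Rigid groups defined by constraint-connected components (ring triplets);
# every other bead moves on its own.
constraint_groups <- function(topology) {
  nb <- n_beads(topology)
  cons <- topology$terms[topology$terms$kind == "constraint", ]
  parent <- seq_len(nb)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(cons))) {
    a <- find(cons$i[r]); b <- find(cons$j[r])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_len(nb), find, integer(1))
  split(seq_len(nb), root)
}

# Pivot move definitions: for every bond whose removal disconnects the
# bonded graph, the smaller component rotates about the bond axis. Each
# entry is c(axis_i, axis_j, moved beads...).
pivot_sets <- function(topology) {
  nb <- n_beads(topology)
  t <- topology$terms
  edges <- t[t$kind %in% c("bond", "constraint"), c("i", "j")]
  adj <- vector("list", nb)
  for (r in seq_len(nrow(edges))) {
    adj[[edges$i[r]]] <- c(adj[[edges$i[r]]], r)
    adj[[edges$j[r]]] <- c(adj[[edges$j[r]]], r)
  }
  bonds <- which(t$kind == "bond")
  out <- list()
  for (b in seq_len(nrow(edges))) {
    if (t$kind[t$kind %in% c("bond", "constraint")][b] != "bond") next
    i <- edges$i[b]; j <- edges$j[b]
    # BFS from j avoiding edge b; if i unreachable the cut is valid
    seen <- logical(nb); seen[j] <- TRUE
    queue <- j
    ok <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (e in adj[[v]]) {
        if (e == b) next
        w <- if (edges$i[e] == v) edges$j[e] else edges$i[e]
        if (w == i) { ok <- FALSE; break }
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
      if (!ok) break
    }
    if (!ok) next
    moved <- which(seen)
    if (length(moved) == nb || length(moved) < 1) next
    # rotate the smaller side for cheaper incidence
    if (length(moved) > nb / 2) {
      moved <- setdiff(seq_len(nb), moved)
      out[[length(out) + 1L]] <- as.integer(c(j, i, moved))
    } else {
      out[[length(out) + 1L]] <- as.integer(c(i, j, moved))
    }
  }
  out
}

#' Sample a single-molecule bonded ensemble by Metropolis Monte Carlo
#'
#' Stand-in for a coarse-grained simulation inside the parameter-refinement
#' loop: samples the Boltzmann distribution of the bonded potential at
#' temperature `temperature` using single-bead displacement moves, with
#' constraint-closed ring triplets moved as rigid bodies
#' (translation + rotation) so constraint lengths are conserved exactly,
#' plus pivot moves (rotation of one side of the chain about a bond axis)
#' that decorrelate torsions and angles quickly.
#' Only equilibrium distributions are needed downstream, so no dynamics or
#' thermostat is involved.
#'
#' @param topology an `sma_topology`.
#' @param temperature K (default 310, the simulation temperature of the
#'   membrane systems).
#' @param n_steps Monte Carlo steps (>= 1); one step is one attempted move.
#' @param seed RNG seed; identical seeds give identical chains.
#' @param trans_step maximum displacement per move, nm.
#' @param rot_step maximum rigid-group rotation per move, radians.
#' @param p_pivot fraction of moves that are pivots (when the topology has
#'   severable bonds).
#' @param sample_every store a frame every this many steps (default chosen
#'   to keep about 20000 frames).
#' @param start optional starting `cg_frame`; defaults to
#'   [generate_initial_coords()] in extended mode.
#' @return A `cg_traj` of sampled frames with attributes `acceptance` (rate
#'   in (0,1)) and `samples` (an `n_frames x n_beads x 3` array used by
#'   [measure_term()] as a fast path).
#' @export
sample_bonded_ensemble <- function(topology, temperature = 310,
                                   n_steps = 1e5, seed = 1,
                                   trans_step = 0.06, rot_step = 0.5,
                                   p_pivot = 0.3, sample_every = NULL,
                                   start = NULL) {
  validate_topology(topology)
  if (n_steps < 1) stop("n_steps must be >= 1", call. = FALSE)
  if (is.null(sample_every)) sample_every <- max(1L, n_steps %/% 20000L)
  nb <- n_beads(topology)
  f0 <- if (is.null(start)) generate_initial_coords(topology) else start
  xyz <- coords_from(f0, nb)
  enc <- terms_to_cpp(topology$terms)
  groups <- unname(constraint_groups(topology))
  res <- cpp_sample(as.numeric(t(xyz)), enc$tidx, enc$tkind, enc$tpar,
                    lapply(groups, as.integer), pivot_sets(topology),
                    p_pivot, KB * temperature,
                    as.integer(n_steps), trans_step, rot_step,
                    as.integer(sample_every), as.integer(seed))
  if (res$acceptance == 0) {
    warning("sampling failure: zero acceptance after ", n_steps,
            " steps (trans_step = ", trans_step, " nm, kT = ",
            signif(KB * temperature, 4), " kJ/mol); consider smaller steps")
  }
  ns <- res$n_samples
  arr <- array(res$samples, dim = c(3, nb, ns))  # (coord, bead, frame)
  arr <- aperm(arr, c(3, 2, 1))                  # (frame, bead, coord)
  box <- rep(1e6, 3)                             # effectively unbounded
  template <- tibble::tibble(
    molid = 1L, resid = 1L,
    resname = substr(topology$molecule_name, 1, 5),
    name = topology$beads$name, mass = topology$beads$mass,
    x = 0, y = 0, z = 0
  )
  # plain-list column replacement: avoids tibble subassignment overhead
  # when materialising tens of thousands of frames
  tmpl <- unclass(template)
  cls <- c("cg_frame", class(tibble::tibble()))
  frames <- vector("list", ns)
  for (s in seq_len(ns)) {
    tl <- tmpl
    tl$x <- arr[s, , 1]; tl$y <- arr[s, , 2]; tl$z <- arr[s, , 3]
    attr(tl, "box") <- box
    attr(tl, "time") <- s * sample_every
    class(tl) <- cls
    frames[[s]] <- tl
  }
  traj <- structure(frames, class = "cg_traj")
  attr(traj, "acceptance") <- res$acceptance
  attr(traj, "samples") <- arr
  traj
}

# Fast path for sampler output: measure a bonded coordinate directly on the
# stored (frame, bead, coord) array, no periodic box.
measure_term_array <- function(arr, kind, idx) {
  variable <- term_variable(kind)
  p <- lapply(idx, function(i) arr[, i, , drop = TRUE])
  p <- lapply(p, function(m) if (is.null(dim(m))) matrix(m, nrow = 1) else m)
  if (variable == "length") {
    d <- p[[2]] - p[[1]]
    out <- sqrt(rowSums(d^2))
    attr(out, "n_degenerate") <- 0L
    return(out)
  }
  if (variable == "angle") {
    u <- p[[1]] - p[[2]]; v <- p[[3]] - p[[2]]
    nu <- sqrt(rowSums(u^2)); nv <- sqrt(rowSums(v^2))
    ok <- nu > 1e-9 & nv > 1e-9
    ct <- rowSums(u * v)[ok] / (nu[ok] * nv[ok])
    out <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  } else {
    b1 <- p[[2]] - p[[1]]; b2 <- p[[3]] - p[[2]]; b3 <- p[[4]] - p[[3]]
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
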