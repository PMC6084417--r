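# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

random_unit_vector <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-8) return(v / n)
  }
}

# Any unit vector orthogonal to u.
orthogonal_unit <- function(u) {
  a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- a - sum(a * u) * u
  w / sqrt(sum(w^2))
}

#' Generate starting coordinates for a topology
#'
#' Places beads so that every bond sits exactly at its reference length and
#' every ring constraint is satisfied to machine precision: non-ring beads
#' are laid down along the bond graph (a planar zig-zag in `extended` mode,
#' random directions in `self_avoiding_walk` mode), and each
#' constraint-closed ring triplet is built as an exact equilateral triangle
#' on its anchor bead. Self-avoiding mode rejects placements with any
#' nonbonded pair closer than `min_sep` and retries up to `max_retries`
#' times.
#'
#' @param topology an `sma_topology`.
#' @param mode `"extended"` or `"self_avoiding_walk"`.
#' @param seed RNG seed (self-avoiding mode); same seed, same coordinates.
#' @param min_sep minimum nonbonded bead separation accepted in
#'   self-avoiding mode (nm).
#' @param max_retries placement attempts before failing.
#' @return A `cg_frame` with one row per bead (box padded 2 nm around the
#'   chain).
#' @export
generate_initial_coords <- function(topology,
                                    mode = c("extended", "self_avoiding_walk"),
                                    seed = 1, min_sep = 0.25,
                                    max_retries = 100) {
  mode <- match.arg(mode)
  validate_topology(topology)
  nb <- n_beads(topology)
  t <- topology$terms
  bonds <- t[t$kind == "bond", ]
  cons <- t[t$kind == "constraint", ]

  # constraint-connected rigid groups (aromatic ring triplets)
  parent <- seq_len(nb)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (r in seq_len(nrow(cons))) {
    a <- find(cons$i[r]); b <- find(cons$j[r])
    if (a != b) parent[a] <- b
  }
  root <- vapply(seq_len(nb), find, integer(1))
  grp_ids <- unique(root[duplicated(root)])
  groups <- lapply(grp_ids, function(g) sort(which(root == g)))
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes > 3)) {
    stop("constraint networks larger than 3 beads are not supported",
         call. = FALSE)
  }
  rings <- groups[sizes == 3]
  # pair constraints behave like fixed-length bonds for placement
  pair_cons <- cons[0, ]
  for (g in groups[sizes == 2]) {
    hit <- cons[(cons$i %in% g) & (cons$j %in% g), ][1, ]
    pair_cons <- rbind(pair_cons, hit)
  }
  edges <- rbind(bonds[, c("i", "j", "c0")], pair_cons[, c("i", "j", "c0")])
  ring_beads <- unlist(rings)
  is_ring <- seq_len(nb) %in% ring_beads

  blen <- function(a, b) {
    hit <- which((edges$i == a & edges$j == b) | (edges$i == b & edges$j == a))
    if (length(hit) == 0) stop("no bond between beads ", a, " and ", b,
                               call. = FALSE)
    edges$c0[hit[1]]
  }
  # adjacency over non-ring beads
  adj <- vector("list", nb)
  for (r in seq_len(nrow(edges))) {
    i <- edges$i[r]; j <- edges$j[r]
    if (!is_ring[i] && !is_ring[j]) {
      adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
    }
  }

  place_once <- function(random) {
    pos <- matrix(NA_real_, nb, 3)
    step <- 0L
    backbone <- which(!is_ring)
    placed <- logical(nb)
    for (start in backbone) {
      if (placed[start]) next
      pos[start, ] <- if (step == 0L) c(0, 0, 0) else
        pos[max(which(placed)), ] + c(0, 1, 0)   # disconnected fragment offset
      placed[start] <- TRUE
      queue <- start
      while (length(queue)) {
        p <- queue[1]; queue <- queue[-1]
        for (v in sort(adj[[p]])) {
          if (placed[v]) next
          step <- step + 1L
          dir <- if (random) random_unit_vector() else {
            a <- 0.4363 * if (step %% 2L == 0L) 1 else -1
            c(cos(a), sin(a), 0)
          }
          pos[v, ] <- pos[p, ] + blen(p, v) * dir
          placed[v] <- TRUE
          queue <- c(queue, v)
        }
      }
    }
    for (gidx in seq_along(rings)) {
      g <- rings[[gidx]]
      anchor_bond <- bonds[xor(bonds$i %in% g, bonds$j %in% g), ]
      if (nrow(anchor_bond) == 0) stop("ring without anchor bond", call. = FALSE)
      a <- if (anchor_bond$i[1] %in% g) anchor_bond$j[1] else anchor_bond$i[1]
      r1 <- if (anchor_bond$i[1] %in% g) anchor_bond$i[1] else anchor_bond$j[1]
      rest <- setdiff(g, r1)
      cl <- cons$c0[cons$i %in% g & cons$j %in% g][1]
      u <- if (random) random_unit_vector() else
        c(0, 0, if (gidx %% 2L == 0L) -1 else 1)
      w <- orthogonal_unit(u)
      pos[r1, ] <- pos[a, ] + anchor_bond$c0[1] * u
      pos[rest[1], ] <- pos[r1, ] + (cl / 2) * w + (cl * sqrt(3) / 2) * u
      pos[rest[2], ] <- pos[r1, ] - (cl / 2) * w + (cl * sqrt(3) / 2) * u
    }
    pos
  }

  # exclude topological neighbours (graph distance <= 3 over bonds and
  # constraints) from the clash check, the usual self-avoiding convention
  full_adj <- vector("list", nb)
  all_edges <- rbind(cbind(bonds$i, bonds$j), cbind(cons$i, cons$j))
  for (r in seq_len(nrow(all_edges))) {
    i <- all_edges[r, 1]; j <- all_edges[r, 2]
    full_adj[[i]] <- c(full_adj[[i]], j); full_adj[[j]] <- c(full_adj[[j]], i)
  }
  near_mask <- matrix(FALSE, nb, nb)
  for (start in seq_len(nb)) {
    dist <- rep(NA_integer_, nb); dist[start] <- 0L
    queue <- start
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (dist[v] >= 3L) next
      for (w in full_adj[[v]]) {
        if (is.na(dist[w])) { dist[w] <- dist[v] + 1L; queue <- c(queue, w) }
      }
    }
    near_mask[start, !is.na(dist)] <- TRUE
  }

  clashes <- function(pos) {
    d <- as.matrix(stats::dist(pos))
    d[near_mask] <- Inf
    min(d[upper.tri(d)]) < min_sep
  }

  build <- function() {
    if (mode == "extended") return(place_once(FALSE))
    for (try in seq_len(max_retries)) {
      pos <- place_once(TRUE)
      if (!clashes(pos)) return(pos)
    }
    stop("self-avoiding placement failed after ", max_retries, " retries",
         call. = FALSE)
  }
  pos <- if (mode == "extended") build() else with_seed(seed, build)

  pos <- sweep(pos, 2, apply(pos, 2, min) - 1)   # shift into positive octant
  box <- apply(pos, 2, max) + 1
  cg_frame(
    tibble::tibble(
      molid = 1L, resid = 1L,
      resname = substr(topology$molecule_name, 1, 5),
      name = topology$beads$name, mass = topology$beads$mass,
      x = pos[, 1], y = pos[, 2], z = pos[, 3]
    ),
    box = box
  )
}
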