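STANDARD_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06)

guess_atomic_mass <- function(name) {
  el <- toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
  m <- STANDARD_MASS[el]
  if (anyNA(m)) {
    stop("cannot infer a mass for atom name(s): ",
         paste(unique(name[is.na(m)]), collapse = ", "), call. = FALSE)
  }
  unname(m)
}

#' Mapping schemes: atomistic atoms to CG beads
#'
#' A mapping scheme partitions the atoms of one residue (molecule) into CG
#' beads; each bead is placed at the mass-weighted centroid of its atoms
#' (center-of-mass mapping). Every atom must belong to exactly one bead and
#' all weights must be positive. Weights default to standard atomic masses
#' inferred from the leading element letter of the atom name.
#'
#' The plain-text scheme format is a sequence of `[ bead NAME ]` sections,
#' each followed by one atom name per line with an optional weight column;
#' an optional `resname XYZ` line restricts the scheme to residues with that
#' name. `;`/`#` start comments.
#'
#' @param table data frame with columns `bead`, `atom` and optionally
#'   `weight`.
#' @param resname residue name the scheme applies to, or `NULL` for all.
#' @return A `mapping_scheme` tibble.
#' @export
#' @examples
#' sch <- mapping_scheme(data.frame(bead = "B", atom = c("C1", "C2")))
mapping_scheme <- function(table, resname = NULL) {
  table <- tibble::as_tibble(table)
  stopifnot(all(c("bead", "atom") %in% names(table)))
  if (!"weight" %in% names(table)) table$weight <- NA_real_
  miss <- is.na(table$weight)
  if (any(miss)) table$weight[miss] <- guess_atomic_mass(table$atom[miss])
  if (any(table$weight <= 0)) stop("weights must be positive", call. = FALSE)
  dup <- duplicated(table$atom)
  if (any(dup)) {
    stop("atom(s) assigned to more than one bead: ",
         paste(unique(table$atom[dup]), collapse = ", "), call. = FALSE)
  }
  structure(table, resname = resname,
            class = c("mapping_scheme", class(tibble::tibble())))
}

#' @rdname mapping_scheme
#' @param path scheme file path.
#' @export
read_mapping <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rows <- list(); bead <- NULL; resname <- NULL
  for (ln in seq_along(lines)) {
    code <- trimws(sub("[;#].*", "", lines[ln]))
    if (!nzchar(code)) next
    m <- regmatches(code, regexec("^\\[\\s*bead\\s+(\\S+)\\s*\\]$", code))[[1]]
    if (length(m) == 2) { bead <- m[2]; next }
    m <- regmatches(code, regexec("^resname\\s+(\\S+)$", code))[[1]]
    if (length(m) == 2) { resname <- m[2]; next }
    if (is.null(bead)) stop_parse(path, ln, "atom line before any [bead] section")
    f <- strsplit(code, "\\s+")[[1]]
    w <- if (length(f) >= 2) suppressWarnings(as.numeric(f[2])) else NA_real_
    if (length(f) >= 2 && is.na(w)) stop_parse(path, ln, "bad weight")
    rows[[length(rows) + 1L]] <- tibble::tibble(bead = bead, atom = f[1],
                                                weight = w)
  }
  if (length(rows) == 0) stop_parse(path, 1L, "no bead sections found")
  mapping_scheme(dplyr::bind_rows(rows), resname = resname)
}

#' @rdname mapping_scheme
#' @param scheme a `mapping_scheme`.
#' @export
write_mapping <- function(scheme, path) {
  out <- "; CG mapping scheme (smalpr)"
  if (!is.null(attr(scheme, "resname"))) {
    out <- c(out, paste("resname", attr(scheme, "resname")))
  }
  for (b in unique(scheme$bead)) {
    rows <- scheme[scheme$bead == b, ]
    out <- c(out, sprintf("[ bead %s ]", b),
             sprintf("%-6s %.6g", rows$atom, rows$weight))
  }
  writeLines(out, path)
  invisible(path)
}

#' Map an atomistic frame or trajectory to pseudo-CG beads
#'
#' Each residue whose name matches the scheme is reduced to one bead per
#' scheme bead, placed at the mass-weighted centroid of its atoms. Atom
#' groups split across a periodic boundary are unwrapped by minimum image
#' relative to the group's first atom before averaging, so bead positions
#' are independent of wrapping. Residues the scheme does not apply to are
#' dropped from the output. Within a mapped residue the scheme must cover
#' its atoms exactly: a scheme atom missing from the residue, or a residue
#' atom missing from the scheme, is an error.
#'
#' @param frame a `cg_frame` of atomistic coordinates.
#' @param scheme a [mapping_scheme()].
#' @return A pseudo-CG `cg_frame`; bead masses are the summed weights.
#' @export
map_frame <- function(frame, scheme) {
  stopifnot(inherits(frame, "cg_frame"), inherits(scheme, "mapping_scheme"))
  rn <- attr(scheme, "resname")
  sel <- if (is.null(rn)) rep(TRUE, nrow(frame)) else frame$resname == rn
  if (!any(sel)) stop("no residues match the mapping scheme", call. = FALSE)
  box <- frame_box(frame)
  sub <- frame[sel, ]
  groups <- split(seq_len(nrow(sub)), list(sub$molid, sub$resid), drop = TRUE)
  # stable residue order: first appearance in the frame
  groups <- groups[order(vapply(groups, min, integer(1)))]
  beads <- unique(scheme$bead)
  out <- dplyr::bind_rows(lapply(groups, function(idx) {
    res <- sub[idx, ]
    absent <- setdiff(scheme$atom, res$name)
    if (length(absent)) {
      stop("mapping atom(s) missing from residue ", res$resid[1], ": ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    extra <- setdiff(res$name, scheme$atom)
    if (length(extra)) {
      stop("atom(s) not covered by the mapping scheme: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    dplyr::bind_rows(lapply(beads, function(b) {
      rows <- scheme[scheme$bead == b, ]
      hit <- match(rows$atom, res$name)
      xyz <- unwrap_group(coords_matrix(res)[hit, , drop = FALSE], box)
      w <- rows$weight / sum(rows$weight)
      com <- colSums(xyz * w)
      tibble::tibble(
        molid = res$molid[1], resid = res$resid[1], resname = res$resname[1],
        name = b, mass = sum(rows$weight),
        x = com[1], y = com[2], z = com[3]
      )
    }))
  }))
  cg_frame(out, box = box, time = frame_time(frame))
}

#' @rdname map_frame
#' @param traj a `cg_traj` (or single `cg_frame`).
#' @export
map_trajectory <- function(traj, scheme) {
  frames <- as_frames(traj)
  if (length(frames) == 0) stop("empty trajectory", call. = FALSE)
  mapped <- purrr::map(frames, map_frame, scheme = scheme)
  if (length(mapped) == 1) mapped[[1]] else cg_trajectory(mapped)
}
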