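KIND_ORDER <- c("bond", "constraint", "angle", "dihedral_proper",
                "dihedral_improper", "flat_bottom_restraint")

canonical_terms <- function(terms) {
  terms$kind <- factor(terms$kind, levels = KIND_ORDER)
  terms <- dplyr::arrange(terms, .data$kind, .data$i, .data$j, .data$k, .data$l)
  terms$kind <- as.character(terms$kind)
  terms
}

#' Write / read topology files in the GROMACS-ITP dialect
#'
#' Sections emitted: `[moleculetype]`, `[atoms]` (index, type, resnr,
#' resname, atomname, cgnr, charge, mass), `[bonds]` (function 1, harmonic),
#' `[constraints]` (function 1), `[angles]` (function 2, cosine-harmonic),
#' `[dihedrals]` (function 1 proper periodic, function 2 improper harmonic)
#' and, when present, a `[flat_bottom]` extension section for flat-bottomed
#' z-restraints. Whitespace-delimited; `;`/`#` start comments. Bead class,
#' role and repeat-unit index are carried in structured `;` comments on the
#' atom lines so that `read_itp(write_itp(t))` reproduces the topology
#' field-for-field.
#'
#' @param topology an `sma_topology`.
#' @param path output (input) file path.
#' @return `write_itp()`: `path` invisibly; `read_itp()`: an `sma_topology`.
#' @export
write_itp <- function(topology, path) {
  validate_topology(topology)
  b <- topology$beads
  t <- canonical_terms(topology$terms)
  out <- c(
    "; CG SMA copolymer topology (smalpr)",
    "[ moleculetype ]",
    "; name  nrexcl",
    sprintf("%s  1", topology$molecule_name),
    "",
    "[ atoms ]",
    ";  nr type resnr resname atom cgnr charge mass",
    sprintf("%5d %6s %5d %7s %5s %5d %9.4f %9.4f ; class=%s role=%s unit=%d",
            b$index, b$type_code, b$unit_index,
            substr(topology$molecule_name, 1, 5), b$name, b$index,
            b$charge, b$mass, b$bead_class, b$role, b$unit_index)
  )
  sect <- function(rows, header, fmt) {
    if (nrow(rows) == 0) return(character())
    c("", header, fmt(rows))
  }
  out <- c(
    out,
    sect(t[t$kind == "bond", ], c("[ bonds ]", ";  i   j func b0 kb"),
         function(r) sprintf("%5d %5d  1  %.8g %.8g", r$i, r$j, r$c0, r$c1)),
    sect(t[t$kind == "constraint", ], c("[ constraints ]", ";  i   j func length"),
         function(r) sprintf("%5d %5d  1  %.8g", r$i, r$j, r$c0)),
    sect(t[t$kind == "angle", ], c("[ angles ]", ";  i   j   k func theta0 ka"),
         function(r) sprintf("%5d %5d %5d  2  %.8g %.8g", r$i, r$j, r$k,
                             r$c0, r$c1)),
    sect(t[t$kind == "dihedral_proper", ],
         c("[ dihedrals ]", ";  i   j   k   l func phase kphi mult"),
         function(r) sprintf("%5d %5d %5d %5d  1  %.8g %.8g %d", r$i, r$j,
                             r$k, r$l, r$c0, r$c1, as.integer(r$c2))),
    sect(t[t$kind == "dihedral_improper", ],
         c("[ dihedrals ]", ";  i   j   k   l func xi0 kxi"),
         function(r) sprintf("%5d %5d %5d %5d  2  %.8g %.8g", r$i, r$j,
                             r$k, r$l, r$c0, r$c1)),
    sect(t[t$kind == "flat_bottom_restraint", ],
         c("[ flat_bottom ]", ";  i func d0 k zref"),
         function(r) sprintf("%5d  1  %.8g %.8g %.8g", r$i, r$c0, r$c1, r$c2))
  )
  if (nrow(topology$exclusions) > 0) {
    out <- c(out, "", "[ exclusions ]",
             sprintf("%5d %5d", topology$exclusions$i, topology$exclusions$j))
  }
  writeLines(out, path)
  invisible(path)
}

#' @rdname write_itp
#' @export
read_itp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  beads <- list(); terms <- list(); excl <- list()
  mol_name <- NULL
  section <- ""
  for (ln in seq_along(lines)) {
    raw <- lines[ln]
    meta <- regmatches(raw, regexec(
      ";\\s*class=(\\S+)\\s+role=(\\S+)\\s+unit=(\\d+)", raw))[[1]]
    code <- sub("[;#].*", "", raw)
    code <- trimws(code)
    if (!nzchar(code)) next
    if (grepl("^\\[", code)) {
      m <- regmatches(code, regexec("^\\[\\s*(\\S+)\\s*\\]$", code))[[1]]
      if (length(m) != 2) stop_parse(path, ln, "malformed section header")
      section <- tolower(m[2])
      next
    }
    f <- strsplit(code, "\\s+")[[1]]
    num <- function(i) {
      v <- suppressWarnings(as.numeric(f[i]))
      if (anyNA(v)) stop_parse(path, ln, "non-numeric field")
      v
    }
    if (section == "moleculetype") {
      mol_name <- f[1]
    } else if (section == "atoms") {
      if (length(f) < 8) stop_parse(path, ln, "atom line needs 8 columns")
      beads[[length(beads) + 1L]] <- tibble::tibble(
        index = as.integer(num(1)), name = f[5],
        bead_class = if (length(meta) == 4) meta[2] else "regular",
        type_code = f[2], mass = num(8), charge = num(7),
        unit_index = if (length(meta) == 4) as.integer(meta[4])
                     else as.integer(num(3)),
        role = if (length(meta) == 4) meta[3] else "backbone"
      )
    } else if (section %in% c("bonds", "constraints", "angles", "dihedrals",
                              "flat_bottom", "exclusions")) {
      row <- switch(section,
        bonds = {
          if (length(f) < 5) stop_parse(path, ln, "bond line needs 5 columns")
          list(kind = "bond", idx = as.integer(num(1:2)), c = num(4:5))
        },
        constraints = {
          if (length(f) < 4) stop_parse(path, ln, "constraint line needs 4 columns")
          list(kind = "constraint", idx = as.integer(num(1:2)), c = num(4))
        },
        angles = {
          if (length(f) < 6) stop_parse(path, ln, "angle line needs 6 columns")
          list(kind = "angle", idx = as.integer(num(1:3)), c = num(5:6))
        },
        dihedrals = {
          if (length(f) < 7) stop_parse(path, ln, "dihedral line needs >= 7 columns")
          fn <- as.integer(num(5))
          if (fn == 1) {
            if (length(f) < 8) stop_parse(path, ln, "proper dihedral needs 8 columns")
            list(kind = "dihedral_proper", idx = as.integer(num(1:4)),
                 c = num(6:8))
          } else if (fn == 2) {
            list(kind = "dihedral_improper", idx = as.integer(num(1:4)),
                 c = num(6:7))
          } else stop_parse(path, ln, "unknown dihedral function type")
        },
        flat_bottom = {
          if (length(f) < 5) stop_parse(path, ln, "flat_bottom line needs 5 columns")
          list(kind = "flat_bottom_restraint", idx = as.integer(num(1)),
               c = num(3:5))
        },
        exclusions = {
          excl[[length(excl) + 1L]] <- as.integer(num(1:2))
          NULL
        }
      )
      if (!is.null(row)) {
        idx <- c(row$idx, rep(NA_integer_, 4 - length(row$idx)))
        cc <- c(row$c, rep(NA_real_, 3 - length(row$c)))
        terms[[length(terms) + 1L]] <- tibble::tibble(
          kind = row$kind, i = idx[1], j = idx[2], k = idx[3], l = idx[4],
          c0 = cc[1], c1 = cc[2], c2 = cc[3], line = ln
        )
      }
    }
  }
  if (is.null(mol_name)) stop_parse(path, 1L, "missing [moleculetype]")
  if (length(beads) == 0) stop_parse(path, 1L, "missing [atoms]")
  beads <- dplyr::bind_rows(beads)
  terms <- if (length(terms)) dplyr::bind_rows(terms) else
    tibble::tibble(kind = character(), i = integer(), j = integer(),
                   k = integer(), l = integer(), c0 = double(),
                   c1 = double(), c2 = double(), line = integer())
  nb <- nrow(beads)
  bad <- which(apply(cbind(terms$i, terms$j, terms$k, terms$l), 1, function(v) {
    v <- v[!is.na(v)]
    any(v < 1 | v > nb)
  }))
  if (length(bad)) {
    stop_parse(path, terms$line[bad[1]], "bonded term references undefined bead index")
  }
  terms$line <- NULL
  n_units <- max(beads$unit_index)
  charged <- vapply(seq_len(n_units), function(u) {
    any(beads$charge[beads$unit_index == u] < 0)
  }, logical(1))
  top <- structure(
    list(molecule_name = mol_name, n_units = n_units,
         charged_units = charged, beads = beads,
         terms = canonical_terms(terms),
         exclusions = if (length(excl)) {
           m <- do.call(rbind, excl)
           tibble::tibble(i = m[, 1], j = m[, 2])
         } else tibble::tibble(i = integer(), j = integer())),
    class = "sma_topology"
  )
  validate_topology(top)
  top
}
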