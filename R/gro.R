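#' Read and write GRO coordinate files
#'
#' Fixed-column GRO dialect: per frame a title line, an atom count, one line
#' per atom (`%5d%-5s%5s%5d%8.3f%8.3f%8.3f`: residue number, residue name,
#' atom name, atom number, x, y, z in nm) and a final box line with the three
#' orthorhombic edge lengths. Multiple frames are stored by concatenation;
#' `read_gro()` returns a `cg_frame` for a single-frame file and a `cg_traj`
#' otherwise. Molecule ids are taken from the residue number.
#'
#' Frame times are parsed from (and written into) a `t= <ps>` token on the
#' title line when present.
#'
#' @param path file path.
#' @return `read_gro()`: a `cg_frame` or `cg_traj`. `write_gro()`: `path`,
#'   invisibly.
#' @export
read_gro <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    if (i + 1L > length(lines)) stop_parse(path, i, "missing atom count line")
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat) || nat < 0) stop_parse(path, i + 1L, "bad atom count")
    last <- i + 1L + nat + 1L
    if (last > length(lines)) {
      stop_parse(path, length(lines), "truncated frame (expected more atom/box lines)")
    }
    at <- lines[(i + 2L):(i + 1L + nat)]
    if (any(nchar(at) < 44)) {
      bad <- which(nchar(at) < 44)[1]
      stop_parse(path, i + 1L + bad, "atom line too short")
    }
    resid <- suppressWarnings(as.integer(substr(at, 1, 5)))
    resname <- trimws(substr(at, 6, 10))
    name <- trimws(substr(at, 11, 15))
    x <- suppressWarnings(as.numeric(substr(at, 21, 28)))
    y <- suppressWarnings(as.numeric(substr(at, 29, 36)))
    z <- suppressWarnings(as.numeric(substr(at, 37, 44)))
    if (anyNA(resid) || anyNA(x) || anyNA(y) || anyNA(z)) {
      bad <- which(is.na(resid) | is.na(x) | is.na(y) | is.na(z))[1]
      stop_parse(path, i + 1L + bad, "unparsable atom fields")
    }
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]]))
    if (length(box) < 3 || anyNA(box[1:3])) stop_parse(path, last, "bad box line")
    tm <- 0
    m <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    frames[[length(frames) + 1L]] <- cg_frame(
      tibble::tibble(
        molid = resid, resid = resid, resname = resname, name = name,
        x = x, y = y, z = z
      ),
      box = box[1:3], time = tm
    )
    i <- last + 1L
  }
  if (length(frames) == 0) stop_parse(path, 1L, "no frames found")
  if (length(frames) == 1) frames[[1]] else cg_trajectory(frames)
}

stop_parse <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' @rdname read_gro
#' @param x a `cg_frame` or `cg_traj`.
#' @param title title string for each frame's header line.
#' @export
write_gro <- function(x, path, title = "written by smalpr") {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in as_frames(x)) {
    b <- frame_box(f)
    writeLines(sprintf("%s t= %.5f", title, frame_time(f)), con)
    writeLines(sprintf("%5d", nrow(f)), con)
    # GRO residue/atom numbers wrap at 5 digits
    writeLines(sprintf(
      "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
      f$resid %% 100000L, substr(f$resname, 1, 5), substr(f$name, 1, 5),
      seq_len(nrow(f)) %% 100000L, f$x, f$y, f$z
    ), con)
    writeLines(trimws(sprintf("%12.5f %12.5f %12.5f", b[1], b[2], b[3])), con)
  }
  invisible(path)
}
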