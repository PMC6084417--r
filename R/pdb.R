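#' Read and write PDB coordinate files
#'
#' Minimal multi-model PDB support for coarse-grained frames: `ATOM`/`HETATM`
#' records are parsed by fixed columns, coordinates are converted between
#' angstrom (PDB) and nm (internal), and multi-frame trajectories map onto
#' `MODEL`/`ENDMDL` blocks. The box is taken from the `CRYST1` record when
#' present, else a bounding box is used on read.
#'
#' @inheritParams read_gro
#' @return `read_pdb()`: a `cg_frame` or `cg_traj`; `write_pdb()`: `path`,
#'   invisibly.
#' @export
read_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  ci <- which(rec == "CRYST1")
  if (length(ci) > 0) {
    l <- lines[ci[1]]
    box <- as.numeric(c(substr(l, 7, 15), substr(l, 16, 24), substr(l, 25, 33))) / 10
  }
  model_starts <- which(trimws(rec) == "MODEL")
  if (length(model_starts) == 0) {
    blocks <- list(which(rec %in% c("ATOM  ", "HETATM")))
  } else {
    ends <- which(trimws(rec) == "ENDMDL")
    if (length(ends) != length(model_starts)) {
      stop_parse(path, length(lines), "unbalanced MODEL/ENDMDL")
    }
    blocks <- purrr::map2(model_starts, ends, function(s, e) {
      idx <- s:e
      idx[rec[idx] %in% c("ATOM  ", "HETATM")]
    })
  }
  frames <- purrr::imap(blocks, function(idx, k) {
    if (length(idx) == 0) stop_parse(path, 1L, "model with no atoms")
    at <- lines[idx]
    name <- trimws(substr(at, 13, 16))
    resname <- trimws(substr(at, 18, 21))
    resid <- suppressWarnings(as.integer(substr(at, 23, 26)))
    x <- suppressWarnings(as.numeric(substr(at, 31, 38))) / 10
    y <- suppressWarnings(as.numeric(substr(at, 39, 46))) / 10
    z <- suppressWarnings(as.numeric(substr(at, 47, 54))) / 10
    if (anyNA(x) || anyNA(y) || anyNA(z) || anyNA(resid)) {
      bad <- idx[which(is.na(x) | is.na(y) | is.na(z) | is.na(resid))[1]]
      stop_parse(path, bad, "unparsable ATOM record")
    }
    b <- box
    if (is.null(b)) b <- pmax(apply(cbind(x, y, z), 2, function(v) diff(range(v))), 1)
    cg_frame(
      tibble::tibble(molid = resid, resid = resid, resname = resname,
                     name = name, x = x, y = y, z = z),
      box = b, time = k - 1
    )
  })
  if (length(frames) == 1) frames[[1]] else cg_trajectory(frames)
}

#' @rdname read_pdb
#' @param x a `cg_frame` or `cg_traj`.
#' @export
write_pdb <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  frames <- as_frames(x)
  b <- frame_box(frames[[1]]) * 10
  writeLines(sprintf(
    "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", b[1], b[2], b[3],
    90, 90, 90
  ), con)
  for (k in seq_along(frames)) {
    f <- frames[[k]]
    if (length(frames) > 1) writeLines(sprintf("MODEL %8d", k), con)
    writeLines(sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00",
      seq_len(nrow(f)) %% 100000L, substr(f$name, 1, 4),
      substr(f$resname, 1, 4), f$resid %% 10000L,
      f$x * 10, f$y * 10, f$z * 10
    ), con)
    if (length(frames) > 1) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
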