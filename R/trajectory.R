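#' Coordinate trajectories
#'
#' An `iface_trajectory` bundles a fixed atom roster (a structure tibble whose
#' coordinates are the reference frame) with a `natoms x 3 x nframes` array of
#' coordinates in Angstrom and optional frame times in ns.
#'
#' @param roster A structure data frame ([as_structure()]); its coordinate
#'   columns give frame 1 unless `coords` is supplied.
#' @param coords A `natoms x 3 x nframes` numeric array.
#' @param times Optional numeric vector of frame times (ns), one per frame.
#' @return An object of class `iface_trajectory`.
#' @export
trajectory <- function(roster, coords, times = NULL) {
  roster <- as_structure(roster)
  if (length(dim(coords)) != 3 || dim(coords)[1] != nrow(roster) ||
      dim(coords)[2] != 3) {
    abort("coords must be a natoms x 3 x nframes array matching the roster")
  }
  if (dim(coords)[3] < 1) abort("a trajectory needs at least one frame")
  if (!is.null(times) && length(times) != dim(coords)[3]) {
    abort("times must have one entry per frame")
  }
  structure(
    list(roster = roster, coords = coords, times = times),
    class = "iface_trajectory"
  )
}

#' @export
print.iface_trajectory <- function(x, ...) {
  cat(sprintf("<iface_trajectory> %d atoms x %d frames\n",
              dim(x$coords)[1], dim(x$coords)[3]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory An `iface_trajectory`.
#' @export
n_frames <- function(trajectory) dim(trajectory$coords)[3]

#' Extract one frame of a trajectory as a structure
#'
#' @param trajectory An `iface_trajectory`.
#' @param frame 1-based frame index.
#' @return An `iface_structure` tibble with that frame's coordinates.
#' @export
trajectory_frame <- function(trajectory, frame) {
  nf <- n_frames(trajectory)
  if (frame < 1 || frame > nf) {
    abort(sprintf("frame %d out of range (trajectory has %d frames)",
                  frame, nf))
  }
  s <- trajectory$roster
  s$x <- trajectory$coords[, 1, frame]
  s$y <- trajectory$coords[, 2, frame]
  s$z <- trajectory$coords[, 3, frame]
  s
}

#' @method tidy iface_trajectory
#' @export
tidy.iface_trajectory <- function(x, ...) {
  nf <- n_frames(x)
  na <- nrow(x$roster)
  tibble(
    frame = rep(seq_len(nf), each = na),
    serial = rep(x$roster$serial, nf),
    chain = rep(x$roster$chain, nf),
    resno = rep(x$roster$resno, nf),
    name = rep(x$roster$name, nf),
    x = as.vector(x$coords[, 1, ]),
    y = as.vector(x$coords[, 2, ]),
    z = as.vector(x$coords[, 3, ])
  )
}

#' Read a trajectory from disk
#'
#' Two plain-text formats are supported: multi-model PDB (`MODEL`/`ENDMDL`
#' records) and a minimal "frame-table" format — a header line with the atom
#' count, then per frame one `index x y z` line per atom, frames separated by
#' one blank line. The frame-table format carries no chemistry, so a reference
#' `roster` structure may be supplied to attach chain/residue metadata.
#'
#' @param path Input file.
#' @param format `"pdb"` or `"frame-table"`.
#' @param roster Optional structure giving atom metadata for frame-table input.
#' @return An `iface_trajectory`.
#' @export
read_trajectory <- function(path, format = c("pdb", "frame-table"),
                            roster = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("trajectory file not found: ", path))
  if (format == "pdb") {
    check_pdb_coordinate_lines(path)
    check_model_atom_counts(path)
    pdb <- suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                            verbose = FALSE))
    ref <- read_pdb(path, model_index = 1)
    nf <- nrow(pdb$xyz)
    na <- nrow(ref)
    coords <- array(NA_real_, dim = c(na, 3, nf))
    for (k in seq_len(nf)) {
      coords[, , k] <- matrix(pdb$xyz[k, ], ncol = 3, byrow = TRUE)
    }
    tr <- trajectory(ref, coords)
  } else {
    tr <- read_frame_table(path, roster)
  }
  inform(sprintf("read trajectory: %d frames of %d atoms from %s",
                 n_frames(tr), nrow(tr$roster), basename(path)))
  tr
}

check_model_atom_counts <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) < 2) return(invisible(TRUE))
  model_ends <- which(rec == "ENDMDL")
  counts <- mapply(function(a, b) {
    sum(rec[a:b] %in% c("ATOM  ", "HETATM"))
  }, model_starts, model_ends)
  if (length(unique(counts)) > 1) {
    bad <- which(counts != counts[1])[1]
    abort(sprintf("frame %d has %d atoms, expected %d",
                  bad, counts[bad], counts[1]))
  }
  invisible(TRUE)
}

read_frame_table <- function(path, roster = NULL) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort("empty frame-table file")
  na <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(na) || na < 1) abort("frame-table header must be the atom count")
  body <- lines[-1]
  # split on blank lines into frames
  blank <- !nzchar(trimws(body))
  frames <- split(body[!blank], cumsum(blank)[!blank])
  nf <- length(frames)
  coords <- array(NA_real_, dim = c(na, 3, nf))
  for (k in seq_len(nf)) {
    rows <- frames[[k]]
    if (length(rows) != na) {
      abort(sprintf("frame %d has %d atoms, expected %d", k, length(rows), na))
    }
    m <- matrix(scan(text = rows, quiet = TRUE), ncol = 4, byrow = TRUE)
    coords[m[, 1], , k] <- m[, 2:4]
  }
  if (is.null(roster)) {
    roster <- as_structure(tibble(
      serial = seq_len(na), name = "CA", element = "C",
      resno = seq_len(na), resid = "GLY", chain = "A",
      x = coords[, 1, 1], y = coords[, 2, 1], z = coords[, 3, 1]
    ))
  } else {
    roster <- as_structure(roster)
    if (nrow(roster) != na) {
      abort(sprintf("roster has %d atoms but file declares %d",
                    nrow(roster), na))
    }
  }
  trajectory(roster, coords)
}

#' Write a trajectory to disk
#'
#' @inheritParams read_trajectory
#' @param trajectory An `iface_trajectory`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path,
                             format = c("pdb", "frame-table")) {
  format <- match.arg(format)
  nf <- n_frames(trajectory)
  if (format == "pdb") {
    con <- file(path, "w")
    on.exit(close(con))
    r <- trajectory$roster
    for (k in seq_len(nf)) {
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(format_pdb_atom_line(
        r$serial, r$name, r$resid, r$chain, r$resno,
        trajectory$coords[, 1, k], trajectory$coords[, 2, k],
        trajectory$coords[, 3, k], r$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  } else {
    na <- nrow(trajectory$roster)
    chunks <- vector("list", nf)
    for (k in seq_len(nf)) {
      chunks[[k]] <- sprintf("%d %.17g %.17g %.17g", seq_len(na),
                             trajectory$coords[, 1, k],
                             trajectory$coords[, 2, k],
                             trajectory$coords[, 3, k])
    }
    body <- unlist(lapply(chunks, function(ch) c(ch, "")), use.names = FALSE)
    writeLines(c(as.character(na), body[-length(body)]), path)
  }
  invisible(path)
}
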