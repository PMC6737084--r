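#' Trajectory container
#'
#' A trajectory couples a [read_topology()] table with an array of per-frame
#' coordinates, `coords[frame, atom, xyz]`, in Angstrom. Frame times (ps) are
#' optional. No unit conversion and no periodic-boundary handling is done
#' anywhere: input trajectories are assumed whole-molecule imaged upstream.
#'
#' @param topology a `topology`.
#' @param coords numeric array `n_frames x n_atoms x 3`, finite.
#' @param times optional numeric vector of frame times in ps.
#' @return a `trajectory` object (list with `topology`, `coords`, `times`).
#' @export
new_trajectory <- function(topology, coords, times = NULL) {
  if (length(dim(coords)) != 3 || dim(coords)[3] != 3) {
    stop("coords must be an n_frames x n_atoms x 3 array")
  }
  if (dim(coords)[2] != nrow(topology)) {
    stop("coords has ", dim(coords)[2], " atoms but topology has ",
         nrow(topology))
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(times) && length(times) != dim(coords)[1]) {
    stop("times length must equal the number of frames")
  }
  structure(list(topology = topology, coords = coords, times = times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> ", n_frames(x), " frames x ", n_atoms(x), " atoms",
      if (!is.null(x$times)) paste0(", ", round(diff(range(x$times)), 3),
                                    " ps span"),
      "\n", sep = "")
  invisible(x)
}

#' Number of frames / atoms in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

#' @rdname n_frames
#' @export
n_atoms <- function(traj) dim(traj$coords)[2]

#' Extract one frame as an n_atoms x 3 matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) {
  m <- traj$coords[i, , , drop = FALSE]
  dim(m) <- dim(traj$coords)[2:3]
  m
}

# frames x 3N matrix in bio3d xyz ordering (x1 y1 z1 x2 ...)
traj_xyz_matrix <- function(traj) {
  nf <- n_frames(traj); na <- n_atoms(traj)
  m <- aperm(traj$coords, c(3, 2, 1))    # xyz, atom, frame
  dim(m) <- c(3 * na, nf)
  t(m)
}

xyz_matrix_to_coords <- function(xyz) {
  nf <- nrow(xyz); na <- ncol(xyz) / 3
  m <- t(xyz)
  dim(m) <- c(3, na, nf)
  aperm(m, c(3, 2, 1))
}

#' Read a multi-frame trajectory
#'
#' Two plain-text dialects are supported: multi-frame XYZ (blocks of
#' atom-count line, comment line, then `element x y z` rows) and multi-MODEL
#' PDB (via [bio3d::read.pdb()]). Coordinates are taken as Angstrom with no
#' conversion. Every frame must carry exactly one coordinate triple per
#' topology atom; a mismatch aborts with the offending frame index.
#'
#' @param path file path.
#' @param topology the `topology` the frames correspond to.
#' @param format `"xyz_multiframe"` or `"pdb_multimodel"`.
#' @return a [new_trajectory()] object.
#' @export
read_trajectory <- function(path, topology,
                            format = c("xyz_multiframe", "pdb_multimodel")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  na <- nrow(topology)
  if (format == "xyz_multiframe") {
    lines <- readLines(path, warn = FALSE)
    pos <- 1L; frames <- list(); fi <- 0L
    while (pos <= length(lines)) {
      if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
      fi <- fi + 1L
      cnt <- suppressWarnings(as.integer(trimws(lines[pos])))
      if (is.na(cnt)) stop("bad atom-count line at frame ", fi)
      if (cnt != na) {
        stop("atom-count mismatch at frame ", fi, ": file has ", cnt,
             ", topology has ", na)
      }
      if (pos + 1L + cnt > length(lines)) {
        stop("truncated frame ", fi, ": expected ", cnt, " atom lines")
      }
      block <- lines[(pos + 2L):(pos + 1L + cnt)]
      fields <- strsplit(trimws(block), "[[:space:]]+")
      bad <- which(lengths(fields) < 4L)
      if (length(bad) > 0) stop("malformed atom line in frame ", fi)
      xyz <- vapply(fields, function(f) as.numeric(f[2:4]), numeric(3))
      if (anyNA(xyz)) stop("non-numeric coordinates in frame ", fi)
      frames[[fi]] <- t(xyz)
      pos <- pos + 2L + cnt
    }
    if (fi == 0L) stop("no frames in ", path)
    coords <- array(0, dim = c(fi, na, 3))
    for (k in seq_len(fi)) coords[k, , ] <- frames[[k]]
    new_trajectory(topology, coords)
  } else {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    xyz <- pdb$xyz
    if (ncol(xyz) != 3 * na) {
      stop("atom-count mismatch at frame 1: file has ", ncol(xyz) / 3,
           ", topology has ", na)
    }
    new_trajectory(topology, xyz_matrix_to_coords(unclass(xyz)))
  }
}

#' Write a trajectory
#'
#' XYZ frames are written with `%.3f` coordinates (the format's customary
#' precision; round-trips reproduce coordinates to 1e-3 Angstrom). PDB output
#' wraps each frame in MODEL/ENDMDL records.
#'
#' @param traj a `trajectory`.
#' @param path output path.
#' @param format `"xyz_multiframe"` or `"pdb_multimodel"`.
#' @param digits decimal places for XYZ output.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path,
                             format = c("xyz_multiframe", "pdb_multimodel"),
                             digits = 3) {
  format <- match.arg(format)
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  if (format == "xyz_multiframe") {
    fmt <- paste0("%-3s %.", digits, "f %.", digits, "f %.", digits, "f")
    for (k in seq_len(n_frames(traj))) {
      fr <- frame_coords(traj, k)
      writeLines(c(as.character(nrow(top)), paste0("frame ", k),
                   sprintf(fmt, top$element, fr[, 1], fr[, 2], fr[, 3])), con)
    }
  } else {
    for (k in seq_len(n_frames(traj))) {
      fr <- frame_coords(traj, k)
      writeLines(sprintf("MODEL     %4d", k), con)
      writeLines(sprintf(
        "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
        top$atom_id %% 100000, substr(top$atom_name, 1, 4),
        substr(top$residue_name, 1, 3), top$chain_id,
        top$residue_index %% 10000,
        fr[, 1], fr[, 2], fr[, 3], top$element), con)
      writeLines("ENDMDL", con)
    }
    writeLines("END", con)
  }
  invisible(path)
}
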