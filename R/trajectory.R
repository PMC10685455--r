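#' Trajectory container
#'
#' Coordinates for a sequence of frames of one solute, paired with its
#' topology. Coordinates are in Angstrom; `frame_interval` is the
#' simulation time per saved frame in nanoseconds.
#'
#' @param coords numeric array `frames x atoms x 3` (a single `atoms x 3`
#'   matrix is promoted to one frame).
#' @param top a [topology()] object with matching atom count.
#' @param frame_interval time per saved frame, ns (> 0).
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(coords, top, frame_interval = 1) {
  if (is.matrix(coords)) coords <- array(coords, c(1L, dim(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stopf("coords must be a frames x atoms x 3 array")
  if (dim(coords)[2] != n_atoms(top))
    stopf("frame atom count (%d) does not match topology (%d)",
          dim(coords)[2], n_atoms(top))
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stopf("frame_interval must be > 0 ns")
  structure(list(coords = coords, topology = top,
                 frame_interval = frame_interval),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  d <- dim(x$coords)
  cat(sprintf("trajectory: %d frames x %d atoms, %.4g ns/frame (%.4g ns total)\n",
              d[1], d[2], x$frame_interval, d[1] * x$frame_interval))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a [trajectory()] object.
#' @export
n_frames <- function(traj) dim(traj$coords)[1]

# one frame as an atoms x 3 matrix
frame_coords <- function(traj, i) {
  matrix(traj$coords[i, , ], ncol = 3)
}

#' Read a trajectory file
#'
#' Supported formats: multi-frame XYZ (`.xyz`), multi-model PDB (`.pdb`)
#' and binary DCD (`.dcd`, via bio3d). Frames are returned in file order;
#' a truncated final XYZ frame is dropped with a warning.
#'
#' @param path trajectory file.
#' @param top the solute [topology()]; atom counts must match.
#' @param frame_interval time per saved frame, ns.
#' @param format one of `"auto"`, `"xyz"`, `"pdb"`, `"dcd"`.
#' @return A [trajectory()] object.
#' @export
read_trajectory <- function(path, top, frame_interval = 1, format = "auto") {
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)),
                     xyz = "xyz", pdb = "pdb", dcd = "dcd",
                     stopf("cannot guess trajectory format of %s", path))
  coords <- switch(format,
    xyz = read_xyz_frames(path),
    dcd = {
      xyz <- bio3d::read.dcd(path, verbose = FALSE)
      array(aperm(array(t(xyz), c(3, ncol(xyz) / 3, nrow(xyz))), c(3, 2, 1)),
            c(nrow(xyz), ncol(xyz) / 3, 3))
    },
    pdb = {
      pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
      xyz <- pdb$xyz
      array(aperm(array(t(xyz), c(3, ncol(xyz) / 3, nrow(xyz))), c(3, 2, 1)),
            c(nrow(xyz), ncol(xyz) / 3, 3))
    },
    stopf("unknown trajectory format '%s'", format))
  if (dim(coords)[2] != n_atoms(top))
    stopf("trajectory atom count (%d) does not match topology (%d)",
          dim(coords)[2], n_atoms(top))
  trajectory(coords, top, frame_interval)
}

# multi-frame XYZ: repeated blocks of [n_atoms] [comment] [n_atoms lines:
# element x y z]
read_xyz_frames <- function(path) {
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  pos <- 1L
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stopf("malformed XYZ atom-count at line %d of %s", pos, path)
    if (pos + 1L + nat > length(lines)) {
      warnf("truncated final XYZ frame dropped (%s)", path)
      break
    }
    block <- lines[(pos + 2L):(pos + 1L + nat)]
    flds <- strsplit(trimws(block), "\\s+")
    if (any(lengths(flds) < 4L))
      stopf("malformed XYZ coordinate line near line %d of %s", pos + 2L, path)
    xyz <- t(vapply(flds, function(f) as.numeric(f[2:4]), numeric(3)))
    if (anyNA(xyz))
      stopf("non-numeric XYZ coordinate near line %d of %s", pos + 2L, path)
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + nat
  }
  if (!length(frames)) stopf("no frames found in %s", path)
  nat <- nrow(frames[[1]])
  if (any(vapply(frames, nrow, integer(1)) != nat))
    stopf("inconsistent atom counts across XYZ frames in %s", path)
  out <- array(NA_real_, c(length(frames), nat, 3))
  for (i in seq_along(frames)) out[i, , ] <- frames[[i]]
  out
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param traj a [trajectory()] object.
#' @param path output file.
#' @param digits coordinate precision in decimal places.
#' @export
write_xyz <- function(traj, path, digits = 6) {
  top <- traj$topology
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- sprintf("%%-4s %%.%df %%.%df %%.%df", digits, digits, digits)
  for (i in seq_len(n_frames(traj))) {
    writeLines(c(as.character(n_atoms(top)), sprintf("frame %d", i)), con)
    xyz <- frame_coords(traj, i)
    writeLines(sprintf(fmt, top$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3]),
               con)
  }
  invisible(path)
}

#' Write a topology (and one conformation) as PDB
#'
#' @param top a [topology()] object.
#' @param coords atoms x 3 coordinate matrix, Angstrom.
#' @param path output file.
#' @param conect write CONECT records from the bond list.
#' @export
write_pdb <- function(top, coords, path, conect = TRUE) {
  n <- n_atoms(top)
  lines <- sprintf(
    "ATOM  %5d  %-4s%-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(top$atoms$name, 1, 3),
    substr(top$atoms$residue_name, 1, 3), top$atoms$residue_id,
    coords[, 1], coords[, 2], coords[, 3], top$atoms$element)
  if (conect && nrow(top$bonds)) {
    adj <- bond_adjacency(top)
    lines <- c(lines, unlist(lapply(seq_len(n), function(i) {
      if (!length(adj[[i]])) return(character(0))
      sprintf("CONECT%5d%s", i, paste(sprintf("%5d", sort(adj[[i]])), collapse = ""))
    })))
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
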