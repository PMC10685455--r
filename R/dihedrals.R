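#' Torsion definitions
#'
#' A set of torsions, each defined by four distinct atom indices
#' (1-based), with labels such as `"T1".."T11"`.
#'
#' @param quadruples 4-column integer matrix, one torsion per row.
#' @param labels optional character labels (default `T1, T2, ...`).
#' @param top optional [topology()] used to validate indices.
#' @return An object of class `torsion_set`.
#' @export
torsion_set <- function(quadruples, labels = NULL, top = NULL) {
  quadruples <- matrix(as.integer(quadruples), ncol = 4)
  if (any(apply(quadruples, 1, anyDuplicated) > 0))
    stopf("a torsion quadruple repeats an atom")
  if (any(quadruples < 1L)) stopf("torsion atom indices must be >= 1")
  if (!is.null(top) && any(quadruples > n_atoms(top)))
    stopf("torsion references atom index beyond topology (%d atoms)",
          n_atoms(top))
  if (is.null(labels)) labels <- paste0("T", seq_len(nrow(quadruples)))
  if (length(labels) != nrow(quadruples))
    stopf("labels length (%d) does not match torsion count (%d)",
          length(labels), nrow(quadruples))
  structure(list(quadruples = quadruples, labels = as.character(labels)),
            class = "torsion_set")
}

#' @export
print.torsion_set <- function(x, ...) {
  cat(sprintf("torsion_set: %d torsions (%s)\n", nrow(x$quadruples),
              paste(utils::head(x$labels, 6), collapse = ", ")))
  invisible(x)
}

#' Read torsion definitions
#'
#' Whitespace-separated file, one torsion per line: four 1-based atom
#' indices and an optional trailing label. Lines starting with `#` are
#' ignored.
#'
#' @inheritParams torsion_set
#' @param path definition file.
#' @return A [torsion_set()] object.
#' @export
read_torsions <- function(path, top = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stopf("no torsion definitions in %s", path)
  flds <- strsplit(lines, "\\s+")
  quads <- t(vapply(flds, function(f) {
    v <- suppressWarnings(as.integer(f[1:4]))
    if (anyNA(v)) stopf("malformed torsion line in %s", path)
    v
  }, integer(4)))
  labels <- vapply(flds, function(f) if (length(f) >= 5) f[5] else NA_character_,
                   character(1))
  if (anyNA(labels)) labels <- NULL
  torsion_set(quads, labels, top)
}

#' Write torsion definitions
#' @param torsions a [torsion_set()] object.
#' @param path output file.
#' @export
write_torsions <- function(torsions, path) {
  writeLines(sprintf("%d %d %d %d %s",
                     torsions$quadruples[, 1], torsions$quadruples[, 2],
                     torsions$quadruples[, 3], torsions$quadruples[, 4],
                     torsions$labels), path)
  invisible(path)
}

# signed dihedral (degrees) of four 3D points, atan2 formulation;
# wrap convention (-180, 180], -180 mapped to +180
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  if (vnorm(n1) < 1e-10 || vnorm(n2) < 1e-10)
    stopf("undefined dihedral: collinear atoms in quadruple")
  m1 <- c(b2[2] * n1[3] - b2[3] * n1[2],
          b2[3] * n1[1] - b2[1] * n1[3],
          b2[1] * n1[2] - b2[2] * n1[1]) / vnorm(b2)
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Compute torsion angles over a trajectory
#'
#' Standard signed dihedrals from four atom positions, in degrees with
#' wrap convention (-180, 180] (exact -180 reported as +180).
#'
#' @param traj a [trajectory()] object.
#' @param torsions a [torsion_set()] valid for the trajectory's topology.
#' @return Numeric matrix `frames x torsions`, columns named by torsion
#'   labels.
#' @export
compute_dihedrals <- function(traj, torsions) {
  if (any(torsions$quadruples > n_atoms(traj$topology)))
    stopf("torsion references atom index beyond topology")
  nf <- n_frames(traj)
  nt <- nrow(torsions$quadruples)
  out <- matrix(NA_real_, nf, nt, dimnames = list(NULL, torsions$labels))
  for (t in seq_len(nt)) {
    q <- torsions$quadruples[t, ]
    for (f in seq_len(nf)) {
      out[f, t] <- dihedral_angle(traj$coords[f, q[1], ], traj$coords[f, q[2], ],
                                  traj$coords[f, q[3], ], traj$coords[f, q[4], ])
    }
  }
  out
}
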