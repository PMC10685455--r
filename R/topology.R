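#' Molecular topology
#'
#' A light-weight solute topology: an atom table plus a bond list. Atom
#' indices are 1-based and contiguous; PDB serial numbers are converted on
#' read. Bonds are stored once per pair with `i < j`.
#'
#' @param atoms data.frame with columns `name`, `element`, `residue_id`,
#'   `residue_name` (one row per atom, in index order).
#' @param bonds two-column integer matrix of bonded atom index pairs.
#' @param formal_charge integer molecular formal charge, elementary units.
#' @return An object of class `topology` with elements `atoms`, `bonds`
#'   and `formal_charge`.
#' @export
topology <- function(atoms, bonds, formal_charge = 0L) {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  need <- c("name", "element", "residue_id", "residue_name")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stopf("atom table lacks column(s): %s", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (n == 0L) stopf("topology must contain at least one atom")
  bonds <- normalize_bonds(bonds, n)
  structure(list(atoms = atoms, bonds = bonds,
                 formal_charge = as.integer(formal_charge)),
            class = "topology")
}

normalize_bonds <- function(bonds, n_atoms) {
  if (is.null(bonds) || length(bonds) == 0L)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("i", "j"))))
  bonds <- matrix(as.integer(bonds), ncol = 2)
  if (any(!is.finite(bonds)) || any(bonds < 1L) || any(bonds > n_atoms))
    stopf("bond references an atom index outside 1..%d", n_atoms)
  if (any(bonds[, 1] == bonds[, 2])) stopf("self-bonds are not allowed")
  bonds <- cbind(pmin(bonds[, 1], bonds[, 2]), pmax(bonds[, 1], bonds[, 2]))
  bonds <- unique(bonds)
  bonds <- bonds[order(bonds[, 1], bonds[, 2]), , drop = FALSE]
  dimnames(bonds) <- list(NULL, c("i", "j"))
  bonds
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d atoms, %d bonds, formal charge %+d\n",
              n_atoms(x), nrow(x$bonds), x$formal_charge))
  elems <- table(x$atoms$element)
  cat("  composition:",
      paste(sprintf("%s%d", names(elems), as.integer(elems)), collapse = " "),
      "\n")
  invisible(x)
}

#' Number of atoms in a topology
#' @param top a [topology()] object.
#' @export
n_atoms <- function(top) nrow(top$atoms)

#' Read a topology from a PDB file
#'
#' ATOM/HETATM records are parsed with bio3d; CONECT records, if present,
#' supply the bond list. Without CONECT records bonds are inferred from
#' interatomic distances using covalent radii (cutoff r_i + r_j + `fudge`).
#'
#' @param path PDB file with at least one ATOM/HETATM record.
#' @param formal_charge molecular formal charge (not stored in PDB).
#' @param fudge slack added to the covalent-radius sum, Angstrom.
#' @return A [topology()] object.
#' @export
read_topology <- function(path, formal_charge = 0L, fudge = 0.4) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) stopf("PDB parse error in %s: %s",
                                            path, conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L)
    stopf("no ATOM/HETATM records in %s", path)
  element <- at$elesy
  blank <- is.na(element) | !nzchar(trimws(element))
  element[blank] <- guess_element(at$elety[blank])
  atoms <- data.frame(name = trimws(at$elety),
                      element = trimws(element),
                      residue_id = at$resno,
                      residue_name = trimws(at$resid),
                      stringsAsFactors = FALSE)
  coords <- cbind(at$x, at$y, at$z)
  serial <- at$eleno
  bonds <- read_conect(path, serial)
  top <- topology(atoms, bonds, formal_charge)
  if (nrow(top$bonds) == 0L)
    top$bonds <- infer_bonds(coords, atoms$element, fudge = fudge)
  attr(top, "coords") <- coords
  top
}

# element symbol from a PDB atom name, e.g. "HA2" -> "H", "CL1" -> "Cl"
guess_element <- function(name) {
  name <- trimws(name)
  two <- c("Cl", "Br")
  vapply(name, function(nm) {
    up <- toupper(nm)
    for (el in two) if (startsWith(up, toupper(el))) return(el)
    sub1 <- substr(gsub("[0-9]", "", up), 1, 1)
    if (!nzchar(sub1)) "C" else sub1
  }, character(1), USE.NAMES = FALSE)
}

read_conect <- function(path, serial) {
  lines <- readLines(path, warn = FALSE)
  con <- grep("^CONECT", lines, value = TRUE)
  if (!length(con)) return(NULL)
  pairs <- list()
  for (k in seq_along(con)) {
    flds <- suppressWarnings(as.integer(strsplit(trimws(sub("^CONECT", "", con[k])),
                                                 "\\s+")[[1]]))
    if (any(is.na(flds)) || length(flds) < 2L)
      stopf("malformed CONECT record at line %d",
            which(lines == con[k])[1])
    from <- match(flds[1], serial)
    to <- match(flds[-1], serial)
    if (is.na(from) || anyNA(to))
      stopf("CONECT references unknown atom serial (line %d)",
            which(lines == con[k])[1])
    pairs[[k]] <- cbind(from, to)
  }
  do.call(rbind, pairs)
}

#' Infer bonds from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of their
#' covalent radii plus `fudge`. Symmetric by construction, no self-bonds.
#'
#' @param coords n x 3 coordinate matrix, Angstrom.
#' @param elements character vector of element symbols.
#' @param fudge slack in Angstrom (default 0.4).
#' @return Two-column bond index matrix.
#' @export
infer_bonds <- function(coords, elements, fudge = 0.4) {
  n <- nrow(coords)
  rad <- covalent_radius(elements)
  d <- as.matrix(stats::dist(coords))
  cutoff <- outer(rad, rad, "+") + fudge
  hit <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  normalize_bonds(hit, n)
}

# adjacency list from the bond matrix
bond_adjacency <- function(top) {
  adj <- vector("list", n_atoms(top))
  for (k in seq_len(nrow(top$bonds))) {
    i <- top$bonds[k, 1]; j <- top$bonds[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# bond-graph (topological) distances from one atom via BFS; Inf if disconnected
bond_graph_distances <- function(top, from) {
  adj <- bond_adjacency(top)
  n <- n_atoms(top)
  d <- rep(Inf, n)
  d[from] <- 0
  queue <- from
  while (length(queue)) {
    cur <- queue[1]; queue <- queue[-1]
    for (nb in adj[[cur]]) if (d[nb] > d[cur] + 1) {
      d[nb] <- d[cur] + 1
      queue <- c(queue, nb)
    }
  }
  d
}
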