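# Independent oracles used across the suite. These deliberately use
# different formulations than the package internals.

# dihedral via explicit plane normals: unsigned angle from acos, sign from
# the triple product of the first normal with the third bond vector
oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  cosang <- sum(n1 * n2) / (sqrt(sum(n1^2)) * sqrt(sum(n2^2)))
  cosang <- max(-1, min(1, cosang))
  ang <- acos(cosang) * 180 / pi
  if (sum(n1 * b3) < 0) ang <- -ang  # det[b1,b2,b3] sets the sign (IUPAC)
  if (ang <= -180) ang <- ang + 360
  ang
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# brute-force H-bond detection: plain triple loop over donor/H/acceptor
# with explicit distance, angle and graph-separation tests
oracle_detect <- function(coords, donors, acceptors, criteria, top) {
  sep <- macrorew:::pair_separation(top, donors, acceptors)
  out <- matrix(FALSE, nrow(donors), nrow(acceptors),
                dimnames = list(donors$label, acceptors$label))
  for (d in seq_len(nrow(donors))) {
    for (a in seq_len(nrow(acceptors))) {
      dh <- donors$heavy[d]; hy <- donors$hydrogen[d]
      ac <- acceptors$atom[a]
      if (ac == dh) next
      if (sep[d, a] < criteria$min_separation) next
      ref <- if (criteria$distance_from == "heavy") dh else hy
      if (sqrt(sum((coords[ac, ] - coords[ref, ])^2)) > criteria$d_max) next
      v1 <- coords[dh, ] - coords[hy, ]
      v2 <- coords[ac, ] - coords[hy, ]
      ang <- acos(max(-1, min(1, sum(v1 * v2) /
                                sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang >= criteria$angle_min) out[d, a] <- TRUE
    }
  }
  out
}

# brute-force optimal-superposition RMSD: center both, coarse search over
# Euler-angle grid, refine the best grid point with Nelder-Mead
oracle_superposed_rmsd <- function(a, b, n_grid = 10) {
  a <- sweep(a, 2, colMeans(a))
  b <- sweep(b, 2, colMeans(b))
  rot <- function(ang) {
    cx <- cos(ang[1]); sx <- sin(ang[1])
    cy <- cos(ang[2]); sy <- sin(ang[2])
    cz <- cos(ang[3]); sz <- sin(ang[3])
    Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, byrow = TRUE)
    Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, byrow = TRUE)
    Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, byrow = TRUE)
    Rz %*% Ry %*% Rx
  }
  obj <- function(ang) sqrt(mean(rowSums((a %*% t(rot(ang)) - b)^2)))
  grid <- seq(0, 2 * pi, length.out = n_grid + 1)[-(n_grid + 1)]
  cand <- as.matrix(expand.grid(grid, grid, grid))
  vals <- apply(cand, 1, obj)
  # refine the best grid points from several starts; keep the global best
  starts <- cand[order(vals)[1:8], , drop = FALSE]
  min(apply(starts, 1, function(s)
    stats::optim(s, obj, method = "Nelder-Mead",
                 control = list(reltol = 1e-15, maxit = 10000))$value))
}

# N-methylacetamide-like topology: CH3-C(=O)-N(H)-CH3 with explicit H
nma_topology <- function() {
  atoms <- data.frame(
    name = c("CT1", "H11", "H12", "H13", "C", "O", "N", "H", "CT2",
             "H21", "H22", "H23"),
    element = c("C", "H", "H", "H", "C", "O", "N", "H", "C", "H", "H", "H"),
    residue_id = 1L, residue_name = "NMA", stringsAsFactors = FALSE)
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5), c(5, 6), c(5, 7),
                 c(7, 8), c(7, 9), c(9, 10), c(9, 11), c(9, 12))
  topology(atoms, bonds)
}

# canonical strong-boost condition for the 1D harmonic reweighting oracle:
# threshold two kB*T above the mean unbiased potential, alpha = kB*T
harmonic_boost_params <- function(temperature = 300, k = 1) {
  kbt <- KB_KCAL * temperature
  amd_params(e_dih = 1, alpha_dih = 1,
             e_tot = kbt / 2 + 2 * kbt, alpha_tot = kbt)
}

# weights with a designed exact subset: frames 1 and 2 sum to 0.37
weights_for_037 <- function(n = 100) {
  c(0.2, 0.17, rep(0.63 / (n - 2), n - 2))
}

tmpfile <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
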