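#' Geometric hydrogen-bond criteria
#'
#' A donor-acceptor pair counts as an intramolecular hydrogen bond (IMHB)
#' in a frame when (i) the donor-heavy-atom to acceptor-heavy-atom
#' distance is at most `d_max`, (ii) the donor-H...acceptor angle (at the
#' hydrogen) is at least `angle_min`, and (iii) donor and acceptor heavy
#' atoms are at least `min_separation` bonds apart in the bond graph (so
#' covalently adjacent polar atoms are not self-counted). Both geometric
#' cutoffs are inclusive. The permissive 90 degree angle cutoff
#' deliberately captures unconventional short-range IMHBs.
#'
#' @param d_max heavy-atom distance cutoff, Angstrom (default 3.5).
#' @param angle_min minimum D-H...A angle, degrees (default 90).
#' @param min_separation minimum bond-graph separation (default 3).
#' @param distance_from measure the distance from the donor `"heavy"`
#'   atom (default) or from the `"hydrogen"`.
#' @return An object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 3.5, angle_min = 90, min_separation = 3,
                           distance_from = c("heavy", "hydrogen")) {
  if (d_max <= 0) stopf("d_max must be > 0")
  if (angle_min < 0 || angle_min > 180) stopf("angle_min must be in [0, 180]")
  structure(list(d_max = d_max, angle_min = angle_min,
                 min_separation = as.integer(min_separation),
                 distance_from = match.arg(distance_from)),
            class = "hbond_criteria")
}

#' Identify hydrogen-bond donors and acceptors in a topology
#'
#' Donors are N or O atoms bonded to at least one hydrogen — one donor
#' entry per N-H/O-H pair. Acceptors are oxygens (carbonyl O always
#' qualifies) and nitrogens with an available lone pair; amide nitrogens
#' are excluded as acceptors, and nitrogens bearing hydrogens are treated
#' as donors only (the conventional choice in geometric H-bond analyses
#' of peptide-like molecules).
#'
#' @param top a [topology()] object with explicit hydrogens and bonds.
#' @return List with `donors` (data.frame: `heavy`, `hydrogen`, `label`)
#'   and `acceptors` (data.frame: `atom`, `label`).
#' @export
find_donors_acceptors <- function(top) {
  el <- top$atoms$element
  if (!any(el == "H"))
    stopf("topology has no explicit hydrogens; hydrogen-bond detection requires them")
  adj <- bond_adjacency(top)
  donors <- list()
  for (i in which(el %in% c("N", "O"))) {
    for (h in adj[[i]]) if (el[h] == "H")
      donors[[length(donors) + 1L]] <- c(heavy = i, hydrogen = h)
  }
  donors <- if (length(donors)) as.data.frame(do.call(rbind, donors))
            else data.frame(heavy = integer(0), hydrogen = integer(0))
  donors$label <- sprintf("D%d", seq_len(nrow(donors)))

  carbonyl_c <- which(el == "C" &
    vapply(adj, function(nb) any(el[nb] == "O" & lengths(adj[nb]) == 1L),
           logical(1)))
  acceptors <- integer(0)
  for (i in which(el %in% c("N", "O"))) {
    if (el[i] == "O") {
      acceptors <- c(acceptors, i)           # all O (carbonyl, hydroxyl, ether)
    } else {
      amide <- any(adj[[i]] %in% carbonyl_c)
      has_h <- any(el[adj[[i]]] == "H")
      heavy_deg <- sum(el[adj[[i]]] != "H")
      if (!amide && !has_h && heavy_deg < 4L) acceptors <- c(acceptors, i)
    }
  }
  acceptors <- data.frame(atom = acceptors,
                          label = sprintf("A%d", seq_along(acceptors)))
  list(donors = donors, acceptors = acceptors)
}

# pairwise bond-graph separation between donor heavies and acceptors
pair_separation <- function(top, donors, acceptors) {
  sep <- matrix(Inf, nrow(donors), nrow(acceptors))
  for (d in seq_len(nrow(donors))) {
    dist <- bond_graph_distances(top, donors$heavy[d])
    sep[d, ] <- dist[acceptors$atom]
  }
  sep
}

#' Detect hydrogen bonds in a single frame
#'
#' Applies [hbond_criteria()] to one coordinate frame. The angle is
#' measured at the hydrogen between the H->donor and H->acceptor vectors
#' (180 degrees = linear bond).
#'
#' @param coords `atoms x 3` coordinate matrix, Angstrom.
#' @param donors,acceptors output of [find_donors_acceptors()].
#' @param criteria an [hbond_criteria()] object.
#' @param top the [topology()] (for bond-graph separations).
#' @return Logical matrix `donors x acceptors` of contacts.
#' @export
detect_frame <- function(coords, donors, acceptors, criteria, top) {
  nd <- nrow(donors); na <- nrow(acceptors)
  out <- matrix(FALSE, nd, na,
                dimnames = list(donors$label, acceptors$label))
  if (!nd || !na) return(out)
  sep <- attr(donors, "separation")
  if (is.null(sep)) sep <- pair_separation(top, donors, acceptors)
  angle_tol <- 1e-9  # degrees; keeps the >= comparison inclusive under
                     # floating-point rounding at the exact boundary
  for (d in seq_len(nd)) {
    dh <- donors$heavy[d]; hy <- donors$hydrogen[d]
    for (a in seq_len(na)) {
      ac <- acceptors$atom[a]
      if (ac == dh || sep[d, a] < criteria$min_separation) next
      ref <- if (criteria$distance_from == "heavy") dh else hy
      dist <- vnorm(coords[ac, ] - coords[ref, ])
      if (dist > criteria$d_max) next
      v1 <- coords[dh, ] - coords[hy, ]
      v2 <- coords[ac, ] - coords[hy, ]
      cosang <- sum(v1 * v2) / (vnorm(v1) * vnorm(v2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang >= criteria$angle_min - angle_tol) out[d, a] <- TRUE
    }
  }
  out
}

#' Reweighted hydrogen-bond contact map
#'
#' Occupancy of each donor-acceptor pair is the weighted fraction of
#' frames in which the contact is present:
#' `occ(d, a) = sum_f w_f * 1[contact in frame f]`.
#'
#' @param traj a [trajectory()] object.
#' @param weights per-frame weights (normalized if not already).
#' @param criteria an [hbond_criteria()] object.
#' @param donors,acceptors optional [find_donors_acceptors()] output
#'   (computed from the trajectory's topology when omitted).
#' @return An object of class `contact_map`: list with `occupancy`
#'   (donors x acceptors matrix in `[0, 1]`), `donors`, `acceptors`.
#' @export
contact_occupancy <- function(traj, weights, criteria = hbond_criteria(),
                              donors = NULL, acceptors = NULL) {
  top <- traj$topology
  if (is.null(donors) || is.null(acceptors)) {
    da <- find_donors_acceptors(top)
    donors <- da$donors; acceptors <- da$acceptors
  }
  weights <- check_weights(weights, n_frames(traj))
  attr(donors, "separation") <- pair_separation(top, donors, acceptors)
  occ <- matrix(0, nrow(donors), nrow(acceptors),
                dimnames = list(donors$label, acceptors$label))
  for (f in seq_len(n_frames(traj))) {
    hit <- detect_frame(frame_coords(traj, f), donors, acceptors, criteria, top)
    occ <- occ + weights[f] * hit
  }
  structure(list(occupancy = occ, donors = donors, acceptors = acceptors,
                 criteria = criteria),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("contact_map: %d donors x %d acceptors, total occupancy %.3f\n",
              nrow(x$occupancy), ncol(x$occupancy), sum(x$occupancy)))
  print(round(x$occupancy, 3))
  invisible(x)
}

#' @describeIn contact_occupancy heat-map plot of the occupancy matrix.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.contact_map <- function(x, ...) {
  occ <- x$occupancy
  graphics::image(seq_len(ncol(occ)), seq_len(nrow(occ)), t(occ),
                  zlim = c(0, 1), col = grDevices::hcl.colors(64, "Purples 3",
                                                              rev = TRUE),
                  axes = FALSE, xlab = "acceptor", ylab = "donor", ...)
  graphics::axis(1, seq_len(ncol(occ)), colnames(occ))
  graphics::axis(2, seq_len(nrow(occ)), rownames(occ))
  invisible(x)
}

#' Per-donor contribution to total hydrogen bonding
#'
#' Each donor's share of the summed occupancy, in percent. Shares sum to
#' 100 whenever any IMHB exists; for an all-zero map all shares are `NA`.
#'
#' @param map a [contact_occupancy()] contact map.
#' @return Named numeric vector of percentages (class
#'   `donor_contribution`).
#' @export
donor_contributions <- function(map) {
  rowsum <- rowSums(map$occupancy)
  tot <- sum(rowsum)
  share <- if (tot > 0) 100 * rowsum / tot else rep(NA_real_, length(rowsum))
  names(share) <- rownames(map$occupancy)
  structure(share, class = "donor_contribution")
}

#' @export
print.donor_contribution <- function(x, ...) {
  cat("donor contributions (% of total IMHB occupancy):\n")
  print(round(unclass(x), 1))
  invisible(x)
}

#' Polar-vs-apolar contact-map comparison
#'
#' Differences (apolar minus polar) of per-pair occupancies and per-donor
#' sums, with each donor-acceptor pair classified as short-range (donor
#' and acceptor residues adjacent around the macrocycle ring: cyclic
#' sequence separation <= 1) or long-range.
#'
#' @param map_polar,map_apolar [contact_occupancy()] maps with identical
#'   donor/acceptor orderings.
#' @param top the shared [topology()] (for residue assignments).
#' @param n_residues number of residues around the ring; defaults to the
#'   number of distinct residue ids in `top`.
#' @return List with `difference` (matrix), `donor_difference`, `range_class`
#'   (character matrix `"short"`/`"long"`), and summed differences per class.
#' @export
compare_phases <- function(map_polar, map_apolar, top, n_residues = NULL) {
  if (!identical(dimnames(map_polar$occupancy), dimnames(map_apolar$occupancy)))
    stopf("contact maps have mismatched donor/acceptor labels")
  diff <- map_apolar$occupancy - map_polar$occupancy
  res <- top$atoms$residue_id
  if (is.null(n_residues)) n_residues <- length(unique(res))
  d_res <- res[map_polar$donors$heavy]
  a_res <- res[map_polar$acceptors$atom]
  sep <- outer(d_res, a_res, function(a, b) {
    s <- abs(a - b) %% n_residues
    pmin(s, n_residues - s)  # minimum of the two ring directions
  })
  range_class <- ifelse(sep <= 1, "short", "long")
  dimnames(range_class) <- dimnames(diff)
  list(difference = diff,
       donor_difference = rowSums(diff),
       range_class = range_class,
       short_range_total = sum(diff[range_class == "short"]),
       long_range_total = sum(diff[range_class == "long"]))
}
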