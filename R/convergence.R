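#' Pairwise 2D-RMSD matrix
#'
#' Optimal-superposition (Kabsch) RMSD between every pair of sampled
#' frames, by default on heavy atoms only with frames sampled every
#' `stride` nanoseconds.
#'
#' @param traj a [trajectory()] object.
#' @param stride sampling interval, ns; must be a positive multiple of
#'   the trajectory's `frame_interval` (default: the frame interval, but
#'   at least 1 ns when the trajectory resolves finer).
#' @param selection `"heavy"` (default: hydrogens excluded), `"all"`, or
#'   an integer vector of atom indices.
#' @return An object of class `rmsd_matrix`: list with `values` (n x n,
#'   Angstrom), `frames` (sampled frame indices) and `stride`.
#' @export
pairwise_rmsd <- function(traj, stride = NULL, selection = "heavy") {
  fi <- traj$frame_interval
  if (is.null(stride)) stride <- max(fi, 1)
  step <- stride / fi
  if (step <= 0 || abs(step - round(step)) > 1e-9)
    stopf("stride (%g ns) must be a positive multiple of the frame interval (%g ns)",
          stride, fi)
  idx <- seq(1L, n_frames(traj), by = as.integer(round(step)))
  if (length(idx) < 2L) stopf("fewer than 2 sampled frames at stride %g ns", stride)
  sel <- if (identical(selection, "heavy")) {
    which(traj$topology$atoms$element != "H")
  } else if (identical(selection, "all")) {
    seq_len(n_atoms(traj$topology))
  } else as.integer(selection)
  n <- length(idx)
  vals <- matrix(0, n, n)
  xyz <- lapply(idx, function(f) as.vector(t(traj$coords[f, sel, ])))
  ii <- seq_along(xyz[[1]])
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    # Kabsch superposition via bio3d; RMSD computed unrounded
    fitted <- bio3d::fit.xyz(xyz[[i]], xyz[[j]], ii, ii)
    r <- sqrt(mean((fitted - xyz[[i]])^2) * 3)
    vals[i, j] <- r; vals[j, i] <- r
  }
  structure(list(values = vals, frames = idx, stride = stride),
            class = "rmsd_matrix")
}

#' @export
print.rmsd_matrix <- function(x, ...) {
  cat(sprintf("rmsd_matrix: %d x %d frames (stride %g ns), max %.2f A\n",
              nrow(x$values), ncol(x$values), x$stride, max(x$values)))
  invisible(x)
}

#' @describeIn pairwise_rmsd image plot of the matrix.
#' @param x,... an `rmsd_matrix` and arguments passed to
#'   [graphics::image()].
#' @export
plot.rmsd_matrix <- function(x, ...) {
  t_ns <- (x$frames - 1) * x$stride
  graphics::image(t_ns, t_ns, x$values,
                  col = grDevices::hcl.colors(64, "Viridis"),
                  xlab = "time (ns)", ylab = "time (ns)", ...)
  invisible(x)
}

# weighted 2D histogram normalized to sum 1 over in-range bins
hist2d_prob <- function(x, y, w, x_edges, y_edges) {
  ix <- bin_index(x, x_edges)
  iy <- bin_index(y, y_edges)
  p <- matrix(0, length(x_edges) - 1L, length(y_edges) - 1L)
  ok <- ix > 0L & iy > 0L
  if (any(!ok))
    warnf("%d frame(s) fall outside the shared histogram grid", sum(!ok))
  for (k in which(ok)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + w[k]
  if (sum(p) > 0) p / sum(p) else p
}

#' Jensen-Shannon divergence between two discrete distributions
#'
#' Base-2 logarithm, so the result is in bits and bounded by `[0, 1]`.
#' Zero bins contribute nothing (0 log 0 = 0).
#'
#' @param p,q non-negative arrays of equal shape; normalized internally.
#' @return JSD in bits.
#' @export
js_divergence <- function(p, q) {
  p <- as.vector(p); q <- as.vector(q)
  if (length(p) != length(q)) stopf("distributions differ in length")
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Split-half convergence report
#'
#' Cuts the trajectory at its midpoint (an odd frame count gives the
#' first half the extra frame), renormalizes each half's weights, and
#' compares the halves' reweighted hydrogen-bond contact maps and PC-plane
#' densities on shared axes: the PCA is fitted once on the full
#' trajectory and both halves are projected onto it, and both halves use
#' the same histogram grid.
#'
#' @param traj a [trajectory()] object.
#' @param weights per-frame weights for the full trajectory.
#' @param torsions a [torsion_set()] (used to compute angles when
#'   `angles` is not supplied).
#' @param angles optional precomputed `frames x torsions` angle matrix.
#' @param criteria an [hbond_criteria()] object.
#' @param pca optional prefitted [fit_pca()] model on the circular
#'   encoding; fitted on the full trajectory when omitted.
#' @param nbins number of bins per PC axis.
#' @return An object of class `convergence_report`: `contact_divergence`
#'   (max absolute occupancy difference), `density_divergence` (JSD,
#'   bits), `n_first`, `n_second`, `odd_split`.
#' @export
split_half_report <- function(traj, weights, torsions = NULL, angles = NULL,
                              criteria = hbond_criteria(), pca = NULL,
                              nbins = 40) {
  nf <- n_frames(traj)
  if (nf < 2L) stopf("need at least 2 frames to split")
  weights <- check_weights(weights, nf)
  if (is.null(angles)) {
    if (is.null(torsions)) stopf("supply either torsions or angles")
    angles <- compute_dihedrals(traj, torsions)
  }
  if (nrow(angles) != nf) stopf("angle matrix does not match frame count")
  feats <- encode_circular(angles)
  if (is.null(pca)) pca <- fit_pca(feats)
  pc <- project_pca(feats, pca, n = 2)
  x_edges <- seq(min(pc[, 1]), max(pc[, 1]), length.out = nbins + 1L)
  y_edges <- seq(min(pc[, 2]), max(pc[, 2]), length.out = nbins + 1L)

  cut <- ceiling(nf / 2)
  first <- seq_len(cut); second <- seq.int(cut + 1L, nf)
  halves <- lapply(list(first, second), function(idx) {
    w <- weights[idx] / sum(weights[idx])
    sub <- trajectory(traj$coords[idx, , , drop = FALSE], traj$topology,
                      traj$frame_interval)
    list(map = contact_occupancy(sub, w, criteria),
         dens = hist2d_prob(pc[idx, 1], pc[idx, 2], w, x_edges, y_edges))
  })
  structure(list(
    contact_divergence = max(abs(halves[[1]]$map$occupancy -
                                 halves[[2]]$map$occupancy)),
    density_divergence = js_divergence(halves[[1]]$dens, halves[[2]]$dens),
    n_first = length(first), n_second = length(second),
    odd_split = nf %% 2L == 1L,
    half_maps = list(halves[[1]]$map, halves[[2]]$map)),
    class = "convergence_report")
}

#' @export
print.convergence_report <- function(x, ...) {
  cat("split-half convergence report\n")
  cat(sprintf("  frames: %d + %d%s\n", x$n_first, x$n_second,
              if (x$odd_split) " (odd count; first half has the extra frame)" else ""))
  cat(sprintf("  contact divergence: %.4f (max |occupancy difference|)\n",
              x$contact_divergence))
  cat(sprintf("  density divergence: %.4f bits (Jensen-Shannon)\n",
              x$density_divergence))
  invisible(x)
}

#' Cross-run overlap of reweighted PC densities
#'
#' Histogram intersection `sum_bins min(p_a, p_b)` of two reweighted
#' densities on a shared grid: 1 for identical densities, 0 for disjoint
#' supports. Both runs must be projected on the same PCA axes.
#'
#' @param coords_a,coords_b `frames x 2` PC coordinates of the two runs.
#' @param weights_a,weights_b per-frame weights.
#' @param x_edges,y_edges shared histogram grid.
#' @param pass_threshold reproducibility pass mark (default 0.7).
#' @return List with `overlap` in `[0, 1]` and logical `pass`.
#' @export
run_overlap <- function(coords_a, weights_a, coords_b, weights_b,
                        x_edges, y_edges, pass_threshold = 0.7) {
  coords_a <- as.matrix(coords_a); coords_b <- as.matrix(coords_b)
  if (ncol(coords_a) != 2L || ncol(coords_b) != 2L)
    stopf("run coordinates must have 2 columns")
  wa <- check_weights(weights_a, nrow(coords_a))
  wb <- check_weights(weights_b, nrow(coords_b))
  pa <- hist2d_prob(coords_a[, 1], coords_a[, 2], wa, x_edges, y_edges)
  pb <- hist2d_prob(coords_b[, 1], coords_b[, 2], wb, x_edges, y_edges)
  ov <- sum(pmin(pa, pb))
  list(overlap = ov, pass = ov >= pass_threshold)
}
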