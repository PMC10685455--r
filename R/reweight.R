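#' Reweighting parameters
#'
#' Controls how boost energies become statistical weights. The raw
#' reweighting factor for a frame with boost dV is `exp(beta * dV)` with
#' `beta = 1/(kB * T)`; in `"maclaurin"` mode the exponential is replaced
#' by its Maclaurin series truncated at `order`, which trades a small
#' systematic bias for a large reduction in weight variance.
#'
#' @param temperature simulation temperature, K (default 300).
#' @param order Maclaurin truncation order (default 20).
#' @param mode `"maclaurin"` or `"exponential"`.
#' @param component which boost enters the reweighting: `"both"` (sum of
#'   dihedral and total boosts, the dual-boost default), `"total"`, or
#'   `"dihedral"`.
#' @return An object of class `weight_params`.
#' @export
weight_params <- function(temperature = 300, order = 20,
                          mode = c("maclaurin", "exponential"),
                          component = c("both", "total", "dihedral")) {
  mode <- match.arg(mode)
  component <- match.arg(component)
  if (temperature <= 0) stopf("temperature must be > 0 K")
  order <- as.integer(order)
  if (order < 0) stopf("order must be >= 0")
  structure(list(temperature = temperature, order = order, mode = mode,
                 component = component),
            class = "weight_params")
}

total_boost <- function(dv, component) {
  switch(component,
         both = dv$dv_dihedral + dv$dv_total,
         total = dv$dv_total,
         dihedral = dv$dv_dihedral)
}

# Maclaurin partial sum of exp(x), term-recursive
maclaurin_exp <- function(x, order) {
  term <- rep(1, length(x))
  acc <- term
  for (n in seq_len(order)) {
    term <- term * x / n
    acc <- acc + term
  }
  acc
}

#' Per-frame statistical weights from boost energies
#'
#' Converts a [boost_series()] into normalized per-frame weights. In
#' exponential mode the raw weight is `exp(beta * dV)` (computed with the
#' maximum subtracted for overflow safety, which cancels on
#' normalization); in Maclaurin mode it is the order-`order` partial sum
#' of the exponential series. Weights are normalized to sum to 1.
#'
#' @param dv a [boost_series()] object.
#' @param params a [weight_params()] object.
#' @return Numeric vector of class `weight_vector`: non-negative weights
#'   summing to 1.
#' @export
compute_weights <- function(dv, params = weight_params()) {
  x <- total_boost(dv, params$component) / (KB_KCAL * params$temperature)
  if (any(!is.finite(x))) stopf("non-finite boost energy")
  raw <- if (params$mode == "exponential") {
    exp(x - max(x))
  } else {
    if (params$order == 0L)
      warnf("Maclaurin order 0: all raw weights are 1 (no reweighting)")
    maclaurin_exp(x, params$order)
  }
  w <- raw / sum(raw)
  structure(w, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  ess <- 1 / sum(unclass(x)^2)
  cat(sprintf("weight_vector: %d frames, effective sample size %.1f (%.1f%%)\n",
              length(x), ess, 100 * ess / length(x)))
  invisible(x)
}

#' Uniform weights
#' @param n number of frames.
#' @export
uniform_weights <- function(n) structure(rep(1 / n, n), class = "weight_vector")

check_weights <- function(weights, n) {
  weights <- as.numeric(weights)
  if (length(weights) != n)
    stopf("weights length (%d) does not match frame count (%d)",
          length(weights), n)
  if (any(weights < 0)) stopf("weights must be >= 0")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) weights <- weights / s
  weights
}

#' Reweighted histogram
#'
#' Per-bin probability is the summed weight of the frames falling in the
#' bin. Bins are half-open `[lo, hi)` with the last bin closed. Values
#' outside the edge range are accumulated into an `overflow` attribute
#' and reported with a warning.
#'
#' @param values per-frame scalars.
#' @param weights per-frame weights (normalized if not already).
#' @param edges increasing bin boundaries.
#' @return Numeric vector of bin probabilities with attribute `overflow`.
#' @export
reweighted_histogram <- function(values, weights, edges) {
  if (length(values) != length(weights))
    stopf("values and weights differ in length")
  weights <- check_weights(weights, length(values))
  idx <- bin_index(values, edges)
  nb <- length(edges) - 1L
  p <- numeric(nb)
  inside <- idx > 0L
  if (any(!inside)) {
    warnf("%d value(s) outside histogram range (weight %.3g) counted as overflow",
          sum(!inside), sum(weights[!inside]))
  }
  for (b in seq_len(nb)) p[b] <- sum(weights[inside & idx == b])
  attr(p, "overflow") <- sum(weights[!inside])
  p
}

#' Reweighted 2D free-energy surface
#'
#' Bins two per-frame coordinates on a grid, accumulates reweighted bin
#' probabilities, and converts them to free energies
#' `F = -kB T log(p / p_max)`, so the most probable bin sits at exactly
#' 0 kcal/mol. Bins with zero probability are *unoccupied*: their free
#' energy is `NA` and they are flagged, not assigned an arbitrary cap.
#'
#' @param x,y per-frame scalars (e.g. the first two PC coordinates).
#' @param weights per-frame weights.
#' @param x_edges,y_edges increasing bin boundaries.
#' @param temperature temperature, K, setting the kB*T energy scale.
#' @return An object of class `fes2d` with elements `x_edges`, `y_edges`,
#'   `probability` (matrix, sums to 1 over occupied bins plus overflow),
#'   `free_energy` (kcal/mol, `NA` where unoccupied) and `occupied`
#'   (logical matrix).
#' @export
free_energy_surface <- function(x, y, weights, x_edges, y_edges,
                                temperature = 300) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  weights <- check_weights(weights, length(x))
  ix <- bin_index(x, x_edges)
  iy <- bin_index(y, y_edges)
  nx <- length(x_edges) - 1L
  ny <- length(y_edges) - 1L
  p <- matrix(0, nx, ny)
  inside <- ix > 0L & iy > 0L
  if (any(!inside))
    warnf("%d frame(s) outside the FES grid ignored (weight %.3g)",
          sum(!inside), sum(weights[!inside]))
  for (k in which(inside)) p[ix[k], iy[k]] <- p[ix[k], iy[k]] + weights[k]
  occupied <- p > 0
  if (sum(occupied) <= 1L)
    warnf("degenerate free-energy surface: all frames in one bin")
  fe <- matrix(NA_real_, nx, ny)
  fe[occupied] <- -KB_KCAL * temperature * log(p[occupied] / max(p))
  structure(list(x_edges = x_edges, y_edges = y_edges, probability = p,
                 free_energy = fe, occupied = occupied,
                 temperature = temperature),
            class = "fes2d")
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf("fes2d: %d x %d grid, %d occupied bins, max F = %.3f kcal/mol (T = %g K)\n",
              nrow(x$probability), ncol(x$probability), sum(x$occupied),
              max(x$free_energy, na.rm = TRUE), x$temperature))
  invisible(x)
}

#' @describeIn free_energy_surface image plot of the surface; unoccupied
#'   bins are left white.
#' @param ... further arguments to [graphics::image()].
#' @export
plot.fes2d <- function(x, ...) {
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  graphics::image(mids(x$x_edges), mids(x$y_edges), x$free_energy,
                  col = grDevices::hcl.colors(64, "Blues 3"),
                  xlab = "PC1", ylab = "PC2", ...)
  invisible(x)
}
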