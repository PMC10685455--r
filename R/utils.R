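stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

# Run code with a temporary RNG seed, restoring global RNG state on exit.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Single-linkage covalent radii (Angstrom) for distance-based bond inference.
COVALENT_RADII <- c(
  H = 0.37, C = 0.77, N = 0.75, O = 0.73, F = 0.71, P = 1.06, S = 1.02,
  Cl = 0.99, Br = 1.14, I = 1.33
)

covalent_radius <- function(element) {
  r <- COVALENT_RADII[element]
  r[is.na(r)] <- 0.77  # unknown elements treated as carbon-like
  unname(r)
}

vnorm <- function(v) sqrt(sum(v * v))

# Half-open binning [lo, hi) with the last bin closed; 0 marks out-of-range.
bin_index <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx >= length(edges)] <- 0L  # beyond the last edge (rightmost.closed
                                   # already put x == max edge in last bin)
  idx
}
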