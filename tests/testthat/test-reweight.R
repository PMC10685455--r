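kbt300 <- KB_KCAL * 300

test_that("zero boost gives uniform weights in every mode", {
  dv <- boost_series(rep(0, 7), rep(0, 7))
  for (mode in c("exponential", "maclaurin")) {
    w <- compute_weights(dv, weight_params(mode = mode))
    expect_equal(as.numeric(w), rep(1 / 7, 7))
  }
})

test_that("order-20 Maclaurin reproduces e at beta*dV = 1 to machine precision", {
  # direct factorial-sum oracle
  oracle <- sum(1 / factorial(0:20))
  got <- macrorew:::maclaurin_exp(1, 20)
  expect_equal(got, oracle, tolerance = 1e-15)
  expect_lt(abs(got - exp(1)) / exp(1), 1e-15)
})

test_that("exponential weights follow the closed form for two frames", {
  dv <- boost_series(c(0, 0), kbt300 * c(0, log(2)))
  w <- compute_weights(dv, weight_params(mode = "exponential"))
  expect_equal(as.numeric(w), c(1 / 3, 2 / 3), tolerance = 1e-12)
})

test_that("dihedral and total boosts are summed by default, selectable alone", {
  dv <- boost_series(dv_dihedral = kbt300 * c(1, 0),
                     dv_total = kbt300 * c(0, 1))
  both <- compute_weights(dv, weight_params(mode = "exponential"))
  expect_equal(as.numeric(both), c(0.5, 0.5))
  dih <- compute_weights(dv, weight_params(mode = "exponential",
                                           component = "dihedral"))
  expect_equal(as.numeric(dih), c(exp(1), 1) / (exp(1) + 1), tolerance = 1e-12)
})

test_that("Maclaurin weights converge to exponential from below", {
  set.seed(5)
  x <- runif(20, 0, 6)  # beta*dV values
  dv <- boost_series(rep(0, 20), x * kbt300)
  prev <- rep(0, 20)
  for (ord in c(0, 2, 5, 10, 20, 30)) {
    raw <- macrorew:::maclaurin_exp(x, ord)
    expect_true(all(raw >= prev))                    # monotone in order
    expect_true(all(raw <= exp(x) * (1 + 1e-12)))    # from below for x > 0
    prev <- raw
  }
  # truncation error of the order-20 series is tiny for moderate boosts
  # and grows steeply with beta*dV (about 1.6e-3 at beta*dV = 10)
  rel_err <- function(x) (exp(x) - macrorew:::maclaurin_exp(x, 20)) / exp(x)
  expect_lt(rel_err(8), 1e-4)
  expect_gt(rel_err(10), 1e-3)
  expect_lt(rel_err(10), 2e-3)
})

test_that("compute_weights is permutation-equivariant", {
  set.seed(6)
  dv <- boost_series(runif(15), runif(15))
  perm <- sample(15)
  w <- compute_weights(dv, weight_params())
  wp <- compute_weights(boost_series(dv$dv_dihedral[perm], dv$dv_total[perm]),
                        weight_params())
  expect_equal(as.numeric(wp), as.numeric(w)[perm], tolerance = 1e-14)
})

test_that("order 0 warns and non-finite boosts error", {
  dv <- boost_series(c(0, 1), c(1, 0))
  expect_warning(compute_weights(dv, weight_params(order = 0)), "order 0")
  expect_error(boost_series(c(0, NaN), c(0, 0)), "finite")
})

test_that("reweighted histograms allocate weight by bin", {
  p <- reweighted_histogram(c(0.5, 1.5), uniform_weights(2), edges = 0:2)
  expect_equal(as.numeric(p), c(0.5, 0.5))
  p2 <- reweighted_histogram(c(0.5, 1.5), c(0.9, 0.1), edges = 0:2)
  expect_equal(as.numeric(p2), c(0.9, 0.1))
  # half-open bins, last closed
  p3 <- reweighted_histogram(c(1, 2), uniform_weights(2), edges = 0:2)
  expect_equal(as.numeric(p3), c(0, 1))
  expect_warning(
    p4 <- reweighted_histogram(c(0.5, 9), uniform_weights(2), edges = 0:2),
    "overflow")
  expect_equal(attr(p4, "overflow"), 0.5)
})

test_that("exponential reweighting recovers the unbiased density", {
  # boosted harmonic-well samples, exact exponential weights: the
  # reweighted histogram must match the analytic Boltzmann density
  s <- sample_boosted_potential(list(kind = "harmonic", k = 1),
                                harmonic_boost_params(), 300,
                                n_steps = 1e4, seed = 9)
  w <- compute_weights(s$boost, weight_params(mode = "exponential"))
  edges <- seq(-4, 4, length.out = 41)
  p <- suppressWarnings(reweighted_histogram(s$samples, w, edges))
  sd_an <- sqrt(kbt300)
  target <- diff(pnorm(edges, 0, sd_an))
  tv <- sum(abs(p / sum(p) - target / sum(target))) / 2
  expect_lt(tv, 0.03)
})

test_that("free-energy surfaces satisfy the two-bin closed form", {
  # two occupied bins with probability ratio e at 300 K
  x <- c(0.5, 1.5); y <- c(0.5, 0.5)
  w <- c(exp(1), 1) / (exp(1) + 1)
  fes <- free_energy_surface(x, y, w, x_edges = 0:2, y_edges = 0:1,
                             temperature = 300)
  dF <- fes$free_energy[2, 1] - fes$free_energy[1, 1]
  expect_equal(fes$free_energy[1, 1], 0)
  expect_equal(dF, KB_KCAL * 300, tolerance = 1e-6)
})

test_that("degenerate and unoccupied bins are flagged, not capped", {
  expect_warning(
    fes <- free_energy_surface(rep(0.5, 4), rep(0.5, 4), uniform_weights(4),
                               x_edges = 0:2, y_edges = 0:2),
    "degenerate")
  expect_equal(fes$free_energy[1, 1], 0)
  expect_equal(sum(fes$occupied), 1)
  expect_true(all(is.na(fes$free_energy[!fes$occupied])))
  expect_equal(sum(fes$probability), 1)
})

test_that("a sampled 2D harmonic density yields a quadratic surface", {
  set.seed(10)
  n <- 4e5
  sd_an <- sqrt(kbt300)  # k = 1 kcal/mol/A^2 at 300 K
  x <- rnorm(n, sd = sd_an); y <- rnorm(n, sd = sd_an)
  lim <- 2.5 * sd_an
  fes <- suppressWarnings(
    free_energy_surface(x, y, uniform_weights(n),
                        x_edges = seq(-lim, lim, length.out = 21),
                        y_edges = seq(-lim, lim, length.out = 21)))
  mids <- function(e) (e[-1] + e[-length(e)]) / 2
  grid <- expand.grid(x = mids(fes$x_edges), y = mids(fes$y_edges))
  r2 <- 0.5 * (grid$x^2 + grid$y^2)  # analytic F up to a constant
  f <- as.vector(fes$free_energy)
  # compare where the density estimate is well sampled (>= 25 counts)
  keep <- !is.na(f) & as.vector(fes$probability) >= 25 / n
  fit <- lm(f[keep] ~ r2[keep])
  expect_gt(summary(fit)$r.squared, 0.99)
})

test_that("probabilities sum to one and the FES minimum is exactly zero", {
  set.seed(12)
  for (rep in 1:5) {
    x <- runif(200); y <- runif(200)
    w <- runif(200); w <- w / sum(w)
    fes <- free_energy_surface(x, y, w, x_edges = seq(0, 1, 0.25),
                               y_edges = seq(0, 1, 0.25))
    expect_equal(sum(fes$probability), 1, tolerance = 1e-12)
    expect_identical(min(fes$free_energy, na.rm = TRUE), 0)
  }
})

test_that("the DMSO potential-boost threshold scales as 0.56 per atom", {
  p <- dual_boost_params(avg_dihedral_energy = 50, avg_total_potential = -1000,
                         n_free_backbone_dihedrals = 5, n_atoms = 100,
                         solvent_class = "dmso")
  expect_equal(p$e_tot, -944.0)
  # linearity in atom count
  p2 <- dual_boost_params(50, -1000, 5, 200, "dmso")
  expect_equal(p2$e_tot - (-1000), 2 * (p$e_tot - (-1000)))
  # no movable dihedrals: zero dihedral boost window
  p0 <- dual_boost_params(50, -1000, 0, 100, "dmso")
  expect_equal(p0$e_dih, 50)
  expect_error(dual_boost_params(50, -1000, -1, 100), ">= 0")
})

test_that("the boost functional is zero above threshold and continuous below", {
  expect_equal(boost_energy(5, e = 5, alpha = 1), 0)
  expect_equal(boost_energy(4, e = 5, alpha = 1), 0.5)
  # numeric scan: continuous, non-negative, non-increasing in v
  v <- seq(-3, 7, by = 0.01)
  dv <- boost_energy(v, e = 5, alpha = 2)
  expect_true(all(dv >= 0))
  expect_true(all(diff(dv) <= 1e-12))
  expect_lt(max(abs(diff(dv))), 0.02)  # no jumps on a 0.01 grid
  expect_error(boost_energy(1, 2, alpha = 0), "alpha")
})

test_that("boosted Metropolis plus exact reweighting recovers the thermal variance", {
  s <- sample_boosted_potential(list(kind = "harmonic", k = 1),
                                harmonic_boost_params(), 300,
                                n_steps = 1e5, seed = 42)
  w <- compute_weights(s$boost, weight_params(mode = "exponential"))
  v <- sum(w * s$samples^2) - sum(w * s$samples)^2
  expect_lt(abs(v - kbt300) / kbt300, 0.05)
})
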