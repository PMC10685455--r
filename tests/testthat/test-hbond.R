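test_that("amide donors and acceptors are found in an NMA-like molecule", {
  top <- nma_topology()
  da <- find_donors_acceptors(top)
  expect_equal(nrow(da$donors), 1)          # the amide N-H
  expect_equal(top$atoms$name[da$donors$heavy], "N")
  expect_equal(top$atoms$name[da$donors$hydrogen], "H")
  expect_equal(nrow(da$acceptors), 1)       # the carbonyl O
  expect_equal(top$atoms$name[da$acceptors$atom], "O")
})

test_that("N-methylation removes the donor but keeps the acceptor", {
  top <- nma_topology()
  # replace the amide H with a methyl carbon: no N-H left
  top$atoms$element[8] <- "C"
  top$atoms$name[8] <- "CM"
  da <- find_donors_acceptors(top)
  expect_equal(nrow(da$donors), 0)
  expect_equal(nrow(da$acceptors), 1)
})

test_that("topologies without explicit hydrogens are rejected", {
  atoms <- data.frame(name = c("N", "C", "O"), element = c("N", "C", "O"),
                      residue_id = 1L, residue_name = "X")
  top <- topology(atoms, rbind(c(1, 2), c(2, 3)))
  expect_error(find_donors_acceptors(top), "hydrogens")
})

# hand-built N-H...O=C geometry: donor triad plus a distant carbonyl,
# bonded as one chain so graph separation is controllable
hb_probe <- function(no_dist, angle) {
  # atoms: N(1) H(2) C(3) C(4) C(5)=O(6); N...O separation via 4 bonds
  atoms <- data.frame(name = c("N", "H", "CA", "CB", "C", "O"),
                      element = c("N", "H", "C", "C", "C", "O"),
                      residue_id = 1L, residue_name = "X")
  top <- topology(atoms, rbind(c(1, 2), c(1, 3), c(3, 4), c(4, 5), c(5, 6)))
  n <- c(0, 0, 0); h <- c(1.01, 0, 0)
  # place O so that the angle at H between H->N and H->O equals `angle`
  th <- angle * pi / 180
  v <- c(cos(th) * (-1), sin(th), 0)  # H->N direction is (-1, 0, 0)
  # solve for t with |O - N| = no_dist
  ca <- cos(th)
  t <- 1.01 * ca + sqrt(1.01^2 * ca^2 - 1.01^2 + no_dist^2)
  o <- h + t * v
  coords <- rbind(n, h, c(-1.2, 0.5, 0), c(-1.2, 1.9, 0), o + c(0, 1.23, 0), o)
  list(top = top, coords = coords)
}

test_that("distance and angle cutoffs are inclusive at the boundary", {
  crit <- hbond_criteria()  # 3.5 A, 90 deg, >= 3 bonds
  run <- function(no_dist, angle) {
    p <- hb_probe(no_dist, angle)
    da <- find_donors_acceptors(p$top)
    sum(detect_frame(p$coords, da$donors, da$acceptors, crit, p$top))
  }
  expect_equal(run(2.9, 180), 1)   # ideal linear geometry
  expect_equal(run(3.6, 180), 0)   # beyond 3.5 A
  expect_equal(run(3.5, 180), 1)   # inclusive distance boundary
  expect_equal(run(2.9, 90), 1)    # inclusive angle boundary
  expect_equal(run(2.9, 89.9), 0)  # just below the angle cutoff
})

test_that("bond-graph separation suppresses adjacent polar atoms", {
  p <- hb_probe(2.9, 180)
  da <- find_donors_acceptors(p$top)
  strict <- hbond_criteria(min_separation = 5)  # N..O path is 4 bonds
  expect_equal(sum(detect_frame(p$coords, da$donors, da$acceptors,
                                strict, p$top)), 0)
})

test_that("frame detection equals the brute-force triple loop", {
  mol <- toy_macrocycle(3, 2)
  da <- find_donors_acceptors(mol$topology)
  crit <- hbond_criteria()
  set.seed(51)
  for (f in 1:100) {
    coords <- mol$coords + matrix(rnorm(length(mol$coords), sd = 1.2),
                                  ncol = 3)
    got <- detect_frame(coords, da$donors, da$acceptors, crit, mol$topology)
    want <- oracle_detect(coords, da$donors, da$acceptors, crit, mol$topology)
    expect_identical(got, want)
  }
})

test_that("occupancy is the weighted fraction of contact frames", {
  mol <- toy_macrocycle(3, 2)
  plan <- data.frame(donor = 1L, acceptor = 2L, target = 1.0)
  traj <- plant_hbond_trajectory(mol, plan, n_frames = 8, seed = 1)
  occ <- contact_occupancy(traj, uniform_weights(8))
  expect_equal(unname(occ$occupancy[1, 2]), 1.0)

  plan$target <- 0.5
  traj2 <- plant_hbond_trajectory(mol, plan, n_frames = 8, seed = 1)
  occ2 <- contact_occupancy(traj2, uniform_weights(8))
  expect_equal(unname(occ2$occupancy[1, 2]), 0.5)
  rest <- occ2$occupancy; rest[1, 2] <- 0
  expect_true(all(rest == 0))
})

test_that("planted occupancy under nonuniform weights is recovered exactly", {
  mol <- toy_macrocycle(3, 2)
  w <- weights_for_037()
  plan <- data.frame(donor = 1L, acceptor = 2L, target = 0.37)
  traj <- plant_hbond_trajectory(mol, plan, weights = w, n_frames = 100,
                                 seed = 3)
  achieved <- attr(traj, "achieved")
  occ <- contact_occupancy(traj, w)
  expect_identical(unname(occ$occupancy[1, 2]), unname(achieved[[1]]))
  expect_equal(unname(achieved[[1]]), 0.37, tolerance = 1e-12)
})

test_that("occupancy is invariant under rigid-body motion of every frame", {
  mol <- toy_macrocycle(3, 2)
  plan <- data.frame(donor = 2L, acceptor = 3L, target = 0.5)
  traj <- plant_hbond_trajectory(mol, plan, n_frames = 10, seed = 2)
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  moved <- traj
  for (f in 1:10)
    moved$coords[f, , ] <- traj$coords[f, , ] %*% t(rot) +
      matrix(c(5, -3, 2), n_atoms(mol$topology), 3, byrow = TRUE)
  w <- uniform_weights(10)
  expect_equal(contact_occupancy(moved, w)$occupancy,
               contact_occupancy(traj, w)$occupancy, tolerance = 1e-12)
})

test_that("weight-proportional mixing of split halves reproduces the full map", {
  mol <- toy_macrocycle(3, 2)
  set.seed(52)
  w <- runif(20); w <- w / sum(w)
  plan <- data.frame(donor = 1L, acceptor = 1L, target = 0.4)
  traj <- suppressWarnings(
    plant_hbond_trajectory(mol, plan, weights = w, n_frames = 20, seed = 4))
  full <- contact_occupancy(traj, w)
  halves <- lapply(list(1:10, 11:20), function(idx) {
    sub <- trajectory(traj$coords[idx, , ], mol$topology)
    contact_occupancy(sub, w[idx] / sum(w[idx]))
  })
  mixed <- sum(w[1:10]) * halves[[1]]$occupancy +
    sum(w[11:20]) * halves[[2]]$occupancy
  expect_equal(mixed, full$occupancy, tolerance = 1e-12)
})

test_that("donor contributions are shares of total occupancy", {
  map <- structure(list(occupancy = matrix(c(0.3, 0.1, 0, 0), 2, 2,
                                           dimnames = list(c("D1", "D2"),
                                                           c("A1", "A2")))),
                   class = "contact_map")
  shares <- donor_contributions(map)
  expect_equal(unname(unclass(shares)), c(75, 25))
  expect_equal(sum(shares), 100, tolerance = 1e-9)
  # single nonzero cell takes all of it; empty maps are undefined
  map$occupancy <- matrix(c(0, 0, 0.2, 0), 2, 2)
  expect_equal(unname(unclass(donor_contributions(map)))[1], 100)
  map$occupancy[] <- 0
  expect_true(all(is.na(donor_contributions(map))))
  # random maps match hand summation
  set.seed(53)
  for (rep in 1:5) {
    m <- matrix(runif(12), 3, 4)
    map$occupancy <- m
    expect_equal(unname(unclass(donor_contributions(map))),
                 100 * rowSums(m) / sum(m))
  }
})

test_that("phase comparison subtracts maps and classifies ring distance", {
  mol <- toy_macrocycle(3, 2)
  da <- find_donors_acceptors(mol$topology)
  dn <- list(donors = da$donors, acceptors = da$acceptors)
  mk <- function(m) structure(list(occupancy = m, donors = da$donors,
                                   acceptors = da$acceptors),
                              class = "contact_map")
  set.seed(54)
  a <- matrix(runif(12), 4, 3, dimnames = list(da$donors$label,
                                               da$acceptors$label))
  b <- matrix(runif(12), 4, 3, dimnames = dimnames(a))
  cmp <- compare_phases(mk(a), mk(b), mol$topology)
  expect_equal(cmp$difference, b - a)
  expect_equal(cmp$donor_difference, rowSums(b - a))
  # identical maps: all zero
  cmp0 <- compare_phases(mk(a), mk(a), mol$topology)
  expect_true(all(cmp0$difference == 0))
  # D1 (amine, residue 4 on the 4-residue ring) with A1 (residue 1):
  # adjacent around the ring; D2 (residue 2) with A3 (residue 3 carbonyl
  # pointing to residue 4 side) stays within the ring metric
  res <- mol$topology$atoms$residue_id
  d_res <- res[da$donors$heavy]; a_res <- res[da$acceptors$atom]
  n_res <- length(unique(res))
  for (i in 1:4) for (j in 1:3) {
    s <- abs(d_res[i] - a_res[j]) %% n_res
    s <- min(s, n_res - s)
    expect_equal(cmp$range_class[i, j], if (s <= 1) "short" else "long")
  }
  # label mismatch is structural
  bad <- mk(a); rownames(bad$occupancy)[1] <- "DX"
  expect_error(compare_phases(mk(a), bad, mol$topology), "mismatch")
})
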