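#' Toy macrocycle topology and geometry
#'
#' Builds a simplified semipeptidic macrocycle: `n_residues` amide units
#' (N, H, C-alpha, carbonyl C, carbonyl O) chained head-to-tail, closed
#' through a secondary amine and an alkyl linker of `linker_len` CH2
#' groups. Bond lengths are idealized; heavy ring atoms sit on a circle
#' and substituents point outward (carbonyl O), inward-and-up (amide/amine
#' H) or out of plane (CH2 H). All amide N-H, the ring amine N-H, and the
#' carbonyl oxygens are discoverable by [find_donors_acceptors()].
#'
#' @param n_residues number of amide units (>= 2).
#' @param linker_len number of CH2 groups in the linker (>= 2).
#' @return List with `topology` (a [topology()] with explicit bonds) and
#'   `coords` (atoms x 3 matrix, Angstrom).
#' @export
toy_macrocycle <- function(n_residues = 3, linker_len = 2) {
  if (n_residues < 2) stopf("n_residues must be >= 2")
  if (linker_len < 2) stopf("linker_len must be >= 2")
  R <- n_residues; L <- linker_len
  # heavy ring sequence: (N CA C) x R, amine N, CH2 x L, closed to first N
  ring <- character(0); res <- integer(0); nm <- character(0)
  for (i in seq_len(R)) {
    ring <- c(ring, "N", "C", "C"); res <- c(res, rep(i, 3))
    nm <- c(nm, "N", "CA", "C")
  }
  ring <- c(ring, "N", rep("C", L)); res <- c(res, rep(R + 1L, 1L + L))
  nm <- c(nm, "NL", paste0("CL", seq_len(L)))
  n_ring <- length(ring)
  radius <- 1.45 / (2 * sin(pi / n_ring))
  theta <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
  pos <- cbind(radius * cos(theta), radius * sin(theta), 0)

  atoms <- data.frame(name = nm, element = ring, residue_id = res,
                      residue_name = ifelse(res <= R, "AMD", "LNK"),
                      stringsAsFactors = FALSE)
  coords <- pos
  bonds <- cbind(seq_len(n_ring), c(seq_len(n_ring)[-1], 1L))

  add_atom <- function(name, element, residue, xyz) {
    atoms <<- rbind(atoms, data.frame(name = name, element = element,
                                      residue_id = residue,
                                      residue_name = if (residue <= R) "AMD" else "LNK",
                                      stringsAsFactors = FALSE))
    coords <<- rbind(coords, xyz)
    nrow(atoms)
  }
  outward <- function(i) c(cos(theta[i]), sin(theta[i]), 0)

  for (i in seq_len(n_ring)) {
    u <- outward(i)
    if (nm[i] %in% c("N", "NL")) {
      # one H per nitrogen, tilted inward and up to avoid close contacts
      h <- pos[i, ] + 1.01 * (-0.6 * u + c(0, 0, 0.8))
      bonds <- rbind(bonds, c(i, add_atom("H", "H", res[i], h)))
    } else if (nm[i] == "C") {
      o <- pos[i, ] + 1.23 * u
      bonds <- rbind(bonds, c(i, add_atom("O", "O", res[i], o)))
    } else if (startsWith(nm[i], "CL")) {
      for (s in c(1, -1)) {
        h <- pos[i, ] + c(0, 0, s * 1.09)
        bonds <- rbind(bonds, c(i, add_atom(paste0("H", nm[i]), "H", res[i], h)))
      }
    }
  }
  rownames(coords) <- NULL
  list(topology = topology(atoms, bonds, formal_charge = 0L), coords = coords)
}

#' Metropolis sampling from a boosted low-dimensional potential
#'
#' Samples the *boosted* surface `V*(x) = V(x) + dV(V(x))`, where `dV`
#' is the aMD boost functional ([boost_energy()]) applied to the total
#' potential, and records the exact per-step boost energy. Reweighting
#' the samples by `exp(beta * dV)` recovers the canonical ensemble of
#' `V`, which makes this sampler an exact oracle for the reweighting
#' machinery.
#'
#' @param potential `list(kind = "harmonic", k = )` for `V = k x^2 / 2`,
#'   or `list(kind = "double_well", barrier = , a = )` for
#'   `V = barrier ((x/a)^2 - 1)^2`.
#' @param amd an [amd_params()] object; only the total-potential boost
#'   (`e_tot`, `alpha_tot`) is used in 1D.
#' @param temperature temperature, K.
#' @param n_steps number of Metropolis steps (>= 1).
#' @param seed RNG seed.
#' @param step_size Gaussian proposal standard deviation (default: the
#'   unboosted thermal width of the well).
#' @param x0 starting coordinate.
#' @return List with `samples` (length `n_steps`), `boost` (a
#'   [boost_series()] of the per-step total boosts) and
#'   `acceptance_rate`.
#' @export
sample_boosted_potential <- function(potential, amd, temperature = 300,
                                     n_steps = 1e4, seed = 1,
                                     step_size = NULL, x0 = 0) {
  if (n_steps < 1) stopf("n_steps must be >= 1")
  V <- switch(potential$kind,
    harmonic = function(x) 0.5 * potential$k * x^2,
    double_well = function(x) potential$barrier * ((x / potential$a)^2 - 1)^2,
    stopf("unknown potential kind '%s'", potential$kind))
  if (is.null(step_size))
    step_size <- switch(potential$kind,
      harmonic = sqrt(KB_CAL_T(temperature) / potential$k),
      double_well = potential$a / 2)
  beta <- 1 / (KB_KCAL * temperature)
  vstar <- function(x) {
    v <- V(x)
    v + boost_energy(v, amd$e_tot, amd$alpha_tot)
  }
  x <- numeric(n_steps)
  dv <- numeric(n_steps)
  with_seed(seed, {
    cur <- x0
    cur_vs <- vstar(cur)
    acc <- 0L
    for (i in seq_len(n_steps)) {
      prop <- cur + stats::rnorm(1, sd = step_size)
      prop_vs <- vstar(prop)
      if (stats::runif(1) < exp(-beta * (prop_vs - cur_vs))) {
        cur <- prop; cur_vs <- prop_vs; acc <- acc + 1L
      }
      x[i] <- cur
      v <- V(cur)
      dv[i] <- boost_energy(v, amd$e_tot, amd$alpha_tot)
    }
    rate <- acc / n_steps
    if (rate < 0.01) warnf("Metropolis acceptance rate %.2f%% (< 1%%)", 100 * rate)
    list(samples = x, boost = boost_series(rep(0, n_steps), dv),
         acceptance_rate = rate)
  })
}

KB_CAL_T <- function(temperature) KB_KCAL * temperature

#' Planted clusters on the torsion torus
#'
#' Draws `k` cluster centers uniformly on the `n_torsions`-torus and
#' samples frames around them with wrapped Gaussian noise of standard
#' deviation `1/sqrt(concentration)` radians (the von-Mises
#' large-concentration limit). Frame-to-cluster assignment is multinomial
#' with the requested populations.
#'
#' @param n_torsions torsions per frame (default 11).
#' @param k number of clusters.
#' @param populations cluster probabilities, summing to 1.
#' @param concentration von-Mises-like concentration parameter.
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return List with `angles` (`frames x n_torsions`, degrees in
#'   (-180, 180]), `labels` (true cluster of each frame) and `centers`.
#' @export
plant_torus_clusters <- function(n_torsions = 11, k = 3,
                                 populations = rep(1 / k, k),
                                 concentration = 50, n_frames = 1000,
                                 seed = 1) {
  if (abs(sum(populations) - 1) > 1e-9) stopf("populations must sum to 1")
  if (length(populations) != k) stopf("populations must have length k")
  if (k > n_frames) stopf("k (%d) exceeds n_frames (%d)", k, n_frames)
  with_seed(seed, {
    centers <- matrix(stats::runif(k * n_torsions, -180, 180), k, n_torsions)
    labels <- sample.int(k, n_frames, replace = TRUE, prob = populations)
    sd_deg <- (1 / sqrt(concentration)) * 180 / pi
    noise <- matrix(stats::rnorm(n_frames * n_torsions, sd = sd_deg),
                    n_frames, n_torsions)
    angles <- wrap_degrees(centers[labels, , drop = FALSE] + noise)
    colnames(angles) <- paste0("T", seq_len(n_torsions))
    list(angles = angles, labels = labels, centers = centers)
  })
}

# wrap to (-180, 180], ties at -180 mapped to +180
wrap_degrees <- function(x) {
  y <- x - 360 * floor((x + 180) / 360)
  y[y == -180] <- 180
  y
}

#' Trajectory with planted hydrogen-bond occupancies
#'
#' Builds frames from two template geometries per planned donor-acceptor
#' pair — contact formed (heavy-atom distance 2.9 A, D-H...A angle 165
#' degrees) or broken (5.5 A) — scheduled so that the *weighted* contact
#' occupancy matches each pair's target as closely as the weight vector
#' allows (greedy largest-weight-first subset; exact for uniform weights
#' with an integer frame count, and for weight vectors designed to sum to
#' the target). The base geometry is expanded so that no unplanned pair
#' is ever in contact; the generator verifies this and the achieved
#' occupancies are returned as ground truth.
#'
#' @param mol output of [toy_macrocycle()] (list with `topology`,
#'   `coords`).
#' @param contact_plan data.frame with columns `donor`, `acceptor`
#'   (indices into the donor/acceptor tables of
#'   [find_donors_acceptors()]) and `target` occupancy in `[0, 1]`.
#'   Donors and acceptors may appear in at most one planned pair.
#' @param weights optional per-frame weights (default uniform);
#'   normalized internally.
#' @param n_frames number of frames.
#' @param seed RNG seed (used to shuffle the formed-frame schedule).
#' @param criteria the [hbond_criteria()] the downstream analysis will
#'   use (needed to verify the planted geometry).
#' @return A [trajectory()] with attributes `achieved` (named numeric,
#'   the exact weighted occupancy of each planned pair), `schedule`
#'   (logical frames x pairs), `donors`, `acceptors`.
#' @export
plant_hbond_trajectory <- function(mol, contact_plan, weights = NULL,
                                   n_frames = 100, seed = 1,
                                   criteria = hbond_criteria()) {
  top <- mol$topology
  da <- find_donors_acceptors(top)
  if (any(contact_plan$target < 0 | contact_plan$target > 1))
    stopf("targets must be in [0, 1]")
  if (anyDuplicated(contact_plan$donor) || anyDuplicated(contact_plan$acceptor))
    stopf("each donor/acceptor may appear in at most one planned pair")
  np <- nrow(contact_plan)
  if (is.null(weights)) weights <- rep(1 / n_frames, n_frames)
  weights <- check_weights(weights, n_frames)

  sep <- pair_separation(top, da$donors, da$acceptors)
  for (p in seq_len(np)) {
    if (sep[contact_plan$donor[p], contact_plan$acceptor[p]] < criteria$min_separation)
      stopf("planned pair %d is closer than min_separation in the bond graph", p)
  }

  # expand until the base geometry has no contact at all, then verify the
  # formed templates produce exactly the planned contacts
  for (scale in c(3, 4, 6, 10)) {
    base <- expand_geometry(mol$coords, top, scale)
    formed <- base
    for (p in seq_len(np)) {
      d <- da$donors[contact_plan$donor[p], ]
      a <- da$acceptors$atom[contact_plan$acceptor[p]]
      formed[a, ] <- place_acceptor(base[d$heavy, ], base[d$hydrogen, ],
                                    dist = 2.9, angle = 165)
      base[a, ] <- place_acceptor(base[d$heavy, ], base[d$hydrogen, ],
                                  dist = 5.5, angle = 165)
    }
    hit_base <- detect_frame(base, da$donors, da$acceptors, criteria, top)
    hit_formed <- detect_frame(formed, da$donors, da$acceptors, criteria, top)
    want <- matrix(FALSE, nrow(da$donors), nrow(da$acceptors))
    want[cbind(contact_plan$donor, contact_plan$acceptor)] <- TRUE
    if (!any(hit_base) && identical(unname(hit_formed), want)) break
    if (scale == 10) stopf("could not realize the planted geometry cleanly")
  }

  schedule <- matrix(FALSE, n_frames, np)
  achieved <- numeric(np)
  ord <- order(weights, decreasing = TRUE)
  for (p in seq_len(np)) {
    target <- contact_plan$target[p]
    cum <- 0
    pick <- logical(n_frames)
    for (f in ord) {
      if (cum + weights[f] <= target + 1e-12) {
        pick[f] <- TRUE
        cum <- cum + weights[f]
      }
    }
    schedule[, p] <- pick
    achieved[p] <- sum(weights * pick)  # frame-order sum: the oracle value
    if (abs(achieved[p] - target) > 1e-9)
      warnf("pair %d: target %.4f not achievable under these weights; achieved %.4f",
            p, target, achieved[p])
  }
  # shuffle which frames are formed (keeps the weighted sum by permuting
  # only among equal-weight frames)
  schedule <- with_seed(seed, {
    for (p in seq_len(np)) {
      for (w in unique(weights)) {
        grp <- which(weights == w)
        if (length(grp) > 1)
          schedule[grp, p] <- schedule[sample(grp), p]
      }
    }
    schedule
  })
  achieved <- vapply(seq_len(np), function(p) sum(weights * schedule[, p]),
                     numeric(1))

  coords <- array(NA_real_, c(n_frames, n_atoms(top), 3))
  for (f in seq_len(n_frames)) {
    fr <- base
    for (p in seq_len(np)) if (schedule[f, p]) {
      d <- da$donors[contact_plan$donor[p], ]
      a <- da$acceptors$atom[contact_plan$acceptor[p]]
      fr[a, ] <- formed[a, ]
    }
    coords[f, , ] <- fr
  }
  traj <- trajectory(coords, top, frame_interval = 1)
  names(achieved) <- sprintf("%s-%s", da$donors$label[contact_plan$donor],
                             da$acceptors$label[contact_plan$acceptor])
  attr(traj, "achieved") <- achieved
  attr(traj, "schedule") <- schedule
  attr(traj, "weights") <- weights
  traj
}

# expand a molecule by scaling the multiply-bonded skeleton while keeping
# terminal atoms (H, carbonyl O, ...) at their bond length from the parent
expand_geometry <- function(coords, top, scale) {
  adj <- bond_adjacency(top)
  deg <- lengths(adj)
  out <- coords * scale
  for (i in which(deg == 1L)) {
    parent <- adj[[i]][1]
    out[i, ] <- out[parent, ] + (coords[i, ] - coords[parent, ])
  }
  out
}

# place an acceptor at `dist` Angstrom from the donor heavy atom such
# that the D-H...A angle (at H) equals `angle` degrees
place_acceptor <- function(p_d, p_h, dist, angle) {
  u <- (p_d - p_h) / vnorm(p_d - p_h)
  e <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  w <- c(u[2] * e[3] - u[3] * e[2],
         u[3] * e[1] - u[1] * e[3],
         u[1] * e[2] - u[2] * e[1])
  w <- w / vnorm(w)
  ca <- cos(angle * pi / 180); sa <- sin(angle * pi / 180)
  v <- ca * u + sa * w
  dhd <- vnorm(p_d - p_h)
  t <- dhd * ca + sqrt(dhd^2 * ca^2 - dhd^2 + dist^2)
  p_h + t * v
}
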