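# Independent oracles and fixture builders used across the suite.
# All fixtures are generated in code under fixed seeds; no data files.

K_COULOMB <- 332.0716

# explicit double-loop pair energies (the O(N^2) oracle)
brute_pair_energies <- function(system, ia, ib, d_in) {
  at <- system$atoms
  xyz <- coords(system)
  ec <- 0; ev <- 0
  for (i in ia) for (j in ib) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    ec <- ec + K_COULOMB * at$charge[i] * at$charge[j] / (d_in * r)
    rmin <- at$lj_rmin_half[i] + at$lj_rmin_half[j]
    eps <- sqrt(at$lj_epsilon[i] * at$lj_epsilon[j])
    ev <- ev + eps * ((rmin / r)^12 - 2 * (rmin / r)^6)
  }
  list(coulomb = ec, vdw = ev)
}

# sliding-window motif oracle
brute_find_motif <- function(sequence, pattern = "DXXDXDXE") {
  s <- strsplit(toupper(sequence), "")[[1]]
  p <- strsplit(toupper(pattern), "")[[1]]
  starts <- integer(0)
  if (length(s) >= length(p)) {
    for (i in seq_len(length(s) - length(p) + 1)) {
      win <- s[i:(i + length(p) - 1)]
      if (all(p == "X" | win == p)) starts <- c(starts, i)
    }
  }
  starts
}

born_analytic <- function(q, a, d_in, d_solv) {
  -(K_COULOMB / 2) * q^2 / a * (1 / d_in - 1 / d_solv)
}

# two-term (monopole + dipole) Kirkwood expansion for charges in a
# spherical cavity of radius a centered at the origin
kirkwood_two_term <- function(q, pos, a, d_in, d_solv) {
  monopole <- sum(q)^2
  dip <- colSums(q * pos)
  dipole2 <- sum(dip^2)
  f_l <- function(l) {
    ((l + 1) * (d_solv - d_in)) /
      (d_in * (d_solv * (l + 1) + d_in * l)) / a^(2 * l + 1)
  }
  -(K_COULOMB / 2) * (f_l(0) * monopole + f_l(1) * dipole2)
}

# exposed area of two equal overlapping spheres (spherical-cap formula)
two_sphere_area <- function(R, d) {
  stopifnot(d < 2 * R)
  h <- R - d / 2
  2 * (4 * pi * R^2 - 2 * pi * R * h)
}

# random fully-parameterized system; coordinates spread enough to avoid
# near-singular pair distances
random_system <- function(n, seed, spread = 8) {
  set.seed(seed)
  repeat {
    xyz <- matrix(runif(n * 3, 0, spread), n, 3)
    if (min(dist(xyz)) > 0.8) break
  }
  molecular_system(data.frame(
    name = paste0("A", seq_len(n)), element = "C",
    resname = "RND", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = runif(n, -1, 1),
    lj_epsilon = runif(n, 0.05, 0.3),
    lj_rmin_half = runif(n, 1, 2),
    boundary_radius = runif(n, 1.2, 2),
    stringsAsFactors = FALSE
  ), tag = "random")
}

# minimal hand-built system: atoms on given coordinates with given charges
point_system <- function(xyz, charge, radius = 1.5, eps = 0.1,
                         rmin_half = 1.5) {
  n <- nrow(xyz)
  molecular_system(data.frame(
    name = paste0("P", seq_len(n)), element = "C",
    resname = "PNT", resid = seq_len(n), chain = "A",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge,
    lj_epsilon = rep_len(eps, n),
    lj_rmin_half = rep_len(rmin_half, n),
    boundary_radius = rep_len(radius, n),
    stringsAsFactors = FALSE
  ))
}

# a single-pair trajectory with prescribed inter-atom distances
distance_trajectory <- function(distances) {
  sys <- point_system(rbind(c(0, 0, 0), c(0, 0, 2.75)), charge = c(0, 0))
  frames <- lapply(distances, function(d) rbind(c(0, 0, 0), c(0, 0, d)))
  trajectory(sys, frames)
}

random_protein <- function(len, seed) {
  set.seed(seed)
  # D and E enriched so motif-like windows actually occur
  alphabet <- c("A", "C", "D", "D", "D", "E", "E", "F", "G", "H", "I", "K",
                "L", "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

coarse_grid <- function(spacing = 0.8) {
  grid_spec(spacing = spacing, padding = 4 * spacing)
}

small_complex_spec <- function(...) {
  toy_complex_spec(n_sugar_units = 2, pocket_atoms = 4, contact_unit = 2,
                   ...)
}
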