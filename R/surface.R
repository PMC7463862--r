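#' Molecular (probe-inflated accessible) surface area
#'
#' Rolling-probe area over spheres of radius
#' `rho * boundary_radius + probe`, by deterministic equal-area spiral
#' point sampling: a point on atom i's inflated sphere contributes area
#' `4 pi R_i^2 / n_points` when it lies outside every other inflated
#' sphere. Results are bit-reproducible for a given `n_points`.
#'
#' @param system parameterized `molecular_system`.
#' @param probe solvent probe radius, Angstrom.
#' @param rho boundary-radius scaling (SIE rho).
#' @param n_points sample points per atom sphere.
#' @return total area in Angstrom^2, with attribute `per_atom`.
#' @export
molecular_surface_area <- function(system, probe = 1.4, rho = 1.1,
                                   n_points = 960) {
  assert_parameterized(system, "molecular_surface_area")
  stopifnot(probe >= 0, n_points >= 8)
  xyz <- coords(system)
  radii <- rho * system$atoms$boundary_radius + probe
  na <- nrow(xyz)
  unit <- spiral_points(n_points)
  per_atom <- numeric(na)
  for (i in seq_len(na)) {
    pts <- sweep(unit * radii[i], 2, xyz[i, ], `+`)
    exposed <- rep(TRUE, n_points)
    for (j in seq_len(na)) {
      if (j == i) next
      # skip spheres too far to occlude
      if (sum((xyz[j, ] - xyz[i, ])^2) >= (radii[i] + radii[j])^2) next
      d2 <- (pts[, 1] - xyz[j, 1])^2 + (pts[, 2] - xyz[j, 2])^2 +
        (pts[, 3] - xyz[j, 3])^2
      exposed <- exposed & (d2 > radii[j]^2)
      if (!any(exposed)) break
    }
    per_atom[i] <- 4 * pi * radii[i]^2 * sum(exposed) / n_points
  }
  total <- sum(per_atom)
  attr(total, "per_atom") <- per_atom
  total
}

# generalized spiral (golden-angle) points on the unit sphere; deterministic
spiral_points <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(1 - z^2, 0))
  lon <- k * pi * (3 - sqrt(5))
  cbind(r * cos(lon), r * sin(lon), z)
}

#' Change in molecular surface area upon binding
#'
#' `MSA(complex) - MSA(receptor) - MSA(ligand)` at frozen coordinates;
#' non-positive whenever any receptor-ligand sphere pair overlaps (buried
#' surface), exactly zero for separated partners.
#'
#' @param complex parameterized `molecular_system`.
#' @param receptor,ligand selections partitioning the complex.
#' @inheritParams molecular_surface_area
#' @return area change in Angstrom^2.
#' @export
delta_msa <- function(complex, receptor, ligand, probe = 1.4, rho = 1.1,
                      n_points = 960) {
  check_partition(complex, receptor, ligand)
  msa <- function(sys) as.numeric(molecular_surface_area(sys, probe, rho, n_points))
  msa(complex) -
    msa(subset_system(complex, receptor, "receptor")) -
    msa(subset_system(complex, ligand, "ligand"))
}
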