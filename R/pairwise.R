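#' Intermolecular screened Coulomb energy
#'
#' Sum over all receptor-ligand atom pairs of `k q_i q_j / (d_in r_ij)`
#' with `k = 332.0716` kcal A / (mol e^2). No distance cutoff by default:
#' the endpoint sum is exact. Intra-set pairs are never counted.
#'
#' @param system parameterized `molecular_system` holding both partners.
#' @param receptor,ligand disjoint selections from [select_atoms()].
#' @param d_in solute interior dielectric constant (> 0).
#' @param cutoff optional distance cutoff in Angstrom (`Inf` = none).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(system, receptor, ligand, d_in = 2.25,
                           cutoff = Inf) {
  pe <- pair_setup(system, receptor, ligand, "coulomb_energy")
  stopifnot(d_in > 0)
  e <- COULOMB_K * outer(pe$qa, pe$qb) / (d_in * pe$r)
  if (is.finite(cutoff)) e[pe$r > cutoff] <- 0
  sum(e)
}

#' Intermolecular Lennard-Jones energy
#'
#' 12-6 form in the AMBER Rmin convention:
#' `eps_ij * ((Rmin_ij/r)^12 - 2 (Rmin_ij/r)^6)` with Lorentz-Berthelot
#' combination `Rmin_ij = rmin_half_i + rmin_half_j`,
#' `eps_ij = sqrt(eps_i eps_j)`.
#'
#' @inheritParams coulomb_energy
#' @return energy in kcal/mol.
#' @export
lennard_jones_energy <- function(system, receptor, ligand, cutoff = Inf) {
  pe <- pair_setup(system, receptor, ligand, "lennard_jones_energy")
  at <- system$atoms
  rmin <- outer(at$lj_rmin_half[pe$ia], at$lj_rmin_half[pe$ib], `+`)
  eps <- sqrt(outer(at$lj_epsilon[pe$ia], at$lj_epsilon[pe$ib]))
  s6 <- (rmin / pe$r)^6
  e <- eps * (s6^2 - 2 * s6)
  if (is.finite(cutoff)) e[pe$r > cutoff] <- 0
  sum(e)
}

#' Both intermolecular pair energies at once
#'
#' @inheritParams coulomb_energy
#' @return list with `coulomb` (kcal/mol), `vdw` (kcal/mol), `n_pairs`.
#' @export
pair_energies <- function(system, receptor, ligand, d_in = 2.25,
                          cutoff = Inf) {
  list(coulomb = coulomb_energy(system, receptor, ligand, d_in, cutoff),
       vdw = lennard_jones_energy(system, receptor, ligand, cutoff),
       n_pairs = length(receptor) * length(ligand))
}

pair_setup <- function(system, receptor, ligand, what) {
  assert_parameterized(system, what)
  ia <- as.integer(receptor); ib <- as.integer(ligand)
  if (length(ia) < 1 || length(ib) < 1) stop(what, ": empty selection")
  if (length(intersect(ia, ib)) > 0) {
    stop(what, ": receptor and ligand selections overlap")
  }
  xyz <- coords(system)
  r <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE])
  if (any(r == 0)) stop(what, ": coincident atoms across selections (r = 0)")
  list(ia = ia, ib = ib, r = r,
       qa = system$atoms$charge[ia], qb = system$atoms$charge[ib])
}

# |A| x |B| Euclidean distance matrix (optionally minimum-image periodic).
cross_distances <- function(a, b, box = NULL) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in 1:3) {
    dk <- outer(a[, k], b[, k], `-`)
    if (!is.null(box)) dk <- dk - box[k] * round(dk / box[k])
    d2 <- d2 + dk * dk
  }
  sqrt(d2)
}
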