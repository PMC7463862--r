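#' Specification for a synthetic pocket / chito-oligosaccharide complex
#'
#' Describes the toy system the generator builds: a rigid receptor
#' "pocket" — a ring of neutral carbon pseudo-atoms plus one aspartate
#' carboxylate (residue number 440, mirroring the GH18 last-Asp
#' convention) — bound to a linear chain of pseudo-GlcNAc units, each a
#' four-atom caricature (ring-center carbon C1, amide nitrogen N2, amide
#' oxygen O7, hydroxyl oxygen O3; residue name NAG, numbered from the
#' nonreducing end = unit 1). One designed contact pairs the carboxylate
#' oxygen OD1 with the amide nitrogen of `contact_unit`; over a generated
#' trajectory that distance follows a truncated Normal with the given mean
#' and sd, while every other atom jitters independently.
#'
#' @param n_sugar_units number of pseudo-GlcNAc units (e.g. 3 or 12).
#' @param pocket_atoms number of neutral ring atoms in the pocket.
#' @param contact_unit 1-based index of the unit carrying the contact.
#' @param contact_distance_mean designed OD1-N2 distance mean, Angstrom.
#' @param contact_distance_sd designed contact-distance sd, Angstrom.
#' @param jitter_sd positional noise sd for all other atoms, Angstrom.
#' @param seed integer RNG seed for trajectory generation.
#' @return object of class `toy_complex_spec`.
#' @export
toy_complex_spec <- function(n_sugar_units = 3, pocket_atoms = 12,
                             contact_unit = 2, contact_distance_mean = 2.75,
                             contact_distance_sd = 0.1, jitter_sd = 0.05,
                             seed = 1L) {
  stopifnot(n_sugar_units >= 1, pocket_atoms >= 0,
            contact_unit >= 1, contact_unit <= n_sugar_units,
            contact_distance_mean > 0, contact_distance_sd >= 0,
            jitter_sd >= 0)
  structure(list(n_sugar_units = as.integer(n_sugar_units),
                 pocket_atoms = as.integer(pocket_atoms),
                 contact_unit = as.integer(contact_unit),
                 contact_distance_mean = contact_distance_mean,
                 contact_distance_sd = contact_distance_sd,
                 jitter_sd = jitter_sd, seed = as.integer(seed)),
            class = "toy_complex_spec")
}

#' Build the toy complex described by a spec
#'
#' Deterministic construction (no randomness): the sugar chain runs along
#' the x axis with 5-Angstrom unit spacing, and the carboxylate OD1 sits
#' exactly `contact_distance_mean` above the contact unit's N2 along +z.
#' All atoms are parameterized from the shipped parameter table. Chain A
#' holds the receptor (ASP 440 plus pocket carbons, resname PKT), chain B
#' the NAG units.
#'
#' @param spec a [toy_complex_spec()].
#' @param table parameter table; defaults to the shipped one.
#' @return parameterized `molecular_system`, tagged `"toy complex"`.
#' @export
build_toy_complex <- function(spec = toy_complex_spec(),
                              table = default_parameter_table()) {
  stopifnot(inherits(spec, "toy_complex_spec"))
  unit_x <- function(u) (u - 1) * 5.0
  sugar <- do.call(rbind, lapply(seq_len(spec$n_sugar_units), function(u) {
    cx <- unit_x(u)
    data.frame(
      name = c("C1", "N2", "O7", "O3"),
      element = c("C", "N", "O", "O"),
      resname = "NAG", resid = u, chain = "B",
      x = cx + c(0, 0, 0.7, 0),
      y = c(0, 1.45, 2.35, -1.43),
      z = c(0, 0, 0.5, 0),
      stringsAsFactors = FALSE
    )
  }))
  n2_contact <- c(unit_x(spec$contact_unit), 1.45, 0)
  od1 <- n2_contact + c(0, 0, spec$contact_distance_mean)
  asp <- data.frame(
    name = c("OD1", "OD2", "CG"),
    element = c("O", "O", "C"),
    resname = "ASP", resid = 440L, chain = "A",
    x = od1[1] + c(0, 2.2, 1.1),
    y = od1[2] + c(0, 0, 0),
    z = od1[3] + c(0, 0.4, 0.75),
    stringsAsFactors = FALSE
  )
  atoms <- rbind(asp, sugar)
  if (spec$pocket_atoms > 0) {
    theta <- 2 * pi * (seq_len(spec$pocket_atoms) - 1) / spec$pocket_atoms
    pocket <- data.frame(
      name = paste0("C", seq_len(spec$pocket_atoms)),
      element = "C", resname = "PKT",
      resid = seq_len(spec$pocket_atoms), chain = "A",
      x = n2_contact[1] + 6.0 * cos(theta),
      y = n2_contact[2] + 6.0 * sin(theta),
      z = od1[3] + 1.0,
      stringsAsFactors = FALSE
    )
    atoms <- rbind(asp, pocket, sugar)
  }
  assign_parameters(molecular_system(atoms, tag = "toy complex"), table)
}

#' Generate a mock trajectory for a toy complex
#'
#' Each frame perturbs every atom independently with isotropic Normal
#' noise of sd `jitter_sd`, then re-places the carboxylate OD1 exactly
#' `d_f` above the (jittered) contact N2 along +z, where `d_f` is drawn
#' i.i.d. from Normal(`contact_distance_mean`, `contact_distance_sd`)
#' truncated at > 0. The designed contact distance is therefore exact in
#' every frame, and the designed hydrogen-bond occupancy at a cutoff c is
#' `pnorm((c - mean)/sd)` (up to truncation). Fully reproducible from
#' `spec$seed`.
#'
#' @param complex system from [build_toy_complex()].
#' @param spec the [toy_complex_spec()] used to build it.
#' @param n_frames number of frames (>= 1).
#' @return a `trajectory` with `frame_times` 1..n (ps).
#' @export
generate_trajectory <- function(complex, spec, n_frames) {
  stopifnot(inherits(complex, "molecular_system"),
            inherits(spec, "toy_complex_spec"))
  if (n_frames < 1) stop("n_frames must be at least 1")
  base <- coords(complex)
  i_od1 <- select_atoms(complex, "resname ASP and resid 440 and name OD1")
  i_n2 <- select_atoms(complex,
                       query = paste("resname NAG and name N2 and resid",
                                     spec$contact_unit))
  if (length(i_od1) != 1 || length(i_n2) != 1) {
    stop("complex does not contain the designed OD1/N2 contact pair")
  }
  set.seed(spec$seed)
  na <- nrow(base)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    xyz <- base + matrix(rnorm(na * 3, sd = spec$jitter_sd), na, 3)
    d <- rnorm(1, spec$contact_distance_mean, spec$contact_distance_sd)
    while (d <= 0) d <- rnorm(1, spec$contact_distance_mean,
                              spec$contact_distance_sd)
    xyz[i_od1, ] <- xyz[i_n2, ] + c(0, 0, d)
    frames[[f]] <- xyz
  }
  trajectory(complex, frames, frame_times = as.numeric(seq_len(n_frames)))
}
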