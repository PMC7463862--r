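#' Construct a molecular system
#'
#' A molecular system is an ordered table of atoms with coordinates (in
#' Angstrom) and, once [assign_parameters()] has been applied, the per-atom
#' physical parameters used by the energy terms: partial charge (e),
#' Lennard-Jones well depth (kcal/mol) and minimum-energy half-distance
#' (Angstrom), and the dielectric-boundary radius (Angstrom, before the
#' SIE rho scaling).
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`,
#'   `resid` (integer), `chain`, `x`, `y`, `z` and optionally `charge`,
#'   `lj_epsilon`, `lj_rmin_half`, `boundary_radius`.
#' @param tag free-text label, e.g. `"receptor"`, `"ligand"`, `"complex"`.
#' @return object of class `molecular_system`.
#' @export
molecular_system <- function(atoms, tag = "") {
  stopifnot(is.data.frame(atoms))
  required <- c("name", "element", "resname", "resid", "chain", "x", "y", "z")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols) > 0) {
    stop("atom table is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1) stop("a molecular system needs at least one atom")
  for (col in c("charge", "lj_epsilon", "lj_rmin_half", "boundary_radius")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  atoms$resid <- as.integer(atoms$resid)
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("atom coordinates must be finite")
  }
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, tag = as.character(tag)),
            class = "molecular_system")
}

#' @export
print.molecular_system <- function(x, ...) {
  cat(sprintf("<molecular_system%s: %d atoms, %d residues>\n",
              if (nzchar(x$tag)) paste0(" '", x$tag, "'") else "",
              n_atoms(x), length(unique(residue_keys(x)))))
  invisible(x)
}

#' Number of atoms in a system or trajectory topology
#' @param x a `molecular_system` or `trajectory`.
#' @return integer count.
#' @export
n_atoms <- function(x) {
  if (inherits(x, "trajectory")) x <- x$topology
  nrow(x$atoms)
}

residue_keys <- function(system) {
  with(system$atoms, paste(chain, resname, resid, sep = "|"))
}

#' Atom coordinates as an n x 3 matrix
#' @param system a `molecular_system`.
#' @return numeric matrix, Angstrom.
#' @export
coords <- function(system) {
  as.matrix(system$atoms[, c("x", "y", "z")])
}

set_coords <- function(system, xyz) {
  stopifnot(nrow(xyz) == n_atoms(system), ncol(xyz) == 3)
  system$atoms$x <- xyz[, 1]
  system$atoms$y <- xyz[, 2]
  system$atoms$z <- xyz[, 3]
  system
}

#' Construct a trajectory
#'
#' A trajectory couples a topology (a [molecular_system()]) with an ordered
#' list of coordinate frames sharing the topology's atom count and order.
#'
#' @param topology a `molecular_system`.
#' @param frames list of n_atoms x 3 coordinate matrices, Angstrom.
#' @param frame_times optional numeric vector of frame times, ps.
#' @return object of class `trajectory`.
#' @export
trajectory <- function(topology, frames, frame_times = NULL) {
  stopifnot(inherits(topology, "molecular_system"), is.list(frames))
  if (length(frames) < 1) stop("a trajectory needs at least one frame")
  na <- n_atoms(topology)
  ok <- vapply(frames, function(f) is.matrix(f) && nrow(f) == na && ncol(f) == 3,
               logical(1))
  if (!all(ok)) {
    stop("frame(s) ", paste(which(!ok), collapse = ", "),
         " do not match the topology atom count (", na, ")")
  }
  if (!is.null(frame_times) && length(frame_times) != length(frames)) {
    stop("frame_times length must equal the number of frames")
  }
  structure(list(topology = topology, frames = frames,
                 frame_times = frame_times),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory: %d frames x %d atoms>\n",
              n_frames(x), n_atoms(x)))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @return integer count.
#' @export
n_frames <- function(traj) length(traj$frames)

#' Materialize one trajectory frame as a molecular system
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return `molecular_system` with the frame's coordinates.
#' @export
frame_system <- function(traj, i) {
  stopifnot(i >= 1, i <= n_frames(traj))
  set_coords(traj$topology, traj$frames[[i]])
}

#' Select atoms of a molecular system
#'
#' Resolves a selection to unique, in-range atom indices. Selections can be
#' given as named filters (combined with AND) or as a compact query string
#' of `and`-joined clauses, e.g. `"resid 440 and name OD1 OD2"` or
#' `"resname NAG and name N2"`. `resid` clauses accept single numbers and
#' `lo-hi` ranges.
#'
#' @param x a `molecular_system` or `trajectory` (selection is resolved on
#'   the topology and applies identically to every frame).
#' @param query optional selection string.
#' @param resname,name,element,chain optional character filters (any of the
#'   given values matches).
#' @param resid optional integer vector of residue numbers.
#' @return integer vector of atom indices with class `atom_selection`.
#' @export
select_atoms <- function(x, query = NULL, resname = NULL, resid = NULL,
                         name = NULL, element = NULL, chain = NULL) {
  if (inherits(x, "trajectory")) x <- x$topology
  stopifnot(inherits(x, "molecular_system"))
  at <- x$atoms
  keep <- rep(TRUE, nrow(at))
  if (!is.null(query)) {
    f <- parse_selection_query(query)
    resname <- f$resname %||% resname
    resid <- f$resid %||% resid
    name <- f$name %||% name
    element <- f$element %||% element
    chain <- f$chain %||% chain
  }
  if (!is.null(resname)) keep <- keep & at$resname %in% resname
  if (!is.null(resid)) keep <- keep & at$resid %in% as.integer(resid)
  if (!is.null(name)) keep <- keep & at$name %in% name
  if (!is.null(element)) keep <- keep & toupper(at$element) %in% toupper(element)
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  idx <- which(keep)
  structure(idx, class = c("atom_selection", class(idx)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_selection_query <- function(query) {
  clauses <- strsplit(trimws(query), "\\s+and\\s+")[[1]]
  out <- list()
  for (cl in clauses) {
    tok <- strsplit(trimws(cl), "\\s+")[[1]]
    if (length(tok) < 2) stop("cannot parse selection clause: '", cl, "'")
    key <- tok[1]
    vals <- tok[-1]
    if (key == "resid") {
      ids <- integer(0)
      for (v in vals) {
        if (grepl("^[0-9]+-[0-9]+$", v)) {
          rng <- as.integer(strsplit(v, "-")[[1]])
          ids <- c(ids, seq(rng[1], rng[2]))
        } else if (grepl("^[0-9]+$", v)) {
          ids <- c(ids, as.integer(v))
        } else stop("bad resid token '", v, "' in clause '", cl, "'")
      }
      out$resid <- ids
    } else if (key %in% c("resname", "name", "element", "chain")) {
      out[[key]] <- vals
    } else {
      stop("unknown selection keyword '", key, "' (use resname/resid/name/element/chain)")
    }
  }
  out
}

#' Extract a subsystem by selection
#' @param system a `molecular_system`.
#' @param selection indices from [select_atoms()] (or any integer vector).
#' @param tag label for the subsystem.
#' @return `molecular_system` holding only the selected atoms, in order.
#' @export
subset_system <- function(system, selection, tag = system$tag) {
  idx <- as.integer(selection)
  if (length(idx) < 1) stop("empty selection")
  if (any(idx < 1 | idx > n_atoms(system))) stop("selection index out of range")
  if (anyDuplicated(idx)) stop("selection indices must be unique")
  molecular_system(system$atoms[idx, , drop = FALSE], tag = tag)
}

check_partition <- function(system, receptor, ligand) {
  r <- as.integer(receptor); l <- as.integer(ligand)
  if (length(intersect(r, l)) > 0) stop("receptor and ligand selections overlap")
  if (!setequal(c(r, l), seq_len(n_atoms(system)))) {
    stop("receptor and ligand selections must partition the complex atoms")
  }
  invisible(TRUE)
}

assert_parameterized <- function(system, what = "operation") {
  p <- system$atoms[, c("charge", "lj_epsilon", "lj_rmin_half", "boundary_radius")]
  bad <- which(!stats::complete.cases(p))
  if (length(bad) > 0) {
    stop(what, " requires a parameterized system; atoms without parameters: ",
         paste(utils::head(bad, 8), collapse = ", "),
         if (length(bad) > 8) " ..." else "",
         " (apply assign_parameters() first)")
  }
  invisible(TRUE)
}
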