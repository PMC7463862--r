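#' Read a PDB or multi-model PDB file
#'
#' Single-model files yield a [molecular_system()]; files with MODEL/ENDMDL
#' blocks yield a [trajectory()] whose topology is the first model. ATOM and
#' HETATM records are treated identically. Atoms carry name, element and
#' residue identity from the file but placeholder (`NA`) physical parameters
#' until [assign_parameters()] is applied. Coordinates are stored in
#' Angstrom; files written in nm can be converted on input.
#'
#' @param path PDB file path.
#' @param units `"angstrom"` (default) or `"nm"`; with `"nm"` coordinates
#'   are multiplied by 10 on input.
#' @param tag label passed to the resulting system.
#' @return `molecular_system` or `trajectory`.
#' @export
read_pdb <- function(path, units = c("angstrom", "nm"), tag = "") {
  units <- match.arg(units)
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  validate_pdb_lines(lines, path)

  multi <- any(startsWith(lines, "MODEL"))
  pdb <- suppressWarnings(suppressMessages(
    bio3d::read.pdb(path, multi = multi, verbose = FALSE)
  ))
  at <- pdb$atom
  altloc <- at$alt
  if (!is.null(altloc) && any(!is.na(altloc) & !(altloc %in% c("", "A")))) {
    warning("alternate-location records other than blank/'A' were dropped")
  }
  element <- at$elesy
  if (is.null(element) || all(is.na(element)) || all(!nzchar(trimws(element)))) {
    element <- substr(trimws(at$elety), 1, 1)
  }
  element <- ifelse(is.na(element) | !nzchar(trimws(element)),
                    substr(trimws(at$elety), 1, 1), trimws(element))
  chain <- ifelse(is.na(at$chain), "", at$chain)
  scale <- if (units == "nm") 10 else 1
  atoms <- data.frame(
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    resid = as.integer(at$resno),
    chain = chain,
    x = at$x * scale, y = at$y * scale, z = at$z * scale,
    stringsAsFactors = FALSE
  )
  system <- molecular_system(atoms, tag = tag)
  if (!multi) return(system)

  xyz <- pdb$xyz
  nf <- nrow(xyz)
  frames <- lapply(seq_len(nf), function(i) {
    matrix(xyz[i, ], ncol = 3, byrow = TRUE) * scale
  })
  system <- set_coords(system, frames[[1]])
  trajectory(system, frames)
}

# Structural pre-scan: line-numbered malformed-record errors and the
# equal-atom-count-per-model requirement, neither reported by bio3d.
validate_pdb_lines <- function(lines, path) {
  is_atom <- startsWith(lines, "ATOM") | startsWith(lines, "HETATM")
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": fewer than 54 columns")
    }
    xyz <- c(substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))
    if (anyNA(suppressWarnings(as.numeric(xyz)))) {
      stop("malformed ATOM/HETATM record at line ", i, " of ", path,
           ": non-numeric coordinate field")
    }
  }
  model_starts <- which(startsWith(lines, "MODEL"))
  if (length(model_starts) > 1) {
    ends <- which(startsWith(lines, "ENDMDL"))
    if (length(ends) != length(model_starts)) {
      stop("unbalanced MODEL/ENDMDL records in ", path)
    }
    counts <- mapply(function(s, e) sum(is_atom[s:e]), model_starts, ends)
    if (length(unique(counts)) != 1) {
      stop("models in ", path, " have differing atom counts: ",
           paste(counts, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write a PDB or multi-model PDB file
#'
#' Standard fixed-column PDB output; trajectories are written as
#' MODEL/ENDMDL blocks. Output is byte-deterministic for a given input
#' (no timestamps or comments), so regenerated synthetic trajectories
#' round-trip identically.
#'
#' @param x a `molecular_system` or `trajectory`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(x, path) {
  if (inherits(x, "molecular_system")) {
    lines <- c(format_pdb_model(x$atoms, coords(x)), "END")
  } else if (inherits(x, "trajectory")) {
    at <- x$topology$atoms
    blocks <- lapply(seq_along(x$frames), function(i) {
      c(sprintf("MODEL     %4d", i),
        format_pdb_model(at, x$frames[[i]]),
        "ENDMDL")
    })
    lines <- c(unlist(blocks), "END")
  } else {
    stop("write_pdb expects a molecular_system or trajectory")
  }
  writeLines(lines, path)
  invisible(path)
}

format_pdb_model <- function(atoms, xyz) {
  if (any(xyz > 9999.999 | xyz < -999.999)) {
    stop("coordinates out of PDB fixed-column range (-999.999..9999.999)")
  }
  name4 <- ifelse(nchar(atoms$name) < 4,
                  sprintf(" %-3s", atoms$name),
                  substr(atoms$name, 1, 4))
  sprintf("ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          seq_len(nrow(atoms)), name4, substr(atoms$resname, 1, 3),
          substr(paste0(atoms$chain, " "), 1, 1), atoms$resid,
          xyz[, 1], xyz[, 2], xyz[, 3], 1, 0,
          toupper(substr(atoms$element, 1, 2)))
}
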