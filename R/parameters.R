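#' Read a per-atom parameter table
#'
#' The table is a TSV with columns `resname`, `atom`, `element`, `charge`
#' (e), `lj_epsilon` (kcal/mol), `lj_rmin_half` (Angstrom) and
#' `boundary_radius` (Angstrom). Rows with both `resname` and `atom` set
#' are exact (residue, atom-name) entries; rows with only `element` set are
#' element fallbacks.
#'
#' @param path TSV file path.
#' @return data.frame with the columns above.
#' @export
read_parameter_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("resname", "atom", "element", "charge",
                "lj_epsilon", "lj_rmin_half", "boundary_radius")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols) > 0) {
    stop("parameter table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  num <- c("charge", "lj_epsilon", "lj_rmin_half", "boundary_radius")
  for (col in num) tab[[col]] <- as.numeric(tab[[col]])
  bad <- !is.finite(tab$charge) | tab$lj_epsilon < 0 |
    tab$lj_rmin_half <= 0 | tab$boundary_radius <= 0
  if (any(bad)) {
    stop("invalid parameter rows (epsilon < 0, rmin_half <= 0, or radius <= 0): ",
         paste(which(bad), collapse = ", "))
  }
  tab
}

#' The parameter table shipped with the package
#'
#' A minimal self-consistent set (carboxylate O/C, sugar amide N, carbonyl
#' and hydroxyl O, aliphatic C, water, plus element fallbacks) sufficient
#' for the toy complexes built by [build_toy_complex()]. It is not a force
#' field; real systems should be parameterized from a user-supplied table.
#'
#' @return data.frame, see [read_parameter_table()].
#' @export
default_parameter_table <- function() {
  read_parameter_table(system.file("extdata", "atom_params.tsv",
                                   package = "siechit", mustWork = TRUE))
}

#' Assign physical parameters to the atoms of a system
#'
#' Lookup precedence per atom: exact (residue name, atom name) entry, then
#' element fallback, else a missing-parameter error listing the offending
#' atoms. Re-applying the same table is a no-op.
#'
#' @param system a `molecular_system`.
#' @param table parameter table (data.frame from [read_parameter_table()]);
#'   defaults to the shipped table.
#' @return the parameterized `molecular_system`.
#' @export
assign_parameters <- function(system, table = default_parameter_table()) {
  stopifnot(inherits(system, "molecular_system"))
  at <- system$atoms
  has_pair <- !is.na(table$resname) & nzchar(trimws(as.character(table$resname))) &
    !is.na(table$atom) & nzchar(trimws(as.character(table$atom)))
  pair_rows <- table[has_pair, , drop = FALSE]
  elem_rows <- table[!has_pair & !is.na(table$element) &
                       nzchar(trimws(as.character(table$element))), , drop = FALSE]
  pair_key <- paste(pair_rows$resname, pair_rows$atom, sep = "|")
  if (anyDuplicated(pair_key)) stop("duplicate (resname, atom) rows in parameter table")
  elem_key <- toupper(trimws(elem_rows$element))
  if (anyDuplicated(elem_key)) stop("duplicate element fallback rows in parameter table")

  atom_pair <- paste(at$resname, at$name, sep = "|")
  i_pair <- match(atom_pair, pair_key)
  i_elem <- match(toupper(trimws(at$element)), elem_key)
  unmatched <- which(is.na(i_pair) & is.na(i_elem))
  if (length(unmatched) > 0) {
    labels <- with(at[unmatched, , drop = FALSE],
                   paste0(resname, resid, ":", name, " (", element, ")"))
    stop("no parameters for atom(s): ",
         paste(utils::head(labels, 10), collapse = ", "),
         if (length(labels) > 10) " ..." else "")
  }
  pick <- function(col) {
    ifelse(!is.na(i_pair), pair_rows[[col]][i_pair], elem_rows[[col]][i_elem])
  }
  at$charge <- pick("charge")
  at$lj_epsilon <- pick("lj_epsilon")
  at$lj_rmin_half <- pick("lj_rmin_half")
  at$boundary_radius <- pick("boundary_radius")
  system$atoms <- at
  system
}
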