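AA_CODES <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N",
              "P", "Q", "R", "S", "T", "V", "W", "Y")

# average residue (condensed) masses, Da
AA_MASSES <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760,
  V = 99.1326
)
WATER_MASS <- 18.0153

validate_sequence <- function(sequence, allow_x = TRUE) {
  s <- toupper(sequence)
  allowed <- c(AA_CODES, if (allow_x) "X")
  ch <- strsplit(s, "")[[1]]
  bad <- which(!(ch %in% allowed))
  if (length(bad) > 0) {
    stop("illegal residue code '", ch[bad[1]], "' at position ", bad[1])
  }
  s
}

#' Locate a catalytic-motif pattern in a protein sequence
#'
#' Finds all (possibly overlapping) occurrences of a motif such as the
#' glycoside hydrolase family 18 catalytic motif `DXXDXDXE`, reported in
#' 1-based residue coordinates ascending by start. In the pattern, `X` is
#' a wildcard matching any residue (including an unknown `X` in the
#' sequence); a literal pattern letter matches only itself, so an unknown
#' `X` in the sequence never satisfies a literal `D` or `E`.
#'
#' For each match the catalytically relevant positions are recorded: the
#' last aspartate of the motif (the substrate-amide hydrogen-bonding
#' residue, e.g. Asp440 when the motif starts at residue 435) and the
#' glutamate (the catalytic acid).
#'
#' @param sequence amino-acid string (one-letter codes, case-insensitive).
#' @param pattern motif string over one-letter codes plus the `X` wildcard.
#' @return data.frame of class `motif_match` with columns `start`, `end`,
#'   `matched`, `last_asp`, `glu` (1-based; `NA` when the pattern has no
#'   literal D or E).
#' @export
find_motif <- function(sequence, pattern = "DXXDXDXE") {
  s <- validate_sequence(sequence)
  p <- toupper(pattern)
  pch <- strsplit(p, "")[[1]]
  badp <- which(!(pch %in% c(AA_CODES, "X")))
  if (length(badp) > 0) {
    stop("illegal pattern character '", pch[badp[1]], "' at position ", badp[1])
  }
  if (length(pch) == 0) stop("empty motif pattern")

  rx <- paste0("(?=", paste0(ifelse(pch == "X", "[A-Z]", pch), collapse = ""),
               ")")
  starts <- integer(0)
  if (nchar(s) >= length(pch)) {
    m <- gregexpr(rx, s, perl = TRUE)[[1]]
    if (m[1] != -1) starts <- as.integer(m)
  }
  d_off <- if (any(pch == "D")) max(which(pch == "D")) - 1L else NA_integer_
  e_off <- if (any(pch == "E")) max(which(pch == "E")) - 1L else NA_integer_
  out <- if (length(starts) == 0) {
    data.frame(start = integer(0), end = integer(0), matched = character(0),
               last_asp = integer(0), glu = integer(0),
               stringsAsFactors = FALSE)
  } else {
    data.frame(
      start = starts,
      end = starts + length(pch) - 1L,
      matched = substring(s, starts, starts + length(pch) - 1L),
      last_asp = starts + d_off,
      glu = starts + e_off,
      stringsAsFactors = FALSE
    )
  }
  class(out) <- c("motif_match", class(out))
  out
}

#' Catalytic residue positions of motif matches
#'
#' For the GH18 `DXXDXDXE` motif a match starting at residue s places the
#' substrate-binding aspartate at s+5 and the catalytic glutamate at s+7.
#'
#' @param match a `motif_match` data.frame from [find_motif()].
#' @return data.frame with columns `last_asp` and `glu` (1-based indices).
#' @export
catalytic_residues <- function(match) {
  stopifnot(inherits(match, "motif_match") || is.data.frame(match))
  match[, c("last_asp", "glu"), drop = FALSE]
}

#' Average molecular weight of a protein sequence
#'
#' Sum of standard average residue masses plus one water (the condensation
#' identity: a free amino acid is its residue mass plus water). Empty
#' sequences and unknown residues are rejected.
#'
#' @param sequence amino-acid string over the 20 one-letter codes.
#' @return molecular weight in Da.
#' @export
protein_mw <- function(sequence) {
  s <- validate_sequence(sequence, allow_x = FALSE)
  if (nchar(s) == 0) stop("empty sequence has no molecular weight")
  ch <- strsplit(s, "")[[1]]
  sum(AA_MASSES[ch]) + WATER_MASS
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), names(set))
}
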