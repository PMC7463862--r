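#' Radial distribution function between two atom selections
#'
#' Histograms all cross-pair distances between two selections over every
#' frame. In `"shell-volume"` mode counts are divided by the spherical
#' shell volume `4 pi r^2 dr` and by the mean pair density inside the
#' `r_max` sphere, so an ideal gas gives g(r) ~ 1; in `"counts-only"` mode
#' the normalized histogram (summing to 1) is returned. When the two
#' selections are identical, unique unordered pairs are used (self-RDF);
#' partially overlapping selections are rejected.
#'
#' @param traj a `trajectory` (or a single `molecular_system`).
#' @param sel_a,sel_b atom selections (see [select_atoms()]).
#' @param bin_width histogram bin width, Angstrom.
#' @param r_max histogram range, Angstrom.
#' @param normalization `"shell-volume"` or `"counts-only"`.
#' @param box optional periodic box lengths (3-vector, Angstrom) for
#'   minimum-image distances; intended for homogeneous-fluid validation,
#'   not for compact complexes.
#' @return object of class `rdf_profile` with fields `bin_edges`, `g`,
#'   `raw_counts`, `n_frames`, `n_pairs`, `normalization`.
#' @export
radial_distribution <- function(traj, sel_a, sel_b, bin_width = 0.05,
                                r_max = 8,
                                normalization = c("shell-volume",
                                                  "counts-only"),
                                box = NULL) {
  normalization <- match.arg(normalization)
  stopifnot(bin_width > 0, r_max > bin_width)
  if (inherits(traj, "molecular_system")) {
    traj <- trajectory(traj, list(coords(traj)))
  }
  stopifnot(inherits(traj, "trajectory"))
  ia <- as.integer(sel_a); ib <- as.integer(sel_b)
  if (length(ia) < 1 || length(ib) < 1) stop("empty selection")
  self_mode <- setequal(ia, ib)
  if (!self_mode && length(intersect(ia, ib)) > 0) {
    stop("selections overlap but are not identical; use disjoint selections ",
         "or the same selection twice for a self-RDF")
  }
  edges <- seq(0, r_max, by = bin_width)
  if (edges[length(edges)] < r_max) edges <- c(edges, edges[length(edges)] + bin_width)
  nbin <- length(edges) - 1
  counts <- numeric(nbin)
  nf <- n_frames(traj)

  ext <- apply(traj$frames[[1]], 2, function(v) diff(range(v)))
  if (is.null(box) && r_max > sqrt(sum(ext^2))) {
    warning("r_max (", r_max, " A) exceeds the first frame's bounding ",
            "sphere; outer bins can never be populated")
  }

  for (f in seq_len(nf)) {
    xyz <- traj$frames[[f]]
    d <- cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE],
                         box = box)
    if (self_mode) d <- d[upper.tri(d)]
    d <- d[d < r_max]
    if (length(d) > 0) {
      counts <- counts + tabulate(pmin(floor(d / bin_width) + 1L, nbin),
                                  nbins = nbin)
    }
  }
  n_pairs <- if (self_mode) length(ia) * (length(ia) - 1) / 2 else
    length(ia) * length(ib)

  r_mid <- (edges[-1] + edges[-length(edges)]) / 2
  if (normalization == "shell-volume") {
    mean_counts <- counts / nf
    density <- sum(mean_counts) / ((4 / 3) * pi * r_max^3)
    shell <- 4 * pi * r_mid^2 * bin_width
    g <- if (density > 0) mean_counts / (shell * density) else numeric(nbin)
  } else {
    total <- sum(counts)
    g <- if (total > 0) counts / total else counts
  }
  structure(list(bin_edges = edges, g = g, raw_counts = counts,
                 n_frames = nf, n_pairs = n_pairs,
                 normalization = normalization),
            class = "rdf_profile")
}

#' @export
print.rdf_profile <- function(x, ...) {
  cat(sprintf("<rdf_profile: %d bins to %.2f A, %d frames, %d pairs/frame (%s)>\n",
              length(x$g), max(x$bin_edges), x$n_frames, x$n_pairs,
              x$normalization))
  if (any(x$g > 0)) cat(sprintf("  peak at %.3f A\n", rdf_peak(x)))
  invisible(x)
}

#' Peak position of an RDF profile
#'
#' Center of the bin with maximal g; ties are broken toward smaller r.
#'
#' @param profile an `rdf_profile`.
#' @return peak position, Angstrom.
#' @export
rdf_peak <- function(profile) {
  stopifnot(inherits(profile, "rdf_profile"))
  if (all(profile$g == 0)) stop("all-zero RDF profile has no peak")
  i <- which.max(profile$g)  # which.max takes the first (smallest-r) maximum
  (profile$bin_edges[i] + profile$bin_edges[i + 1]) / 2
}

#' Distance-criterion hydrogen-bond occupancy
#'
#' A frame counts as hydrogen-bonded when the minimum donor-acceptor
#' cross-pair distance is at or below `cutoff`. Purely geometric
#' (distance-only, no angle term), matching the 3.0-Angstrom
#' donor-acceptor convention used for the Asp-carboxylate /
#' GlcNAc-amide-nitrogen contact.
#'
#' @param traj a `trajectory`.
#' @param donors,acceptors atom selections.
#' @param cutoff distance criterion, Angstrom.
#' @return object of class `hbond_report`: `cutoff`, `frame_bonded`
#'   (logical per frame), `occupancy` (fraction of frames), and
#'   `min_distance` (per-frame minimum cross distance, Angstrom).
#' @export
hbond_occupancy <- function(traj, donors, acceptors, cutoff = 3.0) {
  stopifnot(inherits(traj, "trajectory"), cutoff > 0)
  ia <- as.integer(donors); ib <- as.integer(acceptors)
  if (length(ia) < 1 || length(ib) < 1) stop("empty selection")
  mind <- vapply(traj$frames, function(xyz) {
    min(cross_distances(xyz[ia, , drop = FALSE], xyz[ib, , drop = FALSE]))
  }, numeric(1))
  bonded <- mind <= cutoff
  structure(list(cutoff = cutoff, frame_bonded = bonded,
                 occupancy = mean(bonded), min_distance = mind),
            class = "hbond_report")
}

#' @export
print.hbond_report <- function(x, ...) {
  cat(sprintf("<hbond_report: occupancy %.3f at cutoff %.2f A over %d frames>\n",
              x$occupancy, x$cutoff, length(x$frame_bonded)))
  invisible(x)
}
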