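#' Canonical microstate template maps
#'
#' Deterministically constructs the four canonical microstate topographies
#' A-D on a montage, realizing the classical symmetry geometries: A and B
#' are mirror-image diagonal gradients (right-left and left-right
#' asymmetry), C is an anterior-posterior gradient (horizontal symmetry)
#' and D is a radial, vertex-centred profile (circular symmetry). Each map
#' is a linear function of electrode position, then centred across channels
#' and scaled to unit Euclidean norm.
#'
#' @param montage an `eeg_montage` with electrode positions
#' @return object of class `microstate_templates`: list with `maps`
#'   (channels x 4 matrix, columns `A`..`D`, zero channel mean, unit norm)
#'   and `class_ids`.
#' @export
synth_templates <- function(montage) {
  validate_montage(montage)
  p <- montage$positions
  ## diagonal gradient axes in the horizontal plane, azimuth from +y (nasion)
  axis_map <- function(azim_deg) {
    a <- azim_deg * pi / 180
    normalize_map(p[, "x"] * sin(a) + p[, "y"] * cos(a))
  }
  ## A/B axes at +-60 degrees from the midline: the lateral-dominant
  ## diagonals balance the pairwise map correlations (A-B and A-C/B-C all
  ## +-0.5 on this montage); a pure left-right gradient and its mirror
  ## would be perfectly anticorrelated
  maps <- cbind(
    A = axis_map(60),            # right-frontal / left-posterior diagonal
    B = axis_map(-60),           # mirror image of A
    C = axis_map(0),             # anterior-posterior gradient
    D = normalize_map(p[, "z"])  # radial distance-from-vertex profile
  )
  rownames(maps) <- montage$channel_names
  structure(list(maps = maps, class_ids = c("A", "B", "C", "D")),
            class = "microstate_templates")
}

#' @export
print.microstate_templates <- function(x, ...) {
  cat("<microstate_templates> classes ",
      paste(x$class_ids, collapse = ""), " on ", nrow(x$maps),
      " channels\n", sep = "")
  invisible(x)
}

#' Candidate template banks for the combination search
#'
#' Generates the per-class candidate template sets fed to
#' [search_template_combinations()]. Each class's candidates are parametric
#' perturbations of its canonical map: the defining gradient axis of A, B
#' and C is rotated over an evenly spaced fan of azimuth angles, and D's
#' radial profile is raised to a fan of sharpness exponents. The default
#' counts (7, 5, 6, 3) give 7 x 5 x 6 x 3 = 630 initialization combinations.
#'
#' @param montage an `eeg_montage`
#' @param counts integer vector of candidate counts per class (A, B, C, D)
#' @param fan_deg half-width in degrees of the rotation fan for A-C
#' @return named list (`A`..`D`) of lists of zero-mean unit-norm channel maps
#' @export
candidate_templates <- function(montage, counts = c(7L, 5L, 6L, 3L),
                                fan_deg = 30) {
  validate_montage(montage)
  stopifnot(length(counts) == 4L, all(counts >= 1L))
  p <- montage$positions
  axis_map <- function(azim_deg) {
    a <- azim_deg * pi / 180
    normalize_map(p[, "x"] * sin(a) + p[, "y"] * cos(a))
  }
  fan <- function(center, n) {
    if (n == 1L) return(center)
    center + seq(-fan_deg, fan_deg, length.out = n)
  }
  radial <- function(k) normalize_map((pmax(p[, "z"], 0) + 0.25)^k)
  list(
    A = lapply(fan(60, counts[1]), axis_map),
    B = lapply(fan(-60, counts[2]), axis_map),
    C = lapply(fan(0, counts[3]), axis_map),
    D = lapply(seq_len(counts[4]), radial)
  )
}

#' Mirror a channel map across the sagittal midline
#'
#' Swaps every channel value with its left-right homologue (midline
#' channels are unchanged), e.g. turning a microstate-A-like diagonal
#' topography into its B-like mirror image.
#'
#' @param map numeric channel vector in montage order
#' @param montage an `eeg_montage`
#' @return mirrored channel vector
#' @export
mirror_map <- function(map, montage) {
  idx <- match(montage$mirror, montage$channel_names)
  out <- map[idx]
  names(out) <- montage$channel_names
  out
}
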