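#' Morpho-colorimetric feature profile of a digital plant
#'
#' Computes the eight shape/intensity descriptors used to profile each
#' seedling:
#'
#' * `area`: pixel count of the digital plant;
#' * `perimeter`: polygonal length of the traced outer contour (Moore
#'   neighbour tracing; axis steps count 1, diagonal steps `sqrt(2)`;
#'   interior holes are ignored);
#' * `circularity`: normalised isoperimetric ratio
#'   `4*pi*area / perimeter^2` (1 for a disk, towards 0 for elongated
#'   objects). The raw perimeter-squared-over-area ratio is also
#'   returned as `circularity_raw`;
#' * `compactness`: `area / perimeter`;
#' * `major_axis`, `minor_axis`: full axis lengths of the
#'   equivalent ellipse derived from the second central moments of the
#'   pixel set (`4 * sqrt(eigenvalue)`), i.e. the axis about which the
#'   shape needs least effort to rotate. Each pixel is treated as a unit
#'   square (its own `1/12` moment is included), so the minor axis is
#'   strictly positive even for 1-pixel-wide objects;
#' * `eccentricity`: `major_axis / minor_axis`, always `>= 1`;
#' * `hisgreypeak`: the modal grayscale intensity of the plant pixels
#'   (the highest peak of the intensity histogram; the lowest intensity
#'   wins ties).
#'
#' Plants with fewer than 4 pixels are flagged `degenerate`; their
#' contour may collapse to a point (perimeter 0), in which case
#' circularity and compactness are `NA`. No input raises an error.
#' If the pixel set is disconnected (possible for merged shoot+root
#' plants when erosion opens a small gap), the traced perimeter is that
#' of the topmost connected part; the moment-based features always use
#' the full pixel set.
#'
#' @param plant a [digital_plant()] or a 2-column `(x, y)` coordinate
#'   matrix (0-based).
#' @param gray intensity raster covering the plant (for `hisgreypeak`);
#'   may be `NULL`, in which case `hisgreypeak` is `NA`.
#' @return A one-row data frame of class `morpho_profile`.
#' @export
compute_morphology <- function(plant, gray = NULL) {
  coords <- if (inherits(plant, "digital_plant")) plant$coords else plant
  area <- nrow(coords)
  stopifnot(area >= 1)
  # outer contour on a padded bounding-box mask
  x0 <- min(coords[, 1]); y0 <- min(coords[, 2])
  sub <- matrix(FALSE, max(coords[, 2]) - y0 + 3L,
                max(coords[, 1]) - x0 + 3L)
  sub[cbind(coords[, 2] - y0 + 2L, coords[, 1] - x0 + 2L)] <- TRUE
  perim <- trace_contour_cpp(sub)$perimeter
  # second central moments with the unit-square pixel term
  mx <- mean(coords[, 1]); my <- mean(coords[, 2])
  dx <- coords[, 1] - mx; dy <- coords[, 2] - my
  cxx <- mean(dx * dx) + 1 / 12
  cyy <- mean(dy * dy) + 1 / 12
  cxy <- mean(dx * dy)
  tr <- (cxx + cyy) / 2
  det <- sqrt(((cxx - cyy) / 2)^2 + cxy^2)
  l1 <- tr + det; l2 <- max(tr - det, 0)
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  peak <- NA_integer_
  if (!is.null(gray)) {
    g <- gray[cbind(coords[, 2] + 1L, coords[, 1] + 1L)]
    counts <- tabulate(g + 1L, 256L)
    peak <- which.max(counts) - 1L  # which.max takes the first (lowest) mode
  }
  out <- data.frame(
    area = area,
    perimeter = perim,
    circularity = if (perim > 0) 4 * pi * area / perim^2 else NA_real_,
    circularity_raw = if (area > 0 && perim > 0) perim^2 / area else NA_real_,
    compactness = if (perim > 0) area / perim else NA_real_,
    major_axis = major,
    minor_axis = minor,
    eccentricity = major / minor,
    hisgreypeak = peak,
    degenerate = area < 4)
  class(out) <- c("morpho_profile", class(out))
  out
}

#' Hue-class histogram of a digital plant
#'
#' The hue channel is divided into `K` equal classes (`floor(H * K / 256)`
#' on the 8-bit hue scale) and each plant pixel is classified; the profile
#' is the vector of class fractions, which always sums to 1. Achromatic
#' pixels carry hue 0 and fall in class 0 unless `exclude_achromatic` is
#' set.
#'
#' @inheritParams compute_morphology
#' @param hsb an [rgb_to_hsb()] result covering the plant.
#' @param K number of hue classes (16 for salt/arsenic, 32 for freezing).
#' @param exclude_achromatic drop pixels with saturation 0 before
#'   classifying (default `FALSE`).
#' @return Named numeric vector `hue_00 ... hue_<K-1>` of fractions.
#' @export
hue_class_histogram <- function(plant, hsb, K = 16,
                                exclude_achromatic = FALSE) {
  stopifnot(K >= 2)
  coords <- if (inherits(plant, "digital_plant")) plant$coords else plant
  idx <- cbind(coords[, 2] + 1L, coords[, 1] + 1L)
  h <- hsb$H[idx]
  if (exclude_achromatic) h <- h[hsb$S[idx] > 0]
  cls <- floor(h * K / 256)
  frac <- tabulate(cls + 1L, K)
  frac <- if (length(h)) frac / length(h) else rep(0, K)
  names(frac) <- sprintf("hue_%02d", 0:(K - 1))
  frac
}

#' Yellowish leaf-damage fraction (freezing assay)
#'
#' Freezing damage bleaches leaf tissue from green towards yellow, so the
#' fraction of a seedling's pixels falling in the low-hue (red-through-
#' yellow) classes is used as a damage index. With 32 hue classes of
#' width 8 on the `[0, 255]` scale, the damage set is the five lowest
#' bins (centres 4, 12, 20, 28, 36), i.e. hue in `[0, 40)`. A seedling is
#' called damaged when strictly more than half of its pixels are
#' yellowish.
#'
#' @inheritParams hue_class_histogram
#' @param classes 0-based indices of the yellowish hue bins.
#' @param K number of hue classes.
#' @return List with `fraction` in `[0, 1]` and logical `damaged`
#'   (`fraction > 0.5`).
#' @export
yellow_damage_fraction <- function(plant, hsb, classes = 0:4, K = 32) {
  frac <- hue_class_histogram(plant, hsb, K = K)
  f <- sum(frac[classes + 1L])
  list(fraction = f, damaged = f > 0.5)
}

# hue bins regarded as green tissue, used to give the two colour-cluster
# groups their alive/germinated semantics: hue in [64, 128) on the 8-bit
# scale (90 - 180 degrees)
green_class_indices <- function(K) {
  cls <- 0:(K - 1)
  lo <- cls * 256 / K
  hi <- (cls + 1) * 256 / K
  which(hi > 64 & lo < 128)  # 1-based indices into the histogram
}
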