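#' Object filter specification
#'
#' Geometric acceptance bounds applied to labeled components before they
#' become digital plants. All comparisons are strict, exactly as the
#' thresholds are printed in the assay configs: `area > min_area`,
#' `area < max_area`, `circ_min < circularity < circ_max`,
#' `distance < max_dist_to_center`. Circularity is the normalised
#' isoperimetric ratio `4*pi*area / perimeter^2` (1 for a disk, towards 0
#' for elongated objects such as roots); see [compute_morphology()].
#'
#' @param min_area minimum pixel count (strict), >= 0.
#' @param max_area optional maximum pixel count (strict).
#' @param circ_min,circ_max optional circularity bounds (strict).
#' @param max_dist_to_center optional maximum Euclidean distance (pixels,
#'   strict) from the component centroid to the nearest layout reference
#'   point.
#' @return An object of class `object_filter_spec`.
#' @export
object_filter_spec <- function(min_area = 0, max_area = NULL,
                               circ_min = NULL, circ_max = NULL,
                               max_dist_to_center = NULL) {
  stopifnot(min_area >= 0)
  if (!is.null(max_area) && max_area <= min_area)
    stop("max_area must exceed min_area")
  if (!is.null(circ_min) && !is.null(circ_max) && circ_max <= circ_min)
    stop("circ_max must exceed circ_min")
  structure(list(min_area = min_area, max_area = max_area,
                 circ_min = circ_min, circ_max = circ_max,
                 max_dist_to_center = max_dist_to_center),
            class = "object_filter_spec")
}

#' Filter labeled components by geometry and position
#'
#' Removes components violating any bound of the filter spec. Distance is
#' measured from the component centroid to the nearest layout reference
#' point ([plate_layout()]'s `dist_centers` when present, else the seed
#' cell centres); every survivor is annotated with its nearest *seed*
#' cell, which downstream selection and merging use.
#'
#' Components whose traced perimeter is zero (isolated pixels) have
#' undefined circularity and are rejected whenever a circularity bound is
#' set.
#'
#' @param components a [label_components()] result.
#' @param spec an [object_filter_spec()].
#' @param layout a [plate_layout()]; required when `max_dist_to_center`
#'   is set.
#' @return A `labeled_components` object whose `summary` keeps only
#'   surviving components, gaining columns `perimeter`, `circularity`,
#'   `cell` and `dist_to_center`.
#' @export
filter_objects <- function(components, spec, layout = NULL) {
  s <- components$summary
  if (!nrow(s)) return(components)
  keep <- s$area > spec$min_area
  if (!is.null(spec$max_area)) keep <- keep & s$area < spec$max_area
  need_circ <- !is.null(spec$circ_min) || !is.null(spec$circ_max)
  s$perimeter <- NA_real_
  s$circularity <- NA_real_
  if (need_circ) {
    cand <- which(keep)
    for (i in cand) {
      p <- component_perimeter(components, s$label[i])
      s$perimeter[i] <- p
      s$circularity[i] <- if (p > 0) 4 * pi * s$area[i] / p^2 else NA_real_
    }
    if (!is.null(spec$circ_min))
      keep <- keep & !is.na(s$circularity) & s$circularity > spec$circ_min
    if (!is.null(spec$circ_max))
      keep <- keep & !is.na(s$circularity) & s$circularity < spec$circ_max
  }
  s$cell <- NA_integer_
  s$dist_to_center <- NA_real_
  if (!is.null(spec$max_dist_to_center)) {
    if (is.null(layout))
      stop("distance filtering requires a plate layout with cell centres")
    nd <- nearest_center(layout, s$cx, s$cy)
    s$dist_to_center <- nd$dist
    keep <- keep & nd$dist < spec$max_dist_to_center
  }
  if (!is.null(layout)) {
    nc <- nearest_cell(layout, s$cx, s$cy)
    s$cell <- nc$cell
  }
  out <- components
  out$summary <- s[keep, , drop = FALSE]
  out
}

#' Digital plant
#'
#' The set of image pixels segmented as one seedling, with its plate
#' bookkeeping. `coords` is a 2-column integer matrix of 0-based `(x, y)`
#' pixel coordinates; `parts` optionally splits the pixel set into shoot
#' and root for merged phosphate plants.
#'
#' @param coords 2-column `(x, y)` matrix.
#' @param cell seed-cell index or `NA` (round plates).
#' @param line_id mutant line id.
#' @param parts named list of coordinate matrices (`shoot`, `root`).
#' @param plate_id plate identifier.
#' @return An object of class `digital_plant`.
#' @export
digital_plant <- function(coords, cell = NA_integer_, line_id = NA_character_,
                          parts = NULL, plate_id = NA_character_) {
  if (!nrow(coords)) stop("a digital plant needs a non-empty pixel set")
  structure(list(coords = coords,
                 centroid = c(x = mean(coords[, 1]), y = mean(coords[, 2])),
                 cell = cell, line_id = line_id, parts = parts,
                 plate_id = plate_id),
            class = "digital_plant")
}

#' @export
print.digital_plant <- function(x, ...) {
  cat(sprintf("<digital_plant> line %s, cell %s, %d px\n",
              x$line_id, x$cell, nrow(x$coords)))
  invisible(x)
}

#' Keep the largest object in each grid cell
#'
#' Each seedling must end up represented by exactly one object, so within
#' each seed cell only the maximum-area component survives. Ties go to
#' the lowest component label (raster-scan order), a deterministic
#' tie-break. Cells with no surviving object are absent from the result
#' (the seedling counts as not detected downstream).
#'
#' @param components a [filter_objects()] result (components annotated
#'   with cells).
#' @param layout a [plate_layout()] supplying `cell_to_line`.
#' @param plate_id carried into each plant.
#' @return Named list (by cell index) of [digital_plant()] objects.
#' @export
select_largest_per_cell <- function(components, layout, plate_id = NA) {
  s <- components$summary
  if (!nrow(s)) return(structure(list(), names = character(0)))
  if (all(is.na(s$cell))) stop("components carry no cell annotation; ",
                               "run filter_objects() with a layout first")
  s <- s[order(s$cell, -s$area, s$label), ]
  s <- s[!duplicated(s$cell), ]
  out <- lapply(seq_len(nrow(s)), function(i) {
    digital_plant(component_coords(components, s$label[i]),
                  cell = s$cell[i],
                  line_id = layout$cell_to_line[match(s$cell[i],
                                                      layout$cell_centers$cell)],
                  plate_id = plate_id)
  })
  names(out) <- as.character(s$cell)
  out
}

#' Merge shoot and root objects into whole plants
#'
#' On vertical phosphate plates the shoot and root of a seedling are
#' segmented separately (different masks) and must be re-joined. Each
#' shoot is paired with at most one root lying in the same grid column
#' (the embossed vertical lines of the plate are the column reference)
#' whose topmost pixel is the nearest below the shoot centroid; the
#' merged plant is the union of both pixel sets. Shoots with no root in
#' their column become shoot-only plants; unpaired roots are dropped.
#'
#' @param shoots,roots [filter_objects()] results for the shoot and root
#'   masks (annotated with cells).
#' @param layout a [plate_layout()] whose cell x-positions define the
#'   grid columns.
#' @param plate_id carried into each plant.
#' @return List of [digital_plant()] objects with `parts$shoot` /
#'   `parts$root` filled in.
#' @export
merge_shoot_root <- function(shoots, roots, layout, plate_id = NA) {
  ss <- shoots$summary
  rs <- roots$summary
  if (!nrow(ss)) return(list())
  col_x <- sort(unique(layout$cell_centers$cx))
  col_of <- function(cx) vapply(cx, function(v) which.min(abs(col_x - v)),
                                integer(1))
  ss$col <- col_of(ss$cx)
  if (nrow(rs)) rs$col <- col_of(rs$cx)
  used_roots <- integer(0)
  plants <- vector("list", nrow(ss))
  for (i in seq_len(nrow(ss))) {
    sc <- component_coords(shoots, ss$label[i])
    rc <- NULL
    if (nrow(rs)) {
      cand <- which(rs$col == ss$col[i] & rs$ymin > ss$cy[i] &
                      !(rs$label %in% used_roots))
      if (length(cand)) {
        j <- cand[which.min(rs$ymin[cand] - ss$cy[i])]
        rc <- component_coords(roots, rs$label[j])
        used_roots <- c(used_roots, rs$label[j])
      }
    }
    coords <- if (is.null(rc)) sc else unique(rbind(sc, rc))
    plants[[i]] <- digital_plant(
      coords, cell = ss$cell[i],
      line_id = layout$cell_to_line[match(ss$cell[i],
                                          layout$cell_centers$cell)],
      parts = list(shoot = sc, root = rc), plate_id = plate_id)
  }
  plants
}
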