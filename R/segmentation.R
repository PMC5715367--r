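#' Local mean thresholding for dark objects on a bright backlit field
#'
#' A pixel is foreground iff its intensity is below the mean intensity of
#' the surrounding `(2*radius + 1)^2` window minus `offset`. The window is
#' clipped at image borders (means are taken over the in-image part), so
#' the operator is well defined everywhere. Implemented with an integral
#' image, so cost is independent of the radius.
#'
#' If `radius` is at least as large as both image dimensions the local
#' mean equals the global mean everywhere and the operator degrades to
#' global-mean thresholding (a message is emitted).
#'
#' @param gray integer/numeric intensity matrix.
#' @param radius window half-width in pixels (default 15).
#' @param offset intensity offset subtracted from the local mean
#'   (default 0); raising it suppresses faint background texture.
#' @return Logical foreground mask with a `"provenance"` attribute.
#' @export
local_mean_threshold <- function(gray, radius = 15, offset = 0) {
  if (radius < 1) stop("`radius` must be >= 1")
  H <- nrow(gray); W <- ncol(gray)
  if (radius >= H && radius >= W)
    message("local_mean_threshold: radius >= image size, ",
            "falling back to the global mean")
  # integral image with a zero top row / left column
  ii <- rbind(0, cbind(0, t(apply(apply(gray, 2, cumsum), 1, cumsum))))
  y0 <- pmax(seq_len(H) - radius - 1, 0)      # exclusive lower row bound
  y1 <- pmin(seq_len(H) + radius, H)
  x0 <- pmax(seq_len(W) - radius - 1, 0)
  x1 <- pmin(seq_len(W) + radius, W)
  sums <- ii[y1 + 1, x1 + 1] - ii[y0 + 1, x1 + 1] -
    ii[y1 + 1, x0 + 1] + ii[y0 + 1, x0 + 1]
  counts <- outer(y1 - y0, x1 - x0)
  mask <- gray < (sums / counts - offset)
  attr(mask, "provenance") <-
    sprintf("local_mean_threshold(radius=%g, offset=%g)", radius, offset)
  mask
}

#' Connected-component labeling
#'
#' Partitions the foreground of a binary mask into maximal connected
#' components (8-connectivity by default, matching contour-tracing
#' labelers; 4-connectivity available). Components are labeled 1, 2, ...
#' in raster-scan order of their first pixel, which also fixes the
#' deterministic tie-break used by [select_largest_per_cell()].
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return An object of class `labeled_components`: a list with `labels`
#'   (integer matrix, 0 = background), and `summary`, a data frame with
#'   one row per component (label, area, bounding box, centroid; all
#'   coordinates 0-based, x = column, y = row).
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask))
  storage.mode(mask) <- "logical"
  mask[is.na(mask)] <- FALSE
  lab <- cc_label_cpp(mask, as.integer(connectivity))
  n <- max(lab)
  if (n == 0L) {
    summ <- data.frame(label = integer(0), area = integer(0),
                       xmin = integer(0), xmax = integer(0),
                       ymin = integer(0), ymax = integer(0),
                       cx = numeric(0), cy = numeric(0))
  } else {
    idx <- which(lab > 0L)
    l <- lab[idx]
    y <- (idx - 1L) %% nrow(lab)       # 0-based row
    x <- (idx - 1L) %/% nrow(lab)      # 0-based column
    summ <- data.frame(
      label = seq_len(n),
      area = as.integer(tabulate(l, n)),
      xmin = as.integer(tapply(x, l, min)),
      xmax = as.integer(tapply(x, l, max)),
      ymin = as.integer(tapply(y, l, min)),
      ymax = as.integer(tapply(y, l, max)),
      cx = as.numeric(tapply(x, l, mean)),
      cy = as.numeric(tapply(y, l, mean)))
  }
  structure(list(labels = lab, summary = summ, connectivity = connectivity),
            class = "labeled_components")
}

#' @export
print.labeled_components <- function(x, ...) {
  cat(sprintf("<labeled_components> %d component(s), %d-connectivity\n",
              nrow(x$summary), x$connectivity))
  invisible(x)
}

#' Pixel coordinates of one labeled component
#'
#' @param lc a [label_components()] result.
#' @param label component label.
#' @return Two-column integer matrix of 0-based `(x, y)` coordinates.
#' @export
component_coords <- function(lc, label) {
  idx <- which(lc$labels == label)
  cbind(x = as.integer((idx - 1L) %/% nrow(lc$labels)),
        y = as.integer((idx - 1L) %% nrow(lc$labels)))
}

# Binary mask (bounding box + 1 px pad) for one component.
component_mask <- function(lc, label) {
  s <- lc$summary[lc$summary$label == label, ]
  sub <- lc$labels[(s$ymin:s$ymax) + 1L, (s$xmin:s$xmax) + 1L,
                   drop = FALSE] == label
  out <- matrix(FALSE, nrow(sub) + 2L, ncol(sub) + 2L)
  out[2:(nrow(sub) + 1L), 2:(ncol(sub) + 1L)] <- sub
  attr(out, "origin") <- c(x = s$xmin - 1L, y = s$ymin - 1L)
  out
}

# Outer-contour polygonal perimeter of one component (axis steps 1,
# diagonal steps sqrt(2), Moore tracing).
component_perimeter <- function(lc, label) {
  trace_contour_cpp(component_mask(lc, label))$perimeter
}

#' Binary erosion with a 3x3 square structuring element
#'
#' A foreground pixel survives iff all 8 neighbours (image border counts
#' as background) are foreground. Applied `px` times.
#'
#' @param mask logical matrix.
#' @param px number of 1-pixel erosion passes.
#' @return Logical matrix.
#' @export
erode_mask <- function(mask, px = 1) {
  H <- nrow(mask); W <- ncol(mask)
  for (i in seq_len(px)) {
    padded <- matrix(FALSE, H + 2L, W + 2L)
    padded[2:(H + 1L), 2:(W + 1L)] <- mask
    acc <- matrix(TRUE, H, W)
    for (dy in -1:1) for (dx in -1:1) {
      acc <- acc & padded[(2:(H + 1L)) + dy, (2:(W + 1L)) + dx]
    }
    mask <- acc
  }
  mask
}

clear_long_runs <- function(mask, max_run, margin = 1) {
  # margin = 1: horizontal runs (within rows); margin = 2: vertical runs
  if (margin == 2) return(t(clear_long_runs(t(mask), max_run, 1)))
  for (i in seq_len(nrow(mask))) {
    r <- rle(mask[i, ])
    kill <- r$values & r$lengths > max_run
    if (any(kill)) {
      r$values <- r$values & !kill
      mask[i, ] <- inverse.rle(r)
    }
  }
  mask
}

#' Remove embossed-grid artifacts from a foreground mask
#'
#' The grid embossed on vertical phosphate plates shows up in the
#' local-threshold mask as long straight runs. Cleanup proceeds in the
#' order: (1) contiguous horizontal foreground runs longer than
#' `max_h_run` pixels are cleared; (2) vertical runs longer than
#' `max_v_run` are cleared; (3) `erode_px` passes of 3x3 binary erosion;
#' (4) all rows inside the excluded y-bands (inclusive, 0-based) are
#' cleared. Defaults are the phosphate assay constants (h > 50 px,
#' v > 240 px, 1 px erosion, border bands 50-260 and 1698-1798).
#'
#' @param mask logical matrix.
#' @param max_h_run,max_v_run maximum run lengths kept, in pixels.
#' @param erode_px erosion passes.
#' @param excluded_row_bands list of `c(y_lo, y_hi)` 0-based inclusive
#'   row bands to clear; bands beyond the image height are clipped with
#'   a warning.
#' @return Logical matrix, a subset of the input foreground.
#' @export
remove_grid_artifacts <- function(mask, max_h_run = 50, max_v_run = 240,
                                  erode_px = 1,
                                  excluded_row_bands = list(c(50, 260),
                                                            c(1698, 1798))) {
  stopifnot(max_h_run >= 0, max_v_run >= 0, erode_px >= 0)
  mask <- clear_long_runs(mask, max_h_run, margin = 1)
  mask <- clear_long_runs(mask, max_v_run, margin = 2)
  if (erode_px > 0) mask <- erode_mask(mask, erode_px)
  H <- nrow(mask)
  for (band in excluded_row_bands) {
    if (band[1] >= H) {
      warning("excluded row band beyond image height; skipped")
      next
    }
    if (band[2] >= H) {
      warning("excluded row band clipped at image height")
      band[2] <- H - 1L
    }
    mask[(band[1]:band[2]) + 1L, ] <- FALSE
  }
  mask
}
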