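#' Plate layout description
#'
#' Maps plate geometry to mutant-line identity. For square gridded plates
#' each grid cell holds one seed and `cell_to_line` names the line sown in
#' it (for the screen's design a whole plate carries one line, so all
#' cells map to the same id). Round freezing plates carry no per-cell
#' assignment: `shape = "round"`, seedlings are not mapped to cells and
#' the whole plate maps to one line.
#'
#' `dist_centers` optionally supplies a denser set of reference points
#' for the distance-to-cell-centre object filters. On vertical phosphate
#' plates the embossed grid is much finer than the seed spacing and
#' distances are measured to the nearest embossed-grid cell centre, which
#' keeps long roots (spanning several grid cells) inside the distance
#' bound. When omitted, `cell_centers` is used.
#'
#' @param shape `"square_grid"` or `"round"`.
#' @param n_rows,n_cols grid dimensions (seed positions).
#' @param cell_centers data frame with columns `cell` (1-based index),
#'   `cx`, `cy` (0-based pixel coordinates).
#' @param cell_to_line character vector of line ids, one per cell.
#' @param image_dims `c(H, W)` in pixels.
#' @param dist_centers optional 2-column matrix of reference points for
#'   distance filtering.
#' @return An object of class `plate_layout`.
#' @export
plate_layout <- function(shape = c("square_grid", "round"),
                         n_rows, n_cols, cell_centers, cell_to_line,
                         image_dims, dist_centers = NULL) {
  shape <- match.arg(shape)
  stopifnot(is.data.frame(cell_centers),
            all(c("cell", "cx", "cy") %in% names(cell_centers)))
  if (length(cell_to_line) != nrow(cell_centers))
    stop("`cell_to_line` must name one line per cell")
  if (any(cell_centers$cx < 0 | cell_centers$cx >= image_dims[2] |
          cell_centers$cy < 0 | cell_centers$cy >= image_dims[1]))
    stop("cell centers must lie inside the image")
  structure(list(shape = shape, n_rows = n_rows, n_cols = n_cols,
                 cell_centers = cell_centers,
                 cell_to_line = cell_to_line,
                 image_dims = image_dims,
                 dist_centers = dist_centers),
            class = "plate_layout")
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf("<plate_layout> %s %dx%d, %d cells, %d line(s)\n",
              x$shape, x$n_rows, x$n_cols, nrow(x$cell_centers),
              length(unique(x$cell_to_line))))
  invisible(x)
}

#' Regular square-grid layout
#'
#' Cell centres on a uniform `n_rows x n_cols` lattice centred in the
#' image, the usual geometry of gridded square Petri plates.
#'
#' @inheritParams plate_layout
#' @param line_id single line id, or one id per cell (row-major order).
#' @param pitch cell spacing in pixels; defaults to an even split of the
#'   smaller image dimension.
#' @param center_y optional row coordinate of the (single) seed row for
#'   vertical plates.
#' @return A [plate_layout].
#' @export
grid_layout <- function(n_rows, n_cols, image_dims, line_id = "line",
                        pitch = NULL, center_y = NULL,
                        dist_centers = NULL) {
  H <- image_dims[1]; W <- image_dims[2]
  pitch <- pitch %||% floor(min(H, W) / max(n_rows, n_cols))
  xs <- (seq_len(n_cols) - (n_cols + 1) / 2) * pitch + (W - 1) / 2
  ys <- if (!is.null(center_y) && n_rows == 1L) center_y
        else (seq_len(n_rows) - (n_rows + 1) / 2) * pitch + (H - 1) / 2
  cc <- expand.grid(col = seq_len(n_cols), row = seq_len(n_rows))
  centers <- data.frame(cell = seq_len(nrow(cc)),
                        cx = xs[cc$col], cy = ys[cc$row])
  lines <- if (length(line_id) == 1L) rep(line_id, nrow(centers)) else line_id
  plate_layout("square_grid", n_rows, n_cols, centers, lines, image_dims,
               dist_centers = dist_centers)
}

#' Round-plate layout (no grid cells)
#'
#' @inheritParams grid_layout
#' @param n_positions nominal number of sowing positions (bookkeeping
#'   only; detection on round plates does not assign cells).
#' @return A [plate_layout] with shape `"round"`.
#' @export
round_layout <- function(image_dims, line_id = "line", n_positions = 60) {
  centers <- data.frame(cell = 1L, cx = (image_dims[2] - 1) / 2,
                        cy = (image_dims[1] - 1) / 2)
  out <- plate_layout("round", 1L, 1L, centers, rep(line_id, 1L), image_dims)
  out$n_positions <- n_positions
  out
}

# nearest layout reference point for distance filtering
nearest_center <- function(layout, cx, cy, use_dist_centers = TRUE) {
  pts <- if (use_dist_centers && !is.null(layout$dist_centers))
    layout$dist_centers
  else as.matrix(layout$cell_centers[, c("cx", "cy")])
  d2 <- outer(cx, pts[, 1], "-")^2 + outer(cy, pts[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  list(dist = sqrt(d2[cbind(seq_along(cx), j)]), index = j)
}

# nearest seed cell (always cell_centers) for cell assignment
nearest_cell <- function(layout, cx, cy) {
  pts <- as.matrix(layout$cell_centers[, c("cx", "cy")])
  d2 <- outer(cx, pts[, 1], "-")^2 + outer(cy, pts[, 2], "-")^2
  j <- max.col(-d2, ties.method = "first")
  list(cell = layout$cell_centers$cell[j],
       dist = sqrt(d2[cbind(seq_along(cx), j)]))
}

#' Write / read a plate layout as YAML
#'
#' @param layout a [plate_layout].
#' @param path file path.
#' @return `read_layout_yaml` returns a [plate_layout].
#' @export
write_layout_yaml <- function(layout, path) {
  obj <- list(shape = layout$shape, n_rows = layout$n_rows,
              n_cols = layout$n_cols,
              image_dims = as.integer(layout$image_dims),
              cells = lapply(seq_len(nrow(layout$cell_centers)), function(i)
                list(cell = layout$cell_centers$cell[i],
                     cx = layout$cell_centers$cx[i],
                     cy = layout$cell_centers$cy[i],
                     line = layout$cell_to_line[i])))
  if (!is.null(layout$dist_centers))
    obj$dist_centers <- apply(layout$dist_centers, 1, as.list)
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_layout_yaml
#' @export
read_layout_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cells <- do.call(rbind, lapply(obj$cells, function(cl)
    data.frame(cell = cl$cell, cx = cl$cx, cy = cl$cy)))
  lines <- vapply(obj$cells, function(cl) as.character(cl$line), character(1))
  dc <- if (!is.null(obj$dist_centers))
    do.call(rbind, lapply(obj$dist_centers, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
  else NULL
  plate_layout(obj$shape, obj$n_rows, obj$n_cols, cells, lines,
               as.numeric(obj$image_dims), dist_centers = dc)
}
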