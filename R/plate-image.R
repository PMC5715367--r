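# channel extraction that never drops dimensions
chan <- function(px, i) matrix(px[, , i], dim(px)[1], dim(px)[2])

#' Plate image container
#'
#' An 8-bit RGB photograph of one assay plate, together with the metadata
#' the pipeline needs: imaging modality (visible light `"VIS"` or
#' chlorophyll-fluorescence `"FLUO"`), assay, growth condition and a plate
#' identifier. Pixels are stored as an `H x W x 3` integer array with
#' channel values in `[0, 255]`; the first array index is the image row
#' (y, increasing downwards), the second the column (x, increasing
#' rightwards), both 0-based in all coordinate outputs.
#'
#' @param pixels `H x W x 3` numeric array, channels R, G, B in `[0, 255]`.
#' @param modality `"VIS"` or `"FLUO"`. The freezing and phosphate assays
#'   are imaged in visible light only.
#' @param assay one of `"salt"`, `"arsenic"`, `"freezing"`, `"phosphate"`.
#' @param condition `"stress"` (default) or `"standard"`.
#' @param plate_id character scalar used in records and log messages.
#' @return An object of class `plate_image`.
#' @export
plate_image <- function(pixels, modality = c("VIS", "FLUO"),
                        assay = c("salt", "arsenic", "freezing", "phosphate"),
                        condition = c("stress", "standard"),
                        plate_id = "plate") {
  modality <- match.arg(modality)
  assay <- match.arg(assay)
  condition <- match.arg(condition)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (any(dim(pixels)[1:2] < 1L)) stop("image dimensions must be positive")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("channel values must lie in [0, 255]")
  if (modality == "FLUO" && assay %in% c("freezing", "phosphate"))
    stop(sprintf("the %s assay is imaged in visible light only", assay))
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels, modality = modality, assay = assay,
                 condition = condition, plate_id = plate_id),
            class = "plate_image")
}

#' @export
print.plate_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<plate_image> %s  %s/%s/%s  %d x %d px\n",
              x$plate_id, x$assay, x$modality, x$condition, d[1], d[2]))
  invisible(x)
}

#' @export
dim.plate_image <- function(x) dim(x$pixels)[1:2]

#' Read a plate photograph from PNG or TIFF
#'
#' 8-bit RGB (or RGBA; the alpha channel is dropped) images are supported.
#'
#' @param path file path ending in `.png`, `.tif` or `.tiff`.
#' @inheritParams plate_image
#' @return A [plate_image].
#' @export
read_plate_image <- function(path, modality = "VIS", assay = "salt",
                             condition = "stress",
                             plate_id = sub("\\.[^.]+$", "", basename(path))) {
  ext <- tolower(sub(".*\\.", "", path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(raw)) == 2L) raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  px <- round(raw * 255)
  plate_image(px, modality = modality, assay = assay, condition = condition,
              plate_id = plate_id)
}

#' Write a binary mask as a black-and-white PNG for visual inspection
#'
#' @param mask logical matrix (foreground `TRUE`).
#' @param path output `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' RGB to HSB conversion on the 8-bit scale
#'
#' Standard RGB to hue/saturation/brightness conversion with all three
#' channels rescaled to integers in `[0, 255]` (the 8-bit imaging
#' convention; every hue or saturation threshold in the assay configs is
#' expressed on this scale). The hue of achromatic pixels (saturation 0)
#' is defined as 0, so the conversion is a total function.
#'
#' @param image a [plate_image], or an `H x W x 3` array in `[0, 255]`.
#' @return A list with integer matrices `H`, `S` and `Bri`.
#' @export
rgb_to_hsb <- function(image) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  r <- chan(px, 1); g <- chan(px, 2); b <- chan(px, 3)
  v <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  c_ <- v - mn
  s <- ifelse(v == 0, 0, round(255 * c_ / v))
  # hue in degrees, then rescaled to [0, 255]
  h <- matrix(0, nrow(r), ncol(r))
  nz <- c_ > 0
  hr <- nz & v == r
  hg <- nz & v == g & !hr
  hb <- nz & v == b & !hr & !hg
  h[hr] <- (60 * ((g[hr] - b[hr]) / c_[hr])) %% 360
  h[hg] <- 60 * (2 + (b[hg] - r[hg]) / c_[hg])
  h[hb] <- 60 * (4 + (r[hb] - g[hb]) / c_[hb])
  h <- round(h * 255 / 360) %% 256L
  lapply(list(H = h, S = s, Bri = v), function(m) {
    storage.mode(m) <- "integer"
    m
  })
}

#' HSB (8-bit scale) to RGB conversion
#'
#' Inverse of [rgb_to_hsb()]; used by the synthetic-plate renderer to turn
#' sampled hue/saturation/brightness values into RGB pixels.
#'
#' @param h,s,v numeric vectors in `[0, 255]`.
#' @return A 3-column integer matrix with columns R, G, B.
#' @export
hsb_to_rgb <- function(h, s, v) {
  hd <- (h * 360 / 255) %% 360
  sf <- s / 255
  vf <- v / 255
  c_ <- vf * sf
  hp <- hd / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- vf - c_
  sector <- pmin(floor(hp), 5)
  # per-sector (R, G, B) assembly from chroma C, intermediate X and 0
  perm <- list(c(2, 3, 1), c(3, 2, 1), c(1, 2, 3), c(1, 3, 2),
               c(3, 1, 2), c(2, 1, 3))  # index into cbind(0, C, X)
  out <- matrix(0, length(hd), 3)
  vals <- cbind(0, c_, x)
  for (sec in 0:5) {
    idx <- which(sector == sec)
    if (!length(idx)) next
    sel <- perm[[sec + 1L]]
    out[idx, ] <- vals[idx, sel, drop = FALSE]
  }
  rgb <- round(255 * (out + m))
  storage.mode(rgb) <- "integer"
  colnames(rgb) <- c("R", "G", "B")
  rgb
}

#' Grayscale transformation
#'
#' Converts an RGB plate image to a single intensity raster in `[0, 255]`.
#' The default is the unweighted channel mean; Rec. 601 luma weights are
#' available via `method = "luma"`.
#'
#' @inheritParams rgb_to_hsb
#' @param method `"mean"` (default) or `"luma"`.
#' @return Integer matrix of rounded intensities.
#' @export
to_gray <- function(image, method = c("mean", "luma")) {
  method <- match.arg(method)
  px <- if (inherits(image, "plate_image")) image$pixels else image
  w <- if (method == "mean") c(1, 1, 1) / 3 else c(0.299, 0.587, 0.114)
  g <- round(chan(px, 1) * w[1] + chan(px, 2) * w[2] + chan(px, 3) * w[3])
  storage.mode(g) <- "integer"
  g
}
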