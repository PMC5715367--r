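#' Rule-based foreground masks
#'
#' Each assay tags foreground pixels with a small conjunction of per-pixel
#' threshold clauses on raw or derived channels. A rule is an ordered list
#' of clauses combined by logical AND; a clause compares one channel
#' against a constant (`<` or `>`, both strict, exactly as the thresholds
#' are written in the assay configs) or tests membership in a union of
#' closed intervals (`"in"`).
#'
#' Available channels: `R`, `G`, `B` (raw), `H`, `S`, `Bri` (8-bit HSB,
#' computed internally via [rgb_to_hsb()]), `gray` (via [to_gray()]) and
#' `normdiff_RB`, the normalised red-blue difference `(R - B) / (R + B)`
#' in `[-1, 1]` (0 where `R + B = 0`) used by the freezing assay, where
#' healthy tissue reflects far more red than blue light.
#'
#' @param channel channel selector (see Details).
#' @param op `"<"`, `">"` or `"in"`.
#' @param value a single constant for `"<"`/`">"`; for `"in"`, a list of
#'   `c(lo, hi)` closed intervals whose union defines the kept band.
#' @return `pixel_clause()` returns one clause; `pixel_rule(...)` bundles
#'   clauses into a `pixel_rule` object.
#' @examples
#' # the freezing-assay foreground rule
#' pixel_rule(pixel_clause("B", "<", 127),
#'            pixel_clause("normdiff_RB", ">", 0.20))
#' @export
pixel_clause <- function(channel, op, value) {
  channels <- c("R", "G", "B", "H", "S", "Bri", "gray", "normdiff_RB")
  if (!channel %in% channels)
    stop("unknown channel in pixel rule: ", channel)
  if (!op %in% c("<", ">", "in"))
    stop("unknown comparator in pixel rule: ", op)
  rng <- if (channel == "normdiff_RB") c(-1, 1) else c(0, 255)
  vals <- unlist(value)
  if (any(vals < rng[1]) || any(vals > rng[2]))
    stop(sprintf("constant out of range [%g, %g] for channel %s",
                 rng[1], rng[2], channel))
  if (op == "in") {
    if (!is.list(value)) value <- list(value)
    bad <- vapply(value, function(iv) length(iv) != 2L || iv[1] > iv[2],
                  logical(1))
    if (any(bad)) stop("'in' clause intervals must be c(lo, hi) with lo <= hi")
  } else if (length(vals) != 1L) {
    stop("'<' and '>' clauses take a single constant")
  }
  structure(list(channel = channel, op = op, value = value),
            class = "pixel_clause")
}

#' @rdname pixel_clause
#' @param ... `pixel_clause` objects.
#' @export
pixel_rule <- function(...) {
  clauses <- list(...)
  if (length(clauses) == 1L && is.list(clauses[[1]]) &&
      !inherits(clauses[[1]], "pixel_clause"))
    clauses <- clauses[[1]]
  if (!length(clauses)) stop("a pixel rule needs at least one clause")
  ok <- vapply(clauses, inherits, logical(1), "pixel_clause")
  if (!all(ok)) stop("all arguments must be pixel_clause objects")
  structure(list(clauses = clauses), class = "pixel_rule")
}

#' @export
print.pixel_rule <- function(x, ...) {
  fmt <- vapply(x$clauses, function(cl) {
    if (cl$op == "in") {
      ivs <- vapply(cl$value, function(iv) sprintf("[%g,%g]", iv[1], iv[2]),
                    character(1))
      sprintf("%s in %s", cl$channel, paste(ivs, collapse = " U "))
    } else sprintf("%s %s %g", cl$channel, cl$op, cl$value)
  }, character(1))
  cat("<pixel_rule> ", paste(fmt, collapse = "  AND  "), "\n", sep = "")
  invisible(x)
}

channel_raster <- function(image, channel, hsb = NULL, gray = NULL) {
  px <- if (inherits(image, "plate_image")) image$pixels else image
  switch(channel,
    R = chan(px, 1), G = chan(px, 2), B = chan(px, 3),
    H = (hsb %||% rgb_to_hsb(px))$H,
    S = (hsb %||% rgb_to_hsb(px))$S,
    Bri = (hsb %||% rgb_to_hsb(px))$Bri,
    gray = gray %||% to_gray(px),
    normdiff_RB = {
      r <- chan(px, 1); b <- chan(px, 3)
      den <- r + b
      ifelse(den == 0, 0, (r - b) / den)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply a pixel rule to a plate image
#'
#' Returns the binary mask of pixels satisfying every clause of the rule.
#' Derived channels (HSB, gray, normalised red-blue difference) are
#' computed internally as needed. All `<`/`>` comparisons are strict;
#' `"in"` intervals are closed at both endpoints.
#'
#' @inheritParams rgb_to_hsb
#' @param rule a [pixel_rule()].
#' @return Logical matrix (`TRUE` = foreground) with a `"provenance"`
#'   attribute describing the rule.
#' @export
apply_pixel_rule <- function(image, rule) {
  if (!inherits(rule, "pixel_rule")) stop("`rule` must be a pixel_rule")
  px <- if (inherits(image, "plate_image")) image$pixels else image
  needs_hsb <- any(vapply(rule$clauses, function(cl)
    cl$channel %in% c("H", "S", "Bri"), logical(1)))
  hsb <- if (needs_hsb) rgb_to_hsb(px) else NULL
  mask <- NULL
  for (cl in rule$clauses) {
    ch <- channel_raster(px, cl$channel, hsb = hsb)
    m <- switch(cl$op,
      `<` = ch < cl$value,
      `>` = ch > cl$value,
      `in` = {
        acc <- matrix(FALSE, nrow(ch), ncol(ch))
        for (iv in cl$value) acc <- acc | (ch >= iv[1] & ch <= iv[2])
        acc
      })
    mask <- if (is.null(mask)) m else mask & m
  }
  attr(mask, "provenance") <- format_rule(rule)
  mask
}

format_rule <- function(rule) {
  paste(vapply(rule$clauses, function(cl) {
    if (cl$op == "in") {
      ivs <- vapply(cl$value, function(iv) sprintf("[%g,%g]", iv[1], iv[2]),
                    character(1))
      sprintf("%s in %s", cl$channel, paste(ivs, collapse = "U"))
    } else sprintf("%s%s%g", cl$channel, cl$op, cl$value)
  }, character(1)), collapse = " & ")
}

#' Built-in foreground rules for each assay
#'
#' The per-assay, per-modality pixel rules with their default thresholds:
#'
#' * salt VIS: `S > 49` (stress; `S > 74` under standard growth) AND
#'   gray in `[0,140] U [150,255]` (a narrow mid-gray band belonging to
#'   the plate grid is excluded);
#' * salt FLUO: `S > 20`;
#' * arsenic VIS: `R < 254 & G < 246 & B < 254` (backlit near-white
#'   background);
#' * arsenic FLUO: `S > 50`;
#' * freezing VIS: `B < 127 & (R - B)/(R + B) > 0.20`;
#' * phosphate shoot (VIS): `23 < Bri < 138`. (The phosphate root mask
#'   uses local-mean thresholding of the grayscale image instead of a
#'   pixel rule; see [local_mean_threshold()].)
#'
#' @param assay assay id.
#' @param modality `"VIS"` or `"FLUO"`.
#' @param condition `"stress"` or `"standard"`; only the salt VIS
#'   saturation threshold differs between conditions.
#' @param part `"whole"` (default) or `"shoot"` (phosphate only).
#' @return A [pixel_rule()].
#' @export
default_pixel_rule <- function(assay, modality = "VIS",
                               condition = "stress", part = "whole") {
  key <- paste(assay, modality, sep = "/")
  switch(key,
    "salt/VIS" = pixel_rule(
      pixel_clause("S", ">", if (condition == "standard") 74 else 49),
      pixel_clause("gray", "in", list(c(0, 140), c(150, 255)))),
    "salt/FLUO" = pixel_rule(pixel_clause("S", ">", 20)),
    "arsenic/VIS" = pixel_rule(
      pixel_clause("R", "<", 254),
      pixel_clause("G", "<", 246),
      pixel_clause("B", "<", 254)),
    "arsenic/FLUO" = pixel_rule(pixel_clause("S", ">", 50)),
    "freezing/VIS" = pixel_rule(
      pixel_clause("B", "<", 127),
      pixel_clause("normdiff_RB", ">", 0.20)),
    "phosphate/VIS" = if (part == "shoot") pixel_rule(
      pixel_clause("Bri", ">", 23),
      pixel_clause("Bri", "<", 138))
    else stop("the phosphate root mask uses local_mean_threshold(), ",
              "not a pixel rule"),
    stop("no default rule for ", key))
}
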