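#' Assay configuration
#'
#' Bundles every constant one assay pipeline needs: the foreground pixel
#' rules per modality, the object filter specs, the number of hue
#' classes, clustering settings, the line-vs-wild-type test, and the
#' experimental design. Defaults reproduce the screen's constants:
#'
#' | assay     | VIS filter                               | FLUO filter | K  | test   | design      |
#' |-----------|------------------------------------------|-------------|----|--------|-------------|
#' | salt      | area>40, dist<130                        | area>20     | 16 | fisher | 36 x 3 reps |
#' | arsenic   | area>10, circ>0.099, dist<130            | area>20     | 16 | fisher | 36 x 3 reps |
#' | freezing  | 10000<area<40000                         | (none)      | 32 | fisher | 60 x 3 reps |
#' | phosphate | root: area>109, circ<0.70, dist<145; shoot: area>10, circ>0.099, dist<130 | (none) | - | anova | 6 x 2 reps |
#'
#' Phosphate-specific extras: local-mean threshold radius 15 px with an
#' intensity offset of 10 (the named algorithm's window size and the
#' camera noise floor; both configurable), grid-line removal constants
#' (horizontal runs > 50 px, vertical runs > 240 px, 1 px erosion,
#' border bands 50-260 and 1698-1798) and the major axis of the merged
#' plant as root-length proxy. Freezing-specific extras: 32 hue classes
#' and yellow damage bins `0:4` (hue < 40).
#'
#' @param assay assay id.
#' @param condition `"stress"` (default) or `"standard"`; only the salt
#'   VIS saturation threshold differs between the two (49 vs 74).
#' @param overrides named list merged over the defaults (nested lists
#'   merge recursively); unknown keys are an error.
#' @return A list of class `assay_config`.
#' @export
assay_config <- function(assay = c("salt", "arsenic", "freezing", "phosphate"),
                         condition = c("stress", "standard"),
                         overrides = list()) {
  assay <- match.arg(assay)
  condition <- match.arg(condition)
  base <- switch(assay,
    salt = list(
      vis_rule = default_pixel_rule("salt", "VIS", condition),
      fluo_rule = default_pixel_rule("salt", "FLUO", condition),
      vis_filter = object_filter_spec(min_area = 40,
                                      max_dist_to_center = 130),
      fluo_filter = object_filter_spec(min_area = 20),
      K = 16, test = "fisher",
      group_labels = c("alive", "dead"),
      seeds_per_plate = 36, replicates = 3),
    arsenic = list(
      vis_rule = default_pixel_rule("arsenic", "VIS", condition),
      fluo_rule = default_pixel_rule("arsenic", "FLUO", condition),
      vis_filter = object_filter_spec(min_area = 10, circ_min = 0.099,
                                      max_dist_to_center = 130),
      fluo_filter = object_filter_spec(min_area = 20),
      K = 16, test = "fisher",
      group_labels = c("germinated", "seed"),
      seeds_per_plate = 36, replicates = 3),
    freezing = list(
      vis_rule = default_pixel_rule("freezing", "VIS", condition),
      vis_filter = object_filter_spec(min_area = 10000, max_area = 40000),
      K = 32, yellow_classes = 0:4, test = "fisher",
      group_labels = c("undamaged", "damaged"),
      seeds_per_plate = 60, replicates = 3),
    phosphate = list(
      shoot_rule = default_pixel_rule("phosphate", "VIS", condition,
                                      part = "shoot"),
      threshold_radius = 15, threshold_offset = 10,
      max_h_run = 50, max_v_run = 240, erode_px = 1,
      excluded_row_bands = list(c(50, 260), c(1698, 1798)),
      root_filter = object_filter_spec(min_area = 109, circ_max = 0.70,
                                       max_dist_to_center = 145),
      shoot_filter = object_filter_spec(min_area = 10, circ_min = 0.099,
                                        max_dist_to_center = 130),
      test = "anova",
      seeds_per_plate = 6, replicates = 2))
  base$assay <- assay
  base$condition <- condition
  base$linkage <- "average"
  cfg <- merge_config(base, overrides)
  class(cfg) <- "assay_config"
  cfg
}

merge_config <- function(base, overrides) {
  for (key in names(overrides)) {
    if (!key %in% names(base))
      stop("unknown configuration key: ", key)
    if (is.list(base[[key]]) && is.list(overrides[[key]]) &&
        !inherits(base[[key]], c("pixel_rule", "object_filter_spec")) &&
        !is.null(names(overrides[[key]])))
      base[[key]] <- merge_config(base[[key]], overrides[[key]])
    else base[[key]] <- overrides[[key]]
  }
  base
}
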