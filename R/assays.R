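# The four end-to-end assay pipelines: plate image(s) + layout -> one
# record per detected seedling. Records are plain wide data frames (one
# column per feature / hue class) so they round-trip through CSV.

empty_profile <- function(K, prefix) {
  setNames(rep(0, K), sprintf("%s_hue_%02d", prefix, 0:(K - 1)))
}

seedling_record <- function(plate_id, assay, condition, replicate, line_id,
                            cell, morpho, vis_profile = NULL,
                            fluo_profile = NULL, detected_vis = NA,
                            detected_fluo = NA, damage = NULL,
                            centroid = c(NA, NA)) {
  base <- data.frame(plate_id = plate_id, assay = assay,
                     condition = condition, replicate = replicate,
                     line_id = line_id, cell = cell,
                     detected_vis = detected_vis,
                     detected_fluo = detected_fluo,
                     centroid_x = centroid[1], centroid_y = centroid[2])
  m <- morpho[, setdiff(names(morpho), "degenerate"), drop = FALSE]
  base <- cbind(base, m, degenerate = morpho$degenerate)
  if (!is.null(damage)) {
    base$damage_fraction <- damage$fraction
    base$damaged <- damage$damaged
  }
  if (!is.null(vis_profile)) base <- cbind(base, as.list(vis_profile))
  if (!is.null(fluo_profile)) base <- cbind(base, as.list(fluo_profile))
  base
}

# shared two-modality (VIS + FLUO) pipeline used by salt and arsenic
run_two_modality_plate <- function(vis, fluo, layout, config, replicate) {
  if (is.null(vis) || is.null(fluo))
    stop("the ", config$assay, " assay needs both VIS and FLUO images")
  stopifnot(inherits(vis, "plate_image"), inherits(fluo, "plate_image"))
  K <- config$K
  vis_hsb <- rgb_to_hsb(vis)
  fluo_hsb <- rgb_to_hsb(fluo)
  vis_gray <- to_gray(vis)
  fluo_gray <- to_gray(fluo)

  vis_lc <- filter_objects(label_components(apply_pixel_rule(vis,
                                                             config$vis_rule)),
                           config$vis_filter, layout)
  fluo_lc <- filter_objects(label_components(apply_pixel_rule(fluo,
                                                              config$fluo_rule)),
                            config$fluo_filter, layout)
  vis_plants <- select_largest_per_cell(vis_lc, layout, vis$plate_id)
  fluo_plants <- if (nrow(fluo_lc$summary))
    select_largest_per_cell(fluo_lc, layout, fluo$plate_id)
  else list()

  cells <- sort(unique(as.integer(c(names(vis_plants), names(fluo_plants)))))
  rows <- lapply(cells, function(cell) {
    vp <- vis_plants[[as.character(cell)]]
    fp <- fluo_plants[[as.character(cell)]]
    anchor <- vp %||% fp
    gray <- if (!is.null(vp)) vis_gray else fluo_gray
    morpho <- compute_morphology(anchor, gray)
    vprof <- if (!is.null(vp))
      setNames(hue_class_histogram(vp, vis_hsb, K), names(empty_profile(K, "vis")))
    else empty_profile(K, "vis")
    fprof <- if (!is.null(fp))
      setNames(hue_class_histogram(fp, fluo_hsb, K), names(empty_profile(K, "fluo")))
    else empty_profile(K, "fluo")
    seedling_record(vis$plate_id, config$assay, config$condition, replicate,
                    anchor$line_id, cell, morpho,
                    vis_profile = vprof, fluo_profile = fprof,
                    detected_vis = !is.null(vp),
                    detected_fluo = !is.null(fp),
                    centroid = anchor$centroid)
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the salt assay pipeline on one plate
#'
#' VIS foreground = high-saturation pixels (S > 49 under stress, S > 74
#' under standard growth) whose gray value avoids the plate-grid band
#' (141-149); FLUO foreground = S > 20. Objects are labeled, filtered
#' (VIS: area > 40 px, centroid distance < 130 px to the cell centre;
#' FLUO: area > 20 px) and reduced to the largest object per grid cell,
#' so each seedling is represented by one object. Each record joins the
#' 16-class VIS hue profile with the 16-class FLUO profile (a modality in
#' which the seedling was not detected is zero-filled and flagged).
#'
#' @param vis,fluo [plate_image()]s of the same plate in both modalities.
#' @param layout the [plate_layout()] shared by both images.
#' @param config an [assay_config()] (defaults: `assay_config("salt")`).
#' @param replicate replicate index carried into the records.
#' @return Data frame with one row per detected seedling.
#' @export
run_salt_plate <- function(vis, fluo, layout, config = assay_config("salt"),
                           replicate = NA_integer_) {
  run_two_modality_plate(vis, fluo, layout, config, replicate)
}

#' Run the arsenic assay pipeline on one plate
#'
#' VIS foreground excludes the backlit near-white background
#' (`R < 254 & G < 246 & B < 254`); objects are kept with area > 10 px,
#' circularity > 0.099 and distance < 130 px, so both brown seeds
#' (non-germinated) and green seedlings are retained. FLUO foreground is
#' `S > 50`, filter area > 20 px. Germination is resolved downstream by
#' [two_group_color_clustering()] of the joined hue profiles.
#'
#' @inheritParams run_salt_plate
#' @return Data frame with one row per detected object (seed or
#'   seedling).
#' @export
run_arsenic_plate <- function(vis, fluo, layout,
                              config = assay_config("arsenic"),
                              replicate = NA_integer_) {
  run_two_modality_plate(vis, fluo, layout, config, replicate)
}

#' Run the freezing assay pipeline on one plate
#'
#' VIS-only. Foreground = `B < 127` and normalised red-blue difference
#' `(R-B)/(R+B) > 0.20`; only objects with area strictly between 10,000
#' and 40,000 px count as seedlings (round plates, no grid cells). Each
#' record carries the 32-class hue profile and the yellowish damage
#' fraction with its `damaged` call (fraction > 0.5).
#'
#' @inheritParams run_salt_plate
#' @param vis the VIS [plate_image()].
#' @return Data frame with one row per detected seedling.
#' @export
run_freezing_plate <- function(vis, layout, config = assay_config("freezing"),
                               replicate = NA_integer_) {
  stopifnot(inherits(vis, "plate_image"))
  hsb <- rgb_to_hsb(vis)
  gray <- to_gray(vis)
  lc <- filter_objects(label_components(apply_pixel_rule(vis,
                                                         config$vis_rule)),
                       config$vis_filter, layout)
  s <- lc$summary
  line_id <- layout$cell_to_line[1]
  rows <- lapply(seq_len(nrow(s)), function(i) {
    plant <- digital_plant(component_coords(lc, s$label[i]),
                           cell = NA_integer_, line_id = line_id,
                           plate_id = vis$plate_id)
    morpho <- compute_morphology(plant, gray)
    prof <- setNames(hue_class_histogram(plant, hsb, config$K),
                     names(empty_profile(config$K, "vis")))
    dmg <- yellow_damage_fraction(plant, hsb, classes = config$yellow_classes,
                                  K = config$K)
    seedling_record(vis$plate_id, config$assay, config$condition, replicate,
                    line_id, NA_integer_, morpho, vis_profile = prof,
                    detected_vis = TRUE, damage = dmg,
                    centroid = plant$centroid)
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Run the phosphate-limitation assay pipeline on one plate
#'
#' VIS-only, vertical plates, backlit. The grayscale image is thresholded
#' with the local-mean algorithm, embossed grid lines are removed
#' (horizontal runs > 50 px, vertical runs > 240 px, 1 px erosion,
#' top/bottom border bands cleared), and the remaining dark objects are
#' filtered to root candidates (area > 109 px, circularity < 0.70,
#' distance < 145 px). The shoot mask keeps pixels with HSB brightness
#' strictly between 23 and 138, filtered to shoot candidates
#' (area > 10 px, circularity > 0.099, distance < 130 px). Shoots and
#' roots are merged per grid column ([merge_shoot_root()]); the record's
#' root-length proxy is the major axis of the merged digital plant.
#'
#' @inheritParams run_freezing_plate
#' @return Data frame with one row per detected plant.
#' @export
run_phosphate_plate <- function(vis, layout,
                                config = assay_config("phosphate"),
                                replicate = NA_integer_) {
  stopifnot(inherits(vis, "plate_image"))
  gray <- to_gray(vis)
  H <- nrow(gray)
  bands <- config$excluded_row_bands
  if (any(vapply(bands, function(b) b[2] >= H, logical(1))))
    warning("image height below the excluded border bands; bands clipped")
  root_mask <- local_mean_threshold(gray, config$threshold_radius,
                                    config$threshold_offset)
  root_mask <- remove_grid_artifacts(root_mask, config$max_h_run,
                                     config$max_v_run, config$erode_px,
                                     bands)
  shoot_mask <- apply_pixel_rule(vis, config$shoot_rule)
  # the dark shoot also falls below the local-mean threshold; removing
  # shoot-mask pixels from the root mask keeps each root a separate
  # object anchored just below its shoot instead of fusing with it
  roots <- filter_objects(label_components(root_mask & !shoot_mask),
                          config$root_filter, layout)
  shoots <- filter_objects(label_components(shoot_mask),
                           config$shoot_filter, layout)
  plants <- merge_shoot_root(shoots, roots, layout, vis$plate_id)
  rows <- lapply(plants, function(p) {
    morpho <- compute_morphology(p, gray)
    rec <- seedling_record(vis$plate_id, config$assay, config$condition,
                           replicate, p$line_id, p$cell, morpho,
                           detected_vis = TRUE, centroid = p$centroid)
    rec$has_root <- !is.null(p$parts$root)
    rec
  })
  if (!length(rows)) return(NULL)
  do.call(rbind, rows)
}

#' Write seedling records to CSV
#'
#' @param records data frame from the `run_*_plate` functions.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(records, path) {
  write.csv(records, path, row.names = FALSE)
  invisible(path)
}
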